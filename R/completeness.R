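#' Default resonance inventories for assignment-completeness accounting
#'
#' `backbone_inventory()` returns the atom names counted as backbone
#' resonances per residue: N, amide H, CA, CB and C' — glycine has no CB and
#' proline contributes no amide H (its nitrogen still counts). What counts as
#' a "potential" resonance is a bookkeeping convention, so both inventories
#' are plain R objects the caller can replace.
#'
#' `sidechain_inventory()` returns, per residue type (1-letter code), the
#' side-chain atom names counted as potential resonances: aliphatic and
#' aromatic carbons and their attached protons (one entry per methyl group,
#' two per diastereotopic methylene pair), plus side-chain nitrogens with
#' observable protons. Hydroxyl and thiol protons are excluded (exchange
#' broadened in aqueous samples).
#'
#' @return `backbone_inventory()`: character vector of backbone atom names.
#'   `sidechain_inventory()`: named list, one character vector per 1-letter
#'   residue code.
#' @export
backbone_inventory <- function() c("N", "H", "CA", "CB", "C")

#' @rdname backbone_inventory
#' @export
sidechain_inventory <- function() {
  list(
    A = c("HB"),
    R = c("HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3", "NE", "HE", "CZ"),
    N = c("HB2", "HB3", "CG", "ND2", "HD21", "HD22"),
    D = c("HB2", "HB3", "CG"),
    C = c("HB2", "HB3"),
    Q = c("HB2", "HB3", "CG", "HG2", "HG3", "CD", "NE2", "HE21", "HE22"),
    E = c("HB2", "HB3", "CG", "HG2", "HG3", "CD"),
    G = character(),
    H = c("HB2", "HB3", "CG", "ND1", "CD2", "HD2", "CE1", "HE1", "NE2"),
    I = c("HB", "CG1", "HG12", "HG13", "CG2", "HG2", "CD1", "HD1"),
    L = c("HB2", "HB3", "CG", "HG", "CD1", "HD1", "CD2", "HD2"),
    K = c("HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3", "CE", "HE2",
          "HE3", "NZ"),
    M = c("HB2", "HB3", "CG", "HG2", "HG3", "CE", "HE"),
    F = c("HB2", "HB3", "CG", "CD1", "HD1", "CD2", "HD2", "CE1", "HE1",
          "CE2", "HE2", "CZ", "HZ"),
    P = c("HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3"),
    S = c("HB2", "HB3"),
    T = c("HB", "CG2", "HG2"),
    W = c("HB2", "HB3", "CG", "CD1", "HD1", "CD2", "NE1", "HE1", "CE2",
          "CE3", "HE3", "CZ2", "HZ2", "CZ3", "HZ3", "CH2", "HH2"),
    Y = c("HB2", "HB3", "CG", "CD1", "HD1", "CD2", "HD2", "CE1", "HE1",
          "CE2", "HE2", "CZ"),
    V = c("HB", "CG1", "HG1", "CG2", "HG2")
  )
}

#' Assignment completeness of a chemical-shift list
#'
#' Fraction of potential backbone and side-chain resonances that carry an
#' assigned shift, the statistic conventionally quoted for an NMR structure
#' (e.g. "97% backbone / 87% side chain"). Prolines are disregarded in the
#' amide count; an initial stretch of tag residues can be excluded entirely
#' via `n_term_ignore`. The potential-atom inventory is table-driven: pass
#' your own `backbone_atoms`/`sidechain_table` to change the convention.
#'
#' @param shifts `data.frame` with columns `residue` and `atom` (e.g. from
#'   [read_nmrstar_shifts()]); `HN` is treated as `H`.
#' @param sequence Protein sequence as a 1-letter string; residue `i` of the
#'   shift list is `substr(sequence, i, i)`.
#' @param n_term_ignore Number of leading residues excluded from both
#'   denominators (default 0).
#' @param backbone_atoms Backbone inventory; default [backbone_inventory()].
#' @param sidechain_table Side-chain inventory; default
#'   [sidechain_inventory()].
#' @return List with `backbone_fraction`, `sidechain_fraction`, and the four
#'   underlying counts. Empty shift list gives fractions of 0.
#' @export
assignment_completeness <- function(shifts, sequence, n_term_ignore = 0L,
                                    backbone_atoms = backbone_inventory(),
                                    sidechain_table = sidechain_inventory()) {
  stopifnot(n_term_ignore >= 0L)
  seq_chars <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(seq_chars)
  if (nrow(shifts) && any(shifts$residue < 1L | shifts$residue > n)) {
    bad <- shifts$residue[shifts$residue < 1L | shifts$residue > n]
    stop("shift residue number(s) outside sequence: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  use <- setdiff(seq_len(n), seq_len(n_term_ignore))

  potential_bb <- 0L
  potential_sc <- 0L
  bb_sets <- vector("list", n)
  for (i in use) {
    aa <- seq_chars[i]
    bb <- backbone_atoms
    if (aa == "G") bb <- setdiff(bb, "CB")
    if (aa == "P") bb <- setdiff(bb, "H")
    bb_sets[[i]] <- bb
    potential_bb <- potential_bb + length(bb)
    sc <- sidechain_table[[aa]]
    potential_sc <- potential_sc + length(sc)
  }

  assigned_bb <- 0L
  assigned_sc <- 0L
  if (nrow(shifts)) {
    atom <- ifelse(shifts$atom == "HN", "H", shifts$atom)
    key <- paste(shifts$residue, atom)
    keep <- !duplicated(key) & shifts$residue %in% use
    for (k in which(keep)) {
      i <- shifts$residue[k]
      aa <- seq_chars[i]
      if (atom[k] %in% bb_sets[[i]]) {
        assigned_bb <- assigned_bb + 1L
      } else if (atom[k] %in% sidechain_table[[aa]]) {
        assigned_sc <- assigned_sc + 1L
      }
    }
  }

  list(
    backbone_fraction = if (potential_bb > 0L) assigned_bb / potential_bb else 0,
    sidechain_fraction = if (potential_sc > 0L) assigned_sc / potential_sc else 0,
    assigned_backbone = assigned_bb, potential_backbone = potential_bb,
    assigned_sidechain = assigned_sc, potential_sidechain = potential_sc
  )
}
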