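#' @importFrom stats coef median nls predict qnorm rnorm runif sd setNames
#' @importFrom utils head modifyList read.delim write.table
NULL

# Elements with a van der Waals radius in the shipped table; see sasa.R.

.element_from_name <- function(atom_name) {
  # PDB atom-name heuristic: columns 13-16; a leading digit (e.g. "1HB1")
  # or a name starting in column 14 means the element is the first letter.
  nm <- gsub("[0-9']", "", trimws(atom_name))
  if (nchar(nm) == 0L) return(NA_character_)
  two <- toupper(substr(nm, 1L, 2L))
  # two-letter elements only when the raw name occupies column 13
  if (two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA", "SE") &&
      !grepl("^ ", atom_name) && nchar(trimws(atom_name)) > 1L &&
      substr(atom_name, 1L, 1L) != " ") {
    return(substr(two, 1L, 1L) %+% tolower(substr(two, 2L, 2L)))
  }
  toupper(substr(nm, 1L, 1L))
}

`%+%` <- function(a, b) paste0(a, b)

#' Read a protein structure from PDB-format text
#'
#' Parses fixed-column `ATOM` (and optionally `HETATM`) records into an atom
#' table. Only the first `MODEL` of a multi-model file is kept, matching the
#' single-conformer convention used for surface and geometry calculations.
#' Alternate locations are reduced to a single conformer by keeping the
#' highest-occupancy altloc (ties broken by first occurrence). The element is
#' taken from columns 77-78 when present, otherwise inferred from the atom
#' name. Author residue numbering is preserved verbatim.
#'
#' @param file Path to a PDB file, or a character vector of PDB lines via
#'   `text`.
#' @param text Optional character scalar/vector of PDB text (overrides
#'   `file`).
#' @param keep_hetatm Keep `HETATM` records (default `FALSE`).
#' @param keep_water Keep water residues (HOH/WAT/DOD); default `FALSE`.
#' @return An object of class `pdb_structure`: a `data.frame` with columns
#'   `serial`, `name`, `altloc`, `resname`, `chain`, `resno`, `x`, `y`, `z`,
#'   `occupancy`, `element`, plus attributes `chains` and `source_id`.
#' @examples
#' txt <- c("ATOM      1  CA  ALA A   1      11.000  12.000  13.000  1.00  0.00           C")
#' s <- read_pdb(text = txt)
#' nrow(s)
#' @export
read_pdb <- function(file = NULL, text = NULL, keep_hetatm = FALSE,
                     keep_water = FALSE) {
  if (is.null(text)) {
    stopifnot(is.character(file), length(file) == 1L)
    lines <- readLines(file, warn = FALSE)
    src <- basename(file)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
    src <- "text"
  }

  # first MODEL only
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    end1 <- grep("^ENDMDL", lines)
    end1 <- if (length(end1)) end1[1L] else length(lines)
    lines <- lines[seq_len(end1)]
  }

  rec <- substr(lines, 1L, 6L)
  want <- rec == "ATOM  " | (keep_hetatm & rec == "HETATM")
  idx <- which(want)
  if (!length(idx)) stop("no ATOM records found: empty structure", call. = FALSE)

  bad <- idx[nchar(lines[idx]) < 54L]
  if (length(bad)) {
    stop(sprintf("malformed fixed-column ATOM record at line %d (needs >= 54 columns)",
                 bad[1L]), call. = FALSE)
  }
  ln <- lines[idx]
  fld <- function(a, b) substr(ln, a, b)
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(fld(a, b)))
    if (anyNA(v)) {
      stop(sprintf("malformed fixed-column ATOM record at line %d (bad %s field)",
                   idx[which(is.na(v))[1L]], what), call. = FALSE)
    }
    v
  }
  occ_raw <- suppressWarnings(as.numeric(fld(55, 60)))
  occ_raw[is.na(occ_raw)] <- 1.0
  elem <- toupper(trimws(fld(77, 78)))
  name <- fld(13, 16)
  need <- elem == "" | is.na(elem)
  if (any(need)) elem[need] <- vapply(name[need], .element_from_name, "")

  atoms <- data.frame(
    serial   = as.integer(num(7, 11, "serial")),
    name     = trimws(name),
    altloc   = trimws(fld(17, 17)),
    resname  = trimws(fld(18, 20)),
    chain    = fld(22, 22),
    resno    = as.integer(num(23, 26, "residue number")),
    x        = num(31, 38, "x"),
    y        = num(39, 46, "y"),
    z        = num(47, 54, "z"),
    occupancy = occ_raw,
    element  = elem,
    stringsAsFactors = FALSE
  )

  if (!keep_water) {
    atoms <- atoms[!atoms$resname %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
    if (!nrow(atoms)) stop("no ATOM records found: empty structure", call. = FALSE)
  }

  # altloc: keep highest occupancy per (chain, resno, atom name); first wins ties
  if (any(atoms$altloc != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "\r")
    ord <- order(factor(key, levels = unique(key)), -atoms$occupancy,
                 seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$name,
                                     sep = "\r")), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }

  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) records after altloc reduction",
         call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in ATOM records", call. = FALSE)
  }
  rownames(atoms) <- NULL
  new_structure(atoms, source_id = src)
}

#' Construct a `pdb_structure` from an atom table
#'
#' @param atoms `data.frame` with at least `name`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z`, `element`; `serial`, `altloc` and `occupancy`
#'   are filled with defaults when absent.
#' @param source_id Free-text provenance label.
#' @return A `pdb_structure`.
#' @export
new_structure <- function(atoms, source_id = "constructed") {
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1.0
  atoms <- atoms[, c("serial", "name", "altloc", "resname", "chain", "resno",
                     "x", "y", "z", "occupancy", "element")]
  structure(atoms,
            chains = sort(unique(atoms$chain)),
            source_id = source_id,
            class = c("pdb_structure", "data.frame"))
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure> %d atoms, %d chain(s) [%s], source: %s\n",
              nrow(x), length(attr(x, "chains")),
              paste(attr(x, "chains"), collapse = ","),
              attr(x, "source_id")))
  invisible(x)
}

#' Write a structure as PDB-format text
#'
#' Coordinates are written with three decimals in the standard fixed columns,
#' so `read_pdb(write_pdb(x))` round-trips coordinates and atom order.
#'
#' @param structure A `pdb_structure`.
#' @param file Optional output path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `file` is `NULL`), the PDB lines.
#' @export
write_pdb <- function(structure, file = NULL) {
  a <- structure
  name4 <- vapply(seq_len(nrow(a)), function(i) {
    nm <- a$name[i]
    # element occupies columns 13-14 only for long or two-letter-element names
    if (nchar(nm) >= 4L || nchar(a$element[i]) == 2L) {
      formatC(nm, width = -4)
    } else {
      " " %+% formatC(nm, width = -3)
    }
  }, "")
  lines <- sprintf(
    "ATOM  %5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L, name4, a$altloc, a$resname, a$chain, a$resno,
    a$x, a$y, a$z, a$occupancy, 0, formatC(a$element, width = 2))
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Select atoms by chain and residue range
#'
#' Selection preserves input atom order and is idempotent. Residue numbers
#' are the author numbering of the source file.
#'
#' @param structure A `pdb_structure`.
#' @param chain Chain identifier(s), or `NULL` for all chains.
#' @param resno Residue numbers (e.g. `850:893`), or `NULL` for all.
#' @param atom_names Optional atom-name filter (e.g. `c("N","CA","C")`).
#' @return A `pdb_structure` with the (possibly empty) subset.
#' @export
select_atoms <- function(structure, chain = NULL, resno = NULL,
                         atom_names = NULL) {
  keep <- rep(TRUE, nrow(structure))
  if (!is.null(chain)) keep <- keep & structure$chain %in% chain
  if (!is.null(resno)) keep <- keep & structure$resno %in% resno
  if (!is.null(atom_names)) keep <- keep & structure$name %in% atom_names
  out <- as.data.frame(structure)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            chains = sort(unique(out$chain)),
            source_id = attr(structure, "source_id"),
            class = c("pdb_structure", "data.frame"))
}

#' Read a titration peak list
#'
#' Reads a TSV with columns `residue`, `aa`, `H_free`, `N_free`, `H_bound`,
#' `N_bound`. Empty cells mean the peak was not observed in that state. A
#' residue whose free-state peaks are present but whose bound-state peaks are
#' absent is flagged as broadened (exchange-broadened beyond detection).
#'
#' @param file Path to the TSV, or text via `text`.
#' @param text Optional TSV text.
#' @return A `data.frame` of class `titration_pairs` with columns `residue`,
#'   `aa`, `H_free`, `N_free`, `H_bound`, `N_bound`, `broadened`.
#' @export
read_peaklist <- function(file = NULL, text = NULL) {
  df <- read.delim(if (is.null(text)) file else textConnection(text),
                   sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("", "NA"))
  needed <- c("residue", "aa", "H_free", "N_free", "H_bound", "N_bound")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("peak list is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, needed]
  numcol <- function(col) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column %s at row %d",
                   raw[bad[1L]], col, bad[1L]), call. = FALSE)
    }
    v
  }
  out <- data.frame(
    residue = as.integer(numcol("residue")),
    aa      = df$aa,
    H_free  = numcol("H_free"),
    N_free  = numcol("N_free"),
    H_bound = numcol("H_bound"),
    N_bound = numcol("N_bound"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$residue)) {
    stop("duplicate residue numbers in peak list: ",
         paste(unique(out$residue[duplicated(out$residue)]), collapse = ", "),
         call. = FALSE)
  }
  has_free <- !is.na(out$H_free) | !is.na(out$N_free)
  has_all_bound <- !is.na(out$H_bound) & !is.na(out$N_bound)
  out$broadened <- has_free & !has_all_bound
  class(out) <- c("titration_pairs", "data.frame")
  out
}

#' Write a titration peak list
#'
#' @param pairs A `titration_pairs` table (the `broadened` column is dropped;
#'   it is recomputed on read).
#' @param file Output TSV path.
#' @return Invisibly, `file`.
#' @export
write_peaklist <- function(pairs, file) {
  df <- as.data.frame(pairs)[, c("residue", "aa", "H_free", "N_free",
                                 "H_bound", "N_bound")]
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(file)
}

#' Read chemical shifts from an NMR-STAR v3 Atom_chem_shift loop
#'
#' Minimal, read-only support: the first `loop_` whose tags belong to the
#' `_Atom_chem_shift` category is parsed. Rows whose shift value is the STAR
#' missing token (`.` or `?`) are skipped with a warning. Shifts outside the
#' plausible amide windows (1H in -2..15 ppm, 15N in 90..140 ppm) trigger a
#' warning, not an error, since folded or unusual peaks do occur.
#'
#' @param file Path to an NMR-STAR file, or text via `text`.
#' @param text Optional STAR text.
#' @return `data.frame` with columns `residue`, `aa` (1-letter, `NA` when not
#'   derivable), `atom`, `shift`.
#' @export
read_nmrstar_shifts <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)

  loops <- which(lines == "loop_")
  if (!length(loops)) stop("no Atom_chem_shift loop found", call. = FALSE)
  for (start in loops) {
    i <- start + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i]); i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    rows <- character()
    while (i <= length(lines) && !lines[i] %in% c("stop_", "") ) {
      rows <- c(rows, lines[i]); i <- i + 1L
    }
    tagname <- sub("^_Atom_chem_shift\\.", "", tags)
    pick <- function(cands) {
      j <- which(tagname %in% cands)
      if (length(j)) j[1L] else NA_integer_
    }
    j_res  <- pick(c("Seq_ID", "Comp_index_ID", "Auth_seq_ID"))
    j_comp <- pick(c("Comp_ID"))
    j_atom <- pick(c("Atom_ID"))
    j_val  <- pick(c("Val"))
    if (is.na(j_res) || is.na(j_atom) || is.na(j_val)) {
      stop("Atom_chem_shift loop lacks Seq_ID/Atom_ID/Val tags", call. = FALSE)
    }
    tok <- strsplit(rows, "[ \t]+")
    n_skipped <- 0L
    recs <- lapply(tok, function(t) {
      if (length(t) < length(tags)) return(NULL)
      val <- t[j_val]
      if (val %in% c(".", "?")) return("skip")
      data.frame(residue = as.integer(t[j_res]),
                 aa = if (!is.na(j_comp)) .aa3to1(t[j_comp]) else NA_character_,
                 atom = t[j_atom],
                 shift = as.numeric(val),
                 stringsAsFactors = FALSE)
    })
    n_skipped <- sum(vapply(recs, identical, logical(1), "skip"))
    recs <- recs[!vapply(recs, function(r) is.null(r) || identical(r, "skip"),
                         logical(1))]
    if (n_skipped > 0L) {
      warning(sprintf("%d shift row(s) with missing value token skipped",
                      n_skipped), call. = FALSE)
    }
    out <- do.call(rbind, recs)
    if (is.null(out)) out <- data.frame(residue = integer(), aa = character(),
                                        atom = character(), shift = numeric())
    h <- out$atom %in% c("H", "HN") & (out$shift < -2 | out$shift > 15)
    n <- out$atom == "N" & (out$shift < 90 | out$shift > 140)
    if (any(h) || any(n)) {
      warning(sprintf("%d amide shift(s) outside plausible ppm window",
                      sum(h) + sum(n)), call. = FALSE)
    }
    rownames(out) <- NULL
    return(out)
  }
  stop("no Atom_chem_shift loop found", call. = FALSE)
}

.aa_codes <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
               GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
               LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
               SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.aa3to1 <- function(x) {
  out <- .aa_codes[toupper(x)]
  out[is.na(out)] <- NA_character_
  unname(out)
}
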