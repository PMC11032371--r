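#' Van der Waals radius and atomic mass tables
#'
#' Bondi-style van der Waals radii (Angstrom) by element, with a united-atom
#' variant for structures deposited without hydrogens: heavy-atom radii are
#' inflated to absorb their implicit protons. `atomic_masses()` returns
#' standard atomic weights (g/mol) for centre-of-mass calculations.
#'
#' @return Named numeric vectors.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    "F" = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    FE = 1.80, ZN = 1.39, MG = 1.73, CA = 1.97, "NA" = 2.27, K = 2.75,
    MN = 1.80, CU = 1.40)
}

#' @rdname vdw_radii
#' @export
vdw_radii_united <- function() {
  r <- vdw_radii()
  r[["C"]] <- 1.90
  r[["N"]] <- 1.65
  r[["O"]] <- 1.55
  r[["S"]] <- 1.90
  r
}

#' @rdname vdw_radii
#' @export
atomic_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    "F" = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971,
    FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078, "NA" = 22.990,
    K = 39.098, MN = 54.938, CU = 63.546)
}

#' Theoretical maximum per-residue solvent accessibility
#'
#' Reference maxima (Angstrom^2) for normalising per-residue SASA to a
#' relative accessibility, from the theoretical Gly-X-Gly values of Tien et
#' al. (2013). Swappable: any named vector covering the residue types present
#' can be passed to [relative_sasa()], since the outcome of an exposure
#' cutoff (e.g. the 30% rule for active-residue calling) depends on the
#' scale chosen.
#'
#' @return Named numeric vector keyed by 3-letter residue code.
#' @export
max_sasa_reference <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci /
# golden-section spiral). No randomness: SASA values are bit-stable.
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

.atom_radii <- function(structure, mode = c("auto", "explicit", "united")) {
  mode <- match.arg(mode)
  has_h <- any(structure$element == "H")
  table <- if (mode == "united" || (mode == "auto" && !has_h)) {
    vdw_radii_united()
  } else {
    vdw_radii()
  }
  el <- toupper(structure$element)
  r <- table[el]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1L]
    stop(sprintf("unknown element '%s' for atom %s %s%d %s (no van der Waals radius)",
                 structure$element[bad], structure$name[bad],
                 structure$chain[bad], structure$resno[bad],
                 structure$resname[bad]), call. = FALSE)
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the structure by the classic sphere-point
#' method: each atom is expanded by the probe radius and sampled with `n_points`
#' quasi-uniform test points (deterministic golden-section spiral); the SASA
#' of the atom is the fraction of points not buried inside any neighbour's
#' expanded sphere, times the expanded sphere's area. Quadrature error
#' scales as ~1/sqrt(`n_points`); 960 points gives sub-percent accuracy on
#' isolated spheres.
#'
#' @param structure A `pdb_structure`.
#' @param probe Probe (solvent) radius in Angstrom; 1.4 approximates water.
#' @param n_points Test points per atom (>= 100).
#' @param radii `"auto"` uses explicit-hydrogen radii when the structure
#'   contains hydrogens and united-atom radii otherwise; or force
#'   `"explicit"`/`"united"`.
#' @return A `sasa_result`: list with `per_atom` (data.frame `atom`, `sasa`)
#'   and `per_residue` (data.frame `chain`, `resno`, `resname`, `sasa`,
#'   `relative_sasa`, the latter `NA` until [relative_sasa()] is applied),
#'   plus the call settings.
#' @examples
#' s <- make_toy_structure(list(toy_body("single", element = "C")))
#' # explicit-hydrogen radii: ~ 4*pi*(1.7+1.4)^2 = 120.76
#' shrake_rupley(s, radii = "explicit")$per_atom$sasa
#' @export
shrake_rupley <- function(structure, probe = 1.4, n_points = 960L,
                          radii = c("auto", "explicit", "united")) {
  stopifnot(n_points >= 100L, probe >= 0)
  n <- nrow(structure)
  if (!n) stop("empty structure", call. = FALSE)
  r <- .atom_radii(structure, radii) + probe
  xyz <- cbind(structure$x, structure$y, structure$z)
  pts <- .sphere_points(n_points)

  # neighbour lists via a single distance matrix; fine for desk-scale inputs
  d2 <- as.matrix(stats::dist(xyz))^2
  rsum2 <- outer(r, r, "+")^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < rsum2[i, ] & seq_len(n) != i)
    if (!length(nb)) {
      sasa[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
        (p[, 3L] - xyz[j, 3L])^2
      exposed <- exposed & dj2 >= r[j]^2
    }
    sasa[i] <- 4 * pi * r[i]^2 * sum(exposed) / n_points
  }

  per_atom <- data.frame(atom = seq_len(n), sasa = sasa)
  key <- paste(structure$chain, structure$resno, sep = "\r")
  first <- !duplicated(key)
  per_residue <- data.frame(
    chain = structure$chain[first],
    resno = structure$resno[first],
    resname = structure$resname[first],
    sasa = as.numeric(tapply(sasa, factor(key, levels = unique(key)), sum)),
    relative_sasa = NA_real_,
    stringsAsFactors = FALSE
  )
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, %d residues, total SASA %.1f A^2 (probe %.2f, %d points)\n",
              nrow(x$per_atom), nrow(x$per_residue), sum(x$per_atom$sasa),
              x$probe, x$n_points))
  invisible(x)
}

#' Relative per-residue solvent accessibility
#'
#' Normalises each residue's SASA by a residue-type reference maximum; a
#' value of 0.30 means 30% of the reference maximum is solvent exposed.
#' Values above 1 can occur for extended conformations and are kept.
#'
#' @param result A `sasa_result`.
#' @param reference Named vector of maxima by 3-letter code; default
#'   [max_sasa_reference()].
#' @return The `sasa_result` with `per_residue$relative_sasa` filled.
#' @export
relative_sasa <- function(result, reference = max_sasa_reference()) {
  res <- result$per_residue
  ref <- reference[toupper(res$resname)]
  if (anyNA(ref)) {
    bad <- unique(res$resname[is.na(ref)])
    stop("residue type(s) absent from reference table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(ref <= 0)) stop("reference maxima must be positive", call. = FALSE)
  result$per_residue$relative_sasa <- res$sasa / unname(ref)
  result
}

#' Buried surface area of a binary complex
#'
#' Total surface buried on complex formation,
#' `BSA = SASA(A) + SASA(B) - SASA(A+B)`, with identical probe and
#' quadrature settings for all three calls. The conventional "interface
#' area" is sometimes quoted per side; both are returned.
#'
#' @param A,B `pdb_structure` objects with disjoint atoms.
#' @param probe,n_points,radii Passed to [shrake_rupley()].
#' @return List with `bsa` (total, both faces), `bsa_per_side` (`bsa/2`),
#'   and the three component SASA totals.
#' @export
buried_surface_area <- function(A, B, probe = 1.4, n_points = 960L,
                                radii = "auto") {
  if (!nrow(A) || !nrow(B)) stop("empty structure", call. = FALSE)
  keyA <- paste(A$chain, A$resno, A$name, sep = "\r")
  keyB <- paste(B$chain, B$resno, B$name, sep = "\r")
  if (length(intersect(keyA, keyB))) {
    stop("A and B share duplicate atoms; complex SASA would be ill-defined",
         call. = FALSE)
  }
  AB <- new_structure(rbind(as.data.frame(A), as.data.frame(B)),
                      source_id = "complex")
  sA <- sum(shrake_rupley(A, probe, n_points, radii)$per_atom$sasa)
  sB <- sum(shrake_rupley(B, probe, n_points, radii)$per_atom$sasa)
  sAB <- sum(shrake_rupley(AB, probe, n_points, radii)$per_atom$sasa)
  bsa <- sA + sB - sAB
  list(bsa = bsa, bsa_per_side = bsa / 2, sasa_A = sA, sasa_B = sB,
       sasa_complex = sAB)
}

#' Centre of mass of an atom selection
#'
#' Mass-weighted mean position using standard atomic weights, or the
#' unweighted geometric centroid.
#'
#' @param structure A `pdb_structure`.
#' @param chain,resno,atom_names Optional selection (see [select_atoms()]).
#' @param weighted `FALSE` switches to the geometric centroid.
#' @return Numeric 3-vector (Angstrom).
#' @export
center_of_mass <- function(structure, chain = NULL, resno = NULL,
                           atom_names = NULL, weighted = TRUE) {
  s <- select_atoms(structure, chain = chain, resno = resno,
                    atom_names = atom_names)
  if (!nrow(s)) stop("empty selection for centre of mass", call. = FALSE)
  w <- if (weighted) {
    m <- atomic_masses()[toupper(s$element)]
    if (anyNA(m)) {
      stop("unknown element(s) for mass weighting: ",
           paste(unique(s$element[is.na(m)]), collapse = ", "), call. = FALSE)
    }
    unname(m)
  } else {
    rep(1, nrow(s))
  }
  c(x = sum(w * s$x), y = sum(w * s$y), z = sum(w * s$z)) / sum(w)
}

#' Inter-molecular atomic contacts
#'
#' All atom pairs between two structures within a distance cutoff, classed
#' polar when both atoms are nitrogen, oxygen or sulfur (hydrogen-bond or
#' salt-bridge capable), else nonpolar. Sorted by distance.
#'
#' @param A,B `pdb_structure` objects.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @return `data.frame` with the two atoms' chain/resno/resname/name, the
#'   distance, and `category`.
#' @export
find_contacts <- function(A, B, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  if (!nrow(A) || !nrow(B)) {
    return(.empty_contacts())
  }
  xa <- cbind(A$x, A$y, A$z)
  xb <- cbind(B$x, B$y, B$z)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(.empty_contacts())
  i <- hit[, 1L]; j <- hit[, 2L]
  polar_set <- c("N", "O", "S")
  out <- data.frame(
    chain_A = A$chain[i], resno_A = A$resno[i], resname_A = A$resname[i],
    name_A = A$name[i],
    chain_B = B$chain[j], resno_B = B$resno[j], resname_B = B$resname[j],
    name_B = B$name[j],
    distance = sqrt(pmax(0, d2[hit])),
    stringsAsFactors = FALSE
  )
  out$category <- ifelse(toupper(A$element[i]) %in% polar_set &
                           toupper(B$element[j]) %in% polar_set,
                         "polar", "nonpolar")
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_contacts <- function() {
  data.frame(chain_A = character(), resno_A = integer(),
             resname_A = character(), name_A = character(),
             chain_B = character(), resno_B = integer(),
             resname_B = character(), name_B = character(),
             distance = numeric(), category = character(),
             stringsAsFactors = FALSE)
}
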