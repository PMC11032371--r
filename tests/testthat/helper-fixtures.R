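# Shared fixture builders; everything is generated in code.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, element = NULL) {
  name4 <- if (nchar(name) >= 4L) formatC(name, width = -4) else
    paste0(" ", formatC(name, width = -3))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resname, chain, resno, x, y, z, occ, 0,
          if (is.null(element)) "" else element)
}

# a tiny two-residue dipeptide-like fragment with sensible elements
tiny_pdb_text <- function() {
  c(
    pdb_line(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0, element = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0, element = "C"),
    pdb_line(3, "C",  "ALA", "A", 1, 2.2, 1.3, 0.0, element = "C"),
    pdb_line(4, "O",  "ALA", "A", 1, 1.6, 2.4, 0.0, element = "O"),
    pdb_line(5, "N",  "GLY", "A", 2, 3.5, 1.2, 0.0, element = "N"),
    pdb_line(6, "CA", "GLY", "A", 2, 4.3, 2.4, 0.0, element = "C"),
    "END"
  )
}

# fabricate a sasa_result with chosen relative exposures (resno -> rsasa)
fake_sasa <- function(rsasa, chain = "A", resname = "ALA") {
  resno <- as.integer(names(rsasa))
  structure(list(
    per_atom = data.frame(atom = seq_along(resno), sasa = unname(rsasa) * 129),
    per_residue = data.frame(chain = chain, resno = resno, resname = resname,
                             sasa = unname(rsasa) * 129,
                             relative_sasa = unname(rsasa),
                             stringsAsFactors = FALSE),
    probe = 1.4, n_points = 960L), class = "sasa_result")
}

# peak-pair table straight from numbers (no file round trip)
pairs_df <- function(residue, H_free, N_free, H_bound, N_bound,
                     aa = rep("A", length(residue))) {
  out <- data.frame(residue = residue, aa = aa, H_free = H_free,
                    N_free = N_free, H_bound = H_bound, N_bound = N_bound,
                    stringsAsFactors = FALSE)
  out$broadened <- (!is.na(out$H_free)) & (is.na(out$H_bound) | is.na(out$N_bound))
  class(out) <- c("titration_pairs", "data.frame")
  out
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

rotation_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), sin(theta),
           0, -sin(theta), cos(theta)), 3, 3)
}
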