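#' Call active interface residues from CSPs and surface exposure
#'
#' A residue is called active when its chemical shift perturbation exceeds
#' the per-molecule mean CSP and its relative solvent accessibility exceeds
#' `rsasa_min` (default 30%): a strongly perturbed but buried residue
#' responds indirectly and should not drive docking restraints. Buried
#' responders are reported separately for inspection.
#'
#' @param profile A `csp_profile`.
#' @param sasa A `sasa_result` with `relative_sasa` filled (see
#'   [relative_sasa()]), in the same residue numbering as the profile.
#' @param rsasa_min Relative-SASA threshold (fraction; default 0.30).
#' @param molecule_id Free-text label carried into restraints.
#' @return An `interface_call`: list with `molecule_id`, `active`, `passive`
#'   (empty until [call_passive()]), `buried_responders`, `csp_threshold`
#'   (the mean CSP used) and `rsasa_min`.
#' @export
call_active <- function(profile, sasa, rsasa_min = 0.30, molecule_id = "mol") {
  res <- sasa$per_residue
  if (anyNA(res$relative_sasa)) {
    stop("relative_sasa not filled; run relative_sasa() first", call. = FALSE)
  }
  if (!length(intersect(profile$residue, res$resno))) {
    stop("no residue-number overlap between CSP profile and SASA result",
         call. = FALSE)
  }
  responders <- csp_above_mean(profile)
  rsasa <- setNames(res$relative_sasa, res$resno)
  exposed <- responders[!is.na(rsasa[as.character(responders)]) &
                          rsasa[as.character(responders)] > rsasa_min]
  buried <- setdiff(responders, exposed)
  structure(list(molecule_id = molecule_id,
                 active = sort(exposed),
                 passive = integer(),
                 buried_responders = sort(buried),
                 csp_threshold = attr(profile, "mean_delta"),
                 rsasa_min = rsasa_min),
            class = "interface_call")
}

#' @export
print.interface_call <- function(x, ...) {
  cat(sprintf("<interface_call> %s: %d active, %d passive, %d buried responders (CSP > %.4g ppm, rSASA > %.0f%%)\n",
              x$molecule_id, length(x$active), length(x$passive),
              length(x$buried_responders), x$csp_threshold, 100 * x$rsasa_min))
  invisible(x)
}

#' Call passive residues around an active set
#'
#' Passive residues are the solvent-exposed neighbours of the active set:
#' surface residues (relative SASA above `rsasa_min`) with any atom within
#' `neighbour_cutoff` of any active-residue atom, excluding the active
#' residues themselves. They enter ambiguous restraints as allowed, but not
#' required, contact partners.
#'
#' @param structure A `pdb_structure` of the molecule.
#' @param call An `interface_call` (active set non-empty).
#' @param sasa A `sasa_result` with relative SASA filled.
#' @param neighbour_cutoff Distance cutoff in Angstrom (default 6.5).
#' @param rsasa_min Exposure threshold (default 0.30).
#' @return The `interface_call` with `passive` filled.
#' @export
call_passive <- function(structure, call, sasa, neighbour_cutoff = 6.5,
                         rsasa_min = 0.30) {
  if (!length(call$active)) stop("active set is empty", call. = FALSE)
  if (neighbour_cutoff <= 0) {
    call$passive <- integer()
    return(call)
  }
  act <- select_atoms(structure, resno = call$active)
  oth <- select_atoms(structure,
                      resno = setdiff(unique(structure$resno), call$active))
  if (!nrow(act) || !nrow(oth)) {
    call$passive <- integer()
    return(call)
  }
  hits <- find_contacts(oth, act, cutoff = neighbour_cutoff)
  near <- unique(hits$resno_A)
  res <- sasa$per_residue
  rsasa <- setNames(res$relative_sasa, res$resno)
  near <- near[!is.na(rsasa[as.character(near)]) &
                 rsasa[as.character(near)] > rsasa_min]
  call$passive <- sort(near)
  call
}

#' Write ambiguous interaction restraints (AIRs)
#'
#' One ambiguous restraint per active residue of each molecule, pulling it
#' towards the union of the partner's active and passive residues; a
#' restraint is satisfiable by contact with any member of the target group.
#' Serialised in the CNS/HADDOCK `tbl` dialect:
#' `assign (segid A and resid i) ((segid B and resid j) or ...) d d 0`, i.e.
#' distance bounds `[d - d, d + 0] = [0, d_max]` on the effective distance.
#'
#' @param callA,callB `interface_call` objects for the two molecules; their
#'   `molecule_id` is used as the segid.
#' @param d_max Upper distance bound in Angstrom (default 2.0, the usual
#'   docking default for ambiguous effective distances).
#' @param file Optional output path.
#' @return Character vector of tbl lines (invisibly when `file` given). The
#'   parsed form is available via [read_airs()].
#' @export
write_airs <- function(callA, callB, d_max = 2.0, file = NULL) {
  stopifnot(d_max > 0)
  if (!length(callA$active) || !length(callB$active)) {
    stop("each molecule must have at least one active residue", call. = FALSE)
  }
  one <- function(from_call, to_call) {
    targets <- sort(unique(c(to_call$active, to_call$passive)))
    vapply(from_call$active, function(r) {
      sel_from <- sprintf("(segid %s and resid %d)", from_call$molecule_id, r)
      sel_to <- paste(sprintf("(segid %s and resid %d)",
                              to_call$molecule_id, targets),
                      collapse = " or ")
      sprintf("assign %s (%s) %.2f %.2f 0.00", sel_from, sel_to, d_max, d_max)
    }, "")
  }
  lines <- c(one(callA, callB), one(callB, callA))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse a tbl restraint file written by [write_airs()]
#'
#' @param lines Character vector of tbl text (or a file path of length 1
#'   that exists on disk).
#' @return `data.frame` with `from_molecule`, `from_residue`, `to_molecule`,
#'   `to_residues` (list column), `d_max`.
#' @export
read_airs <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[grepl("^\\s*assign", lines)]
  parse_one <- function(ln) {
    sels <- regmatches(ln, gregexpr("segid\\s+(\\S+)\\s+and\\s+resid\\s+(\\d+)", ln))[[1L]]
    parts <- regmatches(sels, regexec("segid\\s+(\\S+)\\s+and\\s+resid\\s+(\\d+)", sels))
    mols <- vapply(parts, `[`, "", 2L)
    res <- as.integer(vapply(parts, `[`, "", 3L))
    nums <- regmatches(ln, gregexpr("[0-9]+\\.[0-9]+(?=\\s|$)", ln, perl = TRUE))[[1L]]
    data.frame(from_molecule = mols[1L], from_residue = res[1L],
               to_molecule = mols[2L],
               to_residues = I(list(sort(unique(res[-1L])))),
               d_max = as.numeric(nums[1L]),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(lines, parse_one))
  rownames(out) <- NULL
  out
}

#' Score a complex pose against ambiguous restraints
#'
#' The effective distance of a restraint is the minimum inter-atomic
#' distance between the restrained residue and any atom of any target-group
#' residue (a deliberate simplification of sum-averaged effective distances:
#' monotone in separation and adequate for ranking). A restraint is
#' satisfied when the effective distance is at most its `d_max`; violations
#' contribute `(d_eff - d_max)^2` to the violation energy. Optionally the
#' buried surface area and a set of named key contacts are evaluated.
#'
#' @param complex A `pdb_structure` containing both molecules.
#' @param restraints Output of [read_airs()] (or [write_airs()] lines).
#' @param chain_map Named character vector mapping molecule id to chain id,
#'   e.g. `c(CUE = "A", UB = "B")`.
#' @param key_contacts Optional list of named contacts, each
#'   `list(chain_A=, resno_A=, chain_B=, resno_B=, category=, cutoff=)`;
#'   `category`/`cutoff` optional (defaults any / 4.0).
#' @param bsa Compute buried surface area between the two mapped chains
#'   (default `TRUE`; uses 960 points).
#' @param com_selections Optional list of two selections
#'   (`list(chain=, resno=)`) whose centre-of-mass distance is reported.
#' @return A `pose_score`: list with `satisfied`, `total`, `satisfaction`,
#'   `violation_energy`, `bsa`, `key_contacts_present`, `com_distance`,
#'   `per_restraint` detail table.
#' @export
score_pose <- function(complex, restraints, chain_map, key_contacts = NULL,
                       bsa = TRUE, com_selections = NULL) {
  if (is.character(restraints)) restraints <- read_airs(restraints)
  xyz_of <- function(mol, resnos) {
    ch <- chain_map[[mol]]
    if (is.null(ch)) stop("molecule '", mol, "' missing from chain_map",
                          call. = FALSE)
    s <- select_atoms(complex, chain = ch, resno = resnos)
    if (!nrow(s)) {
      stop(sprintf("restraint residue(s) %s of molecule %s not resolvable in complex",
                   paste(resnos, collapse = ","), mol), call. = FALSE)
    }
    cbind(s$x, s$y, s$z)
  }
  d_eff <- numeric(nrow(restraints))
  for (k in seq_len(nrow(restraints))) {
    fa <- xyz_of(restraints$from_molecule[k], restraints$from_residue[k])
    ta <- xyz_of(restraints$to_molecule[k], restraints$to_residues[[k]])
    d2 <- outer(rowSums(fa^2), rowSums(ta^2), "+") - 2 * fa %*% t(ta)
    d_eff[k] <- sqrt(max(0, min(d2)))
  }
  dmax <- restraints$d_max
  sat <- d_eff <= dmax
  viol <- sum(pmax(0, d_eff - dmax)^2)

  mols <- unique(c(restraints$from_molecule, restraints$to_molecule))
  bsa_val <- NA_real_
  contacts <- NULL
  if ((bsa || !is.null(key_contacts)) && length(chain_map) >= 2L) {
    chains <- unlist(chain_map[mols[seq_len(min(2L, length(mols)))]])
    A <- select_atoms(complex, chain = chains[1L])
    B <- select_atoms(complex, chain = chains[2L])
    if (bsa) bsa_val <- buried_surface_area(A, B)$bsa
    if (!is.null(key_contacts)) contacts <- find_contacts(A, B, cutoff = 6.0)
  }
  key_present <- NULL
  if (!is.null(key_contacts)) {
    key_present <- vapply(key_contacts, function(kc) {
      cutoff <- if (is.null(kc$cutoff)) 4.0 else kc$cutoff
      hit <- contacts$chain_A == kc$chain_A & contacts$resno_A == kc$resno_A &
        contacts$chain_B == kc$chain_B & contacts$resno_B == kc$resno_B &
        contacts$distance <= cutoff
      if (!is.null(kc$category)) hit <- hit & contacts$category == kc$category
      any(hit)
    }, logical(1))
  }
  com_d <- NA_real_
  if (!is.null(com_selections)) {
    c1 <- do.call(center_of_mass, c(list(complex), com_selections[[1L]]))
    c2 <- do.call(center_of_mass, c(list(complex), com_selections[[2L]]))
    com_d <- sqrt(sum((c1 - c2)^2))
  }
  structure(list(satisfied = sum(sat), total = length(sat),
                 satisfaction = if (length(sat)) sum(sat) / length(sat) else NA_real_,
                 violation_energy = viol, bsa = bsa_val,
                 key_contacts_present = key_present, com_distance = com_d,
                 per_restraint = data.frame(
                   from_molecule = restraints$from_molecule,
                   from_residue = restraints$from_residue,
                   d_eff = d_eff, d_max = dmax, satisfied = sat)),
            class = "pose_score")
}

#' @export
print.pose_score <- function(x, ...) {
  cat(sprintf("<pose_score> %d/%d restraints satisfied (%.0f%%), violation energy %.3g A^2",
              x$satisfied, x$total, 100 * x$satisfaction, x$violation_energy))
  if (!is.na(x$bsa)) cat(sprintf(", BSA %.0f A^2", x$bsa))
  cat("\n")
  if (!is.null(x$key_contacts_present)) {
    cat("  key contacts:",
        paste(sprintf("%s=%s", names(x$key_contacts_present),
                      x$key_contacts_present), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Key contacts of the N4BP1 CUE / ubiquitin interface
#'
#' Default named-contact configuration for this system: the salt bridge
#' between ubiquitin K48 and N4BP1 D893 (polar), and the nonpolar contacts
#' of the ubiquitin I44 hydrophobic patch with the CUE FP motif (F862,
#' P863). Mutating either side of the polar contact (D893A, K48A) abolishes
#' complex formation, so a credible pose must show both.
#'
#' @param ub_chain,cue_chain Chain ids of ubiquitin and the CUE domain.
#' @return List suitable for `key_contacts` of [score_pose()].
#' @export
cue_ub_key_contacts <- function(ub_chain = "B", cue_chain = "A") {
  list(
    K48_D893 = list(chain_A = cue_chain, resno_A = 893L,
                    chain_B = ub_chain, resno_B = 48L, category = "polar"),
    I44_F862 = list(chain_A = cue_chain, resno_A = 862L,
                    chain_B = ub_chain, resno_B = 44L, cutoff = 5.0),
    I44_P863 = list(chain_A = cue_chain, resno_A = 863L,
                    chain_B = ub_chain, resno_B = 44L, cutoff = 5.0)
  )
}

#' Centre-of-mass compatibility of a dimer with tandem diUb binding
#'
#' Two ubiquitin-binding domains can engage both moieties of a linear
#' (M1-linked) diUb simultaneously only if their centres of mass sit at the
#' spacing of the two moieties' binding sites, about 31 Angstrom. This
#' measures the COM distance between two selections of a dimer model and
#' tests it against the target within a tolerance.
#'
#' @param dimer A `pdb_structure` of the dimer model.
#' @param sel1,sel2 Selections for the two domains:
#'   `list(chain =, resno =, atom_names =)` (e.g. `resno = 850:893` per
#'   protomer). `atom_names = c("N","CA","C","O")` restricts to backbone.
#' @param target Target COM distance in Angstrom (default 31).
#' @param tol Tolerance in Angstrom (default 2).
#' @param weighted Mass-weighted COM (default) or geometric centroid.
#' @return List with `com_distance` and logical `pass`.
#' @export
dimer_diub_compatibility <- function(dimer, sel1, sel2, target = 31.0,
                                     tol = 2.0, weighted = TRUE) {
  c1 <- do.call(center_of_mass, c(list(dimer), sel1, list(weighted = weighted)))
  c2 <- do.call(center_of_mass, c(list(dimer), sel2, list(weighted = weighted)))
  d <- sqrt(sum((c1 - c2)^2))
  list(com_distance = d, pass = abs(d - target) <= tol)
}

#' Rank candidate complex models against restraints
#'
#' Deterministic lexicographic ranking: restraint satisfaction (descending),
#' then violation energy (ascending), then buried surface area (descending),
#' then input order (stable).
#'
#' @param models List of `pdb_structure` complexes.
#' @param restraints Restraints as for [score_pose()].
#' @param chain_map As for [score_pose()].
#' @param ... Further arguments to [score_pose()].
#' @return `data.frame` with `model` (input index in ranked order),
#'   `satisfaction`, `violation_energy`, `bsa`.
#' @export
rank_models <- function(models, restraints, chain_map, ...) {
  stopifnot(length(models) >= 1L)
  scores <- lapply(models, score_pose, restraints = restraints,
                   chain_map = chain_map, ...)
  df <- data.frame(
    model = seq_along(models),
    satisfaction = vapply(scores, `[[`, 0, "satisfaction"),
    violation_energy = vapply(scores, `[[`, 0, "violation_energy"),
    bsa = vapply(scores, `[[`, 0, "bsa")
  )
  bsa_key <- ifelse(is.na(df$bsa), -Inf, df$bsa)
  ord <- order(-df$satisfaction, df$violation_energy, -bsa_key, df$model)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
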