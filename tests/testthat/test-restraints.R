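# profile with chosen deltas via a = 1 proton-only displacements
profile_from_deltas <- function(deltas, cap = 1) {
  n <- length(deltas)
  p <- pairs_df(seq_len(n), rep(8, n), rep(120, n), 8 + deltas, rep(120, n))
  compute_csp(p, cap = cap, a = 1)
}

test_that("active residues need both a strong CSP and surface exposure", {
  # residues 1-5 perturbed, 6-10 quiet; residue 5 buried
  prof <- profile_from_deltas(c(rep(0.4, 5), rep(0.01, 5)))
  sasa <- fake_sasa(setNames(c(0.5, 0.5, 0.5, 0.5, 0.1, rep(0.6, 5)),
                             as.character(1:10)))
  call <- call_active(prof, sasa, rsasa_min = 0.30, molecule_id = "CUE")
  expect_equal(call$active, 1:4)
  expect_equal(call$buried_responders, 5L)
  expect_equal(call$csp_threshold, attr(prof, "mean_delta"))
})

test_that("no responders means an empty active set; rsasa_min = 0 keeps any exposure", {
  prof_eq <- profile_from_deltas(rep(0.2, 6))
  sasa <- fake_sasa(setNames(rep(0.5, 6), as.character(1:6)))
  expect_length(call_active(prof_eq, sasa)$active, 0L)

  prof <- profile_from_deltas(c(0.4, 0.4, 0.01, 0.01))
  sasa2 <- fake_sasa(setNames(c(0.05, 0, 0.5, 0.5), as.character(1:4)))
  call <- call_active(prof, sasa2, rsasa_min = 0)
  expect_equal(call$active, 1L)  # residue 2 has zero exposure
})

test_that("raising the exposure threshold never adds active residues", {
  prof <- profile_from_deltas(c(0.5, 0.45, 0.4, 0.02, 0.02, 0.02))
  sasa <- fake_sasa(setNames(c(0.2, 0.35, 0.8, 0.9, 0.9, 0.9),
                             as.character(1:6)))
  prev <- NULL
  for (thr in c(0, 0.1, 0.3, 0.5, 0.9)) {
    act <- call_active(prof, sasa, rsasa_min = thr)$active
    if (!is.null(prev)) expect_true(all(act %in% prev))
    prev <- act
  }
})

test_that("numbering mismatch between profile and SASA is an error", {
  prof <- profile_from_deltas(c(0.4, 0.1))
  sasa <- fake_sasa(setNames(c(0.5, 0.5), c("100", "101")))
  expect_error(call_active(prof, sasa), "overlap")
})

test_that("passive residues are exposed neighbours of the active set", {
  # linear 3-residue chain, 5 A apart, centre active
  chain <- new_structure(data.frame(
    name = "CA", resname = "ALA", chain = "A", resno = 1:3,
    x = c(0, 5, 10), y = 0, z = 0, element = "C"))
  sasa <- fake_sasa(setNames(rep(0.9, 3), as.character(1:3)))
  call <- list(molecule_id = "A", active = 2L, passive = integer())
  out <- call_passive(chain, call, sasa, neighbour_cutoff = 6.5)
  expect_equal(out$passive, c(1L, 3L))
  # buried flank excluded
  sasa2 <- fake_sasa(setNames(c(0.9, 0.9, 0.1), as.character(1:3)))
  expect_equal(call_passive(chain, call, sasa2)$passive, 1L)
  # zero cutoff or no neighbours gives an empty set
  expect_length(call_passive(chain, call, sasa, neighbour_cutoff = 0)$passive, 0L)
  lone <- new_structure(data.frame(
    name = "CA", resname = "ALA", chain = "A", resno = c(1L, 2L),
    x = c(0, 50), y = 0, z = 0, element = "C"))
  expect_length(call_passive(lone, list(active = 1L), sasa)$passive, 0L)
})

test_that("one ambiguous restraint is written per active residue", {
  callA <- list(molecule_id = "A", active = c(5L, 9L), passive = integer())
  callB <- list(molecule_id = "B", active = c(2L, 3L, 4L), passive = 7L)
  tbl <- write_airs(callA, callB, d_max = 2.0)
  expect_length(tbl, 5L)  # 2 from A + 3 from B
  parsed <- read_airs(tbl)
  expect_equal(sum(parsed$from_molecule == "A"), 2L)
  # A-side restraints target the union of B's active and passive residues
  expect_equal(parsed$to_residues[[1L]], c(2L, 3L, 4L, 7L))
  expect_equal(unique(parsed$d_max), 2.0)
  # round trip: writing what we parsed yields the same restraint set
  expect_equal(read_airs(tbl), parsed)
})

test_that("reciprocal single-active restraints and empty-side errors", {
  cA <- list(molecule_id = "A", active = 1L, passive = integer())
  cB <- list(molecule_id = "B", active = 9L, passive = integer())
  tbl <- write_airs(cA, cB)
  expect_length(tbl, 2L)
  expect_error(write_airs(cA, list(molecule_id = "B", active = integer(),
                                   passive = integer())),
               "at least one active")
})

two_body_pose <- function(offset) {
  A <- data.frame(name = "CA", resname = "ALA", chain = "A", resno = 1:2,
                  x = c(0, 4), y = 0, z = 0, element = "C")
  B <- data.frame(name = "CA", resname = "ALA", chain = "B", resno = 1:2,
                  x = c(0, 4) + offset, y = 1.5, z = 0, element = "C")
  new_structure(rbind(A, B))
}

pose_restraints <- function(d_max = 2.0) {
  cA <- list(molecule_id = "MA", active = c(1L, 2L), passive = integer())
  cB <- list(molecule_id = "MB", active = c(1L, 2L), passive = integer())
  read_airs(write_airs(cA, cB, d_max = d_max))
}

test_that("a pose in contact satisfies all restraints; a separated one none", {
  cmap <- c(MA = "A", MB = "B")
  near <- score_pose(two_body_pose(0), pose_restraints(), cmap, bsa = FALSE)
  expect_equal(near$satisfaction, 1.0)
  expect_equal(near$violation_energy, 0)
  far <- score_pose(two_body_pose(50), pose_restraints(), cmap, bsa = FALSE)
  expect_equal(far$satisfaction, 0)
  expect_gt(far$violation_energy, 0)
})

test_that("violation energy grows monotonically along a separation path", {
  cmap <- c(MA = "A", MB = "B")
  v <- vapply(seq(0, 40, by = 5), function(off) {
    score_pose(two_body_pose(off), pose_restraints(), cmap,
               bsa = FALSE)$violation_energy
  }, 0)
  expect_true(all(diff(v) >= 0))
})

test_that("pose scores are invariant under a joint rigid transform", {
  cmap <- c(MA = "A", MB = "B")
  pose <- two_body_pose(3)
  s0 <- score_pose(pose, pose_restraints(), cmap, bsa = FALSE)
  R <- rotation_z(0.7)
  xyz <- as.matrix(as.data.frame(pose)[, c("x", "y", "z")]) %*% t(R)
  moved <- as.data.frame(pose)
  moved$x <- xyz[, 1] + 11; moved$y <- xyz[, 2] - 4; moved$z <- xyz[, 3] + 2
  s1 <- score_pose(new_structure(moved), pose_restraints(), cmap, bsa = FALSE)
  expect_equal(s1$satisfaction, s0$satisfaction)
  expect_equal(s1$violation_energy, s0$violation_energy, tolerance = 1e-9)
})

test_that("unresolvable restraint residues are reported", {
  bad <- pose_restraints()
  bad$from_residue[1] <- 99L
  expect_error(score_pose(two_body_pose(0), bad, c(MA = "A", MB = "B"),
                          bsa = FALSE), "99")
})

test_that("key contacts are detected on a constructed interface", {
  cue <- data.frame(name = c("OD1", "CB", "CG"), resname = c("ASP", "PHE", "PRO"),
                    chain = "A", resno = c(893L, 862L, 863L),
                    x = c(0, 5, 8), y = 0, z = 0,
                    element = c("O", "C", "C"))
  ub <- data.frame(name = c("NZ", "CD1"), resname = c("LYS", "ILE"),
                   chain = "B", resno = c(48L, 44L),
                   x = c(3.0, 6.5), y = 0.5, z = 0, element = c("N", "C"))
  pose <- new_structure(rbind(cue, ub))
  cA <- list(molecule_id = "CUE", active = 893L, passive = integer())
  cB <- list(molecule_id = "UB", active = 48L, passive = integer())
  res <- read_airs(write_airs(cA, cB, d_max = 4.0))
  sc <- score_pose(pose, res, c(CUE = "A", UB = "B"),
                   key_contacts = cue_ub_key_contacts(ub_chain = "B",
                                                      cue_chain = "A"),
                   bsa = FALSE)
  expect_true(sc$key_contacts_present[["K48_D893"]])
  expect_true(sc$key_contacts_present[["I44_F862"]])
})

test_that("centre-of-mass spacing gates tandem diUb compatibility", {
  mk <- function(d) make_toy_structure(
    list(toy_body("single", chain_id = "A"), toy_body("single", chain_id = "B")),
    placements = list(list(t = c(0, 0, 0)), list(t = c(d, 0, 0))))
  ok <- dimer_diub_compatibility(mk(31), list(chain = "A"), list(chain = "B"))
  expect_true(ok$pass)
  expect_equal(ok$com_distance, 31)
  bad <- dimer_diub_compatibility(mk(60), list(chain = "A"), list(chain = "B"))
  expect_false(bad$pass)
  expect_equal(bad$com_distance, 60)
})

test_that("model ranking is lexicographic and stable", {
  cmap <- c(MA = "A", MB = "B")
  res <- pose_restraints()
  models <- lapply(c(0, 30, 3, 10, 0), two_body_pose)
  rk <- rank_models(models, res, cmap, bsa = FALSE)
  expect_equal(rk$model[1], 1L)  # all satisfied, first on ties
  expect_equal(rk$model[2], 5L)  # identical pose, stable order
  # oracle: brute-force lexicographic sort of the individual scores
  sc <- lapply(models, score_pose, restraints = res, chain_map = cmap,
               bsa = FALSE)
  ord <- order(-vapply(sc, `[[`, 0, "satisfaction"),
               vapply(sc, `[[`, 0, "violation_energy"),
               seq_along(sc))
  expect_equal(rk$model, ord)
})
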