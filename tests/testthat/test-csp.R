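test_that("scaling factor is the ratio of pooled 15N and 1H ranges", {
  p <- pairs_df(1:2, H_free = c(6, 10), N_free = c(100, 130),
                H_bound = c(6, 10), N_bound = c(100, 130))
  expect_equal(scaling_factor(p), 30 / 4)  # 7.5
  p2 <- pairs_df(1:2, H_free = c(7, 9), N_free = c(118, 122),
                 H_bound = c(7, 9), N_bound = c(118, 122))
  expect_equal(scaling_factor(p2), 2)
  # bound-state extrema participate in the pooling
  p3 <- pairs_df(1:2, H_free = c(7, 9), N_free = c(118, 122),
                 H_bound = c(7, 9), N_bound = c(118, 126))
  expect_equal(scaling_factor(p3), (126 - 118) / 2)
})

test_that("degenerate dispersions are handled per axis", {
  flatH <- pairs_df(1:2, H_free = c(8, 8), N_free = c(110, 120),
                    H_bound = c(8, 8), N_bound = c(110, 120))
  expect_error(scaling_factor(flatH), "zero proton dispersion")
  flatN <- pairs_df(1:2, H_free = c(7, 9), N_free = c(120, 120),
                    H_bound = c(7.5, 9), N_bound = c(120, 120))
  expect_warning(a <- scaling_factor(flatN), "1H axis only")
  expect_equal(a, 0)
  # with a = 0 the CSP reduces to |dH|
  prof <- suppressWarnings(compute_csp(flatN, cap = 1))
  expect_equal(prof$delta, c(0.5, 0))
})

test_that("CSP combines proton and scaled nitrogen displacements", {
  ident <- pairs_df(1:3, H_free = c(7, 8, 9), N_free = c(110, 120, 130),
                    H_bound = c(7, 8, 9), N_bound = c(110, 120, 130))
  prof <- compute_csp(ident, cap = 0.3, a = 5)
  expect_equal(prof$delta, rep(0, 3))
  expect_equal(attr(prof, "mean_delta"), 0)

  # 3-4-5 closed form at a = 1
  p <- pairs_df(1, H_free = 8, N_free = 120, H_bound = 8.3, N_bound = 120.4)
  expect_equal(compute_csp(p, cap = 1, a = 1)$delta, 0.5)
})

test_that("capping clips large and broadened perturbations at the cap", {
  p <- pairs_df(1:2, H_free = c(8, 9), N_free = c(120, 125),
                H_bound = c(8.6, NA), N_bound = c(120, NA))
  prof <- compute_csp(p, cap = 0.3, a = 1)
  expect_equal(prof$delta, c(0.3, 0.3))
  expect_true(all(prof$capped))
  # broadened residues carry the cap of their molecule (0.5 ppm CUE side)
  expect_equal(compute_csp(p, cap = 0.5, a = 1)$delta[2], 0.5)
})

test_that("residues absent in the free state are missing, not broadened", {
  p <- pairs_df(1:2, H_free = c(8, NA), N_free = c(120, NA),
                H_bound = c(8.1, 9), N_bound = c(120.5, 125))
  prof <- compute_csp(p, cap = 1, a = 1)
  expect_false(prof$missing[1])
  expect_true(prof$missing[2])
  expect_equal(attr(prof, "mean_delta"), prof$delta[1])
})

test_that("CSP is invariant under a uniform additive shift offset", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    p <- pairs_df(1:n, H_free = runif(n, 6.5, 10.5), N_free = runif(n, 103, 133),
                  H_bound = NA, N_bound = NA)
    p$H_bound <- p$H_free + rnorm(n, 0, 0.05)
    p$N_bound <- p$N_free + rnorm(n, 0, 0.3)
    off <- pairs_df(1:n, p$H_free + 1.7, p$N_free + 12,
                    p$H_bound + 1.7, p$N_bound + 12)
    a <- scaling_factor(p)
    expect_equal(compute_csp(off, cap = 5, a = a)$delta,
                 compute_csp(p, cap = 5, a = a)$delta, tolerance = 1e-12)
  }
})

test_that("scaling by a equals pre-dividing nitrogen differences at a = 1", {
  set.seed(42)
  n <- 15
  p <- pairs_df(1:n, runif(n, 6.5, 10.5), runif(n, 103, 133), NA, NA)
  p$H_bound <- p$H_free + rnorm(n, 0, 0.05)
  p$N_bound <- p$N_free + rnorm(n, 0, 0.4)
  a <- scaling_factor(p)
  scaled <- p
  scaled$N_free <- p$N_free / a
  scaled$N_bound <- p$N_bound / a
  expect_equal(compute_csp(p, cap = 5, a = a)$delta,
               compute_csp(scaled, cap = 5, a = 1)$delta, tolerance = 1e-12)
})

test_that("pre-cap CSP is monotone in either displacement magnitude", {
  base <- pairs_df(1, 8, 120, 8.1, 120.5)
  a <- 6
  d0 <- compute_csp(base, cap = 100, a = a)$delta
  for (extra in c(0.05, 0.2, 1)) {
    up_h <- pairs_df(1, 8, 120, 8.1 + extra, 120.5)
    up_n <- pairs_df(1, 8, 120, 8.1, 120.5 + extra)
    expect_gte(compute_csp(up_h, cap = 100, a = a)$delta, d0)
    expect_gte(compute_csp(up_n, cap = 100, a = a)$delta, d0)
  }
})

test_that("stored mean equals an independent brute-force mean", {
  set.seed(3)
  n <- 30
  p <- pairs_df(1:n, runif(n, 6.5, 10.5), runif(n, 103, 133), NA, NA)
  p$H_bound <- p$H_free + rnorm(n, 0, 0.1)
  p$N_bound <- p$N_free + rnorm(n, 0, 0.5)
  p$H_bound[c(4, 9)] <- NA; p$N_bound[c(4, 9)] <- NA  # broadened
  p$H_free[11] <- NA; p$N_free[11] <- NA               # missing
  p$broadened <- !is.na(p$H_free) & is.na(p$H_bound)
  prof <- compute_csp(p, cap = 0.5)
  brute <- mean(prof$delta[!prof$missing])
  expect_equal(attr(prof, "mean_delta"), brute)
})

test_that("the above-mean threshold is strict", {
  p <- pairs_df(1:3, rep(8, 3), rep(120, 3),
                c(8.1, 8.2, 8.3), rep(120, 3))
  prof <- compute_csp(p, cap = 1, a = 1)
  expect_equal(attr(prof, "mean_delta"), 0.2)
  expect_equal(csp_above_mean(prof), 3L)
  eq <- pairs_df(1:3, rep(8, 3), rep(120, 3), rep(8.2, 3), rep(120, 3))
  expect_length(csp_above_mean(compute_csp(eq, cap = 1, a = 1)), 0L)
})

test_that("planted interface residues are exactly the ones above the mean", {
  tt <- make_titration(40, interface_residues = c(5, 6, 7, 24, 38),
                       interface_csp_mean = 0.4, background_csp_sd = 0.01,
                       seed = 11)
  prof <- compute_csp(tt$pairs, cap = 0.5, a = tt$truth$scaling_a)
  expect_setequal(csp_above_mean(prof), tt$truth$interface_residues)
})

test_that("assignment completeness counts a table-driven inventory", {
  # all five backbone resonances of a 3-Ala stretch assigned
  sh <- expand.grid(residue = 1:3, atom = c("N", "H", "CA", "CB", "C"),
                    stringsAsFactors = FALSE)
  cc <- assignment_completeness(sh, "AAA")
  expect_equal(cc$backbone_fraction, 1.0)

  # proline has no amide H: denominator is 5 (Ala) + 4 (Pro)
  sh2 <- data.frame(residue = 1, atom = c("N", "H", "CA", "CB", "C"))
  cc2 <- assignment_completeness(sh2, "AP")
  expect_equal(cc2$potential_backbone, 9L)
  expect_equal(cc2$backbone_fraction, 5 / 9)

  # glycine has no CB
  cc3 <- assignment_completeness(data.frame(residue = 1, atom = "N"), "G")
  expect_equal(cc3$potential_backbone, 4L)
})

test_that("completeness handles tags, side chains, and empty lists", {
  expect_equal(assignment_completeness(
    data.frame(residue = integer(), atom = character()), "AAA")$backbone_fraction, 0)
  # n_term_ignore removes tag residues from the denominator entirely
  sh <- expand.grid(residue = 4:5, atom = c("N", "H", "CA", "CB", "C"),
                    stringsAsFactors = FALSE)
  cc <- assignment_completeness(sh, "GSHAA", n_term_ignore = 3)
  expect_equal(cc$backbone_fraction, 1.0)
  # side-chain accounting: Ala side chain is the single HB methyl resonance
  sc <- assignment_completeness(data.frame(residue = 1, atom = "HB"), "A")
  expect_equal(sc$sidechain_fraction, 1.0)
  expect_error(assignment_completeness(data.frame(residue = 9, atom = "N"), "AAA"),
               "outside sequence")
})
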