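single_c <- function() make_toy_structure(toy_body("single", element = "C"))

test_that("an isolated sphere matches the closed-form area within quadrature", {
  r <- shrake_rupley(single_c(), radii = "explicit")
  expect_equal(r$per_atom$sasa, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)
  # per-residue totals equal summed atom values
  expect_equal(r$per_residue$sasa, sum(r$per_atom$sasa))
})

test_that("disjoint far-apart atoms are additive", {
  s <- make_toy_structure(toy_body("pair", d = 100, element = "C"))
  r <- shrake_rupley(s, radii = "explicit")
  expect_equal(sum(r$per_atom$sasa), 2 * 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("a caged atom is buried", {
  shell <- toy_body("shell", r = 2.5, n = 60L, element = "C", chain_id = "B")
  cage <- make_toy_structure(list(toy_body("single", element = "C"), shell))
  r <- shrake_rupley(cage, radii = "explicit")
  expect_lt(r$per_atom$sasa[1], 1)
})

test_that("SASA is invariant under rigid rotation and translation", {
  b <- toy_body("helix", n = 12L, rise = 1.5, radius = 2.3)
  s0 <- make_toy_structure(list(b))
  s1 <- make_toy_structure(list(b), placements = list(
    list(R = rotation_z(1.1), t = c(5, -3, 7))))
  r0 <- shrake_rupley(s0, radii = "explicit")
  r1 <- shrake_rupley(s1, radii = "explicit")
  expect_equal(r1$per_atom$sasa, r0$per_atom$sasa, tolerance = 0.01)
})

test_that("quadrature converges as the point count grows", {
  # two equal spheres in contact have a closed-form SASA (spherical caps):
  # each exposes 2*pi*r^2 + pi*r*d. Orientation-averaged error (the test
  # points are deterministic, so single orientations oscillate) must shrink
  # monotonically with the point count.
  r <- 1.70 + 1.4
  exact <- 2 * (2 * pi * r^2 + pi * r * 3)
  errs <- vapply(c(250L, 1000L, 4000L), function(np) {
    mean(vapply(1:5, function(k) {
      s <- make_toy_structure(
        list(toy_body("pair", d = 3, element = "C")),
        placements = list(list(R = rotation_z(k) %*% rotation_x(2 * k))))
      abs(sum(shrake_rupley(s, n_points = np,
                            radii = "explicit")$per_atom$sasa) - exact)
    }, 0))
  }, 0)
  expect_true(all(diff(errs) < 0))
  # and the default point count is within 1% of the closed form
  s <- make_toy_structure(toy_body("pair", d = 3, element = "C"))
  expect_equal(sum(shrake_rupley(s, radii = "explicit")$per_atom$sasa),
               exact, tolerance = 0.01)
})

test_that("a larger probe never shrinks a single sphere's surface", {
  s <- single_c()
  a1 <- shrake_rupley(s, probe = 1.4, radii = "explicit")$per_atom$sasa
  a2 <- shrake_rupley(s, probe = 2.8, radii = "explicit")$per_atom$sasa
  expect_gt(a2, a1)
})

test_that("unknown elements are reported by atom", {
  s <- new_structure(data.frame(name = "XX", resname = "UNK", chain = "A",
                                resno = 1L, x = 0, y = 0, z = 0,
                                element = "XX"))
  expect_error(shrake_rupley(s), "unknown element 'XX'")
})

test_that("relative SASA divides by the residue-type reference maximum", {
  res <- fake_sasa(c(`1` = 1))
  res$per_residue$relative_sasa <- NA_real_
  res$per_residue$sasa <- 129.0
  out <- relative_sasa(res)
  expect_equal(out$per_residue$relative_sasa, 1.0)
  res$per_residue$sasa <- 0
  expect_equal(relative_sasa(res)$per_residue$relative_sasa, 0)
  # custom reference table
  res$per_residue$resname <- "GLY"
  res$per_residue$sasa <- 52.2
  expect_equal(relative_sasa(res, c(GLY = 104.4))$per_residue$relative_sasa, 0.5)
  expect_error(relative_sasa(res, c(ALA = 129)), "absent from reference")
})

test_that("buried surface area is zero for separated bodies and symmetric", {
  A <- make_toy_structure(toy_body("helix", n = 6L, chain_id = "A"))
  B <- make_toy_structure(list(toy_body("helix", n = 6L, chain_id = "B")),
                          placements = list(list(t = c(100, 0, 0))))
  far <- buried_surface_area(A, B, n_points = 500L)
  expect_equal(far$bsa, 0, tolerance = 1e-6)
  # in-contact slabs: symmetric and equal to the three-call identity
  Bc <- make_toy_structure(list(toy_body("helix", n = 6L, chain_id = "B")),
                           placements = list(list(t = c(3.6, 0, 0))))
  ab <- buried_surface_area(A, Bc, n_points = 500L)
  ba <- buried_surface_area(Bc, A, n_points = 500L)
  expect_gt(ab$bsa, 0)
  expect_equal(ab$bsa, ba$bsa, tolerance = 1e-9)
  expect_equal(ab$bsa_per_side, ab$bsa / 2)
  # oracle identity from three independent SASA calls
  sA <- sum(shrake_rupley(A, n_points = 500L)$per_atom$sasa)
  sB <- sum(shrake_rupley(Bc, n_points = 500L)$per_atom$sasa)
  AB <- new_structure(rbind(as.data.frame(A), as.data.frame(Bc)))
  sAB <- sum(shrake_rupley(AB, n_points = 500L)$per_atom$sasa)
  expect_equal(ab$bsa, sA + sB - sAB, tolerance = 1e-9)
})

test_that("duplicate atoms across the two bodies are rejected", {
  A <- make_toy_structure(toy_body("single", chain_id = "A"))
  expect_error(buried_surface_area(A, A), "duplicate atoms")
})

test_that("centre of mass is mass-weighted and translation-equivariant", {
  two <- new_structure(data.frame(
    name = c("C1", "C2"), resname = "UNK", chain = "A", resno = 1:2,
    x = c(0, 2), y = 0, z = 0, element = "C"))
  expect_equal(unname(center_of_mass(two)), c(1, 0, 0))
  co <- new_structure(data.frame(
    name = c("C", "O"), resname = "UNK", chain = "A", resno = 1:2,
    x = 0, y = 0, z = c(0, 2), element = c("C", "O")))
  expect_equal(unname(center_of_mass(co))[3],
               2 * 15.999 / (12.011 + 15.999), tolerance = 1e-6)
  shifted <- co
  shifted$x <- co$x + 4; shifted$y <- co$y - 2; shifted$z <- co$z + 1
  expect_equal(unname(center_of_mass(shifted)),
               unname(center_of_mass(co)) + c(4, -2, 1))
  expect_equal(unname(center_of_mass(co, weighted = FALSE))[3], 1)
  expect_error(center_of_mass(co, chain = "Z"), "empty selection")
})

test_that("contacts are found, categorised and sorted by distance", {
  lys <- new_structure(data.frame(name = "NZ", resname = "LYS", chain = "A",
                                  resno = 48L, x = 0, y = 0, z = 0,
                                  element = "N"))
  asp <- new_structure(data.frame(name = c("OD1", "CG"), resname = "ASP",
                                  chain = "B", resno = 893L,
                                  x = c(3.2, 4.5), y = 0, z = 0,
                                  element = c("O", "C")))
  ct <- find_contacts(lys, asp, cutoff = 4.0)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$category, "polar")
  expect_equal(ct$distance, 3.2, tolerance = 1e-9)
  far <- make_toy_structure(list(toy_body("single", chain_id = "C")),
                            placements = list(list(t = c(100, 0, 0))))
  expect_equal(nrow(find_contacts(lys, far)), 0L)
  # sorted by distance with a wider cutoff
  ct2 <- find_contacts(lys, asp, cutoff = 5)
  expect_equal(ct2$distance, sort(ct2$distance))
  expect_equal(ct2$category[2], "nonpolar")
})
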