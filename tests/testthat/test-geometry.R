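mk_atoms <- function(xyz, element = "C") {
  data.frame(auth_seq = seq_len(nrow(xyz)), icode = "", res_name = "UNK",
             name = "X", element = element, x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], b = 0, occ = 1, altloc = "",
             stringsAsFactors = FALSE)
}

test_that("center of mass is mass-weighted with standard atomic masses", {
  two_c <- mk_atoms(rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_equal(center_of_mass(two_c), c(0, 0, 1))

  oh <- mk_atoms(rbind(c(0, 0, 0), c(0, 0, 1)), element = c("O", "H"))
  expect_equal(center_of_mass(oh)[3], 1.008 / (15.999 + 1.008),
               tolerance = 1e-6)
  # geometric mode ignores masses
  expect_equal(center_of_mass(oh, mode = "geometric")[3], 0.5)

  single <- mk_atoms(matrix(c(1, 2, 3), 1))
  expect_equal(center_of_mass(single), c(1, 2, 3))
  expect_error(center_of_mass(single[0, ]), "empty")
})

test_that("distance, hinge midpoint, angle and dihedral follow their definitions", {
  expect_equal(domain_distance(c(0, 0, 0), c(0, 0, 10)), 10)
  expect_equal(domain_distance(c(1, 1, 1), c(1, 1, 1)), 0)

  expect_equal(hinge_com(c(0, 0, 0), c(2, 0, 0)), c(1, 0, 0))
  expect_equal(hinge_com(c(1, 2, 3), c(3, 2, 1)), c(2, 2, 2))
  expect_equal(hinge_com(c(1, 1, 1), c(1, 1, 1)), c(1, 1, 1))

  expect_equal(domain_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(domain_angle(c(-1, 0, 0), c(0, 0, 0), c(5, 0, 0)), 180)
  expect_error(domain_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")

  # planar cis -> 0, trans -> 180, sign convention checks
  expect_equal(domain_dihedral(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0),
                               c(1, 1, 0) + c(2, 0, 0)), 0)
  expect_equal(domain_dihedral(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0),
                               c(3, -1, 0)), 180)
})

test_that("circular dispersion matches closed forms", {
  cs <- circular_dispersion(c(45, 45, 45))
  expect_equal(cs$mean_resultant_R, 1, tolerance = 1e-12)
  expect_equal(cs$circular_sd, 0, tolerance = 1e-6)

  expect_warning(cs0 <- circular_dispersion(c(0, 180)), "infinite")
  expect_equal(cs0$mean_resultant_R, 0, tolerance = 1e-12)
  expect_equal(cs0$circular_sd, Inf)

  cs2 <- circular_dispersion(c(0, 90))
  expect_equal(cs2$mean_resultant_R, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(cs2$circular_sd, sqrt(-2 * log(sqrt(2) / 2)), tolerance = 1e-12)
  expect_equal(cs2$circular_sd, 0.8325546, tolerance = 1e-6)
})

test_that("conformational similarity is cos of the dihedral difference", {
  expect_equal(conformational_similarity(30, 30), 1)
  expect_equal(conformational_similarity(90, -90), -1)
  expect_equal(conformational_similarity(60, 0), 0.5, tolerance = 1e-12)
  # symmetric and 1 on the diagonal for arbitrary angles
  set.seed(1)
  for (a in runif(5, -180, 180)) {
    expect_equal(conformational_similarity(a, a), 1)
    b <- runif(1, -180, 180)
    expect_equal(conformational_similarity(a, b),
                 conformational_similarity(b, a))
  }
})

test_that("homodimer asymmetry flags large inter-monomer differences", {
  r <- homodimer_asymmetry(c(A = 32, B = 46))
  expect_true(r$asymmetric)
  expect_equal(unname(r$max_delta), 14)

  r2 <- homodimer_asymmetry(c(A = 44, B = 44.5))
  expect_false(r2$asymmetric)

  r3 <- homodimer_asymmetry(c(compact = 32, extended = 46),
                            predicted_epsilon = 42.7)
  expect_equal(r3$nearest_state, "extended")
  expect_error(homodimer_asymmetry(c(A = 30)), "at least 2")
})

test_that("descriptors are rigid-invariant and DH flips sign under mirroring", {
  toy <- make_two_domain_toy(30, 40, 110, -70)
  ch <- toy$model$chains[["A"]]
  g0 <- domain_geometry(ch, toy$spans$DBD, toy$spans$LBD)
  set.seed(11)
  for (k in 1:3) {
    ch2 <- transform_chain(ch, random_rotation(), rnorm(3, sd = 20))
    g <- domain_geometry(ch2, toy$spans$DBD, toy$spans$LBD)
    expect_equal(g$epsilon, g0$epsilon, tolerance = 1e-9)
    expect_equal(g$theta, g0$theta, tolerance = 1e-9)
    expect_equal(g$dihedral, g0$dihedral, tolerance = 1e-9)
  }
  # mirror through the xy-plane: epsilon and theta unchanged, DH negated
  at <- ch$atoms
  at$z <- -at$z
  gm <- domain_geometry(chain_model("A", at, ch$source_kind),
                        toy$spans$DBD, toy$spans$LBD)
  expect_equal(gm$epsilon, g0$epsilon, tolerance = 1e-9)
  expect_equal(gm$theta, g0$theta, tolerance = 1e-9)
  expect_equal(gm$dihedral, -g0$dihedral, tolerance = 1e-9)
})

test_that("two-domain toys recover their prescribed descriptors", {
  cases <- list(c(50, 120, -90), c(35, 60, 170), c(45, 95, -30))
  for (tg in cases) {
    toy <- make_two_domain_toy(30, tg[1], tg[2], tg[3])
    g <- domain_geometry(toy$model$chains[["A"]], toy$spans$DBD,
                         toy$spans$LBD)
    expect_equal(g$epsilon, tg[1], tolerance = 1e-6)
    expect_equal(g$theta, tg[2], tolerance = 1e-6)
    expect_equal(g$dihedral, tg[3], tolerance = 1e-6)
  }
  expect_error(make_two_domain_toy(30, 50, 0, 10), "strictly inside")
})
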