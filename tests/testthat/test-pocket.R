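test_that("pocket lining obeys the distance cutoff exactly", {
  # one ligand atom, two protein atoms at 4.9 and 5.1 A
  at <- data.frame(auth_seq = 1:2, icode = "", res_name = "ALA",
                   name = c("CA", "CB"), element = "C",
                   x = c(4.9, 5.1), y = 0, z = 0, b = 0, occ = 1, altloc = "",
                   stringsAsFactors = FALSE)
  lig <- data.frame(chain = "A", auth_seq = 99L, icode = "",
                    res_name = "LIG", name = "C1", element = "C",
                    x = 0, y = 0, z = 0, b = 0, occ = 1, altloc = "",
                    stringsAsFactors = FALSE)
  m <- structure_model("t", list(chain_model("A", at, "experimental")), lig)
  pd <- define_pocket(m, lig, cutoff = 5)
  expect_equal(nrow(pd$lining_atoms), 1)
  expect_equal(pd$lining_atoms$x, 4.9)

  expect_error(define_pocket(m, lig, cutoff = 0.0), "empty lining")
  expect_error(define_pocket(m, lig[0, ]), "empty ligand")

  # overlapping shells of a two-atom ligand: union without duplicates
  lig2 <- rbind(lig, within(lig, x <- 0.5))
  pd2 <- define_pocket(m, lig2, cutoff = 5)
  expect_equal(nrow(pd2$lining_atoms), 2)
  expect_equal(anyDuplicated(pd2$lining_atoms), 0)
})

test_that("SES of an isolated atom equals its vdW sphere", {
  va <- ses_volume_area(list(xyz = matrix(0, 1, 3), radii = 1.9),
                        voxel = 0.15)
  expect_equal(va$V, 4 / 3 * pi * 1.9^3, tolerance = 0.02)
  expect_equal(va$A, 4 * pi * 1.9^2, tolerance = 0.03)
  expect_error(ses_volume_area(list(xyz = matrix(0, 0, 3), radii = numeric(0))),
               "empty")
  expect_error(ses_volume_area(list(xyz = matrix(0, 1, 3), radii = 1.9),
                               voxel = 2), "voxel")
})

test_that("the spherical cavity fixture recovers its analytic volume", {
  cav <- make_spherical_cavity(5)
  pm <- pocket_metrics(cav, cav$hetero_groups, cutoff = 8)
  expect_true(pm$found)
  expect_false(pm$leaked)
  expect_equal(pm$volume, 4 / 3 * pi * 125, tolerance = 0.05)
  expect_equal(pm$sphericity, 1.0, tolerance = 0.03)
  expect_equal(pm$effective_radius, 5, tolerance = 0.05 * 5)

  cav3 <- make_spherical_cavity(3)
  pm3 <- pocket_metrics(cav3, cav3$hetero_groups, cutoff = 6)
  expect_equal(pm3$volume, 4 / 3 * pi * 27, tolerance = 0.05)

  expect_error(make_spherical_cavity(1.0), "probe")
})

test_that("voxel refinement converges: halving the voxel changes V by < 2%", {
  cav <- make_spherical_cavity(5)
  v1 <- pocket_metrics(cav, cav$hetero_groups, cutoff = 8, voxel = 0.4)$volume
  v2 <- pocket_metrics(cav, cav$hetero_groups, cutoff = 8, voxel = 0.2)$volume
  expect_lt(abs(v2 - v1) / v1, 0.02)
})

test_that("sphericity and effective radius match closed forms", {
  # unit sphere
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1, tolerance = 1e-12)
  expect_equal(effective_radius(4 * pi / 3, 4 * pi), 1, tolerance = 1e-12)
  # cube of side 2
  expect_equal(sphericity(8, 24), (pi / 6)^(1 / 3), tolerance = 1e-12)
  expect_equal(sphericity(8, 24), 0.8060, tolerance = 1e-4)
  expect_equal(effective_radius(8, 24), 1)
  # sphere of radius 2
  expect_equal(effective_radius(4 / 3 * pi * 8, 4 * pi * 4), 2,
               tolerance = 1e-12)
  expect_error(sphericity(0, 1), "positive")
  expect_error(effective_radius(1, 0), "positive")
})

test_that("computed pockets respect the isoperimetric bound and rigid invariance", {
  cav <- make_spherical_cavity(4, shell_atom_count = 400)
  pm <- pocket_metrics(cav, cav$hetero_groups, cutoff = 7)
  expect_lte(pm$sphericity, 1 + 0.05)   # voxel tolerance on the bound

  # rotate + translate the whole structure: Psi and r_eff unchanged
  ch <- cav$chains[["A"]]
  set.seed(9)
  R <- random_rotation(); tr <- rnorm(3, sd = 15)
  ch2 <- transform_chain(ch, R, tr)
  lig <- cav$hetero_groups
  xyz <- cbind(lig$x, lig$y, lig$z) %*% t(R) +
    matrix(tr, nrow(lig), 3, byrow = TRUE)
  lig$x <- xyz[, 1]; lig$y <- xyz[, 2]; lig$z <- xyz[, 3]
  cav2 <- structure_model("rot", list(ch2), lig)
  pm2 <- pocket_metrics(cav2, lig, cutoff = 7)
  expect_equal(pm2$sphericity, pm$sphericity, tolerance = 0.02)
  expect_equal(pm2$effective_radius, pm$effective_radius, tolerance = 0.02)
  expect_equal(pm2$volume, pm$volume, tolerance = 0.02)
})

test_that("merged ligand references are returned in the apo frame", {
  toy <- make_two_domain_toy(30, 40, 100, -60)
  apo <- toy$model$chains[["A"]]
  lig <- data.frame(chain = "A", auth_seq = 500L, icode = "",
                    res_name = "LIG", name = c("C1", "C2"), element = "C",
                    x = c(10, 11), y = c(5, 5), z = c(2, 2.5),
                    b = 0, occ = 1, altloc = "", stringsAsFactors = FALSE)
  # identical holo: merged set is the ligand unchanged
  m1 <- merged_ligand_reference(apo, list(apo), list(lig), toy$spans$LBD)
  expect_equal(m1$x, lig$x, tolerance = 1e-9)

  # holo rotated 90 degrees about z: the transform must be undone
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  holo <- transform_chain(apo, R, c(3, -1, 2))
  lig_h <- lig
  xyz <- cbind(lig$x, lig$y, lig$z) %*% t(R) +
    matrix(c(3, -1, 2), 2, 3, byrow = TRUE)
  lig_h$x <- xyz[, 1]; lig_h$y <- xyz[, 2]; lig_h$z <- xyz[, 3]
  m2 <- merged_ligand_reference(apo, list(holo), list(lig_h), toy$spans$LBD)
  expect_equal(m2$x, lig$x, tolerance = 1e-6)
  expect_equal(m2$z, lig$z, tolerance = 1e-6)

  # two holos with identical poses: copies are retained, not deduplicated
  m3 <- merged_ligand_reference(apo, list(apo, apo), list(lig, lig),
                                toy$spans$LBD)
  expect_equal(nrow(m3), 4)
})

test_that("normalization and deviation percentages are plain ratios", {
  expect_equal(pocket_normalization(100, 100), 100)
  expect_equal(pocket_normalization(163.5, 100), 163.5)
  expect_equal(pocket_normalization(50, 100), 50)
  expect_error(pocket_normalization(1, 0), "positive")

  expect_equal(pocket_deviation(100, 100), 0)
  expect_equal(pocket_deviation(90, 100), -10)
  expect_equal(pocket_deviation(120, 100), 20)
  expect_error(pocket_deviation(1, 0), "nonzero")
})
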