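test_that("torsions of the ideal helix recover the construction angles", {
  tor <- backbone_torsions(make_ideal_helix(20))
  interior <- tor[2:19, ]
  expect_equal(interior$phi, rep(-57, 18), tolerance = 1e-6)
  expect_equal(tor$psi[1:19], rep(-47, 19), tolerance = 1e-6)
  expect_true(is.na(tor$phi[1]))     # no preceding C at the chain start
  expect_true(is.na(tor$psi[20]))    # no following N at the chain end
})

test_that("chain breaks make flanking angles undefined", {
  h <- make_ideal_helix(20)
  at <- h$atoms
  sel <- at$auth_seq > 10
  at$x[sel] <- at$x[sel] + 100
  broken <- chain_model("A", at, "predicted")
  tor <- backbone_torsions(broken)
  expect_true(is.na(tor$psi[tor$auth_seq == 10]))
  expect_true(is.na(tor$phi[tor$auth_seq == 11]))
  expect_false(is.na(tor$phi[tor$auth_seq == 10]))
})

test_that("residue classes route glycine, proline and neighbors correctly", {
  h <- make_ideal_helix(8)
  at <- h$atoms
  at$res_name[at$auth_seq == 3] <- "GLY"
  at$res_name[at$auth_seq == 5] <- "PRO"
  at$res_name[at$auth_seq == 6] <- "VAL"
  tor <- backbone_torsions(chain_model("A", at, "predicted"))
  expect_equal(tor$residue_class[3], "glycine")
  expect_equal(tor$residue_class[4], "pre-proline")  # residue before PRO
  expect_equal(tor$residue_class[5], "proline")
  expect_equal(tor$residue_class[6], "ile-val")
  expect_equal(tor$residue_class[2], "general")
})

test_that("wrapped differences stay inside (-180, 180]", {
  expect_equal(wrapped_diff(179, -179), -2)
  expect_equal(abs(wrapped_diff(179, -179)), 2)
  expect_equal(wrapped_diff(-179, 179), 2)
  expect_equal(wrapped_diff(10, 10), 0)
  expect_equal(wrapped_diff(180, 0), 180)
  # antisymmetry
  set.seed(3)
  a <- runif(20, -180, 180); b <- runif(20, -180, 180)
  expect_equal(wrapped_diff(a, b), -wrapped_diff(b, a))
  expect_true(all(abs(wrapped_diff(a, b)) <= 180))
})

test_that("1-D Wasserstein distance matches sorted-sample oracles", {
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(10, 25), 15)
  # equal-size oracle: mean |sorted difference|
  set.seed(3)
  a <- runif(500, -180, 180)
  b <- runif(500, -180, 180)
  expect_equal(wasserstein_1d(a, b), mean(abs(sort(a) - sort(b))),
               tolerance = 1e-9)
  # shift recovery
  a <- runif(1000, -90, 90)
  expect_equal(wasserstein_1d(a + 7, a), 7, tolerance = 1e-9)
  # symmetry and triangle inequality
  c_s <- runif(200, -180, 180)
  a_s <- a[1:200]
  b_s <- b[1:200]
  expect_equal(wasserstein_1d(a_s, b_s), wasserstein_1d(b_s, a_s))
  expect_lte(wasserstein_1d(a_s, b_s),
             wasserstein_1d(a_s, c_s) + wasserstein_1d(c_s, b_s) + 1e-9)
  expect_error(wasserstein_1d(numeric(0), 1), "empty")
})

test_that("torsion comparison metrics respond to shifts and wraps", {
  te <- backbone_torsions(make_ideal_helix(30))
  cmp0 <- torsion_comparison(te, te)
  expect_equal(cmp0$phi$rmsd, 0)
  expect_equal(cmp0$psi$mae, 0)
  expect_equal(cmp0$phi$pearson, 1, tolerance = 1e-6)

  # constant +10 degree shift on psi (no wrap crossing)
  tp <- te
  tp$psi <- tp$psi + 10
  cmp <- torsion_comparison(te, tp)
  expect_equal(cmp$psi$mae, 10, tolerance = 1e-9)
  expect_equal(cmp$psi$wasserstein, 10, tolerance = 1e-9)
  expect_equal(cmp$psi$rmsd, 10, tolerance = 1e-9)

  # wrap rule: 179 vs -179 differ by 2 degrees, not 358
  ta <- te; tb <- te
  ta$phi[5:20] <- 179
  tb$phi[5:20] <- -179
  cmpw <- torsion_comparison(ta, tb)
  expect_lt(cmpw$phi$mae, 179 * mean(!is.na(ta$phi)))
  d <- wrapped_diff(179, -179)
  expect_equal(abs(d), 2)

  short <- te[1:5, ]
  expect_error(torsion_comparison(short, short), "fewer than 10")
})

test_that("Ramachandran classification routes classes and scores basins", {
  expect_equal(ramachandran_classify(-63, -43, "general"), "favored")
  expect_equal(ramachandran_classify(-120, 140, "general"), "favored")
  expect_equal(ramachandran_classify(60, -120, "general"), "outlier")
  # glycine at (90, 0) uses the glycine table: near its left-handed basin
  g <- ramachandran_classify(90, 0, "glycine")
  expect_true(g %in% c("favored", "allowed"))
  expect_equal(ramachandran_classify(90, 0, "general"), "outlier")
  expect_error(ramachandran_classify(NA, 0), "undefined")

  # tallies partition classifiable residues
  tor <- backbone_torsions(make_ideal_helix(30))
  tal <- ramachandran_tally(tor)
  expect_equal(tal$n_classified, sum(!is.na(tor$phi) & !is.na(tor$psi)))
  expect_equal(tal$favored_pct, 100)  # ideal helix sits in the alpha basin
  expect_equal(tal$outlier_count, 0)

  # identical chains classify identically residue-by-residue
  tal2 <- ramachandran_tally(backbone_torsions(make_ideal_helix(30)))
  expect_identical(tal$classes, tal2$classes)
})
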