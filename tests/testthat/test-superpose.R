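test_that("Kabsch superposition handles exact and rigid-shifted inputs", {
  set.seed(1)
  m <- matrix(rnorm(15), 5, 3)
  fit <- kabsch_superpose(m, m)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  shifted <- m + matrix(c(5, 0, 0), 5, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(m, shifted)$rmsd, 0, tolerance = 1e-12)

  expect_error(kabsch_superpose(m, m[1:4, ]), "differ in size")
  expect_error(kabsch_superpose(m[1:2, ], m[1:2, ]), "at least 3")
})

test_that("Kabsch equals the independent quaternion oracle on noisy instances", {
  set.seed(1)
  m <- matrix(rnorm(30), 10, 3)
  R0 <- random_rotation()
  tgt <- m %*% t(R0) + matrix(rnorm(30, sd = 0.1), 10, 3)
  fit <- kabsch_superpose(m, tgt)
  expect_equal(fit$rmsd, horn_rmsd(m, tgt), tolerance = 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # property: agreement to 1e-8 over many random small instances
  worst <- 0
  for (k in 1:1000) {
    n <- sample(4:12, 1)
    a <- matrix(rnorm(3 * n), n, 3)
    b <- a %*% t(random_rotation()) + rep(rnorm(3, sd = 4), each = n) +
      matrix(rnorm(3 * n, sd = 0.2), n, 3)
    worst <- max(worst, abs(kabsch_superpose(a, b)$rmsd - horn_rmsd(a, b)))
  }
  expect_lt(worst, 1e-8)
})

test_that("RMSD is invariant under rigid transforms of either input", {
  set.seed(7)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.3), 10, 3)
  base <- kabsch_superpose(a, b)$rmsd
  for (k in 1:5) {
    Ra <- random_rotation(); Rb <- random_rotation()
    a2 <- a %*% t(Ra) + rep(rnorm(3, sd = 10), each = 10)
    b2 <- b %*% t(Rb) + rep(rnorm(3, sd = 10), each = 10)
    expect_equal(kabsch_superpose(a2, b)$rmsd, base, tolerance = 1e-9)
    expect_equal(kabsch_superpose(a, b2)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("iterative rejection removes displaced atoms and never raises RMSD", {
  h <- make_ideal_helix(20)
  span <- domain_span("DBD", 1, 20)
  shifted <- transform_chain(h, diag(3), c(3, -2, 1))
  fit <- refined_superpose(shifted, h, span, "ca")
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$cycles_run, 1L)

  # displace one CA by 10 A: with a 2 A cutoff that pair must go
  at <- h$atoms
  at$x[at$name == "CA" & at$auth_seq == 10] <-
    at$x[at$name == "CA" & at$auth_seq == 10] + 10
  bumped <- chain_model("A", at, h$source_kind)
  fit2 <- refined_superpose(bumped, h, span, "ca", reject_cutoff = 2)
  expect_equal(fit2$n_rejected, 1L)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-6)
  # oracle: plain fit on the remaining 19 pairs
  keep <- setdiff(1:20, 10)
  xyz_of <- function(df) cbind(df$x, df$y, df$z)
  xm <- xyz_of(select_domain(bumped, span, "ca"))[keep, ]
  xt <- xyz_of(select_domain(h, span, "ca"))[keep, ]
  expect_equal(fit2$rmsd, kabsch_superpose(xm, xt)$rmsd, tolerance = 1e-9)

  # max_cycles = 0 keeps every pair (plain Kabsch)
  fit0 <- refined_superpose(bumped, h, span, "ca", max_cycles = 0)
  expect_equal(fit0$n_pairs, 20L)
  expect_gte(fit0$rmsd, fit2$rmsd)

  expect_error(refined_superpose(bumped, h, span, "ca",
                                 reject_cutoff = 1e-12),
               "over-trimmed")
})

test_that("rmsd_triple separates side-chain from backbone deviation", {
  toy <- make_two_domain_toy(30, 40, 100, -60)
  ch <- toy$model$chains[["A"]]
  span <- toy$spans$DBD
  tr <- rmsd_triple(ch, ch, span)
  expect_equal(c(tr$all_atom, tr$backbone, tr$c_alpha), c(0, 0, 0),
               tolerance = 1e-9)

  # perturb only carbonyl O atoms: all-atom and backbone move, CA does not
  at <- ch$atoms
  sel <- at$name == "O" & at$auth_seq <= span$end
  set.seed(3)
  at$x[sel] <- at$x[sel] + rnorm(sum(sel), sd = 0.4)
  pert <- chain_model("A", at, ch$source_kind)
  tr2 <- rmsd_triple(ch, pert, span)
  expect_gt(tr2$all_atom, 0.05)
  expect_equal(tr2$c_alpha, 0, tolerance = 1e-6)
  expect_gt(tr2$all_atom, tr2$c_alpha)
})

test_that("the RMSD hierarchy check is strict", {
  expect_true(hierarchy_check(list(all_atom = 0.50, backbone = 0.40,
                                   c_alpha = 0.35)))
  expect_false(hierarchy_check(list(all_atom = 0.40, backbone = 0.45,
                                    c_alpha = 0.30)))
  expect_false(hierarchy_check(list(all_atom = 0.40, backbone = 0.40,
                                    c_alpha = 0.30)))
  expect_error(hierarchy_check(list(all_atom = NA, backbone = 1,
                                    c_alpha = 1)), "non-finite")
})
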