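test_that("a deathless, transition-free cohort lives the whole window", {
  P <- array(0, c(10, 8, 3, 3))
  P[, , 1, 1] <- 1; P[, , 2, 2] <- 1; P[, , 3, 3] <- 1
  m <- transition_matrix_set(P, 80:89)
  b <- uniform_baseline(0)
  e <- microsimulate(m, b, c(80, 89), n = 2000, seed = 1)
  expect_equal(e$total_le, 10)
  expect_equal(e$dfle, 10)
  o <- occupancy_oracle(m, b, c(80, 89))
  expect_equal(o$total_le, 10)
})

test_that("constant-mortality occupancy matches the closed form", {
  m <- constant_death_matrices(0.1)
  b <- uniform_baseline(0)
  closed <- (1 - 0.1 / 2) * (1 - 0.9^10) / 0.1
  o <- occupancy_oracle(m, b, c(80, 89))
  expect_equal(o$total_le, closed, tolerance = 1e-12)
  s <- microsimulate(m, b, c(80, 89), n = 100000, seed = 33)
  expect_lt(abs(s$total_le - closed), 3 * s$se[["total_le"]])
})

test_that("microsimulation agrees with the oracle on random dynamics", {
  for (seed in 1:5) {
    m <- random_matrices(seed)
    b <- uniform_baseline(0.3)
    o <- occupancy_oracle(m, b, c(80, 89))
    s <- microsimulate(m, b, c(80, 89), n = 20000, seed = 100 + seed)
    for (q in c("total_le", "dfle", "disabled_le"))
      expect_lt(abs(s[[q]] - o[[q]]), 3 * s$se[[q]] + 1e-9)
    # accounting identity holds exactly for both
    expect_equal(s$total_le, s$dfle + s$disabled_le)
    expect_equal(o$total_le, o$dfle + o$disabled_le)
  }
})

test_that("Monte-Carlo error shrinks like 1/sqrt(n)", {
  m <- random_matrices(7)
  b <- uniform_baseline(0.25)
  o <- occupancy_oracle(m, b, c(80, 89))
  ns <- c(1e3, 1e4, 1e5)
  errs <- ses <- numeric(3)
  for (i in seq_along(ns)) {
    s <- microsimulate(m, b, c(80, 89), n = ns[i], seed = 50 + i)
    errs[i] <- abs(s$total_le - o$total_le)
    ses[i] <- s$se[["total_le"]]
    expect_lt(errs[i], 4 * ses[i])
  }
  # standard errors scale as 1/sqrt(n) (ratio 10 per decade, within 50%)
  expect_lt(ses[3], ses[1] / 5)
  expect_gt(ses[3], ses[1] / 20)
})

test_that("simulated individuals never leave the dead state", {
  # lethal first year: everyone dies at the window's first age
  P <- array(0, c(3, 8, 3, 3))
  P[, , 1, 3] <- 1; P[, , 2, 3] <- 1; P[, , 3, 3] <- 1
  m <- transition_matrix_set(P, 80:82)
  e <- microsimulate(m, uniform_baseline(0.5), c(80, 82), n = 5000, seed = 2,
                     keep_tallies = TRUE)
  # only the half-year death credit is ever accumulated
  expect_equal(e$total_le, 0.5)
  expect_true(all(e$tallies$occ_nd + e$tallies$occ_dis == 0.5))
})

test_that("profile relabelling leaves occupancy unchanged", {
  m <- random_matrices(11)
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  P2 <- m$P[, perm, , , drop = FALSE]
  m2 <- transition_matrix_set(P2, m$ages)
  mass <- cbind(seq(0.05, 0.12, length.out = 8),
                seq(0.08, 0.01, length.out = 8))
  b <- baseline_dist(mass)
  b2 <- baseline_dist(mass[perm, , drop = FALSE])
  o1 <- occupancy_oracle(m, b, c(80, 89))
  o2 <- occupancy_oracle(m2, b2, c(80, 89))
  expect_equal(o1$dfle, o2$dfle, tolerance = 1e-12)
  expect_equal(o1$disabled_le, o2$disabled_le, tolerance = 1e-12)
})

test_that("death-year credit convention is honoured by both engines", {
  m <- constant_death_matrices(0.2, ages = 80:84)
  b <- uniform_baseline(0)
  for (credit in c(0, 0.5, 1)) {
    o <- occupancy_oracle(m, b, c(80, 84), death_credit = credit)
    closed <- sum(0.8^(0:4) * (0.8 + credit * 0.2))
    expect_equal(o$total_le, closed, tolerance = 1e-12)
    s <- microsimulate(m, b, c(80, 84), n = 50000, seed = 9,
                       death_credit = credit)
    expect_lt(abs(s$total_le - closed), 3 * s$se[["total_le"]] + 1e-9)
  }
})

test_that("end-of-life adjustment conserves totals and shifts credit", {
  models <- study_true_model("octogenarian", "earlier")
  m <- transition_matrices(models$nondisabled, models$disabled, 80:89)
  b <- uniform_baseline(0.173)
  e <- microsimulate(m, b, c(80, 89), n = 20000, seed = 14,
                     keep_tallies = TRUE)
  adj <- end_of_life_adjustment(e, seed = 5)
  expect_s3_class(adj, "mslt_sensitivity")
  expect_equal(adj$adjusted$total_le, adj$unadjusted$total_le)
  expect_lt(adj$adjusted$dfle, adj$unadjusted$dfle)
  expect_gt(adj$adjusted$disabled_le, adj$unadjusted$disabled_le)
  expect_equal(adj$unadjusted$dfle - adj$adjusted$dfle,
               adj$adjusted$disabled_le - adj$unadjusted$disabled_le,
               tolerance = 1e-12)

  # expected DFLE reduction per nondisabled death is E(u) * 0.5 = 0.25
  n_nd_death <- sum(e$tallies$death_origin == 1L)
  expected <- 0.25 * n_nd_death / e$n_simulated
  observed <- adj$unadjusted$dfle - adj$adjusted$dfle
  mc_se <- 0.5 * sqrt(1 / 12) * sqrt(n_nd_death) / e$n_simulated
  expect_lt(abs(observed - expected), 4 * mc_se)

  # no deaths: adjustment is the identity
  P <- array(0, c(10, 8, 3, 3))
  P[, , 1, 1] <- 1; P[, , 2, 2] <- 1; P[, , 3, 3] <- 1
  e0 <- microsimulate(transition_matrix_set(P, 80:89), b, c(80, 89),
                      n = 1000, seed = 3, keep_tallies = TRUE)
  adj0 <- end_of_life_adjustment(e0, seed = 4)
  expect_equal(adj0$adjusted$dfle, adj0$unadjusted$dfle)

  # tallies are required
  e_nt <- microsimulate(m, b, c(80, 89), n = 1000, seed = 3)
  expect_error(end_of_life_adjustment(e_nt), "tallies")
})
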