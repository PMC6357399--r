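ref_profile <- data.frame(age = 80, sex = "man", residence = "urban",
                          schooling = "some", stringsAsFactors = FALSE)

test_that("cumulative-logit inversion gives the right category probabilities", {
  zero <- c(alpha1 = 0, alpha2 = log(3), age = 0, woman1 = 0, woman2 = 0,
            rural1 = 0, rural2 = 0, unschooled1 = 0, unschooled2 = 0)
  m <- ppo_params(zero, "nondisabled", age_center = 80)
  p <- predict(m, ref_profile)
  expect_equal(unname(p[1, ]), c(0.5, 0.25, 0.25), tolerance = 1e-12)

  # equal cutpoints collapse the middle category
  eq <- zero; eq["alpha2"] <- 0
  p2 <- predict(ppo_params(eq, "nondisabled", age_center = 80), ref_profile)
  expect_equal(unname(p2[1, 2]), 0)

  # normalization over a full age x profile grid
  g <- profile_grid()
  nd <- expand.grid(age = 80:95, i = 1:8)
  nd <- data.frame(age = nd$age, g[nd$i, c("sex", "residence", "schooling")])
  m2 <- study_true_model("octogenarian", "earlier")$nondisabled
  probs <- predict(m2, nd)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))
  expect_true(all(probs >= 0))
})

test_that("crossed cumulative curves beyond tolerance are an error", {
  bad <- c(alpha1 = 0.5, alpha2 = 0.6, age = 0, woman1 = 2, woman2 = -2,
           rural1 = 0, rural2 = 0, unschooled1 = 0, unschooled2 = 0)
  m <- ppo_params(bad, "nondisabled", age_center = 80)
  nd <- data.frame(age = 80, sex = "woman", residence = "urban",
                   schooling = "some")
  expect_error(predict(m, nd), "cross")
})

test_that("the intercept-only MLE equals empirical cumulative frequencies", {
  py <- data.frame(id = as.character(1:40),
                   age = 80L, origin = "nondisabled",
                   dest = rep(c("nondisabled", "disabled", "dead"),
                              times = c(22, 11, 7)),
                   sex = "man", residence = "urban", schooling = "some",
                   weight = rep(c(1, 2), length.out = 40),
                   cohort = "t", stringsAsFactors = FALSE)
  class(py) <- c("person_years", "data.frame")
  fit <- fit_ppo(py, "nondisabled",
                 terms = ppo_terms(relaxed = character(), age = FALSE))
  W <- tapply(py$weight, py$dest, sum)[c("nondisabled", "disabled", "dead")]
  c1 <- W[[1]] / sum(W); c2 <- (W[[1]] + W[[2]]) / sum(W)
  expect_equal(unname(plogis(coef(fit)[["alpha1"]])), c1, tolerance = 1e-8)
  expect_equal(unname(plogis(coef(fit)[["alpha2"]])), c2, tolerance = 1e-8)
})

test_that("the optimum dominates the truth and random perturbations", {
  truth <- study_true_model("octogenarian", "earlier")$nondisabled
  py <- sample_person_years(truth, 5000, seed = 12)
  fit <- fit_ppo(py, "nondisabled", age_center = 80)
  cells <- cohortmslt:::ppo_cells(py, "nondisabled")
  des <- cohortmslt:::ppo_design(cells$age - 80, cells$z, fit$terms)
  ll <- function(th) cohortmslt:::ppo_loglik(th, des$X1, des$X2, cells$W)
  ll_opt <- ll(coef(fit))
  expect_gte(ll_opt, ll(truth$coefficients))
  set.seed(99)
  for (i in 1:100) {
    pert <- coef(fit) + rnorm(length(coef(fit)), sd = 0.05)
    expect_gte(ll_opt, ll(pert))
  }
})

test_that("the proportional-odds restriction matches an independent fit", {
  skip_if_not_installed("MASS")
  truth <- study_true_model("octogenarian", "earlier")$nondisabled
  py <- sample_person_years(truth, 4000, seed = 5)
  fit <- fit_ppo(py, "nondisabled",
                 terms = ppo_terms(relaxed = character(),
                                   shared = c("woman", "rural", "unschooled")),
                 age_center = 80)
  d <- data.frame(y = factor(py$dest,
                             levels = c("nondisabled", "disabled", "dead"),
                             ordered = TRUE),
                  a = py$age - 80,
                  woman = as.numeric(py$sex == "woman"),
                  rural = as.numeric(py$residence == "rural"),
                  unschooled = as.numeric(py$schooling == "none"))
  ref <- MASS::polr(y ~ a + woman + rural + unschooled, data = d)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  # same parameterization up to sign convention on the slopes
  expect_equal(unname(coef(fit)[c("age", "woman", "rural", "unschooled")]),
               unname(-coef(ref)), tolerance = 1e-4)
})

test_that("the Newton optimum matches a derivative-free search on tiny data", {
  # 24 person-years over 2 ages x 2 sexes with every outcome represented in
  # every cell, so the tiny-sample MLE is interior
  dests <- c("nondisabled", "nondisabled", "nondisabled", "disabled",
             "disabled", "dead")
  py <- expand.grid(age = 80:81, sex = c("man", "woman"), k = 1:6,
                    stringsAsFactors = FALSE)
  py <- data.frame(id = as.character(seq_len(nrow(py))), age = py$age,
                   origin = "nondisabled", dest = dests[py$k],
                   sex = py$sex, residence = "urban", schooling = "some",
                   weight = 1, cohort = "t", stringsAsFactors = FALSE)
  py$dest[py$age == 81 & py$sex == "woman" & py$dest == "dead"] <- "disabled"
  class(py) <- c("person_years", "data.frame")
  terms <- ppo_terms(relaxed = "woman")
  fit <- fit_ppo(py, "nondisabled", terms = terms, age_center = 80)
  cells <- cohortmslt:::ppo_cells(py, "nondisabled")
  des <- cohortmslt:::ppo_design(cells$age - 80, cells$z, terms)
  nll <- function(th) -cohortmslt:::ppo_loglik(th, des$X1, des$X2, cells$W)
  best <- optim(coef(fit) + 0.3, nll, method = "Nelder-Mead",
                control = list(maxit = 20000, reltol = 1e-14))
  expect_lte(-nll(coef(fit)) - (-best$value), 1e-8)  # Newton at least as good
  expect_equal(unname(coef(fit)), unname(best$par), tolerance = 1e-3)
})

test_that("auxiliary age terms are kept and dropped at the right rates", {
  truth_lin <- study_true_model("octogenarian", "earlier")$nondisabled
  n_rep <- 50
  keep_age2 <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    py <- sample_person_years(truth_lin, 4000, seed = 300 + i)
    rep_t <- test_extra_terms(py, "nondisabled", age_center = 80)
    expect_true(all(is.finite(rep_t$std_error)))
    keep_age2[i] <- rep_t$keep[rep_t$term == "age2"]
  }
  # type-I error control at the 5% level (3 binomial SEs of slack)
  expect_lte(sum(keep_age2), ceiling(n_rep * 0.05 + 3 * sqrt(n_rep * 0.05 * 0.95)))

  # power against a strong age x sex interaction
  strong <- truth_lin
  strong$terms <- ppo_terms(age_sex = TRUE)
  strong$coefficients <- c(strong$coefficients["alpha1"],
                           strong$coefficients["alpha2"],
                           age = unname(strong$coefficients["age"]),
                           age_woman = -0.12,
                           strong$coefficients[c("woman1", "woman2", "rural1",
                                                 "rural2", "unschooled1",
                                                 "unschooled2")])
  kept <- logical(20)
  for (i in 1:20) {
    py <- sample_person_years(strong, 8000, seed = 600 + i)
    rep_t <- test_extra_terms(py, "nondisabled", age_center = 80)
    kept[i] <- rep_t$keep[rep_t$term == "age_woman"]
  }
  expect_gte(mean(kept), 0.9)
})

test_that("matrix sets are row-stochastic with absorbing death", {
  models <- study_true_model("nonagenarian", "later")
  m <- transition_matrices(models$nondisabled, models$disabled, 90:99)
  rs <- apply(m$P, c(1, 2, 3), sum)
  expect_true(all(abs(rs - 1) < 1e-12))
  expect_true(all(m$P[, , 3, 3] == 1))

  # pushing the upper cutpoint to +inf sends death probabilities to zero
  nd <- models$nondisabled
  nd$coefficients["alpha2"] <- 40
  d <- models$disabled
  d$coefficients["alpha2"] <- 40
  m2 <- transition_matrices(nd, d, 90:99)
  expect_true(all(m2$P[, , 1:2, 3] < 1e-12))
})
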