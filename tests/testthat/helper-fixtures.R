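# Shared fixtures: all synthetic, built in code.

# A small octogenarian-style generator config. No auxiliary covariate and no
# attrition unless asked for, so tests isolate one mechanism at a time.
quick_config <- function(n = 500, attrition = FALSE, aux = FALSE,
                         prevalence = 0.173, wave_offsets = c(0L, 2L, 4L),
                         sampling_weights = "unit") {
  panel_config(
    n = n, age_window = c(80L, 89L),
    baseline_disabled_prevalence = prevalence,
    wave_offsets = wave_offsets,
    true_model = study_true_model("octogenarian", "earlier"),
    profile_distribution = rep(1 / 8, 8),
    attrition = if (attrition)
      c(intercept = -1.6, woman = -0.1, rural = 0.3, unschooled = 0.2,
        disabled = 0.4, frail = if (aux) 1.2 else 0)
    else c(intercept = -Inf),
    aux = if (aux) list(prevalence = 0.3, transition_shift = 0.7) else NULL,
    sampling_weights = sampling_weights,
    cohort = "test_cohort")
}

# A deterministic degenerate truth: nobody dies, nobody transitions.
frozen_model <- function() {
  list(
    nondisabled = ppo_params(
      c(alpha1 = 30, alpha2 = 35, age = 0, woman1 = 0, woman2 = 0,
        rural1 = 0, rural2 = 0, unschooled1 = 0, unschooled2 = 0),
      "nondisabled", age_center = 80),
    disabled = ppo_params(
      c(alpha1 = -30, alpha2 = 35, age = 0, woman1 = 0, woman2 = 0,
        rural1 = 0, rural2 = 0, unschooled1 = 0, unschooled2 = 0),
      "disabled", age_center = 80))
}

# Transition-matrix set with constant annual death probability q from both
# living states and no disability transitions.
constant_death_matrices <- function(q, ages = 80:89) {
  P <- array(0, c(length(ages), 8, 3, 3))
  P[, , 1, 1] <- 1 - q
  P[, , 1, 3] <- q
  P[, , 2, 2] <- 1 - q
  P[, , 2, 3] <- q
  P[, , 3, 3] <- 1
  transition_matrix_set(P, ages)
}

# Random valid transition-matrix set (seeded), with dead absorbing.
random_matrices <- function(seed, ages = 80:89) {
  set.seed(seed)
  A <- length(ages)
  P <- array(0, c(A, 8, 3, 3))
  for (o in 1:2) {
    raw <- array(stats::rgamma(A * 8 * 3, shape = 1.5), c(A, 8, 3))
    tot <- raw[, , 1] + raw[, , 2] + raw[, , 3]
    for (d in 1:3) P[, , o, d] <- raw[, , d] / tot
  }
  P[, , 3, 3] <- 1
  transition_matrix_set(P, ages)
}

uniform_baseline <- function(p_disabled = 0.2) {
  baseline_dist(cbind(rep((1 - p_disabled) / 8, 8), rep(p_disabled / 8, 8)))
}

# Person-years sampled directly from a known transition model: ages uniform
# on age_range, profiles uniform over the 8 cells, destinations multinomial
# from the model's probabilities. Clean input for parameter-recovery tests.
sample_person_years <- function(model, n, seed, age_range = 80:89) {
  set.seed(seed)
  g <- profile_grid()
  pid <- sample.int(8, n, replace = TRUE)
  age <- sample(age_range, n, replace = TRUE)
  sex <- g$sex[pid]; residence <- g$residence[pid]; schooling <- g$schooling[pid]
  p <- predict(model, data.frame(age = age, sex = sex, residence = residence,
                                 schooling = schooling))
  u <- stats::runif(n)
  dest <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])
  out <- data.frame(id = sprintf("s%06d", seq_len(n)), age = age,
                    origin = model$origin,
                    dest = c("nondisabled", "disabled", "dead")[dest],
                    sex = sex, residence = residence, schooling = schooling,
                    weight = 1, cohort = "sampled",
                    stringsAsFactors = FALSE)
  class(out) <- c("person_years", "data.frame")
  out
}

# Person-years on a balanced factorial design (equal records per age x
# profile cell). With stratified = TRUE the outcome uniforms are stratified
# within each cell, so empirical cell frequencies match the model's
# probabilities up to O(1/per-cell-n): a noise-free design for checking
# that fitting inverts the truth.
balanced_person_years <- function(model, n, seed, ages = 80:89,
                                  stratified = FALSE) {
  g <- profile_grid()
  cells <- expand.grid(age = ages, pid = 1:8)
  per <- n %/% nrow(cells)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    a <- cells$age[i]; pid <- cells$pid[i]
    p <- predict(model, data.frame(age = a, sex = g$sex[pid],
                                   residence = g$residence[pid],
                                   schooling = g$schooling[pid]))
    u <- if (stratified) sample((seq_len(per) - stats::runif(per)) / per)
         else stats::runif(per)
    data.frame(age = a, pid = pid,
               dest = 1L + (u > p[1]) + (u > p[1] + p[2]))
  })
  df <- do.call(rbind, rows)
  out <- data.frame(id = as.character(seq_len(nrow(df))), age = df$age,
                    origin = model$origin,
                    dest = c("nondisabled", "disabled", "dead")[df$dest],
                    sex = g$sex[df$pid], residence = g$residence[df$pid],
                    schooling = g$schooling[df$pid], weight = 1,
                    cohort = "balanced", stringsAsFactors = FALSE)
  class(out) <- c("person_years", "data.frame")
  out
}

# Category-balanced truth used by recovery checks: every outcome has
# substantial mass at every age/profile, so all coefficients are
# well-identified.
recovery_truth <- function() {
  list(
    nondisabled = ppo_params(
      c(alpha1 = 0.3, alpha2 = 1.3, age = -0.06, woman1 = 0.25,
        woman2 = 0.35, rural1 = -0.2, rural2 = -0.25, unschooled1 = -0.3,
        unschooled2 = -0.2), "nondisabled", age_center = 80),
    disabled = ppo_params(
      c(alpha1 = -0.8, alpha2 = 0.6, age = -0.05, woman1 = -0.2,
        woman2 = 0.3, rural1 = -0.15, rural2 = -0.2, unschooled1 = -0.25,
        unschooled2 = -0.15), "disabled", age_center = 80))
}

# Hand-built two-person panel used by several I/O and expansion tests.
two_person_panel <- function() {
  individuals <- data.frame(
    id = c("a", "b"), baseline_age = c(80L, 85L),
    sex = c("man", "woman"), residence = c("urban", "rural"),
    schooling = c("some", "none"), sampling_weight = c(1, 1),
    dead = c(FALSE, TRUE),
    death_date = as.Date(c(NA, "1999-11-26")),  # baseline age 85 + 1.4 years
    lost = c(FALSE, FALSE), stringsAsFactors = FALSE)
  waves <- data.frame(
    id = c("a", "a", "b"), wave_index = c(1L, 2L, 1L),
    wave_date = as.Date(c("1998-07-01", "2000-07-01", "1998-07-01")),
    age = c(80L, 82L, 85L),
    state = c("nondisabled", "nondisabled", "disabled"),
    stringsAsFactors = FALSE)
  cohort_panel(individuals, waves, cohort = "fixture",
               age_window = c(80L, 89L), wave_offsets = c(0L, 2L, 4L))
}

expect_panels_equal <- function(p1, p2) {
  expect_equal(p1$individuals, p2$individuals)
  expect_equal(p1$waves, p2$waves)
  expect_identical(p1$cohort, p2$cohort)
}
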