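#' Configuration for the synthetic-panel generator
#'
#' Defines the ground-truth data-generating process for a synthetic birth
#' cohort: sample size, baseline age window, baseline disabled prevalence,
#' wave schedule, true annual transition dynamics (a pair of transition
#' models, one per origin state), the covariate-profile distribution, a
#' missing-at-random dropout model, an optional auxiliary binary covariate
#' that shifts both transition logits (unobserved by the transition model
#' but available to the attrition model), and a sampling-weight rule.
#'
#' @param n Number of individuals.
#' @param age_window `c(lower, upper)` baseline ages (integers, inclusive).
#' @param baseline_disabled_prevalence Probability of being disabled at the
#'   baseline wave.
#' @param wave_offsets Scheduled wave offsets in years from baseline,
#'   starting at 0 and strictly increasing (e.g. `c(0, 2, 4)`).
#' @param true_model List with elements `nondisabled` and `disabled`, each a
#'   [ppo_params()] model giving the true annual transition probabilities
#'   out of that state.
#' @param profile_distribution Length-8 probability vector over the
#'   covariate profiles in [profile_grid()] order; sums to 1.
#' @param attrition Named numeric vector of logistic coefficients for
#'   per-interval dropout: any of `intercept`, `woman`, `rural`,
#'   `unschooled`, `disabled` (state at interval start), `frail` (the
#'   auxiliary covariate), `sampling_weight`. Missing names mean 0; an
#'   `intercept` of `-Inf` disables dropout.
#' @param aux `NULL`, or a list describing the auxiliary covariate:
#'   `prevalence` (Bernoulli probability) and `transition_shift`
#'   (subtracted from both cumulative logits of both origin models for
#'   carriers, worsening their transitions).
#' @param sampling_weights `"unit"` (all 1) or `"two_stratum"`
#'   (rural-oversampling design: rural weight 1.4, urban 0.7).
#' @param baseline_date Calendar date of the baseline wave.
#' @param cohort Cohort label.
#' @return A validated list of class `panel_config`.
#' @export
panel_config <- function(n, age_window, baseline_disabled_prevalence,
                         wave_offsets, true_model, profile_distribution,
                         attrition = c(intercept = -Inf), aux = NULL,
                         sampling_weights = c("unit", "two_stratum"),
                         baseline_date = as.Date("1998-07-01"),
                         cohort = "synthetic") {
  sampling_weights <- match.arg(sampling_weights)
  stopifnot(n >= 1, length(age_window) == 2, age_window[1] <= age_window[2],
            baseline_disabled_prevalence >= 0,
            baseline_disabled_prevalence <= 1,
            wave_offsets[1] == 0, all(diff(wave_offsets) > 0),
            length(profile_distribution) == 8,
            all(profile_distribution >= 0),
            abs(sum(profile_distribution) - 1) < 1e-8,
            inherits(true_model$nondisabled, "ppo"),
            inherits(true_model$disabled, "ppo"))
  if (!is.null(aux))
    stopifnot(aux$prevalence >= 0, aux$prevalence <= 1,
              is.numeric(aux$transition_shift))
  structure(list(n = as.integer(n), age_window = as.integer(age_window),
                 baseline_disabled_prevalence = baseline_disabled_prevalence,
                 wave_offsets = as.integer(wave_offsets),
                 true_model = true_model,
                 profile_distribution = profile_distribution,
                 attrition = attrition, aux = aux,
                 sampling_weights = sampling_weights,
                 baseline_date = as.Date(baseline_date), cohort = cohort),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config> ", x$cohort, ": n = ", x$n, ", baseline ages ",
      x$age_window[1], "-", x$age_window[2], ", waves at +",
      paste(x$wave_offsets, collapse = "/+"), " years\n", sep = "")
  cat("  baseline disabled prevalence: ",
      100 * x$baseline_disabled_prevalence, "%\n", sep = "")
  invisible(x)
}

# Apply the auxiliary covariate's shared logit shift to a true model.
shift_ppo <- function(model, shift) {
  m <- model
  m$coefficients[c("alpha1", "alpha2")] <-
    m$coefficients[c("alpha1", "alpha2")] - shift
  m
}

attrition_lp <- function(coefs, z, disabled, frail, sampling_weight) {
  g <- function(nm) if (nm %in% names(coefs)) coefs[[nm]] else 0
  g("intercept") + g("woman") * z[, "woman"] + g("rural") * z[, "rural"] +
    g("unschooled") * z[, "unschooled"] + g("disabled") * disabled +
    g("frail") * frail + g("sampling_weight") * sampling_weight
}

#' Generate a synthetic disability panel with known truth
#'
#' Simulates each individual's annual disability/mortality path from their
#' baseline age using the configuration's true transition models, records
#' states only at the scheduled wave offsets, assigns death dates uniformly
#' within the death year, and applies missing-at-random dropout between
#' waves. Fully reproducible given `seed`.
#'
#' @param config A [panel_config()].
#' @param seed Integer seed.
#' @return A validated [cohort_panel()]; auxiliary covariates appear as
#'   `aux_*` columns of the individuals table.
#' @export
generate_panel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "panel_config"))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  n <- config$n
  g <- profile_grid()
  pid <- sample.int(8L, n, replace = TRUE, prob = config$profile_distribution)
  sex <- g$sex[pid]; residence <- g$residence[pid]; schooling <- g$schooling[pid]
  z <- profile_dummies(sex, residence, schooling)
  age0 <- sample(seq(config$age_window[1], config$age_window[2]), n,
                 replace = TRUE)
  state0 <- 1L + stats::rbinom(n, 1L, config$baseline_disabled_prevalence)
  frail <- if (is.null(config$aux)) integer(n)
           else stats::rbinom(n, 1L, config$aux$prevalence)
  sw <- switch(config$sampling_weights,
               unit = rep(1, n),
               two_stratum = ifelse(residence == "rural", 1.4, 0.7))

  models <- list(config$true_model$nondisabled, config$true_model$disabled)
  models_frail <- if (is.null(config$aux)) models
                  else lapply(models, shift_ppo, config$aux$transition_shift)

  max_off <- max(config$wave_offsets)
  states <- matrix(3L, n, max_off + 1L)  # state at integer offsets 0..max
  states[, 1] <- state0
  death_time <- rep(NA_real_, n)  # offset years from baseline, fractional

  for (t in seq_len(max_off)) {
    cur <- states[, t]
    nxt <- cur
    for (o in 1:2) {
      for (fr in unique(frail)) {
        sel <- which(cur == o & frail == fr)
        if (!length(sel)) next
        mod <- if (fr == 1L) models_frail[[o]] else models[[o]]
        p <- ppo_probs(mod, age0[sel] + (t - 1L), z[sel, , drop = FALSE])
        u <- stats::runif(length(sel))
        nxt[sel] <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])
      }
    }
    died <- which(cur != 3L & nxt == 3L)
    if (length(died))
      death_time[died] <- (t - 1L) + stats::runif(length(died), 0.01, 0.99)
    states[, t + 1L] <- nxt
  }

  # MAR dropout between consecutive scheduled waves: evaluated at the start
  # of each interval for individuals still alive and under observation.
  K <- length(config$wave_offsets)
  observed_until <- rep(K, n)  # last wave index under observation
  lost <- rep(FALSE, n)
  a_int <- if ("intercept" %in% names(config$attrition))
    config$attrition[["intercept"]] else -Inf
  if (K > 1 && is.finite(a_int)) {
    for (j in seq_len(K - 1L)) {
      off_j <- config$wave_offsets[j]
      at_risk <- which(observed_until == K & !lost &
                         states[, off_j + 1L] != 3L)
      if (!length(at_risk)) next
      lp <- attrition_lp(as.list(config$attrition),
                         z[at_risk, , drop = FALSE],
                         disabled = as.numeric(states[at_risk, off_j + 1L] == 2L),
                         frail = frail[at_risk],
                         sampling_weight = sw[at_risk])
      drop <- stats::runif(length(at_risk)) < stats::plogis(lp)
      idx <- at_risk[drop]
      lost[idx] <- TRUE
      observed_until[idx] <- j
    }
  }

  # deaths are ascertained only while under observation: dropout is drawn at
  # the interval start among those alive, so every death of a lost
  # individual falls after dropout and goes unobserved
  dead <- !is.na(death_time) & !lost
  death_date <- as.Date(rep(NA, n))
  death_date[dead] <- config$baseline_date +
    round(365.25 * death_time[dead])

  ids <- sprintf("i%06d", seq_len(n))
  individuals <- data.frame(id = ids, baseline_age = age0, sex = sex,
                            residence = residence, schooling = schooling,
                            sampling_weight = sw, dead = dead,
                            death_date = death_date, lost = lost,
                            stringsAsFactors = FALSE)
  if (!is.null(config$aux)) individuals$aux_frail <- frail

  # wave rows: observed waves while alive and under observation
  wave_list <- vector("list", K)
  for (j in seq_len(K)) {
    off <- config$wave_offsets[j]
    sel <- which(observed_until >= j & states[, off + 1L] != 3L)
    wave_list[[j]] <- data.frame(
      id = ids[sel], wave_index = j,
      wave_date = config$baseline_date + round(365.25 * off),
      age = age0[sel] + off,
      state = STATE_LEVELS[states[sel, off + 1L]],
      stringsAsFactors = FALSE)
  }
  waves <- do.call(rbind, wave_list)

  cohort_panel(individuals, waves, cohort = config$cohort,
               age_window = config$age_window,
               wave_offsets = config$wave_offsets)
}

#' Exact life-table quantities implied by a generator configuration
#'
#' Ground-truth oracle: computes the partial LE, DFLE, and disabled LE that
#' the configuration's true transition models and baseline distribution
#' imply over an age window, deterministically via [occupancy_oracle()]
#' (mixing over the auxiliary covariate when present). No simulation.
#'
#' @param config A [panel_config()].
#' @param window `c(lower, upper)` ages; defaults to the config's window.
#' @param death_credit Occupancy credit in the death year (see
#'   [microsimulate()]).
#' @return An `mslt_estimate`.
#' @export
true_estimates <- function(config, window = NULL, death_credit = 0.5) {
  stopifnot(inherits(config, "panel_config"))
  if (is.null(window)) window <- config$age_window
  ages <- window[1]:window[2]
  p <- config$baseline_disabled_prevalence
  base <- baseline_dist(cbind(config$profile_distribution * (1 - p),
                              config$profile_distribution * p))
  est_for <- function(m_nd, m_d) {
    occupancy_oracle(transition_matrices(m_nd, m_d, ages), base, window,
                     death_credit = death_credit)
  }
  e0 <- est_for(config$true_model$nondisabled, config$true_model$disabled)
  if (is.null(config$aux) || config$aux$prevalence == 0) return(e0)
  pf <- config$aux$prevalence
  e1 <- est_for(shift_ppo(config$true_model$nondisabled,
                          config$aux$transition_shift),
                shift_ppo(config$true_model$disabled,
                          config$aux$transition_shift))
  mslt_estimate((1 - pf) * e0$dfle + pf * e1$dfle,
                (1 - pf) * e0$disabled_le + pf * e1$disabled_le,
                window, method = "oracle", death_credit = death_credit)
}

# True-model coefficient sets for the three age groups, calibrated once so
# that oracle-implied partial LE magnitudes are realistic for an oldest-old
# cohort (octogenarian totals near 6.5 years over ages 80-89, nonagenarian
# near 4, centenarian near 1.4). Values are calibration choices, not
# estimates from any dataset.
study_true_model <- function(age_group = c("octogenarian", "nonagenarian",
                                           "centenarian"),
                             cohort = c("earlier", "later")) {
  age_group <- match.arg(age_group)
  cohort <- match.arg(cohort)
  center <- switch(age_group, octogenarian = 80, nonagenarian = 90,
                   centenarian = 100)
  intercepts <- list(
    octogenarian = list(
      earlier = c(2.2281, 3.2080, -0.4056, 1.1873),
      later = c(2.2116, 3.2998, -0.4299, 1.2207)),
    nonagenarian = list(
      earlier = c(1.0596, 2.4372, -0.9903, 0.7194),
      later = c(1.3005, 2.1635, -0.8363, 0.6077)),
    centenarian = list(
      earlier = c(-0.4536, 0.6448, -1.7463, -0.5522),
      later = c(-0.3505, 0.6459, -1.8590, -0.6492)))
  ic <- intercepts[[age_group]][[cohort]]
  slopes <- switch(age_group,
    octogenarian = c(nd = -0.085, d = -0.07),
    nonagenarian = c(nd = -0.080, d = -0.06),
    centenarian = c(nd = -0.075, d = -0.05))
  base <- list(
    nd = c(alpha1 = ic[1], alpha2 = ic[2], age = slopes[["nd"]],
           woman1 = 0.05, woman2 = 0.30, rural1 = -0.05, rural2 = -0.15,
           unschooled1 = -0.15, unschooled2 = -0.10),
    d = c(alpha1 = ic[3], alpha2 = ic[4], age = slopes[["d"]],
          woman1 = -0.10, woman2 = 0.30, rural1 = -0.05, rural2 = -0.10,
          unschooled1 = -0.10, unschooled2 = -0.10))
  list(nondisabled = ppo_params(base$nd, "nondisabled",
                                age_center = center),
       disabled = ppo_params(base$d, "disabled", age_center = center))
}

#' Default study-design generator configurations
#'
#' Six named configurations — three paired age groups (octogenarians
#' 80-89, nonagenarians 90-99, centenarians 100-105) times earlier/later
#' birth cohort — emulating the paired-cohort design: the earlier cohort is
#' observed at waves +0/+2/+4 years, the later at +0/+3/+6; age-group totals
#' of 7334, 7705, and 5481 individuals are split near-evenly between the
#' paired cohorts; octogenarian baseline disabled prevalence is 17.3%
#' (earlier) and 11.8% (later), with assumed higher prevalences at older
#' ages. True transition coefficients are calibrated so implied partial LE
#' magnitudes are realistic for each age group.
#'
#' @return Named list of six [panel_config()] objects
#'   (`octogenarian_earlier`, `octogenarian_later`, ...).
#' @export
default_study_configs <- function() {
  totals <- c(octogenarian = 7334L, nonagenarian = 7705L,
              centenarian = 5481L)
  windows <- list(octogenarian = c(80L, 89L), nonagenarian = c(90L, 99L),
                  centenarian = c(100L, 105L))
  prevalence <- list(octogenarian = c(earlier = 0.173, later = 0.118),
                     nonagenarian = c(earlier = 0.32, later = 0.26),
                     centenarian = c(earlier = 0.52, later = 0.45))
  # joint profile distribution: women 57%, rural 62%, no schooling 61%,
  # with schooling less common among women and in rural areas
  g <- profile_grid()
  pw <- ifelse(g$sex == "woman", 0.57, 0.43)
  pr <- ifelse(g$residence == "rural", 0.62, 0.38)
  ps <- ifelse(g$schooling == "none",
               0.40 + 0.25 * (g$sex == "woman") + 0.10 * (g$residence == "rural"),
               NA)
  ps[is.na(ps)] <- 1 - ps[!is.na(ps)]
  prof <- pw * pr * ps
  prof <- prof / sum(prof)

  attr_coefs <- c(intercept = -2.1, woman = -0.10, rural = 0.25,
                  unschooled = 0.15, disabled = 0.35, frail = 0.80)
  aux <- list(prevalence = 0.30, transition_shift = 0.50)

  out <- list()
  for (ag in names(totals)) {
    n_earlier <- totals[[ag]] %/% 2L
    n_later <- totals[[ag]] - n_earlier
    for (co in c("earlier", "later")) {
      out[[paste(ag, co, sep = "_")]] <- panel_config(
        n = if (co == "earlier") n_earlier else n_later,
        age_window = windows[[ag]],
        baseline_disabled_prevalence = prevalence[[ag]][[co]],
        wave_offsets = if (co == "earlier") c(0L, 2L, 4L) else c(0L, 3L, 6L),
        true_model = study_true_model(ag, co),
        profile_distribution = prof,
        attrition = attr_coefs,
        aux = aux,
        sampling_weights = "unit",
        baseline_date = as.Date(if (co == "earlier") "1998-07-01"
                                else "2008-07-01"),
        cohort = paste(ag, co, sep = "_"))
    }
  }
  out
}
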