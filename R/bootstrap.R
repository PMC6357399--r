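#' Run the full DFLE estimation pipeline on one cohort panel
#'
#' Attrition weighting, person-year expansion, origin-stratified transition
#' model fits, transition-matrix construction, and state-occupancy
#' estimation for a bounded age window, in one call.
#'
#' @param panel A validated [cohort_panel()].
#' @param window `c(lower, upper)` ages (upper inclusive); defaults to the
#'   panel's declared age window.
#' @param weighting Use inverse-probability-of-attrition weights times
#'   sampling weights (`TRUE`, default) or unit weights (`FALSE`).
#' @param truncate Weight-truncation percentiles, or `NULL` (see
#'   [analysis_weights()]).
#' @param terms Transition-model [ppo_terms()].
#' @param method `"microsimulation"` (the primary method) or `"oracle"`
#'   (exact occupancy computation from the fitted matrices — deterministic,
#'   equal to the infinite-`n` microsimulation limit).
#' @param sim_n Synthetic-cohort size for microsimulation.
#' @param seed Integer seed governing the person-year expansion and the
#'   microsimulation.
#' @param death_credit Death-year occupancy credit (see [microsimulate()]).
#' @param keep_fits Attach the fitted models and matrices to the result.
#' @param keep_tallies Passed to [microsimulate()] (needed for
#'   [end_of_life_adjustment()]).
#' @return An `mslt_estimate`; when `keep_fits = TRUE` it carries a `fits`
#'   element with the attrition model, transition models, and matrices.
#' @export
dfle_pipeline <- function(panel, window = NULL, weighting = TRUE,
                          truncate = c(0.01, 0.99), terms = ppo_terms(),
                          method = c("microsimulation", "oracle"),
                          sim_n = 100000L, seed = 1L, death_credit = 0.5,
                          keep_fits = FALSE, keep_tallies = FALSE) {
  method <- match.arg(method)
  if (is.null(window)) window <- panel$age_window
  if (is.null(window))
    stop("no age window given and none declared in the panel", call. = FALSE)
  seeds <- child_seeds(seed, 2L)

  wts <- NULL
  att <- NULL
  if (weighting) {
    att <- fit_attrition(panel)
    wts <- analysis_weights(att, panel, truncate = truncate)
  }
  py <- expand_person_years(panel, seed = seeds[1], weights = wts)

  ages <- window[1]:window[2]
  fit_nd <- fit_ppo(py, "nondisabled", terms = terms, age_center = window[1])
  fit_d <- fit_ppo(py, "disabled", terms = terms, age_center = window[1])
  mats <- transition_matrices(fit_nd, fit_d, ages)
  base <- baseline_distribution(panel)

  est <- if (method == "microsimulation")
    microsimulate(mats, base, window, n = sim_n, seed = seeds[2],
                  death_credit = death_credit, keep_tallies = keep_tallies)
  else
    occupancy_oracle(mats, base, window, death_credit = death_credit)
  if (keep_fits)
    est$fits <- list(attrition = att, nondisabled = fit_nd, disabled = fit_d,
                     matrices = mats, baseline = base, weights = wts)
  est
}

# Fast structural resample of a panel: individuals drawn with replacement,
# re-keyed to unique ids. Skips re-validation (the source panel is valid).
resample_panel <- function(panel, idx) {
  new_id <- sprintf("b%06d", seq_along(idx))
  ind <- lapply(panel$individuals, `[`, idx)
  ind$id <- new_id
  attr(ind, "row.names") <- .set_row_names(length(idx))
  class(ind) <- "data.frame"
  wsplit <- attr(panel, "wave_split")
  if (is.null(wsplit))
    wsplit <- split(seq_len(nrow(panel$waves)),
                    factor(panel$waves$id, levels = panel$individuals$id))
  rows <- wsplit[idx]
  lens <- lengths(rows)
  flat <- unlist(rows, use.names = FALSE)
  waves <- lapply(panel$waves, `[`, flat)
  waves$id <- rep(new_id, lens)
  attr(waves, "row.names") <- .set_row_names(length(flat))
  class(waves) <- "data.frame"
  structure(list(individuals = ind, waves = waves,
                 cohort = panel$cohort, age_window = panel$age_window,
                 wave_offsets = panel$wave_offsets),
            class = "cohort_panel")
}

#' Full-pipeline bootstrap for a cohort's life-table estimates
#'
#' Resamples individuals (all their waves together) with replacement within
#' the cohort and re-runs the entire analysis sequence — attrition weights,
#' person-year expansion (transition placements re-drawn per replicate by
#' default, so placement uncertainty propagates), transition-model fits, and
#' microsimulation — for each of `B` replicates. Confidence intervals are
#' the central 95% of the replicate distribution. The point estimate always
#' comes from the full sample.
#'
#' @inheritParams dfle_pipeline
#' @param B Number of bootstrap replicates (499 in the reference design).
#' @param sim_n Microsimulation size per replicate (the full-sample point
#'   estimate uses `point_sim_n`).
#' @param point_sim_n Microsimulation size for the point estimate.
#' @param redraw_expansion Re-draw the uniform transition placements inside
#'   each replicate (default `TRUE`); `FALSE` freezes one expansion seed.
#' @param level Confidence level for percentile intervals.
#' @param max_retry Replicates whose model fit fails are re-drawn (logged)
#'   up to this many times, then dropped with a warning.
#' @return Object of class `mslt_boot`: `point` (an `mslt_estimate` with
#'   `ci` filled), `replicates` (B x 3 matrix), `B`, `seed`, `window`.
#' @export
bootstrap_dfle <- function(panel, window = NULL, B = 499L, seed = 1L,
                           weighting = TRUE, truncate = c(0.01, 0.99),
                           terms = ppo_terms(),
                           method = c("microsimulation", "oracle"),
                           sim_n = 100000L, point_sim_n = sim_n,
                           redraw_expansion = TRUE, level = 0.95,
                           death_credit = 0.5, max_retry = 5L) {
  method <- match.arg(method)
  if (is.null(window)) window <- panel$age_window
  stopifnot(B >= 1)
  seeds <- child_seeds(seed, 2L * B + 2L)

  point <- dfle_pipeline(panel, window, weighting = weighting,
                         truncate = truncate, terms = terms, method = method,
                         sim_n = point_sim_n, seed = seeds[1],
                         death_credit = death_credit)

  # precompute the wave-row index per individual once
  attr(panel, "wave_split") <-
    split(seq_len(nrow(panel$waves)),
          factor(panel$waves$id, levels = panel$individuals$id))
  n <- nrow(panel$individuals)

  reps <- matrix(NA_real_, B, 3,
                 dimnames = list(NULL, c("total_le", "dfle", "disabled_le")))
  n_failed <- 0L
  for (b in seq_len(B)) {
    rep_seed <- seeds[1L + b]
    est <- NULL
    for (try in seq_len(max_retry)) {
      sub_seeds <- child_seeds(rep_seed + (try - 1L), 2L)
      old <- local_seed(sub_seeds[1])
      idx <- sample.int(n, n, replace = TRUE)
      restore_seed(old)
      bp <- resample_panel(panel, idx)
      pipe_seed <- if (redraw_expansion) sub_seeds[2] else seeds[2L * B + 2L]
      est <- tryCatch(
        dfle_pipeline(bp, window, weighting = weighting, truncate = truncate,
                      terms = terms, method = method, sim_n = sim_n,
                      seed = pipe_seed, death_credit = death_credit),
        error = function(e) NULL)
      if (!is.null(est)) break
    }
    if (is.null(est)) {
      n_failed <- n_failed + 1L
      next
    }
    reps[b, ] <- c(est$total_le, est$dfle, est$disabled_le)
  }
  if (n_failed > 0) {
    warning(n_failed, " bootstrap replicate(s) failed after ", max_retry,
            " attempts and were dropped", call. = FALSE)
    reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  }

  if (nrow(reps) >= 2) {
    point$ci <- list(total_le = percentile_interval(reps[, 1], level),
                     dfle = percentile_interval(reps[, 2], level),
                     disabled_le = percentile_interval(reps[, 3], level))
  } else {
    point$ci <- list(total_le = rep(reps[1, 1], 2),
                     dfle = rep(reps[1, 2], 2),
                     disabled_le = rep(reps[1, 3], 2))
  }
  structure(list(point = point, replicates = reps, B = nrow(reps),
                 seed = seed, window = point$window, level = level,
                 cohort = panel$cohort),
            class = "mslt_boot")
}

#' @export
print.mslt_boot <- function(x, ...) {
  cat("Bootstrap life-table estimate (", x$B, " replicates), cohort: ",
      x$cohort, "\n", sep = "")
  print(x$point)
  invisible(x)
}

#' Central percentile interval
#'
#' The central `level` share of a bootstrap distribution, using the linearly
#' interpolated quantile definition (index `1 + p(B - 1)`).
#'
#' @param samples Numeric vector of replicate values (length >= 2).
#' @param level Coverage level (default 0.95).
#' @return `c(low, high)`.
#' @export
percentile_interval <- function(samples, level = 0.95) {
  if (length(samples) < 2)
    stop("need at least 2 samples for a percentile interval", call. = FALSE)
  a <- (1 - level) / 2
  stats::quantile(samples, c(a, 1 - a), type = 7, names = FALSE)
}

#' Nonparametric bootstrap p-value for a cohort difference
#'
#' Two-sided sign-based p-value from the replicate-difference distribution:
#' `p = 2 * min(#{d <= 0}, #{d >= 0}) / B`, capped at 1. When one side has
#' zero count the p-value is below the resolution of `B` replicates and is
#' reported with the conventional `"< 0.001"` label.
#'
#' @param diff_replicates Replicate differences (later minus earlier).
#' @return List with numeric `p` and display `label`.
#' @export
nonparametric_p <- function(diff_replicates) {
  B <- length(diff_replicates)
  stopifnot(B >= 1)
  cmin <- min(sum(diff_replicates <= 0), sum(diff_replicates >= 0))
  p <- min(1, 2 * cmin / B)
  label <- if (cmin == 0) "< 0.001" else format(round(p, 3), nsmall = 3)
  list(p = p, label = label)
}

#' Compare two cohorts' bootstrap life-table estimates
#'
#' Differences (later minus earlier) in partial total LE, DFLE, and disabled
#' LE, with percentile confidence intervals and nonparametric p-values from
#' the replicate-difference distribution (replicates paired by index).
#'
#' @param earlier,later `mslt_boot` results for the same window and
#'   analysis settings, with equal `B`.
#' @return Data frame of class `cohort_comparison`: one row per quantity
#'   with point estimates, intervals, `diff`, and p-value.
#' @export
compare_cohorts <- function(earlier, later) {
  stopifnot(inherits(earlier, "mslt_boot"), inherits(later, "mslt_boot"))
  if (!identical(earlier$window, later$window))
    stop("cohorts were estimated on different age windows", call. = FALSE)
  if (earlier$B != later$B)
    stop("bootstrap replicate counts differ (", earlier$B, " vs ", later$B,
         ")", call. = FALSE)
  qty <- c("total_le", "dfle", "disabled_le")
  rows <- lapply(qty, function(q) {
    e <- earlier$point[[q]]; l <- later$point[[q]]
    d <- l - e
    dr <- later$replicates[, q] - earlier$replicates[, q]
    ci <- if (length(dr) >= 2) percentile_interval(dr) else rep(d, 2)
    pv <- nonparametric_p(dr)
    data.frame(quantity = q,
               earlier = e, earlier_low = earlier$point$ci[[q]][1],
               earlier_high = earlier$point$ci[[q]][2],
               later = l, later_low = later$point$ci[[q]][1],
               later_high = later$point$ci[[q]][2],
               diff = d, diff_low = ci[1], diff_high = ci[2],
               p_value = pv$p, p_label = pv$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_comparison", "data.frame")
  out
}
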