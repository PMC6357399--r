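#' Fit the inverse-probability-of-attrition model
#'
#' Models loss to follow-up as a sequence of interval-specific dropout
#' events: for every scheduled inter-wave interval, individuals observed at
#' the interval's first wave are at risk of dropping out before the next
#' wave, and a pooled maximum-likelihood logistic regression relates that
#' event to the sociodemographic covariates, the disability state at the
#' interval start, every auxiliary predictor (`aux_*` column), and the
#' cross-sectional sampling weight (plus an interval indicator when there
#' is more than one at-risk interval). An individual's complete-case
#' probability is the product of their fitted interval-wise retention
#' probabilities; death under observation counts as complete — the outcome
#' is observed, and down-weighting mortality would bias the life table.
#' Fit one model per cohort and age group.
#'
#' @param panel A validated [cohort_panel()].
#' @return Object of class `attrition_model` wrapping the [stats::glm()]
#'   fit, with per-individual complete-case probabilities `p_complete`,
#'   per-interval retention probabilities, and diagnostics.
#' @export
fit_attrition <- function(panel) {
  stopifnot(inherits(panel, "cohort_panel"))
  ind <- panel$individuals
  wav <- panel$waves
  aux <- aux_columns(ind)
  K <- if (!is.null(panel$wave_offsets)) length(panel$wave_offsets)
       else max(wav$wave_index)

  if (!any(ind$lost) || K < 2) {
    # no loss to follow-up: every complete-case probability is 1 and the
    # model degenerates to the identity weighting
    return(structure(list(fit = NULL, ids = ind$id,
                          p_complete = rep(1, nrow(ind)),
                          intervals = NULL, n_intervals = K - 1L,
                          vcov = NULL, logLik = 0, converged = TRUE,
                          predictors = character(),
                          cohort = panel$cohort),
                     class = "attrition_model"))
  }

  wo <- order(wav$id, wav$wave_index, method = "radix")
  ws <- wav[wo, , drop = FALSE]
  lw <- ws$wave_index[!duplicated(ws$id, fromLast = TRUE)]
  names(lw) <- ws$id[!duplicated(ws$id, fromLast = TRUE)]
  last_wave <- lw[ind$id]
  risk <- ws[ws$wave_index < K, , drop = FALSE]
  m <- match(risk$id, ind$id)
  df <- data.frame(
    id = risk$id, interval = risk$wave_index,
    dropped = as.numeric(ind$lost[m] & last_wave[m] == risk$wave_index),
    woman = as.numeric(ind$sex[m] == "woman"),
    rural = as.numeric(ind$residence[m] == "rural"),
    unschooled = as.numeric(ind$schooling[m] == "none"),
    disabled = as.numeric(risk$state == "disabled"),
    sampling_weight = ind$sampling_weight[m],
    stringsAsFactors = FALSE)
  for (col in aux) df[[col]] <- ind[[col]][m]

  preds <- setdiff(names(df), c("id", "interval", "dropped"))
  keep <- vapply(df[preds], function(x) length(unique(x)) > 1, logical(1))
  terms <- preds[keep]
  X <- cbind(`(Intercept)` = rep(1, nrow(df)),
             as.matrix(df[terms]))
  ints <- sort(unique(df$interval))
  for (j in ints[-1])
    X <- cbind(X, as.numeric(df$interval == j))
  if (length(ints) > 1)
    colnames(X)[(ncol(X) - length(ints) + 2L):ncol(X)] <-
      paste0("interval", ints[-1])
  # drop aliased (collinear) columns before the ML fit
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  fit <- stats::glm.fit(X, df$dropped, family = stats::binomial())
  if (!fit$converged)
    stop("attrition model did not converge", call. = FALSE)
  cf <- fit$coefficients
  big <- !is.na(cf) & abs(cf) > 15 & names(cf) != "(Intercept)"
  if (any(big))
    stop("possible perfect separation in attrition model; predictor(s): ",
         paste(names(cf)[big], collapse = ", "), call. = FALSE)
  q <- fit$fitted.values
  if (any(q <= 0 | q >= 1))
    stop("degenerate fitted dropout probabilities", call. = FALSE)
  vc <- tryCatch(solve(crossprod(X * sqrt(fit$weights))),
                 error = function(e) NULL)
  if (!is.null(vc)) dimnames(vc) <- list(names(cf), names(cf))

  # cumulative observation probability through each at-risk interval, and
  # the complete-case probability as the full product (df rows are already
  # (id, interval)-sorted because `risk` came from the sorted wave table)
  retain <- 1 - q
  cum <- retain
  cont <- which(duplicated(df$id))
  while (length(cont)) {  # one pass per extra interval (at most K - 2)
    cum[cont] <- cum[cont - 1L] * retain[cont]
    cont <- cont[duplicated(df$id[cont])]
  }
  intervals <- data.frame(id = df$id, interval = df$interval,
                          p_dropout = q, p_observed = cum,
                          stringsAsFactors = FALSE)
  lastrow <- !duplicated(df$id, fromLast = TRUE)
  pc <- cum[lastrow]
  names(pc) <- df$id[lastrow]
  p_complete <- pc[ind$id]
  p_complete[is.na(p_complete)] <- 1  # individuals never at risk

  structure(list(fit = fit, ids = ind$id,
                 p_complete = unname(p_complete), intervals = intervals,
                 n_intervals = K - 1L, vcov = vc,
                 logLik = (2 * length(cf) - fit$aic) / 2,
                 converged = fit$converged,
                 predictors = colnames(X)[-1],
                 cohort = panel$cohort),
            class = "attrition_model")
}

#' @export
print.attrition_model <- function(x, ...) {
  cat("Attrition (interval dropout) model for cohort:", x$cohort, "\n")
  if (is.null(x$fit)) {
    cat("  no loss to follow-up: all complete-case probabilities are 1\n")
    return(invisible(x))
  }
  cat("  logit P(dropout) ~", paste(x$predictors, collapse = " + "), "\n")
  cat(sprintf("  %d individuals, %d at-risk intervals, logLik = %.2f\n",
              length(x$ids), nrow(x$intervals), x$logLik))
  cat(sprintf("  complete-case probability: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$p_complete), min(x$p_complete), max(x$p_complete)))
  invisible(x)
}

#' @export
coef.attrition_model <- function(object, ...) {
  if (is.null(object$fit)) return(c(`(Intercept)` = -Inf))
  stats::coef(object$fit)
}

#' Combine attrition and sampling weights into analysis weights
#'
#' The analysis weight for a person-year record in inter-wave interval `j`
#' is the individual's sampling weight divided by their fitted probability
#' of still being under observation through interval `j` (the cumulative
#' product of interval-wise retention probabilities). For complete cases'
#' final interval this equals sampling weight / complete-case probability —
#' the classical inverse-probability-of-attrition weight. Weights are
#' optionally truncated at empirical percentiles to bound variance, and
#' attach to person-year records via [expand_person_years()].
#'
#' @param model An [fit_attrition()] model.
#' @param panel The same [cohort_panel()].
#' @param truncate Percentile pair (e.g. `c(0.01, 0.99)`) at which the
#'   combined interval weights are clamped, or `NULL` for no truncation.
#' @return Data frame with one row per individual and at-risk interval:
#'   `id`, `wave_index` (interval start), `p_observed`, `analysis_weight`;
#'   attribute `individual` holds the per-individual summary (`id`,
#'   `p_complete`, `ipw`, `analysis_weight` for the complete case).
#' @export
analysis_weights <- function(model, panel, truncate = c(0.01, 0.99)) {
  stopifnot(inherits(model, "attrition_model"),
            inherits(panel, "cohort_panel"))
  ind <- panel$individuals
  m <- match(ind$id, model$ids)
  if (anyNA(m))
    stop("attrition model was fitted on a different panel", call. = FALSE)
  if (any(!is.finite(ind$sampling_weight) | ind$sampling_weight <= 0))
    stop("sampling weights must be positive", call. = FALSE)
  sw <- ind$sampling_weight
  p_complete <- model$p_complete[m]

  if (is.null(model$intervals)) {
    out <- data.frame(id = rep(ind$id, each = max(1L, model$n_intervals)),
                      wave_index = rep(seq_len(max(1L, model$n_intervals)),
                                       times = nrow(ind)),
                      p_observed = 1,
                      analysis_weight = rep(sw, each = max(1L, model$n_intervals)),
                      stringsAsFactors = FALSE)
  } else {
    iv <- model$intervals
    out <- data.frame(id = iv$id, wave_index = iv$interval,
                      p_observed = iv$p_observed,
                      analysis_weight = sw[match(iv$id, ind$id)] /
                        iv$p_observed,
                      stringsAsFactors = FALSE)
  }
  if (!is.null(truncate)) {
    stopifnot(length(truncate) == 2, truncate[1] < truncate[2])
    bounds <- stats::quantile(out$analysis_weight, truncate, type = 7,
                              names = FALSE)
    out$analysis_weight <- pmin(pmax(out$analysis_weight, bounds[1]),
                                bounds[2])
  }
  attr(out, "individual") <- data.frame(
    id = ind$id, p_complete = p_complete, ipw = 1 / p_complete,
    analysis_weight = sw / p_complete, stringsAsFactors = FALSE)
  out
}
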