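#' Term selection for the annual transition model
#'
#' The transition model is a cumulative-logit regression of the ordered
#' outcome nondisabled < disabled < dead on age and three binary covariates.
#' By default the proportional-odds assumption is relaxed for sex, residence,
#' and schooling (each gets a separate coefficient on the two cumulative
#' logits) while the age slope is shared across logits.
#'
#' @param relaxed Covariates with logit-specific effects. Any subset of
#'   `c("woman", "rural", "unschooled")`.
#' @param shared Covariates with a single shared (proportional-odds) effect.
#'   Covariates listed here must not also be in `relaxed`.
#' @param age Include the shared linear age slope (default `TRUE`; only
#'   disable for intercept-only fits on single-age data).
#' @param age2 Include a shared quadratic age term.
#' @param age_sex Include a shared age-by-sex (woman) interaction.
#' @return A list of class `ppo_terms`.
#' @export
ppo_terms <- function(relaxed = c("woman", "rural", "unschooled"),
                      shared = character(), age = TRUE, age2 = FALSE,
                      age_sex = FALSE) {
  covs <- c("woman", "rural", "unschooled")
  stopifnot(all(relaxed %in% covs), all(shared %in% covs),
            !length(intersect(relaxed, shared)))
  structure(list(relaxed = relaxed, shared = shared, age = isTRUE(age),
                 age2 = isTRUE(age2), age_sex = isTRUE(age_sex)),
            class = "ppo_terms")
}

ppo_coef_names <- function(terms) {
  nm <- c("alpha1", "alpha2")
  if (terms$age %||% TRUE) nm <- c(nm, "age")
  if (terms$age2) nm <- c(nm, "age2")
  if (terms$age_sex) nm <- c(nm, "age_woman")
  for (v in terms$relaxed) nm <- c(nm, paste0(v, "1"), paste0(v, "2"))
  c(nm, terms$shared)
}

# Design matrices for the two cumulative logits at cells with centered age
# `a` and dummy matrix `z` (columns woman, rural, unschooled).
ppo_design <- function(a, z, terms) {
  n <- length(a)
  nm <- ppo_coef_names(terms)
  X1 <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  X2 <- X1
  X1[, "alpha1"] <- 1
  X2[, "alpha2"] <- 1
  if ("age" %in% nm) X1[, "age"] <- X2[, "age"] <- a
  if (terms$age2) X1[, "age2"] <- X2[, "age2"] <- a^2
  if (terms$age_sex)
    X1[, "age_woman"] <- X2[, "age_woman"] <- a * z[, "woman"]
  for (v in terms$relaxed) {
    X1[, paste0(v, "1")] <- z[, v]
    X2[, paste0(v, "2")] <- z[, v]
  }
  for (v in terms$shared) X1[, v] <- X2[, v] <- z[, v]
  list(X1 = X1, X2 = X2)
}

ppo_loglik <- function(theta, X1, X2, W) {
  F1 <- stats::plogis(drop(X1 %*% theta))
  F2 <- stats::plogis(drop(X2 %*% theta))
  p <- cbind(F1, F2 - F1, 1 - F2)
  if (any(p[W > 0] <= 0)) return(-Inf)
  sum(W[W > 0] * log(p[W > 0]))
}

ppo_grad_hess <- function(theta, X1, X2, W) {
  eta1 <- drop(X1 %*% theta); eta2 <- drop(X2 %*% theta)
  F1 <- stats::plogis(eta1); F2 <- stats::plogis(eta2)
  f1 <- F1 * (1 - F1); f2 <- F2 * (1 - F2)
  f1p <- f1 * (1 - 2 * F1); f2p <- f2 * (1 - 2 * F2)
  p1 <- pmax(F1, 1e-300); p2 <- pmax(F2 - F1, 1e-300); p3 <- pmax(1 - F2, 1e-300)
  W1 <- W[, 1]; W2 <- W[, 2]; W3 <- W[, 3]

  g1 <- W1 * f1 / p1 - W2 * f1 / p2
  g2 <- W2 * f2 / p2 - W3 * f2 / p3
  grad <- drop(crossprod(X1, g1) + crossprod(X2, g2))

  h11 <- W1 * (f1p / p1 - (f1 / p1)^2) - W2 * (f1p / p2 + (f1 / p2)^2)
  h22 <- W2 * (f2p / p2 - (f2 / p2)^2) - W3 * (f2p / p3 + (f2 / p3)^2)
  h12 <- W2 * f1 * f2 / p2^2
  H <- crossprod(X1 * h11, X1) + crossprod(X2 * h22, X2) +
    crossprod(X1 * h12, X2) + crossprod(X2 * h12, X1)
  list(grad = grad, hess = H)
}

# Aggregate person-year records into multinomial cells: unique
# (age, woman, rural, unschooled) with weighted destination counts.
ppo_cells <- function(records, origin) {
  d <- records[records$origin == origin, , drop = FALSE]
  if (!nrow(d)) stop("no person-years with origin state '", origin, "'",
                     call. = FALSE)
  z <- profile_dummies(d$sex, d$residence, d$schooling)
  key <- d$age * 8L + z[, "woman"] * 4L + z[, "rural"] * 2L + z[, "unschooled"]
  dest <- state_code(d$dest)
  uk <- sort(unique(key))
  ki <- match(key, uk)
  W <- matrix(0, length(uk), 3)
  for (j in 1:3) {
    sel <- dest == j
    if (any(sel)) {
      agg <- rowsum(d$weight[sel], ki[sel])
      W[as.integer(rownames(agg)), j] <- agg[, 1]
    }
  }
  list(age = uk %/% 8L,
       z = cbind(woman = (uk %% 8L) %/% 4L,
                 rural = (uk %% 4L) %/% 2L,
                 unschooled = uk %% 2L),
       W = W)
}

#' Fit the partial-proportional-odds annual transition model
#'
#' Maximum-likelihood fit of a weighted cumulative-logit model for the
#' ordered annual outcome nondisabled < disabled < dead, restricted to
#' person-years that start in one origin state (the two origin strata are
#' fitted fully separately). Age enters as a continuous predictor with a
#' shared slope; the binary covariates (sex, residence, schooling) have
#' logit-specific coefficients unless moved to `shared` in `terms`.
#'
#' The fit is a deterministic Newton iteration on the analytic weighted
#' log-likelihood (step-halved, gradient tolerance `1e-8`, at most 100
#' iterations). Standard errors come from the observed information.
#'
#' @param records A person-year table from [expand_person_years()] (columns
#'   `age`, `origin`, `dest`, `sex`, `residence`, `schooling`, `weight`).
#' @param origin Origin state: `"nondisabled"` or `"disabled"`.
#' @param terms A [ppo_terms()] selection.
#' @param age_center Age subtracted from `age` before fitting; defaults to
#'   the youngest age present. Intercepts are cumulative logits at this age
#'   for the reference profile (man, urban, some schooling).
#' @param control List: `tol` (gradient norm), `maxit`.
#' @return An object of class `ppo` with `coefficients`, `vcov`, `logLik`,
#'   `converged`, `iterations`, and the aggregated data cells.
#' @seealso [predict.ppo()], [transition_matrices()], [test_extra_terms()]
#' @export
fit_ppo <- function(records, origin = c("nondisabled", "disabled"),
                    terms = ppo_terms(), age_center = NULL,
                    control = list()) {
  origin <- match.arg(origin)
  tol <- control$tol %||% 1e-8
  maxit <- control$maxit %||% 100L

  cells <- ppo_cells(records, origin)
  if (is.null(age_center)) age_center <- min(cells$age)
  a <- cells$age - age_center
  if (any(colSums(cells$W) == 0))
    stop("outcome category with zero observed weight from origin '", origin,
         "' (boundary); cannot fit", call. = FALSE)

  des <- ppo_design(a, cells$z, terms)
  X1 <- des$X1; X2 <- des$X2; W <- cells$W

  n <- sum(W)
  c1 <- sum(W[, 1]) / n
  c2 <- sum(W[, 1] + W[, 2]) / n
  theta <- stats::setNames(numeric(ncol(X1)), colnames(X1))
  theta["alpha1"] <- stats::qlogis(c1)
  theta["alpha2"] <- stats::qlogis(c2)

  ll <- ppo_loglik(theta, X1, X2, W)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    gh <- ppo_grad_hess(theta, X1, X2, W)
    if (max(abs(gh$grad)) < tol) { converged <- TRUE; break }
    nH <- -gh$hess
    step <- tryCatch(solve(nH, gh$grad), error = function(e) NULL)
    if (is.null(step)) {
      ridge <- 1e-6 * max(abs(diag(nH)))
      step <- solve(nH + diag(ridge, nrow(nH)), gh$grad)
    }
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      ll_new <- ppo_loglik(cand, X1, X2, W)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10)
        stop("transition-model fit failed: step halving exhausted (origin '",
             origin, "', iteration ", iter, ")", call. = FALSE)
    }
    theta <- cand
    ll <- ll_new
  }
  gh <- ppo_grad_hess(theta, X1, X2, W)
  if (max(abs(gh$grad)) < tol) converged <- TRUE
  if (!converged)
    stop("transition-model fit did not converge in ", maxit,
         " iterations (origin '", origin, "'); final gradient norm ",
         format(max(abs(gh$grad))), call. = FALSE)

  vc <- tryCatch(solve(-gh$hess), error = function(e) matrix(NA_real_,
    length(theta), length(theta)))
  dimnames(vc) <- list(names(theta), names(theta))

  obj <- structure(list(coefficients = theta, vcov = vc, logLik = ll,
                        origin = origin, terms = terms,
                        age_center = age_center, n = n,
                        ages = sort(unique(cells$age)),
                        cells = cells, iterations = iter,
                        converged = converged, call = match.call()),
                   class = "ppo")
  check_ppo_validity(obj, ages = obj$ages, warn = TRUE)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a transition model from known coefficients
#'
#' Builds a `ppo` object directly from coefficient values, without data.
#' Used to define the synthetic-panel generator's ground-truth dynamics and
#' in tests.
#'
#' @param coefficients Named numeric vector matching the naming of
#'   [fit_ppo()] (`alpha1`, `alpha2`, `age`, `woman1`, `woman2`, ...).
#' @param origin Origin state the model applies to.
#' @param terms A [ppo_terms()] describing which names are present.
#' @param age_center Centering age for the `age` terms.
#' @return A `ppo` object usable with [predict.ppo()] and
#'   [transition_matrices()].
#' @export
ppo_params <- function(coefficients, origin = c("nondisabled", "disabled"),
                       terms = ppo_terms(), age_center = 80) {
  origin <- match.arg(origin)
  nm <- ppo_coef_names(terms)
  miss <- setdiff(nm, names(coefficients))
  if (length(miss))
    stop("missing coefficients: ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(list(coefficients = coefficients[nm], vcov = NULL, logLik = NA,
                 origin = origin, terms = terms, age_center = age_center,
                 n = NA, ages = NULL, cells = NULL, iterations = 0L,
                 converged = TRUE, call = match.call()),
            class = "ppo")
}

# Category probabilities on an (age, dummies) grid. Returns n x 3 matrix.
ppo_probs <- function(object, age, z, clamp_tol = 1e-8) {
  a <- age - object$age_center
  des <- ppo_design(a, z, object$terms)
  F1 <- stats::plogis(drop(des$X1 %*% object$coefficients))
  F2 <- stats::plogis(drop(des$X2 %*% object$coefficients))
  p <- cbind(nondisabled = F1, disabled = F2 - F1, dead = 1 - F2)
  neg <- p[, "disabled"] < 0
  if (any(p[, "disabled"] < -clamp_tol)) {
    worst <- which.min(p[, "disabled"])
    stop("cumulative logits cross (partial-proportional-odds violation): ",
         "middle-category probability ", format(min(p[, "disabled"])),
         " at age ", age[worst], ", profile (woman=", z[worst, "woman"],
         ", rural=", z[worst, "rural"], ", unschooled=",
         z[worst, "unschooled"], ")", call. = FALSE)
  }
  if (any(neg)) {
    p[neg, "disabled"] <- 0
    p[neg, ] <- p[neg, , drop = FALSE] / rowSums(p[neg, , drop = FALSE])
  }
  p
}

# Check predicted probabilities on an age x profile grid; warn or error.
check_ppo_validity <- function(object, ages, warn = FALSE) {
  g <- profile_grid()
  z <- profile_dummies(g$sex, g$residence, g$schooling)
  grid_age <- rep(ages, each = nrow(g))
  grid_z <- z[rep(seq_len(nrow(g)), times = length(ages)), , drop = FALSE]
  res <- tryCatch(ppo_probs(object, grid_age, grid_z),
                  error = function(e) e)
  if (inherits(res, "error")) {
    if (warn) warning(conditionMessage(res), call. = FALSE) else stop(res)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' Predict annual transition probabilities
#'
#' @param object A fitted or constructed [fit_ppo()] / [ppo_params()] model.
#' @param newdata Data frame with columns `age`, `sex`, `residence`,
#'   `schooling`.
#' @param ... Unused.
#' @return Matrix with one row per row of `newdata` and columns
#'   `nondisabled`, `disabled`, `dead`, each row summing to 1. Middle-category
#'   probabilities in `[-1e-8, 0)` (numerically crossed cumulative curves)
#'   are clamped to zero and the row renormalized; larger violations are an
#'   error.
#' @export
predict.ppo <- function(object, newdata, ...) {
  z <- profile_dummies(newdata$sex, newdata$residence, newdata$schooling)
  ppo_probs(object, newdata$age, z)
}

#' @export
print.ppo <- function(x, ...) {
  cat("Partial-proportional-odds transition model (origin:", x$origin, ")\n")
  cat("Outcome order: nondisabled < disabled < dead; age centered at",
      x$age_center, "\n")
  print(round(x$coefficients, 4))
  if (!is.na(x$logLik))
    cat("logLik:", format(x$logLik), " person-years:", format(x$n),
        " iterations:", x$iterations, "\n")
  invisible(x)
}

#' @export
coef.ppo <- function(object, ...) object$coefficients

#' @export
vcov.ppo <- function(object, ...) object$vcov

#' @export
logLik.ppo <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
summary.ppo <- function(object, ...) {
  se <- if (is.null(object$vcov)) rep(NA_real_, length(object$coefficients))
        else sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(origin = object$origin, coefficients = tab,
              logLik = object$logLik, n = object$n,
              converged = object$converged, iterations = object$iterations)
  class(out) <- "summary.ppo"
  out
}

#' @export
print.summary.ppo <- function(x, ...) {
  cat("Partial-proportional-odds transition model (origin:", x$origin, ")\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nlogLik:", format(x$logLik), " weighted person-years:", format(x$n),
      "\n")
  invisible(x)
}

#' Wald tests for auxiliary age terms
#'
#' Refits the transition model with a quadratic age term and an age-by-sex
#' interaction added, and reports a Wald z test per extra term with a
#' keep/drop recommendation at the 0.05 level. Mirrors the standard model
#' selection step of testing and discarding non-significant curvature terms.
#'
#' @inheritParams fit_ppo
#' @param alpha Significance level for the keep recommendation.
#' @return Data frame with one row per extra term: estimate, standard error,
#'   Wald z, p-value, and `keep` flag.
#' @export
test_extra_terms <- function(records, origin = c("nondisabled", "disabled"),
                             terms = ppo_terms(), alpha = 0.05,
                             age_center = NULL) {
  origin <- match.arg(origin)
  ext <- terms
  ext$age2 <- TRUE
  ext$age_sex <- TRUE
  fit <- fit_ppo(records, origin, terms = ext, age_center = age_center)
  keep_nm <- c("age2", "age_woman")
  est <- fit$coefficients[keep_nm]
  se <- sqrt(diag(fit$vcov)[keep_nm])
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = keep_nm, estimate = unname(est), std_error = unname(se),
             z = unname(z), p_value = unname(p), keep = unname(p < alpha),
             stringsAsFactors = FALSE)
}
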