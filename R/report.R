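fmt2 <- function(x) format(round(x, 2), nsmall = 2, trim = TRUE)

#' Assemble a cohort-comparison table
#'
#' Lays out [compare_cohorts()] results as a publication-style table: one
#' row per stratum and quantity, point estimates with 95% intervals in
#' brackets, the later-minus-earlier difference, and the nonparametric
#' p-value, everything rounded to 2 decimals for display (differences and
#' p-values are computed from unrounded estimates, then rounded).
#'
#' @param comparisons Named list of [compare_cohorts()] results, one per
#'   stratum (e.g. `list(overall = ..., men = ..., women = ...)`).
#' @return Data frame of class `cohort_table` with character display
#'   columns. Strata whose rounded total differs from the rounded sum of
#'   its parts by 0.01 (pure display rounding) are listed in the
#'   `rounding_note` attribute.
#' @export
cohort_table <- function(comparisons) {
  stopifnot(is.list(comparisons), length(comparisons) >= 1,
            !is.null(names(comparisons)))
  qty_label <- c(total_le = "Total", dfle = "Disability-free",
                 disabled_le = "ADL disabled")
  rows <- list()
  notes <- character()
  for (stratum in names(comparisons)) {
    cmp <- comparisons[[stratum]]
    if (!inherits(cmp, "cohort_comparison"))
      stop("missing or invalid comparison for stratum '", stratum, "'",
           call. = FALSE)
    for (q in names(qty_label)) {
      r <- cmp[cmp$quantity == q, ]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = stratum, quantity = qty_label[[q]],
        earlier = sprintf("%s [%s-%s]", fmt2(r$earlier), fmt2(r$earlier_low),
                          fmt2(r$earlier_high)),
        later = sprintf("%s [%s-%s]", fmt2(r$later), fmt2(r$later_low),
                        fmt2(r$later_high)),
        diff = fmt2(r$diff),
        p = if (r$p_label == "< 0.001") "< 0.001" else fmt2o(r$p_value),
        stringsAsFactors = FALSE)
    }
    tot <- cmp$earlier[cmp$quantity == "total_le"]
    parts <- cmp$earlier[cmp$quantity == "dfle"] +
      cmp$earlier[cmp$quantity == "disabled_le"]
    if (abs(round(tot, 2) - round(parts, 2)) > 0.005)
      notes <- c(notes, sprintf(
        "%s: rounded total (%s) differs from rounded parts (%s) by display rounding",
        stratum, fmt2(tot), fmt2(parts)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "rounding_note") <- notes
  out
}

fmt2o <- function(p) format(round(p, 3), nsmall = 3, trim = TRUE)

#' @export
print.cohort_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  notes <- attr(x, "rounding_note")
  if (length(notes)) cat("Note:", paste(notes, collapse = "; "), "\n")
  invisible(x)
}

#' Shares of partial life expectancy spent disability-free and disabled
#'
#' @param estimate An `mslt_estimate` with positive total LE.
#' @return Named vector `c(share_dfle, share_disabled)` summing to 1.
#' @export
disability_shares <- function(estimate) {
  stopifnot(inherits(estimate, "mslt_estimate"))
  if (estimate$total_le <= 0)
    stop("total LE must be positive to compute shares", call. = FALSE)
  c(share_dfle = estimate$dfle / estimate$total_le,
    share_disabled = estimate$disabled_le / estimate$total_le)
}

estimate_as_list <- function(e) {
  out <- list(window = e$window, total_le = e$total_le, dfle = e$dfle,
              disabled_le = e$disabled_le, method = e$method,
              death_credit = e$death_credit)
  if (is.finite(e$n_simulated)) out$n_simulated <- e$n_simulated
  if (!is.null(e$ci)) out$ci <- e$ci
  out
}

#' Run a complete cohort-comparison analysis
#'
#' End-to-end orchestration: for each configured pair of cohorts, obtain
#' the panels (generating synthetic ones from [panel_config()]s or reading
#' CSVs), run [bootstrap_dfle()] on each cohort, compare them, and write
#' machine-readable JSON plus CSV tables and a manifest logging every seed
#' and convention. Outputs are deterministic given the config and seed.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{pairs}{Named list; each element a list with `earlier` and
#'       `later` (each a [panel_config()] or a panel CSV path) and `window`
#'       (optional, defaults to the panel's).}
#'     \item{B}{Bootstrap replicates (default 499).}
#'     \item{sim_n}{Microsimulation size per replicate (default 100000).}
#'     \item{point_sim_n}{Microsimulation size for point estimates
#'       (default `sim_n`).}
#'     \item{seed}{Integer master seed.}
#'     \item{weighting, truncate, death_credit, method}{Passed through to
#'       [bootstrap_dfle()].}
#'     \item{sensitivity}{Logical: also run the end-of-life adjustment and
#'       emit paired unadjusted/adjusted estimates.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of per-pair results (`earlier`, `later`,
#'   `comparison`, `table`, optionally `sensitivity`).
#' @export
run_analysis <- function(config, out_dir) {
  stopifnot(is.list(config$pairs), length(config$pairs) >= 1)
  B <- config$B %||% 499L
  sim_n <- config$sim_n %||% 100000L
  point_sim_n <- config$point_sim_n %||% sim_n
  seed <- config$seed %||% 1L
  weighting <- config$weighting %||% TRUE
  truncate <- if ("truncate" %in% names(config)) config$truncate
              else c(0.01, 0.99)
  death_credit <- config$death_credit %||% 0.5
  method <- config$method %||% "microsimulation"
  sensitivity <- isTRUE(config$sensitivity)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pair_seeds <- child_seeds(seed, length(config$pairs) * 3L)
  results <- list()
  manifest <- list(seed = seed, B = B, sim_n = sim_n,
                   point_sim_n = point_sim_n, weighting = weighting,
                   truncate = truncate, death_credit = death_credit,
                   method = method, sensitivity = sensitivity, pairs = list())

  get_panel <- function(x, what) {
    if (inherits(x, "cohort_panel")) return(x)
    if (inherits(x, "panel_config"))
      return(generate_panel(x, seed = what))
    if (is.character(x)) return(read_panel(x))
    stop("pair element must be a cohort_panel, panel_config, or CSV path",
         call. = FALSE)
  }

  for (i in seq_along(config$pairs)) {
    nm <- names(config$pairs)[i]
    pair <- config$pairs[[i]]
    s <- pair_seeds[(i - 1L) * 3L + 1:3]
    message("pair '", nm, "': preparing panels")
    earlier <- tryCatch(get_panel(pair$earlier, s[1]),
                        error = function(e) stop("pair '", nm,
                          "', stage panels: ", conditionMessage(e),
                          call. = FALSE))
    later <- tryCatch(get_panel(pair$later, s[1] + 1L),
                      error = function(e) stop("pair '", nm,
                        "', stage panels: ", conditionMessage(e),
                        call. = FALSE))
    window <- pair$window %||% earlier$age_window

    message("pair '", nm, "': bootstrap (B = ", B, ")")
    stage <- function(tag, expr) tryCatch(expr, error = function(e)
      stop("pair '", nm, "', stage ", tag, ": ", conditionMessage(e),
           call. = FALSE))
    boot_e <- stage("bootstrap-earlier",
      bootstrap_dfle(earlier, window, B = B, seed = s[2],
                     weighting = weighting, truncate = truncate,
                     method = method, sim_n = sim_n,
                     point_sim_n = point_sim_n,
                     death_credit = death_credit))
    boot_l <- stage("bootstrap-later",
      bootstrap_dfle(later, window, B = B, seed = s[3],
                     weighting = weighting, truncate = truncate,
                     method = method, sim_n = sim_n,
                     point_sim_n = point_sim_n,
                     death_credit = death_credit))
    cmp <- stage("compare", compare_cohorts(boot_e, boot_l))
    tab <- cohort_table(stats::setNames(list(cmp), nm))

    res <- list(earlier = boot_e, later = boot_l, comparison = cmp,
                table = tab)
    out_json <- list(pair = nm, window = window,
                     earlier = estimate_as_list(boot_e$point),
                     later = estimate_as_list(boot_l$point),
                     comparison = cmp)

    if (sensitivity) {
      sens <- stage("sensitivity", {
        est <- dfle_pipeline(earlier, window, weighting = weighting,
                             truncate = truncate, method = "microsimulation",
                             sim_n = point_sim_n, seed = s[2],
                             death_credit = death_credit,
                             keep_tallies = TRUE)
        adj <- end_of_life_adjustment(est, seed = s[2] + 1L)
        est_l <- dfle_pipeline(later, window, weighting = weighting,
                               truncate = truncate,
                               method = "microsimulation",
                               sim_n = point_sim_n, seed = s[3],
                               death_credit = death_credit,
                               keep_tallies = TRUE)
        adj_l <- end_of_life_adjustment(est_l, seed = s[3] + 1L)
        list(earlier = adj, later = adj_l)
      })
      res$sensitivity <- sens
      sens_tab <- data.frame(
        cohort = rep(c("earlier", "later"), each = 3),
        quantity = rep(c("total_le", "dfle", "disabled_le"), 2),
        unadjusted = c(sens$earlier$unadjusted$total_le,
                       sens$earlier$unadjusted$dfle,
                       sens$earlier$unadjusted$disabled_le,
                       sens$later$unadjusted$total_le,
                       sens$later$unadjusted$dfle,
                       sens$later$unadjusted$disabled_le),
        adjusted = c(sens$earlier$adjusted$total_le,
                     sens$earlier$adjusted$dfle,
                     sens$earlier$adjusted$disabled_le,
                     sens$later$adjusted$total_le,
                     sens$later$adjusted$dfle,
                     sens$later$adjusted$disabled_le),
        stringsAsFactors = FALSE)
      out_json$sensitivity <- sens_tab
      utils::write.csv(sens_tab,
                       file.path(out_dir, paste0(nm, "_sensitivity.csv")),
                       row.names = FALSE)
    }

    jsonlite::write_json(out_json, file.path(out_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(as.data.frame(tab),
                     file.path(out_dir, paste0(nm, "_table.csv")),
                     row.names = FALSE)
    manifest$pairs[[nm]] <- list(window = window, seeds = s,
                                 n_earlier = nrow(earlier$individuals),
                                 n_later = nrow(later$individuals))
    results[[nm]] <- res
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Published cohort life-expectancy reference estimates
#'
#' Loads the published partial LE / DFLE / disabled-LE point estimates for
#' the paired CLHLS birth cohorts (ages 80-89, 90-99, 100-105; overall and
#' by sex) shipped with the package, used for arithmetic-consistency checks
#' of the reporting conventions (printed differences equal differences of
#' printed estimates; printed totals equal sums of the parts up to 0.01
#' display rounding).
#'
#' @return Data frame with columns `age_group`, `stratum`, `quantity`,
#'   `earlier`, `later`, `diff`, `p`.
#' @export
published_reference <- function() {
  utils::read.csv(system.file("extdata", "clhls_published_estimates.csv",
                              package = "cohortmslt"),
                  stringsAsFactors = FALSE)
}
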