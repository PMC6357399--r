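#' Construct and validate a longitudinal disability panel
#'
#' A `cohort_panel` holds one birth cohort's panel survey: a per-individual
#' table of time-invariant fields and a per-wave table of state observations.
#' All estimation entry points ([expand_person_years()], [fit_attrition()],
#' [dfle_pipeline()], [bootstrap_dfle()]) consume this class.
#'
#' @param individuals Data frame with one row per individual: columns `id`,
#'   `baseline_age`, `sex` (`"man"`/`"woman"`), `residence`
#'   (`"urban"`/`"rural"`), `schooling` (`"some"`/`"none"`),
#'   `sampling_weight` (positive), `dead` (logical), `death_date`
#'   (`Date`, `NA` when unknown or alive), `lost` (logical, lost to
#'   follow-up), plus any number of auxiliary attrition predictors in
#'   columns named `aux_*`.
#' @param waves Data frame with one row per individual-wave actually
#'   observed: columns `id`, `wave_index` (1-based), `wave_date` (`Date`),
#'   `age` (integer years at interview), `state` (`"nondisabled"` /
#'   `"disabled"`).
#' @param cohort Cohort label (e.g. `"octogenarian_earlier"`).
#' @param age_window Integer vector `c(lower, upper)`: the design's baseline
#'   age window.
#' @param wave_offsets Integer offsets (years) of the scheduled waves from
#'   baseline, starting at 0 (e.g. `c(0, 2, 4)`).
#' @return An object of class `cohort_panel`.
#' @seealso [read_panel()], [write_panel()], [generate_panel()]
#' @export
cohort_panel <- function(individuals, waves, cohort = "cohort",
                         age_window = NULL, wave_offsets = NULL) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  waves <- as.data.frame(waves, stringsAsFactors = FALSE)

  need_ind <- c("id", "baseline_age", "sex", "residence", "schooling",
                "sampling_weight", "dead", "death_date", "lost")
  miss <- setdiff(need_ind, names(individuals))
  if (length(miss))
    stop("individuals table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  need_wav <- c("id", "wave_index", "wave_date", "age", "state")
  miss <- setdiff(need_wav, names(waves))
  if (length(miss))
    stop("waves table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  individuals$id <- as.character(individuals$id)
  waves$id <- as.character(waves$id)
  individuals$death_date <- as.Date(individuals$death_date)
  waves$wave_date <- as.Date(waves$wave_date)
  waves <- waves[order(waves$id, waves$wave_index), , drop = FALSE]
  rownames(waves) <- NULL
  rownames(individuals) <- NULL

  obj <- structure(list(individuals = individuals, waves = waves,
                        cohort = cohort,
                        age_window = if (is.null(age_window)) NULL
                                     else as.integer(age_window),
                        wave_offsets = if (is.null(wave_offsets)) NULL
                                       else as.integer(wave_offsets)),
                   class = "cohort_panel")
  validate_panel(obj)
  obj
}

#' Validate a cohort panel's structural invariants
#'
#' Checks id uniqueness, covariate levels, strictly increasing wave dates and
#' ages within individual, absence of observations after death, at most one
#' death, positive sampling weights, and (when an age window is declared)
#' baseline ages inside it. Violations raise an error naming the offending
#' ids.
#'
#' @param panel A [cohort_panel()].
#' @return `panel`, invisibly, if valid.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "cohort_panel"))
  ind <- panel$individuals
  wav <- panel$waves

  if (anyDuplicated(ind$id))
    stop("duplicate individual ids: ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "),
         call. = FALSE)
  key <- paste(wav$id, wav$wave_index)
  if (anyDuplicated(key))
    stop("duplicate (id, wave) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  orphan <- setdiff(wav$id, ind$id)
  if (length(orphan))
    stop("wave rows with unknown ids: ", paste(orphan, collapse = ", "),
         call. = FALSE)

  if (!all(ind$sex %in% SEX_LEVELS) ||
      !all(ind$residence %in% RESIDENCE_LEVELS) ||
      !all(ind$schooling %in% SCHOOLING_LEVELS))
    stop("invalid covariate levels in individuals table", call. = FALSE)
  if (!all(wav$state %in% STATE_LEVELS[1:2]))
    stop("wave states must be 'nondisabled' or 'disabled'", call. = FALSE)
  if (any(!is.finite(ind$sampling_weight) | ind$sampling_weight <= 0))
    stop("sampling weights must be positive: ids ",
         paste(ind$id[!is.finite(ind$sampling_weight) |
                        ind$sampling_weight <= 0], collapse = ", "),
         call. = FALSE)
  if (any(ind$dead & ind$lost))
    stop("individuals flagged both dead and lost: ",
         paste(ind$id[ind$dead & ind$lost], collapse = ", "), call. = FALSE)
  if (any(!ind$dead & !is.na(ind$death_date)))
    stop("death_date present for individuals not flagged dead: ",
         paste(ind$id[!ind$dead & !is.na(ind$death_date)], collapse = ", "),
         call. = FALSE)

  # per-individual ordering and death checks (vectorized by split on id)
  ord <- order(wav$id, wav$wave_index)
  w <- wav[ord, ]
  same <- duplicated(w$id)
  if (any(same)) {
    prev <- c(NA, head(seq_len(nrow(w)), -1))
    bad_date <- same & !(w$wave_date > w$wave_date[prev])
    bad_age <- same & !(w$age > w$age[prev])
    if (any(bad_date, na.rm = TRUE))
      stop("wave dates not strictly increasing for ids: ",
           paste(unique(w$id[which(bad_date)]), collapse = ", "),
           call. = FALSE)
    if (any(bad_age, na.rm = TRUE))
      stop("ages not strictly increasing for ids: ",
           paste(unique(w$id[which(bad_age)]), collapse = ", "),
           call. = FALSE)
  }
  dd <- ind$death_date[match(w$id, ind$id)]
  after <- !is.na(dd) & w$wave_date >= dd
  if (any(after))
    stop("observations on/after death date for ids: ",
         paste(unique(w$id[after]), collapse = ", "), call. = FALSE)

  if (!is.null(panel$age_window) && nrow(ind)) {
    base_age <- ind$baseline_age
    out <- base_age < panel$age_window[1] | base_age > panel$age_window[2]
    if (any(out))
      stop("baseline ages outside window [",
           panel$age_window[1], ", ", panel$age_window[2], "]: ids ",
           paste(ind$id[out], collapse = ", "), call. = FALSE)
  }
  invisible(panel)
}

aux_columns <- function(individuals)
  grep("^aux_", names(individuals), value = TRUE)

#' @export
print.cohort_panel <- function(x, ...) {
  cat("<cohort_panel> ", x$cohort, "\n", sep = "")
  cat("  individuals: ", nrow(x$individuals),
      "  wave rows: ", nrow(x$waves), "\n", sep = "")
  if (!is.null(x$age_window))
    cat("  baseline ages: ", x$age_window[1], "-", x$age_window[2], "\n",
        sep = "")
  if (!is.null(x$wave_offsets))
    cat("  wave offsets: ", paste(x$wave_offsets, collapse = ", "), "\n",
        sep = "")
  cat("  deaths: ", sum(x$individuals$dead),
      "  lost to follow-up: ", sum(x$individuals$lost), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cohort_panel <- function(object, ...) {
  ind <- object$individuals
  base <- object$waves[object$waves$wave_index == 1L, ]
  out <- list(
    cohort = object$cohort,
    n = nrow(ind),
    n_waves = length(unique(object$waves$wave_index)),
    deaths = sum(ind$dead),
    lost = sum(ind$lost),
    baseline_disabled = mean(base$state == "disabled"),
    profile_table = table(sex = ind$sex, residence = ind$residence,
                          schooling = ind$schooling)
  )
  class(out) <- "summary.cohort_panel"
  out
}

#' @export
print.summary.cohort_panel <- function(x, ...) {
  cat("Cohort panel:", x$cohort, "\n")
  cat(sprintf("  n = %d over %d waves; %d deaths, %d lost to follow-up\n",
              x$n, x$n_waves, x$deaths, x$lost))
  cat(sprintf("  baseline disabled prevalence: %.1f%%\n",
              100 * x$baseline_disabled))
  invisible(x)
}

#' Read a disability panel from its long-format CSV
#'
#' The schema is one row per observed individual-wave; time-invariant fields
#' (covariates, death/loss flags, weights, `aux_*` attrition predictors) are
#' repeated on each row and checked for within-id consistency. Disability
#' state is taken from the `state` column when present, otherwise derived
#' from the six Katz ADL item columns via [derive_disability_state()].
#'
#' @param path CSV file path.
#' @param cohort Optional cohort label override; defaults to the file's
#'   `cohort` column (or `"cohort"`).
#' @param age_window,wave_offsets Optional design metadata (see
#'   [cohort_panel()]); inferred as `NULL` when absent.
#' @return A validated [cohort_panel()].
#' @export
read_panel <- function(path, cohort = NULL, age_window = NULL,
                       wave_offsets = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  need <- c("id", "wave_index", "wave_date", "age", "dead", "death_date",
            "lost", "sex", "residence", "schooling", "sampling_weight")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("panel file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  if (!"state" %in% names(raw) || all(is.na(raw$state)) ||
      all(raw$state == "")) {
    miss_adl <- setdiff(ADL_ITEMS, names(raw))
    if (length(miss_adl))
      stop("panel file has neither a usable 'state' column nor ADL items (",
           paste(miss_adl, collapse = ", "), " missing)", call. = FALSE)
    raw$state <- derive_disability_state(raw$bathing, raw$transferring,
                                         raw$dressing, raw$eating,
                                         raw$toileting, raw$continence)
  } else {
    blank <- is.na(raw$state) | raw$state == ""
    if (any(blank)) {
      if (!all(ADL_ITEMS %in% names(raw)))
        stop("rows with blank state and no ADL items: rows ",
             paste(which(blank), collapse = ", "), call. = FALSE)
      raw$state[blank] <- derive_disability_state(
        raw$bathing[blank], raw$transferring[blank], raw$dressing[blank],
        raw$eating[blank], raw$toileting[blank], raw$continence[blank])
    }
  }

  raw$dead <- as.logical(raw$dead)
  raw$lost <- as.logical(raw$lost)
  raw$death_date[!is.na(raw$death_date) & raw$death_date == ""] <- NA
  raw$death_date <- as.Date(raw$death_date)
  raw$wave_date <- as.Date(raw$wave_date)

  aux <- grep("^aux_", names(raw), value = TRUE)
  invariant <- c("dead", "death_date", "lost", "sex", "residence",
                 "schooling", "sampling_weight", aux)
  first <- !duplicated(raw$id)
  for (col in invariant) {
    ref <- raw[[col]][first][match(raw$id, raw$id[first])]
    differs <- ifelse(is.na(raw[[col]]) | is.na(ref),
                      xor(is.na(raw[[col]]), is.na(ref)),
                      raw[[col]] != ref)
    if (any(differs))
      stop("time-invariant column '", col, "' differs across waves for ids: ",
           paste(unique(raw$id[differs]), collapse = ", "), call. = FALSE)
  }

  base <- raw[first, , drop = FALSE]
  base_age <- raw$age[raw$wave_index == 1L][match(base$id,
                                                  raw$id[raw$wave_index == 1L])]
  individuals <- data.frame(id = base$id, baseline_age = as.integer(base_age),
                            sex = base$sex, residence = base$residence,
                            schooling = base$schooling,
                            sampling_weight = base$sampling_weight,
                            dead = base$dead, death_date = base$death_date,
                            lost = base$lost, stringsAsFactors = FALSE)
  for (col in aux) individuals[[col]] <- base[[col]]

  waves <- data.frame(id = raw$id, wave_index = as.integer(raw$wave_index),
                      wave_date = raw$wave_date, age = as.integer(raw$age),
                      state = raw$state, stringsAsFactors = FALSE)

  lab <- cohort
  if (is.null(lab))
    lab <- if ("cohort" %in% names(raw) && nrow(raw)) raw$cohort[1] else "cohort"
  cohort_panel(individuals, waves, cohort = lab, age_window = age_window,
               wave_offsets = wave_offsets)
}

#' Write a disability panel to long-format CSV
#'
#' Inverse of [read_panel()]: one row per observed individual-wave, with
#' time-invariant fields repeated, absent death dates written as empty
#' fields, and a header-only file for an empty panel.
#'
#' @param panel A [cohort_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "cohort_panel"))
  ind <- panel$individuals
  wav <- panel$waves
  aux <- aux_columns(ind)

  m <- match(wav$id, ind$id)
  out <- data.frame(id = wav$id, cohort = rep(panel$cohort, nrow(wav)),
                    wave_index = wav$wave_index,
                    wave_date = format(wav$wave_date, "%Y-%m-%d"),
                    age = wav$age, state = wav$state,
                    dead = ind$dead[m],
                    death_date = ifelse(is.na(ind$death_date[m]), "",
                                        format(ind$death_date[m], "%Y-%m-%d")),
                    lost = ind$lost[m], sex = ind$sex[m],
                    residence = ind$residence[m],
                    schooling = ind$schooling[m],
                    sampling_weight = ind$sampling_weight[m],
                    stringsAsFactors = FALSE)
  for (col in aux) out[[col]] <- ind[[col]][m]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
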