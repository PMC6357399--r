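#' Expand wave-level panel observations to annual person-year records
#'
#' Converts each observed inter-wave interval into one record per whole year
#' of exposure, assuming at most one transition per interval (first-order
#' Markov): if the states at both ends agree, every year keeps that state;
#' if they differ, the single transition year is drawn uniformly among the
#' interval's years; a death with a known date is placed in the year
#' containing it (prior years keep the last observed state), and a death
#' with an unknown date has its year drawn uniformly over the remaining
#' scheduled interval. Intervals ending in loss to follow-up contribute no
#' records beyond the last observation.
#'
#' @param panel A validated [cohort_panel()].
#' @param seed Integer seed for the uniform transition placements
#'   (independent of, and logged alongside, any simulation seeds).
#' @param weights Optional analysis weights: the per-interval data frame
#'   returned by [analysis_weights()] (columns `id`, `wave_index`,
#'   `analysis_weight`; records take the weight of the inter-wave interval
#'   they fall in), a per-individual data frame (`id`, `analysis_weight`),
#'   or a numeric vector aligned with `panel$individuals`. Defaults to 1
#'   for everyone.
#' @return A data frame of class `person_years` with columns `id`, `age`
#'   (at the start of the year), `origin`, `dest`, `sex`, `residence`,
#'   `schooling`, `weight`, `cohort`, and attribute `seed`.
#' @export
expand_person_years <- function(panel, seed = 1L, weights = NULL) {
  stopifnot(inherits(panel, "cohort_panel"))
  ind <- panel$individuals
  wav <- panel$waves

  interval_w <- NULL
  if (is.null(weights)) {
    w_ind <- rep(1, nrow(ind))
  } else if (is.data.frame(weights) && "wave_index" %in% names(weights)) {
    interval_w <- weights
    # per-individual fallback: the individual's last-interval weight
    last <- weights[order(weights$id, weights$wave_index), ]
    last <- last[!duplicated(last$id, fromLast = TRUE), ]
    w_ind <- last$analysis_weight[match(ind$id, last$id)]
    w_ind[is.na(w_ind)] <- 1
  } else if (is.data.frame(weights)) {
    w_ind <- weights$analysis_weight[match(ind$id, weights$id)]
    if (anyNA(w_ind))
      stop("weights data frame lacks some panel ids", call. = FALSE)
  } else {
    stopifnot(length(weights) == nrow(ind))
    w_ind <- as.numeric(weights)
  }
  lookup_w <- function(id, interval) {
    if (is.null(interval_w)) return(w_ind[match(id, ind$id)])
    w <- interval_w$analysis_weight[match(paste(id, interval),
                                          paste(interval_w$id,
                                                interval_w$wave_index))]
    miss <- is.na(w)
    if (any(miss)) w[miss] <- w_ind[match(id[miss], ind$id)]
    w
  }

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  ord <- order(wav$id, wav$wave_index, method = "radix")
  w <- wav[ord, ]
  nxt <- c(seq_len(nrow(w))[-1], NA)
  has_next <- !is.na(nxt) & w$id[nxt] == w$id
  i0 <- which(has_next)
  iv <- data.frame(id = w$id[i0], wi = w$wave_index[i0],
                   age0 = w$age[i0], age1 = w$age[nxt[i0]],
                   s0 = state_code(w$state[i0]),
                   s1 = state_code(w$state[nxt[i0]]),
                   stringsAsFactors = FALSE)
  if (any(iv$age1 == iv$age0))
    stop("zero-year observation gap for ids: ",
         paste(unique(iv$id[iv$age1 == iv$age0]), collapse = ", "),
         call. = FALSE)
  iv$L <- iv$age1 - iv$age0
  # transition year offset within the interval: 0 for same-state intervals
  # (unused), uniform over 0..L-1 otherwise
  iv$t <- ifelse(iv$s0 == iv$s1, 0L,
                 floor(stats::runif(nrow(iv)) * iv$L))

  # terminal segment: last observation -> death (when ascertained)
  last_row <- which(!has_next)
  li <- data.frame(id = w$id[last_row], wi = w$wave_index[last_row],
                   age_last = w$age[last_row],
                   date_last = w$wave_date[last_row],
                   s_last = state_code(w$state[last_row]),
                   stringsAsFactors = FALSE)
  m <- match(li$id, ind$id)
  li$dead <- ind$dead[m]
  li$death_date <- ind$death_date[m]
  dd <- li[li$dead, , drop = FALSE]
  if (nrow(dd)) {
    k <- numeric(nrow(dd))
    known <- !is.na(dd$death_date)
    if (any(known)) {
      age_at_death <- dd$age_last[known] +
        as.numeric(dd$death_date[known] - dd$date_last[known]) / 365.25
      k[known] <- floor(age_at_death) - dd$age_last[known]
      if (any(k[known] < 0))
        stop("death date before last observation for ids: ",
             paste(dd$id[known][k[known] < 0], collapse = ", "),
             call. = FALSE)
    }
    if (any(!known)) {
      # unknown death date: draw the death year uniformly over the years
      # remaining until the next scheduled wave (1 year when no schedule)
      gap <- rep(1L, sum(!known))
      if (!is.null(panel$wave_offsets)) {
        base_age <- ind$baseline_age[match(dd$id[!known], ind$id)]
        done <- dd$age_last[!known] - base_age
        remaining <- max(panel$wave_offsets) - done
        gap <- pmax(1L, remaining)
      }
      k[!known] <- floor(stats::runif(sum(!known)) * gap)
    }
    dd$t <- as.integer(k)
    dd$L <- dd$t + 1L
  }

  build <- function(id, wi, age0, L, t, s0, s1, death = FALSE) {
    if (!length(id)) return(NULL)
    reps <- rep(seq_along(id), L)
    off <- sequence(L) - 1L
    tt <- t[reps]
    o <- ifelse(off <= tt, s0[reps], s1[reps])
    d <- ifelse(off < tt, s0[reps], s1[reps])
    if (death) {
      o <- s0[reps]
      d <- ifelse(off == tt, 3L, s0[reps])
    }
    data.frame(id = id[reps], wi = wi[reps], age = age0[reps] + off,
               origin = o, dest = d, stringsAsFactors = FALSE)
  }

  same <- iv$s0 == iv$s1
  recs <- rbind(
    build(iv$id[same], iv$wi[same], iv$age0[same], iv$L[same], iv$t[same],
          iv$s0[same], iv$s1[same]),
    build(iv$id[!same], iv$wi[!same], iv$age0[!same], iv$L[!same],
          iv$t[!same], iv$s0[!same], iv$s1[!same]),
    if (nrow(dd)) build(dd$id, dd$wi, dd$age_last, dd$L, dd$t, dd$s_last,
                        dd$s_last, death = TRUE))
  if (is.null(recs))
    recs <- data.frame(id = character(), wi = integer(), age = integer(),
                       origin = integer(), dest = integer(),
                       stringsAsFactors = FALSE)

  m <- match(recs$id, ind$id)
  out <- data.frame(id = recs$id, age = as.integer(recs$age),
                    origin = STATE_LEVELS[recs$origin],
                    dest = STATE_LEVELS[recs$dest],
                    sex = ind$sex[m], residence = ind$residence[m],
                    schooling = ind$schooling[m],
                    weight = lookup_w(recs$id, recs$wi),
                    cohort = rep(panel$cohort, nrow(recs)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$id, out$age, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("person_years", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' @export
print.person_years <- function(x, ...) {
  cat("<person_years> ", nrow(x), " person-year records, ",
      length(unique(x$id)), " individuals\n", sep = "")
  if (nrow(x)) {
    tab <- table(origin = x$origin, dest = x$dest)
    print(tab)
  }
  invisible(x)
}
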