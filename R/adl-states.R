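#' @keywords internal
"_PACKAGE"

# State space of the multistate model. Integer codes are used internally
# (1 = nondisabled, 2 = disabled, 3 = dead); dead is absorbing everywhere.
STATE_LEVELS <- c("nondisabled", "disabled", "dead")

ADL_ACTIVITIES <- c("bathing", "transferring", "dressing", "eating", "toileting")
ADL_ITEMS <- c(ADL_ACTIVITIES, "continence")

SEX_LEVELS <- c("man", "woman")
RESIDENCE_LEVELS <- c("urban", "rural")
SCHOOLING_LEVELS <- c("some", "none")

#' Code a disability state from Katz ADL items
#'
#' Applies the Katz activities-of-daily-living rule used throughout the
#' package: a person is `"disabled"` if they need personal assistance in one
#' or more of the five essential activities (bathing, transferring, dressing,
#' eating, toileting) **or** are incontinent; otherwise `"nondisabled"`.
#'
#' @param bathing,transferring,dressing,eating,toileting Character vectors
#'   with values `"independent"` or `"needs_assistance"`.
#' @param continence Character vector with values `"continent"` or
#'   `"incontinent"`.
#' @return Character vector of `"nondisabled"` / `"disabled"`.
#'
#' Missing items are an error: no item-level imputation is performed.
#'
#' @examples
#' derive_disability_state("independent", "independent", "independent",
#'                         "independent", "independent", "incontinent")
#' @export
derive_disability_state <- function(bathing, transferring, dressing,
                                    eating, toileting, continence) {
  items <- list(bathing = bathing, transferring = transferring,
                dressing = dressing, eating = eating, toileting = toileting)
  n <- length(bathing)
  for (nm in names(items)) {
    x <- items[[nm]]
    if (length(x) != n)
      stop("ADL item lengths differ ('", nm, "')", call. = FALSE)
    if (anyNA(x))
      stop("missing ADL item '", nm, "' in rows ",
           paste(which(is.na(x)), collapse = ", "),
           "; item-level imputation is not supported", call. = FALSE)
    bad <- !x %in% c("independent", "needs_assistance")
    if (any(bad))
      stop("invalid value for ADL item '", nm, "': ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  if (length(continence) != n)
    stop("ADL item lengths differ ('continence')", call. = FALSE)
  if (anyNA(continence))
    stop("missing ADL item 'continence' in rows ",
         paste(which(is.na(continence)), collapse = ", "), call. = FALSE)
  bad <- !continence %in% c("continent", "incontinent")
  if (any(bad))
    stop("invalid value for ADL item 'continence': ",
         paste(unique(continence[bad]), collapse = ", "), call. = FALSE)

  any_assist <- Reduce(`|`, lapply(items, function(x) x == "needs_assistance"))
  ifelse(any_assist | continence == "incontinent", "disabled", "nondisabled")
}

#' The eight covariate profiles
#'
#' Fixed ordering of the 2 x 2 x 2 covariate profiles (sex, residence,
#' schooling) used to index transition-matrix sets and baseline
#' distributions: row `i` is profile id `i`.
#'
#' @return Data frame with columns `sex`, `residence`, `schooling`,
#'   `profile_id`.
#' @export
profile_grid <- function() {
  g <- expand.grid(sex = SEX_LEVELS, residence = RESIDENCE_LEVELS,
                   schooling = SCHOOLING_LEVELS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$profile_id <- seq_len(nrow(g))
  g
}

# Map sex/residence/schooling vectors to profile ids 1..8.
profile_id_of <- function(sex, residence, schooling) {
  s <- match(sex, SEX_LEVELS)
  r <- match(residence, RESIDENCE_LEVELS)
  e <- match(schooling, SCHOOLING_LEVELS)
  if (anyNA(s) || anyNA(r) || anyNA(e))
    stop("invalid covariate level in sex/residence/schooling", call. = FALSE)
  s + 2L * (r - 1L) + 4L * (e - 1L)
}

# Dummy coding used by all models: woman = 1, rural = 1, unschooled = 1.
profile_dummies <- function(sex, residence, schooling) {
  cbind(woman = as.numeric(sex == "woman"),
        rural = as.numeric(residence == "rural"),
        unschooled = as.numeric(schooling == "none"))
}

state_code <- function(state) {
  code <- match(state, STATE_LEVELS)
  if (anyNA(code))
    stop("invalid disability state: ",
         paste(unique(state[is.na(code)]), collapse = ", "), call. = FALSE)
  code
}
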