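make_panel <- function(waves_ab, dead = FALSE, death_date = NA,
                       offsets = c(0L, 2L, 4L)) {
  individuals <- data.frame(
    id = "a", baseline_age = waves_ab$age[1], sex = "man",
    residence = "urban", schooling = "some", sampling_weight = 1,
    dead = dead, death_date = as.Date(death_date), lost = FALSE,
    stringsAsFactors = FALSE)
  cohort_panel(individuals, waves_ab, cohort = "t",
               wave_offsets = offsets)
}

test_that("a stable interval expands to one record per exposure year", {
  w <- data.frame(id = "a", wave_index = 1:2,
                  wave_date = as.Date(c("1998-07-01", "2000-07-01")),
                  age = c(80L, 82L),
                  state = c("nondisabled", "nondisabled"),
                  stringsAsFactors = FALSE)
  py <- expand_person_years(make_panel(w), seed = 1)
  expect_equal(nrow(py), 2)
  expect_equal(py$age, c(80L, 81L))
  expect_true(all(py$origin == "nondisabled" & py$dest == "nondisabled"))
})

test_that("unobserved transition times are uniform over the interval", {
  # 10,000 independent two-year intervals with a state change: the
  # transition year falls on the first year half the time
  n <- 10000
  individuals <- data.frame(
    id = sprintf("i%05d", 1:n), baseline_age = 80L, sex = "man",
    residence = "urban", schooling = "some", sampling_weight = 1,
    dead = FALSE, death_date = as.Date(NA), lost = FALSE,
    stringsAsFactors = FALSE)
  waves <- rbind(
    data.frame(id = individuals$id, wave_index = 1L,
               wave_date = as.Date("1998-07-01"), age = 80L,
               state = "nondisabled", stringsAsFactors = FALSE),
    data.frame(id = individuals$id, wave_index = 2L,
               wave_date = as.Date("2000-07-01"), age = 82L,
               state = "disabled", stringsAsFactors = FALSE))
  p <- cohort_panel(individuals, waves, wave_offsets = c(0L, 2L))
  py <- expand_person_years(p, seed = 31)
  first_year <- py[py$age == 80L, ]
  share <- mean(first_year$dest == "disabled")
  expect_lt(abs(share - 0.5), 0.015)
  # every interval has exactly one state change
  changes <- tapply(py$origin != py$dest, py$id, sum)
  expect_true(all(changes == 1))
})

test_that("a dated death is placed in the year containing the death date", {
  w <- data.frame(id = "a", wave_index = 1L,
                  wave_date = as.Date("1998-07-01"), age = 80L,
                  state = "nondisabled", stringsAsFactors = FALSE)
  # death at age 81.4
  p <- make_panel(w, dead = TRUE,
                  death_date = as.Date("1998-07-01") + round(1.4 * 365.25))
  py <- expand_person_years(p, seed = 1)
  expect_equal(nrow(py), 2)
  expect_equal(py$age, c(80L, 81L))
  expect_equal(py$origin, c("nondisabled", "nondisabled"))
  expect_equal(py$dest, c("nondisabled", "dead"))
})

test_that("person-years are conserved and expansion is seed-deterministic", {
  p <- generate_panel(quick_config(n = 400, attrition = TRUE), seed = 5)
  py1 <- expand_person_years(p, seed = 11)
  py2 <- expand_person_years(p, seed = 11)
  py3 <- expand_person_years(p, seed = 12)
  expect_identical(py1, py2)
  expect_false(identical(as.data.frame(py1), as.data.frame(py3)))

  # conservation: observed inter-wave exposure plus death tails
  wav <- p$waves
  ord <- order(wav$id, wav$wave_index)
  w <- wav[ord, ]
  nxt <- c(seq_len(nrow(w))[-1], NA)
  has_next <- !is.na(nxt) & w$id[nxt] == w$id
  interval_years <- sum(w$age[nxt[has_next]] - w$age[has_next])
  ind <- p$individuals
  last_age <- tapply(w$age, w$id, max)[ind$id]
  first_date <- tapply(as.numeric(w$wave_date), w$id, min)[ind$id]
  dead <- ind$dead
  death_years <- sum(floor(last_age[dead] +
    (as.numeric(ind$death_date[dead]) -
       tapply(as.numeric(w$wave_date), w$id, max)[ind$id][dead]) / 365.25) -
    last_age[dead] + 1)
  expect_equal(nrow(py1), interval_years + death_years)

  # single transition per interval, never out of the dead state
  expect_false(any(py1$origin == "dead"))
})

test_that("loss to follow-up contributes nothing beyond the last observation", {
  individuals <- data.frame(
    id = "a", baseline_age = 80L, sex = "man", residence = "urban",
    schooling = "some", sampling_weight = 1, dead = FALSE,
    death_date = as.Date(NA), lost = TRUE, stringsAsFactors = FALSE)
  waves <- data.frame(id = "a", wave_index = 1L,
                      wave_date = as.Date("1998-07-01"), age = 80L,
                      state = "nondisabled", stringsAsFactors = FALSE)
  p <- cohort_panel(individuals, waves, wave_offsets = c(0L, 2L, 4L))
  py <- expand_person_years(p, seed = 1)
  expect_equal(nrow(py), 0)
})

test_that("zero-year observation gaps are rejected", {
  w <- data.frame(id = "a", wave_index = 1:2,
                  wave_date = as.Date(c("1998-07-01", "1998-12-01")),
                  age = c(80L, 80L),
                  state = c("nondisabled", "nondisabled"),
                  stringsAsFactors = FALSE)
  individuals <- data.frame(
    id = "a", baseline_age = 80L, sex = "man", residence = "urban",
    schooling = "some", sampling_weight = 1, dead = FALSE,
    death_date = as.Date(NA), lost = FALSE, stringsAsFactors = FALSE)
  # bypass age-monotonicity validation to hit the expansion check directly
  p <- structure(list(individuals = individuals, waves = w, cohort = "t",
                      age_window = NULL, wave_offsets = NULL),
                 class = "cohort_panel")
  expect_error(expand_person_years(p, seed = 1), "zero-year")
})
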