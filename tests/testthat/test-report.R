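fake_comparison <- function(diff_total = 0.199999, p_total = 0.044,
                            p_label_total = "0.044") {
  qty <- c("total_le", "dfle", "disabled_le")
  data.frame(quantity = qty,
             earlier = c(6.38, 5.32, 1.06),
             earlier_low = c(6.10, 5.01, 0.95),
             earlier_high = c(6.59, 5.50, 1.24),
             later = c(6.38 + diff_total, 5.47, 1.10),
             later_low = c(6.36, 5.20, 0.96),
             later_high = c(6.82, 5.72, 1.28),
             diff = c(diff_total, 0.15, 0.04),
             diff_low = c(0.01, -0.02, -0.05),
             diff_high = c(0.40, 0.33, 0.13),
             p_value = c(p_total, 0.110, 0.740),
             p_label = c(p_label_total, "0.110", "0.740"),
             stringsAsFactors = FALSE) -> d
  class(d) <- c("cohort_comparison", "data.frame")
  d
}

test_that("cohort tables round for display without corrupting values", {
  tab <- cohort_table(list(overall = fake_comparison()))
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 3)
  expect_identical(tab$diff[tab$quantity == "Total"], "0.20")
  expect_identical(tab$p[tab$quantity == "Total"], "0.044")

  # "< 0.001" sentinel passes through verbatim
  tab2 <- cohort_table(list(overall = fake_comparison(
    p_total = 0.000, p_label_total = "< 0.001")))
  expect_identical(tab2$p[tab2$quantity == "Total"], "< 0.001")

  # row count scales with strata
  tab3 <- cohort_table(list(overall = fake_comparison(),
                            men = fake_comparison(),
                            women = fake_comparison()))
  expect_equal(nrow(tab3), 9)

  # missing stratum errors
  expect_error(cohort_table(list(overall = NULL)), "overall")
})

test_that("disability shares partition total life expectancy", {
  e <- structure(list(window = c(90L, 99L), total_le = 3.96, dfle = 2.47,
                      disabled_le = 1.49, n_simulated = NA,
                      method = "oracle", seed = NA, death_credit = 0.5,
                      se = NULL, tallies = NULL, ci = NULL),
                 class = "mslt_estimate")
  s <- disability_shares(e)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_equal(unname(s["share_dfle"]), 2.47 / 3.96, tolerance = 1e-12)
  expect_equal(round(100 * s[["share_dfle"]], 1), 62.4)

  e$dfle <- 0; e$disabled_le <- e$total_le
  expect_equal(unname(disability_shares(e)), c(0, 1))

  e$total_le <- 0
  expect_error(disability_shares(e), "positive")
})

test_that("run_analysis produces a reproducible report directory", {
  cfg_e <- quick_config(n = 250, attrition = TRUE)
  cfg_l <- quick_config(n = 250, attrition = TRUE, prevalence = 0.118,
                        wave_offsets = c(0L, 3L, 6L))
  cfg_l$cohort <- "test_later"
  conf <- list(pairs = list(octo = list(earlier = cfg_e, later = cfg_l,
                                        window = c(80L, 89L))),
               B = 5L, sim_n = 3000L, point_sim_n = 3000L, seed = 77L,
               sensitivity = TRUE)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- suppressMessages(run_analysis(conf, d1))
  suppressMessages(run_analysis(conf, d2))

  expect_true(file.exists(file.path(d1, "octo.json")))
  expect_true(file.exists(file.path(d1, "octo_table.csv")))
  expect_true(file.exists(file.path(d1, "octo_sensitivity.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))

  # byte-identical reruns
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)

  # sensitivity table carries paired unadjusted/adjusted columns with the
  # expected qualitative pattern
  sens <- read.csv(file.path(d1, "octo_sensitivity.csv"))
  expect_setequal(names(sens), c("cohort", "quantity", "unadjusted",
                                 "adjusted"))
  tot <- sens[sens$quantity == "total_le", ]
  expect_equal(tot$unadjusted, tot$adjusted, tolerance = 1e-12)
  dfle <- sens[sens$quantity == "dfle", ]
  expect_true(all(dfle$adjusted <= dfle$unadjusted))

  # printed table values are recomputable from the emitted JSON
  j <- jsonlite::read_json(file.path(d1, "octo.json"), simplifyVector = TRUE)
  tab <- read.csv(file.path(d1, "octo_table.csv"),
                  colClasses = "character")
  expect_identical(tab$diff[tab$quantity == "Total"],
                   format(round(j$later$total_le - j$earlier$total_le, 2),
                          nsmall = 2))
})

test_that("published reference estimates load with the documented schema", {
  ref <- published_reference()
  expect_equal(nrow(ref), 27)
  expect_setequal(unique(ref$age_group), c("80-89", "90-99", "100-105"))
  expect_setequal(names(ref),
                  c("age_group", "stratum", "quantity", "earlier", "later",
                    "diff", "p"))
})
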