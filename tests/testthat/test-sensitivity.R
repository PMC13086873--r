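test_that("the sensitivity dataset keeps positive/negative rows of positive compounds", {
  rec <- dplyr::bind_rows(
    make_records("neg-only", c("negative", "negative"), 474L, c("S1", "S2")),
    make_records("mixed", c("positive", "ambiguous", "negative"), 474L,
                 paste0("S", 1:3)),
    make_records("other-tg", "positive", 471L, "S1")
  )
  d <- prepare_sensitivity_dataset(rec, 474)
  expect_equal(unique(d$com_name), "mixed")
  expect_setequal(d$result, c("positive", "negative"))
  expect_equal(nrow(d), 2)
  expect_equal(nrow(prepare_sensitivity_dataset(rec[0, ], 474)), 0)
})

test_that("option-vs-rest pairs need both groups and count positives", {
  rec <- make_records("A", c("positive", "negative", "negative"), 474L,
                      paste0("S", 1:3))
  rec$strain <- c("SWISS", "CD-1", "CD-1")
  p <- option_vs_rest_pairs(rec, "strain", "SWISS")
  expect_equal(p$frac_pos_option, 1)
  expect_equal(p$frac_pos_rest, 0)
  expect_equal(p$diff, 1)
  # compound tested only under the option is excluded
  rec2 <- make_records("B", c("positive", "positive"), 474L, c("S1", "S2"))
  rec2$strain <- c("SWISS", "SWISS")
  expect_equal(nrow(option_vs_rest_pairs(dplyr::bind_rows(rec, rec2),
                                         "strain", "SWISS")), 1)
  expect_error(option_vs_rest_pairs(rec, "strain", "BALB/c"), "observed")
  expect_error(option_vs_rest_pairs(rec, "no_such_column", "x"), "not present")
})

test_that("per-compound fractions are counted directly on a 3-compound fixture", {
  rec <- dplyr::bind_rows(
    make_records("c1", c("positive", "positive", "negative", "negative"),
                 474L, paste0("S", 1:4)),
    make_records("c2", c("positive", "negative", "negative"), 474L,
                 paste0("S", 1:3)),
    make_records("c3", c("negative", "positive"), 474L, c("S1", "S2"))
  )
  rec$strain <- c("SWISS", "SWISS", "CD-1", "NMRI",
                  "SWISS", "CD-1", "CD-1",
                  "SWISS", "NMRI")
  p <- option_vs_rest_pairs(rec, "strain", "SWISS")
  expect_equal(nrow(p), 3)
  expect_equal(p$frac_pos_option[p$com_name == "c1"], 1)
  expect_equal(p$frac_pos_rest[p$com_name == "c1"], 0)
  expect_equal(p$frac_pos_option[p$com_name == "c2"], 1)
  expect_equal(p$frac_pos_rest[p$com_name == "c2"], 0)
  expect_equal(p$frac_pos_option[p$com_name == "c3"], 0)
  expect_equal(p$frac_pos_rest[p$com_name == "c3"], 1)
})

test_that("median dichotomization sends ties to the lower group", {
  rec <- make_records("A", rep("positive", 3), 474L, paste0("S", 1:3))
  rec$exp_period_hours <- c(2, 24, 48)
  d <- dichotomize(rec, "exp_period_hours")
  expect_equal(d$exp_period_class, c("short", "short", "long"))
  rec2 <- make_records("B", rep("positive", 4), 474L, paste0("S", 1:4))
  rec2$n_individuals <- c(5L, 10L, 15L, 20L)
  d2 <- dichotomize(rec2, "n_individuals")
  expect_equal(d2$n_individuals_class, c("low", "low", "high", "high"))
  expect_equal(attr(d2, "median"), 12.5)
  rec3 <- make_records("C", rep("positive", 3), 474L, paste0("S", 1:3))
  rec3$n_individuals <- c(5L, 5L, 5L)
  expect_error(dichotomize(rec3, "n_individuals"), "no contrast")
})

test_that("swapping option and rest negates the mean difference only", {
  cfg <- synth_config(seed = 77)
  rec <- apply_filters(generate_records(cfg)$records)
  d <- prepare_sensitivity_dataset(rec, 474)
  a <- option_vs_rest_test(d, 474, "strain", "SWISS", prepared = TRUE)
  b <- option_vs_rest_test(d, 474, "strain", "not-SWISS",
                           option_values = c("CD-1", "NMRI", "ICR"),
                           prepared = TRUE)
  expect_equal(a$mean_diff, -b$mean_diff)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$n_compounds, b$n_compounds)
})

test_that("panels handle pooled routes, sex restriction and dichotomized variables", {
  cfg <- synth_config(seed = 19, n_compounds = 80)
  rec <- apply_filters(generate_records(cfg)$records)
  panel <- tibble::tibble(
    tg = 474L,
    variable = c("strain", "route", "sex", "exp_period_hours",
                 "n_individuals"),
    option = c("SWISS", "oral", "male", "long", "high")
  )
  res <- run_panel(rec, panel)
  expect_equal(nrow(res), 5)
  expect_equal(res$variable, panel$variable)
  done <- res[!res$skipped, ]
  expect_true(all(done$p_value > 0 & done$p_value <= 1))
  expect_true(all(abs(done$mean_diff) <= 1))
  # sex comparison only uses male and male/female records
  d <- prepare_sensitivity_dataset(rec, 474)
  d_sex <- d[d$sex %in% c("male", "male_and_female"), ]
  manual <- option_vs_rest_test(d_sex, 474, "sex", "male", prepared = TRUE)
  expect_equal(res$p_value[res$variable == "sex"], manual$p_value)
  # empty panel -> typed empty result
  empty <- run_panel(rec, tibble::tibble(tg = integer(), variable = character(),
                                         option = character()))
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "sensitivity_panel")
})

test_that("under-populated comparisons are reported as skipped", {
  rec <- make_records("A", c("positive", "negative"), 474L, c("S1", "S2"))
  rec$strain <- c("SWISS", "CD-1")
  res <- option_vs_rest_test(rec, 474, "strain", "SWISS")
  expect_true(res$skipped)
  expect_true(is.na(res$p_value))
  expect_equal(res$n_compounds, 1L)
})
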