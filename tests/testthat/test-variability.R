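test_that("quality filters keep only TG-conform acceptable records", {
  rec <- make_records(
    com_name = c("A", "B", "C", "D"),
    result = "negative",
    tg = c(471L, 478L, 471L, 471L)
  )
  rec$acceptability[3] <- "not acceptable"
  rec$guideline_qualifier[4] <- "No guideline followed"
  kept <- apply_filters(rec)
  expect_equal(kept$com_name, "A")
  expect_equal(nrow(apply_filters(rec[0, ])), 0)
})

test_that("study conclusions match the three-clause rule on all tuples", {
  # exhaustive over all result tuples of length 1..4
  for (len in 1:4) {
    grid <- expand.grid(rep(list(c("positive", "negative", "ambiguous",
                                   "inconclusive")), len),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      results <- unlist(grid[i, ], use.names = FALSE)
      expect_equal(study_conclusion(results),
                   oracle_study_conclusion(results),
                   info = paste(results, collapse = ","))
    }
  }
  expect_error(study_conclusion(character()), "empty")
})

test_that("grouping drops under-replicated compounds per approach", {
  # 4 records in 2 studies: A keeps a group of 4, B concludes 2 studies and
  # drops the compound at the minimum of 3
  rec <- make_records(
    com_name = "A", result = c("negative", "negative", "positive", "negative"),
    study_ref = c("S1", "S1", "S2", "S2")
  )
  ga <- group_replicates(rec, "A")
  gb <- group_replicates(rec, "B")
  expect_equal(ga$n_replicates, 4L)
  expect_equal(nrow(gb), 0)
  # 3 records in 3 distinct studies: both approaches give size 3
  rec3 <- make_records(com_name = "B", result = rep("negative", 3),
                       study_ref = c("S1", "S2", "S3"))
  expect_equal(group_replicates(rec3, "A")$n_replicates, 3L)
  expect_equal(group_replicates(rec3, "B")$n_replicates, 3L)
  # 2 records only: absent from both outputs
  rec2 <- make_records(com_name = "C", result = rep("negative", 2),
                       study_ref = c("S1", "S2"))
  expect_equal(nrow(group_replicates(rec2, "A")), 0)
})

test_that("approach B concludes studies before grouping", {
  rec <- make_records(
    com_name = "A",
    result = c("negative", "positive", "negative", "negative", "ambiguous",
               "negative"),
    study_ref = c("S1", "S1", "S2", "S2", "S3", "S3")
  )
  gb <- group_replicates(rec, "B")
  expect_equal(sort(unlist(gb$calls)),
               sort(c("positive", "negative", "ambiguous_or_inconclusive")))
})

test_that("similarity is the modal-category fraction", {
  expect_equal(similarity(c(positive = 3, negative = 0,
                            ambiguous_or_inconclusive = 0)), 1)
  expect_equal(similarity(c(positive = 2, negative = 1,
                            ambiguous_or_inconclusive = 0)), 2 / 3)
  expect_equal(similarity(c(positive = 2, negative = 2,
                            ambiguous_or_inconclusive = 1)), 0.4)
  expect_error(similarity(c(positive = 0, negative = 0,
                            ambiguous_or_inconclusive = 0)), "at least one")
  # pairwise match-probability estimator for sensitivity analysis
  expect_equal(similarity(c(positive = 2, negative = 1,
                            ambiguous_or_inconclusive = 0), "pairwise"),
               (2 / 3)^2 + (1 / 3)^2)
})

test_that("similarity bins place the boundaries in the middle bin", {
  expect_equal(bin_similarity(0.5), "very_low")
  expect_equal(bin_similarity(2 / 3), "low")
  expect_equal(bin_similarity(0.66), "low")
  expect_equal(bin_similarity(0.85), "low")
  expect_equal(bin_similarity(0.851), "high")
  expect_equal(bin_similarity(1), "high")
  expect_equal(bin_similarity(0.6599), "very_low")
})

test_that("majority calls break ties by the fixed precedence", {
  expect_equal(majority_call(c(positive = 2, negative = 1,
                               ambiguous_or_inconclusive = 0)),
               list(call = "positive", tie_broken = FALSE))
  tie <- majority_call(c(positive = 2, negative = 2,
                         ambiguous_or_inconclusive = 0))
  expect_equal(tie$call, "positive")
  expect_true(tie$tie_broken)
  expect_equal(majority_call(c(positive = 0, negative = 0,
                               ambiguous_or_inconclusive = 3))$call,
               "ambiguous_or_inconclusive")
  tie2 <- majority_call(c(positive = 0, negative = 2,
                          ambiguous_or_inconclusive = 2))
  expect_equal(tie2$call, "ambiguous_or_inconclusive")
})

test_that("per-TG summaries aggregate bin shares and replicate counts", {
  # four compounds with similarities 0.5 (3 reps), 0.7, 0.9, 1.0
  rec <- dplyr::bind_rows(
    make_records("W", c("positive", "negative", "ambiguous"), 471L,
                 paste0("S", 1:3)),
    make_records("X", c(rep("positive", 7), rep("negative", 3)), 471L,
                 paste0("S", 1:10)),
    make_records("Y", c(rep("positive", 9), "negative"), 471L,
                 paste0("S", 1:10)),
    make_records("Z", rep("negative", 4), 471L, paste0("S", 1:4))
  )
  cs <- replicate_similarity(rec, "A")
  expect_equal(sort(cs$similarity), c(1 / 3, 0.7, 0.9, 1.0))
  tg <- summarize_tg(cs)
  expect_equal(tg$n_compounds, 4L)
  expect_equal(tg$pct_very_low, 25)
  expect_equal(tg$pct_low, 25)
  expect_equal(tg$pct_high, 50)
  expect_equal(tg$rep_min, 3L)
  expect_equal(tg$rep_median, 4L) # lower median of 3,4,10,10
  expect_equal(tg$rep_max, 10L)
  maj <- majority_by_bin(cs)
  expect_equal(sum(maj$n_compounds), 4L)
})

test_that("bin shares always sum to 100 and B never exceeds A in groups", {
  set.seed(21)
  for (i in 1:10) {
    cfg <- synth_config(seed = 100 + i, n_compounds = 25)
    rec <- apply_filters(generate_records(cfg)$records)
    ga <- group_replicates(rec, "A")
    gb <- group_replicates(rec, "B")
    expect_lte(nrow(gb), nrow(ga))
    # approach B units = distinct (compound, study) pairs above threshold
    expected_units <- rec |>
      dplyr::distinct(com_name, tg, study_ref) |>
      dplyr::count(com_name, tg) |>
      dplyr::filter(n >= 3)
    expect_equal(sum(gb$n_replicates), sum(expected_units$n))
    cs <- replicate_similarity(rec, "A")
    if (nrow(cs) > 0) {
      tg <- summarize_tg(cs)
      expect_equal(tg$pct_very_low + tg$pct_low + tg$pct_high,
                   rep(100, nrow(tg)), tolerance = 1e-8)
      # adding a duplicate of the modal category never lowers similarity
      counts <- c(positive = cs$n_positive[1], negative = cs$n_negative[1],
                  ambiguous_or_inconclusive = cs$n_ambiguous_or_inconclusive[1])
      modal <- names(counts)[which.max(counts)]
      counts2 <- counts
      counts2[modal] <- counts2[modal] + 1
      expect_gte(similarity(counts2), similarity(counts))
    }
  }
})

test_that("similarity is bounded below by the three-category pigeonhole", {
  set.seed(31)
  lv <- c("positive", "negative", "ambiguous_or_inconclusive")
  for (i in 1:100) {
    n <- sample(3:15, 1)
    counts <- as.vector(table(factor(sample(lv, n, replace = TRUE),
                                     levels = lv)))
    names(counts) <- lv
    expect_gte(similarity(counts), ceiling(n / 3) / n)
  }
})

test_that("identical input and config give byte-identical summary CSVs", {
  cfg <- synth_config(seed = 5, n_compounds = 20)
  rec <- apply_filters(generate_records(cfg)$records)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(summarize_tg(replicate_similarity(rec, "B")), f1)
  readr::write_csv(summarize_tg(replicate_similarity(rec, "B")), f2)
  expect_identical(readLines(f1), readLines(f2))
})
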