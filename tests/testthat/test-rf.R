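test_that("a perfect categorical separator captures every split", {
  x <- tibble::tibble(
    sep = c("a", "a", "b", "b"),
    const = c("z", "z", "z", "z")
  )
  y <- c("positive", "positive", "negative", "negative")
  f <- train_forest(x, y, n_trees = 25, seed = 1)
  imp <- rf_importance(f)
  expect_equal(unname(imp["sep"]), 1)
  expect_equal(unname(imp["const"]), 0)
  expect_equal(predict(f, x), y)
  rel <- feature_relevance(f)
  expect_equal(rel$variable[rel$relevant], "sep")
  expect_true(attr(rel, "explained"))
})

test_that("all-constant variables leave the compound unexplained", {
  x <- tibble::tibble(a = rep("u", 4), b = rep(1, 4))
  y <- c("positive", "negative", "positive", "negative")
  f <- train_forest(x, y, n_trees = 10, seed = 2)
  expect_true(all(rf_importance(f) == 0))
  expect_false(attr(feature_relevance(f), "explained"))
})

test_that("redundant perfect separators share all the importance", {
  x <- tibble::tibble(
    u = c("a", "a", "a", "b", "b", "b"),
    v = c("p", "p", "p", "q", "q", "q")
  )
  y <- c(rep("positive", 3), rep("negative", 3))
  f <- train_forest(x, y, n_trees = 50, seed = 3)
  imp <- rf_importance(f)
  expect_equal(unname(imp["u"] + imp["v"]), 1)
  expect_true(imp["u"] > 0 && imp["v"] > 0)
})

test_that("importances are a probability vector, invariant to row order", {
  set.seed(5)
  x <- tibble::tibble(
    a = sample(letters[1:3], 12, replace = TRUE),
    b = runif(12),
    c = sample(c("m", "f"), 12, replace = TRUE)
  )
  y <- sample(c("positive", "negative"), 12, replace = TRUE)
  while (length(unique(y)) < 2) y <- sample(c("positive", "negative"), 12, TRUE)
  f1 <- train_forest(x, y, n_trees = 20, seed = 7)
  imp <- rf_importance(f1)
  expect_true(all(imp >= 0))
  expect_true(abs(sum(imp) - 1) < 1e-12 || all(imp == 0))
  p <- sample(12)
  f2 <- train_forest(x[p, ], y[p], n_trees = 20, seed = 7)
  expect_equal(rf_importance(f2), imp)
  # fixed seed reproduces the forest exactly
  f3 <- train_forest(x, y, n_trees = 20, seed = 7)
  expect_identical(f3$trees, f1$trees)
})

test_that("single-tree full-feature mode matches hand-computed gains", {
  # parent entropy H(2+,4-) = 0.9183; splitting on x (a vs b) gives the
  # largest gain (0.4591); the impure left child then splits on z <= 2.5
  x <- tibble::tibble(
    x = c("a", "a", "a", "b", "b", "b"),
    z = c(1, 2, 3, 1, 2, 3)
  )
  y <- c("positive", "positive", "negative", "negative", "negative",
         "negative")
  f <- train_forest(x, y, n_trees = 1, mtry = 2, bootstrap = FALSE, seed = 1)
  tree <- f$trees[[1]]
  expect_false(tree$leaf)
  expect_equal(f$variables[tree$var], "x")
  inner <- if (tree$left$leaf) tree$right else tree$left
  expect_equal(f$variables[inner$var], "z")
  expect_equal(inner$type, "num")
  expect_equal(inner$value, 2.5)
  expect_equal(predict(f, x), y)
  imp <- rf_importance(f)
  expect_equal(unname(imp["x"]), 0.5)
  expect_equal(unname(imp["z"]), 0.5)
})

test_that("feature tables encode labels, classes and missing values", {
  rec <- make_records("A", c("positive", "negative", "negative"),
                      474L, paste0("S", 1:3))
  rec$strain <- c("SWISS", NA, "CD-1")
  rec$n_individuals <- c(5L, 6L, NA)
  ft <- build_feature_table(rec)
  expect_equal(length(ft$y), 3)
  expect_equal(ft$x$strain[2], "(missing)")
  expect_true(is.numeric(ft$x$n_individuals))
  expect_error(build_feature_table(rec[1, ]), "at least 2")
  rec$result <- "negative"
  expect_error(build_feature_table(rec), "no conflicting")
})

test_that("the driver screen selects eligible compounds and reports coverage", {
  rec <- dplyr::bind_rows(
    make_records("multi", c("positive", "negative", "negative"), 474L,
                 paste0("S", 1:3)),
    make_records("uniform", rep("negative", 3), 474L, paste0("S", 1:3)),
    make_records("single", "positive", 474L, "S1")
  )
  rec$strain <- c("SWISS", "CD-1", "CD-1", rep("CD-1", 4))
  d <- rf_compound_drivers(rec, tg = 474, n_trees = 20, seed = 1)
  expect_equal(d$com_name, "multi")
  expect_true(d$explained)
  expect_true("strain" %in% d$relevant[[1]])
  cov <- coverage_report(d)
  expect_equal(cov$k_compounds[cov$variable == "strain"], 1L)
  expect_equal(cov$pct_coverage[cov$variable == "strain"], 100)
  # 2 of 4 explained -> 50% coverage
  fake <- tibble::tibble(
    com_name = letters[1:4], tg = 474L, n_records = 3L, n_classes = 2L,
    explained = TRUE,
    relevant = list("sex", c("sex", "route"), "route", "route"),
    importance = list(NULL, NULL, NULL, NULL)
  )
  cov2 <- coverage_report(fake)
  expect_equal(cov2$pct_coverage[cov2$variable == "sex"], 50)
  expect_equal(cov2$pct_coverage[cov2$variable == "route"], 75)
  expect_equal(nrow(coverage_report(fake[0, ])), 0)
})

test_that("tidy and glance summarise a fitted forest", {
  x <- tibble::tibble(sep = c("a", "a", "b", "b"))
  y <- c("positive", "positive", "negative", "negative")
  f <- train_forest(x, y, n_trees = 10, seed = 1)
  td <- tidy(f)
  expect_equal(td$variable[1], "sep")
  gl <- glance(f)
  expect_equal(gl$training_accuracy, 1)
  expect_equal(gl$n_trees, 10L)
})
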