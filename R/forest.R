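#' Random-forest classifier for per-compound result discrimination
#'
#' A compact random forest for small, mixed-type tables: each tree is grown
#' on a bootstrap resample of the same size as the input, and at every node
#' the split is chosen among a fresh random draw of max(1, floor(sqrt(m)))
#' of the m variables. Categorical variables split one-category-vs-rest;
#' numeric variables split at midpoints between sorted observed values.
#' When none of the drawn candidates admits an impurity-improving split, the
#' search extends through the remaining variables in drawn order, so growth
#' stops only at pure nodes or when no variable varies at the node.
#' Prediction is by simple majority voting over trees.
#'
#' With `n_trees = 1`, `mtry = ncol(x)` and `bootstrap = FALSE` the forest
#' reduces to a single deterministic decision tree, which is how the split
#' logic is verified against hand-computed information gain.
#'
#' @param x data frame of predictor variables (character/factor columns are
#'   treated as categorical, numeric columns as continuous; `NA` in a
#'   numeric column routes to the right child).
#' @param y class labels (character or factor), at least two distinct.
#' @param n_trees number of trees.
#' @param mtry candidate variables drawn per node; default
#'   `max(1, floor(sqrt(ncol(x))))`.
#' @param split_criterion `"information_gain"` (entropy) or `"gini"`.
#' @param seed integer seed governing bootstrap and candidate draws. Rows are
#'   sorted canonically before fitting, so at fixed seed the forest is
#'   invariant under row permutation of the input.
#' @param bootstrap draw bootstrap row sets (default `TRUE`).
#' @return object of class `"genotox_rf"` with [predict()][predict.genotox_rf],
#'   [tidy()] (split-count importances) and [glance()] methods.
#' @export
train_forest <- function(x, y, n_trees = 100L, mtry = NULL,
                         split_criterion = c("information_gain", "gini"),
                         seed = NULL, bootstrap = TRUE) {
  split_criterion <- match.arg(split_criterion)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  y <- as.character(y)
  if (nrow(x) < 2 || length(unique(y)) < 2) {
    abort("training needs at least 2 rows and 2 distinct classes")
  }
  if (n_trees < 1) abort("n_trees must be >= 1")
  for (j in seq_along(x)) {
    if (is.factor(x[[j]])) x[[j]] <- as.character(x[[j]])
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  # canonical row order: seed then governs only the random draws
  ord <- do.call(order, c(unname(x), list(y)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  classes <- sort(unique(y))
  fit <- function() {
    lapply(seq_len(n_trees), function(t) {
      idx <- if (bootstrap) {
        sort(sample.int(nrow(x), nrow(x), replace = TRUE))
      } else {
        seq_len(nrow(x))
      }
      grow_tree(x, y, idx, mtry, split_criterion, classes)
    })
  }
  trees <- if (is.null(seed)) fit() else withr::with_seed(seed, fit())
  structure(
    list(trees = trees, variables = names(x), classes = classes,
         n_trees = n_trees, mtry = mtry, split_criterion = split_criterion,
         seed = seed, x = as_tibble(x), y = y),
    class = "genotox_rf"
  )
}

node_impurity <- function(counts, criterion) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  if (criterion == "information_gain") -sum(p * log2(p)) else 1 - sum(p^2)
}

class_counts <- function(y, idx, classes) {
  vapply(classes, function(cl) sum(y[idx] == cl), numeric(1))
}

grow_tree <- function(x, y, idx, mtry, criterion, classes) {
  counts <- class_counts(y, idx, classes)
  pred <- classes[which.max(counts)]
  if (sum(counts > 0) <= 1 || length(idx) < 2) {
    return(list(leaf = TRUE, pred = pred, n = length(idx)))
  }
  m <- length(x)
  # candidates are drawn without replacement; if none of the first mtry
  # admits a valid split the search extends through the remaining variables
  # in drawn order, so a node only becomes a leaf when no variable varies
  perm <- sample.int(m, m)
  parent_imp <- node_impurity(counts, criterion)
  best <- NULL
  best_gain <- 1e-12
  n_tried <- 0L
  for (j in perm) {
    if (n_tried >= min(mtry, m) && !is.null(best)) break
    n_tried <- n_tried + 1L
    col <- x[[j]][idx]
    if (is.numeric(col)) {
      vals <- sort(unique(col[!is.na(col)]))
      if (length(vals) < 2) next
      thresholds <- (vals[-1] + vals[-length(vals)]) / 2
      for (thr in thresholds) {
        left <- !is.na(col) & col <= thr
        gain <- split_gain(y, idx, left, parent_imp, criterion, classes)
        if (!is.null(gain) && gain > best_gain) {
          best_gain <- gain
          best <- list(var = j, type = "num", value = thr, left = left)
        }
      }
    } else {
      vals <- unique(col)
      if (length(vals) < 2) next
      for (v in vals) {
        left <- !is.na(col) & col == v
        gain <- split_gain(y, idx, left, parent_imp, criterion, classes)
        if (!is.null(gain) && gain > best_gain) {
          best_gain <- gain
          best <- list(var = j, type = "cat", value = v, left = left)
        }
      }
    }
  }
  if (is.null(best)) {
    return(list(leaf = TRUE, pred = pred, n = length(idx)))
  }
  list(
    leaf = FALSE,
    var = best$var, type = best$type, value = best$value,
    n = length(idx),
    left = grow_tree(x, y, idx[best$left], mtry, criterion, classes),
    right = grow_tree(x, y, idx[!best$left], mtry, criterion, classes)
  )
}

split_gain <- function(y, idx, left, parent_imp, criterion, classes) {
  nl <- sum(left)
  if (nl == 0 || nl == length(idx)) return(NULL)
  cl <- class_counts(y, idx[left], classes)
  cr <- class_counts(y, idx[!left], classes)
  n <- length(idx)
  parent_imp -
    (nl / n) * node_impurity(cl, criterion) -
    ((n - nl) / n) * node_impurity(cr, criterion)
}

route_row <- function(tree, xrow) {
  while (!tree$leaf) {
    v <- xrow[[tree$var]]
    goes_left <- if (tree$type == "num") {
      !is.na(v) && v <= tree$value
    } else {
      !is.na(v) && v == tree$value
    }
    tree <- if (goes_left) tree$left else tree$right
  }
  tree$pred
}

#' Predict classes from a fitted forest
#'
#' @param object a `"genotox_rf"` from [train_forest()].
#' @param newdata data frame with the training variables; defaults to the
#'   training table.
#' @param ... unused.
#' @return character vector of majority-vote class labels (ties broken by
#'   class-label order).
#' @export
predict.genotox_rf <- function(object, newdata = NULL, ...) {
  newdata <- as.data.frame(newdata %||% object$x, stringsAsFactors = FALSE)
  vapply(seq_len(nrow(newdata)), function(i) {
    xrow <- lapply(object$variables, function(v) newdata[[v]][i])
    votes <- vapply(object$trees, route_row, character(1), xrow = xrow)
    tab <- class_counts(votes, seq_along(votes), object$classes)
    object$classes[which.max(tab)]
  }, character(1))
}

count_splits <- function(tree, acc) {
  if (tree$leaf) return(acc)
  acc[tree$var] <- acc[tree$var] + 1
  acc <- count_splits(tree$left, acc)
  count_splits(tree$right, acc)
}

#' Split-count variable importance
#'
#' Importance of a variable is the number of internal nodes split on it
#' across all trees, divided by the total number of internal nodes. Sums to
#' 1 when any split occurred; all-zero otherwise.
#'
#' @param forest a `"genotox_rf"`.
#' @return named numeric vector over variables.
#' @export
rf_importance <- function(forest) {
  acc <- setNames(rep(0, length(forest$variables)),
                  seq_along(forest$variables))
  for (tree in forest$trees) acc <- count_splits(tree, acc)
  total <- sum(acc)
  out <- if (total > 0) acc / total else acc
  setNames(as.numeric(out), forest$variables)
}

#' Rank the variables relevant to a compound's conflicting results
#'
#' @param forest a `"genotox_rf"`.
#' @param threshold minimal importance (share of splits) for a variable to
#'   count as relevant.
#' @return tibble sorted by descending importance with columns `variable`,
#'   `importance`, `relevant`; attribute `explained` is `TRUE` when at least
#'   one variable is relevant (i.e. the forest found structure that
#'   discriminates the outcomes).
#' @export
feature_relevance <- function(forest, threshold = 0.05) {
  imp <- rf_importance(forest)
  out <- tibble(
    variable = names(imp),
    importance = as.numeric(imp)
  ) |>
    arrange(dplyr::desc(.data$importance), .data$variable) |>
    mutate(relevant = .data$importance >= threshold & .data$importance > 0)
  attr(out, "explained") <- any(out$relevant)
  out
}

#' @export
print.genotox_rf <- function(x, ...) {
  cat(sprintf(
    "Random forest: %d trees, %d variables (mtry %d, %s), classes: %s\n",
    x$n_trees, length(x$variables), x$mtry, x$split_criterion,
    paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

#' @describeIn train_forest importance table (`variable`, `importance`).
#' @export
tidy.genotox_rf <- function(x, ...) {
  feature_relevance(x)[, c("variable", "importance")]
}

#' @describeIn train_forest one-row fit summary (tree/node counts, training
#'   accuracy).
#' @export
glance.genotox_rf <- function(x, ...) {
  n_internal <- sum(vapply(x$trees, function(t) {
    cnt <- function(tr) if (tr$leaf) 0L else 1L + cnt(tr$left) + cnt(tr$right)
    cnt(t)
  }, integer(1)))
  tibble(
    n_trees = x$n_trees,
    n_variables = length(x$variables),
    n_internal_nodes = n_internal,
    n_classes = length(x$classes),
    training_accuracy = mean(predict(x) == x$y)
  )
}
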