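# Protocol variables screened by the driver analysis, in canonical order.
RF_VARIABLES <- c("species", "strain", "n_individuals", "sex", "route",
                  "exp_period_hours", "tissue_exposure_evidence",
                  "opinion_year", "study_ref")

#' Build the per-compound feature table for the driver analysis
#'
#' Extracts, for one compound's records, the protocol variables (species,
#' strain, number of individuals, sex, route, experimental period,
#' target-tissue exposure evidence, opinion year, literature reference) as
#' predictors and the study results as labels. Categorical missing values
#' become an explicit `"(missing)"` category; numeric variables stay numeric
#' (missing values are handled by the tree's routing rule).
#'
#' @param records assay-record tibble for a single compound.
#' @param variables which record columns to use as predictors.
#' @return list with `x` (predictor tibble) and `y` (character label vector).
#'   Errors if the compound has fewer than 2 records or no conflicting
#'   results (a single distinct label).
#' @export
build_feature_table <- function(records, variables = RF_VARIABLES) {
  records <- as_tibble(records)
  if (nrow(records) < 2) abort("need at least 2 records for one compound")
  y <- records$result
  if (length(unique(y)) < 2) abort("no conflicting results for this compound")
  variables <- intersect(variables, names(records))
  x <- records[, variables, drop = FALSE]
  for (v in names(x)) {
    if (!is.numeric(x[[v]])) {
      col <- as.character(x[[v]])
      col[is.na(col) | col == ""] <- "(missing)"
      x[[v]] <- col
    }
  }
  list(x = x, y = y)
}

#' Per-compound random-forest driver screen
#'
#' For every compound in a TG with conflicting results (at least two records
#' and at least two distinct result calls), fits a random forest of the
#' protocol variables against the results and extracts the variables whose
#' split-count importance reaches the relevance threshold. A compound is
#' "explained" when at least one variable is relevant; compounds whose
#' variables show no variation that discriminates the outcomes remain
#' unexplained.
#'
#' @param records quality-filtered assay-record tibble (approach-A view).
#' @param tg the TG to analyse; `NULL` uses all records as given.
#' @param n_trees,split_criterion,seed forwarded to [train_forest()].
#' @param threshold relevance threshold on the importance share
#'   ([feature_relevance()]).
#' @param variables predictor columns ([build_feature_table()]).
#' @return tibble of class `"rf_drivers"`, one row per eligible compound:
#'   `com_name`, `tg`, `n_records`, `n_classes`, `explained`,
#'   `relevant` (list of variable names), `importance` (list column of
#'   importance tibbles).
#' @export
rf_compound_drivers <- function(records, tg = NULL, n_trees = 100L,
                                split_criterion = "information_gain",
                                seed = 1L, threshold = 0.05,
                                variables = RF_VARIABLES) {
  records <- as_tibble(records)
  if (!is.null(tg)) records <- records[records$tg == tg, , drop = FALSE]
  eligible <- records |>
    group_by(.data$com_name) |>
    filter(n() >= 2, dplyr::n_distinct(.data$result) >= 2) |>
    ungroup()
  compounds <- sort(unique(eligible$com_name))
  rows <- purrr::imap(compounds, function(cmp, i) {
    rec <- eligible[eligible$com_name == cmp, , drop = FALSE]
    ft <- build_feature_table(rec, variables)
    forest <- train_forest(ft$x, ft$y, n_trees = n_trees,
                           split_criterion = split_criterion,
                           seed = seed + i - 1L)
    rel <- feature_relevance(forest, threshold)
    tibble(
      com_name = cmp,
      tg = rec$tg[1],
      n_records = nrow(rec),
      n_classes = length(unique(ft$y)),
      explained = attr(rel, "explained"),
      relevant = list(rel$variable[rel$relevant]),
      importance = list(rel)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(com_name = character(), tg = integer(),
                  n_records = integer(), n_classes = integer(),
                  explained = logical(), relevant = list(),
                  importance = list())
  }
  class(out) <- c("rf_drivers", class(out))
  out
}

#' Variable coverage across explained compounds
#'
#' For each protocol variable, the number of explained compounds in which it
#' was flagged relevant, and that count as a percentage of all explained
#' compounds (e.g. a variable relevant in 11 of 25 explained compounds has
#' 44% coverage).
#'
#' @param drivers an `"rf_drivers"` tibble ([rf_compound_drivers()]).
#' @return tibble: `variable`, `k_compounds`, `pct_coverage`, sorted by
#'   descending coverage. Empty when no compound is explained.
#' @export
coverage_report <- function(drivers) {
  explained <- drivers[drivers$explained, , drop = FALSE]
  n_expl <- nrow(explained)
  if (n_expl == 0) {
    return(tibble(variable = character(), k_compounds = integer(),
                  pct_coverage = numeric()))
  }
  tibble(variable = unlist(explained$relevant)) |>
    dplyr::count(.data$variable, name = "k_compounds") |>
    mutate(pct_coverage = 100 * .data$k_compounds / n_expl) |>
    arrange(dplyr::desc(.data$pct_coverage), .data$variable)
}
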