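#' Configuration for the option-vs-rest sensitivity analysis
#'
#' @param alpha significance level for flagging options (tests are
#'   two-sided; direction is read off the mean difference).
#' @param oral_group route labels pooled into a single "oral" option.
#' @param min_nonzero minimal number of non-zero paired differences required
#'   to report a p-value; under-populated comparisons are marked skipped.
#' @return list of class `"assoc_config"`.
#' @export
assoc_config <- function(alpha = 0.10,
                         oral_group = c("oral: gavage", "oral: feed",
                                        "oral: capsule", "oral: unspecified"),
                         min_nonzero = 3L) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  structure(
    list(alpha = alpha, oral_group = oral_group,
         min_nonzero = as.integer(min_nonzero)),
    class = "assoc_config"
  )
}

#' Restrict records to the sensitivity-analysis dataset for one TG
#'
#' Keeps, within the TG of interest, only positive and negative results
#' (ambiguous and inconclusive are excluded), and only compounds with at
#' least one positive test in that TG: compounds that never test positive
#' carry no information about what drives sensitivity.
#'
#' @param records quality-filtered assay-record tibble (approach-A view).
#' @param tg the TG of interest.
#' @return the filtered tibble.
#' @export
prepare_sensitivity_dataset <- function(records, tg) {
  d <- as_tibble(records)
  d <- d[d$tg == tg & d$result %in% c("positive", "negative"), , drop = FALSE]
  pos_compounds <- unique(d$com_name[d$result == "positive"])
  d[d$com_name %in% pos_compounds, , drop = FALSE]
}

#' Per-compound positive fractions for one option versus the rest
#'
#' Splits a prepared dataset into records run under one option of a protocol
#' variable and records run under all other options combined, and computes
#' per compound the fraction of positive results in each group. Only
#' compounds tested in both groups contribute a pair (which implies at least
#' two replicates distributed over the two groups); records with a missing
#' value on the variable are excluded.
#'
#' @param records prepared tibble ([prepare_sensitivity_dataset()]).
#' @param variable record column holding the protocol variable.
#' @param option the option of interest.
#' @param option_values values counted as the option (defaults to
#'   `option` itself; e.g. the pooled oral route labels).
#' @return tibble: `com_name`, `frac_pos_option`, `frac_pos_rest`, `diff`.
#' @export
option_vs_rest_pairs <- function(records, variable, option,
                                 option_values = option) {
  d <- as_tibble(records)
  if (!(variable %in% names(d))) {
    abort(sprintf("variable '%s' not present on the records", variable))
  }
  v <- d[[variable]]
  d <- d[!is.na(v), , drop = FALSE]
  v <- v[!is.na(v)]
  observed <- sort(unique(as.character(v)))
  if (!any(as.character(v) %in% option_values)) {
    abort(sprintf("option '%s' not observed for %s; observed options: %s",
                  option, variable, paste(observed, collapse = ", ")))
  }
  d$.in_option <- as.character(v) %in% option_values
  d |>
    group_by(.data$com_name) |>
    filter(any(.data$.in_option), any(!.data$.in_option)) |>
    summarise(
      frac_pos_option = mean(.data$result[.data$.in_option] == "positive"),
      frac_pos_rest = mean(.data$result[!.data$.in_option] == "positive"),
      .groups = "drop"
    ) |>
    mutate(diff = .data$frac_pos_option - .data$frac_pos_rest)
}

#' Dichotomize a numeric protocol variable at its per-TG median
#'
#' Experimental periods become `short` (at or below the median) / `long`
#' (above), numbers of individuals `low` / `high`; values exactly at the
#' median go to the lower group in both cases. The median is computed over
#' the records passed in (i.e. over the prepared dataset of one TG).
#'
#' @param records prepared tibble for one TG.
#' @param variable `"exp_period_hours"` or `"n_individuals"`.
#' @return `records` with an added character column `exp_period_class`
#'   (`short`/`long`) or `n_individuals_class` (`low`/`high`); the cut point
#'   is stored in attribute `"median"`. Errors when all values are identical
#'   (no contrast to analyse).
#' @export
dichotomize <- function(records, variable = c("exp_period_hours",
                                              "n_individuals")) {
  variable <- match.arg(variable)
  d <- as_tibble(records)
  vals <- d[[variable]]
  med <- median(vals, na.rm = TRUE)
  non_na <- vals[!is.na(vals)]
  if (length(unique(non_na)) < 2) {
    abort(sprintf("no contrast: all %s values are identical", variable))
  }
  labels <- if (variable == "exp_period_hours") c("short", "long") else c("low", "high")
  cls <- ifelse(is.na(vals), NA_character_,
                ifelse(vals <= med, labels[1], labels[2]))
  d[[paste0(sub("_hours$", "", variable), "_class")]] <- cls
  attr(d, "median") <- med
  d
}

#' Test whether one protocol option shifts study sensitivity
#'
#' The option-vs-rest comparison for one TG, variable and option: per-
#' compound positive fractions in the two groups, their mean paired
#' difference, and a two-sided Wilcoxon signed-rank test of the differences.
#' Comparisons with fewer than `cfg$min_nonzero` non-zero differences are
#' reported but marked skipped (no p-value).
#'
#' @param records quality-filtered records (approach-A view) or, with
#'   `prepared = TRUE`, an already-prepared dataset.
#' @param tg TG of interest.
#' @param variable record column with the protocol variable.
#' @param option option of interest.
#' @param option_values values pooled into the option (see
#'   [option_vs_rest_pairs()]).
#' @param restrict_values if given, only records whose variable value lies in
#'   this set enter the comparison (e.g. sex restricted to male and
#'   male/female).
#' @param cfg an [assoc_config()].
#' @param prepared set `TRUE` when `records` already passed
#'   [prepare_sensitivity_dataset()].
#' @return one-row tibble: `tg`, `variable`, `option`, `n_compounds`,
#'   `mean_diff`, `statistic`, `p_value`, `significant`, `skipped`.
#' @export
option_vs_rest_test <- function(records, tg, variable, option,
                                option_values = option,
                                restrict_values = NULL,
                                cfg = assoc_config(), prepared = FALSE) {
  d <- if (prepared) as_tibble(records) else prepare_sensitivity_dataset(records, tg)
  if (!is.null(restrict_values) && variable %in% names(d)) {
    d <- d[!is.na(d[[variable]]) & d[[variable]] %in% restrict_values, ,
           drop = FALSE]
  }
  empty <- tibble(
    tg = tg, variable = variable, option = option, n_compounds = 0L,
    mean_diff = NA_real_, statistic = NA_real_, p_value = NA_real_,
    significant = FALSE, skipped = TRUE
  )
  if (nrow(d) == 0) return(empty)
  pairs <- tryCatch(
    option_vs_rest_pairs(d, variable, option, option_values),
    error = function(e) NULL
  )
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  n_nonzero <- sum(pairs$diff != 0)
  if (n_nonzero < cfg$min_nonzero) {
    empty$n_compounds <- nrow(pairs)
    empty$mean_diff <- mean(pairs$diff)
    return(empty)
  }
  test <- signed_rank_test(pairs$diff)
  tibble(
    tg = tg, variable = variable, option = option,
    n_compounds = nrow(pairs),
    mean_diff = mean(pairs$diff),
    statistic = test$statistic,
    p_value = test$p_value,
    significant = test$p_value < cfg$alpha,
    skipped = FALSE
  )
}

#' Run a panel of option-vs-rest sensitivity tests
#'
#' Executes one [option_vs_rest_test()] per panel row. Besides plain
#' categorical options, the panel understands three conventions:
#' \itemize{
#'   \item `variable = "route"`, `option = "oral"`: the oral route labels of
#'     the configuration are pooled into one group;
#'   \item `variable = "sex"`, `option = "male"`: the comparison is
#'     restricted to records reported as male or male/female;
#'   \item `variable = "exp_period_hours"` or `"n_individuals"`: the
#'     variable is dichotomized at its per-TG median
#'     ([dichotomize()]) and the option refers to the derived class
#'     (`long`/`short`, `high`/`low`).
#' }
#'
#' @param records quality-filtered records (approach-A view).
#' @param panel tibble with columns `tg`, `variable`, `option`.
#' @param cfg an [assoc_config()].
#' @return tibble of class `"sensitivity_panel"`, one row per panel entry
#'   (see [option_vs_rest_test()]).
#' @export
run_panel <- function(records, panel, cfg = assoc_config()) {
  panel <- as_tibble(panel)
  if (nrow(panel) == 0) {
    out <- tibble(tg = integer(), variable = character(), option = character(),
                  n_compounds = integer(), mean_diff = numeric(),
                  statistic = numeric(), p_value = numeric(),
                  significant = logical(), skipped = logical())
    class(out) <- c("sensitivity_panel", class(out))
    return(out)
  }
  rows <- purrr::pmap(panel[, c("tg", "variable", "option")],
                      function(tg, variable, option) {
    d <- prepare_sensitivity_dataset(records, tg)
    opt_values <- option
    restrict <- NULL
    var <- variable
    if (variable == "route" && option == "oral") {
      opt_values <- cfg$oral_group
    }
    if (variable == "sex" && option == "male") {
      restrict <- c("male", "male_and_female")
    }
    if (variable %in% c("exp_period_hours", "n_individuals")) {
      d2 <- tryCatch(dichotomize(d, variable), error = function(e) NULL)
      if (is.null(d2)) {
        return(tibble(tg = tg, variable = variable, option = option,
                      n_compounds = 0L, mean_diff = NA_real_,
                      statistic = NA_real_, p_value = NA_real_,
                      significant = FALSE, skipped = TRUE))
      }
      d <- d2
      var <- paste0(sub("_hours$", "", variable), "_class")
    }
    res <- option_vs_rest_test(d, tg, var, option, option_values = opt_values,
                               restrict_values = restrict, cfg = cfg,
                               prepared = TRUE)
    res$variable <- variable
    res
  })
  out <- bind_rows(rows)
  class(out) <- c("sensitivity_panel", class(out))
  out
}
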