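#' Quality-filter configuration for TG-conform study records
#'
#' Defaults mirror the standard regulatory selection: studies conducted
#' according to (or equivalent/similar to) the OECD TG acceptable at the time
#' of the opinion, judged acceptable, in one of the analysed genotoxicity
#' TGs, and with at least three pseudo-replicates per compound (applied after
#' grouping).
#'
#' @param allowed_qualifiers guideline qualifiers that pass the filter
#'   (matched case-insensitively after whitespace normalization).
#' @param required_acceptability acceptability label that passes.
#' @param tg_whitelist TGs retained for analysis.
#' @param min_replicates minimum replicate units per compound group (>= 2).
#' @return list of class `"filter_config"`.
#' @export
filter_config <- function(allowed_qualifiers = c("According to",
                                                 "Equivalent or similar to"),
                          required_acceptability = "acceptable",
                          tg_whitelist = c(471L, 473L, 476L, 487L, 490L, 474L,
                                           475L, 483L, 486L, 488L, 489L),
                          min_replicates = 3L) {
  if (min_replicates < 2) abort("min_replicates must be at least 2")
  structure(
    list(
      allowed_qualifiers = allowed_qualifiers,
      required_acceptability = required_acceptability,
      tg_whitelist = as.integer(tg_whitelist),
      min_replicates = as.integer(min_replicates)
    ),
    class = "filter_config"
  )
}

#' Apply quality filters to study records
#'
#' Keeps records whose guideline qualifier, acceptability and TG satisfy the
#' configuration. The minimum-replicate condition is applied later, after
#' grouping ([group_replicates()]).
#'
#' @param records assay-record tibble ([read_assay_records()]).
#' @param cfg a [filter_config()].
#' @return the filtered tibble.
#' @export
apply_filters <- function(records, cfg = filter_config()) {
  qual <- normalize_name(records$guideline_qualifier)
  acc <- normalize_name(records$acceptability)
  records[
    qual %in% normalize_name(cfg$allowed_qualifiers) &
      acc == normalize_name(cfg$required_acceptability) &
      records$tg %in% cfg$tg_whitelist,
    ,
    drop = FALSE
  ]
}

#' Collapse study-level result calls to three categories
#'
#' Ambiguous and inconclusive results are pooled into a single
#' `ambiguous_or_inconclusive` category for the replicate-agreement analysis.
#'
#' @param result character vector of result calls
#'   (`positive`/`negative`/`ambiguous`/`inconclusive`).
#' @return character vector over the three collapsed categories.
#' @export
collapse_call <- function(result) {
  stopifnot(all(result %in% RESULT_LEVELS))
  ifelse(result %in% c("ambiguous", "inconclusive"),
         "ambiguous_or_inconclusive", result)
}

#' Conclude a single call for one study
#'
#' A study with several test results is concluded at the study level: if any
#' result is positive the study is positive; if all results are negative it
#' is negative; otherwise (only negative and/or inconclusive/ambiguous
#' results) it is inconclusive/ambiguous.
#'
#' @param results non-empty character vector of result calls.
#' @return a single collapsed call.
#' @examples
#' study_conclusion(c("negative", "inconclusive", "positive"))
#' @export
study_conclusion <- function(results) {
  if (length(results) == 0) abort("cannot conclude an empty study")
  stopifnot(all(results %in% RESULT_LEVELS))
  if (any(results == "positive")) return("positive")
  if (all(results == "negative")) return("negative")
  "ambiguous_or_inconclusive"
}

#' Group pseudo-replicates per compound
#'
#' Approach A groups all records of a compound within a TG (one collapsed
#' call per record): variability within and between studies. Approach B first
#' concludes one call per study ([study_conclusion()]) and then groups the
#' study conclusions per compound: variability between studies. Groups with
#' fewer than `cfg$min_replicates` units are dropped.
#'
#' @param records quality-filtered assay-record tibble.
#' @param approach `"A"` or `"B"`.
#' @param cfg a [filter_config()] (supplies `min_replicates`).
#' @return tibble with columns `com_name`, `tg`, `calls` (list column of
#'   collapsed calls), `n_replicates`.
#' @export
group_replicates <- function(records, approach = c("A", "B"),
                             cfg = filter_config()) {
  approach <- match.arg(approach)
  records <- as_tibble(records)
  if (approach == "A") {
    units <- records |>
      mutate(call = collapse_call(.data$result)) |>
      select("com_name", "tg", "call")
  } else {
    units <- records |>
      group_by(.data$com_name, .data$tg, .data$study_ref) |>
      summarise(call = study_conclusion(.data$result), .groups = "drop") |>
      select("com_name", "tg", "call")
  }
  out <- units |>
    group_by(.data$com_name, .data$tg) |>
    summarise(calls = list(.data$call), n_replicates = n(), .groups = "drop") |>
    filter(.data$n_replicates >= cfg$min_replicates)
  out
}

#' Probability of an identical result upon replication
#'
#' For one compound's replicate calls, the default `"modal"` estimator is the
#' modal-category fraction max(counts)/n: the probability that a further
#' replicate agrees with the prevailing call. At the minimum of three
#' replicates, a 2-of-3 split lands exactly on the 66% bin boundary (twice as
#' likely to get the same result as not). The alternative `"pairwise"`
#' estimator, the match probability of two random replicates
#' (sum of squared category shares), is available for sensitivity analysis.
#'
#' @param counts named non-negative integer vector over the collapsed
#'   categories (sum >= 1).
#' @param estimator `"modal"` (default) or `"pairwise"`.
#' @return similarity in \[1/3, 1\] (modal) or \[0, 1\] (pairwise).
#' @examples
#' similarity(c(positive = 2, negative = 1, ambiguous_or_inconclusive = 0))
#' @export
similarity <- function(counts, estimator = c("modal", "pairwise")) {
  estimator <- match.arg(estimator)
  n <- sum(counts)
  if (n < 1) abort("similarity needs at least one replicate")
  if (estimator == "modal") max(counts) / n else sum((counts / n)^2)
}

#' Bin a similarity value
#'
#' Bins are `very_low` (< 66% probability of an identical result), `low`
#' (66-85%, both boundaries included) and `high` (> 85%).
#'
#' @param s numeric vector of similarities in \[0, 1\].
#' @return character vector of bins.
#' @export
bin_similarity <- function(s) {
  stopifnot(all(s >= 0 & s <= 1))
  dplyr::case_when(
    s < 0.66 ~ "very_low",
    s <= 0.85 ~ "low",
    TRUE ~ "high"
  )
}

#' Majority call across replicates
#'
#' The plurality category of the replicate calls. Ties are broken by the
#' fixed precedence positive > ambiguous_or_inconclusive > negative
#' (consistent with the any-positive convention at study level) and flagged.
#'
#' @inheritParams similarity
#' @return list with `call` (collapsed category) and `tie_broken` (logical).
#' @export
majority_call <- function(counts) {
  if (sum(counts) < 1) abort("majority call needs at least one replicate")
  stopifnot(all(names(counts) %in% COLLAPSED_LEVELS))
  prec <- c("positive", "ambiguous_or_inconclusive", "negative")
  full <- setNames(rep(0, 3), prec)
  full[names(counts)] <- counts
  top <- names(full)[full == max(full)]
  list(call = top[1], tie_broken = length(top) > 1)
}

#' Per-compound replicate-similarity summaries
#'
#' Runs the grouping and agreement computation in one step: collapse (A) or
#' conclude-then-collapse (B), drop under-replicated compounds, and compute
#' per compound the category counts, similarity, similarity bin, and
#' majority call.
#'
#' @param records quality-filtered assay-record tibble.
#' @inheritParams group_replicates
#' @inheritParams similarity
#' @return tibble of class `"compound_summary"`: `com_name`, `tg`,
#'   `approach`, `n_replicates`, `n_positive`, `n_negative`,
#'   `n_ambiguous_or_inconclusive`, `similarity`, `bin`, `majority_call`,
#'   `tie_broken`.
#' @export
replicate_similarity <- function(records, approach = c("A", "B"),
                                 cfg = filter_config(),
                                 estimator = c("modal", "pairwise")) {
  approach <- match.arg(approach)
  estimator <- match.arg(estimator)
  groups <- group_replicates(records, approach, cfg)
  if (nrow(groups) == 0) {
    out <- tibble(
      com_name = character(), tg = integer(), approach = character(),
      n_replicates = integer(), n_positive = integer(),
      n_negative = integer(), n_ambiguous_or_inconclusive = integer(),
      similarity = numeric(), bin = character(), majority_call = character(),
      tie_broken = logical()
    )
    class(out) <- c("compound_summary", class(out))
    return(out)
  }
  out <- groups |>
    mutate(stats = purrr::map(.data$calls, function(calls) {
      counts <- vapply(COLLAPSED_LEVELS, function(l) sum(calls == l), integer(1))
      maj <- majority_call(counts)
      tibble(
        n_positive = counts[["positive"]],
        n_negative = counts[["negative"]],
        n_ambiguous_or_inconclusive = counts[["ambiguous_or_inconclusive"]],
        similarity = similarity(counts, estimator),
        bin = bin_similarity(similarity(counts, estimator)),
        majority_call = maj$call,
        tie_broken = maj$tie_broken
      )
    })) |>
    tidyr::unnest("stats") |>
    mutate(approach = approach) |>
    select("com_name", "tg", "approach", "n_replicates", "n_positive",
           "n_negative", "n_ambiguous_or_inconclusive", "similarity", "bin",
           "majority_call", "tie_broken") |>
    arrange(.data$tg, .data$com_name)
  class(out) <- c("compound_summary", class(out))
  out
}

lower_median <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

#' Per-TG variability summary
#'
#' Aggregates per-compound summaries by TG (and approach): number of
#' compounds with enough replicates, the minimum / lower-median / maximum
#' replicate count, and the percentage of compounds per similarity bin.
#'
#' @param summaries a `"compound_summary"` tibble ([replicate_similarity()]).
#' @return tibble of class `"tg_summary"`: `tg`, `approach`, `n_compounds`,
#'   `rep_min`, `rep_median`, `rep_max`, `pct_very_low`, `pct_low`,
#'   `pct_high`.
#' @export
summarize_tg <- function(summaries) {
  out <- as_tibble(summaries) |>
    group_by(.data$tg, .data$approach) |>
    summarise(
      n_compounds = n(),
      rep_min = min(.data$n_replicates),
      rep_median = lower_median(.data$n_replicates),
      rep_max = max(.data$n_replicates),
      pct_very_low = 100 * mean(.data$bin == "very_low"),
      pct_low = 100 * mean(.data$bin == "low"),
      pct_high = 100 * mean(.data$bin == "high"),
      .groups = "drop"
    )
  class(out) <- c("tg_summary", class(out))
  out
}

#' Majority-call composition of each similarity bin
#'
#' The content of the stacked per-TG variability figure: within each
#' similarity bin, how many compounds carry a negative,
#' ambiguous/inconclusive or positive majority call.
#'
#' @inheritParams summarize_tg
#' @return tibble: `tg`, `approach`, `bin`, `majority_call`, `n_compounds`.
#' @export
majority_by_bin <- function(summaries) {
  as_tibble(summaries) |>
    group_by(.data$tg, .data$approach, .data$bin, .data$majority_call) |>
    summarise(n_compounds = n(), .groups = "drop") |>
    arrange(.data$tg, .data$approach,
            match(.data$bin, SIMILARITY_BINS),
            match(.data$majority_call, COLLAPSED_LEVELS))
}
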