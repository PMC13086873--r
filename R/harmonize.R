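#' Collapse raw ECVAM micronucleus categories to four overall calls
#'
#' The ECVAM genotoxicity database reports five raw categories (Positive,
#' Weak positive, Negative, Equivocal, Inconclusive); for cross-database
#' comparison these collapse to four, with weak positives folded into the
#' positive class.
#'
#' @param raw character vector of raw labels (case-insensitive).
#' @return character vector of overall calls
#'   (`positive`/`negative`/`equivocal`/`inconclusive`).
#' @examples
#' collapse_ecvam_category(c("Weak positive", "Negative"))
#' @export
collapse_ecvam_category <- function(raw) {
  key <- stringr::str_squish(tolower(as.character(raw)))
  map <- c(
    "positive" = "positive", "weak positive" = "positive",
    "negative" = "negative", "equivocal" = "equivocal",
    "inconclusive" = "inconclusive"
  )
  out <- unname(map[key])
  if (any(is.na(out))) {
    abort(sprintf("unknown ECVAM category label(s): %s",
                  paste(unique(raw[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Aggregate several overall calls under the any-positive convention
#'
#' A compound with several study-level or group-level calls receives a single
#' overall call: positive in the presence of at least one positive result;
#' negative only when all results are negative; otherwise equivocal if any
#' result is equivocal, else inconclusive.
#'
#' @param calls non-empty character vector of overall calls.
#' @return a single overall call.
#' @examples
#' aggregate_any_positive(c("negative", "positive"))
#' @export
aggregate_any_positive <- function(calls) {
  if (length(calls) == 0) abort("cannot aggregate an empty list of calls")
  stopifnot(all(calls %in% OVERALL_LEVELS))
  if (any(calls == "positive")) return("positive")
  if (all(calls == "negative")) return("negative")
  if (any(calls == "equivocal")) return("equivocal")
  "inconclusive"
}

#' Derive an ISSMIC-style overall micronucleus call from experimental groups
#'
#' ISSMIC concludes per compound from outcomes in experimental groups
#' (species x sex): positive if any group is positive; equivocal if at least
#' one group is equivocal and the others negative; when all groups are
#' negative, the call is negative only with clear evidence of target-cell
#' exposure (target toxicity observed in some group), and inconclusive when
#' neither micronucleus induction nor target-cell toxicity was seen or
#' toxicity information is unavailable.
#'
#' @param groups data frame with columns `group_id` (non-empty text),
#'   `mn_result` (`positive`/`negative`/`equivocal`) and `target_toxicity`
#'   (`observed`/`not_observed`/`unknown`).
#' @return a single overall call.
#' @examples
#' issmic_overall(data.frame(
#'   group_id = c("mouse male", "rat female"),
#'   mn_result = c("positive", "negative"),
#'   target_toxicity = c("unknown", "observed")
#' ))
#' @export
issmic_overall <- function(groups) {
  groups <- as_tibble(groups)
  if (nrow(groups) == 0) abort("cannot conclude from an empty group list")
  stopifnot(
    all(c("group_id", "mn_result", "target_toxicity") %in% names(groups)),
    all(nchar(groups$group_id) > 0),
    all(groups$mn_result %in% c("positive", "negative", "equivocal")),
    all(groups$target_toxicity %in% c("observed", "not_observed", "unknown"))
  )
  if (any(groups$mn_result == "positive")) return("positive")
  if (any(groups$mn_result == "equivocal")) return("equivocal")
  # all groups negative for micronucleus induction
  if (any(groups$target_toxicity == "observed")) return("negative")
  "inconclusive"
}

#' Harmonize a set of raw calls under a named scheme
#'
#' Convenience dispatcher used when several databases are processed with one
#' configuration: `"ecvam_collapse"` applies [collapse_ecvam_category()],
#' `"identity"` passes two-category (positive/negative) data through
#' unchanged and rejects anything else, since no aggregation rule is on
#' record for such databases.
#'
#' @param raw character vector of raw labels.
#' @param scheme `"ecvam_collapse"` or `"identity"`.
#' @return character vector of overall calls.
#' @export
harmonize_calls <- function(raw, scheme = c("identity", "ecvam_collapse")) {
  scheme <- match.arg(scheme)
  if (scheme == "ecvam_collapse") return(collapse_ecvam_category(raw))
  key <- stringr::str_squish(tolower(as.character(raw)))
  if (!all(key %in% c("positive", "negative"))) {
    abort(sprintf(
      "identity scheme accepts only positive/negative calls; got: %s",
      paste(setdiff(unique(key), c("positive", "negative")), collapse = ", ")
    ))
  }
  key
}
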