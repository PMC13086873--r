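#' Parse free-text exposure durations into hours
#'
#' Study records report the experimental period in hours, days or weeks
#' ("0.25 h", "2 days", "13 weeks"); downstream analyses need a single unit.
#' A bare number is taken to be hours already.
#'
#' @param x character vector of durations (`"<number> <unit>"`).
#' @return numeric vector of hours.
#' @examples
#' parse_period(c("24 h", "2 days", "13 weeks"))
#' @export
parse_period <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  blank <- is.na(x) | stringr::str_squish(x) == ""
  todo <- which(!blank)
  if (length(todo) == 0) return(out)
  s <- stringr::str_squish(tolower(x[todo]))
  m <- stringr::str_match(s, "^([0-9]*\\.?[0-9]+)\\s*([a-z]*)$")
  num <- suppressWarnings(as.numeric(m[, 2]))
  unit <- m[, 3]
  mult <- dplyr::case_when(
    unit %in% c("", "h", "hr", "hrs", "hour", "hours") ~ 1,
    unit %in% c("d", "day", "days") ~ 24,
    unit %in% c("w", "wk", "wks", "week", "weeks") ~ 168,
    TRUE ~ NA_real_
  )
  bad <- is.na(num) | is.na(mult)
  if (any(bad)) {
    abort(sprintf(
      "cannot parse exposure period: %s",
      paste(unique(x[todo][bad]), collapse = ", ")
    ))
  }
  hours <- num * mult
  if (any(hours <= 0)) {
    abort("exposure period must be positive")
  }
  out[todo] <- hours
  out
}

parse_tg <- function(x) {
  raw <- as.character(x)
  digits <- stringr::str_extract(raw, "\\d{3}")
  tg <- suppressWarnings(as.integer(digits))
  bad <- !is.na(raw) & raw != "" & (is.na(tg) | !(tg %in% TG_SET))
  if (any(bad)) {
    abort(sprintf(
      "unrecognized test guideline value(s): %s",
      paste(unique(raw[bad]), collapse = ", ")
    ))
  }
  tg
}

#' Read study-level assay records from a CSV file
#'
#' Reads one row per test result into the package's canonical record layout.
#' Mandatory logical fields (`com_name`, `study_ref`, `tg`, `result`,
#' `guideline_qualifier`, `acceptability`) must be mapped by the dialect and
#' present in the file; optional protocol variables mapped to `NA` (or missing
#' from the file) come back as `NA` columns, so exports that hide some test
#' variables remain readable.
#'
#' @param path CSV file (RFC 4180, header row).
#' @param dialect a [efsa_dialect()] object mapping logical fields to columns.
#' @param drop_exact_duplicates drop rows that are identical on every mapped
#'   field. Default `FALSE`: apparently duplicated lines may differ on test
#'   variables hidden from the export, so they are kept.
#' @return A tibble with columns `com_name`, `cas`, `smiles`, `study_ref`,
#'   `guideline_qualifier`, `acceptability`, `tg`, `result`, `species`,
#'   `strain`, `sex`, `route`, `n_individuals`, `exp_period_hours`,
#'   `tissue_exposure_evidence`, `metabolic_activation`, `opinion_year`,
#'   `row` (source row number).
#' @seealso [write_assay_records()], [parse_period()]
#' @export
read_assay_records <- function(path, dialect = efsa_dialect(),
                               drop_exact_duplicates = FALSE) {
  stopifnot(inherits(dialect, "gtx_dialect"))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  cols <- dialect$columns
  mandatory <- c("com_name", "study_ref", "guideline_qualifier",
                 "acceptability", "tg", "result")
  for (f in mandatory) {
    if (is.na(cols[[f]]) || !(cols[[f]] %in% names(raw))) {
      abort(sprintf("mandatory column '%s' (field %s) missing from %s",
                    cols[[f]], f, path))
    }
  }
  pick <- function(f) {
    col <- cols[[f]]
    if (is.na(col) || !(col %in% names(raw))) {
      rep(NA_character_, nrow(raw))
    } else {
      raw[[col]]
    }
  }
  rec <- tibble(
    com_name = pick("com_name"),
    cas = pick("cas"),
    smiles = pick("smiles"),
    study_ref = pick("study_ref"),
    guideline_qualifier = pick("guideline_qualifier"),
    acceptability = pick("acceptability"),
    tg = parse_tg(pick("tg")),
    result = normalize_labels(pick("result"), dialect$result_labels, "result"),
    species = pick("species"),
    strain = pick("strain"),
    sex = normalize_labels(pick("sex"), dialect$sex_labels, "sex"),
    route = pick("route"),
    n_individuals = parse_positive_int(pick("n_individuals"), "n_individuals"),
    exp_period_hours = parse_period(pick("exp_period")),
    tissue_exposure_evidence = pick("tissue_exposure_evidence"),
    metabolic_activation = normalize_labels(pick("metabolic_activation"),
                                            dialect$met_labels,
                                            "metabolic_activation"),
    opinion_year = parse_positive_int(pick("opinion_year"), "opinion_year"),
    row = seq_len(nrow(raw))
  )
  if (drop_exact_duplicates) {
    rec <- distinct(rec, dplyr::across(-"row"), .keep_all = TRUE)
  }
  rec
}

parse_positive_int <- function(x, field) {
  x <- as.character(x)
  out <- suppressWarnings(as.integer(round(as.numeric(x))))
  bad <- !is.na(x) & x != "" & (is.na(out) | out <= 0)
  if (any(bad)) {
    abort(sprintf("invalid %s value(s): %s", field,
                  paste(unique(x[bad]), collapse = ", ")))
  }
  out[is.na(x) | x == ""] <- NA_integer_
  out
}

#' Write assay records back to CSV in a given dialect
#'
#' The inverse of [read_assay_records()]: mapped fields are written under the
#' dialect's column names (durations as hours, e.g. `"24 h"`), so
#' `read_assay_records(write_assay_records(x, f), dialect)` round-trips all
#' mapped fields.
#'
#' @param records tibble as returned by [read_assay_records()].
#' @param path output CSV path.
#' @inheritParams read_assay_records
#' @return `path`, invisibly.
#' @export
write_assay_records <- function(records, path, dialect = efsa_dialect()) {
  cols <- dialect$columns
  out <- list()
  for (f in names(cols)) {
    col <- cols[[f]]
    if (is.na(col)) next
    src <- switch(f,
      tg = as.character(records$tg),
      exp_period = ifelse(is.na(records$exp_period_hours), NA_character_,
                          paste(format_num(records$exp_period_hours), "h")),
      sex = recode_back(records$sex, c(male_and_female = "male/female")),
      as.character(records[[f]])
    )
    out[[col]] <- src
  }
  readr::write_csv(as_tibble(out), path, na = "")
  invisible(path)
}

format_num <- function(x) {
  ifelse(x == round(x), format(as.integer(round(x))), format(x))
}

recode_back <- function(x, map) {
  hit <- x %in% names(map)
  x[hit] <- unname(map[x[hit]])
  x
}

#' Read a per-compound overall-call dataset
#'
#' Reads one overall genotoxicity call per compound for one database. Rows
#' without any chemical identifier (name, CAS or SMILES all empty) are dropped
#' with a warning. Duplicate compounds with identical calls are collapsed;
#' duplicates with conflicting calls are an error unless
#' `duplicate_policy = "worst_case"`, which resolves them any-positive ->
#' positive, else any-equivocal -> equivocal, else all-negative -> negative,
#' else inconclusive.
#'
#' @param path CSV file with identifier column(s) and a call column.
#' @param dialect a [call_dialect()].
#' @param name dataset name used in reports (defaults to the file name).
#' @param vocabulary the overall-call vocabulary this database can emit;
#'   inferred from the observed calls when `NULL`.
#' @param duplicate_policy `"error"` (default) or `"worst_case"`.
#' @return A tibble of class `"call_dataset"` with columns `name`, `cas`,
#'   `smiles`, `call` and attributes `dataset_name` and `vocabulary`.
#' @export
read_call_dataset <- function(path, dialect = call_dialect(),
                              name = basename(path), vocabulary = NULL,
                              duplicate_policy = c("error", "worst_case")) {
  duplicate_policy <- match.arg(duplicate_policy)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  cols <- dialect$columns
  if (!(cols$call %in% names(raw))) {
    abort(sprintf("call column '%s' missing from %s", cols$call, path))
  }
  pick <- function(f) {
    col <- cols[[f]]
    if (is.na(col) || !(col %in% names(raw))) rep(NA_character_, nrow(raw)) else raw[[col]]
  }
  d <- tibble(
    name = pick("name"),
    cas = blank_to_na(pick("cas")),
    smiles = blank_to_na(pick("smiles")),
    call = normalize_labels(pick("call"), dialect$call_labels, "overall call")
  )
  d$name <- blank_to_na(d$name)
  no_id <- is.na(d$name) & is.na(d$cas) & is.na(d$smiles)
  if (any(no_id)) {
    warn(sprintf("dropping %d row(s) without any chemical identifier", sum(no_id)))
    d <- d[!no_id, , drop = FALSE]
  }
  as_call_dataset(d, name = name, vocabulary = vocabulary,
                  duplicate_policy = duplicate_policy)
}

#' Construct a call dataset from a data frame
#'
#' @param x data frame with columns `name` and `call` (optionally `cas`,
#'   `smiles`).
#' @inheritParams read_call_dataset
#' @return A `"call_dataset"` tibble; see [read_call_dataset()].
#' @export
as_call_dataset <- function(x, name = "dataset", vocabulary = NULL,
                            duplicate_policy = c("error", "worst_case")) {
  duplicate_policy <- match.arg(duplicate_policy)
  x <- as_tibble(x)
  if (!("cas" %in% names(x))) x$cas <- NA_character_
  if (!("smiles" %in% names(x))) x$smiles <- NA_character_
  stopifnot(all(c("name", "call") %in% names(x)))
  if (!all(x$call %in% OVERALL_LEVELS)) {
    abort(sprintf("unknown overall call(s): %s",
                  paste(setdiff(unique(x$call), OVERALL_LEVELS), collapse = ", ")))
  }
  x$.key <- compound_key(x$name, x$cas, x$smiles)
  x <- resolve_duplicate_keys(x, duplicate_policy)
  vocab <- vocabulary %||% intersect(OVERALL_LEVELS, unique(x$call))
  if (!all(x$call %in% vocab)) {
    abort("observed call outside the declared vocabulary")
  }
  x <- select(x, "name", "cas", "smiles", "call")
  structure(x, dataset_name = name, vocabulary = vocab,
            class = c("call_dataset", class(x)))
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & stringr::str_squish(x) == ""] <- NA_character_
  x
}

#' Normalize a chemical name for matching
#'
#' Trims, collapses internal whitespace and case-folds. No synonym resolution
#' is attempted.
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  stringr::str_squish(tolower(as.character(x)))
}

# Single equality key with identifier precedence CAS > SMILES > normalized
# name (used for within-dataset de-duplication).
compound_key <- function(name, cas, smiles) {
  dplyr::case_when(
    !is.na(cas) ~ paste0("cas|", stringr::str_squish(cas)),
    !is.na(smiles) ~ paste0("smi|", stringr::str_squish(smiles)),
    TRUE ~ paste0("name|", normalize_name(name))
  )
}

resolve_duplicate_keys <- function(x, policy) {
  dup_keys <- unique(x$.key[duplicated(x$.key)])
  if (length(dup_keys) == 0) return(x)
  keep <- x[!(x$.key %in% dup_keys), , drop = FALSE]
  resolved <- purrr::map_dfr(dup_keys, function(k) {
    g <- x[x$.key == k, , drop = FALSE]
    calls <- unique(g$call)
    if (length(calls) > 1) {
      if (policy == "error") {
        abort(sprintf("conflicting calls for duplicated compound '%s': %s",
                      g$name[1], paste(calls, collapse = ", ")))
      }
      g$call <- aggregate_any_positive(g$call)
    }
    g[1, , drop = FALSE]
  })
  bind_rows(keep, resolved)
}
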