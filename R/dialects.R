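#' Column dialects for study-record and call-dataset files
#'
#' A dialect maps the package's logical field names onto the column names of a
#' particular CSV layout, and carries label maps for the categorical
#' vocabularies. [efsa_dialect()] describes the public EFSA genotoxicity
#' database export (`com_name`, `literature_reference`, `RESULTS`, ...);
#' [call_dialect()] describes a generic per-compound overall-call table with
#' chemical identifiers.
#'
#' Only the mandatory fields must be mapped; optional fields whose column is
#' `NA` (or absent from the file) are returned as `NA` so that files hiding
#' some test variables can still be read.
#'
#' @param ... named overrides, logical field -> column name (use `NA` to mark
#'   a field as absent from the file).
#' @return A named list with class `"gtx_dialect"`: `$columns` (logical field
#'   -> column name), `$result_labels` / `$call_labels` (raw label ->
#'   normalized level), `$sex_labels`, `$met_labels`.
#' @examples
#' d <- efsa_dialect(com_name = "substance")
#' d$columns$com_name
#' @export
efsa_dialect <- function(...) {
  columns <- list(
    com_name = "com_name",
    cas = NA_character_,
    smiles = NA_character_,
    study_ref = "literature_reference",
    guideline_qualifier = "guideline_qualifier",
    acceptability = "acceptability",
    tg = "genotoxguidelines",
    result = "RESULTS",
    species = "SPECIES",
    strain = "STRAIN",
    sex = "SEX",
    route = "ROUTE",
    n_individuals = "NUMBER_INDIVIDUALS",
    exp_period = "EXP_PERIOD",
    tissue_exposure_evidence = "INVIVOTISSUEEXP",
    metabolic_activation = "MET_INDICATOR",
    opinion_year = "opinion_pub_year"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(columns))
  if (length(bad) > 0) {
    abort(paste0("unknown dialect field(s): ", paste(bad, collapse = ", ")))
  }
  columns[names(over)] <- over
  structure(
    list(
      columns = columns,
      result_labels = default_result_labels(),
      sex_labels = default_sex_labels(),
      met_labels = default_met_labels()
    ),
    class = "gtx_dialect"
  )
}

#' @rdname efsa_dialect
#' @export
call_dialect <- function(...) {
  columns <- list(
    name = "name",
    cas = "cas",
    smiles = "smiles",
    call = "call"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(columns))
  if (length(bad) > 0) {
    abort(paste0("unknown dialect field(s): ", paste(bad, collapse = ", ")))
  }
  columns[names(over)] <- over
  structure(
    list(columns = columns, call_labels = default_call_labels()),
    class = "gtx_dialect"
  )
}

default_result_labels <- function() {
  c(
    positive = "positive", negative = "negative",
    ambiguous = "ambiguous", inconclusive = "inconclusive",
    pos = "positive", neg = "negative", amb = "ambiguous", inc = "inconclusive"
  )
}

default_call_labels <- function() {
  c(
    positive = "positive", negative = "negative",
    equivocal = "equivocal", inconclusive = "inconclusive",
    pos = "positive", neg = "negative", eq = "equivocal", inc = "inconclusive"
  )
}

default_sex_labels <- function() {
  c(
    "male" = "male", "m" = "male",
    "female" = "female", "f" = "female",
    "male/female" = "male_and_female", "male and female" = "male_and_female",
    "male_and_female" = "male_and_female",
    "unknown" = "unknown", "not reported" = "unknown"
  )
}

default_met_labels <- function() {
  c(
    "with" = "with", "with metabolic activation" = "with", "+s9" = "with",
    "without" = "without", "without metabolic activation" = "without",
    "-s9" = "without",
    "unknown" = "unknown", "not reported" = "unknown", "not applicable" = "unknown"
  )
}

# Map raw labels through a (lowercased, trimmed) label table; error on unknown
# labels, naming them and their row numbers.
normalize_labels <- function(x, table, field) {
  key <- stringr::str_squish(tolower(as.character(x)))
  out <- unname(table[key])
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    abort(sprintf(
      "unparseable %s label(s): %s (row %s)",
      field,
      paste(unique(x[bad]), collapse = ", "),
      paste(head(which(bad), 5L), collapse = ", ")
    ))
  }
  out[is.na(x) | x == ""] <- NA_character_
  out
}
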