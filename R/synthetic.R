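default_variable_catalogs <- function() {
  list(
    species = tibble(
      option = c("House mouse", "Rat", "Hamster"),
      weight = c(0.60, 0.35, 0.05)
    ),
    strain = tibble(
      option = c("SWISS", "CD-1", "NMRI", "ICR"),
      weight = c(0.30, 0.25, 0.25, 0.20)
    ),
    sex = tibble(
      option = c("male", "male_and_female", "female"),
      weight = c(0.45, 0.50, 0.05)
    ),
    route = tibble(
      option = c("oral: gavage", "intraperitoneal", "oral: unspecified",
                 "inhalation: unspecified", "oral: feed", "dermal",
                 "oral: capsule", "intravenous", "other"),
      weight = c(0.35, 0.30, 0.10, 0.05, 0.08, 0.05, 0.04, 0.02, 0.01)
    ),
    n_individuals = tibble(
      option = c(4, 5, 6, 8, 10),
      weight = c(0.15, 0.40, 0.20, 0.15, 0.10)
    ),
    exp_period_hours = tibble(
      option = c(24, 48, 72),
      weight = c(0.5, 0.35, 0.15)
    ),
    tissue_exposure_evidence = tibble(
      option = c("direct evidence-cytotoxicity",
                 "indirect evidence-systemic toxicity", "no evidence"),
      weight = c(0.35, 0.45, 0.20)
    )
  )
}

#' Configuration of the synthetic EFSA-style data generator
#'
#' Defines a generative model for TG study records with known ground truth:
#' each compound carries a latent genotoxicity class (Bernoulli with
#' `prevalence`); each of its records draws protocol options from the
#' variable catalogs; a genotoxic compound tests positive with probability
#' `plogis(qlogis(baseline_sensitivity) + sum of effect shifts)` for the
#' drawn options, a non-genotoxic one with `false_positive_rate`. A record's
#' call is then replaced by ambiguous or inconclusive (evenly split) with
#' probability `ambiguous_rate`, and a fraction `acceptability_noise` of
#' records is tagged non-acceptable or non-TG-conform to exercise the
#' quality filters.
#'
#' @param seed integer seed; generation is fully reproducible.
#' @param n_compounds number of compounds.
#' @param prevalence probability that a compound is genotoxic.
#' @param tg_set TGs to sample records from.
#' @param studies_per_compound integer range `c(min, max)` of studies per
#'   compound.
#' @param records_per_study integer range `c(min, max)` of records per study.
#' @param variable_catalogs named list of tibbles `option`/`weight`, one per
#'   protocol variable.
#' @param baseline_sensitivity P(positive | genotoxic) at reference options.
#' @param effect_sizes named list, variable -> named numeric vector of
#'   additive log-odds shifts per option (e.g.
#'   `list(strain = c(SWISS = 2.5))`). Effects act on sensitivity only.
#' @param false_positive_rate P(positive | not genotoxic).
#' @param ambiguous_rate probability a record's call is replaced by
#'   ambiguous/inconclusive.
#' @param acceptability_noise fraction of records tagged so that the quality
#'   filters remove them.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L,
                         n_compounds = 60L,
                         prevalence = 0.7,
                         tg_set = 474L,
                         studies_per_compound = c(2L, 6L),
                         records_per_study = c(1L, 3L),
                         variable_catalogs = default_variable_catalogs(),
                         baseline_sensitivity = 0.5,
                         effect_sizes = list(),
                         false_positive_rate = 0.05,
                         ambiguous_rate = 0.05,
                         acceptability_noise = 0.1) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!in01(prevalence)) abort("prevalence must be in [0, 1]")
  if (!is.numeric(baseline_sensitivity) || baseline_sensitivity <= 0 ||
      baseline_sensitivity >= 1) {
    abort("baseline_sensitivity must be in (0, 1)")
  }
  if (!in01(false_positive_rate) || false_positive_rate >= 1) {
    abort("false_positive_rate must be in [0, 1)")
  }
  if (!in01(ambiguous_rate) || ambiguous_rate >= 1) {
    abort("ambiguous_rate must be in [0, 1)")
  }
  if (!in01(acceptability_noise) || acceptability_noise >= 1) {
    abort("acceptability_noise must be in [0, 1)")
  }
  if (n_compounds < 1) abort("n_compounds must be positive")
  if (!all(tg_set %in% TG_SET)) abort("tg_set contains unrecognized TGs")
  stopifnot(length(studies_per_compound) == 2, length(records_per_study) == 2,
            studies_per_compound[1] >= 1, records_per_study[1] >= 1,
            diff(studies_per_compound) >= 0, diff(records_per_study) >= 0)
  for (v in names(variable_catalogs)) {
    cat_v <- variable_catalogs[[v]]
    if (nrow(cat_v) == 0 || any(cat_v$weight <= 0)) {
      abort(sprintf("catalog for %s must be non-empty with positive weights", v))
    }
  }
  for (v in names(effect_sizes)) {
    if (!(v %in% names(variable_catalogs))) {
      abort(sprintf("effect on unknown variable '%s'", v))
    }
    unknown <- setdiff(names(effect_sizes[[v]]),
                       as.character(variable_catalogs[[v]]$option))
    if (length(unknown) > 0) {
      abort(sprintf("effect on unknown option(s) of %s: %s", v,
                    paste(unknown, collapse = ", ")))
    }
  }
  structure(
    list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
         prevalence = prevalence, tg_set = as.integer(tg_set),
         studies_per_compound = as.integer(studies_per_compound),
         records_per_study = as.integer(records_per_study),
         variable_catalogs = variable_catalogs,
         baseline_sensitivity = baseline_sensitivity,
         effect_sizes = effect_sizes,
         false_positive_rate = false_positive_rate,
         ambiguous_rate = ambiguous_rate,
         acceptability_noise = acceptability_noise),
    class = "synth_config"
  )
}

draw_option <- function(catalog, n) {
  catalog$option[sample.int(nrow(catalog), n, replace = TRUE,
                            prob = catalog$weight)]
}

#' Generate synthetic study records with ground truth
#'
#' Draws an EFSA-dialect record table from a [synth_config()] model. Clean
#' records carry `guideline_qualifier = "According to"` and
#' `acceptability = "acceptable"`; noise-tagged records receive either
#' `acceptability = "not acceptable"` or
#' `guideline_qualifier = "No guideline followed"` (evenly split), so the
#' quality filters remove exactly the tagged records.
#'
#' @param cfg a [synth_config()].
#' @return list of class `"synth_data"`:
#'   \item{records}{assay-record tibble in the canonical layout of
#'     [read_assay_records()], plus `record_id`;}
#'   \item{compounds}{ground-truth tibble `com_name`, `genotoxic`;}
#'   \item{record_truth}{per-record ground truth: `record_id`, `com_name`,
#'     `p_positive`, `true_call` (the pre-noise call), `noise_tagged`;}
#'   \item{config}{the configuration used.}
#' @export
generate_records <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, generate_records_impl(cfg))
}

generate_records_impl <- function(cfg) {
  compounds <- tibble(
    com_name = sprintf("SYN-%04d", seq_len(cfg$n_compounds)),
    genotoxic = stats::runif(cfg$n_compounds) < cfg$prevalence
  )
  cats <- cfg$variable_catalogs
  recs <- vector("list", cfg$n_compounds)
  sample_range <- function(rng, n) {
    rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
  }
  for (i in seq_len(cfg$n_compounds)) {
    n_studies <- sample_range(cfg$studies_per_compound, 1)
    per_study <- sample_range(cfg$records_per_study, n_studies)
    n_rec <- sum(per_study)
    recs[[i]] <- tibble(
      com_name = compounds$com_name[i],
      study_ref = rep(sprintf("LIT-%04d-%02d", i, seq_len(n_studies)),
                      per_study),
      tg = cfg$tg_set[sample.int(length(cfg$tg_set), n_rec, replace = TRUE)],
      species = draw_option(cats$species, n_rec),
      strain = draw_option(cats$strain, n_rec),
      sex = draw_option(cats$sex, n_rec),
      route = draw_option(cats$route, n_rec),
      n_individuals = as.integer(draw_option(cats$n_individuals, n_rec)),
      exp_period_hours = as.numeric(draw_option(cats$exp_period_hours, n_rec)),
      tissue_exposure_evidence = draw_option(cats$tissue_exposure_evidence,
                                             n_rec),
      metabolic_activation = NA_character_,
      opinion_year = sample(2005:2016, n_rec, replace = TRUE)
    )
  }
  records <- bind_rows(recs)
  records$record_id <- seq_len(nrow(records))
  # sensitivity model: additive log-odds shifts for the drawn options
  eta <- rep(qlogis(cfg$baseline_sensitivity), nrow(records))
  for (v in names(cfg$effect_sizes)) {
    eff <- cfg$effect_sizes[[v]]
    hit <- match(as.character(records[[v]]), names(eff))
    eta <- eta + ifelse(is.na(hit), 0, eff[hit])
  }
  genotoxic <- compounds$genotoxic[match(records$com_name, compounds$com_name)]
  p_pos <- ifelse(genotoxic, plogis(eta), cfg$false_positive_rate)
  true_call <- ifelse(stats::runif(nrow(records)) < p_pos,
                      "positive", "negative")
  # ambiguity noise: replace the call, split evenly between the two labels
  amb <- stats::runif(nrow(records)) < cfg$ambiguous_rate
  amb_label <- ifelse(stats::runif(nrow(records)) < 0.5,
                      "ambiguous", "inconclusive")
  records$result <- ifelse(amb, amb_label, true_call)
  # acceptability noise: tagged records must fail the quality filters
  noise <- stats::runif(nrow(records)) < cfg$acceptability_noise
  noise_kind <- stats::runif(nrow(records)) < 0.5
  records$guideline_qualifier <- ifelse(noise & noise_kind,
                                        "No guideline followed", "According to")
  records$acceptability <- ifelse(noise & !noise_kind,
                                  "not acceptable", "acceptable")
  records$cas <- NA_character_
  records$smiles <- NA_character_
  records$row <- records$record_id
  records <- records[, c("com_name", "cas", "smiles", "study_ref",
                         "guideline_qualifier", "acceptability", "tg",
                         "result", "species", "strain", "sex", "route",
                         "n_individuals", "exp_period_hours",
                         "tissue_exposure_evidence", "metabolic_activation",
                         "opinion_year", "row", "record_id")]
  structure(
    list(
      records = records,
      compounds = compounds,
      record_truth = tibble(
        record_id = records$record_id,
        com_name = records$com_name,
        p_positive = p_pos,
        true_call = true_call,
        noise_tagged = noise
      ),
      config = cfg
    ),
    class = "synth_data"
  )
}

#' Exact distribution of the modal-fraction similarity
#'
#' For a compound whose replicates are independently positive with
#' probability `p` (two outcomes), enumerates the binomial distribution of
#' the modal-category fraction `max(k, n - k)/n` over `n` replicates — the
#' analytic oracle for the replicate-similarity engine. For example, the
#' probability of a unanimous triple is `p^3 + (1 - p)^3`.
#'
#' @param p per-replicate positive probability.
#' @param n number of replicates (>= 2).
#' @return tibble `similarity`, `probability` (sums to 1).
#' @export
expected_similarity_distribution <- function(p, n) {
  stopifnot(p >= 0, p <= 1, n >= 2)
  k <- 0:n
  tibble(
    similarity = pmax(k, n - k) / n,
    probability = dbinom(k, n, p)
  ) |>
    group_by(.data$similarity) |>
    summarise(probability = sum(.data$probability), .groups = "drop") |>
    arrange(.data$similarity)
}
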