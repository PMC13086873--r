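# Independent brute-force oracles, written directly from the published rules.
# These deliberately do not share code with the package implementation.

# Overall micronucleus call from experimental groups, restated clause by
# clause: positive in >= 1 group -> positive; >= 1 equivocal with the other
# groups negative -> equivocal; all negative with clear evidence of target
# cell exposure -> negative; no induction and no (or unknown) target cell
# toxicity -> inconclusive.
oracle_issmic <- function(mn, tox) {
  if (sum(mn == "positive") >= 1) return("positive")
  others_negative <- function(i) all(mn[-i] %in% c("negative", "equivocal"))
  eq_idx <- which(mn == "equivocal")
  if (length(eq_idx) >= 1 && all(mn[-eq_idx] == "negative")) {
    return("equivocal")
  }
  if (all(mn == "negative")) {
    if (sum(tox == "observed") >= 1) return("negative")
    return("inconclusive")
  }
  stop("unreachable")
}

# Study-level conclusion, restated: all negative -> negative; at least one
# positive -> positive; otherwise (only negative and/or inconclusive or
# ambiguous results) -> inconclusive/ambiguous.
oracle_study_conclusion <- function(results) {
  if (sum(results == "positive") >= 1) return("positive")
  if (all(results == "negative")) return("negative")
  "ambiguous_or_inconclusive"
}

# Two-sided signed-rank p-value by full enumeration of the 2^n sign
# assignments of the ranked absolute differences.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  total <- sum(r)
  w_obs <- min(sum(r[d > 0]), total - sum(r[d > 0]))
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- apply(signs, 1, function(s) {
    plus <- sum(r[s == 1])
    min(plus, total - plus)
  })
  mean(w_all <= w_obs)
}

# Concordance by direct per-compound equality counting.
oracle_concordance <- function(calls_a, calls_b) {
  100 * mean(calls_a == calls_b)
}

# Small record-table builder with filter-passing defaults.
make_records <- function(com_name, result, tg = 471L, study_ref = "S1", ...) {
  n <- max(length(com_name), length(result), length(tg), length(study_ref))
  tibble::tibble(
    com_name = rep_len(com_name, n),
    cas = NA_character_,
    smiles = NA_character_,
    study_ref = rep_len(study_ref, n),
    guideline_qualifier = "According to",
    acceptability = "acceptable",
    tg = rep_len(as.integer(tg), n),
    result = rep_len(result, n),
    species = NA_character_,
    strain = NA_character_,
    sex = NA_character_,
    route = NA_character_,
    n_individuals = NA_integer_,
    exp_period_hours = NA_real_,
    tissue_exposure_evidence = NA_character_,
    metabolic_activation = NA_character_,
    opinion_year = NA_integer_,
    row = seq_len(n),
    ...
  )
}
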