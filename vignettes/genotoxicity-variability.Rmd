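---
title: "Quantifying the variability of genotoxicity test-guideline data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the variability of genotoxicity test-guideline data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(genotoxvar)
library(dplyr)
```

## The problem

Regulatory genotoxicity assessment rests on a small set of standardized OECD
test guidelines (TGs): the bacterial reverse mutation test (TG 471), in vitro
chromosomal aberration and gene mutation assays (TG 473, 476, 487, 490), and
in vivo assays such as the erythrocyte micronucleus test (TG 474) and the bone
marrow chromosomal aberration test (TG 475). Each TG permits protocol variants
(species, strain, route, sampling regime, sex, metabolic activation), so two
TG-conform studies of the same compound are *pseudo-replicates*: replicates up
to protocol options that the guideline allows.

Regulators usually see one study per compound and endpoint, so the replicate
variability of these categorical results is practically invisible to them —
yet it bounds how well any new method (in vitro or in silico) can possibly
agree with the animal data it is validated against. This package quantifies
that variability at three levels:

1. **Between databases** — per-compound *overall calls* from different curated
   databases are harmonized onto one vocabulary and cross-tabulated; their
   concordance rate is the share of common compounds with the same call.
2. **Between pseudo-replicates** — per compound and TG, the probability of an
   identical result upon replication is estimated, binned, and summarised per
   TG, together with the majority call.
3. **Drivers** — two complementary screens ask *which protocol variables* are
   associated with conflicting results (a per-compound random forest) and
   *which protocol options shift sensitivity*, i.e. the fraction of positive
   results (paired Wilcoxon signed-rank tests of per-compound positive
   fractions).

A synthetic-data generator with known ground truth emulates the schema of the
EFSA genotoxicity database, so every stage is testable without downloads.

## Overall-call harmonization

Databases conclude per-compound calls under different conventions. Two
rule-based conventions are implemented:

* a five-to-four **category collapse** (`collapse_ecvam_category()`): raw
  Positive and Weak positive map to positive; Negative, Equivocal and
  Inconclusive map to their like-named categories;
* a **per-group aggregation** (`issmic_overall()`) for in vivo micronucleus
  data reported by experimental group (species × sex): positive if any group
  is positive; else equivocal if any group is equivocal; when all groups are
  negative, negative only with clear evidence of target-cell exposure
  (otherwise inconclusive, since without toxicity at the target one cannot
  distinguish a true negative from a failed exposure).

The rule order positive > equivocal > negative > inconclusive is a design
choice: the convention defines the equivocal call as one equivocal group with
the remaining groups negative, which makes equivocal subordinate to positive
but leaves its interaction with inconclusive-style groups (all-negative, no
toxicity information) unstated. We resolve that open case by letting any
equivocal group dominate a merely-uninformative group; the choice is logged
here rather than asserted as the original curators' intent. Expert
weight-of-evidence judgments (used by some databases "case by case") are not
rule-expressible and are deliberately not simulated.

```{r}
issmic_overall(tibble(
  group_id = c("mouse male", "mouse female"),
  mn_result = c("negative", "negative"),
  target_toxicity = c("not_observed", "unknown")
))
```

## Inter-database concordance

`call_overlap()` matches compounds across datasets with identifier precedence
CAS > SMILES > normalized name (no synonym resolution — names are only
trimmed, case-folded and whitespace-collapsed, because any chemical synonym
step would smuggle in unverifiable chemistry). `cross_tabulate()` and
`concordance_rate()` then reproduce the published comparison: the rate is the
sum of same-call cells over all common compounds. Equivocal or inconclusive
calls compared against a two-category database can never be concordant but
**stay in the denominator** — dropping them would overstate agreement.
Rates are reported both raw and half-up rounded to whole percent, matching
how such tables are printed.

```{r}
x <- xtab_from_counts(
  readr::read_csv(system.file("extdata", "xtab_ecvam_oasis.csv",
                              package = "genotoxvar"),
                  show_col_types = FALSE),
  dataset_a = "ECVAM", dataset_b = "OASIS"
)
x
glance(x)
```

## Pseudo-replicate similarity

Records first pass quality filters (`apply_filters()`): qualifier "According
to" or "Equivalent or similar to", acceptability "acceptable", and one of the
analysed TGs. Apparently duplicated rows are **kept** by default: the public
database hides some test variables, so seemingly identical rows may be
distinct studies; removal is available behind an explicit flag.

Two grouping approaches are offered (`group_replicates()`):

* **Approach A** groups all records of a compound within a TG — variability
  within and between studies;
* **Approach B** first concludes each study (any positive ⇒ positive; all
  negative ⇒ negative; otherwise ambiguous/inconclusive) and then groups the
  study conclusions — the variability a regulator actually faces, since the
  study conclusion is what drives the regulatory call.

Groups need at least `min_replicates = 3` units. Per compound, the calls are
collapsed to three categories (positive / negative / ambiguous-or-
inconclusive) and summarised by the **similarity**: the modal-category
fraction `max(counts)/n`.

*Why the modal fraction?* The analysis bins similarity at 66% and 85% on the
argument that a 66% probability of an identical result means agreement is
twice as likely as disagreement; the modal fraction is the estimator under
which the minimal 2-of-3 split lands exactly on that 66% boundary, which is
how we read the published bin definitions. Because the published text does
not pin the estimator down formally, the pairwise match probability
(sum of squared category shares) is available behind
`similarity(..., estimator = "pairwise")` for sensitivity analysis, but is
never the default. Boundary membership follows the printed labels
("< 66%", "66–85%", "> 85%"): 0.66 and 0.85 belong to the middle bin; raw
(unrounded) similarities are binned.

Majority-call ties are broken positive > ambiguous-or-inconclusive >
negative — the conservative regulatory reading — and flagged with
`tie_broken` so no tie is silent. Replicate-count medians use the lower
median, matching integer-style reporting of replicate counts.

```{r}
synth <- generate_records(synth_config(seed = 42))
rec <- apply_filters(synth$records)
cs <- replicate_similarity(rec, approach = "B")
summarize_tg(cs)
```

The per-TG table (and `majority_by_bin()`, and `autoplot()` on the summary)
mirrors the stacked-bar presentation used in this literature: the share of
compounds in the very-low (< 66%), low (66–85%) and high (> 85%) similarity
ranges, coloured by majority call.

## Random-forest driver screen

For each compound with conflicting results (≥ 2 records, ≥ 2 distinct result
calls), `rf_compound_drivers()` fits a random forest of the protocol
variables (species, strain, number of individuals, sex, route, experimental
period, tissue-exposure evidence, opinion year, literature reference) against
the per-record results:

* trees are grown on bootstrap resamples of the same size as the input;
* at each node, `max(1, floor(sqrt(m)))` candidate variables are drawn; when
  none of the drawn candidates admits an impurity-improving split the search
  extends through the remaining variables in drawn order, so a node only
  becomes a leaf when pure or when nothing varies;
* categorical variables split one-category-vs-rest, numeric variables at
  midpoints between sorted observed values; the default impurity is entropy
  (information gain), with Gini as an option; up to four result classes are
  handled natively by the impurity;
* prediction is by simple majority voting.

The forest is written in plain R rather than delegated to an existing RF
package because the analysis needs a specific, auditable importance metric:
**normalized split counts** — the share of internal nodes split on each
variable — which sums to one whenever any split occurred and is directly
interpretable as "how often the forest used this variable to separate the
conflicting calls". A variable is *relevant* when its share reaches
`threshold = 0.05` (one split in twenty; the source analysis states no
criterion, so the cut-off is explicit and configurable), and a compound is
*explained* when at least one variable is relevant. `coverage_report()`
aggregates relevance across explained compounds. Determinism is part of the
contract: rows are canonically sorted before fitting, so at a fixed seed the
result is invariant to input row order.

With `n_trees = 1`, full candidate set and no bootstrap, the forest reduces
to a deterministic decision tree — that mode is verified in the tests against
hand-computed information gains.

## Option-vs-rest sensitivity testing

`prepare_sensitivity_dataset()` restricts a TG's records to positive/negative
results of compounds with at least one positive — compounds that never test
positive cannot inform what drives sensitivity, and including them would
dilute the paired differences with structural zeros. For a protocol variable
and one of its options, `option_vs_rest_pairs()` computes per compound the
positive fraction under the option and under all other options combined,
keeping only compounds tested in both groups (pairing each compound with
itself controls for the compound's intrinsic genotoxicity). The mean paired
difference is the effect size; a two-sided Wilcoxon signed-rank test
(`signed_rank_test()`) provides the p-value at α = 0.10:

* zero differences are dropped; ties among absolute differences get average
  ranks; `W` is the smaller signed rank-sum;
* the p-value is exact (from the signed-rank null distribution) for up to 12
  non-zero untied differences, otherwise a normal approximation with
  continuity correction and tie-corrected variance; all-zero differences
  give `p = 1`;
* the test is two-sided because direction is reported separately through the
  mean difference.

Panels (`run_panel()`) add three conventions from the field: the four oral
route labels are pooled into one "oral" group; the sex comparison is
restricted to records reported as male or male/female (too few female-only
records exist to analyse); experimental period and number of individuals are
dichotomized at their per-TG median with ties to the lower group (the
published definitions of the two dichotomies conflict slightly at the median;
a uniform ties-to-lower rule is used and noted here). Comparisons with fewer
than 3 non-zero differences are reported as skipped ("not enough compounds
to produce a p-value").

```{r}
panel <- tibble(tg = 474L, variable = "strain", option = "SWISS")
run_panel(rec, panel)
```

## The synthetic-data generator

`synth_config()` / `generate_records()` define the test bed: each compound is
genotoxic with probability `prevalence`; records draw protocol options from
weighted catalogs; a genotoxic compound's record is positive with probability
`plogis(qlogis(baseline_sensitivity) + Σ effects)` for its drawn options, a
non-genotoxic one with `false_positive_rate`. Effects are additive log-odds
shifts on **sensitivity only** (specificity fixed), because the sensitivity
analyses concern positive fractions. Ambiguous/inconclusive results are
modelled as post-hoc label replacement (probability `ambiguous_rate`, evenly
split between the two labels) — the simplest mechanism that exercises the
collapsing rules — rather than as a third latent outcome. A fraction
`acceptability_noise` of records is tagged non-acceptable or non-TG-conform,
and the quality filters must remove exactly those.

Default conditions were fixed once, at design time, to what a dossier-style
genotoxicity dataset plausibly looks like: 60 compounds, prevalence 0.7
(databases of regulatory concern are enriched in positives), 2–6 studies per
compound with 1–3 records each (3–18 records per compound, within the 3–23
replicate range such datasets show), baseline sensitivity 0.5, mouse-strain
catalog SWISS/CD-1/NMRI/ICR with weights 0.30/0.25/0.25/0.20, route catalog
dominated by oral gavage and intraperitoneal administration, 5% false
positives, 5% ambiguity, 10% acceptability noise. A design-stage power
calculation under these conditions showed that a +2.5 log-odds sensitivity
shift on one strain is detectable by the paired panel with ≥ 80% power at 60
compounds, so +2.5 is the canonical injected effect for power demonstrations;
smaller shifts (e.g. +1.5) are detectable only with more replicates per
compound than these conditions provide.

`expected_similarity_distribution()` is the analytic companion: for
two-outcome replicates it enumerates the binomial law of the modal fraction
(e.g. the probability of a unanimous triple is `p³ + (1−p)³`), against which
the empirical similarity distribution of the generator is checked.

```{r}
expected_similarity_distribution(p = 0.7, n = 3)
```

What the generator deliberately does **not** emulate: correlation between
protocol options and compound identity (real databases test related
pesticides under related protocols), missing-not-at-random metadata, hidden
test variables, and chemical-identifier noise. Passing tests on synthetic
data therefore demonstrate that the pipeline's statistics behave as designed
under a known model — not that real EFSA data satisfy that model.

## Numerical choices and degenerate inputs

* Similarity comparisons at the 0.66/0.85 boundaries are exact rational
  arithmetic (counts over n), so 2/3 reliably lands in the middle bin.
* Half-up rounding (`floor(x + 0.5)`) is used for reported integer percents;
  R's banker's rounding would round 43.5 to 44 in some tables printed as 43.
* The forest declines splits with impurity gain ≤ 1e−12 to avoid walking
  into zero-information recursion; numeric `NA` routes to the right child
  (deterministic, and exercised only when metadata are incomplete).
* Empty inputs are contracts, not accidents: empty overlap is allowed,
  concordance of an empty table is an error, empty study lists and all-zero
  count vectors are errors, an all-zero-difference signed-rank test returns
  `p = 1`.
* All randomness flows from explicit seeds; the pipeline (`run_pipeline()`)
  expands one master seed deterministically per stage and records it in a
  JSON manifest with an input hash, so any run can be reproduced exactly.

## Problem sizes used in the checks

The shipped checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerances tested: 500 null datasets for the type-I error of
the panel (binomial SE ≈ 1.3 percentage points), 100 seeded runs each for
panel power and forest recovery, and 2100 three-replicate compounds for the
similarity sampling law (SE ≈ 1 percentage point per support point). The
exhaustive rule checks (group aggregation with up to 3 groups; study
conclusions for all result tuples up to length 4) are complete enumerations,
not samples.

## Known limitations

* Concordance is raw agreement; no chance-corrected statistic (κ) is part of
  the reproduction scope.
* The modal-fraction reading of "probability of identical results" is a
  documented interpretation of the published bins, not a certainty; the
  pairwise estimator is provided for sensitivity analysis.
* The random-forest screen identifies variables *associated with* conflicting
  results per compound; it does not model confounding between variables, and
  the paired sensitivity tests do not correct for mixed effects across
  compounds — both are explicit non-goals.
* Chemical identity matching is string-based; no synonym or structure
  resolution is attempted.
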