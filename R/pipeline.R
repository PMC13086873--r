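#' Run the full variability pipeline
#'
#' Wires the stages end to end: quality filtering, per-compound replicate
#' similarity under approaches A and B with per-TG summaries, the per-
#' compound random-forest driver screen on the most populated TG, and an
#' optional option-vs-rest sensitivity panel. All randomness derives from a
#' single seed, expanded deterministically per stage. When `out_dir` is
#' given, every stage result is written as CSV together with a JSON run
#' manifest (input hash, seed, package version, timestamp).
#'
#' @param records assay-record tibble; alternatively pass `config` to
#'   generate synthetic records.
#' @param config optional [synth_config()] used when `records` is `NULL`
#'   (its seed is replaced by `seed`).
#' @param seed master seed for the run.
#' @param filter_cfg a [filter_config()].
#' @param rf_tg TG for the driver screen; default the most populated TG
#'   after filtering. Set `NA` to skip the screen.
#' @param panel optional sensitivity panel ([run_panel()]).
#' @param assoc_cfg an [assoc_config()].
#' @param n_trees forest size for the driver screen.
#' @param out_dir optional output directory for CSVs and the manifest.
#' @return list of class `"gtx_pipeline"`: `filtered`, `compound_summary`
#'   (A and B stacked), `tg_summary`, `majority_by_bin`, `rf_drivers`,
#'   `coverage`, `sensitivity`, `manifest`.
#' @export
run_pipeline <- function(records = NULL, config = NULL, seed = 1L,
                         filter_cfg = filter_config(), rf_tg = NULL,
                         panel = NULL, assoc_cfg = assoc_config(),
                         n_trees = 100L, out_dir = NULL) {
  seed <- as.integer(seed)
  if (is.null(records)) {
    if (is.null(config)) config <- synth_config(seed = seed)
    config$seed <- seed
    records <- generate_records(config)$records
  }
  filtered <- apply_filters(records, filter_cfg)
  comp <- bind_rows(
    replicate_similarity(filtered, "A", filter_cfg),
    replicate_similarity(filtered, "B", filter_cfg)
  )
  tg_sum <- summarize_tg(comp)
  maj <- majority_by_bin(comp)
  if (is.null(rf_tg)) {
    tg_counts <- table(filtered$tg)
    rf_tg <- if (length(tg_counts) > 0) {
      as.integer(names(tg_counts)[which.max(tg_counts)])
    } else {
      NA_integer_
    }
  }
  drivers <- NULL
  coverage <- NULL
  if (!is.na(rf_tg)) {
    drivers <- rf_compound_drivers(filtered, tg = rf_tg, n_trees = n_trees,
                                   seed = seed + 1000L)
    coverage <- coverage_report(drivers)
  }
  sensitivity <- if (!is.null(panel)) {
    run_panel(filtered, panel, assoc_cfg)
  } else {
    NULL
  }
  manifest <- list(
    tool = "genotoxvar",
    version = as.character(utils::packageVersion("genotoxvar")),
    seed = seed,
    rf_tg = rf_tg,
    n_records_in = nrow(records),
    n_records_filtered = nrow(filtered),
    input_hash = hash_object(records),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  out <- structure(
    list(filtered = filtered, compound_summary = comp, tg_summary = tg_sum,
         majority_by_bin = maj, rf_drivers = drivers, coverage = coverage,
         sensitivity = sensitivity, manifest = manifest),
    class = "gtx_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$compound_summary,
                   file.path(out_dir, "compound_summary.csv"))
  readr::write_csv(as_tibble(x$tg_summary), file.path(out_dir, "tg_summary.csv"))
  readr::write_csv(x$majority_by_bin, file.path(out_dir, "majority_by_bin.csv"))
  if (!is.null(x$rf_drivers) && nrow(x$rf_drivers) > 0) {
    flat <- x$rf_drivers |>
      mutate(relevant = purrr::map_chr(.data$relevant, paste, collapse = ";")) |>
      select(-"importance")
    readr::write_csv(flat, file.path(out_dir, "rf_drivers.csv"))
    readr::write_csv(x$coverage, file.path(out_dir, "rf_coverage.csv"))
  }
  if (!is.null(x$sensitivity)) {
    readr::write_csv(as_tibble(x$sensitivity),
                     file.path(out_dir, "sensitivity_panel.csv"))
  }
  jsonlite::write_json(x$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.gtx_pipeline <- function(x, ...) {
  cat("Genotoxicity variability pipeline run\n")
  cat(sprintf("  records: %d in, %d after quality filters\n",
              x$manifest$n_records_in, x$manifest$n_records_filtered))
  cat(sprintf("  compounds summarised: %d (A: %d, B: %d)\n",
              nrow(x$compound_summary),
              sum(x$compound_summary$approach == "A"),
              sum(x$compound_summary$approach == "B")))
  if (!is.null(x$rf_drivers)) {
    cat(sprintf("  driver screen (TG %s): %d compounds, %d explained\n",
                x$manifest$rf_tg, nrow(x$rf_drivers),
                sum(x$rf_drivers$explained)))
  }
  if (!is.null(x$sensitivity)) {
    cat(sprintf("  sensitivity panel: %d tests, %d significant\n",
                nrow(x$sensitivity),
                sum(x$sensitivity$significant, na.rm = TRUE)))
  }
  invisible(x)
}
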