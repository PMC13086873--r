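#' Overlap two call datasets by compound identity
#'
#' Matches compounds across two datasets with identifier precedence: CAS
#' number where both sides have one, then SMILES among the remainder, then
#' the case/whitespace-normalized chemical name. Each compound contributes at
#' most one matched pair.
#'
#' @param a,b `"call_dataset"` tibbles (see [read_call_dataset()]).
#' @return tibble with one row per common compound: `name`, `cas`, `smiles`
#'   (from `a`), `matched_on` (`cas`/`smiles`/`name`), `call_a`, `call_b`.
#' @export
call_overlap <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  a$.i <- seq_len(nrow(a)); b$.i <- seq_len(nrow(b))
  pairs <- list()
  match_stage <- function(a, b, key_a, key_b, label) {
    ka <- key_a; kb <- key_b
    ok_a <- !is.na(ka) & !duplicated(ka)
    ok_b <- !is.na(kb) & !duplicated(kb)
    idx <- match(ka, ifelse(ok_b, kb, NA_character_))
    hit <- which(ok_a & !is.na(idx))
    if (length(hit) == 0) return(NULL)
    tibble(
      name = a$name[hit], cas = a$cas[hit], smiles = a$smiles[hit],
      matched_on = label,
      call_a = a$call[hit], call_b = b$call[idx[hit]],
      .ia = a$.i[hit], .ib = b$.i[idx[hit]]
    )
  }
  remaining_a <- a; remaining_b <- b
  for (stage in c("cas", "smiles", "name")) {
    key_a <- switch(stage,
      cas = stringr::str_squish(remaining_a$cas),
      smiles = stringr::str_squish(remaining_a$smiles),
      name = normalize_name(remaining_a$name)
    )
    key_b <- switch(stage,
      cas = stringr::str_squish(remaining_b$cas),
      smiles = stringr::str_squish(remaining_b$smiles),
      name = normalize_name(remaining_b$name)
    )
    key_a[!is.na(key_a) & key_a == ""] <- NA_character_
    key_b[!is.na(key_b) & key_b == ""] <- NA_character_
    m <- match_stage(remaining_a, remaining_b, key_a, key_b, stage)
    if (!is.null(m)) {
      pairs[[stage]] <- select(m, -".ia", -".ib")
      remaining_a <- remaining_a[!(remaining_a$.i %in% m$.ia), , drop = FALSE]
      remaining_b <- remaining_b[!(remaining_b$.i %in% m$.ib), , drop = FALSE]
    }
  }
  out <- bind_rows(pairs)
  if (nrow(out) == 0) {
    out <- tibble(name = character(), cas = character(), smiles = character(),
                  matched_on = character(), call_a = character(),
                  call_b = character())
  }
  attr(out, "dataset_a") <- attr(a, "dataset_name", exact = TRUE) %||% "a"
  attr(out, "dataset_b") <- attr(b, "dataset_name", exact = TRUE) %||% "b"
  out
}

#' Cross-tabulate matched overall calls
#'
#' Builds the distribution of overall calls over the common compounds of two
#' databases: a matrix with one row per call in the first dataset's
#' vocabulary and one column per call in the second's.
#'
#' @param pairs tibble of matched pairs from [call_overlap()], or any data
#'   frame with `call_a`/`call_b` columns.
#' @param row_levels,col_levels call vocabularies for rows/columns; default
#'   the four-level overall-call vocabulary restricted to observed calls.
#' @param dataset_a,dataset_b display names.
#' @return object of class `"call_xtab"`: list with `counts` (integer
#'   matrix), `total`, `dataset_a`, `dataset_b`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
cross_tabulate <- function(pairs, row_levels = NULL, col_levels = NULL,
                           dataset_a = NULL, dataset_b = NULL) {
  pairs <- as_tibble(pairs)
  row_levels <- row_levels %||%
    intersect(OVERALL_LEVELS, unique(c(pairs$call_a, character())))
  col_levels <- col_levels %||%
    intersect(OVERALL_LEVELS, unique(c(pairs$call_b, character())))
  if (length(row_levels) == 0) row_levels <- OVERALL_LEVELS
  if (length(col_levels) == 0) col_levels <- OVERALL_LEVELS
  stopifnot(all(pairs$call_a %in% row_levels), all(pairs$call_b %in% col_levels))
  counts <- table(
    factor(pairs$call_a, levels = row_levels),
    factor(pairs$call_b, levels = col_levels)
  )
  counts <- matrix(as.integer(counts), nrow = length(row_levels),
                   dimnames = list(row_levels, col_levels))
  structure(
    list(
      counts = counts,
      total = sum(counts),
      dataset_a = dataset_a %||% attr(pairs, "dataset_a", exact = TRUE) %||% "a",
      dataset_b = dataset_b %||% attr(pairs, "dataset_b", exact = TRUE) %||% "b"
    ),
    class = "call_xtab"
  )
}

#' Build a cross-tabulation directly from printed counts
#'
#' Published database comparisons are printed as contingency tables; this
#' constructor accepts them as a long data frame of `call_a`, `call_b`, `n`.
#'
#' @param counts data frame with columns `call_a`, `call_b`, `n`.
#' @inheritParams cross_tabulate
#' @return a `"call_xtab"` object.
#' @export
xtab_from_counts <- function(counts, row_levels = NULL, col_levels = NULL,
                             dataset_a = "a", dataset_b = "b") {
  counts <- as_tibble(counts)
  stopifnot(all(c("call_a", "call_b", "n") %in% names(counts)),
            all(counts$n >= 0))
  row_levels <- row_levels %||% intersect(OVERALL_LEVELS, unique(counts$call_a))
  col_levels <- col_levels %||% intersect(OVERALL_LEVELS, unique(counts$call_b))
  m <- matrix(0L, length(row_levels), length(col_levels),
              dimnames = list(row_levels, col_levels))
  for (i in seq_len(nrow(counts))) {
    m[counts$call_a[i], counts$call_b[i]] <-
      m[counts$call_a[i], counts$call_b[i]] + as.integer(counts$n[i])
  }
  structure(
    list(counts = m, total = sum(m), dataset_a = dataset_a,
         dataset_b = dataset_b),
    class = "call_xtab"
  )
}

#' Concordance rate of a call cross-tabulation
#'
#' The concordance rate is the sum of the counts on the like-named cells
#' (same overall call in both databases) divided by the total number of
#' common compounds. Calls outside the shared vocabulary (e.g. equivocal or
#' inconclusive against a two-category database) can never be concordant but
#' stay in the denominator. `rate_rounded` applies half-up rounding to whole
#' percent for reporting; the raw rate is retained.
#'
#' @param x a `"call_xtab"`.
#' @return one-row tibble: `dataset_a`, `dataset_b`, `n_common`, `concordant`,
#'   `rate_percent` (raw), `rate_rounded` (integer percent).
#' @export
concordance_rate <- function(x) {
  stopifnot(inherits(x, "call_xtab"))
  if (x$total == 0) abort("cannot compute concordance of an empty overlap")
  shared <- intersect(rownames(x$counts), colnames(x$counts))
  concordant <- sum(vapply(shared, function(l) x$counts[l, l], numeric(1)))
  rate <- 100 * concordant / x$total
  tibble(
    dataset_a = x$dataset_a, dataset_b = x$dataset_b,
    n_common = x$total, concordant = as.integer(concordant),
    rate_percent = rate,
    rate_rounded = as.integer(floor(rate + 0.5))
  )
}

#' @export
print.call_xtab <- function(x, ...) {
  cat(sprintf("Overall-call cross-tabulation: %s (rows) vs %s (columns), n = %d\n",
              x$dataset_a, x$dataset_b, x$total))
  print(x$counts)
  invisible(x)
}

#' @describeIn cross_tabulate long tibble of cells (`call_a`, `call_b`, `n`,
#'   `concordant`).
#' @param x a `"call_xtab"`.
#' @param ... unused.
#' @export
tidy.call_xtab <- function(x, ...) {
  long <- as.data.frame.table(as.table(x$counts), stringsAsFactors = FALSE)
  names(long) <- c("call_a", "call_b", "n")
  long$n <- as.integer(long$n)
  long$concordant <- long$call_a == long$call_b
  as_tibble(long)
}

#' @describeIn cross_tabulate one-row summary, the [concordance_rate()].
#' @export
glance.call_xtab <- function(x, ...) {
  concordance_rate(x)
}
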