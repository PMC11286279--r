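# Dataset-level comparison of all six variants ---------------------------

#' Compare all BWT variants of a collection
#'
#' Builds all six transforms of the collection (multidollar and
#' concatenation BWT under the input order), and assembles the statistics
#' used to describe how much the variants differ on a dataset: per-variant
#' run counts and average run lengths, the run-minimizing baseline,
#' pairwise normalized Hamming distances among the five separator-based
#' texts, edit distances between the eBWT and each separator-based text
#' (on a seeded subsample of whole sequences when requested), the number
#' of interesting intervals, the fraction of transform positions lying in
#' interesting intervals (reported against both the `N` and the `N + k`
#' denominator), and the collection's variability.
#'
#' @param m A [string_collection].
#' @param subsample_size Optional number of whole sequences to subsample
#'   for the edit-distance comparison (the Hamming statistics always use
#'   the full collection).
#' @param seed Seed for the subsample draw (default 1).
#' @param edit_cap Length cap passed to [edit_distance]; edit distances
#'   are skipped (NA) when the texts exceed it.
#' @return A list of class `bwt_comparison`; see the fields of the
#'   printed summary.
#' @export
compare_all <- function(m, subsample_size = NULL, seed = 1L, edit_cap = 1e5) {
  stopifnot(inherits(m, "string_collection"))
  variants <- c("ebwt", "dolebwt", "mdolbwt", "colexbwt", "optbwt", "concbwt")
  tf <- lapply(variants, function(v) bwt_transform(m, v))
  names(tf) <- variants
  texts <- vapply(tf, `[[`, "", "text")
  runs <- vapply(texts, runs_of, 1L)
  nlen <- vapply(tf, `[[`, 1L, "length")
  nr <- nlen / runs
  sep_variants <- c("dolebwt", "mdolbwt", "colexbwt", "optbwt", "concbwt")
  # pairwise normalized Hamming among the separator-based texts
  hmat <- matrix(NA_real_, 5L, 5L, dimnames = list(sep_variants, sep_variants))
  for (i in seq_len(5L)) for (j in seq_len(5L)) {
    hmat[i, j] <- hamming(texts[sep_variants[i]], texts[sep_variants[j]],
                          normalized = TRUE)
  }
  # the headline average excludes the run-minimizing baseline
  noopt <- setdiff(sep_variants, "optbwt")
  avg_hamming <- mean(hmat[noopt, noopt][upper.tri(diag(4L))])
  # edit distance of each separator-based text against the eBWT,
  # optionally on a subsample of whole sequences
  msub <- m
  if (!is.null(subsample_size) && subsample_size < m$k) {
    idx <- withr::with_seed(seed, sort(sample.int(m$k, subsample_size)))
    msub <- string_collection(m$strings[idx])
  }
  sub_texts <- if (identical(msub, m)) texts else {
    v <- vapply(variants, function(v) bwt_transform(msub, v)$text, "")
    stats::setNames(v, variants)
  }
  edit_vs_ebwt <- vapply(sep_variants, function(v) {
    if (nchar(sub_texts[v]) > edit_cap || nchar(sub_texts["ebwt"]) > edit_cap)
      return(NA_integer_)
    edit_distance(sub_texts["ebwt"], sub_texts[v], cap = edit_cap)
  }, 1L)
  iv <- interesting_intervals(m)
  int_len <- if (length(iv)) sum(vapply(iv, `[[`, 1L, "width")) else 0L
  vb <- variability(m)
  structure(list(
    n_sequences = m$k,
    avg_length = m$total_length / m$k,
    total_length = m$total_length,
    transforms = tf,
    runs = runs,
    n_over_r = nr,
    max_nr_nonopt = max(nr[setdiff(variants, "optbwt")]),
    min_nr_nonopt = min(nr[setdiff(variants, "optbwt")]),
    nr_optimal = nr[["optbwt"]],
    hamming_normalized = hmat,
    avg_hamming = avg_hamming,
    edit_vs_ebwt = edit_vs_ebwt,
    subsample_size = msub$k,
    n_interesting_intervals = length(iv),
    interval_positions = int_len,
    interval_ratio_nm = int_len / m$total_length,
    interval_ratio_nmk = int_len / (m$total_length + m$k),
    variability = vb$value,
    variability_defined = vb$defined),
    class = "bwt_comparison")
}

#' @export
print.bwt_comparison <- function(x, ...) {
  cat(sprintf("BWT variant comparison: %d sequences, avg length %.1f\n",
              x$n_sequences, x$avg_length))
  cat(sprintf("  interesting intervals: %d (%.4f of N, %.4f of N+k positions)\n",
              x$n_interesting_intervals, x$interval_ratio_nm,
              x$interval_ratio_nmk))
  cat(sprintf("  variability: %s\n",
              if (x$variability_defined) sprintf("%.4f", x$variability)
              else "undefined (no interesting intervals)"))
  cat(sprintf("  avg normalized Hamming between $-separated BWTs: %.5f\n",
              x$avg_hamming))
  cat(sprintf("  n/r: max %.3f, min %.3f (non-optimal variants), optimal %.3f\n",
              x$max_nr_nonopt, x$min_nr_nonopt, x$nr_optimal))
  cat("  runs per variant:\n")
  for (v in names(x$runs)) {
    cat(sprintf("    %-9s r = %-6d n/r = %.3f\n", v, x$runs[[v]],
                x$n_over_r[[v]]))
  }
  invisible(x)
}

# Table-style flat summary used by the JSON/TSV writers.
comparison_summary <- function(x) {
  list(
    "number of sequences" = x$n_sequences,
    "average length" = x$avg_length,
    "number of interesting intervals" = x$n_interesting_intervals,
    "ratio of positions in interesting intervals (of N)" = x$interval_ratio_nm,
    "ratio of positions in interesting intervals (of N plus k)" = x$interval_ratio_nmk,
    "variability" = x$variability,
    "average normalized Hamming distance" = x$avg_hamming,
    "max n/r" = x$max_nr_nonopt,
    "min n/r" = x$min_nr_nonopt,
    "n/r optimal" = x$nr_optimal)
}
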