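# Seeded synthetic collection generator ----------------------------------

#' Generate a synthetic string collection
#'
#' Deterministic, seeded generator of test collections. Three modes cover
#' the regimes in which the BWT variants behave differently:
#'
#' * `"mutated_copies"` (default): one random ancestor string per
#'   collection, each member an independently mutated copy (per-position
#'   substitutions at `sub_rate`, optional single-character indels at
#'   `indel_rate`). Collections of many similar sequences have many
#'   shared suffixes, hence many interesting intervals — the regime where
#'   variant differences are largest.
#' * `"iid"`: independent uniform strings; few shared suffixes, variants
#'   nearly coincide.
#' * `"shared_suffix"`: independent strings with an explicit common
#'   suffix appended to the first `suffix_count` members, forcing an
#'   interesting interval at that suffix.
#'
#' The same arguments and seed always reproduce the same collection; the
#' global random state is left untouched.
#'
#' @param k Number of strings.
#' @param length_range Integer min/max length per string (before any
#'   suffix or indels).
#' @param alphabet Symbol set (default DNA `A`,`C`,`G`,`T`).
#' @param mode Generation mode, see above.
#' @param sub_rate Per-position substitution probability
#'   (`mutated_copies`).
#' @param indel_rate Per-position insertion/deletion probability
#'   (`mutated_copies`).
#' @param suffix Suffix string for `shared_suffix` mode.
#' @param suffix_count How many members receive `suffix` (default all).
#' @param seed Integer seed.
#' @return A [string_collection].
#' @examples
#' generate_collection(5, c(20, 20), seed = 1)
#' @export
generate_collection <- function(k, length_range = c(20L, 50L),
                                alphabet = c("A", "C", "G", "T"),
                                mode = c("mutated_copies", "iid",
                                         "shared_suffix"),
                                sub_rate = 0.02, indel_rate = 0,
                                suffix = "CA", suffix_count = k,
                                seed = 1L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  length_range <- as.integer(length_range)
  if (k < 1L) stop("k must be at least 1")
  if (length(length_range) == 1L) length_range <- rep(length_range, 2L)
  if (length_range[1L] < 1L || length_range[2L] < length_range[1L])
    stop("degenerate length range")
  rand_len <- function() {
    length_range[1L] + sample.int(length_range[2L] - length_range[1L] + 1L, 1L) - 1L
  }
  rand_str <- function(n) paste(sample(alphabet, n, replace = TRUE),
                                collapse = "")
  strings <- withr::with_seed(seed, {
    switch(mode,
      iid = vapply(seq_len(k), function(i) rand_str(rand_len()), ""),
      mutated_copies = {
        anc <- str_chars(rand_str(rand_len()))
        vapply(seq_len(k), function(i) {
          ch <- anc
          subs <- stats::runif(length(ch)) < sub_rate
          if (any(subs)) {
            ch[subs] <- vapply(ch[subs], function(c0) {
              sample(setdiff(alphabet, c0), 1L)
            }, "")
          }
          if (indel_rate > 0) {
            out <- character(0)
            for (c0 in ch) {
              u <- stats::runif(1L)
              if (u < indel_rate / 2) next                    # deletion
              out <- c(out, c0)
              if (u >= indel_rate / 2 && u < indel_rate)      # insertion
                out <- c(out, sample(alphabet, 1L))
            }
            if (length(out) == 0L) out <- sample(alphabet, 1L)
            ch <- out
          }
          paste(ch, collapse = "")
        }, "")
      },
      shared_suffix = {
        base <- vapply(seq_len(k), function(i) rand_str(rand_len()), "")
        idx <- seq_len(min(suffix_count, k))
        base[idx] <- paste0(base[idx], suffix)
        base
      })
  })
  string_collection(strings)
}
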