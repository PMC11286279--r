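# Pairwise distances between transform texts ------------------------------

#' Hamming distance between two transform texts
#'
#' Number of positions at which two equal-length texts differ; optionally
#' normalized by the length. For separator-based BWTs of the same
#' collection every mismatch lies inside an interesting interval, so the
#' distance is bounded by the total interval length.
#'
#' @param l1,l2 Strings of equal length.
#' @param normalized Divide by the length (default `FALSE`).
#' @return The (possibly normalized) mismatch count.
#' @export
hamming <- function(l1, l2, normalized = FALSE) {
  a <- str_chars(l1); b <- str_chars(l2)
  if (length(a) != length(b))
    stop("texts have different lengths; use edit_distance() instead")
  d <- sum(a != b)
  if (normalized) d / length(a) else d
}

#' Positions at which two equal-length texts differ
#'
#' @param l1,l2 Strings of equal length.
#' @return Integer vector of 1-based mismatch positions.
#' @export
mismatch_positions <- function(l1, l2) {
  a <- str_chars(l1); b <- str_chars(l2)
  if (length(a) != length(b)) stop("texts have different lengths")
  which(a != b)
}

#' Unit-cost edit (Levenshtein) distance between two texts
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming one text into the other; the comparison
#' used between the eBWT (length `N`) and the separator-based variants
#' (length `N + k`). Computed by the standard dynamic program (via
#' [utils::adist]). Quadratic in the text length, hence the size cap;
#' compare subsampled collections when texts are long.
#'
#' @param l1,l2 Strings.
#' @param cap Maximum length accepted for either text (default `1e5`).
#' @return The edit distance, an integer.
#' @export
edit_distance <- function(l1, l2, cap = 1e5) {
  if (nchar(l1) > cap || nchar(l2) > cap)
    stop("texts exceed the edit-distance cap; subsample the collection")
  as.integer(utils::adist(l1, l2))
}
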