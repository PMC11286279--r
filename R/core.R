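# Core string algebra: primitive roots, runs, conjugates, omega-order ----

#' Primitive root and exponent of a string
#'
#' Every string `t` can be written uniquely as `U^m` with `U` primitive
#' (not itself a power of a shorter string); `U` is the root and `m` the
#' exponent of `t`. Computed by checking each divisor of the length as a
#' candidate period.
#'
#' @param t A non-empty string.
#' @return A list of class `root_decomposition` with fields `root` and
#'   `exponent`.
#' @examples
#' primitive_root("ABAB")   # root "AB", exponent 2
#' primitive_root("CAGAGA") # primitive, exponent 1
#' @export
primitive_root <- function(t) {
  ch <- str_chars(t)
  n <- length(ch)
  if (n == 0L) stop("cannot decompose the empty string")
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    if (identical(rep(ch[seq_len(p)], n %/% p), ch)) {
      return(structure(list(root = paste(ch[seq_len(p)], collapse = ""),
                            exponent = n %/% p),
                       class = "root_decomposition"))
    }
  }
}

#' @export
print.root_decomposition <- function(x, ...) {
  cat(sprintf("root = %s, exponent = %d\n", x$root, x$exponent))
  invisible(x)
}

#' Count the runs of a string
#'
#' A run is a maximal substring of equal characters; the number of runs
#' `r` of a BWT is the standard size measure of run-length-compressed
#' BWT-based indexes, and `n/r` the average run length.
#'
#' @param t A non-empty string.
#' @return A list of class `runs_summary` with fields `length`,
#'   `run_count` and `avg_runlength`.
#' @examples
#' count_runs("CAAGGGA")$run_count # 4
#' @export
count_runs <- function(t) {
  ch <- str_chars(t)
  if (length(ch) == 0L) stop("cannot count runs of the empty string")
  r <- length(rle(ch)$lengths)
  structure(list(length = length(ch), run_count = r,
                 avg_runlength = length(ch) / r),
            class = "runs_summary")
}

#' @export
print.runs_summary <- function(x, ...) {
  cat(sprintf("n = %d, r = %d, n/r = %.3f\n",
              x$length, x$run_count, x$avg_runlength))
  invisible(x)
}

# Number of runs as a bare integer.
runs_of <- function(t) count_runs(t)$run_count

#' Compare two strings in the omega-order
#'
#' The omega-order underlies the extended BWT: `s` precedes `t` if they
#' share the same primitive root and `s` has the smaller exponent, or
#' otherwise if the infinite power of `s` is lexicographically smaller
#' than the infinite power of `t`. The infinite comparison is decided
#' within the first `|s| + |t|` symbols (a consequence of the
#' Fine-and-Wilf periodicity theorem), so both powers are truncated
#' there; if still equal, the roots coincide and the exponent rule
#' applies.
#'
#' @param s,t Non-empty strings.
#' @return `-1L`, `0L` or `1L` as `s` precedes, equals, or follows `t`.
#' @examples
#' omega_compare("GTC", "GT") # -1: GTC precedes GT in omega-order
#' @export
omega_compare <- function(s, t) {
  cs <- str_chars(s); ct <- str_chars(t)
  if (length(cs) == 0L || length(ct) == 0L)
    stop("omega_compare requires non-empty strings")
  L <- length(cs) + length(ct)
  ps <- rep_len(cs, L); pt <- rep_len(ct, L)
  d <- which(ps != pt)
  if (length(d)) {
    i <- d[1L]
    return(if (ps[i] < pt[i]) -1L else 1L)
  }
  # equal truncated powers: same primitive root; smaller exponent first
  es <- length(cs) %/% nchar(primitive_root(s)$root)
  et <- length(ct) %/% nchar(primitive_root(t)$root)
  if (es < et) -1L else if (es > et) 1L else 0L
}

#' All conjugates (rotations) of a string
#'
#' The `i`-th rotation starts at position `i + 1` of `t`; duplicates are
#' retained for non-primitive strings.
#'
#' @param t A non-empty string.
#' @return A data frame with columns `rotation` and `offset` (0-based
#'   start offset).
#' @examples
#' conjugates("GT")
#' @export
conjugates <- function(t) {
  ch <- str_chars(t)
  n <- length(ch)
  if (n == 0L) stop("the empty string has no conjugates")
  rot <- vapply(seq_len(n) - 1L, function(o) {
    paste(ch[((seq_len(n) + o - 1L) %% n) + 1L], collapse = "")
  }, "")
  data.frame(rotation = rot, offset = seq_len(n) - 1L)
}
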