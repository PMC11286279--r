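# The six BWT variants ---------------------------------------------------

new_transform <- function(variant, chars, order_used = NULL,
                          conjugate_ranks = NULL, separator_positions = integer(0)) {
  structure(
    list(variant = variant,
         text = paste(chars, collapse = ""),
         length = length(chars),
         separator_positions = separator_positions,
         order_used = order_used,
         conjugate_ranks = conjugate_ranks),
    class = "bwt_transform")
}

#' @export
print.bwt_transform <- function(x, ...) {
  r <- runs_of(x$text)
  txt <- if (x$length > 70L) paste0(substr(x$text, 1, 67), "...") else x$text
  cat(sprintf("%s: n = %d, r = %d, n/r = %.3f\n  %s\n",
              x$variant, x$length, r, x$length / r, txt))
  invisible(x)
}

#' Burrows-Wheeler transform of a single string
#'
#' Concatenates the last characters of the lexicographically sorted
#' rotations of `t`. No end-of-string symbol is added; append one
#' beforehand (or use [mdol_bwt] on a one-string collection) for the
#' dollar-terminated transform.
#'
#' @param t A non-empty string (the separator glyph `"$"` is allowed here
#'   and treated as smaller than every other symbol).
#' @return The transformed string.
#' @examples
#' bwt("CAGAGA") # "GGCAAA"
#' @export
bwt <- function(t) {
  ch <- str_chars(t)
  if (length(ch) == 0L) stop("cannot transform the empty string")
  alphabet <- sort(unique(ch), method = "radix")
  v <- match(ch, alphabet)
  n <- length(v)
  rows <- conjugate_rows(list(v), n, wrap = TRUE)
  ord <- order_rows(rows, seq_len(n))
  last <- v[((ord - 2L) %% n) + 1L]
  paste(alphabet[last], collapse = "")
}

#' Extended BWT (eBWT) of a string collection
#'
#' Concatenates the last characters of all conjugates of all members,
#' listed in omega-order. The eBWT uses no separator symbols, has length
#' exactly `N` (the total collection length), and is independent of the
#' input order. Ties between identical conjugates (duplicated or
#' non-primitive members) are broken stably by input index and offset;
#' the output is unaffected because tied conjugates end with the same
#' character.
#'
#' @param m A [string_collection].
#' @return A `bwt_transform` with `variant = "ebwt"`. The field
#'   `conjugate_ranks` records, for each input string, the omega-rank of
#'   its offset-0 conjugate; these indices make the eBWT reversible (see
#'   [invert_ebwt]).
#' @examples
#' ebwt(string_collection(c("GTC", "GT")))$text # "TCTGG"
#' @export
ebwt <- function(m) {
  stopifnot(inherits(m, "string_collection"))
  srt <- omega_rotation_sort(m$strings, m$alphabet)
  ranks <- vapply(seq_len(m$k), function(i) srt$rank_of[[i]][1L], 1L)
  new_transform("ebwt", srt$chars, conjugate_ranks = ranks)
}

#' Dollar-eBWT of a string collection
#'
#' The eBWT of the collection obtained by appending one (identical)
#' separator to every member. On sentinel-terminated rotations the
#' omega-order coincides with the lexicographic order, so this transform
#' is also the multidollar BWT of the lexicographically sorted
#' collection. Like the eBWT it is independent of the input order.
#'
#' @param m A [string_collection].
#' @return A `bwt_transform` with `variant = "dolebwt"`, length `N + k`.
#' @examples
#' dol_ebwt(string_collection(c("GTC", "GT")))$text # "TCT$$GG"
#' @export
dol_ebwt <- function(m) {
  stopifnot(inherits(m, "string_collection"))
  srt <- sep_rotation_sort(m$strings, m$alphabet, distinct_dollars = FALSE)
  new_transform("dolebwt", srt$chars,
                separator_positions = srt$separator_positions)
}

#' Multidollar BWT of a string collection
#'
#' The BWT of the concatenation `T1 $1 T2 $2 ... Tk $k` where the
#' per-string sentinels rank strictly below every alphabet symbol and
#' `$1 < $2 < ... < $k`. Equivalently: the rotations of the
#' sentinel-terminated strings sorted lexicographically, with ties on the
#' sentinel broken by the string's position in the given order. All
#' sentinels are rendered as the single glyph `"$"` in the output text.
#'
#' @param m A [string_collection].
#' @param order Optional [order_permutation] or integer permutation of
#'   `1:k`; default is the input order.
#' @return A `bwt_transform` with `variant = "mdolbwt"`, length `N + k`.
#' @examples
#' mdol_bwt(string_collection("CAGAGA"))$text # "AGGC$AA"
#' @export
mdol_bwt <- function(m, order = NULL) {
  stopifnot(inherits(m, "string_collection"))
  perm <- order_perm(order, m$k)
  srt <- sep_rotation_sort(m$strings[perm], m$alphabet, distinct_dollars = TRUE)
  kind <- if (inherits(order, "order_permutation")) order$kind else "input"
  new_transform("mdolbwt", srt$chars,
                order_used = order_permutation(perm, kind),
                separator_positions = srt$separator_positions)
}

#' Lexicographic order of a collection
#'
#' Stable sort of the members by plain (byte-wise) lexicographic
#' comparison; equal strings keep their input order.
#'
#' @param m A [string_collection].
#' @return An [order_permutation] of kind `"lex"`.
#' @export
lex_order <- function(m) {
  stopifnot(inherits(m, "string_collection"))
  order_permutation(order(m$strings, method = "radix"), "lex")
}

#' Colexicographic order of a collection
#'
#' Stable sort of the members by the lexicographic order of their
#' reversed strings ("reverse lexicographic" / rlo order). Grouping
#' strings with shared suffixes together is what makes the resulting
#' multidollar BWT run-efficient.
#'
#' @param m A [string_collection].
#' @return An [order_permutation] of kind `"colex"`.
#' @examples
#' colex_order(string_collection(c("TGA", "ACG")))$permutation # 2 1
#' @export
colex_order <- function(m) {
  stopifnot(inherits(m, "string_collection"))
  rev_strings <- vapply(m$strings,
                        function(s) paste(rev(str_chars(s)), collapse = ""), "")
  order_permutation(order(rev_strings, method = "radix"), "colex")
}

#' Colexicographic BWT of a string collection
#'
#' The multidollar BWT built after reordering the collection
#' colexicographically: `colex_bwt(m) = mdol_bwt(m, colex_order(m))`.
#'
#' @param m A [string_collection].
#' @return A `bwt_transform` with `variant = "colexbwt"`.
#' @export
colex_bwt <- function(m) {
  t <- mdol_bwt(m, colex_order(m))
  t$variant <- "colexbwt"
  t
}

#' Run-minimizing (optimal) BWT of a string collection
#'
#' The multidollar BWT under an input order that attains the minimum
#' number of runs over all `k!` orders: `opt_bwt(m) = mdol_bwt(m,
#' opt_order(m))`.
#'
#' @param m A [string_collection].
#' @return A `bwt_transform` with `variant = "optbwt"`.
#' @export
opt_bwt <- function(m) {
  t <- mdol_bwt(m, opt_order(m))
  t$variant <- "optbwt"
  t
}

#' Concatenation BWT of a string collection
#'
#' The BWT of the single string `T1 $ T2 $ ... Tk $ #` in which all
#' separators are the identical symbol `"$"` and the terminator `"#"`
#' ranks strictly below it. The rotation starting with `#` is always the
#' smallest and contributes a leading separator to the transform; under
#' the default normalization this first symbol is removed and the `#` in
#' the output renamed to `"$"`, giving a text of length `N + k`
#' comparable with the other separator-based variants. The raw transform
#' has length `N + k + 1` and retains the `#` glyph.
#'
#' @param m A [string_collection].
#' @param order Optional order permutation; default input order.
#' @param normalized Normalize the output (default `TRUE`).
#' @return A `bwt_transform` with `variant = "concbwt"`.
#' @export
conc_bwt <- function(m, order = NULL, normalized = TRUE) {
  stopifnot(inherits(m, "string_collection"))
  perm <- order_perm(order, m$k)
  letters <- letter_codes(m$strings[perm], m$alphabet, 1L)
  s <- unlist(lapply(letters, function(v) c(v, 1L)))  # "$" -> 1
  s <- c(s, 0L)                                       # "#" -> 0
  n <- length(s)
  rows <- conjugate_rows(list(s), n, wrap = TRUE)
  ord <- order_rows(rows)
  last <- s[((ord - 2L) %% n) + 1L]
  chars <- c(TERMINATOR, SEPARATOR, m$alphabet)[last + 1L]
  kind <- if (inherits(order, "order_permutation")) order$kind else "input"
  if (normalized) {
    stopifnot(chars[1L] == SEPARATOR)
    chars <- chars[-1L]
    chars[chars == TERMINATOR] <- SEPARATOR
  }
  new_transform("concbwt", chars,
                order_used = order_permutation(perm, kind),
                separator_positions = which(chars == SEPARATOR))
}

#' Build any BWT variant by name
#'
#' Dispatches to the variant-specific constructor. The order argument is
#' only meaningful for the order-dependent variants (`mdolbwt`,
#' `concbwt`); supplying one for an order-independent variant raises a
#' warning and is ignored.
#'
#' @param m A [string_collection].
#' @param variant One of `"ebwt"`, `"dolebwt"`, `"mdolbwt"`,
#'   `"colexbwt"`, `"optbwt"`, `"concbwt"`.
#' @param order Optional order permutation for `mdolbwt`/`concbwt`.
#' @param normalized Normalization flag for `concbwt`.
#' @return A `bwt_transform`.
#' @export
bwt_transform <- function(m, variant, order = NULL, normalized = TRUE) {
  variant <- match.arg(variant,
                       c("ebwt", "dolebwt", "mdolbwt", "colexbwt",
                         "optbwt", "concbwt"))
  if (!is.null(order) && !variant %in% c("mdolbwt", "concbwt")) {
    warning(sprintf("variant '%s' is order-independent; 'order' ignored",
                    variant))
    order <- NULL
  }
  switch(variant,
         ebwt = ebwt(m),
         dolebwt = dol_ebwt(m),
         mdolbwt = mdol_bwt(m, order),
         colexbwt = colex_bwt(m),
         optbwt = opt_bwt(m),
         concbwt = conc_bwt(m, order, normalized))
}
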