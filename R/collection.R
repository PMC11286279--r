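# String collections -----------------------------------------------------

# Reserved glyphs: "$" is the end-of-string separator used in all textual
# output, "#" the terminator of the concatenation BWT. Input strings must
# avoid both so that transform texts remain unambiguous.
SEPARATOR <- "$"
TERMINATOR <- "#"

#' Create a string collection
#'
#' An ordered multiset of non-empty strings, the basic input of every BWT
#' variant. The input order is significant and preserved: several variants
#' (multidollar and concatenation BWT) depend on it.
#'
#' @param strings Character vector of non-empty strings. Must not contain
#'   the reserved separator `"$"` or terminator `"#"` glyphs.
#' @return An object of class `string_collection` with fields `strings`,
#'   `k` (number of strings), `total_length` (sum of lengths), `alphabet`
#'   (sorted distinct symbols, byte order) and `sigma` (alphabet size).
#' @examples
#' m <- string_collection(c("GTC", "GT"))
#' m$k
#' m$alphabet
#' @export
string_collection <- function(strings) {
  if (is.list(strings)) strings <- unlist(strings, use.names = FALSE)
  strings <- as.character(strings)
  if (length(strings) < 1L) stop("a collection must contain at least one string")
  if (any(is.na(strings)) || any(!nzchar(strings)))
    stop("empty strings are not allowed in a collection")
  bad <- grepl(SEPARATOR, strings, fixed = TRUE) |
    grepl(TERMINATOR, strings, fixed = TRUE)
  if (any(bad))
    stop("strings must not contain the reserved sentinel glyphs '$' or '#' ",
         "(offending record ", which(bad)[1L], ")")
  lens <- nchar(strings, type = "bytes")
  alphabet <- sort(unique(unlist(strsplit(strings, "", fixed = TRUE))),
                   method = "radix")
  structure(
    list(strings = strings, k = length(strings),
         total_length = sum(lens), lengths = lens,
         alphabet = alphabet, sigma = length(alphabet)),
    class = "string_collection")
}

#' @export
print.string_collection <- function(x, ...) {
  cat(sprintf("String collection: k = %d, N = %d, sigma = %d (%s)\n",
              x$k, x$total_length, x$sigma,
              paste(x$alphabet, collapse = "")))
  show <- utils::head(x$strings, 8L)
  shown <- ifelse(nchar(show) > 60, paste0(substr(show, 1, 57), "..."), show)
  cat(paste0("  [", seq_along(show), "] ", shown, "\n"), sep = "")
  if (x$k > 8L) cat(sprintf("  ... and %d more\n", x$k - 8L))
  invisible(x)
}

#' @export
as.character.string_collection <- function(x, ...) x$strings

#' Reorder a string collection
#'
#' Applies a permutation (an [order_permutation] or a bare integer vector)
#' to the members of a collection, preserving the multiset.
#'
#' @param m A [string_collection].
#' @param order An `order_permutation` or an integer permutation of `1:k`.
#' @return The reordered `string_collection`.
#' @export
apply_order <- function(m, order) {
  perm <- order_perm(order, m$k)
  string_collection(m$strings[perm])
}

#' Order permutations of a collection
#'
#' A tagged bijection on `1:k` recording how a collection is to be listed
#' before building an order-dependent transform.
#'
#' @param permutation Integer vector, a permutation of `1:k`.
#' @param kind One of `"input"`, `"lex"`, `"colex"`, `"opt"`.
#' @return An object of class `order_permutation`.
#' @export
order_permutation <- function(permutation,
                              kind = c("input", "lex", "colex", "opt")) {
  kind <- match.arg(kind)
  permutation <- as.integer(permutation)
  if (!setequal(permutation, seq_along(permutation)))
    stop("'permutation' must be a permutation of 1..k")
  structure(list(permutation = permutation, kind = kind),
            class = "order_permutation")
}

#' @export
print.order_permutation <- function(x, ...) {
  cat(sprintf("Order permutation (%s): %s\n", x$kind,
              paste(x$permutation, collapse = " ")))
  invisible(x)
}

# Resolve an order argument to a bare integer permutation.
order_perm <- function(order, k) {
  if (is.null(order)) return(seq_len(k))
  if (inherits(order, "order_permutation")) order <- order$permutation
  order <- as.integer(order)
  if (length(order) != k || !setequal(order, seq_len(k)))
    stop("order must be a permutation of 1..k")
  order
}

# Split a string into its single-byte characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
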