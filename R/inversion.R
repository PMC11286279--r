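# Inversion of the BWT variants ------------------------------------------
#
# Separator-based texts are inverted by following the last-to-first (LF)
# mapping backwards from each of the first k rows (the sentinel rows),
# stopping at the separator that closes the string. LF steps on alphabet
# characters are exact for every separator-based variant: the relative
# order of equal characters in the text matches the order of their
# prepended rotations regardless of how sentinel ties were broken, so the
# same walk inverts multidollar, colexicographic, optimal, dollar-eBWT
# and (normalized) concatenation texts.

# Stable LF mapping of a character vector with "$" ranked smallest and
# "#" (if present) below "$".
lf_mapping <- function(ch) {
  levels <- c(TERMINATOR, SEPARATOR,
              sort(setdiff(unique(ch), c(TERMINATOR, SEPARATOR)),
                   method = "radix"))
  code <- match(ch, levels)
  counts <- tabulate(code, nbins = length(levels))
  C <- c(0L, cumsum(counts))[seq_along(levels)]
  occ <- stats::ave(seq_along(code), code, FUN = seq_along)
  C[code] + occ
}

new_inversion <- function(strings, mode, order_recovered) {
  structure(list(strings = strings, mode = mode,
                 order_recovered = order_recovered),
            class = "bwt_inversion")
}

#' @export
print.bwt_inversion <- function(x, ...) {
  cat(sprintf("Recovered %d string(s) (%s%s):\n", length(x$strings), x$mode,
              if (x$order_recovered) ", order recovered" else ""))
  show <- utils::head(x$strings, 8L)
  cat(paste0("  ", ifelse(nchar(show) > 60,
                          paste0(substr(show, 1, 57), "..."), show), "\n"),
      sep = "")
  if (length(x$strings) > 8L)
    cat(sprintf("  ... and %d more\n", length(x$strings) - 8L))
  invisible(x)
}

#' Invert a separator-based BWT text
#'
#' Recovers the multiset of strings from the text of any separator-based
#' variant (multidollar, colexicographic, optimal, dollar-eBWT, or
#' normalized concatenation BWT). Strings are returned in the variant's
#' internal concatenation order: re-transforming the result under the
#' identity order reproduces the input text. A raw concatenation BWT
#' (containing the explicit `"#"` glyph) is accepted and normalized
#' first; for `variant = "concbwt"` the concatenation order is in
#' addition re-derived so that the round trip is exact.
#'
#' @param text Transform text over the alphabet plus `"$"` (and possibly
#'   `"#"` for a raw concatenation BWT).
#' @param variant `"mdolbwt"` (default; covers all multidollar-family
#'   texts) or `"concbwt"`.
#' @return A `bwt_inversion` with fields `strings`, `mode =
#'   "exact-multiset"` and `order_recovered`.
#' @examples
#' invert_separator_bwt("AGGC$AA")$strings  # "CAGAGA"
#' invert_separator_bwt("TCT$$GG")$strings  # "GT", "GTC"
#' @export
invert_separator_bwt <- function(text, variant = c("mdolbwt", "concbwt")) {
  variant <- match.arg(variant)
  ch <- str_chars(text)
  if (any(ch == TERMINATOR)) {
    # raw concatenation BWT: strip the leading separator contributed by
    # the terminator rotation and rename the terminator
    variant <- "concbwt"
    if (ch[1L] != SEPARATOR || sum(ch == TERMINATOR) != 1L)
      stop("invalid transform: malformed raw concatenation BWT")
    ch <- ch[-1L]
    ch[ch == TERMINATOR] <- SEPARATOR
  }
  k <- sum(ch == SEPARATOR)
  if (k == 0L) stop("not a separator-based transform: no separator found")
  n <- length(ch)
  lf <- lf_mapping(ch)
  visited <- logical(n)
  strings <- character(k)
  stops <- integer(k)
  for (i in seq_len(k)) {
    pos <- i
    buf <- character(0)
    repeat {
      if (visited[pos]) stop("invalid transform: LF cycles malformed")
      visited[pos] <- TRUE
      c0 <- ch[pos]
      if (c0 == SEPARATOR) { stops[i] <- pos; break }
      buf <- c(c0, buf)
      pos <- lf[pos]
      if (length(buf) > n) stop("invalid transform: LF cycles malformed")
    }
    if (length(buf) == 0L) stop("invalid transform: empty string recovered")
    strings[i] <- paste(buf, collapse = "")
  }
  if (sum(nchar(strings)) + k != n)
    stop("invalid transform: LF cycles malformed")
  if (variant == "concbwt" && k > 1L) {
    ord <- conc_order_from_stops(strings, stops, paste(ch, collapse = ""))
    if (!is.null(ord))
      return(new_inversion(strings[ord], "exact-multiset", TRUE))
    return(new_inversion(strings, "exact-multiset", FALSE))
  }
  new_inversion(strings, "exact-multiset", TRUE)
}

# Re-derive the concatenation order of a normalized concatenation BWT.
#
# Walk i starts at row i (a separator row) and stops at the text position
# of the separator preceding its string, i.e. at the row of the rotation
# that begins with that string. Sorted by row, these stop rows correspond
# one-to-one with the separator start rows 2..k once the first string's
# stop row (whose true predecessor rotation was removed by normalization)
# is excluded. Each candidate exclusion yields a successor chain; the
# first candidate whose chain is a single path and whose re-transform
# reproduces the text is returned.
conc_order_from_stops <- function(strings, stops, text) {
  k <- length(strings)
  for (t in seq_len(k)) {
    s_sorted <- sort(stops[-t])
    succ <- integer(k)  # succ[walk index] = walk of the successor string
    ok <- TRUE
    for (r in seq_len(k - 1L)) {
      succ[1L + r] <- match(s_sorted[r], stops)
    }
    ordr <- integer(k)
    cur <- t
    for (step in seq_len(k)) {
      ordr[step] <- cur
      if (step == k) break
      if (cur == 1L || succ[cur] == 0L) { ok <- FALSE; break }
      nxt <- succ[cur]
      if (nxt %in% ordr[seq_len(step)]) { ok <- FALSE; break }
      cur <- nxt
    }
    if (!ok || ordr[k] != 1L) next
    cand <- strings[ordr]
    if (identical(conc_bwt(string_collection(cand))$text, text))
      return(ordr)
  }
  NULL
}

#' Invert an extended BWT text
#'
#' Decomposes the generalized LF mapping of an eBWT text into cycles.
#' Each cycle spells a primitive word, giving the multiset of primitive
#' conjugacy classes with multiplicities (`mode = "conjugacy-classes"`,
#' representatives rotated to their lexicographically least form and
#' sorted). When the omega-ranks of the input strings' offset-0
#' conjugates are supplied (field `conjugate_ranks` of [ebwt]), each
#' class is rotated and re-exponentiated to the exact input string
#' (`mode = "exact-multiset"`). When several anchored strings share a
#' primitive root and spare cycles remain, the spare exponent is assigned
#' to the largest-ranked anchor (the distribution is not always encoded
#' by the ranks; see the package vignette).
#'
#' @param text eBWT text over the alphabet (no separators).
#' @param ranks Optional integer vector of conjugate ranks, one per input
#'   string in input order.
#' @return A `bwt_inversion`.
#' @examples
#' invert_ebwt("TCTGG", ranks = c(2, 3))$strings  # "GTC", "GT"
#' @export
invert_ebwt <- function(text, ranks = NULL) {
  ch <- str_chars(text)
  n <- length(ch)
  if (n == 0L) stop("cannot invert an empty text")
  if (any(ch %in% c(SEPARATOR, TERMINATOR)))
    stop("text contains separator glyphs; use invert_separator_bwt()")
  lf <- lf_mapping(ch)
  cycle_id <- integer(n)
  words <- character(0)
  for (s in seq_len(n)) {
    if (cycle_id[s] > 0L) next
    id <- length(words) + 1L
    buf <- character(0)
    pos <- s
    repeat {
      cycle_id[pos] <- id
      buf <- c(ch[pos], buf)
      pos <- lf[pos]
      if (pos == s) break
    }
    words[id] <- paste(buf, collapse = "")  # conjugate at row s
  }
  if (is.null(ranks)) {
    reps <- vapply(words, min_rotation, "", USE.NAMES = FALSE)
    return(new_inversion(sort(reps, method = "radix"),
                         "conjugacy-classes", FALSE))
  }
  ranks <- as.integer(ranks)
  if (any(ranks < 1L | ranks > n)) stop("ranks out of range")
  anchor_cycle <- cycle_id[ranks]
  if (anyDuplicated(anchor_cycle))
    stop("ranks must anchor distinct LF cycles")
  # exponents: distribute unanchored cycles of each conjugacy class
  reps <- vapply(words, min_rotation, "", USE.NAMES = FALSE)
  strings <- character(length(ranks))
  for (cl in unique(reps[anchor_cycle])) {
    cycles_in <- which(reps == cl)
    anchors <- which(reps[anchor_cycle] == cl)
    spare <- length(cycles_in) - length(anchors)
    if (spare < 0L) stop("ranks inconsistent with the LF cycle structure")
    exps <- rep(1L, length(anchors))
    exps[which.max(ranks[anchors])] <- 1L + spare
    for (jj in seq_along(anchors)) {
      a <- anchors[jj]
      w <- recover_conjugate(ch, lf, ranks[a])
      strings[a] <- paste(rep(w, exps[jj]), collapse = "")
    }
  }
  if (length(unique(reps)) > length(unique(reps[anchor_cycle])))
    stop("ranks leave some conjugacy classes unanchored")
  new_inversion(strings, "exact-multiset", TRUE)
}

# The primitive word spelled by the cycle through row `start`, aligned so
# that it equals the conjugate occupying that row.
recover_conjugate <- function(ch, lf, start) {
  buf <- character(0)
  pos <- start
  repeat {
    buf <- c(ch[pos], buf)
    pos <- lf[pos]
    if (pos == start) break
  }
  paste(buf, collapse = "")
}

# Lexicographically least rotation of a string (canonical class
# representative).
min_rotation <- function(s) {
  rot <- rotations_of(s)
  sort(rot, method = "radix")[1L]
}
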