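# Interesting intervals, per-interval run bounds, variability ------------

# Recursive partition of the collection by shared suffixes. A node is
# recorded whenever a shared suffix U of length `depth` is left-maximal:
# at least two members have U as suffix and their preceding characters
# differ. A member equal to U contributes the separator as its preceding
# character. Returns nodes in recursion (suffix-trie) order.
suffix_nodes <- function(strings) {
  lens <- nchar(strings, type = "bytes")
  nodes <- list()
  recurse <- function(idx, depth) {
    if (length(idx) < 2L) return(invisible(NULL))
    chars <- vapply(idx, function(i) {
      if (lens[i] == depth) SEPARATOR
      else substr(strings[i], lens[i] - depth, lens[i] - depth)
    }, "")
    lev <- sort(unique(chars), method = "radix")
    cls <- split(idx, factor(chars, levels = lev))
    if (length(cls) > 1L) {
      nodes[[length(nodes) + 1L]] <<- list(depth = depth, members = idx,
                                           classes = cls)
    }
    for (ci in names(cls)) {
      if (ci != SEPARATOR) recurse(cls[[ci]], depth + 1L)
    }
    invisible(NULL)
  }
  recurse(seq_along(strings), 0L)
  nodes
}

# Interval coordinates [b, e] of each node on the multidollar rotation
# sort of the collection in input order; also the input-order BWT text.
interval_coordinates <- function(m) {
  srt <- sep_rotation_sort(m$strings, m$alphabet, distinct_dollars = TRUE)
  nodes <- suffix_nodes(m$strings)
  lens <- m$lengths
  iv <- lapply(nodes, function(nd) {
    # rotation starting with U$ for member i begins at offset |Ti| - depth
    rk <- vapply(nd$members, function(i) {
      srt$rank_of[[i]][lens[i] - nd$depth + 1L]
    }, 1L)
    stopifnot(identical(sort(rk), seq(min(rk), max(rk))))
    c(nd, list(b = min(rk), e = max(rk)))
  })
  iv <- iv[order(vapply(iv, `[[`, 1L, "b"))]
  # distinct interesting intervals are always pairwise disjoint
  if (length(iv) > 1L) {
    bs <- vapply(iv, `[[`, 1L, "b"); es <- vapply(iv, `[[`, 1L, "e")
    stopifnot(all(bs[-1L] > es[-length(es)]))
  }
  list(intervals = iv, text_chars = srt$chars)
}

#' Interesting intervals of a string collection
#'
#' An interesting interval is the rank range `[b, e]` (on the
#' lexicographically sorted rotations of the sentinel-terminated members)
#' of the rotations starting `U$`, for a shared suffix `U` that is a
#' left-maximal repeat: `U` is a suffix of at least two members and the
#' preceding characters differ (the separator playing the role of the
#' preceding character when a member equals `U`). All differences between
#' the separator-based BWT variants of a collection are confined to these
#' intervals, and distinct intervals are disjoint (asserted on every
#' call). Coordinates are 1-based and identical across the
#' separator-based variants.
#'
#' @param m A [string_collection].
#' @return An object of class `interesting_intervals`: a list of
#'   intervals sorted by `b`, each with fields `suffix`, `begin`, `end`,
#'   `width`, `parikh` (named symbol counts over the interval's BWT
#'   characters, separator included), `max_char_count`, `rest_count` and
#'   `var_bound` (the maximum-attainable run count of the interval, see
#'   [interval_max_runs]).
#' @examples
#' interesting_intervals(string_collection(c("AAAA", "CAAA")))
#' @export
interesting_intervals <- function(m) {
  stopifnot(inherits(m, "string_collection"))
  co <- interval_coordinates(m)
  out <- lapply(co$intervals, function(nd) {
    ch <- co$text_chars[nd$b:nd$e]
    parikh <- table(ch)
    parikh <- stats::setNames(as.integer(parikh), names(parikh))
    parikh <- parikh[sort(names(parikh), method = "radix")]
    na <- max(parikh)
    suffix <- if (nd$depth == 0L) "" else {
      s <- m$strings[nd$members[1L]]
      substr(s, nchar(s) - nd$depth + 1L, nchar(s))
    }
    list(suffix = suffix, begin = nd$b, end = nd$e,
         width = nd$e - nd$b + 1L,
         members = nd$members,
         parikh = parikh, max_char_count = na,
         rest_count = (nd$e - nd$b + 1L) - na,
         var_bound = interval_max_runs(parikh))
  })
  structure(out, class = "interesting_intervals")
}

#' @export
print.interesting_intervals <- function(x, ...) {
  if (length(x) == 0L) {
    cat("No interesting intervals\n")
    return(invisible(x))
  }
  cat(sprintf("%d interesting interval(s):\n", length(x)))
  for (iv in x) {
    cat(sprintf("  U = %-10s [%d, %d] width %d, max runs %d, {%s}\n",
                if (nzchar(iv$suffix)) dQuote(iv$suffix, FALSE) else "(empty)",
                iv$begin, iv$end, iv$width, iv$var_bound,
                paste(sprintf("%s:%d", names(iv$parikh), iv$parikh),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.interesting_intervals <- function(x, ...) {
  data.frame(
    suffix = vapply(x, `[[`, "", "suffix"),
    begin = vapply(x, `[[`, 1L, "begin"),
    end = vapply(x, `[[`, 1L, "end"),
    width = vapply(x, `[[`, 1L, "width"),
    max_char_count = vapply(x, `[[`, 1L, "max_char_count"),
    rest_count = vapply(x, `[[`, 1L, "rest_count"),
    var_bound = vapply(x, `[[`, 1L, "var_bound"))
}

#' Maximum run count attainable within an interval
#'
#' Given the Parikh vector (per-symbol counts) of an interval of width
#' `w = sum(parikh)`, the maximum number of runs over all arrangements of
#' those symbols is `w` when `n_a - 1 <= N_a`, and `2 * N_a + 1`
#' otherwise, where `n_a` is the largest count and `N_a = w - n_a` the
#' sum of the remaining counts.
#'
#' @param parikh Non-negative integer vector of symbol counts, summing to
#'   at least 2 (names optional).
#' @return The maximum attainable run count, an integer.
#' @examples
#' interval_max_runs(c(A = 3, C = 1)) # 3
#' interval_max_runs(c(A = 2, C = 2)) # 4
#' @export
interval_max_runs <- function(parikh) {
  parikh <- as.integer(parikh)
  if (any(parikh < 0)) stop("counts must be non-negative")
  w <- sum(parikh)
  if (w == 0L) stop("all-zero Parikh vector")
  na <- max(parikh)
  Na <- w - na
  if (na - 1L <= Na) w else 2L * Na + 1L
}

#' Variability of a string collection
#'
#' The ratio of the summed per-interval maximum run counts to the summed
#' interval widths, over all interesting intervals. It measures how much
#' the run count of a separator-based BWT can be inflated by an adverse
#' input order: a variability near 1 means the interval contents admit
#' almost one run per position.
#'
#' @param m A [string_collection].
#' @return A list with `value` (in `[0, 1]`; 0 when undefined),
#'   `defined` (FALSE when the collection has no interesting interval)
#'   and `n_intervals`.
#' @export
variability <- function(m) {
  iv <- interesting_intervals(m)
  if (length(iv) == 0L)
    return(list(value = 0, defined = FALSE, n_intervals = 0L))
  bounds <- vapply(iv, `[[`, 1L, "var_bound")
  widths <- vapply(iv, `[[`, 1L, "width")
  list(value = sum(bounds) / sum(widths), defined = TRUE,
       n_intervals = length(iv))
}
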