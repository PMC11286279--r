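# Brute-force reference implementations ----------------------------------
#
# Independent ground truths for the fast paths: explicit rotation lists
# sorted as character strings (byte order), with sentinels encoded as
# low-ASCII glyphs ranking below every printable symbol. Intended for
# small inputs only; each operation enforces a size cap.

# Low-ASCII sentinel glyphs: terminator, then k ranked dollars.
naive_glyphs <- function(k) {
  if (k > 30L) stop("naive oracles support at most 30 strings")
  vapply(seq_len(k) + 1L, function(i) rawToChar(as.raw(i)), "")
}

rotations_of <- function(s) {
  ch <- str_chars(s)
  n <- length(ch)
  vapply(seq_len(n) - 1L, function(o) {
    paste(ch[((seq_len(n) + o - 1L) %% n) + 1L], collapse = "")
  }, "")
}

last_char <- function(s) substr(s, nchar(s), nchar(s))

check_cap <- function(m, cap) {
  if (m$total_length > cap)
    stop(sprintf("collection too large for the naive oracle (N = %d > cap %d)",
                 m$total_length, cap))
}

#' Naive omega-sort of all conjugates of a collection
#'
#' Reference implementation of the omega-order conjugate sort underlying
#' the eBWT: every conjugate's infinite power is materialized to four
#' times the maximum member length and the resulting finite strings are
#' sorted bytewise, with residual ties broken by smaller exponent and
#' then stably by input index and offset.
#'
#' @param m A [string_collection].
#' @param cap Maximum total collection length accepted (default 500).
#' @return A data frame with columns `conjugate`, `string` (input index),
#'   `offset`, in omega-order.
#' @examples
#' naive_omega_sort(string_collection(c("GTC", "GT")))$conjugate
#' @export
naive_omega_sort <- function(m, cap = 500L) {
  stopifnot(inherits(m, "string_collection"))
  check_cap(m, cap)
  width <- 4L * max(m$lengths)
  rows <- do.call(rbind, lapply(seq_len(m$k), function(i) {
    rot <- rotations_of(m$strings[i])
    data.frame(conjugate = rot, string = i, offset = seq_along(rot) - 1L)
  }))
  powers <- vapply(rows$conjugate, function(s) {
    paste(rep_len(str_chars(s), width), collapse = "")
  }, "", USE.NAMES = FALSE)
  exps <- vapply(m$strings, function(s) primitive_root(s)$exponent, 1L)
  ord <- order(powers, exps[rows$string], rows$string, rows$offset,
               method = "radix")
  out <- rows[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Naive construction of any BWT variant
#'
#' Reference implementation by explicit rotation enumeration and
#' comparison sort: the eBWT via [naive_omega_sort]; the dollar-eBWT by
#' sorting the sentinel-terminated rotations as plain strings; the
#' multidollar and concatenation BWTs by rotating the full concatenated
#' string with sentinels encoded as distinct low-ASCII glyphs.
#'
#' @param m A [string_collection].
#' @param variant One of the six variant names (see [bwt_transform]).
#' @param order Optional order permutation for the order-dependent
#'   variants.
#' @param normalized Normalization flag for `concbwt`.
#' @param cap Maximum total collection length accepted (default 500).
#' @return The transform text as a single string (separators rendered as
#'   `"$"`).
#' @export
naive_bwt_variant <- function(m, variant, order = NULL, normalized = TRUE,
                              cap = 500L) {
  stopifnot(inherits(m, "string_collection"))
  check_cap(m, cap)
  variant <- match.arg(variant,
                       c("ebwt", "dolebwt", "mdolbwt", "colexbwt",
                         "optbwt", "concbwt"))
  perm <- order_perm(order, m$k)
  if (variant == "colexbwt") { variant <- "mdolbwt"; perm <- colex_order(m)$permutation }
  if (variant == "optbwt") { variant <- "mdolbwt"; perm <- opt_order(m)$permutation }
  strs <- m$strings[perm]
  dollars <- naive_glyphs(m$k)
  render <- function(chars) {
    chars[chars %in% c(dollars, rawToChar(as.raw(1L)))] <- SEPARATOR
    paste(chars, collapse = "")
  }
  if (variant == "ebwt") {
    srt <- naive_omega_sort(m, cap)
    return(paste(vapply(srt$conjugate, last_char, "", USE.NAMES = FALSE),
                 collapse = ""))
  }
  if (variant == "dolebwt") {
    # eBWT of {Ti$}: with one shared sentinel a rotation can be a proper
    # prefix of another, so sort by materialized omega powers (every Ti$
    # is primitive, hence no exponent tie-break; stability by input)
    rows <- do.call(rbind, lapply(seq_along(strs), function(i) {
      rot <- rotations_of(paste0(strs[i], dollars[1L]))
      data.frame(rotation = rot, string = i, offset = seq_along(rot) - 1L)
    }))
    width <- 4L * max(nchar(rows$rotation))
    powers <- vapply(rows$rotation, function(s) {
      paste(rep_len(str_chars(s), width), collapse = "")
    }, "", USE.NAMES = FALSE)
    ord <- order(powers, rows$string, rows$offset, method = "radix")
    return(render(vapply(rows$rotation[ord], last_char, "",
                         USE.NAMES = FALSE)))
  }
  if (variant == "mdolbwt") {
    s <- paste0(paste0(strs, dollars[seq_along(strs)], collapse = ""))
    rot <- sort(rotations_of(s), method = "radix")
    return(render(vapply(rot, last_char, "", USE.NAMES = FALSE)))
  }
  # concbwt: identical separators plus terminator \x01
  s <- paste0(paste0(strs, dollars[1L], collapse = ""), rawToChar(as.raw(1L)))
  rot <- sort(rotations_of(s), method = "radix")
  chars <- vapply(rot, last_char, "", USE.NAMES = FALSE)
  term <- chars == rawToChar(as.raw(1L))
  if (normalized) {
    stopifnot(chars[1L] == dollars[1L])
    chars[term] <- SEPARATOR
    chars <- chars[-1L]
  } else {
    chars[term] <- TERMINATOR
  }
  render(chars)
}

#' Exhaustive search for the run-minimizing input order
#'
#' Enumerates all `k!` input orders, builds the multidollar BWT of each
#' and returns the first order attaining the minimum run count. The
#' independent reference for [opt_order].
#'
#' @param m A [string_collection].
#' @param cap Maximum number of strings accepted (default 7).
#' @return A list with `order` (integer permutation) and `min_runs`.
#' @export
brute_min_runs_order <- function(m, cap = 7L) {
  stopifnot(inherits(m, "string_collection"))
  if (m$k > cap)
    stop(sprintf("k = %d exceeds the exhaustive-search cap %d", m$k, cap))
  perms <- all_permutations(m$k)
  best <- NULL; best_r <- Inf
  for (i in seq_len(nrow(perms))) {
    r <- runs_of(mdol_bwt(m, perms[i, ])$text)
    if (r < best_r) { best_r <- r; best <- perms[i, ] }
  }
  list(order = best, min_runs = best_r)
}

# All permutations of 1..k as rows of a matrix, in lexicographic order.
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Brute-force maximum run count of an interval
#'
#' Enumerates all distinct arrangements of the multiset described by a
#' Parikh vector and returns the maximum run count observed. The
#' independent reference for [interval_max_runs].
#'
#' @param parikh Non-negative integer counts (names optional).
#' @param cap Maximum multiset width accepted (default 10).
#' @return The maximum run count, an integer.
#' @examples
#' brute_interval_max_runs(c(A = 2, C = 2)) # 4
#' @export
brute_interval_max_runs <- function(parikh, cap = 10L) {
  parikh <- as.integer(parikh[parikh > 0])
  w <- sum(parikh)
  if (w == 0L) stop("all-zero Parikh vector")
  if (w > cap) stop(sprintf("width %d exceeds the enumeration cap %d", w, cap))
  best <- 0L
  recurse <- function(remaining, prev, runs, left) {
    if (left == 0L) { best <<- max(best, runs); return(invisible(NULL)) }
    for (s in seq_along(remaining)) {
      if (remaining[s] == 0L) next
      remaining[s] <- remaining[s] - 1L
      recurse(remaining, s, runs + as.integer(s != prev), left - 1L)
      remaining[s] <- remaining[s] + 1L
    }
    invisible(NULL)
  }
  recurse(parikh, 0L, 0L, w)
  best
}
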