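# Run-minimizing input order for the multidollar BWT ---------------------
#
# The order is found by refining the colexicographic idea: outside
# interesting intervals all multidollar BWTs of the same multiset agree,
# and inside an interval the only freedom is the order of its character
# blocks (one block per distinct preceding character; members sharing a
# longer suffix carry the same character here, so their relative order is
# delegated to a deeper interval). The total run count therefore
# decomposes into a fixed skeleton plus, per interval, the number of
# blocks minus the border merges obtained when the first/last block
# character equals the symbol preceding/following the interval. Border
# merges between runs of *adjacent* intervals couple their choices, so
# maximal chains of adjacent intervals are solved exactly by a small
# dynamic program over the last-block character.

#' Run-minimizing input order
#'
#' Computes an input order whose multidollar BWT attains the minimum
#' number of runs over all `k!` input orders. Within every interesting
#' interval the member strings are grouped into one block per preceding
#' character and the blocks are arranged so that, whenever possible, the
#' first and last block characters match the symbols bordering the
#' interval; chains of adjacent intervals are optimized jointly. Block
#' orders compose into a single global permutation via the trie of
#' reversed strings.
#'
#' @param m A [string_collection].
#' @return An [order_permutation] of kind `"opt"` with
#'   `runs(mdol_bwt(m, opt_order(m)))` minimal.
#' @seealso [opt_bwt], [brute_min_runs_order] for the exhaustive
#'   reference.
#' @export
opt_order <- function(m) {
  stopifnot(inherits(m, "string_collection"))
  if (m$k == 1L) return(order_permutation(1L, "opt"))
  co <- interval_coordinates(m)
  iv <- co$intervals
  txt <- co$text_chars
  n <- length(txt)
  decisions <- new.env(parent = emptyenv())
  node_key <- function(depth, members) paste(depth, min(members))

  # solve maximal chains of position-adjacent intervals
  i <- 1L
  while (i <= length(iv)) {
    j <- i
    while (j < length(iv) && iv[[j + 1L]]$b == iv[[j]]$e + 1L) j <- j + 1L
    chain <- iv[i:j]
    p <- if (chain[[1L]]$b > 1L) txt[chain[[1L]]$b - 1L] else NA_character_
    q <- if (chain[[length(chain)]]$e < n) txt[chain[[length(chain)]]$e + 1L]
         else NA_character_
    charsets <- lapply(chain, function(nd) names(nd$classes))
    picks <- chain_block_orders(charsets, p, q)
    for (t in seq_along(chain)) {
      assign(node_key(chain[[t]]$depth, chain[[t]]$members), picks[[t]],
             envir = decisions)
    }
    i <- j + 1L
  }

  lens <- m$lengths
  strings <- m$strings
  build <- function(idx, depth) {
    if (length(idx) == 1L) return(idx)
    chars <- vapply(idx, function(s) {
      if (lens[s] == depth) SEPARATOR
      else substr(strings[s], lens[s] - depth, lens[s] - depth)
    }, "")
    lev <- sort(unique(chars), method = "radix")
    cls <- split(idx, factor(chars, levels = lev))
    if (length(cls) == 1L) {
      if (names(cls) == SEPARATOR) return(idx)  # duplicated strings
      return(build(idx, depth + 1L))
    }
    ord_chars <- get(node_key(depth, idx), envir = decisions)
    out <- integer(0)
    for (ci in ord_chars) {
      sub <- cls[[ci]]
      out <- c(out, if (ci == SEPARATOR) sub else build(sub, depth + 1L))
    }
    out
  }
  order_permutation(build(seq_len(m$k), 0L), "opt")
}

# Optimal block orders for one chain of adjacent intervals.
# charsets: list of sorted character vectors (the blocks of each
# interval); p, q: the fixed symbols bordering the chain (NA when the
# chain touches the start/end of the transform). Returns, per interval,
# the ordered character vector (first block first).
chain_block_orders <- function(charsets, p, q) {
  # DP states: data.frame over the last-block character; backpointers
  # recover the (first, last) choice per interval. Ties are broken
  # deterministically by byte order of (first, last).
  states <- list()
  prev <- data.frame(l = if (is.na(p)) NA_character_ else p, gain = 0L,
                     stringsAsFactors = FALSE)
  for (t in seq_along(charsets)) {
    C <- charsets[[t]]
    cand <- list()
    for (s in seq_len(nrow(prev))) {
      sl <- prev$l[s]
      for (f in C) {
        ls <- if (length(C) == 1L) f else setdiff(C, f)
        for (l in ls) {
          g <- prev$gain[s] + as.integer(!is.na(sl) && f == sl)
          key <- l
          old <- cand[[key]]
          if (is.null(old) || g > old$gain) {
            cand[[key]] <- list(gain = g, f = f, l = l, back = s)
          }
        }
      }
    }
    cand <- cand[sort(names(cand), method = "radix")]
    states[[t]] <- data.frame(
      l = vapply(cand, `[[`, "", "l"),
      f = vapply(cand, `[[`, "", "f"),
      gain = vapply(cand, `[[`, 1L, "gain"),
      back = vapply(cand, `[[`, 1L, "back"),
      stringsAsFactors = FALSE)
    prev <- states[[t]]
  }
  fin <- states[[length(states)]]
  total <- fin$gain + if (!is.na(q)) as.integer(fin$l == q) else 0L
  best <- which(total == max(total))[1L]
  picks <- vector("list", length(charsets))
  s <- best
  for (t in rev(seq_along(charsets))) {
    f <- states[[t]]$f[s]; l <- states[[t]]$l[s]
    C <- charsets[[t]]
    picks[[t]] <- if (length(C) == 1L) C else
      c(f, sort(setdiff(C, c(f, l)), method = "radix"), l)
    s <- states[[t]]$back[s]
  }
  picks
}
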