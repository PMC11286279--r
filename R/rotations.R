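# Internal rotation-sorting engine ---------------------------------------
#
# All variants reduce to sorting rotations of token (integer) vectors.
# Rotations are expanded row-wise into an integer matrix and ordered by a
# positional radix sort (column-wise `order()`), which is exact at desk
# scale; sentinel tokens are ranked strictly below alphabet tokens, and
# the concatenation terminator below the sentinels.

# Integer codes for the characters of each string: sentinel-free letters
# get ranks offset + 1, offset + 2, ... in byte order over the whole
# collection's alphabet.
letter_codes <- function(strings, alphabet, offset) {
  lapply(strings, function(s) match(str_chars(s), alphabet) + offset)
}

# All rotations of a list of integer vectors as rows of a `width`-column
# matrix. Each vector is treated as circular; when `width` exceeds a
# vector's length the surplus columns either wrap (wrap = TRUE) or are
# padded with 0 (safe whenever comparisons are decided within the rotation
# itself, as is the case for sentinel-carrying rotations).
conjugate_rows <- function(vecs, width, wrap = TRUE) {
  blocks <- lapply(vecs, function(v) {
    L <- length(v)
    idx <- (outer(seq_len(L) - 1L, seq_len(width) - 1L, "+") %% L) + 1L
    m <- matrix(v[idx], nrow = L)
    if (!wrap && width > L) m[, (L + 1L):width] <- 0L
    m
  })
  do.call(rbind, blocks)
}

# Row metadata: which string and which 0-based offset each row belongs to.
conjugate_meta <- function(lens) {
  list(string = rep.int(seq_along(lens), lens),
       offset = unlist(lapply(lens, function(L) seq_len(L) - 1L)))
}

# Order matrix rows lexicographically, with optional tie-break vectors.
order_rows <- function(m, ...) {
  cols <- lapply(seq_len(ncol(m)), function(j) m[, j])
  do.call(order, c(cols, list(...)))
}

# Last character (token) of each rotation.
last_token <- function(vecs, meta) {
  mapply(function(i, o) {
    v <- vecs[[i]]
    v[((o + length(v) - 1L) %% length(v)) + 1L]
  }, meta$string, meta$offset)
}

# Sort the rotations of the sentinel-terminated strings T_i$_i.
#
# strings: character vector already listed in the wanted order.
# distinct_dollars: TRUE ranks sentinel i as the i-th smallest symbol
# (multidollar semantics); FALSE gives every string the same sentinel
# (dollar-eBWT semantics).
#
# Returns ranks, per-row metadata in sorted order, the BWT characters and
# separator positions.
sep_rotation_sort <- function(strings, alphabet, distinct_dollars = TRUE) {
  k <- length(strings)
  base <- if (distinct_dollars) k else 1L
  letters <- letter_codes(strings, alphabet, base)
  vecs <- lapply(seq_len(k), function(i) {
    c(letters[[i]], if (distinct_dollars) i else 1L)
  })
  lens <- vapply(vecs, length, 1L)
  # With distinct ranked sentinels any two rotations of different strings
  # differ at or before the earlier sentinel, so rows may be padded to the
  # maximum length. With one shared sentinel (dollar-eBWT) the comparison
  # can continue past it, circularly; rows then wrap to twice the maximum
  # length, which decides every non-identical pair (Fine and Wilf).
  if (distinct_dollars) {
    rows <- conjugate_rows(vecs, max(lens), wrap = FALSE)
  } else {
    rows <- conjugate_rows(vecs, 2L * max(lens), wrap = TRUE)
  }
  meta <- conjugate_meta(lens)
  ord <- order_rows(rows, meta$string, meta$offset)
  lt <- last_token(vecs, meta)[ord]
  chars <- character(length(lt))
  chars[lt <= base] <- SEPARATOR
  chars[lt > base] <- alphabet[lt[lt > base] - base]
  # rank lookup: rank_of[[i]][o + 1] = sorted rank of rotation (i, offset o)
  rk <- integer(length(ord)); rk[ord] <- seq_along(ord)
  rank_of <- split(rk, meta$string)
  list(string = meta$string[ord], offset = meta$offset[ord],
       chars = chars, rank_of = rank_of,
       separator_positions = which(lt <= base))
}

# Sort all conjugates of the raw strings in omega-order (extended BWT).
# Powers are materialized to 2 * max length (sufficient by Fine-and-Wilf);
# residual ties are same-root conjugates, broken by smaller exponent, then
# stably by input index and offset.
omega_rotation_sort <- function(strings, alphabet) {
  letters <- letter_codes(strings, alphabet, 0L)
  lens <- vapply(letters, length, 1L)
  width <- 2L * max(lens)
  rows <- conjugate_rows(letters, width, wrap = TRUE)
  meta <- conjugate_meta(lens)
  exps <- vapply(strings, function(s) primitive_root(s)$exponent, 1L)
  ord <- order_rows(rows, exps[meta$string], meta$string, meta$offset)
  lt <- last_token(letters, meta)[ord]
  rk <- integer(length(ord)); rk[ord] <- seq_along(ord)
  rank_of <- split(rk, meta$string)
  list(string = meta$string[ord], offset = meta$offset[ord],
       chars = alphabet[lt], rank_of = rank_of)
}
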