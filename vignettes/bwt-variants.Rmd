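---
title: "BWT variants for string collections: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BWT variants for string collections: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multibwt)
```

## Why six transforms

The Burrows--Wheeler transform (BWT) of a single string `T` is the
concatenation of the last characters of the lexicographically sorted
rotations of `T`. For a *collection* `M = {T1, ..., Tk}` there is no single
canonical generalization, and the tools in circulation compute genuinely
different transforms. This package implements the six variants those tools
produce, so that any collection can be transformed, inverted, and the
variants compared:

* **eBWT** — last characters of *all conjugates of all members*, listed in
  the omega-order (below). No separators; length `N = sum(|Ti|)`;
  independent of the input order.
* **dolEBWT** — the eBWT of `{Ti$}`: one identical end-of-string symbol
  appended per member. Length `N + k`; order-independent.
* **mdolBWT** — the BWT of `T1$1 T2$2 ... Tk$k` with *distinct* sentinels
  `$1 < $2 < ... < $k`, all below the alphabet. Order-dependent: the
  sentinel ranks encode the input order.
* **colexBWT** — the mdolBWT after reordering the members
  colexicographically (lexicographically by reversed string).
* **optBWT** — the mdolBWT under an input order minimizing the number of
  runs over all `k!` orders.
* **concBWT** — the BWT of the single string `T1$T2$...Tk$#` with
  identical separators and a final terminator `# < $`. Normalized (the
  default) by dropping the leading separator contributed by the
  terminator rotation and renaming `#` to `$`, which makes its length
  `N + k`, comparable with the other separator-based variants.

All separator-based outputs render every sentinel as the glyph `"$"`;
inputs containing `"$"` or `"#"` are rejected rather than escaped.

### The omega-order

The eBWT sorts conjugates by the omega-order: `S` precedes `T` if they
share a primitive root and `S` has the smaller exponent, or if the
infinite power `S^w` is lexicographically smaller than `T^w`. The infinite
comparison is decided within the first `|S| + |T|` symbols — a consequence
of the Fine-and-Wilf periodicity theorem — so `omega_compare()` truncates
both powers there, and the conjugate sorter materializes rotations
circularly to twice the maximum member length. The omega-order and the
lexicographic order agree whenever neither string is a proper prefix of
the other; the classic disagreement is `GTC` before `GT` in omega-order
although `GT <lex GTC`.

One subtlety is worth recording. On rotations of distinct-dollar
terminated strings no rotation can be a proper prefix of another, so the
omega-order coincides with byte order and the mdolBWT sorter may pad
rotation rows. With a single shared dollar (dolEBWT) a rotation *can* be a
proper prefix of another — take the collection `{B, AB}`, whose rotations
include `B$` and `B$A` — and the two orders then differ. The dolEBWT
sorter therefore wraps rows circularly, and its independent oracle sorts
materialized powers; both agree with the identity
`dolEBWT(M) = mdolBWT(lex(M))`, which the suite checks textually on 200
seeded collections.

## The run parameter and interesting intervals

The number of runs `r` of a BWT (maximal blocks of one character) is the
size measure of run-length compressed BWT indexes and an increasingly
popular repetitiveness measure of the dataset itself — which is a problem
when non-equivalent transforms of the same collection disagree on it. The
package's analysis module locates exactly where the variants can differ.

A shared suffix `U` of at least two members whose preceding characters
differ (a *left-maximal* shared suffix, with the separator acting as the
preceding character when a member equals `U`) spans an **interesting
interval**: the contiguous range of rotation ranks beginning `U$`.
Distinct intervals are disjoint, and any two separator-based transforms of
the same multiset agree everywhere outside them — permuting the input only
permutes characters *within* intervals. This yields checkable bounds, all
enforced as invariants in the test suite:

* the Hamming distance between two separator-based texts is at most the
  summed interval width;
* separator positions coincide across variants unless some member is a
  proper suffix of another;
* an interval of width `w` whose most frequent character occurs `n_a`
  times, with `N_a = w - n_a`, can contain at most `w` runs when
  `n_a - 1 <= N_a` and `2*N_a + 1` otherwise (`interval_max_runs()`,
  verified exhaustively against all arrangements up to width 8);
* the **variability** of a collection is the ratio of summed interval run
  bounds to summed interval widths — near 1, an adverse input order can
  pay almost one run per interval position.

```{r}
toy <- string_collection(c("ATATG", "TGA", "ACG", "ATCA", "GGA"))
interesting_intervals(toy)
variability(toy)$value
```

## The run-minimizing order

`opt_order()` computes an input order whose mdolBWT attains the minimum
run count over all `k!` orders. The decomposition that makes this
tractable: outside intervals the text is fixed; inside an interval the
only freedom is the arrangement of its *blocks* (one per distinct
preceding character — members sharing the longer suffix `cU` all
contribute `c` here, so their relative order is delegated to a deeper
interval). Grouping equal characters is never harmful, so an interval
contributes `#blocks` runs minus one for each border where its first/last
block character equals the adjacent symbol. Block orders for different
intervals compose into one global permutation via the trie of reversed
strings.

Two design points were genuinely open:

* **Adjacent intervals couple.** When one interval ends exactly where the
  next begins, the merge at their border depends on both choices, and a
  greedy left-to-right pass can be suboptimal (with block alphabets
  `{a,b}`, `{a,b}` and a following fixed `a`, the first interval must end
  in `b`). Maximal chains of adjacent intervals are therefore solved by a
  small dynamic program over the last-block character — exactness is what
  the exhaustive `k!` oracle (`brute_min_runs_order()`) confirms on 100
  seeded collections with `k <= 6`.
* **Determinism.** DP ties and middle blocks are resolved in byte order
  (separator lowest), and equal strings keep their input order
  everywhere, so the permutation is a pure function of the collection.

On the five-string toy collection the optimal order saves exactly two
runs over the colexicographic order; colexBWT in general exceeds the
optimum by at most twice the number of interesting intervals.

## Inversion

Separator-based texts are inverted by backward LF walks from each of the
first `k` rows (the sentinel rows), stopping at the separator that closes
each string. LF steps on alphabet characters are stable for *every*
separator-based variant regardless of how sentinel ties were broken, so
one routine inverts the whole multidollar family, recovering the strings
in concatenation order. Two non-obvious cases:

* **Normalized concBWT.** The same walk recovers the correct multiset,
  but the concatenation order is permuted (the walk starting at the
  smallest separator row recovers the *last* string). The order is
  re-derived by matching separator start rows with walk stop rows; the
  one string whose predecessor rotation was removed by normalization is
  found by trying each candidate and re-transforming (`O(k)` candidate
  checks), so `invert_separator_bwt(text, "concbwt")` round-trips
  bit-exactly. Raw (un-normalized) texts with an explicit `#` are
  accepted and normalized first.
* **eBWT.** Without side information, LF cycles recover the multiset of
  primitive conjugacy classes — a non-primitive member `U^e` appears as
  `e` cycles of its root, and `{AA}` is indistinguishable from `{A, A}`.
  With the per-string conjugate ranks recorded at construction, each
  class is rotated to the exact input string. When several anchored
  strings share one root and spare cycles remain, the spare exponent is
  assigned to the largest-ranked anchor; collections such as
  `{AB, ABABAB}` versus `{ABAB, ABAB}` produce identical texts *and*
  ranks, so no rank-based inverter can distinguish them — the
  deterministic rule is documented rather than pretended away.

## Synthetic collections

`generate_collection()` produces the seeded inputs used throughout the
tests. The default mode draws one ancestor and mutates copies
(substitution rate 0.02 per position, no indels unless requested) —
emulating the many-similar-short-sequences regime where shared suffixes
abound and the variants differ most; `iid` mode gives the opposite
regime; `shared_suffix` mode plants an interesting interval by
construction. The generator threads a private RNG stream (the global seed
state is saved and restored), so identical specifications reproduce
identical collections.

What it does *not* emulate: quality scores, position- or motif-dependent
error profiles, reverse-complement strandedness, and realistic genome
repeat structure. Passing tests therefore certify the combinatorics of
the transforms on collections with controlled suffix sharing, not
performance claims on real sequencing data.

## Scales, representation, limits

Rotation sorting is a positional radix sort over an integer matrix of
expanded rotations (`order()` over columns): exact, allocation-heavy
(`O(n^2)` in the worst case), and entirely adequate for the scales this
package targets. Test problem sizes were chosen accordingly: 200 seeded
collections of total length at most 200 for the textual identities, 100
collections with `k <= 6` for the exhaustive optimality check, interval
widths up to 8 for arrangement enumeration, and all `k!` permutations up
to `k = 5` for order-independence. The naive oracles cap their inputs
(total length 500, `k <= 7` for the exhaustive order search, width 10 for
arrangement enumeration); caps are arguments, not constants.

Coordinates in all reports are 1-based inclusive, matching the interval
convention `[b, e]`. Strings are treated as opaque byte sequences — no
case folding outside the explicit I/O option — so every transform is an
exact character permutation of its input plus sentinels, an invariant the
suite asserts on every construction.

This package is a reference implementation for studying the transforms'
combinatorics. Engineering-scale construction (prefix-free parsing,
induced sorting, external memory), r-index construction on top of the
transforms, and the xBWT/bijective-BWT families are out of scope.
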