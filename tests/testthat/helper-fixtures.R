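# Shared fixtures and small helpers for the test suite.

# The worked examples used throughout: a two-string collection, a
# suffix-sharing pair, the eight-string read-like collection, and the
# five-string toy collection.
coll_gtc_gt <- function() string_collection(c("GTC", "GT"))
coll_example1 <- function() string_collection(c("AACGAC", "TCAC"))
coll_example2 <- function() {
  string_collection(c("AAAA", "AGCA", "GCAA", "GTCA",
                      "CAAA", "CGCA", "TCAA", "TTCA"))
}
coll_toy <- function() {
  string_collection(c("ATATG", "TGA", "ACG", "ATCA", "GGA"))
}

# A reproducible random collection: k strings of lengths within `lens`
# over `alphabet`, optionally as mutated copies of one ancestor (which
# yields many shared suffixes).
random_collection <- function(seed, k = NULL, lens = c(1L, 8L),
                              alphabet = c("A", "C", "G", "T"),
                              similar = FALSE) {
  withr::with_seed(seed, {
    if (is.null(k)) k <- sample(2:6, 1L)
    if (similar) {
      anc <- sample(alphabet, sample(seq(lens[1L], lens[2L]), 1L),
                    replace = TRUE)
      strs <- vapply(seq_len(k), function(i) {
        ch <- anc
        mut <- runif(length(ch)) < 0.15
        ch[mut] <- sample(alphabet, sum(mut), replace = TRUE)
        paste(ch, collapse = "")
      }, "")
    } else {
      strs <- vapply(seq_len(k), function(i) {
        paste(sample(alphabet, sample(seq(lens[1L], lens[2L]), 1L),
                     replace = TRUE), collapse = "")
      }, "")
    }
    string_collection(strs)
  })
}

separator_positions_of <- function(t) {
  which(strsplit(t$text, "", fixed = TRUE)[[1L]] == "$")
}

ALL_VARIANTS <- c("ebwt", "dolebwt", "mdolbwt", "colexbwt", "optbwt",
                  "concbwt")
SEP_VARIANTS <- setdiff(ALL_VARIANTS, "ebwt")

# Multiset of characters of a text, as a sorted character vector.
char_multiset <- function(text) {
  sort(strsplit(text, "", fixed = TRUE)[[1L]], method = "radix")
}

# Canonical conjugacy-class multiset of a collection: each string
# contributes its primitive root (least rotation) once per exponent,
# matching the cycle decomposition of the eBWT.
class_multiset <- function(strings) {
  sort(unlist(lapply(strings, function(s) {
    rd <- primitive_root(s)
    rep(multibwt:::min_rotation(rd$root), rd$exponent)
  })), method = "radix")
}
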