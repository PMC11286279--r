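# Construction of the six BWT variants.

test_that("worked examples reproduce the expected transform texts", {
  m <- coll_gtc_gt()
  e <- ebwt(m)
  expect_equal(e$text, "TCTGG")
  expect_equal(e$conjugate_ranks, c(2L, 3L))
  expect_equal(e$length, 5L)
  expect_length(e$separator_positions, 0L)
  expect_equal(dol_ebwt(m)$text, "TCT$$GG")

  expect_equal(bwt("CAGAGA"), "GGCAAA")
  expect_equal(bwt("CAGAGA$"), "AGGC$AA")
  expect_equal(mdol_bwt(string_collection("CAGAGA"))$text, "AGGC$AA")

  m1 <- coll_example1()
  expect_equal(ebwt(m1)$text, "CGACATAACC")
  expect_equal(dol_ebwt(m1)$text, "CC$GCAAATAC$")

  m2 <- coll_example2()
  expect_equal(mdol_bwt(m2)$text,
               "AAAAAAAAACACACACACACAC$$GTGTGT$$AC$$GT$$")
  expect_equal(colex_bwt(m2)$text,
               "AAAAAAAAAAAACCCCAACCAC$$GGTTGT$$AC$$GT$$")

  # single-string BWT matrix of GTC$: rows $GTC, C$GT, GTC$, TC$G
  expect_equal(mdol_bwt(string_collection("GTC"))$text, "CT$G")
  expect_equal(ebwt(string_collection("A"))$text, "A")
  expect_equal(dol_ebwt(string_collection("A"))$text, "A$")
  expect_equal(mdol_bwt(string_collection(c("A", "A")))$text, "AA$$")
})

test_that("toy five-string collection matches the naive oracles", {
  toy <- coll_toy()
  # frozen from the brute-force rotation-sort oracles
  expect_equal(ebwt(toy)$text, "CGGGATGTACGTTAAAAA")
  expect_equal(colex_bwt(toy)$text, "AAAGGCGG$$$TTACTGT$AAA$")
  expect_equal(conc_bwt(toy)$text, "AAGAGGGC$$$TTACTGT$AAA$")
  for (v in ALL_VARIANTS) {
    expect_identical(bwt_transform(toy, v)$text, naive_bwt_variant(toy, v),
                     info = v)
  }
})

test_that("colexicographic order sorts by reversed strings, stably", {
  # reversed: AGT (from TGA) sorts before GCA (from ACG)
  expect_equal(colex_order(string_collection(c("TGA", "ACG")))$permutation,
               c(1L, 2L))
  expect_equal(colex_order(string_collection(c("GT", "GT")))$permutation,
               c(1L, 2L))
  expect_equal(colex_order(coll_example2())$permutation,
               c(1L, 5L, 3L, 7L, 2L, 6L, 4L, 8L))
  # lex order on the {GTC, GT} pair puts GT first
  expect_equal(lex_order(coll_gtc_gt())$permutation, c(2L, 1L))
})

test_that("length, character conservation and prefix properties hold", {
  for (seed in 1:25) {
    m <- random_collection(seed, similar = seed %% 2L == 0L)
    last_chars <- substr(m$strings, nchar(m$strings), nchar(m$strings))
    for (v in ALL_VARIANTS) {
      t <- bwt_transform(m, v)
      if (v == "ebwt") {
        expect_equal(t$length, m$total_length)
        expect_identical(char_multiset(t$text),
                         char_multiset(paste(m$strings, collapse = "")))
      } else {
        expect_equal(t$length, m$total_length + m$k)
        expect_identical(char_multiset(t$text),
                         char_multiset(paste(c(m$strings,
                                               rep("$", m$k)), collapse = "")))
        # first k symbols permute the last characters of the members
        prefix <- strsplit(t$text, "", fixed = TRUE)[[1L]][seq_len(m$k)]
        expect_identical(sort(prefix), sort(last_chars))
        expect_length(separator_positions_of(t), m$k)
      }
    }
    expect_equal(conc_bwt(m, normalized = FALSE)$length,
                 m$total_length + m$k + 1L)
  }
})

test_that("eBWT and dollar-eBWT are input-order independent", {
  for (seed in c(3L, 11L)) {
    m <- random_collection(seed, k = 4L, lens = c(1L, 5L))
    perms <- multibwt:::all_permutations(m$k)
    e0 <- ebwt(m)$text
    d0 <- dol_ebwt(m)$text
    for (i in seq_len(nrow(perms))) {
      mp <- apply_order(m, perms[i, ])
      expect_identical(ebwt(mp)$text, e0)
      expect_identical(dol_ebwt(mp)$text, d0)
    }
  }
  # while the multidollar BWT is not: the eight-string example changes
  m2 <- coll_example2()
  expect_false(identical(mdol_bwt(m2)$text,
                         mdol_bwt(m2, colex_order(m2))$text))
})

test_that("sentinel identities connect the variants", {
  for (seed in 1:20) {
    m <- random_collection(seed, similar = seed %% 2L == 0L)
    # dollar-eBWT equals the multidollar BWT of the lex-sorted collection
    expect_identical(dol_ebwt(m)$text,
                     mdol_bwt(m, lex_order(m))$text, info = seed)
    # multidollar BWT equals the BWT of the full concatenation with
    # distinct ranked sentinels (the naive path sorts the N+k rotations
    # of the concatenated string; the fast path sorts per-string
    # conjugates, i.e. the eBWT of {Ti$i})
    expect_identical(mdol_bwt(m)$text, naive_bwt_variant(m, "mdolbwt"),
                     info = seed)
  }
})

test_that("every fast path agrees with its naive oracle on random collections", {
  for (seed in 1:20) {
    m <- random_collection(100L + seed, lens = c(1L, 12L),
                           similar = seed %% 2L == 0L)
    for (v in ALL_VARIANTS) {
      expect_identical(bwt_transform(m, v)$text, naive_bwt_variant(m, v),
                       info = paste(v, seed))
    }
    expect_identical(conc_bwt(m, normalized = FALSE)$text,
                     naive_bwt_variant(m, "concbwt", normalized = FALSE))
  }
  # including collections with duplicated and non-primitive members
  m <- string_collection(c("ABAB", "AB", "AB", "AA", "BA"))
  for (v in ALL_VARIANTS) {
    expect_identical(bwt_transform(m, v)$text, naive_bwt_variant(m, v),
                     info = v)
  }
})

test_that("naive omega sort lists the conjugates of {GTC, GT} in order", {
  srt <- naive_omega_sort(coll_gtc_gt())
  expect_equal(srt$conjugate, c("CGT", "GTC", "GT", "TCG", "TG"))
  expect_equal(naive_omega_sort(string_collection("A"))$conjugate, "A")
  big <- generate_collection(10, c(60, 60), seed = 5)
  expect_error(naive_omega_sort(big, cap = 100L), "too large")
})

test_that("one-string collections collapse the separator-based variants", {
  for (s in c("GTC", "CAGAGA", "A", "ABAB")) {
    m <- string_collection(s)
    ref <- mdol_bwt(m)$text
    expect_identical(dol_ebwt(m)$text, ref)
    expect_identical(colex_bwt(m)$text, ref)
    expect_identical(opt_bwt(m)$text, ref)
    expect_identical(conc_bwt(m)$text, ref)
    expect_identical(ebwt(m)$text, bwt(s))
  }
})

test_that("the dispatcher validates variants and order arguments", {
  m <- coll_gtc_gt()
  expect_error(bwt_transform(m, "xbwt"))
  expect_warning(t <- bwt_transform(m, "ebwt", order = c(2L, 1L)),
                 "order-independent")
  expect_equal(t$text, "TCTGG")
  expect_equal(bwt_transform(m, "mdolbwt", order = c(2L, 1L))$length, 7L)
  expect_error(mdol_bwt(m, c(1L, 1L)), "permutation")
  # identical symbol multisets across separator-based variants
  expect_identical(char_multiset(bwt_transform(m, "concbwt")$text),
                   char_multiset(bwt_transform(m, "mdolbwt")$text))
})

test_that("collection construction enforces its invariants", {
  expect_error(string_collection(character(0)), "at least one")
  expect_error(string_collection(c("AC", "")), "empty")
  expect_error(string_collection("AC$G"), "sentinel")
  expect_error(string_collection("AC#G"), "sentinel")
  m <- string_collection(c("GTC", "GT"))
  expect_equal(m$k, 2L)
  expect_equal(m$total_length, 5L)
  expect_equal(m$alphabet, c("C", "G", "T"))
  expect_equal(m$sigma, 3L)
})
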