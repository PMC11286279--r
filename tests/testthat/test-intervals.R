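# Interesting intervals, run bounds, variability.

test_that("the toy collection has exactly the four expected intervals", {
  iv <- interesting_intervals(coll_toy())
  df <- as.data.frame(iv)
  expect_equal(nrow(df), 4L)
  expect_equal(df$suffix, c("", "A", "G", "GA"))
  expect_equal(df$begin[1L], 1L)
  expect_equal(df$end[1L], 5L)
  expect_equal(df$width, c(5L, 3L, 2L, 2L))
  # U = "A": TGA, ATCA, GGA preceded by G, C, G
  expect_equal(iv[[2L]]$parikh, c(C = 1L, G = 2L))
  # U = "G": ATATG, ACG preceded by T, C; U = "GA": TGA, GGA by T, G
  expect_equal(iv[[3L]]$parikh, c(C = 1L, T = 1L))
  expect_equal(iv[[4L]]$parikh, c(G = 1L, T = 1L))
})

test_that("left-maximality prunes shared but equally-preceded suffixes", {
  # both strings end in A, so the empty suffix is not interesting; AAA is
  # (preceded by A and C); AA and A are shared but both preceded by A
  iv <- interesting_intervals(string_collection(c("AAAA", "CAAA")))
  df <- as.data.frame(iv)
  expect_equal(df$suffix, "AAA")
  expect_equal(df$width, 2L)
  # identical strings: no differing preceding characters anywhere
  expect_length(interesting_intervals(string_collection(c("GT", "GT"))), 0L)
})

test_that("a member that is a proper suffix contributes the separator", {
  iv <- interesting_intervals(string_collection(c("GT", "AGT")))
  df <- as.data.frame(iv)
  expect_equal(df$suffix, "GT")
  expect_equal(iv[[1L]]$parikh, c("$" = 1L, "A" = 1L))
})

test_that("intervals are disjoint and order-invariant on random collections", {
  for (seed in 1:15) {
    m <- random_collection(400L + seed, similar = TRUE, lens = c(2L, 8L))
    iv <- as.data.frame(interesting_intervals(m))
    if (nrow(iv) > 1L) {
      expect_true(all(iv$begin[-1L] > iv$end[-nrow(iv)]))
    }
    # invariance under permuting the input collection
    perm <- withr::with_seed(seed, sample.int(m$k))
    iv2 <- as.data.frame(interesting_intervals(apply_order(m, perm)))
    expect_equal(iv[c("suffix", "begin", "end", "width", "var_bound")],
                 iv2[c("suffix", "begin", "end", "width", "var_bound")])
  }
})

test_that("the interval run bound matches brute-force enumeration", {
  expect_equal(interval_max_runs(c(A = 3, C = 1)), 3L)
  expect_equal(interval_max_runs(c(A = 2, C = 2)), 4L)
  expect_equal(interval_max_runs(c(A = 5)), 1L)
  expect_error(interval_max_runs(c(A = 0)), "zero")
  expect_equal(brute_interval_max_runs(c(A = 3, C = 1)), 3L)
  expect_equal(brute_interval_max_runs(c(A = 2, C = 2)), 4L)
  expect_equal(brute_interval_max_runs(c(A = 1, C = 1, G = 1)), 3L)
  expect_error(brute_interval_max_runs(c(A = 8, C = 8)), "cap")

  # all Parikh vectors of width <= 8 over up to 3 symbols
  for (a in 0:8) for (b in 0:8) for (cc in 0:2) {
    w <- a + b + cc
    if (w < 2L || w > 8L) next
    pk <- c(A = a, B = b, C = cc)
    expect_equal(interval_max_runs(pk), brute_interval_max_runs(pk),
                 info = paste(a, b, cc))
  }
  # and the vectors arising in seeded instances
  for (seed in 1:10) {
    m <- random_collection(500L + seed, similar = TRUE, lens = c(2L, 8L))
    for (iv in interesting_intervals(m)) {
      if (iv$width <= 8L) {
        expect_equal(iv$var_bound, brute_interval_max_runs(iv$parikh))
      }
    }
  }
})

test_that("variability summarizes the interval bounds", {
  v0 <- variability(string_collection(c("GT", "GT")))
  expect_false(v0$defined)
  expect_equal(v0$value, 0)
  # single interval with counts {A:2, C:2}: bound 4 over width 4
  v1 <- variability(string_collection(c("AT", "AT", "CT", "CT")))
  expect_true(v1$defined)
  expect_equal(v1$n_intervals, 1L)
  expect_equal(v1$value, 1)
  # toy collection: bounds 5+3+2+2 over widths 5+3+2+2
  vt <- variability(coll_toy())
  expect_equal(vt$n_intervals, 4L)
  expect_equal(vt$value, 1)
  # variability always lies in [0, 1]
  for (seed in 1:10) {
    v <- variability(random_collection(600L + seed, similar = TRUE))
    expect_gte(v$value, 0)
    expect_lte(v$value, 1)
  }
})

test_that("differences between separator-based variants are confined to intervals", {
  for (seed in 1:12) {
    m <- random_collection(700L + seed, similar = TRUE, lens = c(2L, 8L))
    iv <- interesting_intervals(m)
    covered <- unlist(lapply(iv, function(x) seq(x$begin, x$end)))
    total <- if (length(iv)) sum(vapply(iv, `[[`, 1L, "width")) else 0L
    texts <- vapply(SEP_VARIANTS, function(v) bwt_transform(m, v)$text, "")
    for (i in seq_along(texts)) for (j in seq_along(texts)) {
      if (i >= j) next
      mis <- mismatch_positions(texts[i], texts[j])
      expect_true(all(mis %in% covered),
                  info = paste(seed, SEP_VARIANTS[i], SEP_VARIANTS[j]))
      expect_lte(hamming(texts[i], texts[j]), total)
    }
  }
})

test_that("dollar positions coincide exactly without proper-suffix pairs", {
  # negative case: no member is a proper suffix of another
  m <- string_collection(c("GTC", "AGT"))
  ref <- separator_positions_of(mdol_bwt(m))
  expect_equal(separator_positions_of(mdol_bwt(m, c(2L, 1L))), ref)
  expect_equal(separator_positions_of(conc_bwt(m)), ref)
  expect_equal(separator_positions_of(conc_bwt(m, c(2L, 1L))), ref)
  expect_equal(separator_positions_of(dol_ebwt(m)), ref)
  # positive case: GT is a proper suffix of AGT and positions may move
  m2 <- string_collection(c("GT", "AGT"))
  expect_false(identical(separator_positions_of(mdol_bwt(m2)),
                         separator_positions_of(mdol_bwt(m2, c(2L, 1L)))))
})

test_that("colex runs exceed the optimum by at most twice the interval count", {
  for (seed in 1:15) {
    m <- random_collection(800L + seed, similar = seed %% 2L == 0L)
    cm <- length(interesting_intervals(m))
    expect_lte(count_runs(colex_bwt(m)$text)$run_count,
               count_runs(opt_bwt(m)$text)$run_count + 2L * cm)
  }
})
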