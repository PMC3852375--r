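needle <- scoring_scheme() # match 5 / mismatch -4 / open 30 / ext 0, free ends

test_that("global alignment reproduces hand-checked and oracle-computed scores", {
  expect_equal(global_align("AAAA", "AAAA", needle)$score, 20)
  expect_equal(alignment_identity(global_align("AAAA", "AAAA", needle)), 1)
  # ends-free: the staggered overlap ACGTACGT---/----ACGTCGT is optimal
  # (both terminal gap runs free), as confirmed by exhaustive enumeration
  expect_equal(global_align("ACGTACGT", "ACGTCGT", needle)$score,
               brute_align_score("ACGTACGT", "ACGTCGT", needle))
  # with end gaps charged, the internal single-gap alignment wins
  strict <- scoring_scheme(end_gaps_free = FALSE)
  g <- global_align("ACGTACGT", "ACGTCGT", strict)
  expect_equal(g$score, 5)
  expect_equal(g$aligned_b, "ACGT-CGT")
})

test_that("global alignment score equals brute-force enumeration on short pairs", {
  set.seed(11)
  for (i in 1:25) {
    a <- rand_seq(sample(1:6, 1))
    b <- rand_seq(sample(1:6, 1))
    for (sc in list(needle,
                    scoring_scheme(end_gaps_free = FALSE),
                    scoring_scheme(match = 2, mismatch = -3, gap_open = 5,
                                   gap_extend = 2, end_gaps_free = FALSE))) {
      g <- global_align(a, b, sc)
      expect_equal(g$score, brute_align_score(a, b, sc),
                   info = paste(a, b, sc$gap_open, sc$end_gaps_free))
      expect_identical(gsub("-", "", g$aligned_a), a)
      expect_identical(gsub("-", "", g$aligned_b), b)
    }
  }
})

test_that("self-alignment scores match * length with identity 1", {
  set.seed(12)
  for (i in 1:5) {
    s <- rand_seq(sample(10:80, 1))
    g <- global_align(s, s, needle)
    expect_equal(g$score, 5 * nchar(s))
    expect_equal(alignment_identity(g), 1)
    expect_equal(alignment_identity(g, exclude_gaps = FALSE), 1)
  }
})

test_that("alignment identity counts gaps per the chosen convention", {
  aln <- global_align("ACGTACGT", "ACGTCGT",
                      scoring_scheme(end_gaps_free = FALSE))
  expect_equal(alignment_identity(aln, exclude_gaps = TRUE), 1)
  expect_equal(alignment_identity(aln, exclude_gaps = FALSE), 7 / 8)
  # 4 matches + 3 mismatches + 1 gap column -> 4/7 excluding gaps
  g <- strataclock:::alignment_from_strings("AAAATTT-", "AAAAGGGC")
  expect_equal(g$gap_columns, 1)
  expect_equal(alignment_identity(g), 4 / 7)
  expect_equal(alignment_identity(g, exclude_gaps = FALSE), 4 / 8)
  # all-match 8-column alignment: 1 either way
  h <- strataclock:::alignment_from_strings("ACGTACGT", "ACGTACGT")
  expect_equal(alignment_identity(h), 1)
  expect_equal(alignment_identity(h, FALSE), 1)
})

test_that("dot plot thresholds behave at the window boundary", {
  a <- "ACGTACGTAC"
  expect_equal(dotplot(a, a, window = 10, min_matches = 8),
               data.frame(i = 1L, j = 1L, orientation = "direct"),
               ignore_attr = TRUE)
  b2 <- "ACGTACGTGT" # 2 mismatches: 8 matching positions, exactly threshold
  expect_equal(nrow(dotplot(a, b2, 10, 8)), 1)
  b3 <- "ACGTACGGGT" # 3 mismatches: below threshold
  expect_equal(nrow(dotplot(a, b3, 10, 8)), 0)
  expect_error(dotplot("ACGT", a, window = 10), "window longer")
  expect_error(dotplot(a, a, window = 10, min_matches = 11))
})

test_that("dotplot(a, b) is the transpose of dotplot(b, a)", {
  set.seed(13)
  a <- rand_seq(150)
  b <- paste0(rand_seq(40), substr(a, 20, 90), rand_seq(40))
  d_ab <- dotplot(a, b, window = 10, min_matches = 8)
  d_ba <- dotplot(b, a, window = 10, min_matches = 8)
  expect_gt(nrow(d_ab), 0)
  flipped <- d_ba[, c("j", "i", "orientation")]
  names(flipped) <- c("i", "j", "orientation")
  flipped <- flipped[order(flipped$i, flipped$j), ]
  expect_equal(d_ab[order(d_ab$i, d_ab$j), ], flipped, ignore_attr = TRUE)
})
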