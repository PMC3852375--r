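test_that("a planted identical direct repeat becomes an LTR candidate with exact bounds", {
  set.seed(41)
  blk <- rand_seq(300)
  s <- paste0(rand_seq(1999), blk, rand_seq(5700), blk, rand_seq(11700))
  rp <- find_self_repeats(s)
  cand <- rp[rp$class == "ltr_candidate", ]
  expect_equal(nrow(cand), 1)
  # boundaries recover the planted copy (the maximum-likelihood boundary
  # may include a stray matching flank base, so allow 2 bp of slack)
  expect_lte(abs(cand$left_start - 2000), 2)
  expect_lte(abs(cand$left_end - 2299), 2)
  expect_lte(abs(cand$right_start - 8000), 2)
  expect_lte(abs(cand$right_end - 8299), 2)
  expect_true(cand$left_start <= 2000 && cand$left_end >= 2299)
  expect_gte(cand$identity, 0.99)

  # the same block reverse-complemented is an inverted other_repeat
  s2 <- paste0(rand_seq(1999), blk, rand_seq(5700), revcomp(blk),
               rand_seq(11700))
  rp2 <- find_self_repeats(s2)
  expect_true(all(rp2$class == "other_repeat"))
  expect_true(all(rp2$orientation == "inverted"))
})

test_that("a dinucleotide tract is classified simple_repeat with its period", {
  set.seed(42)
  s <- paste0(rand_seq(3000), strrep("AT", 250), rand_seq(3000))
  rp <- find_self_repeats(s)
  expect_true(nrow(rp) > 0)
  expect_true(all(rp$class == "simple_repeat"))
  expect_true(all(rp$period == 2, na.rm = TRUE))
  expect_true(min(rp$left_start) >= 3001 - 10)
  expect_true(max(rp$right_end) <= 3500 + 10)
})

test_that("element calling applies structural constraints and reports losers", {
  mk_pair <- function(ls, le, rs, re, id = 0.95, class = "ltr_candidate") {
    data.frame(left_start = ls, left_end = le, right_start = rs,
               right_end = re, orientation = "direct",
               length = le - ls + 1, score = 100, identity = id,
               evalue = 1e-60, period = NA_real_, class = class)
  }
  # single candidate -> single element, no nesting
  el <- call_ltr_elements(mk_pair(1000, 1299, 4000, 4299))
  expect_equal(nrow(el), 1)
  expect_true(is.na(el$nested_in))
  expect_equal(el$start, 1000)
  expect_equal(el$end, 4299)
  expect_equal(el$internal_start, 1300)
  expect_equal(el$internal_end, 3999)

  # LTR length ratio 2:1 -> rejected as unresolved
  bad <- call_ltr_elements(mk_pair(1000, 1599, 4000, 4299))
  expect_equal(nrow(bad), 0)
  expect_equal(attr(bad, "unresolved")$reason, "ltr length ratio")

  # identity below the constraint -> unresolved
  low <- call_ltr_elements(mk_pair(1000, 1299, 4000, 4299, id = 0.7))
  expect_equal(nrow(low), 0)
  expect_equal(attr(low, "unresolved")$reason, "low identity")

  # proper nesting: B inside A's internal region
  pairs <- rbind(mk_pair(1000, 1299, 9000, 9299),
                 mk_pair(2000, 2199, 5000, 5199))
  el2 <- call_ltr_elements(pairs)
  expect_equal(nrow(el2), 2)
  expect_equal(el2$nested_in, c(NA_integer_, 1L))

  # partial overlap that is not nesting: lower-identity candidate loses
  pairs3 <- rbind(mk_pair(1000, 1299, 5000, 5299, id = 0.99),
                  mk_pair(2000, 2299, 7000, 7299, id = 0.90))
  el3 <- call_ltr_elements(pairs3)
  expect_equal(nrow(el3), 1)
  expect_equal(el3$identity, 0.99)
  expect_equal(attr(el3, "unresolved")$reason,
               "conflicts with higher-ranked element")
})

test_that("nested planted elements are recovered end to end", {
  set.seed(43)
  ltrA <- rand_seq(300); ltrB <- rand_seq(250)
  inner <- paste0(ltrB, rand_seq(800), ltrB)
  outer <- paste0(ltrA, rand_seq(700), inner, rand_seq(700), ltrA)
  s <- paste0(rand_seq(2000), outer, rand_seq(2000))
  el <- call_ltr_elements(find_self_repeats(s))
  expect_equal(nrow(el), 2)
  outer_row <- which(el$ltr_length > 275)
  inner_row <- setdiff(1:2, outer_row)
  expect_true(is.na(el$nested_in[outer_row]))
  expect_equal(el$nested_in[inner_row], el$id[outer_row])
})

test_that("recovered element LTR pairs re-align at or above the identity constraint", {
  set.seed(44)
  cfg <- sim_config(ancestral_length = 8000L,
                    insertions = data.frame(lineage = "X", time = 1.0e6,
                                            ltr_length = 400L,
                                            internal_length = 1500L,
                                            position = NA_integer_),
                    seed = 44)
  sim <- simulate_xy_pair(cfg)
  el <- call_ltr_elements(find_self_repeats(sim$seq_x))
  expect_gte(nrow(el), 1)
  for (i in seq_len(nrow(el))) {
    l <- substr(sim$seq_x, el$left_ltr_start[i], el$left_ltr_end[i])
    r <- substr(sim$seq_x, el$right_ltr_start[i], el$right_ltr_end[i])
    expect_gte(alignment_identity(global_align(l, r)), 0.85)
  }
})

test_that("X-Y homologous blocks pass the three thresholds and carry divergences", {
  set.seed(45)
  seg <- rand_seq(1000)
  x <- paste0(rand_seq(6000), seg, rand_seq(13000))
  y <- paste0(rand_seq(12000), mutate_seq(seg, 0.1), rand_seq(7000))
  bl <- find_xy_homology(x, y, reps = 100, seed = 1)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$orientation, "direct")
  expect_equal(bl$identity, 0.9, tolerance = 0.02)
  expect_gt(bl$k, 0.05)
  expect_lt(bl$k, 0.2)
  expect_gt(bl$se_k, 0)
  # reverse-complemented segment: inverted, with display y_start > y_end
  y_inv <- paste0(rand_seq(12000), revcomp(mutate_seq(seg, 0.1)),
                  rand_seq(7000))
  bl2 <- find_xy_homology(x, y_inv, compute_k = FALSE)
  expect_equal(bl2$orientation, "inverted")
  expect_gt(bl2$y_start, bl2$y_end)
  # a 400-bp identical segment fails the length threshold
  seg4 <- rand_seq(400)
  x3 <- paste0(rand_seq(3000), seg4, rand_seq(3000))
  y3 <- paste0(rand_seq(2000), seg4, rand_seq(4000))
  expect_equal(nrow(find_xy_homology(x3, y3, compute_k = FALSE)), 0)
})

test_that("X-Y homology search is reciprocal up to role swapping", {
  set.seed(46)
  seg1 <- rand_seq(800); seg2 <- rand_seq(600)
  x <- paste0(rand_seq(2000), seg1, rand_seq(2000), seg2, rand_seq(2000))
  y <- paste0(rand_seq(1000), mutate_seq(seg2, 0.05), rand_seq(3000),
              revcomp(mutate_seq(seg1, 0.05)), rand_seq(1000))
  fw <- find_xy_homology(x, y, compute_k = FALSE)
  bw <- find_xy_homology(y, x, compute_k = FALSE)
  expect_equal(nrow(fw), nrow(bw))
  key_fw <- paste(pmin(fw$x_start, fw$x_end),
                  pmin(bw$x_start, bw$x_end)[order(bw$id)])
  fw_x <- fw[order(fw$x_start), ]
  bw_sw <- bw[order(pmin(bw$y_start, bw$y_end)), ]
  expect_equal(fw_x$orientation, bw_sw$orientation)
  expect_equal(fw_x$x_start, pmin(bw_sw$y_start, bw_sw$y_end))
  expect_equal(fw_x$x_end, pmax(bw_sw$y_start, bw_sw$y_end))
})

test_that("coverage summary reproduces the published coverage percentages", {
  bl <- read_fixture("slap3xy_homology_blocks.tsv")
  seqs <- read_fixture("slap3xy_sequences.tsv")
  cov_x <- coverage_summary(bl, "x",
                            seqs$length_bp[seqs$role == "X"])
  cov_y <- coverage_summary(bl, "y",
                            seqs$length_bp[seqs$role == "Y"])
  expect_equal(cov_x$summed_length, 7713)
  expect_equal(round(cov_x$summed_percent, 1), 6.7)
  expect_equal(cov_y$summed_length, 7709)
  expect_equal(round(cov_y$summed_percent, 1), 10.6)
  # both sides are "7.7 kb" at the reported precision
  expect_equal(round(cov_x$summed_length / 1000, 1), 7.7)
  expect_equal(round(cov_y$summed_length / 1000, 1), 7.7)
  # the merged union counts the row-3/row-4 overlap once
  expect_lt(cov_y$merged_length, cov_y$summed_length)
  expect_equal(round(cov_y$merged_percent, 1), 8.9)
  # empty input
  cov0 <- coverage_summary(bl[0, ], "x", 1000)
  expect_equal(cov0$summed_length, 0)
  expect_equal(cov0$summed_percent, 0)
})
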