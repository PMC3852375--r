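test_that("evolution over zero years is the identity and seeds give determinism", {
  cfg <- sim_config(seed = 1)
  set.seed(71)
  s <- rand_seq(500)
  expect_identical(as.character(evolve_sequence(s, 0, cfg)), s)
  a <- evolve_sequence(s, 2e6, cfg, seed = 42)
  b <- evolve_sequence(s, 2e6, cfg, seed = 42)
  expect_identical(as.character(a), as.character(b))
  c_ <- evolve_sequence(s, 2e6, cfg, seed = 43)
  expect_false(identical(as.character(a), as.character(c_)))
})

test_that("substitution process matches the Jukes-Cantor expectation", {
  # uniform composition, kappa = 1, rt = 0.05:
  # E[p] = (3/4)(1 - exp(-4 * 0.05 / 3)) ~ 0.0484
  cfg <- sim_config(base_composition = rep(0.25, 4), kappa1 = 1,
                    kappa2 = 1, r = 1e-8, indel_rate = 0,
                    insertions = NULL)
  years <- 0.05 / 1e-8
  set.seed(72)
  ps <- replicate(100, {
    s <- rand_seq(10000)
    t <- as.character(evolve_sequence(s, years, cfg))
    mean(strsplit(s, "")[[1]] != strsplit(t, "")[[1]])
  })
  expected <- 0.75 * (1 - exp(-4 * 0.05 / 3))
  mc_se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - expected), 3 * mc_se)
})

test_that("simulated X/Y truth bookkeeping is complete and consistent", {
  ins <- data.frame(lineage = c("X", "X", "Y"),
                    time = c(2e6, 0.5e6, 1e6),
                    ltr_length = 300L, internal_length = 1200L,
                    position = NA_integer_)
  cfg <- sim_config(ancestral_length = 6000L, insertions = ins, seed = 73)
  sim <- simulate_xy_pair(cfg)
  el <- sim$truth$elements
  expect_equal(nrow(el), 3)
  expect_equal(sort(el$lineage), c("X", "X", "Y"))
  # truth intervals lie inside the emitted sequences and are coherent
  for (i in seq_len(nrow(el))) {
    s <- if (el$lineage[i] == "X") sim$seq_x else sim$seq_y
    expect_lte(el$end[i], nchar(s))
    expect_equal(el$start[i], el$left_ltr_start[i])
    expect_equal(el$end[i], el$right_ltr_end[i])
    # LTR intervals keep their configured length (indels never cut LTRs)
    expect_equal(el$left_ltr_end[i] - el$left_ltr_start[i] + 1L, 300L)
    expect_equal(el$right_ltr_end[i] - el$right_ltr_start[i] + 1L, 300L)
  }
  # ancestral-to-final lift is monotone on surviving positions
  for (lift in list(sim$truth$lift_x, sim$truth$lift_y)) {
    alive <- lift[!is.na(lift)]
    expect_true(all(diff(alive) > 0))
  }
  expect_lte(max(sim$truth$lift_x, na.rm = TRUE), nchar(sim$seq_x))
})

test_that("an element inserted at the split with an immediate present has identical LTRs", {
  cfg <- sim_config(ancestral_length = 3000L, t_stop = 1, r = 1.8e-8,
                    indel_rate = 0,
                    insertions = data.frame(lineage = "X", time = 1,
                                            ltr_length = 250L,
                                            internal_length = 500L,
                                            position = NA_integer_),
                    seed = 74)
  sim <- simulate_xy_pair(cfg)
  el <- sim$truth$elements
  left <- substr(sim$seq_x, el$left_ltr_start, el$left_ltr_end)
  right <- substr(sim$seq_x, el$right_ltr_start, el$right_ltr_end)
  expect_identical(left, right)
})

test_that("planted simple repeats and heavy indel traffic keep the truth aligned", {
  cfg <- sim_config(ancestral_length = 5000L,
                    simple_repeats = data.frame(motif = "AT", copies = 200,
                                                position = 1000),
                    indel_rate = 5e-8, # deliberately indel-rich
                    insertions = data.frame(lineage = "Y", time = 1.5e6,
                                            ltr_length = 300L,
                                            internal_length = 1000L,
                                            position = NA_integer_),
                    seed = 75)
  sim <- simulate_xy_pair(cfg)
  expect_gt(nrow(sim$truth$events), 0)
  el <- sim$truth$elements
  # even under heavy indels the LTR copies keep their full length
  expect_equal(el$left_ltr_end - el$left_ltr_start + 1L, 300L)
  expect_equal(el$right_ltr_end - el$right_ltr_start + 1L, 300L)
  expect_lte(el$end, nchar(sim$seq_y))
})

test_that("scheduled insertion times outside the post-split window are rejected", {
  expect_error(sim_config(
    t_stop = 1e6,
    insertions = data.frame(lineage = "X", time = 2e6, ltr_length = 100L,
                            internal_length = 100L,
                            position = NA_integer_)),
    "post-split")
})

test_that("simulation outputs round-trip to FASTA, GFF3 and JSON", {
  cfg <- sim_config(ancestral_length = 3000L,
                    insertions = data.frame(lineage = "X", time = 1e6,
                                            ltr_length = 200L,
                                            internal_length = 400L,
                                            position = NA_integer_),
                    seed = 76)
  sim <- simulate_xy_pair(cfg)
  dir <- tempfile()
  paths <- write_sim_truth(sim, dir)
  expect_true(all(file.exists(paths)))
  fa <- read_fasta(paths["fasta"])
  expect_identical(as.character(fa[["X"]]), sim$seq_x)
  expect_identical(as.character(fa[["Y"]]), sim$seq_y)
  feats <- read_features_gff3(paths["gff3"])
  expect_equal(sum(feats$kind == "element"), 1)
  expect_equal(sum(feats$kind == "ltr"), 2)
  truth_el <- sim$truth$elements
  got <- feats[feats$kind == "element", ]
  expect_equal(got$start, truth_el$start)
  expect_equal(got$end, truth_el$end)
  js <- jsonlite::read_json(paths["events"])
  expect_equal(js$seed, 76)
})

test_that("coding-pair simulation honours omega and T = 0, deterministically", {
  p0 <- simulate_coding_pair(60, t_stop = 0, seed = 1)
  expect_identical(p0$cds_x, p0$cds_y)
  p1 <- simulate_coding_pair(200, t_stop = 3.4e6, omega = 0, seed = 2)
  p2 <- simulate_coding_pair(200, t_stop = 3.4e6, omega = 0, seed = 2)
  expect_identical(p1, p2)
  d <- syn_nonsyn_distance(p1$cds_x, p1$cds_y, se = "none")
  expect_equal(d$dN$k, 0) # omega = 0: no nonsynonymous change, ever
  expect_gt(d$dS$k, 0)
  # no stop codons anywhere
  for (s in c(p1$cds_x, p1$cds_y)) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(Biostrings::GENETIC_CODE[codons] == "*"))
  }
})
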