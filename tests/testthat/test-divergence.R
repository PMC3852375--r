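test_that("TN93 distance is zero for identical sequences and inflates p-distance", {
  set.seed(31)
  s <- rand_seq(500)
  d <- tn93_distance(aligned_pair(s, s))
  expect_equal(d$k, 0)
  expect_equal(d$se, 0)
  expect_equal(d$n_sites, 500)
  for (i in 1:5) {
    a <- rand_seq(1000)
    b <- mutate_seq(a, 0.1)
    pd <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    k <- tn93_distance(aligned_pair(a, b), se = "none")$k
    expect_gte(k, pd)
  }
})

test_that("TN93 reduces to the K80 closed form at uniform base frequencies", {
  # worked example: P1 = P2 = 0.05, Q = 0.04 on 200 uniform columns
  # (equal transition classes, so the two models coincide)
  pr <- uniform_freq_pair(200, n_p1 = 10, n_p2 = 10, n_q = 8)
  k <- tn93_distance(aligned_pair(pr$a, pr$b), se = "none")$k
  expect_equal(k, k80_distance(P = 0.10, Q = 0.04), tolerance = 1e-12)
  expect_equal(k, 0.1581, tolerance = 1e-3)
  # property: any balanced pair with P1 = P2 stays on the K80 closed form
  set.seed(32)
  for (i in 1:10) {
    np <- 2 * sample(0:8, 1)
    nq <- 2 * sample(1:8, 1)
    pr <- uniform_freq_pair(200, np, np, nq)
    k <- tn93_distance(aligned_pair(pr$a, pr$b), se = "none")$k
    expect_equal(k, k80_distance(2 * np / 200, nq / 200),
                 tolerance = 1e-10)
  }
  # with unequal transition classes TN93 separates the two log terms
  pr2 <- uniform_freq_pair(200, 4, 16, 8)
  k2 <- tn93_distance(aligned_pair(pr2$a, pr2$b), se = "none")$k
  expect_false(isTRUE(all.equal(k2, k80_distance(0.10, 0.04),
                                tolerance = 1e-6)))
  expect_equal(k2,
               -0.25 * log(1 - 4 * 0.02 - 0.04) -
                 0.25 * log(1 - 4 * 0.08 - 0.04) -
                 0.25 * log(1 - 2 * 0.04),
               tolerance = 1e-12)
})

test_that("TN93 agrees with an independent implementation on mutated pairs", {
  skip_if_not_installed("ape")
  set.seed(33)
  for (i in 1:5) {
    a <- rand_seq(2000, freqs = c(0.35, 0.15, 0.2, 0.3))
    b <- mutate_seq(a, runif(1, 0.02, 0.15))
    mine <- tn93_distance(aligned_pair(a, b), se = "none")$k
    m <- matrix(c(strsplit(tolower(a), "")[[1]],
                  strsplit(tolower(b), "")[[1]]), nrow = 2, byrow = TRUE)
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "TN93"))
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("TN93 errors on saturation and on empty column sets", {
  # all purine sites transitioned, all pyrimidine sites transitioned:
  # every log argument is non-positive
  a <- strrep("ACGT", 50)
  b <- strrep("GTAC", 50)
  expect_error(tn93_distance(aligned_pair(a, b)), "saturated")
  expect_error(tn93_distance(aligned_pair("N-", "NA")), "zero sites")
  # pairwise deletion removed gap/N columns
  p <- aligned_pair("ACGTN-A", "ACGT-CA")
  expect_equal(p$n_sites, 5)
})

test_that("Nei-Gojobori distances reproduce the hand-counted example", {
  # codons AAA AAA GGG vs AAA AAG GGG: one synonymous Lys->Lys change;
  # S_bar = 5/3, Sd = 1, pS = 0.6, dS = -(3/4) log(0.2)
  d <- syn_nonsyn_distance("AAAAAAGGG", "AAAAAGGGG", se = "none")
  expect_equal(d$dS$k, -0.75 * log(1 - 4 * 0.6 / 3), tolerance = 1e-12)
  expect_equal(d$dS$k, 1.2071, tolerance = 1e-4)
  expect_equal(d$dN$k, 0)
  # symmetry
  d2 <- syn_nonsyn_distance("AAAAAGGGG", "AAAAAAGGG", se = "none")
  expect_equal(d2$dS$k, d$dS$k)
  expect_equal(d2$dN$k, d$dN$k)
})

test_that("Nei-Gojobori handles identical input, stops, and saturation", {
  cds <- strrep("TTT", 50)
  d <- syn_nonsyn_distance(cds, cds, se = "none")
  expect_equal(d$dS$k, 0)
  expect_equal(d$dN$k, 0)
  expect_equal(d$dS$n_sites, 150)
  expect_error(syn_nonsyn_distance("AAATAAGGG", "AAATAAGGG"),
               "stop codon.*codon 2")
  expect_error(syn_nonsyn_distance("AAAA", "AAAA"), "multiple of 3")
  # every codon synonymous-different: pS = 1 >= 3/4
  expect_error(syn_nonsyn_distance(strrep("GGG", 50), strrep("GGA", 50)),
               "correction undefined")
})

test_that("bootstrap SEs are deterministic under a seed and zero at zero divergence", {
  set.seed(34)
  a <- rand_seq(800)
  b <- mutate_seq(a, 0.08)
  d1 <- tn93_distance(aligned_pair(a, b), reps = 200, seed = 99)
  d2 <- tn93_distance(aligned_pair(a, b), reps = 200, seed = 99)
  expect_identical(d1$se, d2$se)
  expect_gt(d1$se, 0)
  d3 <- tn93_distance(aligned_pair(a, b), reps = 200, seed = 100)
  expect_false(identical(d1$se, d3$se))
  expect_equal(tn93_distance(aligned_pair(a, a), reps = 200, seed = 1)$se, 0)
  expect_error(bootstrap_se(aligned_pair(a, b), function(p) 1, reps = 10),
               "reps")
})

test_that("bootstrap SE agrees with the analytic Jukes-Cantor SE", {
  # JC estimator on a pair: d = -(3/4) log(1 - 4p/3); analytic SE
  # sqrt(p(1-p)/n) / (1 - 4p/3)
  jc_est <- function(pair) {
    p <- mean(pair$a != pair$b)
    -0.75 * log(1 - 4 * p / 3)
  }
  set.seed(35)
  n <- 1000L
  ses <- replicate(60, {
    a <- rand_seq(n)
    b <- mutate_seq(a, 0.1) # every mutated site differs: observed p near 0.1
    bootstrap_se(aligned_pair(a, b), jc_est, reps = 100, seed = 7)
  })
  p0 <- 0.1
  analytic <- sqrt(p0 * (1 - p0) / n) / (1 - 4 * p0 / 3)
  expect_equal(mean(ses), analytic, tolerance = 0.15)
})
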