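# Independent oracles and small generators used across the test files.

# Random nucleotide sequence.
rand_seq <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# Point-mutate a sequence: each site replaced with probability `rate`
# by a uniformly random different base.
mutate_seq <- function(s, rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  paste(v, collapse = "")
}

# Brute-force global alignment score by exhaustive enumeration of all
# monotone alignments (feasible for lengths <= 6). Gap runs cost
# gap_open + (L - 1) * gap_extend; with free ends the first and last
# runs, if they are gap runs, cost nothing.
brute_align_score <- function(a, b, sc) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- -Inf
  rec <- function(i, j, moves) {
    if (i > length(ca) && j > length(cb)) {
      runs <- rle(moves)
      ii <- 1L; jj <- 1L; sco <- 0
      for (k in seq_along(runs$values)) {
        v <- runs$values[k]; L <- runs$lengths[k]
        if (v == "D") {
          for (t in seq_len(L)) {
            sco <- sco + if (ca[ii] == cb[jj]) sc$match else sc$mismatch
            ii <- ii + 1L; jj <- jj + 1L
          }
        } else {
          terminal <- sc$end_gaps_free &&
            (k == 1L || k == length(runs$values))
          if (!terminal) sco <- sco - (sc$gap_open + (L - 1) * sc$gap_extend)
          if (v == "U") ii <- ii + L else jj <- jj + L
        }
      }
      best <<- max(best, sco)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) rec(i + 1L, j + 1L, c(moves, "D"))
    if (i <= length(ca)) rec(i + 1L, j, c(moves, "U"))
    if (j <= length(cb)) rec(i, j + 1L, c(moves, "L"))
  }
  rec(1L, 1L, character(0))
  best
}

# Per-base marking oracle for the union length of 1-based intervals.
brute_union_length <- function(starts, ends) {
  marked <- logical(max(ends))
  for (k in seq_along(starts)) marked[starts[k]:ends[k]] <- TRUE
  sum(marked)
}

# Kimura two-parameter closed form from transition/transversion
# proportions (TN93 reduces to this at uniform base frequencies).
k80_distance <- function(P, Q) {
  0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
}

# Build an aligned pair with exactly uniform pooled base frequencies and
# the given numbers of purine transitions, pyrimidine transitions and
# transversions, out of `n` columns (n divisible by 4; changes applied
# in reciprocal pairs so pooled frequencies stay uniform).
uniform_freq_pair <- function(n, n_p1, n_p2, n_q) {
  stopifnot(n %% 4 == 0, n_p1 %% 2 == 0, n_p2 %% 2 == 0, n_q %% 2 == 0,
            n_p1 + n_p2 + n_q <= n)
  a <- rep(c("A", "C", "G", "T"), n / 4)
  b <- a
  ai <- which(a == "A"); gi <- which(a == "G")
  ci <- which(a == "C"); ti <- which(a == "T")
  # reciprocal transitions: A->G at one site, G->A at another
  if (n_p1 > 0) {
    b[ai[seq_len(n_p1 / 2)]] <- "G"
    b[gi[seq_len(n_p1 / 2)]] <- "A"
  }
  if (n_p2 > 0) {
    b[ci[seq_len(n_p2 / 2)]] <- "T"
    b[ti[seq_len(n_p2 / 2)]] <- "C"
  }
  if (n_q > 0) { # reciprocal transversions: A->C and C->A
    used_a <- n_p1 / 2
    used_c <- n_p2 / 2
    b[ai[used_a + seq_len(n_q / 2)]] <- "C"
    b[ci[used_c + seq_len(n_q / 2)]] <- "A"
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

extdata <- function(name) {
  system.file("extdata", name, package = "strataclock", mustWork = TRUE)
}

read_fixture <- function(name) {
  utils::read.table(extdata(name), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
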