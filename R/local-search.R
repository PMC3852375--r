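#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' Solves for the scale parameter `lambda` of local-alignment score
#' statistics (the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1`, found by bisection to 1e-9)
#' and computes the constant `K` by the standard ungapped series
#' approximation for integer-lattice scores
#' (`K = delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))`,
#' where `sigma` is the Karlin-Altschul partial-sum series, `H` the
#' relative entropy per aligned pair and `delta` the greatest common
#' divisor of the score values). For the classic schemes this reproduces
#' the ungapped constants reported by BLASTN (e.g. +2/-3: lambda 0.634,
#' K 0.41). `K` may instead be supplied as a configured constant.
#'
#' @param scoring A [scoring_scheme()] with integer match/mismatch scores.
#' @param freqs Background base frequencies (A, C, G, T), summing to 1.
#' @param K Optional fixed value for `K` (skips the series).
#' @return List with `lambda`, `K`, and `H` (relative entropy, nats).
#' @examples
#' solve_karlin_altschul(scoring_scheme(match = 1, mismatch = -1))$lambda
#' # log(3)
#' @export
solve_karlin_altschul <- function(scoring, freqs = rep(0.25, 4), K = NULL) {
  stopifnot(abs(sum(freqs) - 1) < 1e-9, all(freqs >= 0))
  p_match <- sum(freqs^2)
  scores <- c(scoring$match, scoring$mismatch)
  probs <- c(p_match, 1 - p_match)
  esc <- sum(probs * scores)
  if (esc >= 0) stop("invalid for local statistics: expected score >= 0")
  if (max(scores) <= 0) stop("no positive score attainable")
  f <- function(l) sum(probs * exp(l * scores)) - 1
  # bracket the positive root, then bisect to 1e-9
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 1e-12
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2
  H <- lambda * sum(probs * scores * exp(lambda * scores))
  if (is.null(K)) {
    if (any(scores != round(scores)))
      stop("series approximation for K requires integer scores")
    K <- ka_K_series(as.integer(round(scores)), probs, lambda, H)
  }
  list(lambda = lambda, K = K, H = H)
}

# Series approximation for K on the integer lattice:
# sigma = sum_k (1/k) [ P(S_k >= 0) + E(exp(lambda S_k); S_k < 0) ]
# with S_k the k-step random walk of pair scores.
ka_K_series <- function(scores, probs, lambda, H, max_iter = 120L,
                        tol = 1e-10) {
  delta <- abs(scores[1])
  for (s in scores[-1]) {
    a <- delta; b <- abs(s)
    while (b > 0) { t <- a %% b; a <- b; b <- t }
    delta <- a
  }
  dist <- c(`0` = 1)
  sigma <- 0
  for (k in seq_len(max_iter)) {
    vals <- as.integer(names(dist))
    nv <- c(outer(vals, scores, `+`))
    np <- c(outer(as.numeric(dist), probs))
    dist <- tapply(np, nv, sum)
    v <- as.integer(names(dist))
    term <- sum(dist[v >= 0]) + sum(dist[v < 0] * exp(lambda * v[v < 0]))
    sigma <- sigma + term / k
    if (term / k < tol) break
  }
  delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
}

#' Seed-and-extend local similarity search
#'
#' Finds high-scoring segment pairs (HSPs) between two sequences on both
#' strands, in the manner of an ungapped BLASTN search: exact-match seed
#' words of `word_size` bp, ungapped X-drop extension in both directions,
#' and Karlin-Altschul E-values `E = K * m * n * exp(-lambda * S)` with
#' `m`, `n` the sequence lengths. With `self = TRUE` (comparison of a
#' sequence against itself) the trivial self-diagonal is masked and each
#' unordered off-diagonal pair is reported once.
#'
#' @param query,subject Sequences.
#' @param scoring Ungapped match/mismatch scores; defaults to
#'   [local_scoring()] (+2/-3). The expected pairwise score must be
#'   negative.
#' @param max_evalue Keep hits with `E <= max_evalue`.
#' @param word_size Exact-match seed length (default 11).
#' @param xdrop Terminate extension when the running score drops this far
#'   below the running maximum (default 20).
#' @param self Self-comparison mode (mask the self-diagonal, deduplicate
#'   symmetric hits).
#' @param freqs Background base frequencies for the E-value statistics.
#' @return Data frame of hits sorted by score (ties by query then subject
#'   start): `q_start`, `q_end`, `s_start`, `s_end` (normalized,
#'   `s_start <= s_end`), `orientation`, `length`, `score`, `identity`,
#'   `evalue`.
#' @export
local_search <- function(query, subject, scoring = local_scoring(),
                         max_evalue = 10, word_size = 11L, xdrop = 20,
                         self = FALSE, freqs = rep(0.25, 4)) {
  q <- as_seq_chr(query, "query")
  s <- as_seq_chr(subject, "subject")
  ka <- solve_karlin_altschul(scoring, freqs) # errors if scheme invalid
  m <- nchar(q); n <- nchar(s)
  if (m < word_size || n < word_size) {
    return(empty_hits())
  }
  vq <- seq_to_code(q)
  hits_f <- strand_hits(vq, seq_to_code(s), scoring, word_size, xdrop,
                        self_diag = self)
  vs_rc <- seq_to_code(revcomp(s))
  hits_r <- strand_hits(vq, vs_rc, scoring, word_size, xdrop,
                        self_diag = FALSE)
  if (nrow(hits_r) > 0L) {
    # map reverse-strand subject coordinates back to the forward strand
    tmp_start <- n - hits_r$s_end + 1L
    hits_r$s_end <- n - hits_r$s_start + 1L
    hits_r$s_start <- tmp_start
    hits_r$orientation <- "inverted"
  }
  hits <- rbind(hits_f, hits_r)
  if (self) hits <- dedupe_self_hits(hits)
  if (nrow(hits) == 0L) return(empty_hits())
  hits$evalue <- ka$K * as.numeric(m) * as.numeric(n) *
    exp(-ka$lambda * hits$score)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$q_start, hits$s_start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             orientation = character(0), length = integer(0),
             score = numeric(0), identity = numeric(0),
             evalue = numeric(0))
}

# Ungapped HSPs between two coded sequences on one strand.
strand_hits <- function(vq, vs, scoring, w, xdrop, self_diag = FALSE) {
  nq <- length(vq); ns <- length(vs)
  seeds <- seed_matches(vq, vs, w)
  if (self_diag) seeds <- seeds[seeds$i != seeds$j, , drop = FALSE]
  if (nrow(seeds) == 0L) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      orientation = character(0), length = integer(0),
                      score = numeric(0), identity = numeric(0)))
  }
  seeds <- seeds[order(seeds$i - seeds$j, seeds$i), , drop = FALSE]
  ms <- scoring$match; mm <- scoring$mismatch
  covered <- new.env(parent = emptyenv()) # per-diagonal covered q-intervals
  out <- vector("list", 64L); n_out <- 0L
  for (r in seq_len(nrow(seeds))) {
    i <- seeds$i[r]; j <- seeds$j[r]
    dkey <- as.character(i - j)
    ivs <- get0(dkey, envir = covered, ifnotfound = NULL)
    if (!is.null(ivs) && any(i >= ivs[, 1L] & i <= ivs[, 2L])) next
    left <- xdrop_extend(vq, vs, i - 1L, j - 1L, -1L, ms, mm, xdrop)
    right <- xdrop_extend(vq, vs, i + w, j + w, +1L, ms, mm, xdrop)
    qs <- i - left$len; qe <- i + w - 1L + right$len
    score <- w * ms + left$score + right$score
    matches <- w + left$matches + right$matches
    len <- qe - qs + 1L
    hit <- data.frame(q_start = qs, q_end = qe,
                      s_start = j - left$len, s_end = j + w - 1L + right$len,
                      orientation = "direct", length = len,
                      score = score, identity = matches / len)
    n_out <- n_out + 1L
    if (n_out > length(out)) out <- c(out, vector("list", length(out)))
    out[[n_out]] <- hit
    assign(dkey, rbind(ivs, c(qs, qe)), envir = covered)
  }
  do.call(rbind, out[seq_len(n_out)])
}

# All exact word matches between two coded sequences: data.frame(i, j).
seed_matches <- function(vq, vs, w) {
  kq <- kmer_keys(vq, w); ks <- kmer_keys(vs, w)
  u <- unique(c(kq$key, ks$key))
  qid <- match(kq$key, u); sid <- match(ks$key, u)
  dq <- data.frame(id = qid, i = kq$pos)
  ds <- data.frame(id = sid, j = ks$pos)
  merge(dq, ds, by = "id")[, c("i", "j")]
}

# Word keys for all windows without N; returns positions and string keys.
kmer_keys <- function(v, w) {
  n <- length(v)
  if (n < w) return(list(pos = integer(0), key = character(0)))
  s <- code_to_seq(v)
  pos <- seq_len(n - w + 1L)
  key <- substring(s, pos, pos + w - 1L)
  keep <- !grepl("N", key, fixed = TRUE)
  list(pos = pos[keep], key = key[keep])
}

# Chunked ungapped X-drop extension from (i0, j0) in direction `step`.
xdrop_extend <- function(vq, vs, i0, j0, step, ms, mm, xdrop,
                         chunk = 2048L) {
  nq <- length(vq); ns <- length(vs)
  best <- 0; best_len <- 0L; best_matches <- 0L
  cum <- 0; cum_matches <- 0L; off <- 0L
  repeat {
    if (step > 0L) {
      avail <- min(nq - (i0 + off) + 1L, ns - (j0 + off) + 1L)
    } else {
      avail <- min(i0 - off, j0 - off)
    }
    L <- min(chunk, avail)
    if (L <= 0L) break
    iq <- i0 + step * (off + 0L:(L - 1L))
    is <- j0 + step * (off + 0L:(L - 1L))
    eq <- vq[iq] == vs[is] & vq[iq] != 5L
    sc <- ifelse(eq, ms, mm)
    cs <- cum + cumsum(sc)
    run_best <- cummax(c(best, cs))[-1L]
    stop_at <- which(cs < run_best - xdrop)
    lim <- if (length(stop_at)) stop_at[1L] else L
    pre <- cs[seq_len(lim)]
    k <- which.max(pre)
    if (pre[k] > best) {
      best <- pre[k]
      best_len <- off + k
      best_matches <- cum_matches + sum(eq[seq_len(k)])
    }
    if (length(stop_at) || L == avail) break
    cum <- cs[L]
    cum_matches <- cum_matches + sum(eq)
    off <- off + L
  }
  list(len = best_len, score = best, matches = best_matches)
}

# Keep one representative of each unordered self-hit pair.
dedupe_self_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  a <- pmin(hits$q_start, hits$s_start)
  b <- pmax(hits$q_start, hits$s_start)
  a2 <- pmin(hits$q_end, hits$s_end)
  b2 <- pmax(hits$q_end, hits$s_end)
  key <- paste(a, pmax(a2, b2), b, hits$orientation, hits$score)
  keep <- !duplicated(key)
  # canonical representative: query interval is the leftmost of the pair
  hits <- hits[keep, , drop = FALSE]
  swap <- hits$q_start > hits$s_start
  if (any(swap)) {
    qs <- hits$q_start[swap]; qe <- hits$q_end[swap]
    hits$q_start[swap] <- hits$s_start[swap]
    hits$q_end[swap] <- hits$s_end[swap]
    hits$s_start[swap] <- qs; hits$s_end[swap] <- qe
  }
  hits
}
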