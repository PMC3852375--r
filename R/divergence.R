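#' Gap- and ambiguity-free site pairs from an alignment
#'
#' Applies pairwise deletion to a pairwise alignment: every column
#' containing a gap or an `N` in either sequence is dropped, leaving the
#' residue-pair columns on which pairwise distances are computed.
#'
#' @param a Either a `pairwise_alignment` (from [global_align()]) or a
#'   gapped/ungapped sequence string of the same length as `b`.
#' @param b Second gapped sequence (ignored when `a` is an alignment).
#' @return An `aligned_pair`: list with integer code vectors `a`, `b`
#'   (A=1, C=2, G=3, T=4) and `n_sites`.
#' @export
aligned_pair <- function(a, b = NULL) {
  if (inherits(a, "pairwise_alignment")) {
    ga <- a$aligned_a; gb <- a$aligned_b
  } else {
    ga <- as_seq_chr_gapped(a); gb <- as_seq_chr_gapped(b)
  }
  if (nchar(ga) != nchar(gb)) stop("aligned sequences differ in length")
  va <- gapped_to_code(ga); vb <- gapped_to_code(gb)
  keep <- va <= 4L & vb <= 4L
  structure(list(a = va[keep], b = vb[keep], n_sites = sum(keep)),
            class = "aligned_pair")
}

as_seq_chr_gapped <- function(x) {
  x <- if (is.character(x)) toupper(x) else as_seq_chr(x)
  x
}

# codes: A=1 C=2 G=3 T=4, N=5, gap=6
gapped_to_code <- function(s) {
  map <- c(DNA_CODE, "-" = 6L, "." = 6L)
  v <- map[strsplit(s, "", fixed = TRUE)[[1L]]]
  if (anyNA(v)) stop(sprintf("invalid character at position %d",
                             which(is.na(v))[1L]))
  unname(v)
}

#' Tamura-Nei (1993) pairwise distance
#'
#' Closed-form TN93 distance between two aligned sequences, from the
#' proportions of purine transitions (`A<->G`), pyrimidine transitions
#' (`C<->T`) and transversions, with base frequencies pooled over both
#' sequences. The standard error is attached by column bootstrap
#' (see [bootstrap_se()]).
#'
#' With exactly uniform empirical base frequencies the estimate reduces
#' to the Kimura two-parameter distance.
#'
#' @param pair An [aligned_pair()] (or a `pairwise_alignment`, which is
#'   converted).
#' @param se `"bootstrap"` (default) or `"none"`.
#' @param reps Bootstrap replicates (>= 100).
#' @param seed RNG seed for the bootstrap (for exact reproducibility).
#' @return A `distance_estimate`: list with `k`, `se`, `method`,
#'   `n_sites`.
#' @export
tn93_distance <- function(pair, se = c("bootstrap", "none"), reps = 1000L,
                          seed = NULL) {
  se <- match.arg(se)
  pair <- as_aligned_pair(pair)
  if (pair$n_sites == 0L) stop("zero sites after pairwise deletion")
  k <- tn93_point(pair$a, pair$b)
  se_val <- 0
  if (se == "bootstrap" && k > 0) {
    se_val <- bootstrap_se(pair, function(p) tn93_point(p$a, p$b),
                           reps = reps, seed = seed)
  }
  distance_estimate(k, se_val, "tn93", pair$n_sites)
}

as_aligned_pair <- function(x) {
  if (inherits(x, "aligned_pair")) x else aligned_pair(x)
}

distance_estimate <- function(k, se, method, n_sites) {
  structure(list(k = unname(k), se = unname(se), method = method,
                 n_sites = n_sites),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf("%s distance: k = %.4g (SE %.2g), %d sites\n",
              x$method, x$k, x$se, x$n_sites))
  invisible(x)
}

# TN93 point estimate from coded site vectors (1..4).
tn93_point <- function(va, vb) {
  n <- length(va)
  counts <- table(factor(va, levels = 1:4), factor(vb, levels = 1:4))
  tn93_from_counts(counts / n)
}

# f: 4x4 matrix of site-pair relative frequencies (rows seq a, cols b).
# Order A, C, G, T.
tn93_from_counts <- function(f) {
  pi_ <- (rowSums(f) + colSums(f)) / 2
  piA <- pi_[1]; piC <- pi_[2]; piG <- pi_[3]; piT <- pi_[4]
  piR <- piA + piG; piY <- piC + piT
  P1 <- f[1, 3] + f[3, 1]              # A<->G
  P2 <- f[2, 4] + f[4, 2]              # C<->T
  Q <- sum(f) - sum(diag(f)) - P1 - P2 # transversions
  if (P1 + P2 + Q == 0) return(0)
  c1 <- 2 * piA * piG / piR
  c2 <- 2 * piT * piC / piY
  c3 <- 2 * (piR * piY - piA * piG * piY / piR - piT * piC * piR / piY)
  w1 <- if (c1 > 0) 1 - P1 / c1 - Q / (2 * piR) else 1
  w2 <- if (c2 > 0) 1 - P2 / c2 - Q / (2 * piY) else 1
  w3 <- 1 - Q / (2 * piR * piY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    stop("distance undefined (saturated)")
  unname(-c1 * log(w1) - c2 * log(w2) - c3 * log(w3))
}

#' Bootstrap standard error of a distance estimator
#'
#' Resamples alignment columns (or codon columns) with replacement and
#' returns the standard deviation of the replicate estimates. Replicates
#' on which the estimator is undefined (e.g. bootstrap saturation) are
#' excluded; more than 5% failed replicates is an error.
#'
#' @param pair An `aligned_pair` or `codon_pair` object.
#' @param estimator Function of a resampled pair returning a numeric
#'   point estimate.
#' @param reps Number of replicates (>= 100).
#' @param seed RNG seed; the same seed gives a bit-identical SE.
#' @return The bootstrap standard error (numeric scalar).
#' @export
bootstrap_se <- function(pair, estimator, reps = 1000L, seed = NULL) {
  stopifnot(reps >= 100L)
  point <- estimator(pair) # propagate errors on the point estimate
  n <- if (inherits(pair, "codon_pair")) ncol(pair$a) else length(pair$a)
  with_seed(seed, {
    vals <- numeric(reps)
    failed <- 0L
    for (r in seq_len(reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      rp <- resample_pair(pair, idx)
      v <- tryCatch(estimator(rp), error = function(e) NA_real_)
      if (is.na(v)) failed <- failed + 1L
      vals[r] <- v
    }
    if (failed > 0.05 * reps)
      stop(sprintf("bootstrap failed on %d/%d replicates", failed, reps))
    stats::sd(vals[!is.na(vals)])
  })
}

resample_pair <- function(pair, idx) {
  if (inherits(pair, "codon_pair")) {
    structure(list(a = pair$a[, idx, drop = FALSE],
                   b = pair$b[, idx, drop = FALSE]),
              class = "codon_pair")
  } else {
    structure(list(a = pair$a[idx], b = pair$b[idx], n_sites = length(idx)),
              class = "aligned_pair")
  }
}

## ---- Nei-Gojobori (1986) synonymous / nonsynonymous distances --------

#' Synonymous and nonsynonymous divergence (Nei-Gojobori 1986)
#'
#' Pathway-counting estimates of the synonymous (`dS`) and nonsynonymous
#' (`dN`) distances between two in-frame coding sequences: synonymous and
#' nonsynonymous sites are counted per codon with mutations to stop
#' codons excluded from the denominators, differences between codons are
#' averaged over all minimal-change pathways that avoid stop codons, and
#' the Jukes-Cantor correction `d = -(3/4) log(1 - 4p/3)` is applied.
#' Codon columns containing a gap or `N` are dropped (codon-wise pairwise
#' deletion). Standard nuclear genetic code.
#'
#' @param cds_a,cds_b In-frame coding sequences of equal length (multiple
#'   of 3), no internal stop codons.
#' @param se,reps,seed Bootstrap control as in [tn93_distance()]
#'   (resampling is over codon columns).
#' @return List with elements `dS` and `dN`, each a `distance_estimate`
#'   (`n_sites` is the number of compared nucleotide sites).
#' @examples
#' syn_nonsyn_distance("AAAAAAGGG", "AAAAAGGGG", se = "none")$dS$k
#' # -(3/4) * log(1 - 4 * 0.6 / 3)
#' @export
syn_nonsyn_distance <- function(cds_a, cds_b, se = c("bootstrap", "none"),
                                reps = 1000L, seed = NULL) {
  se <- match.arg(se)
  a <- as_seq_chr(cds_a, "cds_a"); b <- as_seq_chr(cds_b, "cds_b")
  if (nchar(a) != nchar(b)) stop("coding sequences differ in length")
  if (nchar(a) %% 3 != 0) stop("length not a multiple of 3")
  pair <- codon_pair(a, b)
  est <- ng86_estimates(pair)
  out <- list(
    dS = distance_estimate(est["dS"], 0, "syn_ng86", 3L * ncol(pair$a)),
    dN = distance_estimate(est["dN"], 0, "nonsyn_ng86", 3L * ncol(pair$a)))
  if (se == "bootstrap") {
    if (est["dS"] > 0)
      out$dS$se <- bootstrap_se(pair, function(p) ng86_estimates(p)["dS"],
                                reps = reps, seed = seed)
    if (est["dN"] > 0)
      out$dN$se <- bootstrap_se(pair, function(p) ng86_estimates(p)["dN"],
                                reps = reps, seed = seed)
  }
  out
}

# Codon columns (3 x L integer code matrices), codon-wise pairwise
# deletion; errors on internal stop codons (naming the codon index).
# A terminal stop codon is tolerated and dropped from the comparison.
codon_pair <- function(a, b) {
  tab <- codon_tables()
  va <- gapped_to_code(a); vb <- gapped_to_code(b)
  ma <- matrix(va, nrow = 3L); mb <- matrix(vb, nrow = 3L)
  n <- ncol(ma)
  clean <- colSums(ma <= 4L) == 3L & colSums(mb <= 4L) == 3L
  for (side in list(list(m = ma, lab = "cds_a"),
                    list(m = mb, lab = "cds_b"))) {
    idx <- which(clean)
    ids <- codon_ids(side$m[, idx, drop = FALSE])
    stops <- idx[tab$is_stop[ids]]
    internal <- stops[stops < n]
    if (length(internal))
      stop(sprintf("internal stop codon in %s at codon %d",
                   side$lab, internal[1L]))
    clean[stops] <- FALSE
  }
  structure(list(a = ma[, clean, drop = FALSE],
                 b = mb[, clean, drop = FALSE]),
            class = "codon_pair")
}

codon_ids <- function(m) {
  (m[1L, ] - 1L) * 16L + (m[2L, ] - 1L) * 4L + m[3L, ]
}

# NG86 point estimates (dS, dN) for a codon_pair.
ng86_estimates <- function(pair) {
  tab <- codon_tables()
  ia <- codon_ids(pair$a); ib <- codon_ids(pair$b)
  S_bar <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N_bar <- (sum(tab$nonsyn_sites[ia]) + sum(tab$nonsyn_sites[ib])) / 2
  idx <- (ib - 1L) * 64L + ia # column-major [ia, ib]
  Sd <- sum(tab$path_syn[idx])
  Nd <- sum(tab$path_nonsyn[idx])
  pS <- if (S_bar > 0) Sd / S_bar else 0
  pN <- if (N_bar > 0) Nd / N_bar else 0
  c(dS = jc_correct(pS), dN = jc_correct(pN))
}

jc_correct <- function(p) {
  if (p >= 0.75) stop("correction undefined (p >= 3/4)")
  if (p == 0) return(0)
  -0.75 * log(1 - 4 * p / 3)
}

## Codon lookup tables (computed once per session, standard code).
.codon_cache <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- character(64L)
  for (b1 in 1:4) for (b2 in 1:4) for (b3 in 1:4) {
    id <- (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
    codons[id] <- paste0(DNA_BASES[b1], DNA_BASES[b2], DNA_BASES[b3])
  }
  aa <- unname(gc_map[codons])
  is_stop <- aa == "*"
  syn_sites <- numeric(64L)
  for (id in 1:64) {
    if (is_stop[id]) { syn_sites[id] <- NA_real_; next }
    f <- 0
    for (pos in 1:3) {
      cur <- substr(codons[id], pos, pos)
      alts <- setdiff(DNA_BASES, cur)
      alt_codons <- vapply(alts, function(x) {
        z <- codons[id]; substr(z, pos, pos) <- x; z
      }, character(1))
      alt_aa <- gc_map[alt_codons]
      valid <- alt_aa != "*"
      if (any(valid)) f <- f + sum(alt_aa[valid] == aa[id]) / sum(valid)
    }
    syn_sites[id] <- f
  }
  nonsyn_sites <- 3 - syn_sites
  # pathway-averaged (syn, nonsyn) differences for every ordered codon pair
  path_syn <- matrix(0, 64, 64)
  path_nonsyn <- matrix(0, 64, 64)
  for (i in 1:64) {
    if (is_stop[i]) next
    for (j in 1:64) {
      if (is_stop[j] || i == j) next
      d <- codon_path_diffs(codons[i], codons[j], gc_map)
      path_syn[i, j] <- d[1L]
      path_nonsyn[i, j] <- d[2L]
    }
  }
  .codon_cache$tab <- list(codons = codons, aa = aa, is_stop = is_stop,
                           syn_sites = syn_sites,
                           nonsyn_sites = nonsyn_sites,
                           path_syn = path_syn, path_nonsyn = path_nonsyn)
  .codon_cache$tab
}

# Average (syn, nonsyn) step counts over all stop-free mutational
# pathways between two codons; if every pathway passes through a stop
# codon, fall back to averaging over all pathways.
codon_path_diffs <- function(c1, c2, gc_map) {
  diff_pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  perms <- permutations_of(diff_pos)
  tally <- function(allow_stop) {
    tot <- c(0, 0); nvalid <- 0L
    for (p in perms) {
      cur <- c1; sd <- 0L; nd <- 0L; ok <- TRUE
      for (pos in p) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (!allow_stop && gc_map[nxt] == "*") { ok <- FALSE; break }
        if (gc_map[nxt] == gc_map[cur]) sd <- sd + 1L else nd <- nd + 1L
        cur <- nxt
      }
      if (ok) { tot <- tot + c(sd, nd); nvalid <- nvalid + 1L }
    }
    if (nvalid > 0L) tot / nvalid else NULL
  }
  tally(FALSE) %||% tally(TRUE)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    rest <- permutations_of(x[-k])
    out <- c(out, lapply(rest, function(r) c(x[k], r)))
  }
  out
}
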