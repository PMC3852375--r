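#' Kosambi map function
#'
#' Converts a recombination fraction to a map distance in centimorgans
#' under the Kosambi mapping function,
#' `cM = 25 * log((1 + 2 rf) / (1 - 2 rf))`, which allows for partial
#' crossover interference. For small `rf` this approaches `100 * rf`.
#'
#' @param rf Recombination fraction(s), `0 <= rf < 0.5`.
#' @return Map distance(s) in cM.
#' @examples
#' kosambi_cm(0.25) # 25 * log(3)
#' @export
kosambi_cm <- function(rf) {
  if (any(is.na(rf)) || any(rf < 0) || any(rf >= 0.5))
    stop("unlinked (rf must be in [0, 0.5))")
  25 * log((1 + 2 * rf) / (1 - 2 * rf))
}

#' @rdname kosambi_cm
#' @param cm Map distance(s) in cM (the inverse function,
#'   `rf = tanh(cM / 50) / 2`).
#' @export
kosambi_rf <- function(cm) {
  stopifnot(all(cm >= 0))
  tanh(cm / 50) / 2
}

#' Two-point linkage map
#'
#' Orders testcross-coded markers (presence/absence of the
#' male-parent-specific allele in each progeny, coded 1/0/NA) by
#' exhaustive search over marker permutations, minimizing the summed
#' adjacent Kosambi distances. Pairwise recombination fractions are the
#' fraction of discordant calls among co-scored individuals (missing
#' data excluded pairwise).
#'
#' @param geno Marker-by-individual matrix (or data frame) of 1/0/NA
#'   calls with marker names as row names; at least 2 and at most 8
#'   markers.
#' @return List with `order` (marker names, canonicalized so the
#'   lexicographically smaller endpoint comes first), `adjacent_rf`,
#'   `adjacent_cm`, and the full `rf` matrix.
#' @export
two_point_map <- function(geno) {
  geno <- as.matrix(geno)
  m <- nrow(geno)
  if (m < 2L) stop("need at least 2 markers")
  if (m > 8L)
    stop("more than 8 markers: map overlapping subsets instead")
  if (is.null(rownames(geno))) rownames(geno) <- paste0("M", seq_len(m))
  rf <- matrix(0, m, m, dimnames = list(rownames(geno), rownames(geno)))
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    ok <- !is.na(geno[i, ]) & !is.na(geno[j, ])
    if (!any(ok))
      stop(sprintf("markers %s and %s share no scored individuals",
                   rownames(geno)[i], rownames(geno)[j]))
    rf[i, j] <- rf[j, i] <- mean(geno[i, ok] != geno[j, ok])
  }
  d <- suppressWarnings(
    ifelse(rf >= 0.5, Inf, 25 * log((1 + 2 * rf) / (1 - 2 * rf))))
  perms <- marker_permutations(m)
  tot <- vapply(perms, function(p) {
    sum(d[cbind(p[-m], p[-1L])])
  }, numeric(1))
  keys <- vapply(perms, function(p) {
    nm <- rownames(geno)[p]
    if (nm[1L] > nm[m]) nm <- rev(nm)
    paste(nm, collapse = "|")
  }, character(1))
  best <- order(tot, keys)[1L]
  p <- perms[[best]]
  nm <- rownames(geno)[p]
  if (nm[1L] > nm[m]) { p <- rev(p); nm <- rev(nm) }
  adj_rf <- rf[cbind(p[-m], p[-1L])]
  list(order = nm, adjacent_rf = adj_rf,
       adjacent_cm = ifelse(adj_rf >= 0.5, Inf,
                            25 * log((1 + 2 * adj_rf) / (1 - 2 * adj_rf))),
       rf = rf)
}

marker_permutations <- function(m) {
  perm_rec <- function(x) {
    if (length(x) <= 1L) return(list(x))
    out <- list()
    for (k in seq_along(x)) {
      for (r in perm_rec(x[-k])) out <- c(out, list(c(x[k], r)))
    }
    out
  }
  perm_rec(seq_len(m))
}

#' Read a genotype table
#'
#' Reads a TSV of testcross genotype calls: first column marker names,
#' remaining columns one per individual, entries `1`/`0`/`NA`.
#'
#' @param path Path to the TSV.
#' @return Marker-by-individual numeric matrix.
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_plain(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' Simulate a testcross genotype table
#'
#' Simulates presence/absence calls for markers at given map positions in
#' a testcross progeny, with crossovers between adjacent markers
#' occurring independently at the recombination fraction implied by the
#' Kosambi function (no interference beyond it).
#'
#' @param cm_positions Named numeric vector of marker positions in cM
#'   (names become marker names).
#' @param n Number of progeny.
#' @param missing_rate Probability an individual call is missing.
#' @param seed RNG seed.
#' @return Marker-by-individual matrix of 1/0/NA calls.
#' @export
simulate_testcross <- function(cm_positions, n = 96L, missing_rate = 0,
                               seed = NULL) {
  stopifnot(length(cm_positions) >= 2L)
  if (is.null(names(cm_positions)))
    names(cm_positions) <- paste0("M", seq_along(cm_positions))
  with_seed(seed, {
    m <- length(cm_positions)
    rfs <- kosambi_rf(diff(cm_positions))
    g <- matrix(NA_real_, m, n,
                dimnames = list(names(cm_positions), NULL))
    g[1L, ] <- stats::rbinom(n, 1L, 0.5)
    for (i in 2:m) {
      flip <- stats::rbinom(n, 1L, rfs[i - 1L])
      g[i, ] <- ifelse(flip == 1L, 1 - g[i - 1L, ], g[i - 1L, ])
    }
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(m * n) < missing_rate, m, n)
      g[drop] <- NA_real_
    }
    g
  })
}
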