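#' Scoring scheme for pairwise alignment
#'
#' Bundles substitution scores and affine gap penalties. A gap of length
#' `L` costs `gap_open + (L - 1) * gap_extend`; with `end_gaps_free = TRUE`
#' terminal gaps are not charged (ends-free, "overlap" alignment).
#'
#' The default (`match = 5`, `mismatch = -4`, `gap_open = 30`,
#' `gap_extend = 0`, free end gaps) reproduces an EMBOSS-Needle-style
#' configuration with an EDNAFULL-like match/mismatch matrix, a gap
#' penalty of 30 and an extension penalty of 0 — the setting used for
#' intron and LTR alignments throughout the package's reference workflow.
#' [local_scoring()] gives the classic +2/-3 local-search defaults.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score.
#' @param gap_open Gap opening penalty (>= 0, cost of a length-1 gap).
#' @param gap_extend Gap extension penalty (>= 0, per additional gapped
#'   position).
#' @param end_gaps_free Are terminal gaps free?
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap_open = 30,
                           gap_extend = 0, end_gaps_free = TRUE) {
  stopifnot(match > 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 end_gaps_free = isTRUE(end_gaps_free)),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
local_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2) {
  scoring_scheme(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, end_gaps_free = FALSE)
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment of two nucleotide sequences under a
#' [scoring_scheme()], with affine gaps (a gap of length `L` costs
#' `gap_open + (L - 1) * gap_extend`). With `end_gaps_free = TRUE` the
#' alignment still spans both sequences end to end but terminal gap runs
#' cost nothing (the EMBOSS-Needle "endweight off" convention). `N`
#' scores as a mismatch against everything. Traceback is deterministic:
#' diagonal is preferred over a gap in `b` ("up") over a gap in `a`
#' ("left") on score ties.
#'
#' @param a,b Sequences (character, `DNAString`, or single-record
#'   `DNAStringSet`).
#' @param scoring A [scoring_scheme()].
#' @return A `pairwise_alignment` object: list with `aligned_a`,
#'   `aligned_b` (gapped strings), `score`, `columns`, `match_columns`,
#'   `gap_columns`.
#' @examples
#' aln <- global_align("ACGTACGT", "ACGTCGT")
#' aln$score
#' alignment_identity(aln)
#' @export
global_align <- function(a, b, scoring = scoring_scheme()) {
  a <- as_seq_chr(a, "a"); b <- as_seq_chr(b, "b")
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  va <- seq_to_code(a); vb <- seq_to_code(b)
  na <- length(va); nb <- length(vb)
  if ((na + 1) * (nb + 1) > 3e7)
    stop("sequences too long for full global alignment")
  dp <- needle_dp(va, vb, scoring)
  tb <- needle_traceback(dp, va, vb, scoring)
  ca <- c("A", "C", "G", "T", "N", "-")
  alignment_from_strings(paste(ca[tb$a], collapse = ""),
                         paste(ca[tb$b], collapse = ""),
                         score = dp$score)
}

# Affine-gap DP, vectorized per row. States: M (diagonal), Ix (gap in b,
# consumes a), Iy (gap in a, consumes b). Iy within a row is computed
# with a running-maximum formulation, which also covers gap-state
# switches (adjacent gap runs in opposite sequences each pay gap_open).
needle_dp <- function(va, vb, scoring) {
  na <- length(va); nb <- length(vb)
  ms <- scoring$match; mm <- scoring$mismatch
  open <- scoring$gap_open; ext <- scoring$gap_extend
  free <- scoring$end_gaps_free
  NEG <- -1e15
  M <- matrix(NEG, na + 1, nb + 1)
  Ix <- matrix(NEG, na + 1, nb + 1)
  Iy <- matrix(NEG, na + 1, nb + 1)
  M[1, 1] <- 0
  i <- seq_len(na); j <- seq_len(nb)
  Ix[i + 1, 1] <- if (free) 0 else -(open + (i - 1) * ext)
  Iy[1, j + 1] <- if (free) 0 else -(open + (j - 1) * ext)
  kext <- (0:nb) * ext
  for (ii in i) {
    prevM <- M[ii, ]; prevIx <- Ix[ii, ]; prevIy <- Iy[ii, ]
    sub <- ifelse(vb == va[ii] & va[ii] != 5L, ms, mm)
    Mrow <- c(NEG, pmax(prevM, prevIx, prevIy)[j] + sub)
    Ixrow <- c(Ix[ii + 1, 1],
               pmax(pmax(prevM, prevIy)[j + 1] - open,
                    prevIx[j + 1] - ext))
    base <- pmax(Mrow, Ixrow) + kext
    cm <- cummax(base)
    Iyrow <- c(Iy[ii + 1, 1], cm[j] - open - (j - 1) * ext)
    M[ii + 1, ] <- Mrow
    Ix[ii + 1, ] <- Ixrow
    Iy[ii + 1, ] <- pmax(Iy[ii + 1, ], Iyrow)
  }
  best <- pmax(M, Ix, Iy)
  if (free) {
    lr <- best[na + 1, ]; lc <- best[, nb + 1]
    score <- max(lr, lc)
    # deterministic end cell: prefer the bottom-right-most maximum
    wr <- which(lr >= score - 1e-9)
    wc <- which(lc >= score - 1e-9)
    cand <- rbind(
      matrix(c(rep(na + 1L, length(wr)), wr), ncol = 2),
      matrix(c(wc, rep(nb + 1L, length(wc))), ncol = 2))
    pick <- order(-(cand[, 1] + cand[, 2]), -cand[, 1])[1]
    end <- cand[pick, ]
  } else {
    score <- best[na + 1, nb + 1]
    end <- c(na + 1, nb + 1)
  }
  list(M = M, Ix = Ix, Iy = Iy, score = score, end = end, free = free)
}

needle_traceback <- function(dp, va, vb, scoring) {
  ms <- scoring$match; mm <- scoring$mismatch
  open <- scoring$gap_open; ext <- scoring$gap_extend
  na <- length(va); nb <- length(vb)
  i <- dp$end[1]; j <- dp$end[2]
  out_a <- integer(0); out_b <- integer(0)
  # free trailing gaps beyond the chosen end cell
  if (i <= na) { out_a <- va[na:i]; out_b <- rep(6L, na - i + 1L) }
  if (j <= nb) { out_a <- rep(6L, nb - j + 1L); out_b <- vb[nb:j] }
  eps <- 1e-6
  state <- {
    v <- c(dp$M[i, j], dp$Ix[i, j], dp$Iy[i, j])
    c("M", "Ix", "Iy")[which(v >= max(v) - eps)[1L]]
  }
  while (i > 1L || j > 1L) {
    if (i == 1L) { # leading gap in a
      out_a <- c(out_a, rep(6L, j - 1L)); out_b <- c(out_b, vb[(j - 1L):1L])
      break
    }
    if (j == 1L) { # leading gap in b
      out_a <- c(out_a, va[(i - 1L):1L]); out_b <- c(out_b, rep(6L, i - 1L))
      break
    }
    if (state == "M") {
      sub <- if (va[i - 1L] == vb[j - 1L] && va[i - 1L] != 5L) ms else mm
      target <- dp$M[i, j] - sub
      prev <- c(dp$M[i - 1L, j - 1L], dp$Ix[i - 1L, j - 1L],
                dp$Iy[i - 1L, j - 1L])
      out_a <- c(out_a, va[i - 1L]); out_b <- c(out_b, vb[j - 1L])
      i <- i - 1L; j <- j - 1L
      state <- c("M", "Ix", "Iy")[which(abs(prev - target) <= eps)[1L]]
    } else if (state == "Ix") {
      val <- dp$Ix[i, j]
      prev <- c(dp$M[i - 1L, j] - open, dp$Ix[i - 1L, j] - ext,
                dp$Iy[i - 1L, j] - open)
      out_a <- c(out_a, va[i - 1L]); out_b <- c(out_b, 6L)
      i <- i - 1L
      state <- c("M", "Ix", "Iy")[which(abs(prev - val) <= eps)[1L]]
    } else {
      val <- dp$Iy[i, j]
      prev <- c(dp$M[i, j - 1L] - open, dp$Ix[i, j - 1L] - open,
                dp$Iy[i, j - 1L] - ext)
      out_a <- c(out_a, 6L); out_b <- c(out_b, vb[j - 1L])
      j <- j - 1L
      state <- c("M", "Ix", "Iy")[which(abs(prev - val) <= eps)[1L]]
    }
  }
  list(a = rev(out_a), b = rev(out_b))
}

# Build the alignment summary object from two gapped strings.
alignment_from_strings <- function(ga, gb, score = NA_real_) {
  ca <- strsplit(ga, "", fixed = TRUE)[[1L]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  gap <- ca == "-" | cb == "-"
  if (any(ca == "-" & cb == "-")) stop("column gapped in both sequences")
  structure(list(aligned_a = ga, aligned_b = gb, score = unname(score),
                 columns = length(ca),
                 match_columns = sum(!gap & ca == cb & ca != "N"),
                 gap_columns = sum(gap)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: %d columns, score %.1f, identity %.1f%% (excl. gaps)\n",
              x$columns, x$score, 100 * alignment_identity(x)))
  invisible(x)
}

#' Alignment identity
#'
#' Fraction of identical columns, by default excluding gapped columns
#' from the denominator (the convention used when reporting intron
#' similarities "excluding gaps"). Returns 0 when the denominator is 0.
#'
#' @param aln A `pairwise_alignment`.
#' @param exclude_gaps If `TRUE` (default), identity is
#'   `match_columns / (columns - gap_columns)`; otherwise
#'   `match_columns / columns`.
#' @return A fraction in `[0, 1]`.
#' @export
alignment_identity <- function(aln, exclude_gaps = TRUE) {
  den <- if (exclude_gaps) aln$columns - aln$gap_columns else aln$columns
  if (den == 0L) return(0)
  aln$match_columns / den
}

#' Dot-plot comparison of two sequences
#'
#' Slides a window of `window` bp along both sequences and marks a dot at
#' `(i, j)` whenever the windows starting at `i` in `a` and `j` in `b`
#' match at `min_matches` or more positions. The defaults (window 10,
#' 8 matching positions) correspond to the classic HarrPlot-style
#' configuration used for intron comparisons. Forward strand only by
#' default.
#'
#' @param a,b Sequences.
#' @param window Window size in bp.
#' @param min_matches Minimum matching positions within a window
#'   (`0 < min_matches <= window`).
#' @param both_strands Also compare `a` against the reverse complement of
#'   `b` (those dots are returned with `orientation = "inverted"`, `j`
#'   giving the window start on the forward strand of `b`).
#' @return A data frame with columns `i`, `j` (1-based window starts) and
#'   `orientation`.
#' @export
dotplot <- function(a, b, window = 10L, min_matches = 8L,
                    both_strands = FALSE) {
  a <- as_seq_chr(a, "a"); b <- as_seq_chr(b, "b")
  stopifnot(min_matches > 0L, min_matches <= window)
  if (nchar(a) < window || nchar(b) < window)
    stop("window longer than a sequence")
  fwd <- dotplot_strand(a, b, window, min_matches)
  fwd$orientation <- rep("direct", nrow(fwd))
  out <- fwd
  if (both_strands) {
    rev <- dotplot_strand(a, revcomp(b), window, min_matches)
    # window start on the reverse strand -> forward-strand start
    rev$j <- nchar(b) - (rev$j + window - 1L) + 1L
    rev$orientation <- rep("inverted", nrow(rev))
    out <- rbind(fwd, rev)
  }
  out[order(out$i, out$j), , drop = FALSE]
}

dotplot_strand <- function(a, b, window, min_matches) {
  va <- seq_to_code(a); vb <- seq_to_code(b)
  na <- length(va); nb <- length(vb)
  res_i <- integer(0); res_j <- integer(0)
  for (d in (-(nb - 1L)):(na - 1L)) {
    # diagonal: positions i in a, j = i - d in b
    i0 <- max(1L, 1L + d); i1 <- min(na, nb + d)
    len <- i1 - i0 + 1L
    if (len < window) next
    ai <- va[i0:i1]; bi <- vb[(i0 - d):(i1 - d)]
    m <- as.integer(ai == bi & ai != 5L)
    cs <- c(0L, cumsum(m))
    wsum <- cs[(window + 1L):(len + 1L)] - cs[1L:(len - window + 1L)]
    hit <- which(wsum >= min_matches)
    if (length(hit)) {
      res_i <- c(res_i, i0 + hit - 1L)
      res_j <- c(res_j, i0 - d + hit - 1L)
    }
  }
  data.frame(i = res_i, j = res_j)
}

#' Plot a dot plot
#'
#' Base-graphics rendering of a [dotplot()] result.
#'
#' @param dots Data frame from [dotplot()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_dotplot <- function(dots, ...) {
  col <- ifelse(dots$orientation %||% "direct" == "inverted", "red", "black")
  graphics::plot(dots$i, dots$j, pch = ".", col = col,
                 xlab = "position in a (bp)", ylab = "position in b (bp)", ...)
  invisible(dots)
}
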