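#' Find repeats within a single sequence
#'
#' Self-comparison of a sequence by [local_search()] (self-diagonal
#' masked, each unordered pair reported once), with each repeat pair
#' classified as:
#' \describe{
#'   \item{`simple_repeat`}{the two intervals overlap, or the repeat unit
#'     has a detectable short period (<= 10 bp);}
#'   \item{`ltr_candidate`}{direct orientation, non-overlapping, ordered,
#'     and at least `min_ltr_len` bp long — the signature of the two
#'     long terminal repeats of an LTR retroelement;}
#'   \item{`other_repeat`}{anything else (e.g. inverted repeats).}
#' }
#'
#' @param seq The sequence.
#' @param max_evalue E-value threshold for self-hits (default 1e-10).
#' @param min_ltr_len Minimum repeat length for an LTR candidate (bp).
#' @param scoring,word_size,xdrop Passed to [local_search()].
#' @return Data frame of repeat pairs: `left_start`, `left_end`,
#'   `right_start`, `right_end`, `orientation`, `length`, `score`,
#'   `identity`, `evalue`, `class`, `period` (NA unless a short period
#'   was detected).
#' @export
find_self_repeats <- function(seq, max_evalue = 1e-10, min_ltr_len = 100L,
                              scoring = local_scoring(), word_size = 11L,
                              xdrop = 20) {
  s <- as_seq_chr(seq, "seq")
  if (nchar(s) < 2L * word_size) stop("sequence too short for self-search")
  hits <- local_search(s, s, scoring = scoring, max_evalue = max_evalue,
                       word_size = word_size, xdrop = xdrop, self = TRUE)
  if (nrow(hits) == 0L) return(empty_repeat_pairs())
  hits <- refine_direct_hits(s, hits, scoring)
  out <- data.frame(left_start = hits$q_start, left_end = hits$q_end,
                    right_start = hits$s_start, right_end = hits$s_end,
                    orientation = hits$orientation, length = hits$length,
                    score = hits$score, identity = hits$identity,
                    evalue = hits$evalue)
  overlap <- out$left_end >= out$right_start
  period <- vapply(seq_len(nrow(out)), function(r) {
    detect_period(substr(s, out$left_start[r], out$left_end[r]))
  }, numeric(1))
  out$period <- period
  out$class <- ifelse(
    overlap | !is.na(period), "simple_repeat",
    ifelse(out$orientation == "direct" & out$length >= min_ltr_len,
           "ltr_candidate", "other_repeat"))
  out[order(out$left_start, out$right_start), , drop = FALSE]
}

# Likelihood-ratio boundary refinement for ungapped direct self-hits.
# The score-maximum trim of the X-drop extension can over- or undershoot
# a repeat boundary by chance runs; re-trimming each end at the maximum
# of the cumulative log-likelihood ratio (match: log((1-p)/q), mismatch:
# log(p/(1-q)), with p the hit's divergence and q the background match
# probability) is the maximum-likelihood changepoint for the boundary.
refine_direct_hits <- function(s, hits, scoring = local_scoring(), slack = 30L) {
  v <- seq_to_code(s)
  n <- length(v)
  freqs <- tabulate(v[v <= 4L], 4L)
  q_bg <- sum((freqs / sum(freqs))^2)
  for (r in which(hits$orientation == "direct")) {
    d <- hits$s_start[r] - hits$q_start[r]
    if (d == 0L) next
    p_hat <- max(0.01, 1 - hits$identity[r])
    wm <- log((1 - p_hat) / q_bg)
    wx <- log(p_hat / (1 - q_bg))
    mid <- hits$q_start[r] + (hits$q_end[r] - hits$q_start[r]) %/% 2L
    # right boundary: walk from the hit midpoint rightwards
    hi <- min(hits$q_end[r] + slack, n - d, n)
    idx <- (mid + 1L):hi
    fl <- v[idx] == v[idx + d] & v[idx] != 5L & v[idx + d] != 5L
    cum <- cumsum(ifelse(fl, wm, wx))
    new_end <- if (max(cum) > 0) mid + which.max(cum) else mid
    # left boundary: walk leftwards
    lo <- max(hits$q_start[r] - slack, 1L, 1L - d)
    idx <- (mid - 1L):lo
    fl <- v[idx] == v[idx + d] & v[idx] != 5L & v[idx + d] != 5L
    cum <- cumsum(ifelse(fl, wm, wx))
    new_start <- if (max(cum) > 0) mid - which.max(cum) else mid
    seg <- new_start:new_end
    m <- sum(v[seg] == v[seg + d] & v[seg] != 5L)
    len <- length(seg)
    hits$q_start[r] <- new_start; hits$q_end[r] <- new_end
    hits$s_start[r] <- new_start + d; hits$s_end[r] <- new_end + d
    hits$length[r] <- len
    hits$identity[r] <- m / len
    hits$score[r] <- scoring$match * m + scoring$mismatch * (len - m)
  }
  hits
}

empty_repeat_pairs <- function() {
  data.frame(left_start = integer(0), left_end = integer(0),
             right_start = integer(0), right_end = integer(0),
             orientation = character(0), length = integer(0),
             score = numeric(0), identity = numeric(0),
             evalue = numeric(0), period = numeric(0),
             class = character(0))
}

#' Detect a short repeat period
#'
#' Autocorrelation periodicity scan: for each candidate period `p`
#' (1..`max_period`) the fraction of positions with `s[i] == s[i + p]` is
#' computed; the smallest period reaching `min_fraction` is returned,
#' or `NA` if none does.
#'
#' @param s Sequence string.
#' @param max_period Largest period to test (default 10).
#' @param min_fraction Agreement fraction required (default 0.8).
#' @return Integer period or `NA`.
#' @export
detect_period <- function(s, max_period = 10L, min_fraction = 0.8) {
  v <- seq_to_code(toupper(s))
  n <- length(v)
  for (p in seq_len(min(max_period, n - 1L))) {
    if (n - p < 2L * p) break # need at least two full units
    frac <- mean(v[seq_len(n - p)] == v[(p + 1L):n])
    if (frac >= min_fraction) return(p)
  }
  NA_real_
}

#' Call LTR-retroelement-like elements from direct-repeat pairs
#'
#' Turns classified `ltr_candidate` repeat pairs (from
#' [find_self_repeats()]) into elements spanning left-LTR start through
#' right-LTR end, applying structural constraints, resolving conflicting
#' overlapping pairings greedily (descending identity, then descending
#' LTR length), and computing nesting by containment of an element's span
#' within another element's internal region.
#'
#' @param pairs Repeat-pair data frame from [find_self_repeats()].
#' @param min_ltr_length Minimum LTR length (bp, default 100).
#' @param min_identity Minimum identity between the two LTR copies
#'   (default 0.85).
#' @param max_span Maximum element span (bp, default 30000).
#' @param length_ratio Allowed left/right LTR length ratio interval
#'   (default `c(0.8, 1.25)`).
#' @return Data frame of elements (`id`, `start`, `end`, `length`,
#'   `left_ltr_start/end`, `right_ltr_start/end`, `ltr_length`,
#'   `internal_start/end`, `identity`, `evalue`, `type_label`,
#'   `nested_in`), with rejected/conflicting candidates in
#'   `attr(, "unresolved")`.
#' @export
call_ltr_elements <- function(pairs, min_ltr_length = 100L,
                              min_identity = 0.85, max_span = 30000L,
                              length_ratio = c(0.8, 1.25)) {
  cand <- pairs[pairs$class == "ltr_candidate", , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(structure(empty_elements(), unresolved = cand))
  }
  len_l <- cand$left_end - cand$left_start + 1L
  len_r <- cand$right_end - cand$right_start + 1L
  ratio <- len_l / len_r
  span <- cand$right_end - cand$left_start + 1L
  reason <- rep(NA_character_, nrow(cand))
  reason[len_l < min_ltr_length | len_r < min_ltr_length] <- "ltr too short"
  reason[is.na(reason) & (ratio < length_ratio[1] |
                          ratio > length_ratio[2])] <- "ltr length ratio"
  reason[is.na(reason) & cand$identity < min_identity] <- "low identity"
  reason[is.na(reason) & span > max_span] <- "span too long"
  ok <- cand[is.na(reason), , drop = FALSE]
  unresolved <- cand[!is.na(reason), , drop = FALSE]
  unresolved$reason <- reason[!is.na(reason)]
  # greedy conflict resolution
  ord <- order(-ok$identity, -(ok$left_end - ok$left_start))
  accepted <- integer(0)
  for (r in ord) {
    conflict <- FALSE
    for (a in accepted) {
      if (!spans_compatible(ok[r, ], ok[a, ])) { conflict <- TRUE; break }
    }
    if (conflict) {
      row <- ok[r, , drop = FALSE]
      row$reason <- "conflicts with higher-ranked element"
      unresolved <- rbind(unresolved, row)
    } else {
      accepted <- c(accepted, r)
    }
  }
  el <- ok[sort(accepted), , drop = FALSE]
  if (nrow(el) == 0L) {
    return(structure(empty_elements(), unresolved = unresolved))
  }
  out <- data.frame(
    id = seq_len(nrow(el)),
    start = el$left_start, end = el$right_end,
    length = el$right_end - el$left_start + 1L,
    left_ltr_start = el$left_start, left_ltr_end = el$left_end,
    right_ltr_start = el$right_start, right_ltr_end = el$right_end,
    ltr_length = el$left_end - el$left_start + 1L,
    internal_start = el$left_end + 1L, internal_end = el$right_start - 1L,
    identity = el$identity, evalue = el$evalue,
    type_label = "Unknown", nested_in = NA_integer_)
  # nesting: smallest parent whose internal region contains the span
  for (i in seq_len(nrow(out))) {
    parents <- which(out$internal_start <= out$start[i] &
                     out$internal_end >= out$end[i] &
                     seq_len(nrow(out)) != i)
    if (length(parents)) {
      widths <- out$length[parents]
      out$nested_in[i] <- out$id[parents[which.min(widths)]]
    }
  }
  structure(out, unresolved = unresolved)
}

empty_elements <- function() {
  data.frame(id = integer(0), start = integer(0), end = integer(0),
             length = integer(0), left_ltr_start = integer(0),
             left_ltr_end = integer(0), right_ltr_start = integer(0),
             right_ltr_end = integer(0), ltr_length = integer(0),
             internal_start = integer(0), internal_end = integer(0),
             identity = numeric(0), evalue = numeric(0),
             type_label = character(0), nested_in = integer(0))
}

# Two candidate elements are compatible if their spans are disjoint or
# one is fully inside the other's internal region (proper nesting).
spans_compatible <- function(x, y) {
  if (x$right_end < y$left_start || y$right_end < x$left_start) return(TRUE)
  x_in_y <- x$left_start > y$left_end && x$right_end < y$right_start
  y_in_x <- y$left_start > x$left_end && y$right_end < x$right_start
  x_in_y || y_in_x
}

#' Homologous blocks between an X- and a Y-derived sequence
#'
#' Reciprocal local search between two allosome-derived sequences on
#' both strands. Because homologous noncoding blocks are riddled with
#' small indels, collinear ungapped HSPs on nearby diagonals are chained
#' into gapped blocks (the desk-scale analogue of a gapped BLASTN hit):
#' hits in consistent order separated by at most `max_chain_gap` bp on
#' both sequences are merged, the chain score is the sum of member
#' scores minus affine penalties for the junction gaps, and the chain
#' E-value is computed from that score. Blocks are then filtered by the
#' three thresholds (minimum length, maximum E-value, minimum identity);
#' block identity counts matches over the gapped alignment length, and
#' the TN93 divergence is estimated from the ungapped columns of the
#' member segments (the columns pairwise deletion would retain).
#'
#' @param seq_x,seq_y The two sequences.
#' @param min_length Minimum block length in bp (default 500).
#' @param max_evalue Block E-value threshold (default 1e-50).
#' @param min_identity Minimum block identity (default 0.80).
#' @param compute_k Attach TN93 divergence per block (default TRUE).
#' @param scoring Local-search scoring ([local_scoring()] default).
#' @param max_chain_gap Maximum gap between chained HSPs (bp).
#' @param reps,seed Bootstrap control for the per-block TN93 SE.
#' @return Data frame of blocks: `id`, `x_start`, `x_end`, `x_length`,
#'   `y_start`, `y_end`, `y_length` (display coordinates for inverted
#'   blocks have `y_start > y_end`), `orientation`, `evalue`, `identity`,
#'   `aligned_length`, `n_segments`, `k`, `se_k`, `n_sites`.
#' @export
find_xy_homology <- function(seq_x, seq_y, min_length = 500L,
                             max_evalue = 1e-50, min_identity = 0.80,
                             compute_k = TRUE, scoring = local_scoring(),
                             max_chain_gap = 200L,
                             reps = 1000L, seed = NULL) {
  x <- as_seq_chr(seq_x, "seq_x"); y <- as_seq_chr(seq_y, "seq_y")
  ka <- solve_karlin_altschul(scoring)
  # gather fragments well below the block threshold, then chain
  hits <- local_search(x, y, scoring = scoring,
                       max_evalue = max(max_evalue, 1e-4))
  chained <- chain_hits(hits, scoring, max_chain_gap)
  chains <- chained$chains
  if (nrow(chains)) {
    chains$evalue <- ka$K * as.numeric(nchar(x)) * as.numeric(nchar(y)) *
      exp(-ka$lambda * chains$score)
  }
  vx <- seq_to_code(x)
  vy <- seq_to_code(y)
  vy_rc <- seq_to_code(revcomp(y))
  blocks <- NULL
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i, ]
    members <- hits[chained$members[[i]], , drop = FALSE]
    stats <- chain_column_stats(vx, vy, vy_rc, members, nchar(y))
    aligned_length <- max(ch$q_end - ch$q_start + 1L,
                          ch$s_end - ch$s_start + 1L)
    identity <- stats$matches / aligned_length
    if (aligned_length < min_length || identity < min_identity ||
        ch$evalue > max_evalue) next
    row <- data.frame(
      x_start = ch$q_start, x_end = ch$q_end,
      x_length = ch$q_end - ch$q_start + 1L,
      y_start = if (ch$orientation == "inverted") ch$s_end else ch$s_start,
      y_end = if (ch$orientation == "inverted") ch$s_start else ch$s_end,
      y_length = ch$s_end - ch$s_start + 1L,
      orientation = ch$orientation, evalue = ch$evalue,
      identity = identity, aligned_length = aligned_length,
      n_segments = nrow(members),
      k = NA_real_, se_k = NA_real_, n_sites = NA_integer_)
    if (compute_k) {
      pair <- structure(list(a = stats$a, b = stats$b,
                             n_sites = length(stats$a)),
                        class = "aligned_pair")
      est <- tryCatch(tn93_distance(pair, reps = reps, seed = seed),
                      error = function(e) NULL)
      if (!is.null(est)) {
        row$k <- est$k; row$se_k <- est$se; row$n_sites <- est$n_sites
      }
    }
    blocks <- rbind(blocks, row)
  }
  if (is.null(blocks)) {
    return(data.frame(id = integer(0), x_start = integer(0),
                      x_end = integer(0), x_length = integer(0),
                      y_start = integer(0), y_end = integer(0),
                      y_length = integer(0), orientation = character(0),
                      evalue = numeric(0), identity = numeric(0),
                      aligned_length = integer(0), n_segments = integer(0),
                      k = numeric(0), se_k = numeric(0),
                      n_sites = integer(0)))
  }
  blocks <- blocks[order(blocks$x_start, blocks$y_start), , drop = FALSE]
  blocks <- cbind(id = seq_len(nrow(blocks)), blocks)
  rownames(blocks) <- NULL
  blocks
}

# Greedy collinear chaining of ungapped HSPs. Works in a frame where
# both coordinates increase along the alignment: for inverted hits the
# subject is taken on the reverse strand. Two consecutive hits chain if
# the gaps on both sequences are small and non-contradictory.
chain_hits <- function(hits, scoring, max_gap) {
  empty <- data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      orientation = character(0), score = numeric(0))
  if (nrow(hits) == 0L) return(list(chains = empty, members = list()))
  out <- NULL
  member_list <- list()
  for (ori in unique(hits$orientation)) {
    rows_ori <- which(hits$orientation == ori)
    h <- hits[rows_ori, , drop = FALSE]
    # frame coordinate along the subject that increases with the query
    h$f_start <- h$s_start; h$f_end <- h$s_end
    ord <- order(h$q_start)
    h <- h[ord, , drop = FALSE]
    rows_ori <- rows_ori[ord]
    used <- rep(FALSE, nrow(h))
    for (i in seq_len(nrow(h))) {
      if (used[i]) next
      chain <- i; used[i] <- TRUE
      repeat {
        tail_q <- max(h$q_end[chain])
        tail_f <- if (ori == "direct") max(h$f_end[chain]) else
          min(h$f_start[chain])
        cand <- which(!used & h$q_start > tail_q - 10L &
                        h$q_start < tail_q + max_gap)
        if (ori == "direct") {
          cand <- cand[h$f_start[cand] > tail_f - 10L &
                         h$f_start[cand] < tail_f + max_gap]
        } else {
          cand <- cand[h$f_end[cand] < tail_f + 10L &
                         h$f_end[cand] > tail_f - max_gap]
        }
        cand <- setdiff(cand, chain)
        if (!length(cand)) break
        nxt <- cand[order(h$q_start[cand])][1L]
        chain <- c(chain, nxt); used[nxt] <- TRUE
      }
      seg <- h[chain, , drop = FALSE]
      score <- sum(seg$score)
      if (nrow(seg) > 1L) {
        qg <- sort(seg$q_start)
        qe <- sort(seg$q_end)
        jq <- pmax(0L, qg[-1L] - qe[-nrow(seg)] - 1L)
        score <- score - sum(scoring$gap_open + jq * scoring$gap_extend)
      }
      out <- rbind(out, data.frame(
        q_start = min(seg$q_start), q_end = max(seg$q_end),
        s_start = min(seg$s_start), s_end = max(seg$s_end),
        orientation = ori, score = score))
      member_list[[length(member_list) + 1L]] <- rows_ori[chain]
    }
  }
  list(chains = out, members = member_list)
}

# Concatenated ungapped columns of the member segments (query codes vs
# subject codes, subject on the reverse strand for inverted chains),
# with overlapping query positions counted once.
chain_column_stats <- function(vx, vy, vy_rc, members, ny) {
  a <- integer(0); b <- integer(0)
  seen <- integer(0)
  for (i in seq_len(nrow(members))) {
    qs <- members$q_start[i]:members$q_end[i]
    if (members$orientation[i] == "inverted") {
      ss <- (ny - members$s_end[i] + 1L):(ny - members$s_start[i] + 1L)
      sv <- vy_rc[ss]
    } else {
      sv <- vy[members$s_start[i]:members$s_end[i]]
    }
    keep <- !(qs %in% seen)
    seen <- c(seen, qs[keep])
    a <- c(a, vx[qs[keep]])
    b <- c(b, sv[keep])
  }
  ok <- a <= 4L & b <= 4L
  list(a = a[ok], b = b[ok], matches = sum(a == b & ok))
}

#' Coverage of a sequence by homologous blocks
#'
#' Summarizes how much of a sequence is covered by its homologous blocks,
#' reporting both the plain sum of block lengths (overlaps counted twice
#' — the primary statistic, since published coverage figures follow this
#' convention) and the merged union length (overlaps counted once).
#'
#' @param blocks Block data frame from [find_xy_homology()] (or any data
#'   frame with `{x,y}_start`, `{x,y}_end` and optionally `{x,y}_length`
#'   columns).
#' @param which Which side of the comparison: `"x"` or `"y"`.
#' @param total_length Total length of that sequence in bp.
#' @return List with `summed_length`, `merged_length`, `total_length`,
#'   `summed_percent`, `merged_percent` (percents of `total_length`).
#' @export
coverage_summary <- function(blocks, which = c("x", "y"), total_length) {
  which <- match.arg(which)
  stopifnot(total_length > 0)
  sc <- paste0(which, "_start"); ec <- paste0(which, "_end")
  lc <- paste0(which, "_length")
  if (is.null(blocks[[sc]]) || is.null(blocks[[ec]]))
    stop(sprintf("blocks lack %s/%s columns", sc, ec))
  if (nrow(blocks) == 0L) {
    return(list(summed_length = 0L, merged_length = 0L,
                total_length = total_length,
                summed_percent = 0, merged_percent = 0))
  }
  starts <- pmin(blocks[[sc]], blocks[[ec]])
  ends <- pmax(blocks[[sc]], blocks[[ec]])
  if (any(ends > total_length))
    stop("blocks extend beyond total_length; wrong sequence?")
  summed <- if (!is.null(blocks[[lc]])) sum(blocks[[lc]])
            else sum(ends - starts + 1L)
  merged <- interval_union_length(data.frame(start = starts, end = ends))
  list(summed_length = summed, merged_length = merged,
       total_length = total_length,
       summed_percent = 100 * summed / total_length,
       merged_percent = 100 * merged / total_length)
}
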