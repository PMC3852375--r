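#' Molecular clock configuration
#'
#' The substitution rate used to convert divergences to times. The
#' default, 1.8e-8 substitutions per (synonymous) site per year, is the
#' Brassicaceae-derived average rate conventionally applied to
#' *Silene latifolia* sex-chromosome dating.
#'
#' @param r Substitution rate per site per year (> 0).
#' @return A `clock_config` object.
#' @export
clock_config <- function(r = 1.8e-8) {
  stopifnot(is.numeric(r), length(r) == 1L, r > 0)
  structure(list(r = r), class = "clock_config")
}

#' Divergence time from a pairwise distance
#'
#' Converts a pairwise divergence `k` into a time since the two lineages
#' stopped exchanging sequence, `T = k / (2 r)`: both lineages accumulate
#' substitutions independently at rate `r`, so distance grows at `2 r`
#' per year. The standard error is propagated linearly
#' (`se_T = se_k / (2 r)`).
#'
#' @param k A `distance_estimate` (from [tn93_distance()] or
#'   [syn_nonsyn_distance()]) or a numeric divergence.
#' @param se Standard error of `k` (ignored when `k` carries one).
#' @param clock A [clock_config()].
#' @return An `age_estimate`: list with `t_years`, `se_years`.
#' @examples
#' age_mya(divergence_time(0.0030)) # 0.083
#' @export
divergence_time <- function(k, se = 0, clock = clock_config()) {
  if (inherits(k, "distance_estimate")) {
    se <- k$se
    k <- k$k
  }
  if (is.na(k)) return(age_estimate(NA_real_, NA_real_))
  if (k < 0) stop("negative divergence")
  age_estimate(k / (2 * clock$r), se / (2 * clock$r))
}

age_estimate <- function(t_years, se_years) {
  structure(list(t_years = unname(t_years), se_years = unname(se_years)),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("age: %s MYA (SE %s)\n", format(age_mya(x)),
              format(signif2(x$se_years / 1e6))))
  invisible(x)
}

#' Age in MYA, rounded for reporting
#'
#' Converts an [age_estimate()] (or years) to millions of years ago,
#' rounded to two significant figures — the precision used in reported
#' insertion-time tables. Full-precision values remain available in the
#' `age_estimate` itself.
#'
#' @param x An `age_estimate` or numeric years.
#' @param digits Significant figures (default 2).
#' @return Numeric MYA.
#' @export
age_mya <- function(x, digits = 2) {
  yrs <- if (inherits(x, "age_estimate")) x$t_years else x
  signif(yrs / 1e6, digits)
}

#' Date LTR elements from left/right LTR divergence
#'
#' For each called element, extracts the two LTR subsequences, aligns
#' them globally (Needle-style settings), computes the TN93 divergence
#' between them with a bootstrap SE, and converts it to an insertion age
#' with [divergence_time()] — the two LTR copies of a retroelement are
#' identical at insertion, so their divergence clocks the insertion
#' itself. Elements whose LTR pair is saturated keep `NA` ages but are
#' retained.
#'
#' @param elements Element data frame from [call_ltr_elements()].
#' @param seq The sequence the elements were called on.
#' @param clock A [clock_config()].
#' @param align_scoring Scheme for the LTR-LTR global alignment.
#' @param reps,seed Bootstrap control.
#' @return The element data frame with columns `k`, `se_k`, `n_sites`,
#'   `t_years`, `se_t_years` appended.
#' @export
date_ltr_element <- function(elements, seq, clock = clock_config(),
                             align_scoring = scoring_scheme(),
                             reps = 1000L, seed = NULL) {
  s <- as_seq_chr(seq, "seq")
  n <- nrow(elements)
  elements$k <- NA_real_; elements$se_k <- NA_real_
  elements$n_sites <- NA_integer_
  elements$t_years <- NA_real_; elements$se_t_years <- NA_real_
  for (i in seq_len(n)) {
    left <- substr(s, elements$left_ltr_start[i], elements$left_ltr_end[i])
    right <- substr(s, elements$right_ltr_start[i],
                    elements$right_ltr_end[i])
    aln <- global_align(left, right, align_scoring)
    est <- tryCatch(tn93_distance(aligned_pair(aln), reps = reps,
                                  seed = seed),
                    error = function(e) NULL)
    if (is.null(est)) next # saturated: age left undefined
    age <- divergence_time(est, clock = clock)
    elements$k[i] <- est$k; elements$se_k[i] <- est$se
    elements$n_sites[i] <- est$n_sites
    elements$t_years[i] <- age$t_years
    elements$se_t_years[i] <- age$se_years
  }
  elements
}
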