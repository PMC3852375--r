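#' Configuration for the X/Y region simulator
#'
#' Describes the evolutionary process the analysis pipeline assumes: an
#' ancestral region is duplicated into an X and a Y lineage when
#' recombination stops (`t_stop` years before present), after which each
#' lineage accumulates substitutions independently under a TN93 model
#' clocked at `r` substitutions/site/year, receives scheduled
#' LTR-retroelement insertions (two identical LTR copies flanking an
#' internal region, diverging only after insertion), and suffers indels
#' (Poisson events with geometric lengths). Indels never disrupt an
#' element's LTR copies, so boundary-recovery tests are well-posed.
#'
#' Defaults mirror the reference setting: a 100-kb ancestral region,
#' recombination stop 3.4 million years ago, rate 1.8e-8, and six
#' insertions with ages spanning 0.083-1.6 million years, split between
#' the two lineages.
#'
#' @param ancestral_length Ancestral region length (bp).
#' @param base_composition Frequencies of A, C, G, T (sum to 1).
#' @param t_stop Recombination-stop time, years before present.
#' @param r Substitution rate per site per year.
#' @param kappa1,kappa2 Purine (`A<->G`) and pyrimidine (`C<->T`)
#'   transition-rate multipliers relative to transversions.
#' @param insertions Data frame with columns `lineage` (`"X"`/`"Y"`),
#'   `time` (years before present, `0 < time <= t_stop`), `ltr_length`,
#'   `internal_length`, `position` (ancestral coordinate, or `NA` for a
#'   uniformly random insertion site).
#' @param indel_rate Indel events per site per year.
#' @param indel_length_mean Mean indel length (geometric distribution).
#' @param simple_repeats Optional data frame (`motif`, `copies`,
#'   `position`) of tandem repeats written into the ancestral sequence.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(ancestral_length = 100000L,
                       base_composition = c(A = 0.3, C = 0.2,
                                            G = 0.2, T = 0.3),
                       t_stop = 3.4e6, r = 1.8e-8,
                       kappa1 = 2, kappa2 = 2,
                       insertions = default_insertions(t_stop),
                       indel_rate = 2e-9, indel_length_mean = 5,
                       simple_repeats = NULL, seed = 1L) {
  stopifnot(ancestral_length > 0, t_stop >= 0, r >= 0,
            kappa1 > 0, kappa2 > 0, indel_rate >= 0,
            indel_length_mean >= 1,
            abs(sum(base_composition) - 1) < 1e-9)
  if (!is.null(insertions) && nrow(insertions) > 0) {
    if (any(insertions$time <= 0 | insertions$time > t_stop))
      stop("insertion times must satisfy 0 < time <= t_stop (post-split)")
    if (!all(insertions$lineage %in% c("X", "Y")))
      stop("insertion lineage must be 'X' or 'Y'")
  }
  structure(list(ancestral_length = as.integer(ancestral_length),
                 base_composition = base_composition,
                 t_stop = t_stop, r = r, kappa1 = kappa1, kappa2 = kappa2,
                 insertions = insertions, indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 simple_repeats = simple_repeats, seed = seed),
            class = "sim_config")
}

default_insertions <- function(t_stop) {
  ages <- c(0.18, 0.74, 1.6, 0.083, 0.62, 1.2) * 1e6
  data.frame(lineage = c("X", "X", "X", "Y", "Y", "Y"),
             time = pmin(ages, t_stop),
             ltr_length = 400L, internal_length = 3000L,
             position = NA_integer_)
}

# TN93 rate matrix (rows/cols A, C, G, T) scaled to one substitution per
# site per unit time.
tn93_rate_matrix <- function(pi, kappa1, kappa2) {
  pi <- unname(pi)
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    mult <- 1
    if ((i == 1 && j == 3) || (i == 3 && j == 1)) mult <- kappa1
    if ((i == 2 && j == 4) || (i == 4 && j == 2)) mult <- kappa2
    Q[i, j] <- mult * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Transition probability matrix after `years` at rate cfg$r.
trans_matrix <- function(cfg, years) {
  Q <- tn93_rate_matrix(cfg$base_composition, cfg$kappa1, cfg$kappa2)
  P <- as.matrix(Matrix::expm(Q * cfg$r * years))
  P <- pmax(P, 0)
  P / rowSums(P)
}

# Substitute each site by sampling from the transition matrix; N sites
# are left untouched. The new state is drawn from the *old* state for
# every site (a site must not be resampled after it has changed).
substitute_codes <- function(v, P) {
  new <- v
  for (b in 1:4) {
    idx <- which(v == b)
    if (length(idx))
      new[idx] <- sample.int(4L, length(idx), replace = TRUE,
                             prob = P[b, ])
  }
  new
}

#' Evolve a sequence forward in time
#'
#' Applies `years` of neutral evolution to a sequence under the
#' simulator's TN93 substitution model (exact matrix-exponential
#' transition probabilities, not discretized generations) and, if the
#' configuration has a nonzero indel rate, a Poisson indel process with
#' geometric lengths. Deterministic given `seed`.
#'
#' @param seq The sequence (character or Biostrings object).
#' @param years Duration in years (>= 0).
#' @param cfg A [sim_config()] (rate, composition, kappas, indel model).
#' @param seed RNG seed.
#' @return The evolved sequence as a character string, with an
#'   `"indel_events"` attribute (data frame of events, possibly empty).
#' @export
evolve_sequence <- function(seq, years, cfg = sim_config(), seed = NULL) {
  stopifnot(years >= 0)
  v <- seq_to_code(as_seq_chr(seq, "seq"))
  with_seed(seed, {
    if (years > 0) {
      v <- substitute_codes(v, trans_matrix(cfg, years))
      st <- new_lineage_state(v)
      st <- apply_indels(st, years, cfg)
      v <- st$v
      events <- st$events
    } else {
      events <- empty_indel_events()
    }
    structure(code_to_seq(v), indel_events = events)
  })
}

## ---- lineage state machinery -----------------------------------------

new_lineage_state <- function(v, lift = seq_along(v)) {
  list(v = v,
       lift = lift, # ancestral position -> current position (NA deleted)
       feats = data.frame(kind = character(0), element = integer(0),
                          start = integer(0), end = integer(0)),
       prot = matrix(integer(0), ncol = 2L), # indel-protected intervals
       events = empty_indel_events())
}

empty_indel_events <- function() {
  data.frame(type = character(0), time = numeric(0), position = integer(0),
             length = integer(0))
}

shift_on_insert <- function(x, p, len) ifelse(x >= p, x + len, x)

state_insert <- function(st, p, content, time = NA_real_,
                         type = "insertion") {
  len <- length(content)
  st$v <- append(st$v, content, after = p - 1L)
  if (nrow(st$feats)) {
    st$feats$start <- shift_on_insert(st$feats$start, p, len)
    st$feats$end <- ifelse(st$feats$end >= p, st$feats$end + len,
                           st$feats$end)
  }
  if (nrow(st$prot)) {
    st$prot[, 1L] <- shift_on_insert(st$prot[, 1L], p, len)
    st$prot[, 2L] <- ifelse(st$prot[, 2L] >= p, st$prot[, 2L] + len,
                            st$prot[, 2L])
  }
  st$lift <- ifelse(!is.na(st$lift) & st$lift >= p, st$lift + len, st$lift)
  st$events <- rbind(st$events,
                     data.frame(type = type, time = time, position = p,
                                length = len))
  st
}

state_delete <- function(st, a, len, time = NA_real_) {
  b <- a + len - 1L
  st$v <- st$v[-(a:b)]
  adj <- function(x) x - pmax(0L, pmin(b, x) - a + 1L)
  adj_start <- function(x) x - pmax(0L, pmin(b, x - 1L) - a + 1L)
  if (nrow(st$feats)) {
    st$feats$start <- adj_start(st$feats$start)
    st$feats$end <- adj(st$feats$end)
    st$feats <- st$feats[st$feats$end >= st$feats$start, , drop = FALSE]
  }
  if (nrow(st$prot)) {
    st$prot[, 1L] <- adj_start(st$prot[, 1L])
    st$prot[, 2L] <- adj(st$prot[, 2L])
  }
  dead <- !is.na(st$lift) & st$lift >= a & st$lift <= b
  st$lift[dead] <- NA_integer_
  st$lift <- ifelse(!is.na(st$lift) & st$lift > b, st$lift - len, st$lift)
  st$events <- rbind(st$events,
                     data.frame(type = "deletion", time = time,
                                position = a, length = len))
  st
}

# Is insertion point p (material placed between p-1 and p) inside a
# protected interval [s, e]? It is iff s < p <= e.
insertion_point_blocked <- function(st, p) {
  nrow(st$prot) > 0L && any(st$prot[, 1L] < p & p <= st$prot[, 2L])
}

deletion_blocked <- function(st, a, b) {
  nrow(st$prot) > 0L && any(st$prot[, 1L] <= b & st$prot[, 2L] >= a)
}

apply_indels <- function(st, years, cfg, time_at = NA_real_) {
  if (cfg$indel_rate <= 0) return(st)
  L <- length(st$v)
  n_ev <- stats::rpois(1L, cfg$indel_rate * L * years)
  for (k in seq_len(n_ev)) {
    len <- 1L + stats::rgeom(1L, 1 / cfg$indel_length_mean)
    if (stats::runif(1) < 0.5) {
      for (try in 1:50) {
        p <- sample.int(length(st$v) + 1L, 1L)
        if (!insertion_point_blocked(st, p)) break
        p <- NA_integer_
      }
      if (is.na(p)) next
      content <- sample.int(4L, len, replace = TRUE,
                            prob = cfg$base_composition)
      st <- state_insert(st, p, content, time = time_at)
    } else {
      len <- min(len, length(st$v) - 1L)
      for (try in 1:50) {
        a <- sample.int(length(st$v) - len + 1L, 1L)
        if (!deletion_blocked(st, a, a + len - 1L)) break
        a <- NA_integer_
      }
      if (is.na(a)) next
      st <- state_delete(st, a, len, time = time_at)
    }
  }
  st
}

#' Simulate an X/Y sequence pair with ground truth
#'
#' Runs the full generative model of [sim_config()]: draws the ancestral
#' region, duplicates it at `t_stop`, evolves each lineage to the present
#' (substitutions and indels applied per inter-event epoch, element
#' insertions applied at their scheduled times so that each element's two
#' LTR copies are identical at insertion and diverge only afterwards),
#' and returns the two present-day sequences together with a complete
#' ground-truth event log in final coordinates.
#'
#' @param cfg A [sim_config()].
#' @return List with `seq_x`, `seq_y` (character strings) and `truth`, a
#'   list with `elements` (data frame: lineage, element id, insertion
#'   time/age, span and LTR intervals in final coordinates, `nested_in`),
#'   `events` (indels and insertions per lineage), `lift_x`/`lift_y`
#'   (ancestral position to final position maps, `NA` where deleted), and
#'   the `config`.
#' @export
simulate_xy_pair <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    n <- cfg$ancestral_length
    anc <- sample.int(4L, n, replace = TRUE, prob = cfg$base_composition)
    sr <- cfg$simple_repeats
    sr_feats <- NULL
    if (!is.null(sr) && nrow(sr)) {
      for (i in seq_len(nrow(sr))) {
        unit <- seq_to_code(toupper(sr$motif[i]))
        tract <- rep(unit, sr$copies[i])
        a <- sr$position[i]
        b <- min(a + length(tract) - 1L, n)
        anc[a:b] <- tract[seq_len(b - a + 1L)]
        sr_feats <- rbind(sr_feats,
                          data.frame(kind = "simple_repeat",
                                     element = NA_integer_,
                                     start = a, end = b))
      }
    }
    elements <- NULL
    all_events <- NULL
    seqs <- list()
    lifts <- list()
    next_id <- 1L
    for (lineage in c("X", "Y")) {
      st <- new_lineage_state(anc)
      if (!is.null(sr_feats)) st$feats <- rbind(st$feats, sr_feats)
      ins <- cfg$insertions
      ins <- if (is.null(ins)) NULL else
        ins[ins$lineage == lineage, , drop = FALSE]
      if (!is.null(ins) && nrow(ins))
        ins <- ins[order(-ins$time), , drop = FALSE]
      t_prev <- cfg$t_stop
      schedule <- if (is.null(ins)) numeric(0) else ins$time
      for (k in seq_along(schedule)) {
        st <- evolve_epoch(st, t_prev - schedule[k], cfg, schedule[k])
        res <- insert_element(st, ins[k, ], cfg, next_id)
        st <- res$state
        row <- res$record
        row$lineage <- lineage
        elements <- rbind(elements, row)
        next_id <- next_id + 1L
        t_prev <- schedule[k]
      }
      st <- evolve_epoch(st, t_prev, cfg, 0)
      # final coordinates for this lineage's element records
      if (!is.null(elements)) {
        mine <- which(elements$lineage == lineage)
        for (i in mine) {
          f <- st$feats[!is.na(st$feats$element) &
                          st$feats$element == elements$id[i], ,
                        drop = FALSE]
          elements$start[i] <- f$start[f$kind == "element"]
          elements$end[i] <- f$end[f$kind == "element"]
          elements$left_ltr_start[i] <- f$start[f$kind == "ltr"][1L]
          elements$left_ltr_end[i] <- f$end[f$kind == "ltr"][1L]
          elements$right_ltr_start[i] <- f$start[f$kind == "ltr"][2L]
          elements$right_ltr_end[i] <- f$end[f$kind == "ltr"][2L]
        }
      }
      ev <- st$events
      if (nrow(ev)) ev$lineage <- lineage
      all_events <- rbind(all_events, ev)
      seqs[[lineage]] <- code_to_seq(st$v)
      lifts[[lineage]] <- st$lift
    }
    if (is.null(elements)) {
      elements <- data.frame(lineage = character(0), id = integer(0),
                             time = numeric(0), start = integer(0),
                             end = integer(0), left_ltr_start = integer(0),
                             left_ltr_end = integer(0),
                             right_ltr_start = integer(0),
                             right_ltr_end = integer(0),
                             ltr_length = integer(0),
                             nested_in = integer(0))
    }
    list(seq_x = seqs$X, seq_y = seqs$Y,
         truth = list(elements = elements,
                      events = all_events %||% empty_indel_events(),
                      lift_x = lifts$X, lift_y = lifts$Y,
                      config = cfg))
  })
}

# One inter-event epoch: substitutions for `years`, then indels.
evolve_epoch <- function(st, years, cfg, time_at) {
  if (years <= 0) return(st)
  st$v <- substitute_codes(st$v, trans_matrix(cfg, years))
  apply_indels(st, years, cfg, time_at = time_at)
}

# Insert one scheduled element; returns updated state and a truth record
# (coordinates at insertion time; finalized later).
insert_element <- function(st, ins, cfg, id) {
  ltr_len <- as.integer(ins$ltr_length)
  int_len <- as.integer(ins$internal_length)
  total <- 2L * ltr_len + int_len
  L <- length(st$v)
  p <- NA_integer_
  if (!is.na(ins$position)) {
    # scheduled in ancestral coordinates; reposition if deleted
    p <- st$lift[ins$position]
    if (is.na(p)) {
      alive <- which(!is.na(st$lift))
      nearest <- alive[which.min(abs(alive - ins$position))]
      p <- st$lift[nearest]
      message(sprintf(
        "insertion at deleted ancestral position %d repositioned to %d",
        ins$position, nearest))
    }
    if (insertion_point_blocked(st, p)) p <- NA_integer_
  }
  if (is.na(p)) {
    repeat {
      p <- sample.int(L + 1L, 1L)
      if (!insertion_point_blocked(st, p)) break
    }
  }
  ltr <- sample.int(4L, ltr_len, replace = TRUE,
                    prob = cfg$base_composition)
  internal <- sample.int(4L, int_len, replace = TRUE,
                         prob = cfg$base_composition)
  content <- c(ltr, internal, ltr) # identical LTR copies at insertion
  # nesting: is the insertion point inside an existing element's internal?
  host <- NA_integer_
  if (nrow(st$feats)) {
    inside <- st$feats$kind == "internal" &
      st$feats$start < p & p <= st$feats$end
    if (any(inside)) host <- st$feats$element[inside][1L]
  }
  st <- state_insert(st, p, content, time = ins$time,
                     type = "element_insertion")
  st$feats <- rbind(
    st$feats,
    data.frame(kind = c("element", "ltr", "internal", "ltr"),
               element = id,
               start = c(p, p, p + ltr_len, p + ltr_len + int_len),
               end = c(p + total - 1L, p + ltr_len - 1L,
                       p + ltr_len + int_len - 1L, p + total - 1L)))
  st$prot <- rbind(st$prot,
                   c(p, p + ltr_len - 1L),
                   c(p + ltr_len + int_len, p + total - 1L))
  record <- data.frame(id = id, time = ins$time,
                       start = p, end = p + total - 1L,
                       left_ltr_start = p, left_ltr_end = p + ltr_len - 1L,
                       right_ltr_start = p + ltr_len + int_len,
                       right_ltr_end = p + total - 1L,
                       ltr_length = ltr_len, nested_in = host)
  list(state = st, record = record)
}

#' Write simulated sequences and truth to files
#'
#' Emits the simulated pair as FASTA, the ground-truth element/LTR
#' features as GFF3, and the full event log (with the seed and
#' configuration) as JSON.
#'
#' @param sim Result of [simulate_xy_pair()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named vector of the paths written, invisibly.
#' @export
write_sim_truth <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  seqs <- Biostrings::DNAStringSet(c(X = sim$seq_x, Y = sim$seq_y))
  write_fasta(seqs, fa)
  el <- sim$truth$elements
  gff <- file.path(dir, paste0(prefix, "_truth.gff3"))
  if (nrow(el)) {
    feats <- rbind(
      annotated_feature(el$lineage, el$start, el$end, kind = "element",
                        label = sprintf("element_%d", el$id),
                        attributes = sprintf("age_years=%g", el$time)),
      annotated_feature(el$lineage, el$left_ltr_start, el$left_ltr_end,
                        kind = "ltr",
                        label = sprintf("element_%d_ltr5", el$id)),
      annotated_feature(el$lineage, el$right_ltr_start, el$right_ltr_end,
                        kind = "ltr",
                        label = sprintf("element_%d_ltr3", el$id)))
    write_features_gff3(feats, gff)
  } else {
    writeLines("##gff-version 3", gff)
  }
  js <- file.path(dir, paste0(prefix, "_events.json"))
  jsonlite::write_json(
    list(seed = sim$truth$config$seed,
         t_stop = sim$truth$config$t_stop,
         r = sim$truth$config$r,
         elements = el, events = sim$truth$events),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fasta = fa, gff3 = gff, events = js))
}

#' Simulate a diverged coding-sequence pair
#'
#' Evolves a stop-free codon sequence along two independent lineages for
#' `t_stop` years. Synonymous substitutions accrue at `r` per synonymous
#' site per year and nonsynonymous ones at `omega * r` per nonsynonymous
#' site, with sites counted exactly as the Nei-Gojobori estimator counts
#' them (fractional sites per codon position, mutations to stop codons
#' excluded from both the process and the site denominators): each
#' single-nucleotide change at a position with `v` viable (non-stop)
#' alternatives occurs at rate `r / v` (times `omega` if nonsynonymous).
#' The expected synonymous divergence of the pair is therefore
#' `2 * r * t_stop`, the quantity the Ks-based recombination-stop
#' estimate inverts.
#'
#' @param codons Number of codons (>= 50).
#' @param t_stop Divergence time in years.
#' @param r Synonymous substitution rate per synonymous site per year.
#' @param omega Nonsynonymous/synonymous rate ratio (0 = fully
#'   constrained protein).
#' @param seed RNG seed.
#' @return List with `cds_x`, `cds_y` (character strings).
#' @export
simulate_coding_pair <- function(codons = 500L, t_stop = 3.4e6,
                                 r = 1.8e-8, omega = 0, seed = NULL) {
  stopifnot(codons >= 50L, t_stop >= 0, r >= 0, omega >= 0)
  nb <- codon_neighbors()
  with_seed(seed, {
    anc <- sample(nb$sense_ids, codons, replace = TRUE)
    rate_of <- nb$syn_rate * r + nb$nonsyn_rate * omega * r
    evolve <- function(ids) {
      tot <- sum(rate_of[ids])
      t <- 0
      repeat {
        if (tot <= 0) break
        t <- t + stats::rexp(1L, tot)
        if (t > t_stop) break
        i <- sample.int(length(ids), 1L, prob = rate_of[ids])
        cand <- nb$targets[[ids[i]]]
        w <- nb$weights[[ids[i]]] * c(1, omega)[nb$is_nonsyn[[ids[i]]] + 1L]
        j <- cand[sample.int(length(cand), 1L, prob = w)]
        tot <- tot + rate_of[j] - rate_of[ids[i]]
        ids[i] <- j
      }
      ids
    }
    ids_to_seq <- function(ids) {
      paste(codon_tables()$codons[ids], collapse = "")
    }
    list(cds_x = ids_to_seq(evolve(anc)), cds_y = ids_to_seq(evolve(anc)))
  })
}

## per-codon single-nucleotide neighborhoods (stop codons excluded)
.nb_cache <- new.env(parent = emptyenv())

codon_neighbors <- function() {
  if (!is.null(.nb_cache$nb)) return(.nb_cache$nb)
  tab <- codon_tables()
  targets <- vector("list", 64L)
  is_nonsyn <- vector("list", 64L)
  weights <- vector("list", 64L)
  syn_rate <- numeric(64L)
  nonsyn_rate <- numeric(64L)
  for (id in 1:64) {
    if (tab$is_stop[id]) next
    cod <- tab$codons[id]
    tg <- integer(0); ns <- logical(0); wt <- numeric(0)
    for (pos in 1:3) {
      alts <- integer(0); alt_ns <- logical(0)
      for (bs in DNA_BASES) {
        if (substr(cod, pos, pos) == bs) next
        alt <- cod
        substr(alt, pos, pos) <- bs
        aid <- match(alt, tab$codons)
        if (tab$is_stop[aid]) next # stop-creating changes rejected
        alts <- c(alts, aid)
        alt_ns <- c(alt_ns, tab$aa[aid] != tab$aa[id])
      }
      if (!length(alts)) next
      # per-change rate 1/v, v = viable alternatives at this position,
      # so the position contributes its NG86 fractional site count
      tg <- c(tg, alts)
      ns <- c(ns, alt_ns)
      wt <- c(wt, rep(1 / length(alts), length(alts)))
    }
    targets[[id]] <- tg
    is_nonsyn[[id]] <- ns
    weights[[id]] <- wt
    syn_rate[id] <- sum(wt[!ns])
    nonsyn_rate[id] <- sum(wt[ns])
  }
  .nb_cache$nb <- list(targets = targets, is_nonsyn = is_nonsyn,
                       weights = weights, syn_rate = syn_rate,
                       nonsyn_rate = nonsyn_rate,
                       sense_ids = which(!tab$is_stop))
  .nb_cache$nb
}
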