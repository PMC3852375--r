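#' Configuration for an end-to-end report run
#'
#' Collects input paths, thresholds, clock and seed for [run_report()].
#' Every threshold defaults to the reference workflow's value: self-hit
#' E-value 1e-10 for repeat discovery; 500 bp / 1e-50 / 80% for X-Y
#' homologous blocks; Needle-style global alignment (gap penalty 30,
#' extension 0); substitution rate 1.8e-8/site/year.
#'
#' @param x_fasta,y_fasta Paths to the X- and Y-derived FASTA (one
#'   record each).
#' @param gff3 Optional exon annotation (GFF3) for intron comparisons;
#'   exon features must carry a `gene` attribute shared by the X and Y
#'   copy of a gene.
#' @param genotypes Optional genotype TSV for linkage mapping
#'   (see [read_genotypes()]).
#' @param out_dir Output directory.
#' @param seed Seed used for all bootstrap resampling.
#' @param self_evalue,block_min_length,block_evalue,block_identity
#'   Detection thresholds.
#' @param min_ltr_length,min_ltr_identity,max_element_span Element
#'   constraints (see [call_ltr_elements()]).
#' @param clock A [clock_config()].
#' @param reps Bootstrap replicates.
#' @return A `run_config` object.
#' @export
run_config <- function(x_fasta, y_fasta, gff3 = NULL, genotypes = NULL,
                       out_dir = "strataclock_report", seed = 1L,
                       self_evalue = 1e-10, block_min_length = 500L,
                       block_evalue = 1e-50, block_identity = 0.80,
                       min_ltr_length = 100L, min_ltr_identity = 0.85,
                       max_element_span = 30000L,
                       clock = clock_config(), reps = 1000L) {
  structure(list(x_fasta = x_fasta, y_fasta = y_fasta, gff3 = gff3,
                 genotypes = genotypes, out_dir = out_dir, seed = seed,
                 self_evalue = self_evalue,
                 block_min_length = block_min_length,
                 block_evalue = block_evalue,
                 block_identity = block_identity,
                 min_ltr_length = min_ltr_length,
                 min_ltr_identity = min_ltr_identity,
                 max_element_span = max_element_span,
                 clock = clock, reps = reps),
            class = "run_config")
}

#' Run the full X/Y degeneration report
#'
#' Orchestrates the pipeline end to end: reads the two sequences, finds
#' and dates LTR-retroelement-like elements in each, finds homologous
#' blocks between them with per-block divergences, summarizes coverage,
#' optionally compares intron pairs (when exon annotation is given) and
#' maps markers (when genotypes are given), and writes every table as
#' TSV plus a JSON log of the configuration. All numeric report cells
#' are recomputable from the emitted intermediates; runs with the same
#' seed and configuration are byte-identical.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the result tables and output paths.
#' @export
run_report <- function(cfg) {
  for (role in c("x_fasta", "y_fasta")) {
    if (is.null(cfg[[role]]) || !file.exists(cfg[[role]]))
      stop(sprintf("missing input: %s", role))
  }
  for (role in c("gff3", "genotypes")) {
    if (!is.null(cfg[[role]]) && !file.exists(cfg[[role]]))
      stop(sprintf("missing input: %s", role))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  x_set <- read_fasta(cfg$x_fasta)
  y_set <- read_fasta(cfg$y_fasta)
  x <- as.character(x_set[[1L]]); y <- as.character(y_set[[1L]])
  x_id <- names(x_set)[1L]; y_id <- names(y_set)[1L]
  res <- list()
  paths <- character(0)
  log_msgs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_msgs <<- c(log_msgs,
                     sprintf("stage '%s' failed: %s", name,
                             conditionMessage(e)))
      NULL
    })
  }

  for (side in list(list(id = x_id, seq = x, tag = "x"),
                    list(id = y_id, seq = y, tag = "y"))) {
    el <- stage(paste0("elements_", side$tag), {
      reps_found <- find_self_repeats(side$seq,
                                      max_evalue = cfg$self_evalue,
                                      min_ltr_len = cfg$min_ltr_length)
      els <- call_ltr_elements(reps_found,
                               min_ltr_length = cfg$min_ltr_length,
                               min_identity = cfg$min_ltr_identity,
                               max_span = cfg$max_element_span)
      date_ltr_element(els, side$seq, clock = cfg$clock,
                       reps = cfg$reps, seed = cfg$seed)
    })
    if (!is.null(el)) {
      res[[paste0("elements_", side$tag)]] <- el
      p <- file.path(cfg$out_dir,
                     sprintf("elements_%s.tsv", side$tag))
      write_element_table(el, p, seq_id = side$id)
      paths <- c(paths, p)
      if (nrow(el)) {
        gp <- file.path(cfg$out_dir,
                        sprintf("elements_%s.gff3", side$tag))
        write_features_gff3(element_features(el, side$id), gp)
        paths <- c(paths, gp)
      }
    }
  }

  blocks <- stage("homology_blocks", {
    find_xy_homology(x, y, min_length = cfg$block_min_length,
                     max_evalue = cfg$block_evalue,
                     min_identity = cfg$block_identity,
                     reps = cfg$reps, seed = cfg$seed)
  })
  if (!is.null(blocks)) {
    res$blocks <- blocks
    p <- file.path(cfg$out_dir, "homology_blocks.tsv")
    write_block_table(blocks, p, x_id = x_id, y_id = y_id)
    paths <- c(paths, p)
    cov <- rbind(
      data.frame(sequence = x_id,
                 as.data.frame(coverage_summary(blocks, "x", nchar(x)))),
      data.frame(sequence = y_id,
                 as.data.frame(coverage_summary(blocks, "y", nchar(y)))))
    cov$summed_percent <- round(cov$summed_percent, 1)
    cov$merged_percent <- round(cov$merged_percent, 1)
    res$coverage <- cov
    p <- file.path(cfg$out_dir, "coverage.tsv")
    write_tsv_plain(cov, p)
    paths <- c(paths, p)
  }

  if (!is.null(cfg$gff3)) {
    introns <- stage("introns", {
      feats <- read_features_gff3(cfg$gff3)
      intron_identity_table(x, y, feats, x_id = x_id, y_id = y_id)
    })
    if (!is.null(introns)) {
      res$introns <- introns
      p <- file.path(cfg$out_dir, "introns.tsv")
      write_tsv_plain(introns, p)
      paths <- c(paths, p)
    }
  }

  if (!is.null(cfg$genotypes)) {
    lk <- stage("linkage", {
      map <- two_point_map(read_genotypes(cfg$genotypes))
      data.frame(marker = map$order,
                 cm_to_next = c(round(map$adjacent_cm, 2), NA))
    })
    if (!is.null(lk)) {
      res$linkage <- lk
      p <- file.path(cfg$out_dir, "linkage.tsv")
      write_tsv_plain(lk, p)
      paths <- c(paths, p)
    }
  }

  timeline <- stage("timeline", {
    tl <- NULL
    for (tag in c("x", "y")) {
      el <- res[[paste0("elements_", tag)]]
      if (is.null(el) || !nrow(el)) next
      tl <- rbind(tl, data.frame(
        sequence = if (tag == "x") x_id else y_id,
        element = el$id, t_mya = age_mya(el$t_years),
        se_mya = signif2(el$se_t_years / 1e6),
        nested_in = el$nested_in))
    }
    if (!is.null(tl)) tl[order(tl$t_mya), , drop = FALSE] else
      data.frame(sequence = character(0), element = integer(0),
                 t_mya = numeric(0), se_mya = numeric(0),
                 nested_in = integer(0))
  })
  if (!is.null(timeline)) {
    res$timeline <- timeline
    p <- file.path(cfg$out_dir, "timeline.tsv")
    write_tsv_plain(timeline, p)
    paths <- c(paths, p)
  }

  log <- list(package = "strataclock",
              version = as.character(utils::packageVersion("strataclock")),
              seed = cfg$seed,
              clock_rate = cfg$clock$r,
              thresholds = cfg[c("self_evalue", "block_min_length",
                                 "block_evalue", "block_identity",
                                 "min_ltr_length", "min_ltr_identity",
                                 "max_element_span", "reps")],
              inputs = list(x = cfg$x_fasta, y = cfg$y_fasta,
                            gff3 = cfg$gff3, genotypes = cfg$genotypes),
              messages = log_msgs)
  lp <- file.path(cfg$out_dir, "run_log.json")
  jsonlite::write_json(log, lp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, lp)
  res$paths <- paths
  res$log <- log
  invisible(res)
}

# Elements table with the report column layout (ages in MYA to two
# significant figures alongside full-precision values).
write_element_table <- function(el, path, seq_id = "") {
  df <- data.frame(
    ID = el$id, Type = el$type_label,
    Start = el$start, End = el$end, Length = el$length,
    `Left LTR Length` = el$ltr_length,
    `E-value` = signif(el$evalue, 3),
    Identity = round(100 * el$identity),
    K = signif(el$k, 2), SE_K = signif(el$se_k, 2),
    T = age_mya(el$t_years), SE_T = signif2(el$se_t_years / 1e6),
    T_years_full = el$t_years, SE_T_years_full = el$se_t_years,
    Nested_in = el$nested_in,
    check.names = FALSE)
  write_tsv_plain(df, path)
}

element_features <- function(el, seq_id) {
  rbind(
    annotated_feature(seq_id, el$start, el$end, kind = "element",
                      label = sprintf("element_%d", el$id)),
    annotated_feature(seq_id, el$left_ltr_start, el$left_ltr_end,
                      kind = "ltr",
                      label = sprintf("element_%d_ltr5", el$id)),
    annotated_feature(seq_id, el$right_ltr_start, el$right_ltr_end,
                      kind = "ltr",
                      label = sprintf("element_%d_ltr3", el$id)))
}

# Homology-block table; inverted rows are printed with start > end on
# the Y side (display convention for inverted hits).
write_block_table <- function(blocks, path, x_id = "X", y_id = "Y") {
  df <- data.frame(
    ID = blocks$id,
    X_Start = blocks$x_start, X_End = blocks$x_end,
    X_Length = blocks$x_length,
    Y_Start = blocks$y_start, Y_End = blocks$y_end,
    Y_Length = blocks$y_length,
    Direction = ifelse(blocks$orientation == "inverted",
                       "Inverted", "Direct"),
    `E-value` = signif(blocks$evalue, 3),
    Identity = round(100 * blocks$identity),
    Aligned_Length = blocks$aligned_length,
    K = signif(blocks$k, 2), SE_K = signif(blocks$se_k, 2),
    check.names = FALSE)
  attr(df, "x_id") <- x_id
  write_tsv_plain(df, path)
}

#' Intron-by-intron identity between an X and a Y gene copy
#'
#' Derives introns from exon features (gaps between consecutive exons of
#' a gene on each sequence), pairs the X-copy and Y-copy introns by
#' ordinal number, aligns each pair globally with Needle-style settings,
#' and reports identities excluding gaps. Genes are matched between the
#' two sequences via the exon features' `gene` attribute (or label).
#'
#' @param seq_x,seq_y The two sequences.
#' @param features Feature data frame with `kind == "exon"` rows.
#' @param x_id,y_id `seq_id` values identifying the X and Y sequence in
#'   `features`.
#' @param scoring Alignment scheme (default [scoring_scheme()]).
#' @return Data frame: intron ordinal, coordinates and lengths on both
#'   sides, `identity_pct` (excluding gaps).
#' @export
intron_identity_table <- function(seq_x, seq_y, features,
                                  x_id = "X", y_id = "Y",
                                  scoring = scoring_scheme()) {
  x <- as_seq_chr(seq_x, "seq_x"); y <- as_seq_chr(seq_y, "seq_y")
  introns_of <- function(id) {
    ex <- features[features$kind == "exon" & features$seq_id == id, ,
                   drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    ex <- ex[order(ex$start), , drop = FALSE]
    data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
  }
  ix <- introns_of(x_id); iy <- introns_of(y_id)
  if (is.null(ix) || is.null(iy))
    stop("need at least two exon features on each sequence")
  n <- min(nrow(ix), nrow(iy))
  out <- data.frame(intron = seq_len(n),
                    x_start = ix$start[seq_len(n)],
                    x_end = ix$end[seq_len(n)],
                    x_length = ix$end[seq_len(n)] - ix$start[seq_len(n)] + 1L,
                    y_start = iy$start[seq_len(n)],
                    y_end = iy$end[seq_len(n)],
                    y_length = iy$end[seq_len(n)] - iy$start[seq_len(n)] + 1L,
                    identity_pct = NA_real_)
  for (i in seq_len(n)) {
    aln <- global_align(substr(x, out$x_start[i], out$x_end[i]),
                        substr(y, out$y_start[i], out$y_end[i]),
                        scoring)
    out$identity_pct[i] <- round(100 * alignment_identity(aln))
  }
  out
}
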