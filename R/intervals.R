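#' Construct genomic intervals
#'
#' Builds a data frame of 1-based, inclusive genomic intervals with an
#' orientation flag. Intervals supplied with `start > end` are interpreted
#' as inverted-orientation hits (the convention used when an inverted
#' local alignment is reported on forward-strand coordinates): they are
#' stored normalized (`start <= end`, `orientation = "inverted"`) and the
#' original order is preserved in `display_start`/`display_end`.
#'
#' @param seq_id Sequence identifier(s).
#' @param start,end 1-based inclusive coordinates.
#' @param orientation `"direct"` or `"inverted"` (recycled). Ignored in
#'   favour of `"inverted"` whenever `start > end`.
#' @return A data frame with columns `seq_id`, `start`, `end`,
#'   `orientation`, `display_start`, `display_end` and a derived `length`.
#' @export
genomic_interval <- function(seq_id, start, end,
                             orientation = "direct") {
  n <- max(length(seq_id), length(start), length(end))
  seq_id <- rep_len(as.character(seq_id), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  orientation <- rep_len(match.arg(orientation, c("direct", "inverted"),
                                   several.ok = TRUE), n)
  display_start <- start
  display_end <- end
  flip <- start > end
  orientation[flip] <- "inverted"
  tmp <- start[flip]
  start[flip] <- end[flip]
  end[flip] <- tmp
  if (any(start < 1L)) stop("interval start must be >= 1")
  data.frame(seq_id = seq_id, start = start, end = end,
             orientation = orientation,
             display_start = display_start, display_end = display_end,
             length = end - start + 1L,
             stringsAsFactors = FALSE)
}

#' Total length of the union of intervals
#'
#' Length in bp of the merged union of a set of intervals on one sequence;
#' overlapping bases are counted once. Together with the plain sum of
#' interval lengths this distinguishes "summed" from "merged" coverage of
#' homologous blocks (which differ whenever blocks overlap).
#'
#' @param intervals A data frame with `start`/`end` columns (1-based,
#'   inclusive) and optionally `seq_id` (must then be constant).
#' @return Union length in bp (integer).
#' @examples
#' interval_union_length(data.frame(start = c(1, 5), end = c(10, 20))) # 20
#' @export
interval_union_length <- function(intervals) {
  if (nrow(intervals) == 0L) return(0L)
  if (!is.null(intervals$seq_id) &&
      length(unique(intervals$seq_id)) > 1L) {
    stop("intervals span multiple seq_ids; union is per-sequence")
  }
  ir <- IRanges::IRanges(start = intervals$start, end = intervals$end)
  sum(IRanges::width(IRanges::reduce(ir)))
}

## ---- features and GFF3 -----------------------------------------------

FEATURE_KINDS <- c("exon", "intron", "ltr", "internal", "element",
                   "homology_block", "simple_repeat", "other_repeat")

# Bijective map between the package's feature vocabulary and the GFF3
# `type` column (SO-flavoured terms).
KIND_TO_GFF <- c(exon = "exon",
                 intron = "intron",
                 ltr = "long_terminal_repeat",
                 internal = "LTR_retrotransposon_internal_region",
                 element = "LTR_retrotransposon",
                 homology_block = "match",
                 simple_repeat = "tandem_repeat",
                 other_repeat = "repeat_region")

#' Construct annotated features
#'
#' @param seq_id,start,end,orientation Interval fields (see
#'   [genomic_interval()]).
#' @param kind Feature kind; one of `exon`, `intron`, `ltr`, `internal`,
#'   `element`, `homology_block`, `simple_repeat`, `other_repeat`.
#' @param label Free-text label (becomes the GFF3 `Name` attribute).
#' @param attributes Optional named character vector or list of extra
#'   `key=value` attributes, recycled across features.
#' @return A feature data frame.
#' @export
annotated_feature <- function(seq_id, start, end, orientation = "direct",
                              kind, label = "", attributes = NULL) {
  iv <- genomic_interval(seq_id, start, end, orientation)
  kind <- rep_len(kind, nrow(iv))
  bad <- !(kind %in% FEATURE_KINDS)
  if (any(bad)) {
    stop(sprintf("unknown feature kind(s): %s",
                 paste(unique(kind[bad]), collapse = ", ")))
  }
  iv$kind <- kind
  iv$label <- rep_len(as.character(label), nrow(iv))
  iv$attributes <- rep_len(
    if (is.null(attributes)) "" else attr_to_string(attributes), nrow(iv))
  iv
}

attr_to_string <- function(a) {
  if (is.character(a) && is.null(names(a)) && length(a) >= 1L) return(a)
  paste(sprintf("%s=%s", names(a), unlist(a)), collapse = ";")
}

#' Write features as GFF3
#'
#' Serializes a feature data frame (from [annotated_feature()] or the
#' detection functions) to GFF3; the feature `kind` is written to the
#' `type` column, the label to `Name`, and inverted orientation to the
#' `-` strand.
#'
#' @param features Feature data frame.
#' @param path Output path.
#' @param source Value for the GFF3 `source` column.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path, source = "strataclock") {
  gr <- GenomicRanges::GRanges(
    seqnames = features$seq_id,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = ifelse(features$orientation == "inverted", "-", "+"))
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- unname(KIND_TO_GFF[features$kind])
  if (!is.null(features$label)) S4Vectors::mcols(gr)$Name <- features$label
  extra <- features$attributes
  if (!is.null(extra) && any(nzchar(extra))) {
    kv <- parse_attr_strings(extra)
    for (key in names(kv)) S4Vectors::mcols(gr)[[key]] <- kv[[key]]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

parse_attr_strings <- function(x) {
  pairs <- lapply(x, function(s) {
    if (!nzchar(s)) return(character(0))
    items <- strsplit(s, ";", fixed = TRUE)[[1L]]
    kv <- strsplit(items, "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, character(1), 2L),
                    vapply(kv, `[`, character(1), 1L))
  })
  keys <- unique(unlist(lapply(pairs, names)))
  stats::setNames(lapply(keys, function(k) {
    vapply(pairs, function(p) if (k %in% names(p)) p[[k]] else NA_character_,
           character(1))
  }), keys)
}

#' Read features from GFF3
#'
#' Inverse of [write_features_gff3()]: GFF3 `type` values are mapped back
#' to the package's feature vocabulary (unknown types become
#' `other_repeat` unless they are `exon`/`intron`-like).
#'
#' @param path Path to a GFF3 file.
#' @return A feature data frame.
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(S4Vectors::mcols(gr)$type)
  rev_map <- stats::setNames(names(KIND_TO_GFF), KIND_TO_GFF)
  kind <- unname(rev_map[type])
  kind[is.na(kind)] <- "other_repeat"
  lab <- S4Vectors::mcols(gr)$Name
  if (is.null(lab)) lab <- ""
  lab[is.na(lab)] <- ""
  drop <- c("source", "type", "score", "phase", "Name", "ID")
  extra_cols <- setdiff(colnames(S4Vectors::mcols(gr)), drop)
  attrs <- if (length(extra_cols) == 0L) "" else {
    apply(as.data.frame(S4Vectors::mcols(gr)[extra_cols]), 1L, function(row) {
      keep <- !is.na(row)
      paste(sprintf("%s=%s", extra_cols[keep], row[keep]), collapse = ";")
    })
  }
  annotated_feature(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    orientation = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                         "inverted", "direct"),
    kind = kind, label = lab,
    attributes = if (all(!nzchar(attrs))) NULL else attrs)
}
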