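#' Read nucleotide sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a [Biostrings::DNAStringSet].
#' Residues are uppercased; IUPAC ambiguity codes other than `A`, `C`,
#' `G`, `T`, `N` are mapped to `N` (with a message), because downstream
#' distance estimators use pairwise deletion of ambiguous columns anyway.
#' The header text after the first whitespace is kept as the record
#' description in `S4Vectors::mcols()`.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` named by record id, with a `description`
#'   metadata column.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "acgtn"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no records")
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate sequence id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(raw))
  seqs <- vapply(seqs, clean_residues, character(1), USE.NAMES = FALSE)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

# Validate residues, mapping IUPAC ambiguity codes to N; error (with the
# offending position) on anything outside the IUPAC nucleotide alphabet.
clean_residues <- function(s) {
  ok <- "ACGTN"
  ambig <- "RYSWKMBDHVU"
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% strsplit(paste0(ok, ambig), "")[[1L]])
  if (any(bad)) {
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 chars[which(bad)[1L]], which(bad)[1L]))
  }
  n_ambig <- sum(chars %in% strsplit(ambig, "")[[1L]])
  if (n_ambig > 0L) {
    message(sprintf("%d ambiguity code(s) mapped to N", n_ambig))
    s <- chartr(ambig, strrep("N", nchar(ambig)), s)
  }
  s
}

#' Write sequences to FASTA
#'
#' Writes a `DNAStringSet` (or named character vector) as FASTA wrapped at
#' 60 columns, appending the `description` metadata column (if any) to the
#' header line.
#'
#' @param x Sequences: `DNAStringSet` or named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) {
    x <- Biostrings::DNAStringSet(toupper(x))
  }
  desc <- S4Vectors::mcols(x)$description
  hdr <- names(x)
  if (is.null(hdr)) stop("sequences must be named")
  if (!is.null(desc)) {
    hdr <- ifelse(nzchar(desc), paste(hdr, desc), hdr)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", hdr[i]), con)
    s <- as.character(x[[i]])
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' Reverse-complements a nucleotide sequence; `N` maps to `N`. Needed to
#' report inverted-orientation homology blocks on the coordinate system of
#' the forward strand.
#'
#' @param x A sequence (character scalar, `DNAString`, or `DNAStringSet`).
#' @return An object of the same class as the input.
#' @examples
#' revcomp("AAC") # "GTT"
#' @export
revcomp <- function(x) {
  if (is.character(x)) {
    vapply(x, function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
    }, character(1), USE.NAMES = FALSE)
  } else {
    Biostrings::reverseComplement(x)
  }
}
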