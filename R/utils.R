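## Internal helpers shared across modules.

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Coerce a sequence argument (character scalar, DNAString, or a
# single-element DNAStringSet) to a plain uppercase character scalar.
as_seq_chr <- function(x, arg = deparse(substitute(x))) {
  if (methods::is(x, "DNAStringSet") || methods::is(x, "BStringSet")) {
    if (length(x) != 1L)
      stop(sprintf("'%s' must be a single sequence, got %d", arg, length(x)))
    x <- as.character(x[[1L]])
  } else if (methods::is(x, "DNAString") || methods::is(x, "BString")) {
    x <- as.character(x)
  } else if (is.character(x)) {
    if (length(x) != 1L)
      stop(sprintf("'%s' must be a single sequence string", arg))
  } else {
    stop(sprintf("'%s' must be a character string or Biostrings object", arg))
  }
  toupper(x)
}

# Integer codes A=1, C=2, G=3, T=4, N=5 (anything else is an error).
DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
DNA_BASES <- c("A", "C", "G", "T")

seq_to_code <- function(s) {
  v <- DNA_CODE[strsplit(s, "", fixed = TRUE)[[1L]]]
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    stop(sprintf("non-nucleotide character at position %d", bad))
  }
  unname(v)
}

code_to_seq <- function(v) {
  paste(c(DNA_BASES, "N")[v], collapse = "")
}

# Round to two significant figures, the precision used for reported ages.
signif2 <- function(x) signif(x, 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
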