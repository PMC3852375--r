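test_that("FASTA read/write round-trips byte-identically with 60-column wrapping", {
  fa <- tempfile(fileext = ".fa")
  set.seed(101)
  seqs <- Biostrings::DNAStringSet(c(one = rand_seq(130), two = rand_seq(59)))
  S4Vectors::mcols(seqs)$description <- c("first record", "")
  write_fasta(seqs, fa)
  back <- read_fasta(fa)
  expect_identical(names(back), c("one", "two"))
  expect_equal(as.character(back), as.character(seqs))
  expect_identical(S4Vectors::mcols(back)$description,
                   c("first record", ""))
  fa2 <- tempfile(fileext = ".fa")
  write_fasta(back, fa2)
  expect_identical(readLines(fa), readLines(fa2))
  # wrapping actually happened
  expect_true(any(nchar(readLines(fa)) == 60))
})

test_that("FASTA reader normalizes case, maps ambiguity codes, rejects bad input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgtr"), fa)
  expect_message(x <- read_fasta(fa), "ambiguity")
  expect_identical(as.character(x[[1]]), "ACGTN")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(read_fasta(fa), "duplicate.*a")

  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "no records")

  writeLines(c(">s1", "ACXGT"), fa)
  expect_error(read_fasta(fa), "position 3")
})

test_that("revcomp handles N, matches hand examples, and is an involution", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAC"), "GTT")
  expect_identical(revcomp("ANT"), "ANT")
  set.seed(7)
  for (i in 1:20) {
    s <- rand_seq(sample(5:200, 1))
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("intervals normalize inverted rows and keep the display order", {
  iv <- genomic_interval("Y", start = c(100, 3248), end = c(200, 1996))
  expect_equal(iv$orientation, c("direct", "inverted"))
  expect_equal(iv$start, c(100, 1996))
  expect_equal(iv$end, c(200, 3248))
  expect_equal(iv$display_start, c(100, 3248))
  expect_equal(iv$display_end, c(200, 1996))
  expect_equal(iv$length, c(101, 1253))
  expect_error(genomic_interval("X", 0, 5), ">= 1")
})

test_that("published coordinate spans agree with their length columns where applicable", {
  el <- read_fixture("slap3xy_ltr_elements.tsv")
  # elements without nested inserts: span equals the printed length
  plain <- el[el$id %in% c(1, 2, 4, 8), ]
  expect_equal(plain$end - plain$start + 1, plain$length)
  # elements hosting a nested element: printed length excludes the insert
  expect_equal((el$end[3] - el$start[3] + 1) - el$length[4], el$length[3])
  expect_equal((el$end[7] - el$start[7] + 1) - el$length[8], el$length[7])
  bl <- read_fixture("slap3xy_homology_blocks.tsv")
  expect_equal(bl$x_end - bl$x_start + 1, bl$x_length)
})

test_that("interval union length merges overlaps and matches a per-base oracle", {
  expect_equal(interval_union_length(data.frame(start = c(1, 5),
                                                end = c(10, 20))), 20)
  expect_equal(interval_union_length(data.frame(start = c(1, 21),
                                                end = c(10, 30))), 20)
  expect_error(interval_union_length(
    data.frame(seq_id = c("a", "b"), start = 1:2, end = 3:4)),
    "multiple seq_ids")
  # the published Y-side block intervals: rows 3 and 4 overlap, so the
  # union is strictly below both the printed-length sum and the span sum
  bl <- read_fixture("slap3xy_homology_blocks.tsv")
  ys <- pmin(bl$y_start, bl$y_end); ye <- pmax(bl$y_start, bl$y_end)
  u <- interval_union_length(data.frame(start = ys, end = ye))
  expect_equal(u, brute_union_length(ys, ye))
  expect_lt(u, sum(bl$y_length))
  expect_lt(u, sum(ye - ys + 1))
})

test_that("union length <= summed length, equal iff pairwise disjoint", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    st <- sample(1:500, n)
    en <- st + sample(0:80, n, replace = TRUE)
    iv <- data.frame(start = st, end = en)
    u <- interval_union_length(iv)
    expect_lte(u, sum(en - st + 1))
    expect_equal(u, brute_union_length(st, en))
    disjoint <- all(outer(seq_len(n), seq_len(n), function(a, b) {
      a == b | en[a] < st[b] | en[b] < st[a]
    }))
    expect_equal(u == sum(en - st + 1), disjoint)
  }
})

test_that("features round-trip through GFF3", {
  f <- annotated_feature(seq_id = c("X", "X", "Y"),
                         start = c(100, 150, 3248),
                         end = c(400, 220, 1996),
                         kind = c("element", "ltr", "homology_block"),
                         label = c("el1", "el1_ltr5", "blk3"))
  path <- tempfile(fileext = ".gff3")
  write_features_gff3(f, path)
  back <- read_features_gff3(path)
  back <- back[order(back$seq_id, back$start), ]
  f_sorted <- f[order(f$seq_id, f$start), ]
  for (col in c("seq_id", "start", "end", "orientation", "kind", "label")) {
    expect_equal(back[[col]], f_sorted[[col]], ignore_attr = TRUE)
  }
  expect_error(annotated_feature("X", 1, 10, kind = "nonsense"),
               "unknown feature kind")
})
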