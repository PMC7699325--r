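test_that("FASTA reading maps headers to ids and enforces uniqueness", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">A some description", "MKC"), f)
  recs <- read_fasta(f, "protein")
  expect_equal(recs$id, "A")
  expect_equal(recs$residues, "MKC")
  expect_true(all(is.na(recs$signal_peptide)))

  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f, "protein")), 0L)

  writeLines(c(">A", "MK", ">A", "ML"), f)
  expect_error(read_fasta(f, "protein"), "duplicate.*A")

  writeLines(c("MK", ">A", "ML"), f)
  expect_error(read_fasta(f, "protein"), "malformed FASTA.*line 1")
})

test_that("FASTA write/read round-trips sequences and wraps at 60 columns", {
  recs <- chemosensr:::new_seq_records(
    c("seq1", "seq2"),
    c(paste(rep("ACDEFGHIKL", 13), collapse = ""), "MKVLY"),
    "protein")
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(f, "protein")
  expect_equal(back$id, recs$id)
  expect_equal(back$residues, recs$residues)
})

test_that("annotation table round-trips through the TSV dialect", {
  df <- data.frame(id = c("a", "b"), signal_peptide = c(TRUE, FALSE),
                   tm_count = c(0L, 7L),
                   domain_hits = c("OBP_domain", "OR_7tm;IR_iGluR"),
                   completeness = c("full", "partial_5p"),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(df, f)
  expect_equal(read_annotation(f), df)
})

test_that("unigene collapsing merges at the identity threshold with the longest representative", {
  base <- paste(rep(strsplit("ACDEFGHIKL", "")[[1]], 10), collapse = "")
  mut <- function(s, at) { substr(s, at, at) <- "W"; s }
  one_mis <- mut(base, 50)                    # identity 0.99
  three_mis <- mut(mut(mut(base, 10), 50), 90)  # identity 0.97

  recs <- chemosensr:::new_seq_records(c("a", "b"), c(base, one_mis),
                                       "protein")
  u <- collapse_unigenes(recs, 0.98)
  expect_equal(nrow(u$representatives), 1L)
  expect_equal(u$representatives$id, "a")     # equal length: lexicographic
  expect_equal(unname(u$representative_of[["b"]]), "a")

  recs2 <- chemosensr:::new_seq_records(c("a", "b"), c(base, three_mis),
                                        "protein")
  u2 <- collapse_unigenes(recs2, 0.98)
  expect_equal(nrow(u2$representatives), 2L)

  # longer member wins regardless of id order
  recs3 <- chemosensr:::new_seq_records(
    c("zlong", "ashort"), c(paste0(base, "AAAA"), base), "protein")
  u3 <- collapse_unigenes(recs3, 0.90)
  expect_equal(u3$representatives$id, "zlong")

  expect_error(collapse_unigenes(
    chemosensr:::new_seq_records(c("a", "b"), c("MK", "ATG"),
                                 c("protein", "nucleotide"))),
    "single moltype")
})

test_that("collapsing its own representatives is a no-op and identity matches exhaustive alignment", {
  set.seed(11)
  aa <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- replicate(6, paste(sample(aa, 80, replace = TRUE), collapse = ""))
  recs <- chemosensr:::new_seq_records(sprintf("s%d", 1:6), seqs, "protein")
  u <- collapse_unigenes(recs, 0.98)
  again <- collapse_unigenes(u$representatives, 0.98)
  expect_equal(again$representatives$id, u$representatives$id)
  expect_true(all(again$representative_of == names(again$representative_of)))

  # identical sequences always collapse to a single maximal-length member
  recs_id <- chemosensr:::new_seq_records(c("x", "y", "z"),
                                          rep(seqs[1], 3), "protein")
  u_id <- collapse_unigenes(recs_id, 0.98)
  expect_equal(nrow(u_id$representatives), 1L)
  expect_equal(pairwise_identity(seqs[1], seqs[1]), 1)
})

test_that("ORF completeness labels follow start/stop codon presence", {
  expect_equal(flag_completeness(TRUE, TRUE), "full")
  expect_equal(flag_completeness(FALSE, TRUE), "partial_5p")
  expect_equal(flag_completeness(TRUE, FALSE), "partial_3p")
  expect_equal(flag_completeness(FALSE, FALSE), "partial_both")
  expect_equal(flag_completeness(NA, TRUE), "unknown")
  expect_equal(flag_completeness(c(TRUE, FALSE), c(TRUE, TRUE)),
               c("full", "partial_5p"))
})
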