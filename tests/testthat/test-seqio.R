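# Sequence I/O and nucleotide/protein primitives.

test_that("read_fasta normalizes records and preserves order and N runs", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s first seq", "acgt", ">t", "AANN", "NACG"), f)
  recs <- read_fasta(f)
  expect_identical(names(recs), c("s", "t"))
  expect_identical(unname(recs[["s"]]), "ACGT")
  expect_identical(unname(recs[["t"]]), "AANNNACG")  # N survives verbatim
  expect_identical(unname(attr(recs, "descriptions")[["s"]]), "first seq")
})

test_that("read_fasta rejects empty files and duplicate ids", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "no records|FASTA")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate.*a")
})

test_that("ambiguity codes other than N become N with a warning", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACRYGT"), f)
  expect_warning(recs <- read_fasta(f), "ambiguity")
  expect_identical(unname(recs[["a"]]), "ACNNGT")
})

test_that("FASTA round-trips ids and sequences exactly", {
  set.seed(31)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), sample(5:200, 1), TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("rec", 1:5)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f, width = 17L)  # awkward wrap width on purpose
  back <- read_fasta(f)
  expect_identical(unname(back[names(seqs)]), unname(seqs))
  expect_identical(names(back), names(seqs))
})

test_that("translate_cds follows the standard code, N->X, frames, errors", {
  expect_identical(translate_cds("ATGAAATAA", 0), "MK*")
  expect_identical(translate_cds("ATGANATAA", 0), "MX*")
  expect_identical(translate_cds("TTAA", 1), "*")     # frame 1 reads TAA
  expect_identical(translate_cds("ATGAA", 0), "M")    # trailing bases dropped
  expect_error(translate_cds("ATGU--", 0), "non-ACGTN")
  expect_error(translate_cds("AT", 0), "shorter")
})

test_that("reverse_complement handles N, palindromes, and is an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAC"), "GTTT")
  expect_identical(reverse_complement("ANT"), "ANT")
  expect_error(reverse_complement("ACGU"), "non-ACGTN")
  set.seed(7)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1), TRUE),
               collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("minus-strand translation equals an independent codon walk", {
  # oracle: complement each base, reverse, then read codons by hand
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  set.seed(13)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(3:300, 1), TRUE),
               collapse = "")
    rc_chars <- rev(comp[strsplit(s, "")[[1]]])
    aa <- character(0)
    j <- 1L
    while (j + 2L <= length(rc_chars)) {
      codon <- paste(rc_chars[j:(j + 2L)], collapse = "")
      aa <- c(aa, if (grepl("N", codon)) "X" else
        unname(Biostrings::GENETIC_CODE[codon]))
      j <- j + 3L
    }
    expect_identical(translate_cds(reverse_complement(s), 0),
                     paste(aa, collapse = ""))
  }
})

test_that("find_n_runs reports maximal runs at the length cutoff", {
  expect_equal(nrow(find_n_runs("ACGT", 1)), 0)
  expect_equal(find_n_runs("ANNNA", 2),
               cbind(start = 1L, end = 4L), ignore_attr = TRUE)
  expect_equal(find_n_runs("NNAANN", 2),
               cbind(start = c(0L, 4L), end = c(2L, 6L)), ignore_attr = TRUE)
  expect_equal(nrow(find_n_runs("NNAANN", 3)), 0)
})

test_that("query_gene_model validates the CDS contract", {
  expect_error(query_gene_model("g", c("ATGAAA", "TA")), "divisible by 3")
  expect_error(query_gene_model("g", c("ATGTAA", "AAATAA")), "internal stop")
  expect_error(query_gene_model("g", "ATGAAAAAA"), "stop codon")
  q <- query_gene_model("g", c("ATGAA", "ATAA"), accession = "ACC1")
  expect_identical(q$protein, "MK")
  expect_identical(q$exon_cds_offsets, c(0L, 5L))
})

test_that("exon-FASTA query ingestion orders exons by index", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g_exon2", "ATAA", ">g_exon1", "ATGAA"), f)
  q <- read_query_exons_fasta(f)
  expect_identical(q$gene_name, "g")
  expect_identical(q$exons, c("ATGAA", "ATAA"))
  writeLines(c(">oops", "ACGT"), f)
  expect_error(read_query_exons_fasta(f), "exon")
})
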