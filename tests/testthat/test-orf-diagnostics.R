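# Indel extraction, frameshift detection, premature-stop scanning.
#
# The toy gene used by the hand-constructed cases:
#   CDS  ATG AAA CTT CTA AAC GTG AAA TAA   protein MKLLNVK
# with alignments written out by hand so every expected record is known.

toy_gene <- function() query_gene_model("toy", "ATGAAACTTCTAAACGTGAAATAA")

## build a single-exon reconstruction directly from gapped strings
recon_from_alignment <- function(q, aligned_query, aligned_target) {
  a <- structure(list(exon_index = 1L, found = TRUE, score = 1, identity = 1,
                      region_span = c(0L, nchar(gsub("-", "", aligned_target))),
                      span = c(0L, nchar(gsub("-", "", aligned_target))),
                      aligned_query = aligned_query,
                      aligned_target = aligned_target),
                 class = "exon_alignment")
  assemble_gene(q, list(a), "s", "+")
}

test_that("a mutation-free gene yields no indels and no stops", {
  q <- toy_gene()
  rec <- recon_from_alignment(q, q$cds, q$cds)
  expect_equal(nrow(extract_indels(rec, q)), 0)
  expect_equal(nrow(scan_premature_stops(rec, q)), 0)
  expect_false(diagnose_orf(rec, q)$has_frameshift)
})

test_that("a 1-bp deletion shifts the frame into premature stops", {
  q <- toy_gene()
  # delete the C at CDS position 6: the shifted frame reads
  #   ATG AAA TTC TAA ACG TGA AAT -- stops at codons 3 and 5
  rec <- recon_from_alignment(q,
    "ATGAAACTTCTAAACGTGAAATAA",
    "ATGAAA-TTCTAAACGTGAAATAA")
  ind <- extract_indels(rec, q)
  expect_equal(nrow(ind), 1)
  expect_identical(ind$kind, "deletion")
  expect_equal(ind$length_bp, 1L)
  expect_equal(ind$cds_pos, 6L)
  expect_true(detect_frameshift(ind))
  st <- scan_premature_stops(rec, q)
  expect_equal(nrow(st), 2)
  expect_equal(st$codon_index, c(3L, 5L))
  expect_true(all(st$caused_by_frameshift))
})

test_that("a nonsense substitution is a stop without frameshift", {
  q <- toy_gene()
  # codon 5 GTG -> TGA (pure substitution, no indel)
  rec <- recon_from_alignment(q,
    "ATGAAACTTCTAAACGTGAAATAA",
    "ATGAAACTTCTAAACTGAAAATAA")
  expect_equal(nrow(extract_indels(rec, q)), 0)
  st <- scan_premature_stops(rec, q)
  expect_equal(nrow(st), 1)
  expect_equal(st$codon_index, 5L)
  expect_false(st$caused_by_frameshift)
})

test_that("compensating indels restore the frame and produce no stop here", {
  q <- toy_gene()
  # +1 insertion at CDS pos 3, -1 deletion at CDS pos 9: frame disturbed in
  # between (so detect_frameshift is TRUE) but no stop codon arises
  rec <- recon_from_alignment(q,
    "ATG-AAACTTCTAAACGTGAAATAA",
    "ATGGAAACTT-TAAACGTGAAATAA")
  ind <- extract_indels(rec, q)
  expect_equal(nrow(ind), 2)
  expect_identical(ind$kind, c("insertion", "deletion"))
  expect_equal(ind$cds_pos, c(3L, 9L))
  expect_true(detect_frameshift(ind))
  expect_equal(nrow(scan_premature_stops(rec, q)), 0)
})

test_that("frameshift detection follows prefix sums mod 3", {
  mk <- function(kinds, lens, pos = seq_along(kinds)) {
    data.frame(exon_index = rep(1L, length(kinds)), kind = kinds,
               length_bp = lens, cds_pos = pos,
               low_confidence = rep(FALSE, length(kinds)),
               stringsAsFactors = FALSE)
  }
  expect_false(detect_frameshift(mk(character(0), integer(0), integer(0))))
  expect_false(detect_frameshift(mk("deletion", 3L)))           # in-frame
  expect_true(detect_frameshift(mk(c("insertion", "deletion"), c(1L, 1L))))
  # invariance to in-frame indels sprinkled anywhere
  set.seed(61)
  for (t in 1:20) {
    n <- sample(1:6, 1)
    lens <- sample(c(3L, 6L, 9L), n, TRUE)
    kinds <- sample(c("insertion", "deletion"), n, TRUE)
    expect_false(detect_frameshift(mk(kinds, lens)))
  }
})

test_that("terminal stop of a faithful copy is never called premature", {
  q <- fixture_query()
  sim <- small_sim("intact", seed = 63)
  rec <- reconstruct_gene(sim$genome, find_loci(sim$genome, q$protein)[1, ], q)
  expect_equal(nrow(scan_premature_stops(rec, q)), 0)
})

test_that("a multi-indel exon is inventoried record by record", {
  # the classic badly-degraded pseudogene pattern: three 1-bp insertions
  # plus 1-, 2-, 2- and 8-bp deletions, all in the long final exon
  q <- fixture_query()
  mut <- data.frame(
    exon_index = 6L,
    kind = c("ins", "ins", "ins", "del", "del", "del", "del"),
    length_bp = c(1L, 1L, 1L, 1L, 2L, 2L, 8L),
    offset_in_exon = c(100L, 160L, 220L, 400L, 500L, 600L, 700L))
  spec <- gene_state_spec("defective_frameshift", mutations = mut)
  sim <- small_sim(spec, seed = 65)
  loci <- find_loci(sim$genome, q$protein)
  rec <- reconstruct_gene(sim$genome, loci[1, ], q)
  ind <- extract_indels(rec, q)
  expect_equal(nrow(ind), 7)
  expect_true(all(ind$exon_index == 6L))
  expect_equal(sort(ind$length_bp[ind$kind == "insertion"]), c(1L, 1L, 1L))
  expect_equal(sort(ind$length_bp[ind$kind == "deletion"]), c(1L, 2L, 2L, 8L))
  expect_true(detect_frameshift(ind))   # net -10 bp
  expect_gt(nrow(scan_premature_stops(rec, q)), 0)
})

test_that("single planted interior indels are recovered exactly", {
  # exon-level recovery: random exon, one interior indel (1-10 bp), mapped
  # back against its flanked region; the record must match the plant
  set.seed(64)
  bases <- c("A", "C", "G", "T")
  n_trials <- 200
  ok <- 0
  for (t in seq_len(n_trials)) {
    exon <- paste(sample(bases, sample(200:400, 1), TRUE), collapse = "")
    len <- sample(1:10, 1)
    kind <- sample(c("insertion", "deletion"), 1)
    pos <- sample(30:(nchar(exon) - 30 - len), 1)
    mutated <- if (kind == "deletion")
      paste0(substr(exon, 1, pos), substr(exon, pos + len + 1, nchar(exon)))
    else
      paste0(substr(exon, 1, pos), paste(sample(bases, len, TRUE), collapse = ""),
             substr(exon, pos + 1, nchar(exon)))
    region <- paste0(paste(sample(bases, 400, TRUE), collapse = ""), mutated,
                     paste(sample(bases, 400, TRUE), collapse = ""))
    a <- map_exon(exon, region)
    a$exon_index <- 1L
    fake_query <- structure(list(gene_name = "r", exons = exon, cds = exon,
                                 protein = strrep("K", nchar(exon) %/% 3),
                                 exon_cds_offsets = 0L), class = "query_gene")
    rec <- assemble_gene(fake_query, list(a), "s", "+")
    ind <- extract_indels(rec, fake_query)
    if (nrow(ind) == 1 && ind$kind == kind && ind$length_bp == len &&
        ind$exon_index == 1L) ok <- ok + 1
  }
  expect_equal(ok, n_trials)
})
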