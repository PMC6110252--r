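# Synthetic genome generator: determinism, ground truth, composition.

test_that("the synthetic query model satisfies the gene-model contract", {
  q <- fixture_query()
  expect_s3_class(q, "query_gene")
  expect_equal(nchar(q$cds) %% 3, 0)
  expect_equal(sum(nchar(q$exons)), nchar(q$cds))
  expect_false(grepl("*", q$protein, fixed = TRUE))
  expect_identical(translate_cds(q$cds, 0), paste0(q$protein, "*"))
})

test_that("simulation is deterministic under the seed", {
  q <- fixture_query(); nb <- fixture_neighbors()
  s1 <- small_sim("defective_frameshift", seed = 41)
  s2 <- small_sim("defective_frameshift", seed = 41)
  s3 <- small_sim("defective_frameshift", seed = 42)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$genome, s3$genome))
})

test_that("a panel covers all states and re-simulates byte-identically", {
  q <- fixture_query(); nb <- fixture_neighbors()
  p1 <- simulate_panel(q, nb, seed = 5, background_len = 40000L,
                       neighbor_gap = 3000L)
  p2 <- simulate_panel(q, nb, seed = 5, background_len = 40000L,
                       neighbor_gap = 3000L)
  expect_length(p1$genomes, 8)
  expect_equal(nrow(p1$truth_table), 8)
  expect_setequal(p1$truth_table$state, gene_states())
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(unlist(p1$genomes), f1)
  write_fasta(unlist(p2$genomes), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted gene spans and strand are recorded faithfully", {
  q <- fixture_query()
  for (strand in c("+", "-")) {
    sim <- small_sim(gene_state_spec("intact", strand = strand), seed = 43)
    tr <- sim$truth
    expect_identical(tr$strand, strand)
    gs <- tr$gene$gene_span
    planted <- substr(sim$genome[[1]], gs[1] + 1, gs[2])
    # first exon sequence is recoverable from the recorded exon span
    ex1 <- tr$gene$exon_spans[1, ]
    seq1 <- substr(sim$genome[[1]], ex1[1] + 1, ex1[2])
    if (strand == "-") seq1 <- reverse_complement(seq1)
    expect_identical(seq1, q$exons[[1L]])
    expect_equal(nchar(planted), gs[2] - gs[1])
  }
})

test_that("background composition tracks the requested GC content", {
  q <- fixture_query(); nb <- fixture_neighbors()
  sim <- simulate_genome(q, nb, "region_missing", seed = 44,
                         background_len = 100000L, gc = 0.50)
  s <- strsplit(sim$genome[[1]], "")[[1]]
  gc_obs <- mean(s %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.50), 0.02)
})

test_that("mutation specifications are validated", {
  q <- fixture_query(); nb <- fixture_neighbors()
  bad <- gene_state_spec("defective_frameshift", mutations = data.frame(
    exon_index = 2L, kind = "del", length_bp = 7L,
    offset_in_exon = 10000L))
  expect_error(small_sim(bad, seed = 45), "outside exon")
  expect_error(gene_state_spec("defective_frameshift", mutations = data.frame(
    exon_index = 2L, kind = "bogus", length_bp = 7L, offset_in_exon = 5L)))
  expect_error(gene_state_spec("no_such_state"))
})

test_that("default mutation sets realize their states in the truth record", {
  tr <- small_sim("defective_frameshift", seed = 46)$truth
  expect_identical(tr$expected_call, "defective")
  expect_equal(nrow(tr$mutations), 1)
  expect_identical(tr$mutations$kind, "del")
  expect_equal(tr$mutations$length_bp, 7L)
  expect_equal(tr$mutations$exon_index, 2L)
  tr2 <- small_sim("partial_tm", seed = 47)$truth
  expect_identical(tr2$mutations$kind, "del")
  expect_equal(tr2$mutations$length_bp %% 3L, 0L)  # in-frame by construction
  tr3 <- small_sim("region_missing", seed = 48)$truth
  expect_identical(tr3$expected_call, "not_determined")
  expect_false(any(tr3$plant_neighbors))
})

test_that("back-translation is faithful to the protein", {
  set.seed(49)
  prot <- paste(sample(aa20, 120, TRUE), collapse = "")
  cds <- back_translate(prot)
  expect_identical(translate_cds(cds, 0), paste0(prot, "*"))
})

test_that("a panel YAML file round-trips into specs", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 9",
               "background_len: 40000",
               "states:",
               "  - intact",
               "  - state: defective_frameshift",
               "    strand: '-'"), f)
  args <- read_panel_yaml(f)
  expect_length(args$states, 2)
  expect_identical(args$states[[2]]$strand, "-")
  expect_equal(args$seed, 9)
})
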