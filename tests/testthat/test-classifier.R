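# Functionality classification: decision table, rule order, contracts.

test_that("every evidence combination maps to exactly one matching call", {
  # independent restatement of the four rules, evaluated over the full
  # predicate grid and compared with the classifier
  expected_call <- function(too_short, nbr, has_stop, has_n_or_missing, tm7) {
    if (too_short) { if (nbr == "both") "absent" else "not_determined" }
    else if (has_stop) "defective"
    else if (has_n_or_missing) "partial"
    else if (tm7) "intact"
    else "partial"
  }
  params <- search_params()
  grid <- expand.grid(too_short = c(TRUE, FALSE),
                      nbr = c("both", "one", "none"),
                      has_stop = c(TRUE, FALSE),
                      has_n = c(TRUE, FALSE),
                      has_missing = c(TRUE, FALSE),
                      tm7 = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    syn <- switch(g$nbr, both = mock_synteny(TRUE, TRUE),
                  one = mock_synteny(TRUE, FALSE),
                  none = mock_synteny(FALSE, FALSE))
    if (g$too_short) {
      # no reconstruction exists; stop/N/missing/tm predicates are vacuous
      cl <- classify_functionality(empty_loci(), synteny_result = syn,
                                   params = params)
    } else {
      ev <- mock_evidence(g$has_stop, g$has_n, g$has_missing)
      tm <- if (!g$has_stop && !g$has_n && !g$has_missing)
        (if (g$tm7) 7L else 5L) else NULL
      cl <- classify_functionality(mock_loci(), ev$recon, ev$diag,
                                   tm_count = tm, synteny_result = syn,
                                   params = params)
    }
    exp <- expected_call(g$too_short, g$nbr, g$has_stop,
                         g$has_n || g$has_missing, g$tm7)
    expect_identical(cl$call, exp,
                     info = paste(capture.output(print(g)), collapse = " "))
    expect_true(cl$call %in% c("intact", "partial", "defective", "absent",
                               "not_determined"))
  }
})

test_that("the five canonical evidence patterns give the documented calls", {
  p <- search_params()
  # no loci, both neighbors found -> absent
  expect_identical(classify_functionality(
    empty_loci(), synteny_result = mock_synteny(TRUE, TRUE), params = p)$call,
    "absent")
  # no loci, neighbors missing -> not_determined
  expect_identical(classify_functionality(
    empty_loci(), synteny_result = mock_synteny(FALSE, FALSE), params = p)$call,
    "not_determined")
  # frameshift + premature stop -> defective
  ev <- mock_evidence(TRUE, FALSE, FALSE)
  expect_identical(classify_functionality(
    mock_loci(), ev$recon, ev$diag, synteny_result = NULL, params = p)$call,
    "defective")
  # complete N-free CDS with 7 helices -> intact
  ev <- mock_evidence(FALSE, FALSE, FALSE)
  expect_identical(classify_functionality(
    mock_loci(), ev$recon, ev$diag, tm_count = 7L, params = p)$call,
    "intact")
  # exon 1 unmapped, rest clean -> partial
  ev <- mock_evidence(FALSE, FALSE, TRUE)
  expect_identical(classify_functionality(
    mock_loci(), ev$recon, ev$diag, params = p)$call,
    "partial")
})

test_that("defectiveness outranks partialness when both apply", {
  ev <- mock_evidence(TRUE, TRUE, TRUE)  # stop + N + missing exon
  cl <- classify_functionality(mock_loci(), ev$recon, ev$diag,
                               params = search_params())
  expect_identical(cl$call, "defective")
})

test_that("relaxing the both-neighbors requirement licenses one-sided absence", {
  p1 <- search_params()
  p2 <- search_params(require_both_neighbors = FALSE)
  syn <- mock_synteny(TRUE, FALSE)
  expect_identical(classify_functionality(empty_loci(), synteny_result = syn,
                                          params = p1)$call, "not_determined")
  expect_identical(classify_functionality(empty_loci(), synteny_result = syn,
                                          params = p2)$call, "absent")
})

test_that("contract violations are rejected", {
  ev <- mock_evidence(FALSE, FALSE, FALSE)
  # evidence supplied although loci are too short
  expect_error(classify_functionality(empty_loci(), ev$recon, ev$diag,
                                      params = search_params()),
               "too short")
  # usable loci but no reconstruction
  expect_error(classify_functionality(mock_loci(), params = search_params()),
               "missing")
  # clean reconstruction but no TM count
  expect_error(classify_functionality(mock_loci(), ev$recon, ev$diag,
                                      tm_count = NULL, params = search_params()),
               "tm_count")
})

test_that("planted damage moves calls in the expected direction", {
  # monotone damage: a nonsense plant turns the intact fixture defective;
  # deleting the gene while keeping neighbors turns it absent
  q <- fixture_query()
  p <- search_params()
  run_call <- function(state, seed) {
    sim <- small_sim(state, seed = seed)
    loci <- find_loci(sim$genome, q$protein, p)
    if (is_too_short(loci, p)) {
      syn <- check_flanking(sim$genome, fixture_neighbors(), p)
      return(classify_functionality(loci, synteny_result = syn, params = p)$call)
    }
    rec <- reconstruct_gene(sim$genome, loci[1, ], q, p)
    d <- diagnose_orf(rec, q)
    tm <- if (nrow(d$stops) == 0 && !d$has_n && !length(rec$missing_exons))
      count_tm_helices(translate_cds(rec$assembled_cds, 0)) else NULL
    classify_functionality(loci, rec, d, tm_count = tm, params = p)$call
  }
  expect_identical(run_call("intact", 81), "intact")
  expect_identical(run_call("defective_nonsense", 81), "defective")
  expect_identical(run_call("absent_with_synteny", 81), "absent")
})
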