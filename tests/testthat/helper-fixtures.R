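# Shared fixtures and independent oracles for the test suite.

## Brute-force affine-gap local alignment (Gotoh), pure R: the independent
## oracle for the package's alignment engine.  A gap of length k costs
## gap_open + k * gap_extend.
ref_affine_local_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
    F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]], E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- get("BLOSUM62", envir = env)
    }
    cache
  }
})

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## shared (memoized) synthetic query model and neighbor proteins
fixture_query <- local({
  q <- NULL
  function() {
    if (is.null(q)) q <<- synthetic_query_gene(101L)
    q
  }
})

fixture_neighbors <- local({
  nb <- NULL
  function() {
    if (is.null(nb)) nb <<- synthetic_neighbor_proteins(202L)
    nb
  }
})

## the designed seven-helix toy protein: 21-aa leucine blocks separated by
## 15-arginine linkers (and flanked by 15 arginines each side)
toy_seven_tm_protein <- function(n_blocks = 7L, block_len = 21L, linker_len = 15L) {
  linker <- strrep("R", linker_len)
  paste0(linker,
         paste(rep(strrep("L", block_len), n_blocks), collapse = linker),
         linker)
}

## minimal mock reconstruction/diagnosis pair for classifier decision-table
## tests (the classifier only consults the fields built here)
mock_evidence <- function(has_stop, has_n, has_missing) {
  recon <- structure(list(
    gene_name = "g", scaffold_id = "s", strand = "+",
    missing_exons = if (has_missing) 1L else integer(0),
    n_intervals = if (has_n) cbind(start = 0L, end = 5L)
    else matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))),
    class = "gene_reconstruction")
  diag <- structure(list(
    indels = data.frame(),
    stops = if (has_stop)
      data.frame(exon_index = 2L, codon_index = 10L, caused_by_frameshift = TRUE)
    else data.frame(exon_index = integer(0), codon_index = integer(0),
                    caused_by_frameshift = logical(0)),
    has_frameshift = has_stop, has_n = has_n),
    class = "orf_diagnosis")
  list(recon = recon, diag = diag)
}

## a one-row locus table that counts as usable (span >= min_hit_nt)
mock_loci <- function(span = 500L) {
  data.frame(scaffold_id = "s", strand = "+", start = 0L, end = span,
             frame = 0L, score = 500, qstart = 0L, qend = 100L,
             nt_span_len = span, q_coverage = 0.9, n_hits = 1L,
             stringsAsFactors = FALSE)
}

## a synteny result with chosen found flags
mock_synteny <- function(found1, found2) {
  structure(list(gene_name = "g", neighbors = data.frame(
    neighbor = c("NbrA", "NbrB"), found = c(found1, found2),
    scaffold_id = NA_character_, start = NA_integer_, end = NA_integer_,
    score = NA_real_, q_coverage = NA_real_, stringsAsFactors = FALSE)),
    class = "synteny_result")
}

## small fast simulation settings (short neighbor gap, small background)
small_sim <- function(spec, seed, query = fixture_query(),
                      neighbors = fixture_neighbors()) {
  simulate_genome(query, neighbors, spec, seed = seed,
                  background_len = 40000L, neighbor_gap = 3000L)
}
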