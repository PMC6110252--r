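# Alignment engines shared by the search and exon-mapping stages.
#
# Protein local alignment and nucleotide semi-global alignment are both
# affine-gap dynamic programming, delegated to Biostrings::pairwiseAlignment.
# A gap of length k costs gap_open + k * gap_extend (BLAST convention).

## BLOSUM62 with X neutralized: X (the translation of any N-containing
## codon) scores 0 against everything, so unsequenced bases neither help
## nor hurt an alignment.
.matrix_cache <- new.env(parent = emptyenv())

protein_scoring_matrix <- function(matrix_name = "BLOSUM62") {
  if (!is.null(.matrix_cache[[matrix_name]])) return(.matrix_cache[[matrix_name]])
  env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = env)
  m <- get(matrix_name, envir = env)
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0
    m[, "X"] <- 0
  }
  .matrix_cache[[matrix_name]] <- m
  m
}

## ACGTN scoring: N scores 0 against everything (including N), so N runs
## are alignment-neutral, mirroring the X convention for proteins.
nt_scoring_matrix <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Optimal local protein alignment with affine gaps
#'
#' Smith-Waterman local alignment of two amino-acid sequences under an
#' affine gap penalty (a gap of length \eqn{k} costs
#' \code{gap_open + k * gap_extend}).  The score of the empty alignment is
#' 0, so two sequences with no positively scoring residue pair align with
#' score 0.
#'
#' @param a,b Amino-acid strings (may contain \code{X}, which scores 0
#'   against everything).
#' @param params A \code{\link{search_params}} object supplying
#'   \code{matrix_name}, \code{gap_open} and \code{gap_extend}.
#' @return List with \code{score}, gapped strings \code{aligned_a} and
#'   \code{aligned_b}, and 0-based half-open spans \code{a_span} and
#'   \code{b_span} of the aligned segments.
#' @export
local_align_protein <- function(a, b, params = search_params()) {
  stopifnot(nzchar(a), nzchar(b))
  m <- protein_scoring_matrix(params$matrix_name)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = m,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = 0, aligned_a = "", aligned_b = "",
                a_span = c(0L, 0L), b_span = c(0L, 0L)))
  }
  list(score = sc,
       aligned_a = as.character(Biostrings::pattern(pa)),
       aligned_b = as.character(Biostrings::subject(pa)),
       a_span = c(BiocGenerics::start(Biostrings::pattern(pa)) - 1L,
                  BiocGenerics::end(Biostrings::pattern(pa))),
       b_span = c(BiocGenerics::start(Biostrings::subject(pa)) - 1L,
                  BiocGenerics::end(Biostrings::subject(pa))))
}

## Semi-global nucleotide alignment: pattern end-to-end, subject local.
## Returns NULL when pairwiseAlignment cannot produce an alignment.
align_semiglobal_nt <- function(pattern, subject, params) {
  m <- nt_scoring_matrix(params$nt_match, params$nt_mismatch)
  pa <- Biostrings::pairwiseAlignment(
    pattern, subject, type = "global-local", substitutionMatrix = m,
    gapOpening = params$nt_gap_open, gapExtension = params$nt_gap_extend)
  ap <- as.character(Biostrings::pattern(pa))
  at <- as.character(Biostrings::subject(pa))
  list(score = Biostrings::score(pa),
       aligned_query = ap, aligned_target = at,
       target_span = c(BiocGenerics::start(Biostrings::subject(pa)) - 1L,
                       BiocGenerics::end(Biostrings::subject(pa))))
}

## fraction of alignment columns that are exact matches (gaps and N/X
## columns count as non-matches)
alignment_identity <- function(aligned_a, aligned_b) {
  if (!nzchar(aligned_a)) return(0)
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  sum(ca == cb & ca != "-" & ca != "N" & ca != "X") / length(ca)
}
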