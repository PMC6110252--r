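# Translated homology search: the pipeline's TblastN stand-in.
#
# A protein query is searched against all six reading frames of every
# scaffold by exact amino-acid k-mer seeding, ungapped diagonal extension
# (a BLAST-style two-stage filter), and full affine-gap local alignment of
# the query against the seeded window.  Hits on the same scaffold and
# strand within merge_distance are merged into loci, so the exon-wise hits
# of a multi-exon gene separated by introns reunite into one locus.

#' Search and classification parameters
#'
#' One parameter bundle is shared by the search, exon-mapping, synteny and
#' classification stages.  Defaults follow BLAST-like conventions:
#' BLOSUM62 with affine gap costs 11/1 for protein alignment, and an
#' intron-tolerant merge distance so exon hits of one gene coalesce.
#'
#' @param seed_k Amino-acid seed word size (exact match), >= 2.
#' @param matrix_name Protein substitution matrix name (a matrix shipped
#'   with \pkg{Biostrings}), default \code{"BLOSUM62"}.
#' @param gap_open,gap_extend Affine gap costs for protein alignment.
#' @param min_hit_score Minimum local alignment score for a hit to be kept
#'   (default 80; by Karlin-Altschul statistics a raw BLOSUM62 score of 80
#'   has an expectation well below 0.01 on a multi-megabase six-frame
#'   search space, so chance hits on non-homologous sequence are rare).
#' @param min_ungapped_score Minimum ungapped diagonal-segment score for a
#'   seed cluster to be passed to full alignment (an exact amino-acid
#'   4-mer already scores about 20; 40 requires genuine flanking
#'   similarity).
#' @param merge_distance Hits on one scaffold/strand closer than this (bp)
#'   merge into a single locus.
#' @param min_hit_nt Loci spanning fewer than this many base pairs count as
#'   "too short" (default 100, the span below which a locus does not count
#'   as evidence that the gene is present).
#' @param nt_match,nt_mismatch,nt_gap_open,nt_gap_extend Nucleotide
#'   alignment scores used by the exon mapper.
#' @param exon_min_score_frac An exon counts as found when its alignment
#'   score reaches this fraction of the exon's self-alignment score.
#' @param exon_min_identity ...and its column identity reaches this floor.
#' @param pad Bases added on each side of a locus when extending the
#'   searched window to capture the whole coding region (default 50 kb).
#' @param coverage_floor Minimum query coverage for a flanking-gene
#'   (synteny) hit to count as "found".
#' @param require_both_neighbors Require both flanking genes for an
#'   "absent" call (default TRUE); set FALSE to accept one.
#' @return Object of class \code{search_params}.
#' @export
search_params <- function(seed_k = 4L,
                          matrix_name = "BLOSUM62",
                          gap_open = 11,
                          gap_extend = 1,
                          min_hit_score = 80,
                          min_ungapped_score = 40,
                          merge_distance = 20000L,
                          min_hit_nt = 100L,
                          nt_match = 2,
                          nt_mismatch = -3,
                          nt_gap_open = 5,
                          nt_gap_extend = 2,
                          exon_min_score_frac = 0.4,
                          exon_min_identity = 0.5,
                          pad = 50000L,
                          coverage_floor = 0.3,
                          require_both_neighbors = TRUE) {
  stopifnot(seed_k >= 2L, gap_open >= 0, gap_extend >= 0,
            min_hit_nt >= 1L, merge_distance >= 0L, pad >= 0L,
            exon_min_score_frac > 0, exon_min_identity >= 0,
            coverage_floor >= 0, coverage_floor <= 1)
  structure(as.list(environment()), class = "search_params")
}

## empty LocusHit table (the shape of every find_loci result)
empty_loci <- function() {
  data.frame(scaffold_id = character(0), strand = character(0),
              start = integer(0), end = integer(0), frame = integer(0),
              score = numeric(0), qstart = integer(0), qend = integer(0),
              nt_span_len = integer(0), q_coverage = numeric(0),
              n_hits = integer(0), stringsAsFactors = FALSE)
}

## exact k-mer seed positions of `query` in `subject` (both aa strings);
## returns integer matrix (qpos, spos), 0-based; seeds containing X or *
## are skipped.
kmer_seeds <- function(query, subject, k) {
  nq <- nchar(query); ns <- nchar(subject)
  if (nq < k || ns < k) return(cbind(qpos = integer(0), spos = integer(0)))
  qk <- substring(query, 1:(nq - k + 1L), k:nq)
  ok <- !grepl("[X*]", qk)
  qpos_by_kmer <- split(which(ok) - 1L, qk[ok])
  sk <- substring(subject, 1:(ns - k + 1L), k:ns)
  hit <- which(sk %in% names(qpos_by_kmer))
  if (!length(hit)) return(cbind(qpos = integer(0), spos = integer(0)))
  qlists <- qpos_by_kmer[sk[hit]]
  cbind(qpos = unlist(qlists, use.names = FALSE),
        spos = rep(hit - 1L, lengths(qlists)))
}

## Ungapped extension of all seeds on one diagonal: best-scoring contiguous
## segment on the diagonal (Kadane), computed once per diagonal.
## Returns NULL or list(qstart, qend, sstart, send, score), 0-based half-open.
extend_diagonal <- function(qchars, schars, diag, scores_matrix) {
  nq <- length(qchars); ns <- length(schars)
  qlo <- max(0L, -diag); qhi <- min(nq - 1L, ns - 1L - diag)
  if (qhi < qlo) return(NULL)
  qi <- qlo:qhi
  v <- scores_matrix[cbind(qchars[qi + 1L], schars[qi + diag + 1L])]
  # maximal-sum segment via prefix sums (vectorized Kadane)
  cs <- cumsum(v)
  pre <- cummin(c(0, cs[-length(cs)]))   # min prefix strictly before each t
  gain <- cs - pre
  best <- max(gain)
  if (best <= 0) return(NULL)
  j <- which.max(gain)
  i <- which(c(0, cs)[seq_len(j)] == pre[j])[1]
  list(qstart = qlo + i - 1L, qend = qlo + j,
       sstart = qlo + i - 1L + diag, send = qlo + j + diag,
       score = best)
}

## search one translated frame; returns hit rows in aa coordinates
search_frame <- function(query, frame_aa, params, scores_matrix) {
  seeds <- kmer_seeds(query, frame_aa, params$seed_k)
  if (!nrow(seeds)) return(NULL)
  qchars <- strsplit(query, "", fixed = TRUE)[[1]]
  schars <- strsplit(frame_aa, "", fixed = TRUE)[[1]]
  diags <- unique(seeds[, "spos"] - seeds[, "qpos"])
  segs <- list()
  for (d in diags) {
    seg <- extend_diagonal(qchars, schars, d, scores_matrix)
    if (!is.null(seg) && seg$score >= params$min_ungapped_score)
      segs[[length(segs) + 1L]] <- seg
  }
  if (!length(segs)) return(NULL)
  sstart <- vapply(segs, `[[`, integer(1), "sstart")
  send <- vapply(segs, `[[`, integer(1), "send")
  ord <- order(sstart)
  sstart <- sstart[ord]; send <- send[ord]
  # cluster segments along the subject; gaps beyond the query length in aa
  # start a new candidate window
  gap_aa <- max(200L, nchar(query))
  grp <- cumsum(c(1L, as.integer(sstart[-1] > cummax(send)[-length(send)] + gap_aa)))
  hits <- list()
  nq <- nchar(query)
  for (g in unique(grp)) {
    w0 <- max(0L, min(sstart[grp == g]) - nq - 32L)
    w1 <- min(nchar(frame_aa), max(send[grp == g]) + nq + 32L) + 1L
    window <- substr(frame_aa, w0 + 1L, w1)
    al <- local_align_protein(query, window, params)
    if (al$score >= params$min_hit_score) {
      hits[[length(hits) + 1L]] <- data.frame(
        aa_start = w0 + al$b_span[1], aa_end = w0 + al$b_span[2],
        qstart = al$a_span[1], qend = al$a_span[2],
        score = al$score, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

#' Locate candidate gene loci by translated homology search
#'
#' Searches a protein query against all six reading frames of every
#' scaffold (exact amino-acid k-mer seeds, ungapped diagonal filtering,
#' then full affine-gap local alignment), and merges hits on the same
#' scaffold and strand within \code{merge_distance} into loci.  A
#' multi-exon gene typically yields one hit per exon; merging reunites
#' them across introns.
#'
#' @param genome Named character vector of scaffold sequences (ACGTN), as
#'   returned by \code{\link{read_fasta}}.
#' @param protein_query Amino-acid string.
#' @param params \code{\link{search_params}}.
#' @return Data frame of loci with columns \code{scaffold_id},
#'   \code{strand}, \code{start}, \code{end} (forward-strand 0-based
#'   half-open), \code{frame} (frame of the best constituent hit),
#'   \code{score} (best constituent score), \code{qstart}, \code{qend}
#'   (0-based half-open union span on the query), \code{nt_span_len},
#'   \code{q_coverage} (fraction of query residues covered by the union of
#'   constituent hit spans) and \code{n_hits}; sorted by descending score,
#'   ties broken by (scaffold_id, start).  Zero rows when nothing is found.
#' @export
find_loci <- function(genome, protein_query, params = search_params()) {
  stopifnot(length(genome) >= 1L, nzchar(protein_query))
  scores_matrix <- protein_scoring_matrix(params$matrix_name)
  rows <- list()
  for (sid in names(genome)) {
    s <- genome[[sid]]
    L <- nchar(s)
    if (L < 3L) next
    rc <- reverse_complement(s)
    for (strand in c("+", "-")) {
      src <- if (strand == "+") s else rc
      for (f in 0:2) {
        if (nchar(src) < f + 3L) next
        aa <- translate_cds(src, f)
        h <- search_frame(protein_query, aa, params, scores_matrix)
        if (is.null(h)) next
        # aa coords -> nt coords on the translated strand
        nt0 <- f + 3L * h$aa_start
        nt1 <- f + 3L * (h$aa_end + 1L)
        if (strand == "-") { tmp <- nt0; nt0 <- L - nt1; nt1 <- L - tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold_id = sid, strand = strand,
          start = as.integer(nt0), end = as.integer(nt1), frame = f,
          score = h$score, qstart = h$qstart, qend = h$qend + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_loci())
  hits <- do.call(rbind, rows)
  merge_hits_into_loci(hits, nchar(protein_query), params)
}

## merge hit rows into loci per scaffold/strand within merge_distance
merge_hits_into_loci <- function(hits, query_len, params) {
  out <- list()
  for (key in unique(paste(hits$scaffold_id, hits$strand))) {
    h <- hits[paste(hits$scaffold_id, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      h$start[-1] > cummax(h$end)[-nrow(h)] + params$merge_distance)))
    for (g in unique(grp)) {
      hg <- h[grp == g, , drop = FALSE]
      best <- which.max(hg$score)
      qiv <- union_interval_length(hg$qstart, hg$qend)
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = hg$scaffold_id[1], strand = hg$strand[1],
        start = min(hg$start), end = max(hg$end),
        frame = hg$frame[best], score = max(hg$score),
        qstart = min(hg$qstart), qend = max(hg$qend),
        nt_span_len = max(hg$end) - min(hg$start),
        q_coverage = qiv / query_len,
        n_hits = nrow(hg), stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(-loci$score, loci$scaffold_id, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

## total length of the union of 0-based half-open intervals
union_interval_length <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e) { tot <- tot + (cur_e - cur_s); cur_s <- starts[i]; cur_e <- ends[i] }
    else cur_e <- max(cur_e, ends[i])
  }
  tot + (cur_e - cur_s)
}

#' Is a set of loci absent or too short to count as a gene?
#'
#' TRUE when there is no locus at all, or when every locus spans fewer
#' than \code{min_hit_nt} base pairs (default 100).  This is the trigger
#' for the synteny-based absence check.
#'
#' @param loci Data frame from \code{\link{find_loci}}.
#' @param params \code{\link{search_params}}.
#' @return Logical scalar.
#' @export
is_too_short <- function(loci, params = search_params()) {
  nrow(loci) == 0L || all(loci$nt_span_len < params$min_hit_nt)
}

#' Write a locus table to TSV
#'
#' @param loci Data frame from \code{\link{find_loci}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_loci_tsv <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
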