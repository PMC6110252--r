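# Exon mapping and gene reconstruction.
#
# Each query exon is aligned to the (5'/3'-extended) candidate locus with a
# semi-global alignment: the exon end-to-end, the target locally.  Found
# exons are stitched, in gene order and gene orientation, into the
# reconstructed coding sequence that the ORF diagnostics operate on.
# Alignment is accelerated by nucleotide k-mer seeding of candidate
# windows; a full-region alignment is the fallback when no seed exists.

## k-mer index of a region: environment mapping k-mer -> 0-based positions
nt_kmer_index <- function(region, k = 11L) {
  n <- nchar(region)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  if (n < k) return(structure(list(env = idx, k = k, n = n), class = "kmer_index"))
  kmers <- substring(region, 1:(n - k + 1L), k:n)
  keep <- !grepl("N", kmers, fixed = TRUE)
  pos <- split((which(keep) - 1L), kmers[keep])
  idx <- list2env(pos, hash = TRUE, parent = emptyenv())
  structure(list(env = idx, k = k, n = n), class = "kmer_index")
}

## candidate target windows for an exon, from seed diagonals; returns a
## list of c(start, end) 0-based half-open windows on the region
seed_windows <- function(exon_seq, index, max_windows = 5L, margin = 150L) {
  k <- index$k
  ne <- nchar(exon_seq)
  if (ne < k || index$n < k) return(list())
  qpos <- seq(1L, ne - k + 1L, by = 4L)
  kmers <- substring(exon_seq, qpos, qpos + k - 1L)
  diags <- integer(0)
  for (i in seq_along(kmers)) {
    sp <- index$env[[kmers[i]]]
    if (!is.null(sp)) diags <- c(diags, sp - (qpos[i] - 1L))
  }
  if (!length(diags)) return(list())
  diags <- sort(diags)
  grp <- cumsum(c(1L, as.integer(diff(diags) > ne)))
  cnt <- tabulate(grp)
  ord <- order(-cnt)[seq_len(min(max_windows, max(grp)))]
  lapply(ord, function(g) {
    d <- diags[grp == g]
    c(max(0L, min(d) - margin), min(index$n, max(d) + ne + margin))
  })
}

#' Align one query exon to a target region
#'
#' Semi-global alignment: the exon is aligned end-to-end against a local
#' stretch of the region.  The exon counts as found when its score reaches
#' \code{exon_min_score_frac} of the exon's self-alignment score and the
#' column identity reaches \code{exon_min_identity}; both thresholds allow
#' short exons in poor-quality (N-rich) regions to legitimately fail.
#'
#' @param exon_seq Exon nucleotide string.
#' @param region Target nucleotide string (a scaffold window, already
#'   reverse-complemented by the caller for minus-strand genes).
#' @param region_offset Offset added to the reported span (use the window
#'   start to obtain scaffold coordinates for plus-strand regions).
#' @param params \code{\link{search_params}}.
#' @param index Optional precomputed \code{nt_kmer_index} of \code{region}.
#' @return List of class \code{exon_alignment}: \code{found},
#'   \code{score}, \code{identity}, \code{region_span} and \code{span}
#'   (0-based half-open; \code{span} = \code{region_span + region_offset}),
#'   gapped \code{aligned_query} / \code{aligned_target}, and
#'   \code{exon_index} (filled by the caller).
#' @export
map_exon <- function(exon_seq, region, region_offset = 0L,
                     params = search_params(), index = NULL) {
  stopifnot(nzchar(region), nzchar(exon_seq))
  if (is.null(index)) index <- nt_kmer_index(region)
  wins <- seed_windows(exon_seq, index)
  if (!length(wins)) wins <- list(c(0L, nchar(region)))
  best <- NULL
  for (w in wins) {
    al <- align_semiglobal_nt(exon_seq, substr(region, w[1] + 1L, w[2]), params)
    al$target_span <- al$target_span + w[1]
    if (is.null(best) || al$score > best$score) best <- al
  }
  self_score <- params$nt_match * nchar(exon_seq)
  identity <- alignment_identity(best$aligned_query, best$aligned_target)
  found <- best$score >= params$exon_min_score_frac * self_score &&
    identity >= params$exon_min_identity
  structure(list(
    exon_index = NA_integer_,
    found = found,
    score = best$score,
    identity = identity,
    region_span = best$target_span,
    span = best$target_span + region_offset,
    aligned_query = if (found) best$aligned_query else NA_character_,
    aligned_target = if (found) best$aligned_target else NA_character_),
    class = "exon_alignment")
}

#' Extend a locus window in both directions
#'
#' Pads the locus span 5' and 3' (clamped to the scaffold) so that exons
#' falling outside the original homology hits can still be captured.
#'
#' @param locus One-row data frame (or list) with \code{start} and
#'   \code{end}.
#' @param scaffold_len Scaffold length.
#' @param pad Bases added on each side (default 50000).
#' @return Integer vector \code{c(start, end)}, 0-based half-open.
#' @export
extend_window <- function(locus, scaffold_len, pad = 50000L) {
  stopifnot(pad >= 0L)
  c(max(0L, as.integer(locus$start) - as.integer(pad)),
    min(as.integer(scaffold_len), as.integer(locus$end) + as.integer(pad)))
}

#' Stitch exon alignments into a gene reconstruction
#'
#' Concatenates the degapped target sequences of found exons, in gene
#' order, into the reconstructed coding sequence.  Exon spans must be
#' strictly increasing and non-overlapping along the gene orientation;
#' conflicting exons are resolved by dropping the lower-identity exon to
#' missing.
#'
#' @param query \code{\link{query_gene_model}}.
#' @param exon_alignments List of \code{exon_alignment} (one per query
#'   exon, in exon order, all in gene-orientation region coordinates).
#' @param scaffold_id Scaffold the reconstruction lives on.
#' @param strand \code{"+"} or \code{"-"}.
#' @return Object of class \code{gene_reconstruction}: the assembled CDS,
#'   per-exon alignments, \code{missing_exons}, N-run intervals on the
#'   assembled CDS, and per-exon CDS spans (\code{exon_cds_spans}).
#'   Errors with class \code{pseudoscan_no_reconstruction} when every exon
#'   is missing.
#' @export
assemble_gene <- function(query, exon_alignments, scaffold_id, strand = "+") {
  stopifnot(length(exon_alignments) == length(query$exons),
            strand %in% c("+", "-"))
  for (i in seq_along(exon_alignments)) exon_alignments[[i]]$exon_index <- i
  # resolve out-of-order / overlapping exon spans: iteratively drop the
  # lower-identity exon of the first conflicting pair
  repeat {
    fi <- which(vapply(exon_alignments, `[[`, logical(1), "found"))
    if (length(fi) < 2L) break
    spans <- t(vapply(exon_alignments[fi], `[[`, integer(2), "region_span"))
    conflict <- which(spans[-1, 1] < spans[-nrow(spans), 2])
    if (!length(conflict)) break
    j <- conflict[1]
    pair <- fi[c(j, j + 1L)]
    ids <- vapply(exon_alignments[pair], `[[`, numeric(1), "identity")
    drop <- pair[which.min(ids)]
    warning(sprintf("exon %d dropped to missing: span conflicts with a neighboring exon",
                    drop))
    exon_alignments[[drop]]$found <- FALSE
  }
  found <- vapply(exon_alignments, `[[`, logical(1), "found")
  if (!any(found)) {
    stop(structure(class = c("pseudoscan_no_reconstruction", "error", "condition"),
                   list(message = paste0(query$gene_name,
                                         ": no exon could be mapped; no reconstruction"),
                        call = sys.call(-1))))
  }
  pieces <- vapply(exon_alignments[found], function(a)
    gsub("-", "", a$aligned_target, fixed = TRUE), character(1))
  assembled <- paste(pieces, collapse = "")
  ends <- cumsum(nchar(pieces))
  exon_cds_spans <- cbind(start = c(0L, ends[-length(ends)]), end = ends)
  rownames(exon_cds_spans) <- which(found)
  structure(list(gene_name = query$gene_name,
                 scaffold_id = scaffold_id,
                 strand = strand,
                 exon_alignments = exon_alignments,
                 assembled_cds = assembled,
                 missing_exons = which(!found),
                 n_intervals = find_n_runs(assembled, 1L),
                 exon_cds_spans = exon_cds_spans),
            class = "gene_reconstruction")
}

#' @export
print.gene_reconstruction <- function(x, ...) {
  cat(sprintf("gene_reconstruction %s on %s (%s): %d/%d exon(s) found, CDS %d nt, %d N-run(s)\n",
              x$gene_name, x$scaffold_id, x$strand,
              length(x$exon_alignments) - length(x$missing_exons),
              length(x$exon_alignments), nchar(x$assembled_cds),
              nrow(x$n_intervals)))
  invisible(x)
}

#' Reconstruct a gene at a locus
#'
#' Orchestrates the per-locus steps: extends the locus window, orients the
#' region along the gene (reverse complement for minus-strand loci), maps
#' every query exon, and stitches the result.  Exon spans are reported in
#' forward-strand scaffold coordinates regardless of strand.
#'
#' @param genome Named character vector of scaffolds.
#' @param locus One locus row from \code{\link{find_loci}}.
#' @param query \code{\link{query_gene_model}}.
#' @param params \code{\link{search_params}} (supplies \code{pad}).
#' @return A \code{gene_reconstruction} (see \code{\link{assemble_gene}}).
#' @export
reconstruct_gene <- function(genome, locus, query, params = search_params()) {
  sid <- as.character(locus$scaffold_id)
  scaffold <- genome[[sid]]
  if (is.null(scaffold)) stop("locus scaffold not in genome: ", sid)
  L <- nchar(scaffold)
  win <- extend_window(locus, L, params$pad)
  region <- substr(scaffold, win[1] + 1L, win[2])
  strand <- as.character(locus$strand)
  if (strand == "-") region <- reverse_complement(region)
  rlen <- nchar(region)
  index <- nt_kmer_index(region)
  als <- vector("list", length(query$exons))
  for (i in seq_along(query$exons)) {
    a <- map_exon(query$exons[[i]], region, region_offset = 0L,
                  params = params, index = index)
    a$exon_index <- i
    # convert the region-coordinate span to forward-strand scaffold coords
    rs <- a$region_span
    a$span <- if (strand == "+") win[1] + rs
    else c(win[1] + (rlen - rs[2]), win[1] + (rlen - rs[1]))
    als[[i]] <- a
  }
  assemble_gene(query, als, sid, strand)
}
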