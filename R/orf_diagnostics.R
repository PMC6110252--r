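# ORF diagnostics: indel bookkeeping, frameshift status, premature stops.
#
# Indels are read off the per-exon alignments (gap runs), positions are
# expressed on the query CDS, and the reconstructed CDS is translated in
# the query-anchored reading frame to find stop codons that appear before
# the query's terminal stop.  Frame is carried across contiguous found
# exons (so a frameshift in exon 3 can surface as a stop in exon 6); at a
# missing-exon junction the frame is re-anchored to the query, because the
# content of the missing exon is unknown and any carried shift would be
# speculative.

## Per-base annotation of the assembled CDS: for every target base, its
## query-CDS coordinate, cumulative indel shift (insertions +1, deletions
## -1) within its contiguous segment, exon index, and segment id.
annotate_bases <- function(reconstruction, query) {
  found <- which(vapply(reconstruction$exon_alignments, `[[`, logical(1), "found"))
  if (!length(found)) stop("annotate_bases: reconstruction has no found exon")
  seg_id <- cumsum(c(1L, as.integer(diff(found) > 1L)))
  q_pos <- integer(0); delta <- integer(0); exon_id <- integer(0); seg <- integer(0)
  for (k in seq_along(found)) {
    i <- found[k]
    a <- reconstruction$exon_alignments[[i]]
    cq <- strsplit(a$aligned_query, "", fixed = TRUE)[[1]]
    ct <- strsplit(a$aligned_target, "", fixed = TRUE)[[1]]
    qpos <- query$exon_cds_offsets[i]
    pend_del <- 0L
    for (j in seq_along(cq)) {
      if (cq[j] == "-") {            # insertion in target
        q_pos <- c(q_pos, qpos); delta <- c(delta, 1L - pend_del)
        exon_id <- c(exon_id, i); seg <- c(seg, seg_id[k]); pend_del <- 0L
      } else if (ct[j] == "-") {     # deletion: no target base
        pend_del <- pend_del + 1L; qpos <- qpos + 1L
      } else {
        q_pos <- c(q_pos, qpos); delta <- c(delta, -pend_del)
        exon_id <- c(exon_id, i); seg <- c(seg, seg_id[k])
        qpos <- qpos + 1L; pend_del <- 0L
      }
    }
  }
  shift <- integer(length(delta))
  for (s in unique(seg)) shift[seg == s] <- cumsum(delta[seg == s])
  list(q_pos = q_pos, shift = shift, exon_id = exon_id, seg = seg)
}

#' Extract indel records from a gene reconstruction
#'
#' One record per maximal gap run in each found exon's alignment.
#' Insertions are extra bases in the target relative to the query;
#' deletions are query bases absent from the target.  \code{cds_pos} is
#' the query-CDS coordinate of the alignment column where the gap run
#' begins.  Gap runs touching the first or last aligned column of an exon
#' are flagged \code{low_confidence} (alignment-edge uncertainty) rather
#' than dropped.
#'
#' @param reconstruction \code{gene_reconstruction}.
#' @param query \code{\link{query_gene_model}}.
#' @return Data frame with columns \code{exon_index}, \code{kind}
#'   (\code{"insertion"}/\code{"deletion"}), \code{length_bp},
#'   \code{cds_pos}, \code{low_confidence}, ordered 5' to 3'.
#' @export
extract_indels <- function(reconstruction, query) {
  found <- which(vapply(reconstruction$exon_alignments, `[[`, logical(1), "found"))
  if (!length(found)) stop("extract_indels: reconstruction has no found exon")
  rows <- list()
  for (i in found) {
    a <- reconstruction$exon_alignments[[i]]
    cq <- strsplit(a$aligned_query, "", fixed = TRUE)[[1]]
    ct <- strsplit(a$aligned_target, "", fixed = TRUE)[[1]]
    ncol <- length(cq)
    state <- ifelse(cq == "-", "insertion", ifelse(ct == "-", "deletion", "match"))
    r <- rle(state)
    col <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    qpos_at_col <- query$exon_cds_offsets[i] + cumsum(c(0L, (cq != "-")[-ncol]))
    for (t in seq_along(r$values)) {
      if (r$values[t] == "match") next
      rows[[length(rows) + 1L]] <- data.frame(
        exon_index = i, kind = r$values[t], length_bp = r$lengths[t],
        cds_pos = qpos_at_col[col[t]],
        low_confidence = col[t] == 1L || (col[t] + r$lengths[t] - 1L) == ncol,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(exon_index = integer(0), kind = character(0),
                      length_bp = integer(0), cds_pos = integer(0),
                      low_confidence = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$cds_pos, out$exon_index), , drop = FALSE]
}

#' Does a set of indels disrupt the reading frame?
#'
#' TRUE when, after some indel (walking 5' to 3'), the running sum of
#' signed indel lengths (insertions positive, deletions negative) is not a
#' multiple of 3.  In-frame indels (lengths divisible by 3) never trigger
#' it, and compensating indel pairs restore the frame downstream of the
#' compensation point.
#'
#' @param indels Data frame from \code{\link{extract_indels}} (ordered 5'
#'   to 3' by \code{cds_pos}).
#' @return Logical scalar.
#' @export
detect_frameshift <- function(indels) {
  if (nrow(indels) == 0L) return(FALSE)
  signed <- ifelse(indels$kind == "insertion", 1L, -1L) * indels$length_bp
  any(cumsum(signed) %% 3L != 0L)
}

#' Scan a reconstruction for premature stop codons
#'
#' Translates the assembled CDS in the query-anchored reading frame,
#' carrying the frame (and any indel-induced shift) across contiguous
#' found exons and re-anchoring after a missing exon.  Every stop codon
#' strictly before the query's terminal stop yields a record; codons
#' containing N translate to X and are never stops.
#'
#' @param reconstruction \code{gene_reconstruction}.
#' @param query \code{\link{query_gene_model}}.
#' @return Data frame with columns \code{exon_index}, \code{codon_index}
#'   (0-based codon number on the reconstructed frame) and
#'   \code{caused_by_frameshift} (TRUE when the reading frame at the stop
#'   is shifted relative to the query frame).
#' @export
scan_premature_stops <- function(reconstruction, query) {
  ann <- annotate_bases(reconstruction, query)
  bases <- strsplit(reconstruction$assembled_cds, "", fixed = TRUE)[[1]]
  stopifnot(length(bases) == length(ann$q_pos))
  term_q <- 3L * nchar(query$protein)   # CDS coordinate of the terminal stop
  rows <- list()
  codon_counter <- 0L
  for (s in unique(ann$seg)) {
    idx <- which(ann$seg == s)
    # anchor the first codon at the first base sitting on a query codon boundary
    anchor <- idx[which(ann$q_pos[idx] %% 3L == 0L)[1]]
    if (is.na(anchor) || anchor > idx[length(idx)] - 2L) next
    starts <- seq.int(anchor, idx[length(idx)] - 2L, by = 3L)
    for (p in starts) {
      codon <- paste(bases[p:(p + 2L)], collapse = "")
      aa <- unname(.codon_table[codon])
      if (is.na(aa)) aa <- "X"   # codon containing N is never a stop
      if (aa == "*" && ann$q_pos[p] < term_q) {
        rows[[length(rows) + 1L]] <- data.frame(
          exon_index = ann$exon_id[p],
          codon_index = codon_counter,
          caused_by_frameshift = (ann$shift[p] %% 3L) != 0L,
          stringsAsFactors = FALSE)
      }
      codon_counter <- codon_counter + 1L
    }
  }
  if (!length(rows))
    return(data.frame(exon_index = integer(0), codon_index = integer(0),
                      caused_by_frameshift = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Full ORF diagnosis of a reconstruction
#'
#' @param reconstruction \code{gene_reconstruction}.
#' @param query \code{\link{query_gene_model}}.
#' @return Object of class \code{orf_diagnosis}: \code{indels} and
#'   \code{stops} data frames, \code{has_frameshift}, \code{has_n}.
#' @export
diagnose_orf <- function(reconstruction, query) {
  indels <- extract_indels(reconstruction, query)
  stops <- scan_premature_stops(reconstruction, query)
  structure(list(indels = indels,
                 stops = stops,
                 has_frameshift = detect_frameshift(indels),
                 has_n = nrow(reconstruction$n_intervals) > 0L),
            class = "orf_diagnosis")
}

#' @export
print.orf_diagnosis <- function(x, ...) {
  cat(sprintf("orf_diagnosis: %d indel(s), %d premature stop(s), frameshift=%s, N=%s\n",
              nrow(x$indels), nrow(x$stops), x$has_frameshift, x$has_n))
  invisible(x)
}
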