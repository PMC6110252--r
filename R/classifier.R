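# Functionality classification.
#
# The decision rules, applied first-match-wins:
#   1. no locus, or every locus shorter than min_hit_nt:
#        both flanking genes found  -> "absent"
#        otherwise                  -> "not_determined"
#   2. at least one premature stop codon -> "defective" (pseudogene)
#   3. unknown (N) regions in the reconstructed CDS, or missing exons
#        -> "partial"
#   4. all seven transmembrane helices observed -> "intact";
#        otherwise -> "partial"
# Defectiveness outranks partialness because a stop codon is decisive
# damage while N is mere uncertainty; a nonsense substitution without a
# frameshift also counts as defective (it equally disrupts the ORF) and
# is flagged as such in the evidence.

#' Classify the functionality of a gene copy
#'
#' Applies the decision rules above to the accumulated evidence for one
#' gene in one genome.  The reconstruction and diagnosis must be supplied
#' exactly when the loci are usable (\code{\link{is_too_short}} FALSE); a
#' synteny result is required to reach an "absent" call.
#'
#' @param loci Data frame from \code{\link{find_loci}}.
#' @param reconstruction \code{gene_reconstruction} or NULL.
#' @param diagnosis \code{orf_diagnosis} or NULL.
#' @param tm_count Integer helix count of the reconstructed protein, or
#'   NULL when not computed (required once rules 1-3 do not fire).
#' @param synteny_result \code{synteny_result} or NULL.
#' @param params \code{\link{search_params}}.
#' @param gene_name,species Bookkeeping labels carried into the call.
#' @return Object of class \code{functionality_call}: \code{call} (one of
#'   \code{"intact" "partial" "defective" "absent" "not_determined"}),
#'   \code{rule} (which rule fired), and an \code{evidence} list bundling
#'   everything the call was derived from.
#' @export
classify_functionality <- function(loci, reconstruction = NULL, diagnosis = NULL,
                                   tm_count = NULL, synteny_result = NULL,
                                   params = search_params(),
                                   gene_name = NA_character_,
                                   species = NA_character_) {
  too_short <- is_too_short(loci, params)
  if (too_short) {
    if (!is.null(reconstruction) || !is.null(diagnosis))
      stop("classify_functionality: reconstruction/diagnosis supplied although loci are absent or too short")
    call <- if (neighbors_support_absence(synteny_result, params)) "absent"
            else "not_determined"
    rule <- "no_or_too_short_hits"
  } else {
    if (is.null(reconstruction) || is.null(diagnosis))
      stop("classify_functionality: loci are usable but reconstruction/diagnosis are missing")
    if (nrow(diagnosis$stops) > 0L) {
      call <- "defective"; rule <- "premature_stop"
    } else if (diagnosis$has_n || length(reconstruction$missing_exons) > 0L) {
      call <- "partial"; rule <- "n_region_or_missing_exon"
    } else {
      if (is.null(tm_count))
        stop("classify_functionality: complete, stop-free reconstruction but tm_count is missing")
      if (tm_count == 7L) { call <- "intact"; rule <- "seven_tm_helices" }
      else { call <- "partial"; rule <- "tm_helices_not_seven" }
    }
  }
  structure(list(gene_name = gene_name,
                 species = species,
                 call = call,
                 rule = rule,
                 evidence = list(
                   n_loci = nrow(loci),
                   best_locus = if (nrow(loci)) loci[1, ] else NULL,
                   too_short = too_short,
                   diagnosis = diagnosis,
                   missing_exons = if (!is.null(reconstruction)) reconstruction$missing_exons,
                   n_intervals = if (!is.null(reconstruction)) reconstruction$n_intervals,
                   tm_count = tm_count,
                   synteny = synteny_result)),
            class = "functionality_call")
}

#' @export
print.functionality_call <- function(x, ...) {
  cat(sprintf("functionality_call %s / %s: %s (rule: %s)\n",
              x$species, x$gene_name, x$call, x$rule))
  invisible(x)
}
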