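# Synteny: presence/absence of the two flanking genes of a target gene.
#
# An "absent" call for the target gene is only licensed when the genomic
# neighborhood was demonstrably assembled; the two flanking genes (e.g.
# Nol9 and Zbtb48 around Tas1r1) serve as that evidence.  Each flanking
# protein is searched with the same translated homology engine as the
# target; a permissive coverage floor is appropriate because the
# neighbors are only evidence of regional assembly completeness.

#' Check the two flanking genes of a target gene
#'
#' Runs the translated homology search for each of the two flanking-gene
#' protein queries.  A neighbor counts as found when its best locus
#' reaches the score cutoff and covers at least \code{coverage_floor} of
#' the query.  The check never inspects the target gene's own locus, so
#' it is independent evidence.
#'
#' @param genome Named character vector of scaffolds.
#' @param neighbor_queries Named character vector of exactly two
#'   amino-acid query sequences (names are the neighbor gene names).
#' @param params \code{\link{search_params}}.
#' @param gene_name Target gene name (bookkeeping only).
#' @return Object of class \code{synteny_result}: \code{gene_name} and a
#'   two-row data frame \code{neighbors} with columns \code{neighbor},
#'   \code{found}, \code{scaffold_id}, \code{start}, \code{end},
#'   \code{score}, \code{q_coverage} (locus fields NA when not found).
#' @export
check_flanking <- function(genome, neighbor_queries, params = search_params(),
                           gene_name = NA_character_) {
  stopifnot(length(neighbor_queries) == 2L, !is.null(names(neighbor_queries)),
            all(nzchar(names(neighbor_queries))))
  rows <- lapply(names(neighbor_queries), function(nm) {
    loci <- find_loci(genome, neighbor_queries[[nm]], params)
    ok <- loci[loci$score >= params$min_hit_score &
                 loci$q_coverage >= params$coverage_floor, , drop = FALSE]
    if (nrow(ok)) {
      best <- ok[1, ]
      data.frame(neighbor = nm, found = TRUE,
                 scaffold_id = best$scaffold_id, start = best$start,
                 end = best$end, score = best$score,
                 q_coverage = best$q_coverage, stringsAsFactors = FALSE)
    } else {
      data.frame(neighbor = nm, found = FALSE,
                 scaffold_id = NA_character_, start = NA_integer_,
                 end = NA_integer_, score = NA_real_,
                 q_coverage = NA_real_, stringsAsFactors = FALSE)
    }
  })
  structure(list(gene_name = gene_name,
                 neighbors = do.call(rbind, rows)),
            class = "synteny_result")
}

#' @export
print.synteny_result <- function(x, ...) {
  cat(sprintf("synteny_result for %s: %s\n", x$gene_name,
              paste(sprintf("%s=%s", x$neighbors$neighbor,
                            ifelse(x$neighbors$found, "found", "not found")),
                    collapse = ", ")))
  invisible(x)
}

## TRUE when the neighborhood evidence licenses an "absent" call
neighbors_support_absence <- function(synteny_result, params) {
  if (is.null(synteny_result)) return(FALSE)
  found <- synteny_result$neighbors$found
  if (isTRUE(params$require_both_neighbors)) all(found) else any(found)
}
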