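# Pipeline orchestration: search -> map -> diagnose -> classify across
# genomes and genes, plus the report writers (functionality matrix,
# indel table, synteny table).

#' Build a pipeline configuration
#'
#' @param genomes Named list: species name -> genome.  Each genome is
#'   either a FASTA path or a named character vector of scaffolds.
#' @param queries List of \code{\link{query_gene_model}} objects (one per
#'   surveyed gene).
#' @param neighbors Named list: gene name -> named character vector of
#'   exactly two flanking-gene protein sequences.
#' @param params \code{\link{search_params}}.
#' @param tm_window,tm_threshold,tm_min_len,tm_min_gap Hydropathy
#'   predictor settings (see \code{\link{predict_tm_helices}}).
#' @param tm_counts Optional named integer vector of externally computed
#'   helix counts (names \code{"<species>.<gene>"}), e.g. from
#'   \code{\link{import_tm_prediction}}; overrides the internal predictor.
#' @param refine Run a second search pass in which intact reconstructions
#'   from the first pass are added to the query set for genomes whose gene
#'   was not located (default FALSE).
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(genomes, queries, neighbors,
                            params = search_params(),
                            tm_window = 19L, tm_threshold = 1.6,
                            tm_min_len = 15L, tm_min_gap = 3L,
                            tm_counts = NULL, refine = FALSE) {
  if (length(genomes) == 0L) stop("pipeline_config: empty genome list")
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    stop("pipeline_config: genomes must be named by species")
  if (anyDuplicated(names(genomes)))
    stop("pipeline_config: duplicate species names")
  if (length(queries) == 0L) stop("pipeline_config: no query gene models")
  gene_names <- vapply(queries, `[[`, character(1), "gene_name")
  for (g in gene_names) {
    nb <- neighbors[[g]]
    if (is.null(nb) || length(nb) != 2L || is.null(names(nb)))
      stop("pipeline_config: gene ", g,
           " needs exactly two named neighbor protein queries")
  }
  structure(list(genomes = genomes, queries = queries, neighbors = neighbors,
                 params = params, tm_window = tm_window,
                 tm_threshold = tm_threshold, tm_min_len = tm_min_len,
                 tm_min_gap = tm_min_gap, tm_counts = tm_counts,
                 refine = refine),
            class = "pipeline_config")
}

## resolve a genome entry (path or in-memory vector) to scaffolds
load_genome <- function(g) {
  if (is.character(g) && length(g) == 1L && is.null(names(g)) && file.exists(g))
    read_fasta(g)
  else if (is.character(g) && !is.null(names(g))) g
  else stop("genome entry must be a FASTA path or a named character vector")
}

## survey one gene in one genome; returns list(call, reconstruction)
survey_gene <- function(genome, query, neighbor_queries, config,
                        species, extra_queries = NULL) {
  params <- config$params
  loci <- find_loci(genome, query$protein, params)
  if (is_too_short(loci, params) && length(extra_queries)) {
    for (q in extra_queries) {
      loci <- find_loci(genome, q, params)
      if (!is_too_short(loci, params)) break
    }
  }
  if (is_too_short(loci, params)) {
    syn <- check_flanking(genome, neighbor_queries, params,
                          gene_name = query$gene_name)
    call <- classify_functionality(loci, synteny_result = syn, params = params,
                                   gene_name = query$gene_name, species = species)
    return(list(call = call, reconstruction = NULL))
  }
  recon <- tryCatch(
    reconstruct_gene(genome, loci[1, ], query, params),
    pseudoscan_no_reconstruction = function(e) NULL)
  if (is.null(recon)) {
    # homology hits exist but no exon maps: treat like a too-short locus
    syn <- check_flanking(genome, neighbor_queries, params,
                          gene_name = query$gene_name)
    call <- classify_functionality(empty_loci(), synteny_result = syn,
                                   params = params,
                                   gene_name = query$gene_name, species = species)
    return(list(call = call, reconstruction = NULL))
  }
  diag <- diagnose_orf(recon, query)
  tm_count <- NULL
  if (nrow(diag$stops) == 0L && !diag$has_n && !length(recon$missing_exons)) {
    key <- paste0(species, ".", query$gene_name)
    tm_count <- if (!is.null(config$tm_counts) && key %in% names(config$tm_counts))
      as.integer(config$tm_counts[[key]])
    else {
      prot <- translate_cds(recon$assembled_cds, 0L)
      count_tm_helices(prot, config$tm_window, config$tm_threshold,
                       config$tm_min_len, config$tm_min_gap)
    }
  }
  call <- classify_functionality(loci, recon, diag, tm_count = tm_count,
                                 params = params,
                                 gene_name = query$gene_name, species = species)
  list(call = call, reconstruction = recon)
}

#' Run the full survey pipeline
#'
#' For every species x gene pair: translated homology search, exon
#' mapping and reconstruction, ORF diagnosis, transmembrane check, synteny
#' check where the gene is missing, and functionality classification.
#' Deterministic given the configuration.
#'
#' @param config \code{\link{pipeline_config}}.
#' @return Object of class \code{pipeline_result}: \code{calls} (data
#'   frame: species, gene, call, rule, tm_count, missing exon count, stop
#'   and indel counts, frameshift and N flags, neighbor summary),
#'   \code{indel_report} (Table-1-style long form), \code{synteny_report},
#'   and \code{details} (the per-pair \code{functionality_call} objects
#'   and reconstructions, keyed \code{"<species>.<gene>"}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- list(); indel_rows <- list(); syn_rows <- list(); details <- list()
  refine_queries <- list()
  pending <- list()
  for (species in names(config$genomes)) {
    genome <- load_genome(config$genomes[[species]])
    for (query in config$queries) {
      g <- query$gene_name
      res <- survey_gene(genome, query, config$neighbors[[g]], config, species)
      if (config$refine && res$call$call %in% c("absent", "not_determined"))
        pending[[length(pending) + 1L]] <- list(species = species, gene = g)
      if (config$refine && res$call$call == "intact")
        refine_queries[[g]] <- c(refine_queries[[g]],
          stats::setNames(translate_cds(res$reconstruction$assembled_cds, 0L),
                          paste0(species, ".", g)))
      details[[paste0(species, ".", g)]] <- res
    }
  }
  # optional single refinement pass: re-search unresolved genomes with the
  # intact sequences recovered in the first pass as additional queries
  if (config$refine && length(pending)) {
    for (p in pending) {
      extras <- refine_queries[[p$gene]]
      if (is.null(extras)) next
      extras <- vapply(extras, function(a) sub("\\*$", "", a), character(1))
      genome <- load_genome(config$genomes[[p$species]])
      query <- config$queries[[which(vapply(config$queries, `[[`, character(1),
                                            "gene_name") == p$gene)]]
      details[[paste0(p$species, ".", p$gene)]] <-
        survey_gene(genome, query, config$neighbors[[p$gene]], config,
                    p$species, extra_queries = extras)
    }
  }
  for (key in names(details)) {
    res <- details[[key]]
    cl <- res$call
    diag <- cl$evidence$diagnosis
    syn <- cl$evidence$synteny
    nbr_txt <- if (!is.null(syn))
      paste(sprintf("%s%s", syn$neighbors$neighbor,
                    ifelse(syn$neighbors$found, "+", "-")), collapse = "/")
    else NA_character_
    rows[[key]] <- data.frame(
      species = cl$species, gene = cl$gene_name, call = cl$call, rule = cl$rule,
      tm_count = if (is.null(cl$evidence$tm_count)) NA_integer_ else cl$evidence$tm_count,
      n_missing_exons = length(cl$evidence$missing_exons),
      n_indels = if (is.null(diag)) NA_integer_ else nrow(diag$indels),
      n_stops = if (is.null(diag)) NA_integer_ else nrow(diag$stops),
      has_frameshift = if (is.null(diag)) NA else diag$has_frameshift,
      has_n = if (is.null(diag)) NA else diag$has_n,
      neighbors = nbr_txt, stringsAsFactors = FALSE)
    if (!is.null(diag) && nrow(diag$indels)) {
      idf <- diag$indels
      idf$species <- cl$species; idf$gene <- cl$gene_name
      indel_rows[[key]] <- idf
    }
    if (!is.null(syn)) {
      sdf <- syn$neighbors
      sdf$species <- cl$species; sdf$gene <- cl$gene_name
      syn_rows[[key]] <- sdf
    }
  }
  calls <- do.call(rbind, rows); rownames(calls) <- NULL
  structure(list(
    calls = calls,
    indel_report = if (length(indel_rows)) do.call(rbind, indel_rows) else NULL,
    synteny_report = if (length(syn_rows)) do.call(rbind, syn_rows) else NULL,
    details = details), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:\n")
  print(x$calls[, c("species", "gene", "call", "rule")], row.names = FALSE)
  invisible(x)
}

#' Summarize calls as a species x gene matrix
#'
#' One symbol per cell: \code{I} intact, \code{P} partial, \code{D}
#' defective, \code{A} absent, \code{?} not determined.  For absent calls
#' the flanking-gene evidence is appended, e.g. \code{"A(NbrA+/NbrB+)"}.
#'
#' @param calls The \code{calls} data frame of a
#'   \code{\link{run_pipeline}} result.
#' @return Character matrix, species as rows, genes as columns.
#' @export
summarize_matrix <- function(calls) {
  stopifnot(nrow(calls) >= 1L)
  if (anyDuplicated(calls[, c("species", "gene")]))
    stop("summarize_matrix: duplicate species x gene rows")
  symbols <- c(intact = "I", partial = "P", defective = "D",
               absent = "A", not_determined = "?")
  species <- unique(calls$species); genes <- unique(calls$gene)
  m <- matrix(NA_character_, length(species), length(genes),
              dimnames = list(species, genes))
  for (r in seq_len(nrow(calls))) {
    cell <- symbols[[calls$call[r]]]
    if (calls$call[r] == "absent" && !is.na(calls$neighbors[r]))
      cell <- sprintf("%s(%s)", cell, calls$neighbors[r])
    m[calls$species[r], calls$gene[r]] <- cell
  }
  m
}

#' Write the functionality matrix to TSV
#'
#' @param calls Calls data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(calls, path) {
  m <- summarize_matrix(calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gene functionality matrix",
               "# I=intact P=partial D=defective A=absent ?=not_determined",
               "# absent cells carry flanking-gene evidence, e.g. A(NbrA+/NbrB-)"),
             con)
  utils::write.table(cbind(species = rownames(m), as.data.frame(m)), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Format the indel report in the style of a per-exon indel table
#'
#' One row per defective gene and species, with comma-joined insertion
#' and deletion lengths per exon and a premature-stop summary like
#' \code{"2 at exon3; 3 at exon6"}.
#'
#' @param result A \code{pipeline_result}.
#' @return Data frame (zero rows when nothing was defective).
#' @export
format_indel_table <- function(result) {
  out <- list()
  for (key in names(result$details)) {
    cl <- result$details[[key]]$call
    if (cl$call != "defective") next
    diag <- cl$evidence$diagnosis
    n_ex <- length(result$details[[key]]$reconstruction$exon_alignments)
    row <- list(species = cl$species, gene = cl$gene_name)
    for (e in seq_len(n_ex)) {
      ins <- diag$indels$length_bp[diag$indels$exon_index == e &
                                     diag$indels$kind == "insertion"]
      del <- diag$indels$length_bp[diag$indels$exon_index == e &
                                     diag$indels$kind == "deletion"]
      row[[sprintf("exon%d_insertion", e)]] <-
        if (length(ins)) paste0(paste(ins, collapse = ", "), " bp") else "-"
      row[[sprintf("exon%d_deletion", e)]] <-
        if (length(del)) paste0(paste(del, collapse = ", "), " bp") else "-"
    }
    st <- table(diag$stops$exon_index)
    row$premature_stops <- if (length(st))
      paste(sprintf("%d at exon%s", as.integer(st), names(st)), collapse = "; ")
    else "-"
    out[[key]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame())
  # pad to a common column set before binding
  cols <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(d) { d[setdiff(cols, names(d))] <- "-"; d[cols] })
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Write all pipeline reports to a directory
#'
#' Emits \code{calls.tsv}, \code{matrix.tsv}, \code{indel_table.tsv} and
#' \code{synteny.tsv}.
#'
#' @param result A \code{pipeline_result}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$calls, file.path(dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(result$calls, file.path(dir, "matrix.tsv"))
  it <- format_indel_table(result)
  utils::write.table(it, file.path(dir, "indel_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$synteny_report))
    utils::write.table(result$synteny_report, file.path(dir, "synteny.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
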