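# Synthetic genomes with planted gene copies in every functionality state.
#
# The simulator emulates what the survey pipeline actually consumes: a
# background scaffold, a planted multi-exon gene with random introns, two
# planted single-exon flanking genes, and mutations matching the observed
# functionality classes (N blocks, missing exons, helix knockouts,
# frameshift indels, nonsense substitutions, whole-gene absence with or
# without the neighborhood).  Everything is deterministic under a seed and
# every planted feature is recorded as ground truth.

.gene_states <- c("intact", "partial_n", "partial_missing_exon", "partial_tm",
                  "defective_frameshift", "defective_nonsense",
                  "absent_with_synteny", "region_missing")

.state_expected_call <- c(intact = "intact",
                          partial_n = "partial",
                          partial_missing_exon = "partial",
                          partial_tm = "partial",
                          defective_frameshift = "defective",
                          defective_nonsense = "defective",
                          absent_with_synteny = "absent",
                          region_missing = "not_determined")

## codons per amino acid (stop codons excluded), for back-translation
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))
})

#' The eight plantable gene functionality states
#' @return Character vector of state names.
#' @export
gene_states <- function() .gene_states

#' Back-translate a protein with uniform codon choice
#'
#' Draws one synonymous codon uniformly at random per residue and appends
#' a TAA stop.  Uses the current RNG stream (seed it with
#' \code{set.seed} or via the simulator).
#'
#' @param protein Amino-acid string (no stops).
#' @return Nucleotide CDS string.
#' @export
back_translate <- function(protein) {
  stopifnot(!grepl("*", protein, fixed = TRUE))
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(res, function(a) {
    opts <- .codons_by_aa[[a]]
    if (is.null(opts)) stop("back_translate: no codon for residue ", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

## random nucleotide string at a given GC fraction
random_nt <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic seven-transmembrane query gene model
#'
#' Builds a GPCR-like protein -- an initial methionine, a long hydrophilic
#' N-terminal (extracellular) domain, seven hydrophobic 21-residue helix
#' blocks separated by 16-residue hydrophilic loops, and a hydrophilic
#' tail -- back-translates it with random codon usage, and splits the CDS
#' into exons.  The default exon lengths mimic a Tas1r-family gene: a
#' short first exon and a long final exon carrying the transmembrane
#' domain.  The design guarantees that the hydropathy predictor counts
#' exactly seven helices on the intact translation.
#'
#' @param seed Integer seed (the model is deterministic under it).
#' @param gene_name Name for the model.
#' @param exon_lengths Exon lengths in bp; must sum to 3 * (protein length
#'   + 1).  The default protein is 833 aa, CDS 2502 nt.
#' @return A \code{\link{query_gene_model}}.
#' @export
synthetic_query_gene <- function(seed = 101L, gene_name = "Tas1rS",
                                 exon_lengths = c(152L, 280L, 262L, 237L, 176L, 1395L)) {
  with_local_seed(seed, {
    hydrophilic <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P", "H")
    strongly_hydrophilic <- c("D", "E", "K", "R", "N", "Q")
    hydrophobic <- c("L", "I", "V", "F")
    ecto <- paste(sample(hydrophilic, 511L, replace = TRUE), collapse = "")
    blocks <- replicate(7L, paste(sample(hydrophobic, 21L, replace = TRUE),
                                  collapse = ""))
    # loops long and strongly hydrophilic so adjacent expanded helix spans
    # never merge for window widths 17-21
    loops <- replicate(6L, paste(sample(strongly_hydrophilic, 24L, replace = TRUE),
                                 collapse = ""))
    tail <- paste(sample(hydrophilic, 30L, replace = TRUE), collapse = "")
    protein <- paste0("M", ecto,
                      paste0(blocks[-7L], loops, collapse = ""), blocks[7L],
                      tail)
    cds <- back_translate(protein)
    stopifnot(sum(exon_lengths) == nchar(cds))
    ends <- cumsum(exon_lengths)
    exons <- substring(cds, c(1L, ends[-length(ends)] + 1L), ends)
    query_gene_model(gene_name, exons, accession = sprintf("SYN%06d", seed))
  })
}

#' Generate synthetic flanking-gene proteins
#'
#' Random globular proteins standing in for the two genes flanking the
#' target (the real survey used e.g. Nol9/Zbtb48 for Tas1r1).
#'
#' @param seed Integer seed.
#' @param names Names for the two proteins.
#' @param len Protein length in residues.
#' @return Named character vector of two amino-acid sequences.
#' @export
synthetic_neighbor_proteins <- function(seed = 202L,
                                        names = c("NbrA", "NbrB"),
                                        len = 300L) {
  stopifnot(length(names) == 2L)
  aa20 <- setdiff(names(.codons_by_aa), "*")
  with_local_seed(seed, {
    stats::setNames(
      replicate(2L, paste(sample(aa20, len, replace = TRUE), collapse = "")),
      names)
  })
}

#' Specify the planted state of a simulated gene
#'
#' @param state One of \code{\link{gene_states}}.
#' @param mutations NULL (canonical mutations for the state are derived
#'   from the query at simulation time) or a data frame with columns
#'   \code{exon_index}, \code{kind} (\code{ins del nonsense n_block}),
#'   \code{length_bp}, \code{offset_in_exon} (0-based offset within the
#'   exon).
#' @param plant_neighbors Logical pair: plant the upstream / downstream
#'   flanking gene.  Defaults to both TRUE except for
#'   \code{region_missing}.
#' @param strand Strand the gene is planted on (\code{"+"} or \code{"-"}).
#' @return Object of class \code{gene_state_spec}.
#' @export
gene_state_spec <- function(state, mutations = NULL, plant_neighbors = NULL,
                            strand = "+") {
  state <- match.arg(state, .gene_states)
  if (is.null(plant_neighbors))
    plant_neighbors <- if (state == "region_missing") c(FALSE, FALSE) else c(TRUE, TRUE)
  stopifnot(length(plant_neighbors) == 2L, is.logical(plant_neighbors),
            strand %in% c("+", "-"))
  if (!is.null(mutations))
    stopifnot(is.data.frame(mutations),
              all(c("exon_index", "kind", "length_bp", "offset_in_exon") %in%
                    names(mutations)),
              all(mutations$kind %in% c("ins", "del", "nonsense", "n_block")))
  structure(list(state = state,
                 mutations = mutations,
                 plant_neighbors = plant_neighbors,
                 plant_gene = !state %in% c("absent_with_synteny", "region_missing"),
                 strand = strand),
            class = "gene_state_spec")
}

## canonical mutation set for a state, derived from the query model
default_mutations <- function(state, query) {
  k <- length(query$exons)
  lens <- nchar(query$exons)
  offs <- query$exon_cds_offsets
  mid_exon <- if (k >= 3L) 3L else k     # a middle-ish exon for point damage
  no_mut <- data.frame(exon_index = integer(0), kind = character(0),
                       length_bp = integer(0), offset_in_exon = integer(0),
                       stringsAsFactors = FALSE)
  codon_aligned_offset <- function(exon, frac) {
    raw <- floor(lens[exon] * frac)
    off <- raw - ((offs[exon] + raw) %% 3L)
    max(0L, min(off, lens[exon] - 3L))
  }
  switch(state,
    intact = ,
    absent_with_synteny = ,
    region_missing = no_mut,
    partial_n = data.frame(exon_index = mid_exon, kind = "n_block",
                           length_bp = 30L,
                           offset_in_exon = max(1L, lens[mid_exon] %/% 2L - 15L),
                           stringsAsFactors = FALSE),
    partial_missing_exon = data.frame(exon_index = 1L, kind = "n_block",
                                      length_bp = lens[1L], offset_in_exon = 0L,
                                      stringsAsFactors = FALSE),
    partial_tm = {
      hel <- predict_tm_helices(query$protein)
      pick <- NULL
      for (h in seq_len(nrow(hel))) {
        cds0 <- 3L * hel$start[h]; cds1 <- 3L * hel$end[h]
        exon <- findInterval(cds0, offs)
        if (exon >= 1L && cds0 - offs[exon] >= 30L &&
            cds1 <= offs[exon] + lens[exon] - 30L) { pick <- c(exon, cds0, cds1); break }
      }
      if (is.null(pick))
        stop("partial_tm: no transmembrane helix lies fully inside one exon")
      data.frame(exon_index = pick[1], kind = "del",
                 length_bp = pick[3] - pick[2],
                 offset_in_exon = pick[2] - offs[pick[1]],
                 stringsAsFactors = FALSE)
    },
    defective_frameshift = {
      exon <- if (k >= 2L) 2L else 1L
      data.frame(exon_index = exon, kind = "del", length_bp = 7L,
                 offset_in_exon = max(30L, lens[exon] %/% 2L),
                 stringsAsFactors = FALSE)
    },
    defective_nonsense = data.frame(exon_index = mid_exon, kind = "nonsense",
                                    length_bp = 3L,
                                    offset_in_exon = codon_aligned_offset(mid_exon, 0.5),
                                    stringsAsFactors = FALSE)
  )
}

## apply a mutation table to the query exons; returns mutated exon vector
apply_mutations <- function(query, mutations) {
  exons <- query$exons
  if (is.null(mutations) || nrow(mutations) == 0L) return(exons)
  ord <- order(mutations$exon_index, -mutations$offset_in_exon)
  for (r in ord) {
    i <- mutations$exon_index[r]
    off <- mutations$offset_in_exon[r]
    len <- mutations$length_bp[r]
    kind <- mutations$kind[r]
    ex <- exons[[i]]
    if (off < 0L || off > nchar(ex) ||
        (kind %in% c("del", "nonsense", "n_block") && off + len > nchar(ex)))
      stop(sprintf("mutation offset outside exon %d: kind=%s offset=%d length=%d",
                   i, kind, off, len))
    exons[[i]] <- switch(kind,
      ins = paste0(substr(ex, 1L, off), random_nt(len),
                   substr(ex, off + 1L, nchar(ex))),
      del = paste0(substr(ex, 1L, off), substr(ex, off + len + 1L, nchar(ex))),
      n_block = paste0(substr(ex, 1L, off), strrep("N", len),
                       substr(ex, off + len + 1L, nchar(ex))),
      nonsense = {
        cds_off <- query$exon_cds_offsets[i] + off
        if (cds_off %% 3L != 0L)
          stop("nonsense mutation offset is not codon-aligned (CDS position ",
               cds_off, ")")
        paste0(substr(ex, 1L, off), "TGA", substr(ex, off + 4L, nchar(ex)))
      })
  }
  exons
}

## sanity-check that the mutated CDS realizes the requested state
validate_state <- function(state, query, mutated_exons) {
  if (!state %in% c("defective_frameshift", "defective_nonsense")) return(invisible(TRUE))
  cds <- paste(mutated_exons, collapse = "")
  aa <- translate_cds(substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L), 0L)
  body <- substr(aa, 1L, nchar(aa) - 1L)
  if (!grepl("*", body, fixed = TRUE))
    stop(state, ": planted mutations do not produce a premature stop codon; ",
         "choose a different offset")
  invisible(TRUE)
}

#' Simulate one genome with a planted gene copy
#'
#' Plants the (possibly mutated) query gene with independent random
#' introns, and the two flanking genes, into a random background
#' scaffold; deterministic under the seed.  Mutations default to a
#' canonical set realizing the requested state (e.g. a 7-bp exon-2
#' deletion for \code{defective_frameshift}).
#'
#' @param query \code{\link{query_gene_model}}.
#' @param neighbor_proteins Named character vector of two amino-acid
#'   sequences.
#' @param spec \code{\link{gene_state_spec}} (or a state name).
#' @param background_len Scaffold length in bp (default 200000).
#' @param gc Background GC fraction (default 0.41).
#' @param intron_len_range Intron length range in bp (default 200-2000).
#' @param neighbor_gap Distance in bp between the gene and each flanking
#'   gene (default 25000, comfortably beyond the locus merge distance).
#' @param seed Integer seed.
#' @param scaffold_id Name of the emitted scaffold.
#' @return List with \code{genome} (named character vector of one
#'   scaffold) and \code{truth} (class \code{synthetic_truth}): state,
#'   expected call, planted gene/exon/intron/neighbor spans
#'   (forward-strand, 0-based half-open), strand, and the mutation table.
#' @export
simulate_genome <- function(query, neighbor_proteins, spec,
                            background_len = 200000L, gc = 0.41,
                            intron_len_range = c(200L, 2000L),
                            neighbor_gap = 25000L,
                            seed = 1L, scaffold_id = "scaf1") {
  if (is.character(spec)) spec <- gene_state_spec(spec)
  stopifnot(inherits(spec, "gene_state_spec"),
            length(neighbor_proteins) == 2L)
  with_local_seed(seed, {
    mutations <- spec$mutations
    if (is.null(mutations)) mutations <- default_mutations(spec$state, query)
    mutated_exons <- apply_mutations(query, mutations)
    if (spec$plant_gene) validate_state(spec$state, query, mutated_exons)
    n_ex <- length(mutated_exons)
    intron_lens <- if (n_ex > 1L)
      sample(intron_len_range[1]:intron_len_range[2], n_ex - 1L, replace = TRUE)
    else integer(0)
    introns <- vapply(intron_lens, random_nt, character(1), gc = gc)
    pieces <- character(0)
    exon_local <- matrix(integer(0), ncol = 2)
    pos <- 0L
    for (i in seq_len(n_ex)) {
      pieces <- c(pieces, mutated_exons[[i]])
      exon_local <- rbind(exon_local, c(pos, pos + nchar(mutated_exons[[i]])))
      pos <- pos + nchar(mutated_exons[[i]])
      if (i < n_ex) { pieces <- c(pieces, introns[[i]]); pos <- pos + nchar(introns[[i]]) }
    }
    gene_seq <- paste(pieces, collapse = "")
    glen <- nchar(gene_seq)
    nbr_cds <- vapply(neighbor_proteins, back_translate, character(1))
    need <- glen + sum(nchar(nbr_cds)) + 2L * neighbor_gap + 2000L
    if (background_len < need)
      stop(sprintf("background_len %d too small; need at least %d",
                   background_len, need))
    background <- random_nt(background_len, gc)
    gene_start <- nchar(nbr_cds[[1]]) + neighbor_gap + 1000L
    plant <- function(bg, at, seq) {
      paste0(substr(bg, 1L, at), seq, substr(bg, at + nchar(seq) + 1L, nchar(bg)))
    }
    scaffold <- background
    truth_gene <- NULL
    if (spec$plant_gene) {
      planted_seq <- if (spec$strand == "-") reverse_complement(gene_seq) else gene_seq
      scaffold <- plant(scaffold, gene_start, planted_seq)
      to_fwd <- function(sp) {
        if (spec$strand == "+") gene_start + sp
        else c(gene_start + glen - sp[2], gene_start + glen - sp[1])
      }
      exon_spans <- t(apply(exon_local, 1L, to_fwd))
      colnames(exon_spans) <- c("start", "end")
      truth_gene <- list(gene_span = c(gene_start, gene_start + glen),
                         exon_spans = exon_spans,
                         intron_lens = intron_lens)
    }
    nbr_spans <- list(NULL, NULL)
    up_start <- gene_start - neighbor_gap - nchar(nbr_cds[[1]])
    down_start <- gene_start + glen + neighbor_gap
    if (spec$plant_neighbors[1]) {
      scaffold <- plant(scaffold, up_start, nbr_cds[[1]])
      nbr_spans[[1]] <- c(up_start, up_start + nchar(nbr_cds[[1]]))
    }
    if (spec$plant_neighbors[2]) {
      scaffold <- plant(scaffold, down_start, nbr_cds[[2]])
      nbr_spans[[2]] <- c(down_start, down_start + nchar(nbr_cds[[2]]))
    }
    genome <- stats::setNames(scaffold, scaffold_id)
    truth <- structure(list(
      state = spec$state,
      expected_call = unname(.state_expected_call[spec$state]),
      strand = spec$strand,
      gene = truth_gene,
      mutations = mutations,
      neighbor_spans = stats::setNames(nbr_spans, names(neighbor_proteins)),
      plant_neighbors = spec$plant_neighbors,
      seed = seed), class = "synthetic_truth")
    list(genome = genome, truth = truth)
  })
}

#' Simulate a panel of genomes, one per state
#'
#' Seeds for the member genomes are derived deterministically from the
#' master seed, so the same (states, seed) pair always yields
#' byte-identical genomes.
#'
#' @param query \code{\link{query_gene_model}}.
#' @param neighbor_proteins Two named amino-acid sequences.
#' @param states Character vector of states (default: all eight) or list
#'   of \code{\link{gene_state_spec}} objects.
#' @param seed Master seed.
#' @param ... Passed to \code{\link{simulate_genome}}.
#' @return List with \code{genomes} (named list of single-scaffold
#'   genomes, one per state), \code{truths} (list of
#'   \code{synthetic_truth}) and \code{truth_table} (data frame: species
#'   label, state, expected_call, seed).
#' @export
simulate_panel <- function(query, neighbor_proteins, states = gene_states(),
                           seed = 1L, ...) {
  stopifnot(length(states) >= 1L)
  specs <- lapply(states, function(s)
    if (inherits(s, "gene_state_spec")) s else gene_state_spec(s))
  labels <- make.unique(vapply(specs, `[[`, character(1), "state"), sep = "_")
  sub_seeds <- with_local_seed(seed, sample.int(999983L, length(specs)))
  genomes <- list(); truths <- list()
  for (i in seq_along(specs)) {
    sim <- simulate_genome(query, neighbor_proteins, specs[[i]],
                           seed = sub_seeds[i],
                           scaffold_id = paste0("scaf_", labels[i]), ...)
    # genome names double as species labels downstream, matching truth_table
    genomes[[paste0("sim_", labels[i])]] <- sim$genome
    truths[[labels[i]]] <- sim$truth
  }
  truth_table <- data.frame(
    species = paste0("sim_", labels),
    state = vapply(specs, `[[`, character(1), "state"),
    expected_call = vapply(truths, `[[`, character(1), "expected_call"),
    seed = sub_seeds, stringsAsFactors = FALSE)
  list(genomes = genomes, truths = truths, truth_table = truth_table)
}

#' Read a panel specification from YAML
#'
#' Recognized keys: \code{states} (list of state names or of mappings
#' with \code{state}, optional \code{strand} and \code{mutations}),
#' \code{seed}, \code{background_len}, \code{gc}, \code{intron_len_range}.
#'
#' @param path YAML file path.
#' @return List of arguments suitable for \code{\link{simulate_panel}}.
#' @export
read_panel_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$states)) stop("panel YAML lacks a 'states' key")
  states <- lapply(y$states, function(s) {
    if (is.character(s)) return(gene_state_spec(s))
    mut <- if (!is.null(s$mutations))
      do.call(rbind, lapply(s$mutations, as.data.frame))
    gene_state_spec(s$state, mutations = mut,
                    strand = if (is.null(s$strand)) "+" else s$strand)
  })
  args <- list(states = states)
  for (k in c("seed", "background_len", "gc", "intron_len_range"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  args
}
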