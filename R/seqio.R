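# Sequence I/O and nucleotide/protein primitives.
#
# Conventions used throughout the package:
#   * nucleotide alphabet is ACGTN after normalization; IUPAC ambiguity
#     codes other than N are replaced by N (with a warning), because every
#     downstream rule treats non-called bases as assembly uncertainty;
#   * all coordinates are 0-based half-open on the forward strand of a
#     scaffold, with an explicit strand flag where orientation matters.

#' Normalize a nucleotide sequence to the ACGTN alphabet
#'
#' Uppercases the sequence and replaces IUPAC ambiguity codes other than
#' \code{N} (R, Y, S, W, K, M, B, D, H, V) by \code{N}, warning once per
#' call.  Any character outside the IUPAC nucleotide set raises an error.
#'
#' @param seq Character scalar, a nucleotide sequence.
#' @param what Label used in error messages.
#' @return The normalized sequence (uppercase, ACGTN only).
#' @export
normalize_nt <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", s)
  if (nzchar(bad)) {
    stop(sprintf("%s contains non-IUPAC nucleotide characters: %s",
                 what, paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")))
  }
  amb <- gsub("[ACGTN]", "", s)
  if (nzchar(amb)) {
    warning(sprintf("%s: %d IUPAC ambiguity base(s) replaced by N",
                    what, nchar(amb)))
    s <- chartr("RYSWKMBDHV", strrep("N", 10L), s)
  }
  s
}

#' Read a FASTA file into a named character vector
#'
#' Parses a (wrapped or unwrapped, multi-record) FASTA file and returns the
#' sequences as an uppercase named character vector, names taken from the
#' first whitespace-delimited token of each header.  Record order is
#' preserved.  The full header line (minus the id) is kept in the
#' \code{"descriptions"} attribute.
#'
#' @param path Path to a FASTA file.
#' @param alphabet \code{"nt"} (default) normalizes records to ACGTN;
#'   \code{"aa"} leaves amino-acid records as-is apart from uppercasing.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (alphabet == "nt") {
    seqs <- vapply(seq_along(seqs),
                   function(i) normalize_nt(seqs[[i]], what = ids[[i]]),
                   character(1))
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(descs, ids)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## codon -> amino acid lookup (standard genetic code), built once at load
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Translate a coding sequence
#'
#' Standard genetic code.  Stop codons translate to \code{"*"}; any codon
#' containing \code{N} translates to \code{"X"}; a trailing incomplete
#' codon is dropped.
#'
#' @param cds Nucleotide string over ACGTN.
#' @param frame Reading-frame offset 0, 1 or 2 (bases skipped before the
#'   first codon).
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, frame = 0L) {
  stopifnot(length(cds) == 1L, frame %in% 0:2)
  if (grepl("[^ACGTN]", cds)) stop("translate_cds: sequence contains non-ACGTN characters")
  n <- nchar(cds)
  if (n < frame + 3L) stop("translate_cds: sequence shorter than frame + one codon")
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Reverse complement of a nucleotide sequence
#'
#' \code{N} maps to \code{N}; the operation is an involution.
#'
#' @param seq Nucleotide string over ACGTN.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(length(seq) == 1L)
  if (grepl("[^ACGTN]", seq)) stop("reverse_complement: sequence contains non-ACGTN characters")
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six frames.  Minus-strand frames
#' are translated on the reverse complement, so their residue order runs
#' 3' to 5' with respect to the forward strand.
#'
#' @param seq Nucleotide string over ACGTN, length at least 3.
#' @return Named list with elements \code{"+0" "+1" "+2" "-0" "-1" "-2"}.
#' @export
six_frame_translate <- function(seq) {
  rc <- reverse_complement(seq)
  out <- list()
  for (f in 0:2) {
    out[[paste0("+", f)]] <- if (nchar(seq) >= f + 3L) translate_cds(seq, f) else ""
    out[[paste0("-", f)]] <- if (nchar(rc) >= f + 3L) translate_cds(rc, f) else ""
  }
  out
}

#' Find runs of N in a nucleotide sequence
#'
#' @param seq Nucleotide string.
#' @param min_len Minimum run length to report (default 1).
#' @return Two-column integer matrix (\code{start}, \code{end}), 0-based
#'   half-open, sorted, non-overlapping; zero rows when there is no
#'   qualifying run.
#' @export
find_n_runs <- function(seq, min_len = 1L) {
  stopifnot(min_len >= 1L)
  m <- gregexpr("N+", seq)[[1]]
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (m[1] == -1L) return(out)
  len <- attr(m, "match.length")
  keep <- len >= min_len
  if (!any(keep)) return(out)
  cbind(start = as.integer(m[keep]) - 1L,
        end   = as.integer(m[keep]) - 1L + as.integer(len[keep]))
}

#' Construct a query gene model
#'
#' A query gene model is the ordered set of coding exon sequences of a
#' reference gene (e.g. mouse Tas1r1), together with its conceptual
#' translation.  The concatenated exons must form a clean CDS: length a
#' multiple of 3, exactly one stop codon, at the end.
#'
#' @param gene_name Gene symbol, e.g. \code{"Tas1r1"}.
#' @param exons Character vector of exon nucleotide sequences in gene order.
#' @param accession Optional source accession string.
#' @return Object of class \code{query_gene}, a list with fields
#'   \code{gene_name}, \code{accession}, \code{exons}, \code{cds},
#'   \code{protein} (translation without the terminal stop) and
#'   \code{exon_cds_offsets} (0-based CDS offset of each exon).
#' @export
query_gene_model <- function(gene_name, exons, accession = NA_character_) {
  stopifnot(is.character(gene_name), nzchar(gene_name),
            is.character(exons), length(exons) >= 1L)
  exons <- vapply(seq_along(exons), function(i)
    normalize_nt(exons[[i]], what = sprintf("%s exon %d", gene_name, i)),
    character(1))
  cds <- paste(exons, collapse = "")
  if (nchar(cds) %% 3L != 0L)
    stop(gene_name, ": concatenated exon length not divisible by 3")
  aa <- translate_cds(cds, 0L)
  if (!endsWith(aa, "*"))
    stop(gene_name, ": CDS does not end with a stop codon")
  protein <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", protein, fixed = TRUE))
    stop(gene_name, ": CDS contains an internal stop codon")
  offs <- cumsum(c(0L, nchar(exons)))[seq_along(exons)]
  structure(list(gene_name = gene_name,
                 accession = accession,
                 exons = unname(exons),
                 cds = cds,
                 protein = protein,
                 exon_cds_offsets = offs),
            class = "query_gene")
}

#' @export
print.query_gene <- function(x, ...) {
  cat(sprintf("query_gene %s (%s): %d exon(s), CDS %d nt, protein %d aa\n",
              x$gene_name, x$accession, length(x$exons), nchar(x$cds),
              nchar(x$protein)))
  invisible(x)
}

#' Read a query gene model from an exon FASTA file
#'
#' Expects one record per exon named \code{<gene>_exon<k>}; exons are
#' ordered by \code{k}.
#'
#' @param path FASTA file path.
#' @param gene_name Optional gene name; inferred from record names when
#'   omitted.
#' @param accession Optional accession.
#' @return A \code{\link{query_gene_model}}.
#' @export
read_query_exons_fasta <- function(path, gene_name = NULL, accession = NA_character_) {
  seqs <- read_fasta(path, alphabet = "nt")
  ids <- names(seqs)
  m <- regmatches(ids, regexec("^(.*)_exon(\\d+)$", ids))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop("exon FASTA records must be named <gene>_exon<k>; offending id(s): ",
         paste(ids[!ok], collapse = ", "))
  genes <- vapply(m, `[`, character(1), 2L)
  ks <- as.integer(vapply(m, `[`, character(1), 3L))
  if (length(unique(genes)) != 1L)
    stop("exon FASTA mixes multiple genes: ", paste(unique(genes), collapse = ", "))
  if (is.null(gene_name)) gene_name <- genes[[1]]
  query_gene_model(gene_name, seqs[order(ks)], accession = accession)
}

#' Read a query gene model from genomic FASTA plus GFF3 CDS rows
#'
#' Extracts rows of type \code{CDS} for the given gene from a GFF3 file,
#' splices them in genomic order (reverse-complemented for minus-strand
#' genes) and builds the query model.  Requires the \pkg{rtracklayer}
#' package.
#'
#' @param fasta_path Genomic FASTA.
#' @param gff_path GFF3 annotation.
#' @param gene_name Gene name; matched against the GFF3 \code{gene} or
#'   \code{Name} attribute (all CDS rows are used when \code{NULL} and the
#'   file contains a single gene).
#' @param accession Optional accession.
#' @return A \code{\link{query_gene_model}}.
#' @export
read_query_gff3 <- function(fasta_path, gff_path, gene_name = NULL,
                            accession = NA_character_) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_query_gff3 requires the rtracklayer package")
  seqs <- read_fasta(fasta_path, alphabet = "nt")
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS rows in ", gff_path)
  meta <- S4Vectors::mcols(gr)
  lab <- if ("gene" %in% names(meta)) meta$gene else meta$Name
  if (!is.null(gene_name) && !is.null(lab)) {
    gr <- gr[!is.na(lab) & lab == gene_name]
    if (length(gr) == 0L) stop("no CDS rows for gene ", gene_name)
  }
  if (is.null(gene_name)) gene_name <- if (!is.null(lab)) as.character(lab[[1]]) else "query"
  strand <- as.character(BiocGenerics::strand(gr))[1]
  ord <- order(BiocGenerics::start(gr))
  gr <- gr[ord]
  scaf <- as.character(GenomeInfoDb::seqnames(gr))[1]
  if (!scaf %in% names(seqs)) stop("GFF3 seqid not in FASTA: ", scaf)
  exons <- substring(seqs[[scaf]], BiocGenerics::start(gr), BiocGenerics::end(gr))
  if (identical(strand, "-"))
    exons <- rev(vapply(exons, reverse_complement, character(1)))
  query_gene_model(gene_name, unname(exons), accession = accession)
}

## run code under a local RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
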