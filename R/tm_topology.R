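# Transmembrane-helix counting.
#
# A Kyte-Doolittle sliding-window hydropathy scan stands in for an
# HMM-based topology predictor: maximal runs of window centers whose mean
# hydropathy reaches the threshold are expanded to the window extent,
# merged across sub-minimal gaps, and kept when long enough to span a
# membrane.  An import path for externally computed predictions (TMHMM
# short format or a two-column TSV) is provided for users who prefer to
# run a dedicated predictor.

## Kyte-Doolittle hydropathy scale; X (unknown residue) contributes 0.
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
               Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
               L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
               S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
               X = 0)

#' Predict transmembrane helices by sliding-window hydropathy
#'
#' Computes the mean Kyte-Doolittle hydropathy in a sliding window,
#' collects maximal runs of window centers at or above the threshold,
#' expands each run to the full window extent, merges runs separated by
#' fewer than \code{min_gap} residues, and keeps spans of at least
#' \code{min_len} residues.  Defaults (window 19, threshold 1.6) follow
#' the classical Kyte-Doolittle recommendation for membrane-spanning
#' segments.
#'
#' @param protein Amino-acid string; a terminal \code{"*"} is stripped; an
#'   internal stop is an error.  \code{X} residues contribute hydropathy 0.
#' @param window Odd window length in residues (default 19).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @param min_len Minimum helix span length in residues (default 15).
#' @param min_gap Runs closer than this merge (default 3).
#' @return Data frame with 0-based half-open residue spans \code{start},
#'   \code{end} and \code{mean_hydropathy} (mean of the qualifying window
#'   scores in the run); spans are sorted and non-overlapping.  A protein
#'   shorter than the window yields zero rows with a warning.
#' @export
predict_tm_helices <- function(protein, window = 19L, threshold = 1.6,
                               min_len = 15L, min_gap = 3L) {
  stopifnot(nzchar(protein), window %% 2L == 1L, window >= 3L)
  if (endsWith(protein, "*")) protein <- substr(protein, 1L, nchar(protein) - 1L)
  if (grepl("*", protein, fixed = TRUE))
    stop("predict_tm_helices: protein contains an internal stop")
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0))
  n <- nchar(protein)
  if (n < window) {
    warning("protein shorter than the hydropathy window; no prediction")
    return(empty)
  }
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  h <- .kd_scale[res]
  h[is.na(h)] <- 0
  cs <- cumsum(c(0, h))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  half <- (window - 1L) %/% 2L
  centers <- half + seq_along(means) - 1L        # 0-based center positions
  above <- means >= threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  spans <- lapply(runs, function(t) {
    c1 <- centers[starts[t]]; c2 <- centers[ends[t]]
    list(start = max(0L, c1 - half), end = min(n, c2 + half + 1L),
         scores = means[starts[t]:ends[t]])
  })
  # merge spans separated by < min_gap
  merged <- list(spans[[1]])
  if (length(spans) > 1L) for (t in 2:length(spans)) {
    last <- merged[[length(merged)]]
    if (spans[[t]]$start - last$end < min_gap) {
      last$end <- spans[[t]]$end
      last$scores <- c(last$scores, spans[[t]]$scores)
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- spans[[t]]
  }
  keep <- vapply(merged, function(sp) sp$end - sp$start >= min_len, logical(1))
  merged <- merged[keep]
  if (!length(merged)) return(empty)
  data.frame(start = as.integer(vapply(merged, function(sp) as.numeric(sp$start), numeric(1))),
             end = as.integer(vapply(merged, function(sp) as.numeric(sp$end), numeric(1))),
             mean_hydropathy = vapply(merged, function(sp) mean(sp$scores), numeric(1)))
}

#' Count predicted transmembrane helices
#'
#' @inheritParams predict_tm_helices
#' @return Integer helix count.
#' @export
count_tm_helices <- function(protein, window = 19L, threshold = 1.6,
                             min_len = 15L, min_gap = 3L) {
  nrow(predict_tm_helices(protein, window, threshold, min_len, min_gap))
}

#' Import externally computed transmembrane-helix counts
#'
#' Accepts either TMHMM short-format output (lines containing
#' \code{"Number of predicted TMHs:"} or a \code{PredHel=} field) or a
#' two-column TSV \code{id<TAB>count}.  Comment-only and blank lines are
#' skipped in TSV mode.
#'
#' @param path Path to the prediction file.
#' @return Named integer vector of helix counts (possibly empty).
#' @export
import_tm_prediction <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- integer(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) next
    m <- regexec("^#?\\s*(\\S+)\\s+Number of predicted TMHs:\\s*(\\d+)", line)
    g <- regmatches(line, m)[[1]]
    if (length(g) == 3L) { out[g[2]] <- as.integer(g[3]); next }
    m2 <- regexec("^(\\S+)\\s.*PredHel=(\\d+)", line)
    g2 <- regmatches(line, m2)[[1]]
    if (length(g2) == 3L) { out[g2[2]] <- as.integer(g2[3]); next }
    if (startsWith(line, "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2L && grepl("^\\d+$", parts[2])) {
      out[parts[1]] <- as.integer(parts[2]); next
    }
    stop(sprintf("import_tm_prediction: unparseable line %d: %s", ln, line))
  }
  out
}
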