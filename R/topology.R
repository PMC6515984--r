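#' Consensus intervals between two predictors
#'
#' Greedy one-to-one matching in coordinate order: walking both interval
#' lists left to right, a pair contributes its intersection to the
#' consensus iff the intersection spans at least `minOverlap` amino acids
#' (length = end - start + 1); each input interval is used at most once.
#'
#' @param a,b two-column matrices or data.frames of 1-based inclusive
#'   `(start, end)` intervals, each internally non-overlapping and sorted.
#' @param minOverlap minimum intersection length in amino acids.
#' @return data.frame of consensus intervals (`start`, `end`), zero rows
#'   when there is no consensus.
#' @export
consensusIntervals <- function(a, b, minOverlap = 10L) {
  toMat <- function(x) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x)) ||
        (is.matrix(x) && !nrow(x)) || !length(x))
      return(matrix(numeric(), ncol = 2L))
    m <- as.matrix(as.data.frame(x)[, 1:2])
    if (any(is.na(m)) || any(m[, 1] > m[, 2]))
      stop("malformed intervals: need start <= end")
    if (nrow(m) > 1L) {
      if (is.unsorted(m[, 1])) stop("intervals must be sorted by start")
      if (any(m[-1L, 1] <= m[-nrow(m), 2]))
        stop("intervals must be non-overlapping within a predictor")
    }
    m
  }
  if (minOverlap < 1L) stop("'minOverlap' must be a positive integer")
  a <- toMat(a)
  b <- toMat(b)
  out <- matrix(numeric(), ncol = 2L)
  i <- 1L
  j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a[i, 1], b[j, 1])
    e <- min(a[i, 2], b[j, 2])
    if (e - s + 1 >= minOverlap) {
      out <- rbind(out, c(s, e))
      i <- i + 1L
      j <- j + 1L
    } else if (a[i, 2] < b[j, 2]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  data.frame(start = out[, 1], end = out[, 2])
}

#' Topology class from consensus features
#'
#' Two or more consensus transmembrane helices give class `TM`; exactly one
#' gives `membrane-anchored`; none plus a consensus signal peptide gives
#' `secreted`; everything else is `soluble`.
#'
#' @param tmCount number of consensus TM helices.
#' @param signal logical, consensus signal peptide present.
#' @return Character class.
#' @export
classifyTopology <- function(tmCount, signal) {
  stopifnot(length(tmCount) == 1L, tmCount >= 0)
  if (tmCount >= 2) "TM"
  else if (tmCount == 1) "membrane-anchored"
  else if (isTRUE(signal)) "secreted"
  else "soluble"
}

#' Consensus topology calls for a prediction table
#'
#' Applies [consensusIntervals()] per protein to the TM-helix intervals of
#' the two predictors, and the same overlap rule to their signal-peptide
#' regions, then classifies with [classifyTopology()].
#'
#' @param predictions data.frame with columns `protein`, `predictor`,
#'   `feature` (`"tm"` or `"signal"`), `start`, `end`.  Exactly two
#'   predictor labels are expected.
#' @param proteins optional character vector of proteins to report (those
#'   with no prediction rows get zero helices, no signal).
#' @param minOverlap minimum consensus overlap in amino acids.
#' @return data.frame with `protein`, `consensus_tm_count`,
#'   `consensus_signal`, `class`.
#' @export
callTopology <- function(predictions, proteins = NULL, minOverlap = 10L) {
  stopifnot(is.data.frame(predictions),
            all(c("protein", "predictor", "feature", "start", "end") %in%
                  names(predictions)))
  preds <- unique(predictions$predictor)
  if (length(preds) != 2L)
    stop("exactly two predictors expected, got ", length(preds))
  if (is.null(proteins)) proteins <- unique(predictions$protein)
  getIv <- function(p, pr, feat) {
    sub <- predictions[predictions$protein == p &
                         predictions$predictor == pr &
                         predictions$feature == feat, c("start", "end")]
    sub[order(sub$start), , drop = FALSE]
  }
  out <- data.frame(protein = proteins,
                    consensus_tm_count = 0L,
                    consensus_signal = FALSE,
                    class = NA_character_, stringsAsFactors = FALSE)
  for (r in seq_along(proteins)) {
    p <- proteins[r]
    tm <- consensusIntervals(getIv(p, preds[1], "tm"),
                             getIv(p, preds[2], "tm"), minOverlap)
    sig <- consensusIntervals(getIv(p, preds[1], "signal"),
                              getIv(p, preds[2], "signal"), minOverlap)
    out$consensus_tm_count[r] <- nrow(tm)
    out$consensus_signal[r] <- nrow(sig) > 0L
    out$class[r] <- classifyTopology(nrow(tm), nrow(sig) > 0L)
  }
  out
}
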