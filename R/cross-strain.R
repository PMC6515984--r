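#' @noRd
.substitutionMatrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gap costs (via
#' `Biostrings::pairwiseAlignment`).  Identity is the percentage of aligned
#' columns (gaps included) with identical residues; coverage is the aligned
#' query span divided by the query length.
#'
#' @param a query amino-acid string.
#' @param b subject amino-acid string.
#' @param matrix substitution matrix name (default `"BLOSUM62"`) or matrix.
#' @param gapOpen,gapExtend affine gap penalties (positive costs).
#' @return List with `score`, `identity` (percent), `query_coverage`
#'   (percent), and the aligned query range `query_start`/`query_end`.
#'   When no positive-scoring local alignment exists, score 0 is returned
#'   with zero identity and coverage.
#' @export
localAlign <- function(a, b, matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  checkAminoAcids(c(a, b))
  mat <- .substitutionMatrix(matrix)
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gapOpen,
                                      gapExtension = gapExtend)
  s <- Biostrings::score(pa)
  if (s <= 0)
    return(list(score = 0, identity = 0, query_coverage = 0,
                query_start = NA_integer_, query_end = NA_integer_))
  qs <- IRanges::start(Biostrings::pattern(pa))
  qe <- IRanges::end(Biostrings::pattern(pa))
  list(score = s,
       identity = Biostrings::pid(pa),
       query_coverage = 100 * (qe - qs + 1) / nchar(a),
       query_start = qs, query_end = qe)
}

#' Karlin-Altschul E-value
#'
#' `E = k * m * n * exp(-lambda * score)`, the ungapped Karlin-Altschul
#' formula applied to gapped scores as a documented approximation.  The
#' default constants are standard published values for BLOSUM62 scoring
#' with gap costs 11/1.
#'
#' @param score alignment score in substitution-matrix units.
#' @param m query length (residues).
#' @param n database residue count.
#' @param lambda,k Karlin-Altschul parameters.
#' @return The E-value.
#' @export
karlinAltschulEvalue <- function(score, m, n, lambda = 0.3176, k = 0.134) {
  stopifnot(m > 0, n > 0, lambda > 0, k > 0)
  k * m * n * exp(-lambda * score)
}

#' Best-hit ortholog map between two proteomes
#'
#' Every query is locally aligned against every subject; hits with E-value
#' at or above `evalueMax` are discarded, and among survivors the best hit
#' is chosen by lexicographic ranking on (identity, query coverage, score,
#' subject id).  Queries with no surviving hit are reported unmapped.
#'
#' @param query,subject named character vectors or
#'   [Biostrings::AAStringSet]s with unique ids.
#' @param evalueMax E-value ceiling (strict `<`).
#' @param matrix,gapOpen,gapExtend alignment scoring (see [localAlign()]).
#' @param lambda,k Karlin-Altschul constants (see [karlinAltschulEvalue()]).
#' @return List with `pairs` (data.frame: `query`, `subject`, `identity`,
#'   `query_coverage`, `score`, `evalue`) and `unmapped_queries`.
#' @export
bestHitMap <- function(query, subject, evalueMax = 1e-5,
                       matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                       lambda = 0.3176, k = 0.134) {
  q <- asAAStringSet(query)
  s <- asAAStringSet(subject)
  if (anyDuplicated(names(q)) || anyDuplicated(names(s)))
    stop("proteome ids must be unique")
  mat <- .substitutionMatrix(matrix)
  dbRes <- sum(Biostrings::width(s))
  pairs <- data.frame(query = character(), subject = character(),
                      identity = numeric(), query_coverage = numeric(),
                      score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  unmapped <- character()
  if (length(s) == 0L) {
    return(list(pairs = pairs, unmapped_queries = names(q)))
  }
  sOrder <- order(names(s))
  s <- s[sOrder]
  for (i in seq_along(q)) {
    qi <- q[[i]]
    pa <- Biostrings::pairwiseAlignment(s, qi, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = gapOpen,
                                        gapExtension = gapExtend)
    sc <- Biostrings::score(pa)
    ev <- karlinAltschulEvalue(sc, m = length(qi), n = dbRes,
                               lambda = lambda, k = k)
    keep <- which(ev < evalueMax & sc > 0)
    if (!length(keep)) {
      unmapped <- c(unmapped, names(q)[i])
      next
    }
    ## identity over aligned columns; coverage on the query, which is the
    ## 'subject' role in the vectorized call
    idn <- Biostrings::pid(pa)[keep]
    qs <- IRanges::start(Biostrings::subject(pa))[keep]
    qe <- IRanges::end(Biostrings::subject(pa))[keep]
    cov <- 100 * (qe - qs + 1) / length(qi)
    ord <- order(-idn, -cov, -sc[keep], names(s)[keep])[1L]
    j <- keep[ord]
    pairs <- rbind(pairs, data.frame(
      query = names(q)[i], subject = names(s)[j],
      identity = idn[ord], query_coverage = cov[ord],
      score = sc[j], evalue = ev[j], stringsAsFactors = FALSE))
  }
  rownames(pairs) <- NULL
  list(pairs = pairs, unmapped_queries = unmapped)
}

#' Detect blocks of consecutively unmapped reference genes
#'
#' Maximal runs of at least `minBlock` consecutive (in genome order)
#' reference genes with no ortholog in the derivative are reported as
#' candidate deletion blocks, with the bp length measured from the first
#' gene's start to the last gene's end (1-based inclusive).
#'
#' @param referenceGenes reference gene table sorted by `start` (columns
#'   `id`, `start`, `end`).
#' @param map output of [bestHitMap()] (or a character vector of unmapped
#'   reference ids).
#' @param minBlock minimum number of consecutive unmapped genes.
#' @return data.frame with one row per block: `first_gene`, `last_gene`,
#'   `n_genes`, `genes` (`";"`-separated ids), `start`, `end`, `length_bp`;
#'   the attribute `total_deleted_bp` holds the summed block lengths.
#' @export
findMissingBlocks <- function(referenceGenes, map, minBlock = 2L) {
  stopifnot(is.data.frame(referenceGenes),
            all(c("id", "start", "end") %in% names(referenceGenes)))
  if (is.unsorted(referenceGenes$start))
    stop("reference genes must be sorted by start coordinate")
  unmapped <- if (is.list(map)) map$unmapped_queries else as.character(map)
  miss <- referenceGenes$id %in% unmapped
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(first_gene = character(), last_gene = character(),
                    n_genes = integer(), genes = character(),
                    start = integer(), end = integer(),
                    length_bp = integer(), stringsAsFactors = FALSE)
  for (i in which(r$values & r$lengths >= minBlock)) {
    idx <- starts[i]:ends[i]
    out <- rbind(out, data.frame(
      first_gene = referenceGenes$id[idx[1]],
      last_gene = referenceGenes$id[idx[length(idx)]],
      n_genes = length(idx),
      genes = paste(referenceGenes$id[idx], collapse = ";"),
      start = referenceGenes$start[idx[1]],
      end = referenceGenes$end[idx[length(idx)]],
      length_bp = referenceGenes$end[idx[length(idx)]] -
        referenceGenes$start[idx[1]] + 1L,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "total_deleted_bp") <- sum(out$length_bp)
  out
}
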