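#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums the probabilities
#' of all tables with the same margins whose point probability does not
#' exceed that of the observed table (the minimum-likelihood convention).
#'
#' @param a,b,c,d non-negative cell counts: set-and-category,
#'   set-not-category, rest-and-category, rest-not-category.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return The exact p-value.
#' @export
fisherExact <- function(a, b, c, d,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell counts")
  if (any(cells != round(cells))) stop("cell counts must be integers")
  min(1, fisher.test(matrix(as.integer(cells), nrow = 2, byrow = TRUE),
                     alternative = alternative)$p.value)
}

#' COG category enrichment of a gene set
#'
#' One two-sided Fisher's exact test per single-letter category, comparing
#' the annotated members of the gene set against the annotated remainder of
#' the background.  Genes without a category are excluded from the tests
#' and counted.  Significance tiers follow the three thresholds
#' `*` p < 0.01, `**` p < 0.001, `***` p < 0.00001.
#'
#' @param geneSet identifier vector, a subset of `background`.
#' @param annotations named character vector gene -> single-letter COG
#'   category (NA = unannotated), or a data.frame with `gene` and `cog`.
#' @param background identifier vector of the gene universe.
#' @return data.frame with one row per category: `category`, `set_count`,
#'   `set_total`, `bg_count`, `bg_total`, `p`, `direction`
#'   (`"over"`/`"under"`), `tier`.  Attributes `n_unannotated_set` and
#'   `n_unannotated_bg` count the excluded genes.
#' @export
cogEnrichment <- function(geneSet, annotations, background) {
  if (is.data.frame(annotations))
    annotations <- setNames(annotations$cog, annotations$gene)
  geneSet <- unique(geneSet)
  background <- unique(background)
  if (length(setdiff(geneSet, background)))
    stop("'geneSet' must be a subset of 'background'")
  ann <- annotations[background]
  names(ann) <- background
  ## multi-letter annotations: first letter
  ann <- ifelse(is.na(ann) | ann == "", NA_character_, substr(ann, 1L, 1L))
  annSet <- ann[geneSet]
  rest <- setdiff(background, geneSet)
  annRest <- ann[rest]
  nSet <- sum(!is.na(annSet))
  nRest <- sum(!is.na(annRest))
  cats <- sort(unique(stats::na.omit(ann)))
  res <- lapply(cats, function(cc) {
    a <- sum(annSet == cc, na.rm = TRUE)
    b <- nSet - a
    c_ <- sum(annRest == cc, na.rm = TRUE)
    d <- nRest - c_
    p <- fisherExact(a, b, c_, d)
    obs <- if (nSet > 0) a / nSet else 0
    expd <- (a + c_) / (nSet + nRest)
    data.frame(category = cc, set_count = a, set_total = nSet,
               bg_count = a + c_, bg_total = nSet + nRest, p = p,
               direction = if (obs >= expd) "over" else "under",
               tier = if (p < 1e-5) "***" else if (p < 1e-3) "**"
                 else if (p < 0.01) "*" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_unannotated_set") <- sum(is.na(annSet))
  attr(out, "n_unannotated_bg") <- sum(is.na(ann))
  out
}

#' Holm-Sidak step-down correction
#'
#' Sorts the p-values ascending, adjusts the k-th smallest of m as
#' `1 - (1 - p_(k))^(m - k + 1)`, enforces monotonicity with a running
#' maximum, and restores the input order.
#'
#' @param p p-values in `[0, 1]`.
#' @param alpha rejection level for the returned flags.
#' @return List with `adjusted` (same order as input) and `reject`.
#' @export
holmSidak <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  k <- seq_len(m)
  adj <- 1 - (1 - p[o])^(m - k + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  list(adjusted = out, reject = out <= alpha)
}

#' Acetylene-reduction activity units
#'
#' The ethylene fraction of the acetylene + ethylene peak areas, normalized
#' to total nodule dry weight (mg) and to 1 min incubation time — the
#' standard per-plant nitrogenase activity proxy from the acetylene
#' reduction assay.
#'
#' @param c2h4Area ethylene peak area (non-negative).
#' @param c2h2Area acetylene peak area (non-negative).
#' @param noduleDwMg total nodule dry weight per plant, mg (positive).
#' @param minutes incubation time in minutes (positive).
#' @return Activity units: `(c2h4 / (c2h4 + c2h2)) / noduleDwMg / minutes`.
#' @export
acetyleneUnits <- function(c2h4Area, c2h2Area, noduleDwMg, minutes) {
  stopifnot(c2h4Area >= 0, c2h2Area >= 0, noduleDwMg > 0, minutes > 0)
  if (c2h4Area + c2h2Area == 0) stop("both peak areas are zero")
  (c2h4Area / (c2h4Area + c2h2Area)) / noduleDwMg / minutes
}
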