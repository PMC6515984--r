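#' Assemble a PSM count matrix as a SummarizedExperiment
#'
#' @param counts integer matrix, proteins x samples.
#' @param condition factor/character of length `ncol(counts)` with levels
#'   `oxic` (reference) and `microoxic`.
#' @param replicate optional replicate index per sample.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` and `condition`/`replicate` in the column data.
#' @export
psmCountSet <- function(counts, condition, replicate = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stop("'condition' must have one entry per sample")
  bad <- setdiff(unique(condition), c("oxic", "microoxic"))
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  if (length(unique(condition)) < 1L) stop("at least one condition required")
  if (is.null(replicate)) replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = condition,
                                   replicate = as.integer(replicate),
                                   row.names = colnames(counts)))
}

#' @noRd
.getCounts <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    list(counts = as.matrix(SummarizedExperiment::assay(x, "counts")),
         condition = as.character(SummarizedExperiment::colData(x)$condition))
  } else {
    list(counts = as.matrix(x), condition = NULL)
  }
}

#' Median-of-ratios size factors
#'
#' For each sample the factor is the median, over proteins with all-positive
#' counts, of the ratio of the sample's count to the row geometric mean.
#' Factors are rescaled so that their geometric mean is 1.  When no row has
#' all-positive counts the function falls back to total-count ratios with a
#' warning.
#'
#' @param x count matrix or SummarizedExperiment from [psmCountSet()].
#' @return Named numeric vector of per-sample positive size factors.
#' @export
countSizeFactors <- function(x) {
  counts <- .getCounts(x)$counts
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no protein with all-positive counts; using total-count ratios")
    f <- colSums(counts)
    if (any(f == 0)) stop("sample with zero total count")
  } else {
    logGeo <- rowMeans(log(counts[pos, , drop = FALSE]))
    f <- apply(counts[pos, , drop = FALSE], 2L,
               function(cj) median(exp(log(cj) - logGeo)))
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Method-of-moments NB dispersions with trend shrinkage
#'
#' Per protein, a raw dispersion is estimated from normalized counts pooled
#' within conditions as `max(0, (s^2 - m) / m^2)` (variance and mean per
#' condition, combined with degrees-of-freedom weights).  Raw estimates are
#' then shrunk half-way toward a parametric mean-dispersion trend
#' `a0 + a1 / mean` fitted by least squares, and floored at `floor`.
#'
#' @param x count matrix or SummarizedExperiment.
#' @param sizeFactors per-sample size factors from [countSizeFactors()].
#' @param condition condition labels (taken from the SummarizedExperiment
#'   column data when omitted).
#' @param shrink weight on the fitted trend in `[0, 1]` (default 0.5).
#' @param floor lower bound for the returned dispersions.
#' @param prior dispersion used (with a warning) when no condition has
#'   two or more replicates.
#' @return Named numeric vector of per-protein dispersions.
#' @export
countDispersions <- function(x, sizeFactors, condition = NULL,
                             shrink = 0.5, floor = 1e-8, prior = 0.1) {
  g <- .getCounts(x)
  counts <- g$counts
  if (is.null(condition)) condition <- g$condition
  stopifnot(!is.null(condition), length(condition) == ncol(counts))
  norm <- sweep(counts, 2L, sizeFactors, "/")
  conds <- unique(condition)
  nrep <- vapply(conds, function(cc) sum(condition == cc), integer(1))
  if (all(nrep < 2L)) {
    warning("no condition with >= 2 replicates; using prior dispersion")
    return(setNames(rep(prior, nrow(counts)), rownames(counts)))
  }
  num <- rep(0, nrow(counts))
  den <- 0
  for (cc in conds[nrep >= 2L]) {
    sub <- norm[, condition == cc, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    w <- sum(condition == cc) - 1L
    num <- num + w * a
    den <- den + w
  }
  raw <- pmax(0, num / den)
  baseMean <- rowMeans(norm)
  use <- baseMean > 0 & is.finite(raw)
  trend <- rep(0, nrow(counts))
  if (sum(use) >= 3L) {
    fit <- lm(raw[use] ~ I(1 / baseMean[use]))
    a0 <- max(0, coef(fit)[1])
    a1 <- max(0, coef(fit)[2])
    trend <- ifelse(baseMean > 0, a0 + a1 / baseMean, 0)
  }
  disp <- pmax(floor, (1 - shrink) * raw + shrink * trend)
  setNames(disp, rownames(counts))
}

#' @noRd
.nbIrlsFit <- function(y, X, offset, alpha, maxit = 50L, tol = 1e-10) {
  beta <- c(log(max(mean(y / exp(offset)), 1e-8)), 0)
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    fisher <- XtW %*% X
    betaNew <- tryCatch(drop(solve(fisher, XtW %*% z)),
                        error = function(e) beta)
    betaNew <- pmin(pmax(betaNew, -30), 30)
    if (max(abs(betaNew - beta)) < tol) {
      beta <- betaNew
      break
    }
    beta <- betaNew
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  fisher <- t(X * w) %*% X
  cov <- tryCatch(solve(fisher), error = function(e) matrix(NA_real_, 2, 2))
  list(beta = beta, se = sqrt(cov[2, 2]))
}

#' Negative-binomial Wald test for two-condition spectral counts
#'
#' Per protein, fits the two-group NB log-linear model
#' `mu_ij = s_j * q_i * exp(beta * x_j)` (x = 1 for microoxic samples) by
#' iteratively reweighted least squares at fixed dispersion and reports the
#' Wald test of `beta = 0` against the standard normal reference.  Fold
#' changes are microoxic versus oxic.  This is a deliberately compact
#' count-model: no independent filtering, no fold-change shrinkage, normal
#' rather than t reference.
#'
#' @param x count matrix or SummarizedExperiment.
#' @param sizeFactors per-sample size factors.
#' @param dispersions per-protein dispersions.
#' @param condition condition labels (from column data when omitted).
#' @return data.frame with columns `protein`, `base_mean`, `log2fc`, `se`
#'   (standard error on the log2 scale), `p`, `padj` (Benjamini-Hochberg).
#'   All-zero proteins get `log2fc` 0 and missing p-values.
#' @export
nbWaldTest <- function(x, sizeFactors = NULL, dispersions = NULL,
                       condition = NULL) {
  g <- .getCounts(x)
  counts <- g$counts
  if (is.null(condition)) condition <- g$condition
  stopifnot(!is.null(condition), length(condition) == ncol(counts))
  if (!all(c("oxic", "microoxic") %in% condition))
    stop("both conditions must be present")
  if (is.null(sizeFactors)) sizeFactors <- countSizeFactors(counts)
  if (is.null(dispersions))
    dispersions <- countDispersions(counts, sizeFactors, condition)
  xj <- as.numeric(condition == "microoxic")
  X <- cbind(intercept = 1, microoxic = xj)
  offset <- log(sizeFactors)
  norm <- sweep(counts, 2L, sizeFactors, "/")
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("row", seq_len(n))
  out <- data.frame(protein = rownames(counts),
                    base_mean = rowMeans(norm),
                    log2fc = numeric(n), se = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    fit <- .nbIrlsFit(y, X, offset, dispersions[i])
    out$log2fc[i] <- fit$beta[2] / log(2)
    out$se[i] <- fit$se / log(2)
    if (is.finite(fit$se) && fit$se > 0) {
      z <- fit$beta[2] / fit$se
      out$p[i] <- 2 * pnorm(-abs(z))
    }
  }
  out$padj <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; missing values
#' are passed through and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Select core and relaxed differential sets
#'
#' The core sets apply the adjusted-p cutoff used to define the study's top
#' differentially expressed proteins (padj <= 0.2, split by sign of the
#' fold change); the relaxed set applies the transcriptomics-compatible
#' fold-change-only filter (log2 FC >= 1).
#'
#' @param results data.frame from [nbWaldTest()].
#' @param padjMax adjusted-p threshold for the core sets.
#' @param lfcMin log2 fold-change threshold for the relaxed up set.
#' @return List of protein id vectors `core_up`, `core_down`, `relaxed_up`.
#' @export
selectSets <- function(results, padjMax = 0.2, lfcMin = 1.0) {
  stopifnot(is.data.frame(results),
            all(c("protein", "log2fc", "padj") %in% names(results)))
  ok <- !is.na(results$padj)
  list(core_up = results$protein[ok & results$padj <= padjMax & results$log2fc > 0],
       core_down = results$protein[ok & results$padj <= padjMax & results$log2fc < 0],
       relaxed_up = results$protein[!is.na(results$log2fc) &
                                      results$log2fc >= lfcMin &
                                      !is.na(results$p)])
}

#' Read a tab-separated protein x sample count matrix
#'
#' Sample headers carry `:oxic` / `:microoxic` condition suffixes.
#'
#' @param path input file.
#' @return SummarizedExperiment as from [psmCountSet()].
#' @export
readCountMatrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, row.names = 1L)
  cn <- colnames(tab)
  cond <- sub("^.*:", "", cn)
  colnames(tab) <- sub(":[^:]*$", "", cn)
  psmCountSet(as.matrix(tab), cond)
}

#' Write a count SummarizedExperiment as tab-separated text
#'
#' @param se SummarizedExperiment from [psmCountSet()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(se, path) {
  counts <- SummarizedExperiment::assay(se, "counts")
  cond <- SummarizedExperiment::colData(se)$condition
  out <- as.data.frame(counts)
  colnames(out) <- paste0(colnames(counts), ":", cond)
  write.table(cbind(protein = rownames(counts), out), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
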