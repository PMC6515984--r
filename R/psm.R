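#' Target-decoy FDR threshold on PSM scores
#'
#' The FDR at score threshold `t` is estimated as the number of decoy PSMs
#' with score >= `t` divided by the number of target PSMs with score >= `t`.
#' The function scans the distinct observed scores and returns the smallest
#' threshold whose estimated FDR is at or below `targetFdr`; tied scores are
#' admitted together.
#'
#' @param psms data.frame with at least `score` (numeric, higher is better)
#'   and `is_decoy` (logical) columns.
#' @param targetFdr target FDR in (0, 1); the study-level default used
#'   throughout the package is 0.0035 (0.35 %).
#' @return List with `threshold` (score), `fdr` (estimated FDR at the
#'   threshold), and `accepted` (the target PSM rows with score >=
#'   threshold).  If no threshold attains the target FDR the accepted set
#'   is empty, the threshold is `Inf`, and a warning is raised.
#' @export
estimatePsmFdrThreshold <- function(psms, targetFdr = 0.0035) {
  stopifnot(is.data.frame(psms), all(c("score", "is_decoy") %in% names(psms)))
  if (!is.numeric(targetFdr) || targetFdr <= 0 || targetFdr >= 1)
    stop("'targetFdr' must be in (0, 1)")
  if (!any(psms$is_decoy)) stop("no decoy PSMs present; FDR not estimable")
  if (!any(!psms$is_decoy)) stop("no target PSMs present")
  sc <- psms$score
  dec <- psms$is_decoy
  ## cumulative counts at score >= t for every distinct candidate t
  ord <- order(sc, decreasing = TRUE)
  scSorted <- sc[ord]
  cumTarget <- cumsum(!dec[ord])
  cumDecoy <- cumsum(dec[ord])
  lastOfTie <- cumsum(rle(scSorted)$lengths)
  cand <- rev(scSorted[lastOfTie])            # ascending distinct scores
  nTarget <- rev(cumTarget[lastOfTie])
  nDecoy <- rev(cumDecoy[lastOfTie])
  fdr <- ifelse(nTarget > 0L, nDecoy / nTarget, Inf)
  ok <- which(fdr <= targetFdr & nTarget > 0L)
  if (!length(ok)) {
    warning("no score threshold attains the target FDR; returning empty set")
    return(list(threshold = Inf, fdr = NA_real_,
                accepted = psms[!dec & sc >= Inf, , drop = FALSE]))
  }
  i <- ok[1L]
  list(threshold = cand[i], fdr = fdr[i],
       accepted = psms[!dec & sc >= cand[i], , drop = FALSE])
}

#' Infer proteins from unambiguous peptide evidence in one condition
#'
#' Only class 1a and class 3a peptide evidence counts.  A protein (or 3a
#' group of identical-sequence proteins) is identified in a condition iff
#' it has at least two distinct unambiguous peptides, or at least three
#' unambiguous PSMs, within that condition.
#'
#' @param accepted data.frame of FDR-accepted PSMs with columns `peptide`
#'   and `condition`.
#' @param classes peptide classification table from [classifyPeptides()];
#'   must cover every accepted peptide.
#' @param condition the condition to evaluate (`"oxic"`, `"microoxic"`, or
#'   `"decoy"` for a symmetric decoy inference).
#' @return An [IdentificationSet].
#' @export
inferProteins <- function(accepted, classes, condition) {
  stopifnot(is.data.frame(accepted), is.data.frame(classes))
  condition <- match.arg(condition, c("oxic", "microoxic", "decoy"))
  rows <- if (condition == "decoy") accepted
    else accepted[accepted$condition == condition, , drop = FALSE]
  if (!nrow(rows)) {
    warning("no accepted PSMs for condition '", condition, "'")
    return(new("IdentificationSet", condition = condition,
               proteins = character(),
               evidence = data.frame(protein = character(),
                                     n_peptides = integer(),
                                     n_psms = integer(),
                                     identified = logical())))
  }
  missing <- setdiff(unique(rows$peptide), classes$peptide)
  if (length(missing))
    stop("peptide classes missing for ", length(missing), " peptide(s)")
  idx <- match(rows$peptide, classes$peptide)
  keep <- classes$class[idx] %in% c("1a", "3a")
  rows <- rows[keep, , drop = FALSE]
  key <- classes$proteins[idx][keep]
  if (!nrow(rows)) {
    ev <- data.frame(protein = character(), n_peptides = integer(),
                     n_psms = integer(), identified = logical())
  } else {
    npsm <- tapply(rows$peptide, key, length)
    npep <- tapply(rows$peptide, key, function(p) length(unique(p)))
    ev <- data.frame(protein = names(npsm),
                     n_peptides = as.integer(npep[names(npsm)]),
                     n_psms = as.integer(npsm),
                     stringsAsFactors = FALSE)
    ev <- ev[order(ev$protein), , drop = FALSE]
    rownames(ev) <- NULL
    ev$identified <- ev$n_peptides >= 2L | ev$n_psms >= 3L
  }
  new("IdentificationSet", condition = condition,
      proteins = ev$protein[ev$identified], evidence = ev)
}

#' Decoy-based protein-level FDR estimate
#'
#' Ratio of decoy-identified to target-identified proteins, with the decoy
#' identifications computed by applying the same inference rule to decoy
#' PSMs.
#'
#' @param targets [IdentificationSet] from target PSMs.
#' @param decoys [IdentificationSet] from decoy PSMs.
#' @return Estimated protein-level FDR; `NA` (with a warning) when there
#'   are no target identifications.
#' @export
estimateProteinFdr <- function(targets, decoys) {
  stopifnot(is(targets, "IdentificationSet"), is(decoys, "IdentificationSet"))
  nt <- length(identifiedProteins(targets))
  nd <- length(identifiedProteins(decoys))
  if (nt == 0L) {
    warning("no target identifications; protein FDR undefined")
    return(NA_real_)
  }
  nd / nt
}

#' Two-set Venn accounting
#'
#' @param setA,setB identifier vectors (or [IdentificationSet]s).
#' @return List with `shared`, `only_a`, `only_b`, `union` counts.
#' @export
conditionVenn <- function(setA, setB) {
  if (is(setA, "IdentificationSet")) setA <- identifiedProteins(setA)
  if (is(setB, "IdentificationSet")) setB <- identifiedProteins(setB)
  setA <- unique(setA)
  setB <- unique(setB)
  sh <- length(intersect(setA, setB))
  list(shared = sh,
       only_a = length(setA) - sh,
       only_b = length(setB) - sh,
       union = length(setA) + length(setB) - sh)
}

#' Venn counts from printed set sizes
#'
#' Same arithmetic as [conditionVenn()] but starting from the sizes of two
#' sets and of their intersection, for worked examples where only published
#' counts are available.
#'
#' @param nA,nB set sizes.
#' @param nShared size of the intersection.
#' @return List with `shared`, `only_a`, `only_b`, `union` counts.
#' @examples
#' vennFromCounts(2900, 2826, 2538)  # union 3188, only_b 288
#' @export
vennFromCounts <- function(nA, nB, nShared) {
  stopifnot(nShared <= nA, nShared <= nB, nShared >= 0)
  list(shared = nShared,
       only_a = nA - nShared,
       only_b = nB - nShared,
       union = nA + nB - nShared)
}
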