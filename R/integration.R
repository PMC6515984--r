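#' Microoxia-specific union across expression layers
#'
#' Builds the set of genes/proteins expressed only under microoxia at
#' either layer.  With S_t = transcripts detected only microoxically and
#' S_p = proteins detected only microoxically, the result is
#' `(S_t U S_p)` minus members of S_t whose protein was detected oxically,
#' minus members of S_p whose transcript was detected oxically, minus an
#' explicit list of annotation-difference exclusions.
#'
#' @param transcriptCalls data.frame with columns `gene`, `detected_oxic`,
#'   `detected_microoxic` for the transcript layer.
#' @param proteinCalls same layout for the protein layer.  Identifiers
#'   must be harmonized (protein genes present in the transcript table);
#'   offenders raise an error.
#' @param exclusions character vector of genes to exclude (annotation
#'   differences between the strains).
#' @return List with `set` (the final identifier set) and `breakdown`
#'   (named counts: `s_t`, `s_p`, `s_t_and_s_p`, `removed_protein_oxic`,
#'   `removed_transcript_oxic`, `excluded`, `final`), satisfying
#'   `final = s_t + s_p - s_t_and_s_p - removals - excluded`.
#' @export
microoxiaSpecificUnion <- function(transcriptCalls, proteinCalls,
                                   exclusions = character()) {
  need <- c("gene", "detected_oxic", "detected_microoxic")
  stopifnot(all(need %in% names(transcriptCalls)),
            all(need %in% names(proteinCalls)))
  offenders <- setdiff(proteinCalls$gene, transcriptCalls$gene)
  if (length(offenders))
    stop("unharmonized identifiers (protein layer only): ",
         paste(head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) " ...")
  st <- transcriptCalls$gene[transcriptCalls$detected_microoxic &
                               !transcriptCalls$detected_oxic]
  sp <- proteinCalls$gene[proteinCalls$detected_microoxic &
                            !proteinCalls$detected_oxic]
  protOxic <- proteinCalls$gene[proteinCalls$detected_oxic]
  trOxic <- transcriptCalls$gene[transcriptCalls$detected_oxic]
  both <- intersect(st, sp)
  rmT <- intersect(setdiff(st, sp), protOxic)
  rmP <- intersect(setdiff(sp, st), trOxic)
  set0 <- setdiff(union(st, sp), union(rmT, rmP))
  excl <- intersect(set0, exclusions)
  final <- setdiff(set0, excl)
  breakdown <- c(s_t = length(st), s_p = length(sp),
                 s_t_and_s_p = length(both),
                 removed_protein_oxic = length(rmT),
                 removed_transcript_oxic = length(rmP),
                 excluded = length(excl),
                 final = length(final))
  list(set = sort(final), breakdown = breakdown)
}

#' Overlap of induced protein sets with the induced transcriptome
#'
#' @param coreUp proteins induced at the stringent (adjusted-p) threshold.
#' @param relaxedUp proteins induced at the fold-change-only threshold;
#'   must contain `coreUp`.
#' @param transcriptInduced genes induced at the transcript layer.
#' @return List with the id sets `core_overlap` (core and transcript
#'   induced), `expanded` (relaxed and transcript induced, the "expanded
#'   microoxia-induced transcriptome/proteome"), `extra`
#'   (expanded minus core overlap), and their sizes in `counts`.
#' @export
overlapWithTranscriptome <- function(coreUp, relaxedUp, transcriptInduced) {
  coreUp <- unique(coreUp)
  relaxedUp <- unique(relaxedUp)
  transcriptInduced <- unique(transcriptInduced)
  if (length(setdiff(coreUp, relaxedUp)))
    stop("'coreUp' must be a subset of 'relaxedUp'")
  coreOv <- intersect(coreUp, transcriptInduced)
  expanded <- intersect(relaxedUp, transcriptInduced)
  extra <- setdiff(expanded, coreOv)
  list(core_overlap = sort(coreOv), expanded = sort(expanded),
       extra = sort(extra),
       counts = c(core_overlap = length(coreOv),
                  expanded = length(expanded),
                  extra = length(extra)))
}

#' Overlap of a gene set with named regulons
#'
#' @param geneSet identifier vector.
#' @param regulons named list of identifier vectors.
#' @return data.frame with `regulon`, `regulon_size`, `count` (overlap)
#'   and `fraction` (of `geneSet`; `NA` when the gene set is empty).
#' @export
regulonOverlap <- function(geneSet, regulons) {
  stopifnot(is.list(regulons), !is.null(names(regulons)))
  geneSet <- unique(geneSet)
  cnt <- vapply(regulons, function(r) length(intersect(geneSet, r)), integer(1))
  data.frame(regulon = names(regulons),
             regulon_size = lengths(lapply(regulons, unique)),
             count = cnt,
             fraction = if (length(geneSet)) cnt / length(geneSet) else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transcript-up/protein-flat discordance classifier
#'
#' A transcript-induced gene is discordant (a post-transcriptional-control
#' candidate) when its protein-level result shows no induction: log2 FC at
#' or below `lfcMax`, or p-value at or above `pMin`.  Genes without a
#' protein result are excluded and reported separately.
#'
#' @param transcriptInduced genes induced at the transcript layer.
#' @param proteinResults data.frame from [nbWaldTest()] (columns `protein`,
#'   `log2fc`, `p`, `padj`).
#' @param lfcMax protein log2 FC ceiling for discordance (default 0.5,
#'   applied literally, not as -0.5).
#' @param pMin p-value floor for discordance (default 0.9).
#' @param use which p-value the `pMin` rule reads: the multiplicity
#'   adjusted one (default, consistent with the adjusted-p core threshold)
#'   or the raw one.
#' @return List with `discordant` (sorted ids) and `missing` (transcript
#'   induced genes without protein results).
#' @export
classifyDiscordant <- function(transcriptInduced, proteinResults,
                               lfcMax = 0.5, pMin = 0.9,
                               use = c("padj", "p")) {
  use <- match.arg(use)
  stopifnot(is.data.frame(proteinResults),
            all(c("protein", "log2fc", use) %in% names(proteinResults)))
  transcriptInduced <- unique(transcriptInduced)
  idx <- match(transcriptInduced, proteinResults$protein)
  has <- !is.na(idx)
  lfc <- proteinResults$log2fc[idx[has]]
  pv <- proteinResults[[use]][idx[has]]
  hasResult <- !is.na(lfc) & !is.na(pv)
  disc <- (lfc <= lfcMax | pv >= pMin) & hasResult
  list(discordant = sort(transcriptInduced[has][disc]),
       missing = sort(c(transcriptInduced[!has],
                        transcriptInduced[has][!hasResult])))
}

#' Three-criterion filter for post-transcriptional-control candidates
#'
#' Criterion (i): the protein is soluble by consensus topology;
#' (ii): the gene codes for a protein with an assigned function (not a
#' hypothetical protein); (iii): an antibody against the protein (or a
#' cross-reacting ortholog) is available.  A candidate is selected iff all
#' three hold.
#'
#' @param discordant identifier vector from [classifyDiscordant()].
#' @param topologyCalls data.frame from [callTopology()].
#' @param genes gene table with `id` and `has_function` columns.
#' @param antibodies data.frame with `gene` and `antibody` (logical), or a
#'   character vector of genes with antibodies.
#' @return data.frame with one row per discordant gene: `gene`, `soluble`,
#'   `has_function`, `antibody`, `selected`.
#' @export
filterCandidates <- function(discordant, topologyCalls, genes, antibodies) {
  discordant <- unique(discordant)
  if (is.character(antibodies))
    antibodies <- data.frame(gene = antibodies, antibody = TRUE,
                             stringsAsFactors = FALSE)
  missTop <- setdiff(discordant, topologyCalls$protein)
  missGene <- setdiff(discordant, genes$id)
  if (length(missTop) || length(missGene))
    stop("missing annotation rows for: ",
         paste(unique(c(missTop, missGene)), collapse = ", "))
  soluble <- topologyCalls$class[match(discordant, topologyCalls$protein)] ==
    "soluble"
  hasFun <- genes$has_function[match(discordant, genes$id)]
  ab <- discordant %in% antibodies$gene[antibodies$antibody]
  data.frame(gene = discordant, soluble = soluble, has_function = hasFun,
             antibody = ab, selected = soluble & hasFun & ab,
             stringsAsFactors = FALSE)
}
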