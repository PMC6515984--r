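#' Default pipeline thresholds
#'
#' The stage thresholds used throughout the package: PSM-level FDR 0.35 %,
#' adjusted-p cutoff 0.2 for the core differential sets, log2 FC >= 1 for
#' the relaxed set, E-value ceiling 1e-5 for ortholog mapping, >= 10 aa
#' predictor overlap and a 2-TM-domain cutoff for topology, and the
#' log2 FC <= 0.5 / p >= 0.9 discordance rule.
#'
#' @return Named list of thresholds.
#' @export
defaultThresholds <- function() {
  list(psmFdr = 0.0035, padjMax = 0.2, lfcMin = 1.0, evalueMax = 1e-5,
       minOverlap = 10L, lfcMaxDiscordant = 0.5, pMinDiscordant = 0.9,
       minBlock = 2L)
}

#' Run the integrated proteome/transcriptome pipeline
#'
#' Executes the stages in dependency order: peptide classification ->
#' PSM FDR filtering and protein inference -> differential abundance ->
#' cross-strain mapping and deletion-block detection -> topology calls ->
#' expression-set integration and discordance classification -> COG
#' enrichment.  All inputs are in-memory objects; [synthDemo()] wires the
#' synthetic generator into this function.
#'
#' @param config list with elements:
#'   `psms` (PSM table: `peptide`, `score`, `is_decoy`, `sample`,
#'   `condition`, `replicate`), `proteome` (target proteome,
#'   AAStringSet or named character), `decoyProteome` (optional; reversed
#'   target proteome by default), `counts` (SummarizedExperiment from
#'   [psmCountSet()]), `geneTable` (derivative gene table with `id`,
#'   `has_function`), `transcriptCalls` (transcript table, optionally in a
#'   reference-strain id space), `referenceProteome`/`referenceGenes`
#'   (optional; enables best-hit harmonization and deletion-block
#'   detection), `annotations` (list with `cog`, `topology`, `antibody`),
#'   `cogBackground` (optional id vector for enrichment background),
#'   `regulons` (optional named list), `exclusions` (optional id vector),
#'   `thresholds` (optional overrides of [defaultThresholds()]), `seed`
#'   (recorded in the report).
#' @return A pipeline report: list with per-stage counts, the stage
#'   outputs under `$tables`, and provenance under `$provenance`.
#' @export
runPipeline <- function(config) {
  need <- c("psms", "proteome", "counts", "geneTable", "transcriptCalls",
            "annotations")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("pipeline config is missing input(s): ", paste(miss, collapse = ", "))
  thr <- utils::modifyList(defaultThresholds(),
                           if (is.null(config$thresholds)) list()
                           else config$thresholds)
  prot <- asAAStringSet(config$proteome)
  decoyProt <- if (is.null(config$decoyProteome)) reverseProteome(prot)
    else asAAStringSet(config$decoyProteome)
  psms <- config$psms

  ## stage 1: peptide classification -------------------------------------
  targetPeps <- unique(psms$peptide[!psms$is_decoy])
  decoyPeps <- unique(psms$peptide[psms$is_decoy])
  classes <- classifyPeptides(targetPeps, prot)
  decoyClasses <- if (length(decoyPeps))
    classifyPeptides(decoyPeps, decoyProt) else classes[0, ]

  ## stage 2: PSM FDR control and protein inference ----------------------
  filt <- estimatePsmFdrThreshold(psms, thr$psmFdr)
  acceptedDecoys <- psms[psms$is_decoy & psms$score >= filt$threshold, ,
                         drop = FALSE]
  idOx <- inferProteins(filt$accepted, classes, "oxic")
  idMic <- inferProteins(filt$accepted, classes, "microoxic")
  idDecoy <- if (nrow(acceptedDecoys))
    inferProteins(acceptedDecoys, decoyClasses, "decoy")
    else new("IdentificationSet", condition = "decoy",
             proteins = character(),
             evidence = data.frame(protein = character(),
                                   n_peptides = integer(),
                                   n_psms = integer(),
                                   identified = logical()))
  overallTargets <- new("IdentificationSet", condition = "microoxic",
                        proteins = union(identifiedProteins(idOx),
                                         identifiedProteins(idMic)),
                        evidence = data.frame(
                          protein = union(identifiedProteins(idOx),
                                          identifiedProteins(idMic)),
                          n_peptides = 2L, n_psms = 3L, identified = TRUE))
  proteinFdr <- if (length(identifiedProteins(overallTargets)))
    estimateProteinFdr(overallTargets, idDecoy) else NA_real_
  venn <- conditionVenn(idOx, idMic)

  ## stage 3: differential abundance -------------------------------------
  sf <- countSizeFactors(config$counts)
  disp <- countDispersions(config$counts, sf)
  res <- nbWaldTest(config$counts, sf, disp)
  sets <- selectSets(res, thr$padjMax, thr$lfcMin)

  ## stage 4: cross-strain mapping ---------------------------------------
  transcripts <- config$transcriptCalls
  mapInfo <- NULL
  blocks <- NULL
  nDroppedTranscripts <- 0L
  if (!is.null(config$referenceProteome)) {
    mapInfo <- bestHitMap(config$referenceProteome, prot,
                          evalueMax = thr$evalueMax)
    if (!is.null(config$referenceGenes))
      blocks <- findMissingBlocks(config$referenceGenes, mapInfo,
                                  thr$minBlock)
    tr <- mapInfo$pairs$subject[match(transcripts$gene, mapInfo$pairs$query)]
    keep <- !is.na(tr)
    nDroppedTranscripts <- sum(!keep)
    transcripts <- transcripts[keep, , drop = FALSE]
    transcripts$gene <- tr[keep]
  }

  ## stage 5: topology ----------------------------------------------------
  topo <- callTopology(config$annotations$topology,
                       proteins = config$geneTable$id,
                       minOverlap = thr$minOverlap)

  ## stage 6: integration -------------------------------------------------
  protCalls <- proteinCallsFromIdentifications(idOx, idMic,
                                               config$geneTable$id)
  ## restrict to the harmonized universe (inserted/unmapped genes drop out)
  protCalls <- protCalls[protCalls$gene %in% transcripts$gene, , drop = FALSE]
  exclusions <- if (is.null(config$exclusions)) character()
    else config$exclusions
  uni <- microoxiaSpecificUnion(transcripts, protCalls, exclusions)
  transcriptInduced <- transcripts$gene[transcripts$detected_microoxic &
                                          !is.na(transcripts$log2fc) &
                                          transcripts$log2fc >= thr$lfcMin]
  coreForOverlap <- intersect(sets$core_up, sets$relaxed_up)
  overlap <- overlapWithTranscriptome(coreForOverlap, sets$relaxed_up,
                                      transcriptInduced)
  disc <- classifyDiscordant(transcriptInduced, res,
                             thr$lfcMaxDiscordant, thr$pMinDiscordant)
  cand <- filterCandidates(
    intersect(disc$discordant, config$geneTable$id),
    topo, config$geneTable, config$annotations$antibody)
  regulons <- if (is.null(config$regulons)) NULL
    else regulonOverlap(sets$core_up, config$regulons)

  ## stage 7: enrichment ---------------------------------------------------
  enrich <- NULL
  if (!is.null(blocks) && nrow(blocks) && !is.null(config$cogBackground)) {
    blockGenes <- unlist(strsplit(blocks$genes, ";", fixed = TRUE))
    enrich <- cogEnrichment(blockGenes, config$annotations$cog,
                            config$cogBackground)
  }

  report <- list(
    thresholds = thr,
    psm = list(n_records = nrow(psms),
               n_target = sum(!psms$is_decoy),
               n_decoy = sum(psms$is_decoy),
               threshold = filt$threshold,
               psm_fdr = filt$fdr,
               n_accepted = nrow(filt$accepted)),
    identification = list(n_oxic = length(identifiedProteins(idOx)),
                          n_microoxic = length(identifiedProteins(idMic)),
                          shared = venn$shared,
                          only_oxic = venn$only_a,
                          only_microoxic = venn$only_b,
                          union = venn$union,
                          protein_fdr = proteinFdr),
    diff = list(n_tested = sum(!is.na(res$p)),
                core_up = length(sets$core_up),
                core_down = length(sets$core_down),
                relaxed_up = length(sets$relaxed_up)),
    mapping = if (is.null(mapInfo)) NULL else list(
      n_mapped = nrow(mapInfo$pairs),
      n_unmapped = length(mapInfo$unmapped_queries),
      n_blocks = if (is.null(blocks)) NA_integer_ else nrow(blocks),
      total_deleted_bp = if (is.null(blocks)) NA_integer_
        else attr(blocks, "total_deleted_bp"),
      n_dropped_transcripts = nDroppedTranscripts),
    topology = as.list(table(topo$class)),
    integration = list(breakdown = as.list(uni$breakdown),
                       n_transcript_induced = length(transcriptInduced),
                       core_overlap = overlap$counts[["core_overlap"]],
                       expanded = overlap$counts[["expanded"]],
                       extra = overlap$counts[["extra"]],
                       n_discordant = length(disc$discordant),
                       n_missing_protein = length(disc$missing),
                       n_criteria_i_ii = sum(cand$soluble & cand$has_function),
                       n_selected = sum(cand$selected)),
    provenance = list(seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("microxia")))
  )
  report$tables <- list(results = res, sets = sets, topology = topo,
                        identification = list(oxic = idOx, microoxic = idMic),
                        microoxia_specific = uni$set,
                        discordant = disc$discordant,
                        candidates = cand,
                        blocks = blocks,
                        map = mapInfo,
                        enrichment = enrich,
                        regulons = regulons)
  class(report) <- "microxiaReport"
  report
}

#' Serialize a pipeline report (without bulky tables) to JSON
#'
#' The serialized counts are reproducible from the stage outputs; two runs
#' with identical inputs and seed produce byte-identical JSON.
#'
#' @param report a pipeline report from [runPipeline()].
#' @param path optional output file.
#' @return The JSON string, invisibly when `path` is given.
#' @export
reportToJson <- function(report, path = NULL) {
  x <- unclass(report)
  x$tables <- NULL
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                           null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Check the internal count identities of a pipeline report
#'
#' Asserts the set-arithmetic identities every valid report must satisfy:
#' Venn sums per condition, union = |A| + |B| - shared, expanded =
#' core overlap + extra, and the microoxia-specific breakdown identity
#' final = s_t + s_p - overlap - removals - exclusions.
#'
#' @param report a pipeline report from [runPipeline()].
#' @return `TRUE` iff all identities hold.
#' @export
validateReportIdentities <- function(report) {
  id <- report$identification
  ig <- report$integration
  bd <- ig$breakdown
  checks <- c(
    id$only_oxic + id$shared == id$n_oxic,
    id$only_microoxic + id$shared == id$n_microoxic,
    id$union == id$n_oxic + id$n_microoxic - id$shared,
    ig$expanded == ig$core_overlap + ig$extra,
    bd$final == bd$s_t + bd$s_p - bd$s_t_and_s_p -
      bd$removed_protein_oxic - bd$removed_transcript_oxic - bd$excluded
  )
  all(checks)
}

#' Generate a synthetic dataset and run the pipeline end to end
#'
#' Builds a strain pair, plants ground truth, simulates the PSM dataset,
#' transcript calls (in the reference strain's id space, so the best-hit
#' harmonization stage is exercised) and feature annotations, and runs
#' [runPipeline()].  The default problem size (120 reference genes, a
#' 12-gene deletion block, 3 inserted genes, 2 conditions x 3 replicates)
#' keeps a full run in the tens of seconds while leaving every stage with
#' enough signal to recover the planted truth at zero noise.
#'
#' @param seed integer seed driving every random draw.
#' @param nGenes,deletionSize,nInsertions strain-pair geometry.
#' @param noise the demo's single noise knob: detection-flag flip
#'   probability for the transcript layer, predictor noise for the
#'   topology layer, and the random-match (false target) rate of the PSM
#'   generator.  At `noise = 0` every stage can recover the planted truth
#'   exactly.
#' @param truthArgs optional list of overrides for [simulateGroundTruth()].
#' @param psmArgs optional list of overrides for [generatePsmDataset()].
#' @return List with `report` (see [runPipeline()]), `truth`, `pair`, and
#'   the generated `inputs`.
#' @export
synthDemo <- function(seed = 1L, nGenes = 120L, deletionSize = 12L,
                      nInsertions = 3L, noise = 0, truthArgs = list(),
                      psmArgs = list()) {
  pair <- generateStrainPair(nGenes, deletionSize, nInsertions,
                             seed = seed)
  der <- derivativeGenes(pair)
  if (is.null(truthArgs$excludeFromTruth))
    truthArgs$excludeFromTruth <- der$id[is.na(der$ref_id)]
  truth <- do.call(simulateGroundTruth,
                   c(list(genes = der$id, seed = seed + 1L), truthArgs))
  prot <- strainProteome(pair, "derivative")
  if (is.null(psmArgs$falseTargetRate)) psmArgs$falseTargetRate <- noise
  psmData <- do.call(generatePsmDataset,
                     c(list(proteome = prot, truth = truth,
                            seed = seed + 2L), psmArgs))
  ## transcripts are measured in the reference id space
  toRef <- setNames(der$ref_id, der$id)
  refTruth <- truth
  mapSet <- function(x) as.character(stats::na.omit(toRef[x]))
  refTruth@inducedTranscripts <- mapSet(truth@inducedTranscripts)
  refTruth@microoxiaSpecificTranscripts <-
    mapSet(truth@microoxiaSpecificTranscripts)
  refTruth@undetectedTranscripts <- mapSet(truth@undetectedTranscripts)
  refTruth@discordantGenes <- mapSet(truth@discordantGenes)
  refTruth@inducedProteins <- mapSet(truth@inducedProteins)
  refIds <- referenceGenes(pair)$id
  transcripts <- generateTranscriptomeCalls(refIds, refTruth,
                                            noise = noise, seed = seed + 3L)
  ann <- generateFeatureAnnotations(der, truth, predictorNoise = noise,
                                    seed = seed + 4L)
  ## COG annotations for the reference universe (enrichment background)
  refAnn <- generateFeatureAnnotations(
    referenceGenes(pair), refTruth, predictorNoise = 0, seed = seed + 5L,
    deletionBlock = deletedBlock(pair))
  config <- list(
    psms = psmData$psms,
    proteome = prot,
    counts = psmData$counts,
    geneTable = der,
    transcriptCalls = transcripts,
    referenceProteome = strainProteome(pair, "reference"),
    referenceGenes = referenceGenes(pair),
    annotations = list(cog = refAnn$cog, topology = ann$topology,
                       antibody = ann$antibody),
    cogBackground = refIds,
    regulons = list(planted_regulon = truth@inducedProteins),
    seed = seed)
  list(report = runPipeline(config), truth = truth, pair = pair,
       inputs = config)
}
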