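#' StrainPair: a reference strain and a derivative differing by a deletion
#'
#' Container for a pair of annotated bacterial strains in which the
#' derivative lacks one contiguous block of reference genes and may carry a
#' few inserted genes, mirroring the relationship between a sequenced
#' laboratory derivative and its reference genome.  Gene tables are
#' data.frames with columns `id`, `gene_id`, `sequence` (protein, one-letter
#' code), `start`, `end` (1-based inclusive bp), `strand`, `product`,
#' `has_function`, and, for the derivative, `ref_id` (the reference
#' counterpart, `NA` for inserted genes).
#'
#' @slot referenceGenes data.frame of reference-strain genes.
#' @slot derivativeGenes data.frame of derivative-strain genes.
#' @slot deletedBlock character, reference ids of the deleted block.
#' @slot insertedGenes character, derivative ids of inserted genes.
#' @slot referenceLength integer, reference genome length in bp.
#' @slot derivativeLength integer, derivative genome length in bp.
#' @name StrainPair-class
#' @aliases StrainPair
#' @exportClass StrainPair
setClass("StrainPair",
  representation(
    referenceGenes = "data.frame",
    derivativeGenes = "data.frame",
    deletedBlock = "character",
    insertedGenes = "character",
    referenceLength = "integer",
    derivativeLength = "integer"
  )
)

setValidity("StrainPair", function(object) {
  msg <- character()
  ref <- object@referenceGenes
  der <- object@derivativeGenes
  need <- c("id", "gene_id", "sequence", "start", "end", "strand",
            "product", "has_function")
  if (!all(need %in% names(ref))) msg <- c(msg, "reference gene table lacks required columns")
  if (!all(c(need, "ref_id") %in% names(der))) msg <- c(msg, "derivative gene table lacks required columns")
  if (length(msg)) return(msg)
  if (anyDuplicated(ref$id)) msg <- c(msg, "duplicated reference gene ids")
  if (anyDuplicated(der$id)) msg <- c(msg, "duplicated derivative gene ids")
  if (!all(object@deletedBlock %in% ref$id))
    msg <- c(msg, "deleted block genes must be reference genes")
  if (any(object@deletedBlock %in% der$ref_id))
    msg <- c(msg, "deleted block genes must be absent from the derivative")
  if (!all(object@insertedGenes %in% der$id))
    msg <- c(msg, "inserted genes must be derivative genes")
  if (any(!is.na(der$ref_id[der$id %in% object@insertedGenes])))
    msg <- c(msg, "inserted genes must have no reference counterpart")
  if (any(ref$start > ref$end) || any(der$start > der$end))
    msg <- c(msg, "gene coordinates must satisfy start <= end")
  if (length(msg)) msg else TRUE
})

#' @describeIn StrainPair-class reference-strain gene table.
#' @param x a `StrainPair`.
#' @export
referenceGenes <- function(x) {
  stopifnot(is(x, "StrainPair"))
  x@referenceGenes
}

#' @describeIn StrainPair-class derivative-strain gene table.
#' @export
derivativeGenes <- function(x) {
  stopifnot(is(x, "StrainPair"))
  x@derivativeGenes
}

#' @describeIn StrainPair-class ids of the deleted reference gene block.
#' @export
deletedBlock <- function(x) {
  stopifnot(is(x, "StrainPair"))
  x@deletedBlock
}

#' @describeIn StrainPair-class ids of genes only present in the derivative.
#' @export
insertedGenes <- function(x) {
  stopifnot(is(x, "StrainPair"))
  x@insertedGenes
}

#' Extract a strain proteome as an AAStringSet
#'
#' @param x a [StrainPair].
#' @param strain `"reference"` or `"derivative"`.
#' @return An [Biostrings::AAStringSet] named by gene id.
#' @export
strainProteome <- function(x, strain = c("derivative", "reference")) {
  stopifnot(is(x, "StrainPair"))
  strain <- match.arg(strain)
  tab <- if (strain == "reference") x@referenceGenes else x@derivativeGenes
  Biostrings::AAStringSet(setNames(tab$sequence, tab$id))
}

setMethod("show", "StrainPair", function(object) {
  cat("StrainPair\n")
  cat("  reference:  ", nrow(object@referenceGenes), "genes,",
      object@referenceLength, "bp\n")
  cat("  derivative: ", nrow(object@derivativeGenes), "genes,",
      object@derivativeLength, "bp\n")
  cat("  deleted block:", length(object@deletedBlock),
      "genes; inserted:", length(object@insertedGenes), "\n")
})

#' GroundTruth: planted truth labels for the synthetic data generator
#'
#' Records which genes the generator made microoxia-induced at each layer,
#' which are detected only under microoxia, which are planted
#' transcript-up/protein-flat (discordant) genes, the true per-protein
#' log2 fold changes used for count simulation, and the true membrane
#' topology class per protein.  `silentProteins` (never detected at the
#' protein layer) and `undetectedTranscripts` (never detected at the
#' transcript layer) are generator bookkeeping that let the expression-call
#' generators realise the planted cross-layer breakdown.
#'
#' @slot inducedProteins character, microoxia-induced at the protein layer.
#' @slot inducedTranscripts character, microoxia-induced at the transcript layer.
#' @slot microoxiaSpecificTranscripts character, transcript detected only microoxically.
#' @slot microoxiaSpecificProteins character, protein detected only microoxically.
#' @slot discordantGenes character, planted post-transcriptional-control genes.
#' @slot trueLog2fc named numeric, true protein-layer log2 fold change.
#' @slot topologyTruth named character, one of TM / membrane-anchored / secreted / soluble.
#' @slot silentProteins character, never detected at the protein layer.
#' @slot undetectedTranscripts character, never detected at the transcript layer.
#' @name GroundTruth-class
#' @aliases GroundTruth
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    inducedProteins = "character",
    inducedTranscripts = "character",
    microoxiaSpecificTranscripts = "character",
    microoxiaSpecificProteins = "character",
    discordantGenes = "character",
    trueLog2fc = "numeric",
    topologyTruth = "character",
    silentProteins = "character",
    undetectedTranscripts = "character"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(object@discordantGenes %in% object@inducedTranscripts))
    msg <- c(msg, "discordant genes must be a subset of induced transcripts")
  if (length(intersect(object@discordantGenes, object@inducedProteins)))
    msg <- c(msg, "discordant genes must not be induced at the protein layer")
  if (is.null(names(object@trueLog2fc)) && length(object@trueLog2fc))
    msg <- c(msg, "trueLog2fc must be named by gene id")
  bad <- setdiff(unique(object@topologyTruth),
                 c("TM", "membrane-anchored", "secreted", "soluble"))
  if (length(bad)) msg <- c(msg, paste("unknown topology class:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth for", length(object@trueLog2fc), "genes\n")
  cat("  induced proteins:    ", length(object@inducedProteins), "\n")
  cat("  induced transcripts: ", length(object@inducedTranscripts), "\n")
  cat("  microoxia-specific:  ", length(object@microoxiaSpecificTranscripts),
      "transcripts /", length(object@microoxiaSpecificProteins), "proteins\n")
  cat("  discordant genes:    ", length(object@discordantGenes), "\n")
})

#' @describeIn GroundTruth-class true per-protein log2 fold change map.
#' @param x a `GroundTruth`.
#' @export
trueLog2fc <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@trueLog2fc
}

#' @describeIn GroundTruth-class planted discordant (transcript-up/protein-flat) genes.
#' @export
discordantGenes <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@discordantGenes
}

#' @describeIn GroundTruth-class true topology class per protein.
#' @export
topologyTruth <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@topologyTruth
}

#' IdentificationSet: proteins identified in one condition
#'
#' Result of applying the protein-inference rule (at least two distinct
#' unambiguous peptides, or at least three unambiguous PSMs, per condition)
#' to FDR-accepted PSMs.  Identical-sequence (class 3a) protein groups are
#' reported as one entry keyed by the sorted id set joined with ";".
#'
#' @slot condition `"oxic"` or `"microoxic"`.
#' @slot proteins character, identified protein (or 3a group) keys.
#' @slot evidence data.frame with columns `protein`, `n_peptides`,
#'   `n_psms`, `identified` for every protein with any unambiguous evidence.
#' @name IdentificationSet-class
#' @aliases IdentificationSet
#' @exportClass IdentificationSet
setClass("IdentificationSet",
  representation(
    condition = "character",
    proteins = "character",
    evidence = "data.frame"
  )
)

setValidity("IdentificationSet", function(object) {
  msg <- character()
  if (length(object@condition) != 1L ||
      !object@condition %in% c("oxic", "microoxic", "decoy"))
    msg <- c(msg, "condition must be one of 'oxic', 'microoxic', 'decoy'")
  ev <- object@evidence
  if (nrow(ev)) {
    ok <- ev$n_peptides >= 2L | ev$n_psms >= 3L
    if (!setequal(object@proteins, ev$protein[ok]))
      msg <- c(msg, "proteins slot must equal the evidence rows passing the inference rule")
  } else if (length(object@proteins)) {
    msg <- c(msg, "proteins present without evidence")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "IdentificationSet", function(object) {
  cat("IdentificationSet (", object@condition, "): ",
      length(object@proteins), " proteins from ",
      nrow(object@evidence), " evidence rows\n", sep = "")
})

#' @describeIn IdentificationSet-class identified protein keys.
#' @param x an `IdentificationSet`.
#' @export
identifiedProteins <- function(x) {
  stopifnot(is(x, "IdentificationSet"))
  x@proteins
}

#' @describeIn IdentificationSet-class per-protein evidence table.
#' @export
proteinEvidence <- function(x) {
  stopifnot(is(x, "IdentificationSet"))
  x@evidence
}
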