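## Protein sequences are random over the 20-letter alphabet with K/R
## boosted to ~11 % combined so tryptic peptides average 8-12 residues.
.aaFreqs <- function() {
  f <- setNames(rep((1 - 0.11) / 18, 20), AA20)
  f["K"] <- 0.055
  f["R"] <- 0.055
  f
}

#' @noRd
.randomProtein <- function(len) {
  f <- .aaFreqs()
  paste0("M", paste(sample(names(f), len - 1L, replace = TRUE,
                           prob = f), collapse = ""))
}

.productVocabulary <- c(
  "ABC transporter substrate-binding protein", "universal stress protein",
  "cytochrome c oxidase subunit", "nitrogenase iron protein",
  "response regulator", "GNAT family N-acetyltransferase",
  "porin family protein", "short-chain dehydrogenase/reductase",
  "molecular chaperone", "sigma factor", "aminotransferase",
  "efflux RND transporter subunit", "CBS domain-containing protein",
  "oxidoreductase", "methyltransferase", "peptidase", "amidohydrolase",
  "transcriptional regulator", "phosphatase", "ferredoxin")

#' @noRd
.makeGeneTable <- function(ids, lens, intergenicMean) {
  n <- length(ids)
  seqs <- vapply(lens, .randomProtein, character(1))
  bp <- 3L * (lens + 1L)  # CDS length incl. stop codon
  gaps <- rpois(n, intergenicMean)
  starts <- integer(n)
  ends <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    starts[i] <- pos + gaps[i]
    ends[i] <- starts[i] + bp[i] - 1L
    pos <- ends[i] + 1L
  }
  hypo <- runif(n) < 0.3
  prod <- ifelse(hypo, "hypothetical protein",
                 sample(.productVocabulary, n, replace = TRUE))
  data.frame(id = ids, gene_id = ids, sequence = seqs,
             start = starts, end = ends,
             strand = sample(c("+", "-"), n, replace = TRUE),
             product = prod, has_function = !hypo,
             stringsAsFactors = FALSE)
}

#' Generate a reference/derivative strain pair
#'
#' Builds an annotated reference strain of `nGenes` protein-coding genes
#' and a derivative that lacks one contiguous block of `deletionSize`
#' genes and carries `nInsertions` novel genes, emulating a laboratory
#' derivative that diverged from its reference by a single multi-gene
#' deletion plus a few insertions.  Coordinates are 1-based inclusive and
#' non-overlapping per strain.  A configurable fraction of the shared
#' genes carries up to three amino-acid substitutions.
#'
#' @param nGenes number of reference genes.
#' @param deletionSize number of consecutively deleted genes
#'   (< `nGenes`; 0 for no deletion).
#' @param nInsertions number of derivative-only genes.
#' @param seed integer seed; identical parameters and seed reproduce
#'   byte-identical output.
#' @param meanProteinLength mean protein length in residues (lognormal
#'   draw, floored at 50).
#' @param intergenicMean mean intergenic spacing in bp (Poisson draw).
#' @param substitutionFraction fraction of shared genes carrying 1-3
#'   amino-acid substitutions in the derivative.
#' @return A [StrainPair].
#' @export
generateStrainPair <- function(nGenes, deletionSize, nInsertions = 0L,
                               seed = 1L, meanProteinLength = 220,
                               intergenicMean = 120,
                               substitutionFraction = 0.02) {
  if (deletionSize >= nGenes)
    stop("'deletionSize' must be smaller than 'nGenes'")
  if (deletionSize < 0L || nInsertions < 0L || nGenes < 1L)
    stop("invalid parameter: sizes must be non-negative, nGenes positive")
  withLocalSeed(seed, {
    lens <- pmax(50L, round(rlnorm(nGenes, log(meanProteinLength), 0.35)))
    ref <- .makeGeneTable(sprintf("BDREF_%05d", 5L * seq_len(nGenes)),
                          lens, intergenicMean)
    if (deletionSize > 0L) {
      delStart <- sample.int(nGenes - deletionSize + 1L, 1L)
      delIdx <- delStart:(delStart + deletionSize - 1L)
      deleted <- ref$id[delIdx]
      keep <- ref[-delIdx, , drop = FALSE]
    } else {
      deleted <- character()
      keep <- ref
    }
    der <- keep
    der$ref_id <- keep$id
    ## substitutions in a fraction of shared genes
    nSub <- ceiling(substitutionFraction * nrow(der))
    if (nSub > 0L && nrow(der) > 0L) {
      subIdx <- sample.int(nrow(der), nSub)
      for (i in subIdx) {
        s <- strsplit(der$sequence[i], "")[[1]]
        k <- sample.int(3L, 1L)
        pos <- sample(2:length(s), k)
        s[pos] <- sample(AA20, k, replace = TRUE)
        der$sequence[i] <- paste(s, collapse = "")
      }
    }
    if (nInsertions > 0L) {
      insLens <- pmax(50L, round(rlnorm(nInsertions, log(meanProteinLength), 0.35)))
      ins <- .makeGeneTable(sprintf("INS_%03d", seq_len(nInsertions)),
                            insLens, intergenicMean)
      ins$ref_id <- NA_character_
      at <- sort(sample.int(nrow(der) + 1L, nInsertions, replace = TRUE))
      ord <- order(c(seq_len(nrow(der)), at - 0.5))
      der <- rbind(der, ins)[ord, , drop = FALSE]
    }
    ## renumber derivative ids and coordinates
    insertedOld <- der$id[is.na(der$ref_id)]
    newIds <- sprintf("BDDER_%05d", 5L * seq_len(nrow(der)))
    inserted <- newIds[is.na(der$ref_id)]
    der$id <- newIds
    der$gene_id <- newIds
    gaps <- rpois(nrow(der), intergenicMean)
    bp <- der$end - der$start + 1L
    pos <- 1L
    for (i in seq_len(nrow(der))) {
      der$start[i] <- pos + gaps[i]
      der$end[i] <- der$start[i] + bp[i] - 1L
      pos <- der$end[i] + 1L
    }
    rownames(der) <- NULL
    new("StrainPair",
        referenceGenes = ref, derivativeGenes = der,
        deletedBlock = deleted, insertedGenes = inserted,
        referenceLength = as.integer(max(ref$end) + 50L),
        derivativeLength = as.integer(max(der$end) + 50L))
  })
}

#' Plant ground-truth labels on a gene universe
#'
#' Partitions a gene universe into the truth sets the downstream stages
#' are expected to recover: microoxia-induced proteins (true protein
#' log2 FC `inducedLfc`), planted discordant genes (transcript-induced
#' while the protein is flat-to-down, true protein log2 FC
#' `discordantLfc`), and microoxia-specific detection sets at both layers
#' with a controlled cross-layer overlap.  `inducedTranscripts` is the
#' union of the discordant genes and a `transcriptSupportFraction` share
#' of the induced proteins, so that at zero noise the discordance
#' classifier has no false positives relative to truth.
#'
#' Truth-set proteins receive the fixed baseline mean `truthBaselineMean`
#' in [generatePsmDataset()] (other proteins draw lognormal baselines), so
#' that recovery failures reflect planted effects rather than low-count
#' noise.
#'
#' @param genes gene identifier vector (the derivative proteome).
#' @param nInduced,nDiscordant sizes of the planted truth sets.
#' @param nSpecificTranscripts,nSpecificProteins sizes of the
#'   microoxia-specific detection sets; `nSpecificOverlap` of them
#'   coincide.
#' @param nSpecificProteinOxicDetected number of microoxia-specific
#'   transcript genes whose protein is nevertheless detected oxically
#'   (they are removed from the cross-layer union).
#' @param inducedLfc,discordantLfc true protein log2 fold changes.
#' @param transcriptSupportFraction share of induced proteins that are
#'   also transcript-induced.
#' @param excludeFromTruth genes kept out of every planted truth set (they
#'   still receive a zero fold change and a topology class); used for
#'   genes, such as strain-specific insertions, that one expression layer
#'   cannot observe.
#' @param seed integer seed.
#' @return A [GroundTruth].
#' @export
simulateGroundTruth <- function(genes, nInduced = 15L, nDiscordant = 10L,
                                nSpecificTranscripts = 12L,
                                nSpecificProteins = 8L,
                                nSpecificOverlap = 4L,
                                nSpecificProteinOxicDetected = 4L,
                                inducedLfc = 3, discordantLfc = -1.5,
                                transcriptSupportFraction = 0.75,
                                excludeFromTruth = character(),
                                seed = 1L) {
  genes <- as.character(genes)
  eligible <- setdiff(genes, excludeFromTruth)
  nNeed <- nInduced + nDiscordant + nSpecificTranscripts +
    (nSpecificProteins - nSpecificOverlap)
  if (nNeed > length(eligible))
    stop("gene universe too small for the requested truth sets")
  if (nSpecificOverlap > min(nSpecificTranscripts, nSpecificProteins))
    stop("'nSpecificOverlap' larger than a specific set")
  if (nSpecificProteinOxicDetected > nSpecificTranscripts - nSpecificOverlap)
    stop("'nSpecificProteinOxicDetected' exceeds the transcript-only specific set")
  withLocalSeed(seed, {
    pool <- sample(eligible)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    induced <- take(nInduced)
    discordant <- take(nDiscordant)
    specT <- take(nSpecificTranscripts)
    overlap <- specT[seq_len(nSpecificOverlap)]
    specPOnly <- take(nSpecificProteins - nSpecificOverlap)
    specP <- c(overlap, specPOnly)
    tOnly <- setdiff(specT, overlap)
    protOxicDetected <- tOnly[seq_len(nSpecificProteinOxicDetected)]
    silent <- setdiff(tOnly, protOxicDetected)
    inducedTr <- c(discordant,
                   induced[seq_len(round(transcriptSupportFraction * nInduced))])
    lfc <- setNames(rep(0, length(genes)), genes)
    lfc[induced] <- inducedLfc
    lfc[discordant] <- discordantLfc
    topo <- setNames(sample(c("TM", "membrane-anchored", "secreted", "soluble"),
                            length(genes), replace = TRUE,
                            prob = c(0.20, 0.10, 0.10, 0.60)), genes)
    new("GroundTruth",
        inducedProteins = induced,
        inducedTranscripts = inducedTr,
        microoxiaSpecificTranscripts = specT,
        microoxiaSpecificProteins = specP,
        discordantGenes = discordant,
        trueLog2fc = lfc,
        topologyTruth = topo,
        silentProteins = silent,
        undetectedTranscripts = specPOnly)
  })
}

#' Simulate a two-condition PSM dataset with known truth
#'
#' Per-protein per-sample spectral counts are drawn from a negative
#' binomial whose microoxic mean is scaled by `2^trueLog2fc`; baseline
#' means are lognormal (truth-set proteins get the fixed
#' `truthBaselineMean`, microoxia-specific proteins a zero oxic mean,
#' silent proteins zero everywhere).  Each true count becomes one target
#' PSM record carrying a tryptic peptide of its protein and a score from
#' the signal distribution.  Random-match noise is added as false target
#' records (rate `falseTargetRate` of the true records, scores from the
#' null distribution) and decoy records (a `decoyFraction` share of all
#' records, reversed-protein peptides, null scores shifted down by
#' `decoyOffset`).  The returned count matrix tallies the target records,
#' so column sums equal the number of target PSMs per sample.
#'
#' @param proteome named character vector or [Biostrings::AAStringSet].
#' @param truth [GroundTruth] with `trueLog2fc` defined for every protein.
#' @param nReplicates replicates per condition (a warning is logged below
#'   2, where dispersion is not estimable).
#' @param nbDispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   values below 1e-8 give Poisson counts.
#' @param decoyFraction share of all PSM records that are decoys, in (0,1).
#' @param seed integer seed.
#' @param baselineMeanLog,baselineSdLog lognormal baseline parameters for
#'   non-truth proteins.
#' @param baselineFloor minimum baseline mean, so every simulated protein
#'   is comfortably detectable unless the truth labels say otherwise.
#' @param truthBaselineMean fixed baseline mean for truth-set proteins.
#' @param scoreMean,scoreSd signal score distribution.
#' @param decoyOffset downward shift of the null score distribution.
#' @param falseTargetRate false target records per true record.
#' @return List with `psms` (data.frame: `peptide`, `proteins`, `score`,
#'   `is_decoy`, `sample`, `condition`, `replicate`, plus the simulation
#'   truth flag `true_match`) and `counts` (SummarizedExperiment from
#'   [psmCountSet()]).
#' @export
generatePsmDataset <- function(proteome, truth, nReplicates = 3L,
                               nbDispersion = 0.05, decoyFraction = 0.1,
                               seed = 1L,
                               baselineMeanLog = log(9), baselineSdLog = 0.25,
                               baselineFloor = 8, truthBaselineMean = 25,
                               scoreMean = 25, scoreSd = 4,
                               decoyOffset = 10, falseTargetRate = 0.05) {
  prot <- asAAStringSet(proteome)
  stopifnot(is(truth, "GroundTruth"))
  if (decoyFraction <= 0 || decoyFraction >= 1)
    stop("'decoyFraction' must be in (0, 1)")
  if (nReplicates < 2L)
    warning("fewer than 2 replicates: dispersion will not be estimable")
  ids <- names(prot)
  missingLfc <- setdiff(ids, names(truth@trueLog2fc))
  if (length(missingLfc))
    stop("trueLog2fc undefined for ", length(missingLfc), " protein(s)")
  withLocalSeed(seed, {
    n <- length(ids)
    truthSet <- unique(c(truth@inducedProteins, truth@discordantGenes,
                         truth@microoxiaSpecificProteins))
    base <- pmax(rlnorm(n, baselineMeanLog, baselineSdLog), baselineFloor)
    names(base) <- ids
    base[intersect(truthSet, ids)] <- truthBaselineMean
    muOx <- base
    muMic <- base * 2^truth@trueLog2fc[ids]
    muOx[intersect(truth@microoxiaSpecificProteins, ids)] <- 0
    muMic[intersect(truth@microoxiaSpecificProteins, ids)] <- truthBaselineMean
    sil <- intersect(truth@silentProteins, ids)
    muOx[sil] <- 0
    muMic[sil] <- 0
    samples <- c(paste0("oxic_", seq_len(nReplicates)),
                 paste0("microoxic_", seq_len(nReplicates)))
    condition <- rep(c("oxic", "microoxic"), each = nReplicates)
    replicate <- rep(seq_len(nReplicates), 2L)
    drawCounts <- function(mu) {
      if (nbDispersion < 1e-8) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / nbDispersion)
    }
    trueCounts <- sapply(seq_along(samples), function(j) {
      mu <- if (condition[j] == "oxic") muOx else muMic
      drawCounts(mu)
    })
    rownames(trueCounts) <- ids
    colnames(trueCounts) <- samples
    ## tryptic peptide pools (detectable length window)
    pepPool <- lapply(as.character(prot), digest,
                      missedCleavages = 0L, minLen = 7L, maxLen = 45L)
    names(pepPool) <- ids
    decoyProt <- reverseProteome(prot)
    decoyPool <- lapply(as.character(decoyProt), digest,
                        missedCleavages = 0L, minLen = 7L, maxLen = 45L)
    names(decoyPool) <- names(decoyProt)
    samplePeptides <- function(protIds, pool) {
      ## one random peptide per record, grouped by protein for speed
      out <- character(length(protIds))
      for (id in unique(protIds)) {
        idx <- which(protIds == id)
        peps <- pool[[id]]
        out[idx] <- if (length(peps))
          peps[sample.int(length(peps), length(idx), replace = TRUE)]
          else NA_character_
      }
      out
    }
    buildRecords <- function(protIds, sampleIdx, scores, isDecoy, trueMatch,
                             pool) {
      peps <- samplePeptides(protIds, pool)
      keep <- !is.na(peps)
      data.frame(peptide = peps[keep], proteins = protIds[keep],
                 score = scores[keep], is_decoy = isDecoy,
                 sample = samples[sampleIdx[keep]],
                 condition = condition[sampleIdx[keep]],
                 replicate = replicate[sampleIdx[keep]],
                 true_match = trueMatch, stringsAsFactors = FALSE)
    }
    protIdx <- rep(rep(seq_len(n), length(samples)), as.vector(trueCounts))
    sampleIdx <- rep(rep(seq_along(samples), each = n), as.vector(trueCounts))
    psms <- buildRecords(ids[protIdx], sampleIdx,
                         rnorm(length(protIdx), scoreMean, scoreSd),
                         FALSE, TRUE, pepPool)
    nTrue <- nrow(psms)
    nFalse <- round(falseTargetRate * nTrue)
    if (nFalse > 0L) {
      psms <- rbind(psms, buildRecords(
        sample(ids, nFalse, replace = TRUE),
        sample.int(length(samples), nFalse, replace = TRUE),
        rnorm(nFalse, scoreMean - decoyOffset, scoreSd),
        FALSE, FALSE, pepPool))
    }
    nTargets <- nrow(psms)
    nDecoy <- round(decoyFraction * nTargets / (1 - decoyFraction))
    if (nDecoy > 0L) {
      psms <- rbind(psms, buildRecords(
        sample(names(decoyPool), nDecoy, replace = TRUE),
        sample.int(length(samples), nDecoy, replace = TRUE),
        rnorm(nDecoy, scoreMean - decoyOffset, scoreSd),
        TRUE, FALSE, decoyPool))
    }
    rownames(psms) <- NULL
    ## count matrix = tallies of target records
    targets <- psms[!psms$is_decoy, , drop = FALSE]
    counts <- matrix(0L, nrow = n, ncol = length(samples),
                     dimnames = list(ids, samples))
    tal <- table(factor(targets$proteins, levels = ids),
                 factor(targets$sample, levels = samples))
    counts[] <- as.integer(tal)
    list(psms = psms,
         counts = psmCountSet(counts, condition, replicate))
  })
}

#' Generate transcript-layer expression calls
#'
#' Every gene gets oxic/microoxic detection flags and a transcript log2
#' fold change.  Truth-induced transcripts get log2 FC >= 1;
#' microoxia-specific transcripts are detected only microoxically; genes
#' the truth marks transcript-undetected are detected in neither
#' condition; all other genes are detected in both with a near-zero fold
#' change.  A `noise` fraction of detection flags is flipped.
#'
#' @param genes gene identifier vector.
#' @param truth [GroundTruth].
#' @param noise flip probability per detection flag, in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame with `gene`, `detected_oxic`, `detected_microoxic`,
#'   `log2fc`.
#' @export
generateTranscriptomeCalls <- function(genes, truth, noise = 0, seed = 1L) {
  stopifnot(is(truth, "GroundTruth"))
  if (noise < 0 || noise > 1) stop("'noise' must be in [0, 1]")
  genes <- as.character(genes)
  withLocalSeed(seed, {
    n <- length(genes)
    detOx <- rep(TRUE, n)
    detMic <- rep(TRUE, n)
    detOx[genes %in% truth@microoxiaSpecificTranscripts] <- FALSE
    und <- genes %in% truth@undetectedTranscripts
    detOx[und] <- FALSE
    detMic[und] <- FALSE
    lfc <- pmin(pmax(rnorm(n, 0, 0.3), -0.99), 0.99)
    ind <- genes %in% truth@inducedTranscripts
    lfc[ind] <- 1 + pmin(rexp(sum(ind), 1 / 1.5), 5)
    if (noise > 0) {
      flipOx <- runif(n) < noise
      flipMic <- runif(n) < noise
      detOx[flipOx] <- !detOx[flipOx]
      detMic[flipMic] <- !detMic[flipMic]
    }
    data.frame(gene = genes, detected_oxic = detOx,
               detected_microoxic = detMic, log2fc = lfc,
               stringsAsFactors = FALSE)
  })
}

#' @noRd
.truthIntervals <- function(class, len) {
  if (class == "TM") {
    k <- min(2L + len %/% 150L, 5L)
    step <- len %/% (k + 1L)
    starts <- step * seq_len(k)
    data.frame(feature = "tm", start = starts,
               end = pmin(starts + 20L, len))
  } else if (class == "membrane-anchored") {
    data.frame(feature = "tm", start = 8L, end = min(28L, len))
  } else if (class == "secreted") {
    data.frame(feature = "signal", start = 1L, end = min(22L, len))
  } else {
    data.frame(feature = character(), start = integer(), end = integer())
  }
}

#' Generate feature annotations: COG, topology predictions, antibody flags
#'
#' Each gene receives one COG category (with the deletion block enriched
#' for a chosen category), the topology truth is rendered as two
#' predictors' interval lists that agree up to jitter and dropout
#' controlled by `predictorNoise`, and a configurable fraction of genes is
#' flagged as having an antibody available.
#'
#' @param genes gene table (columns `id`, `sequence`) or identifier
#'   vector (protein lengths then default to 250 residues).
#' @param truth [GroundTruth] providing `topologyTruth`.
#' @param predictorNoise in `[0, 1]`: per-interval dropout probability for
#'   the second predictor and scale of its boundary jitter.
#' @param seed integer seed.
#' @param deletionBlock gene ids enriched for `enrichCategory`.
#' @param enrichFactor fold enrichment of `enrichCategory` in the block.
#' @param enrichCategory single COG letter (default `"L"`).
#' @param unannotatedFraction share of genes with no COG category.
#' @param antibodyFraction share of genes with an antibody available.
#' @return List with `cog` (data.frame `gene`, `cog`), `topology`
#'   (data.frame `protein`, `predictor`, `feature`, `start`, `end`), and
#'   `antibody` (data.frame `gene`, `antibody`).
#' @export
generateFeatureAnnotations <- function(genes, truth, predictorNoise = 0,
                                       seed = 1L, deletionBlock = character(),
                                       enrichFactor = 5, enrichCategory = "L",
                                       unannotatedFraction = 0.15,
                                       antibodyFraction = 0.1) {
  stopifnot(is(truth, "GroundTruth"))
  if (predictorNoise < 0 || predictorNoise > 1)
    stop("'predictorNoise' must be in [0, 1]")
  if (is.data.frame(genes)) {
    ids <- genes$id
    lens <- nchar(genes$sequence)
  } else {
    ids <- as.character(genes)
    lens <- rep(250L, length(ids))
  }
  withLocalSeed(seed, {
    cats <- c("C", "E", "F", "G", "H", "I", "J", "K", "L", "M",
              "N", "O", "P", "Q", "S", "T", "U", "V")
    freq <- setNames(rep(1, length(cats)), cats)
    freq["S"] <- 4
    freq <- freq / sum(freq)
    blockFreq <- freq
    blockFreq[enrichCategory] <- blockFreq[enrichCategory] * enrichFactor
    blockFreq <- blockFreq / sum(blockFreq)
    inBlock <- ids %in% deletionBlock
    cog <- character(length(ids))
    cog[!inBlock] <- sample(cats, sum(!inBlock), replace = TRUE, prob = freq)
    if (any(inBlock))
      cog[inBlock] <- sample(cats, sum(inBlock), replace = TRUE,
                             prob = blockFreq)
    cog[runif(length(ids)) < unannotatedFraction] <- NA_character_
    topoRows <- list()
    for (i in seq_along(ids)) {
      cls <- truth@topologyTruth[ids[i]]
      if (is.na(cls)) cls <- "soluble"
      iv <- .truthIntervals(cls, lens[i])
      if (nrow(iv)) {
        topoRows[[length(topoRows) + 1L]] <-
          cbind(protein = ids[i], predictor = "predA", iv)
        keep <- runif(nrow(iv)) >= predictorNoise
        iv2 <- iv[keep, , drop = FALSE]
        if (nrow(iv2) && predictorNoise > 0) {
          jit <- round(rnorm(nrow(iv2), 0, 4 * predictorNoise))
          iv2$start <- pmax(1L, iv2$start + jit)
          iv2$end <- pmax(iv2$start, iv2$end + jit)
        }
        if (nrow(iv2))
          topoRows[[length(topoRows) + 1L]] <-
            cbind(protein = ids[i], predictor = "predB", iv2)
      } else {
        ## soluble: occasionally a spurious helix from the noisy predictor
        if (predictorNoise > 0 && runif(1) < predictorNoise / 2) {
          topoRows[[length(topoRows) + 1L]] <-
            data.frame(protein = ids[i], predictor = "predB",
                       feature = "tm", start = 10L,
                       end = min(30L, lens[i]))
        }
      }
    }
    topo <- if (length(topoRows)) do.call(rbind, topoRows)
      else data.frame(protein = character(), predictor = character(),
                      feature = character(), start = integer(),
                      end = integer())
    rownames(topo) <- NULL
    list(cog = data.frame(gene = ids, cog = cog, stringsAsFactors = FALSE),
         topology = topo,
         antibody = data.frame(gene = ids,
                               antibody = runif(length(ids)) < antibodyFraction,
                               stringsAsFactors = FALSE))
  })
}

#' Derive protein-layer expression calls from identification sets
#'
#' @param oxic,microoxic [IdentificationSet]s for the two conditions.
#' @param genes gene universe to report (absent genes get FALSE flags).
#'   3a group keys are expanded to their member ids.
#' @return data.frame with `gene`, `detected_oxic`, `detected_microoxic`.
#' @export
proteinCallsFromIdentifications <- function(oxic, microoxic, genes) {
  expand <- function(keys) unique(unlist(strsplit(keys, ";", fixed = TRUE)))
  ox <- expand(identifiedProteins(oxic))
  mic <- expand(identifiedProteins(microoxic))
  genes <- as.character(genes)
  data.frame(gene = genes,
             detected_oxic = genes %in% ox,
             detected_microoxic = genes %in% mic,
             stringsAsFactors = FALSE)
}
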