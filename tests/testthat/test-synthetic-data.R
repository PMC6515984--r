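test_that("strain pair geometry follows the deletion/insertion arithmetic", {
  pair <- generateStrainPair(100, 10, 2, seed = 7)
  expect_equal(nrow(referenceGenes(pair)), 100L)
  expect_equal(nrow(derivativeGenes(pair)), 92L)  # 100 - 10 + 2
  expect_length(deletedBlock(pair), 10L)
  expect_length(insertedGenes(pair), 2L)
  ## deleted ids are consecutive reference genes
  ref <- referenceGenes(pair)
  idx <- match(deletedBlock(pair), ref$id)
  expect_equal(idx, seq(min(idx), max(idx)))
  ## no deletion: same gene content up to insertions
  p0 <- generateStrainPair(50, 0, 0, seed = 3)
  expect_setequal(derivativeGenes(p0)$ref_id, referenceGenes(p0)$id)
  expect_error(generateStrainPair(10, 10, 0, seed = 1), "smaller")
})

test_that("gene coordinates are 1-based, sorted and non-overlapping", {
  pair <- generateStrainPair(80, 8, 3, seed = 5)
  for (tab in list(referenceGenes(pair), derivativeGenes(pair))) {
    expect_true(all(tab$start >= 1))
    expect_true(all(tab$end >= tab$start))
    expect_true(all(diff(tab$start) > 0))
    expect_true(all(tab$start[-1] > tab$end[-nrow(tab)]))
  }
})

test_that("same seed reproduces byte-identical FASTA output", {
  f1 <- tempfile(fileext = ".faa")
  f2 <- tempfile(fileext = ".faa")
  writeProteomeFasta(strainProteome(generateStrainPair(200, 20, seed = 1),
                                    "derivative"), f1)
  writeProteomeFasta(strainProteome(generateStrainPair(200, 20, seed = 1),
                                    "derivative"), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ## and the generator does not disturb the caller's RNG
  set.seed(99)
  x <- runif(1)
  set.seed(99)
  invisible(generateStrainPair(20, 2, seed = 4))
  expect_identical(runif(1), x)
})

test_that("ground truth satisfies its set invariants across seeds", {
  for (s in 1:5) {
    pair <- generateStrainPair(120, 10, seed = s)
    tr <- simulateGroundTruth(derivativeGenes(pair)$id, seed = s)
    expect_true(all(tr@discordantGenes %in% tr@inducedTranscripts))
    expect_length(intersect(tr@discordantGenes, tr@inducedProteins), 0)
    expect_true(all(tr@trueLog2fc[tr@inducedProteins] > 0))
    expect_true(all(tr@trueLog2fc[tr@discordantGenes] <= 0))
    expect_true(validObject(tr))
  }
})

test_that("count matrix columns tally the target PSM records", {
  pair <- generateStrainPair(40, 0, seed = 2)
  tr <- simulateGroundTruth(derivativeGenes(pair)$id, seed = 2,
                            nInduced = 5L, nDiscordant = 3L,
                            nSpecificTranscripts = 4L,
                            nSpecificProteins = 3L, nSpecificOverlap = 2L,
                            nSpecificProteinOxicDetected = 1L)
  d <- generatePsmDataset(strainProteome(pair), tr, seed = 2)
  counts <- SummarizedExperiment::assay(d$counts, "counts")
  targets <- d$psms[!d$psms$is_decoy, ]
  perSample <- table(factor(targets$sample, levels = colnames(counts)))
  expect_equal(unname(colSums(counts)), as.vector(perSample))
  ## decoys never contribute to the count matrix
  expect_false(any(grepl("^rev_", rownames(counts))))
})

test_that("null truth gives matched group means for most proteins", {
  pair <- generateStrainPair(60, 0, seed = 6)
  genes <- derivativeGenes(pair)$id
  tr <- simulateGroundTruth(genes, seed = 6, nInduced = 0L, nDiscordant = 0L,
                            nSpecificTranscripts = 0L, nSpecificProteins = 0L,
                            nSpecificOverlap = 0L,
                            nSpecificProteinOxicDetected = 0L)
  d <- generatePsmDataset(strainProteome(pair), tr, nReplicates = 50L,
                          nbDispersion = 0.005, seed = 6,
                          baselineMeanLog = log(30), baselineFloor = 25,
                          falseTargetRate = 0)
  counts <- SummarizedExperiment::assay(d$counts, "counts")
  cond <- SummarizedExperiment::colData(d$counts)$condition
  mOx <- rowMeans(counts[, cond == "oxic"])
  mMic <- rowMeans(counts[, cond == "microoxic"])
  relDiff <- abs(mMic - mOx) / pmax(mOx, 1e-9)
  expect_gte(mean(relDiff < 0.10), 0.95)
})

test_that("near-zero dispersion approaches the Poisson limit", {
  pair <- generateStrainPair(150, 0, seed = 8)
  genes <- derivativeGenes(pair)$id
  tr <- simulateGroundTruth(genes, seed = 8, nInduced = 0L, nDiscordant = 0L,
                            nSpecificTranscripts = 0L, nSpecificProteins = 0L,
                            nSpecificOverlap = 0L,
                            nSpecificProteinOxicDetected = 0L)
  d <- generatePsmDataset(strainProteome(pair), tr, nReplicates = 30L,
                          nbDispersion = 1e-12, seed = 8,
                          falseTargetRate = 0)
  counts <- SummarizedExperiment::assay(d$counts, "counts")
  cond <- SummarizedExperiment::colData(d$counts)$condition
  ox <- counts[, cond == "oxic"]
  ratio <- apply(ox, 1, var) / rowMeans(ox)
  ## variance/mean ratio concentrates around 1
  expect_lt(abs(median(ratio) - 1), 0.15)
})

test_that("decoy share matches the requested fraction", {
  pair <- generateStrainPair(60, 0, seed = 9)
  tr <- simulateGroundTruth(derivativeGenes(pair)$id, seed = 9,
                            nInduced = 5L, nDiscordant = 3L,
                            nSpecificTranscripts = 4L,
                            nSpecificProteins = 3L, nSpecificOverlap = 2L,
                            nSpecificProteinOxicDetected = 1L)
  d <- generatePsmDataset(strainProteome(pair), tr, decoyFraction = 0.5,
                          seed = 9)
  frac <- mean(d$psms$is_decoy)
  n <- nrow(d$psms)
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  expect_error(generatePsmDataset(strainProteome(pair), tr,
                                  decoyFraction = 1.2, seed = 1),
               "decoyFraction")
})

test_that("transcript calls realise the planted truth at zero noise", {
  pair <- generateStrainPair(150, 0, seed = 10)
  genes <- derivativeGenes(pair)$id
  tr <- simulateGroundTruth(genes, seed = 10)
  calls <- generateTranscriptomeCalls(genes, tr, noise = 0, seed = 10)
  specific <- calls$gene[calls$detected_microoxic & !calls$detected_oxic]
  expect_setequal(specific, tr@microoxiaSpecificTranscripts)
  induced <- calls$gene[calls$log2fc >= 1]
  expect_setequal(induced, tr@inducedTranscripts)
})

test_that("empty truth sets leave no induced transcripts", {
  genes <- paste0("g", 1:100)
  tr <- simulateGroundTruth(genes, seed = 1, nInduced = 0L, nDiscordant = 0L,
                            nSpecificTranscripts = 0L, nSpecificProteins = 0L,
                            nSpecificOverlap = 0L,
                            nSpecificProteinOxicDetected = 0L)
  calls <- generateTranscriptomeCalls(genes, tr, noise = 0, seed = 1)
  expect_equal(sum(calls$log2fc >= 1), 0L)
})

test_that("detection-flag flips follow the noise rate", {
  genes <- paste0("g", 1:2000)
  tr <- simulateGroundTruth(genes, seed = 3, nInduced = 0L, nDiscordant = 0L,
                            nSpecificTranscripts = 0L, nSpecificProteins = 0L,
                            nSpecificOverlap = 0L,
                            nSpecificProteinOxicDetected = 0L)
  clean <- generateTranscriptomeCalls(genes, tr, noise = 0, seed = 4)
  noisy <- generateTranscriptomeCalls(genes, tr, noise = 0.05, seed = 4)
  flips <- sum(clean$detected_oxic != noisy$detected_oxic) +
    sum(clean$detected_microoxic != noisy$detected_microoxic)
  n <- 2L * length(genes)
  ci <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(flips, ci[1])
  expect_lte(flips, ci[2])
})

test_that("noise-free predictors agree and match the topology truth", {
  pair <- generateStrainPair(80, 0, seed = 12)
  der <- derivativeGenes(pair)
  tr <- simulateGroundTruth(der$id, seed = 12)
  ann <- generateFeatureAnnotations(der, tr, predictorNoise = 0, seed = 12)
  topo <- ann$topology
  a <- topo[topo$predictor == "predA", c("protein", "feature", "start", "end")]
  b <- topo[topo$predictor == "predB", c("protein", "feature", "start", "end")]
  expect_equal(a[order(a$protein, a$start), ],
               b[order(b$protein, b$start), ], ignore_attr = TRUE)
  calls <- callTopology(topo, proteins = der$id)
  expect_identical(unname(topologyTruth(tr)[calls$protein]),
                   calls$class)
  ## soluble proteins have no predicted features at zero noise
  sol <- names(topologyTruth(tr))[topologyTruth(tr) == "soluble"]
  expect_length(intersect(sol, topo$protein), 0)
})
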