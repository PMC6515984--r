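psmTable <- function(score, isDecoy, condition = "microoxic",
                     peptide = NULL) {
  n <- length(score)
  data.frame(peptide = if (is.null(peptide)) paste0("PEP", seq_len(n))
               else peptide,
             proteins = "x", score = score, is_decoy = isDecoy,
             sample = "s1", condition = rep(condition, length.out = n),
             replicate = 1L, stringsAsFactors = FALSE)
}

test_that("FDR threshold handles clean separations and exact ratios", {
  ## all decoys below all targets
  p <- psmTable(c(10, 9, 8, 1), c(FALSE, FALSE, FALSE, TRUE))
  r <- estimatePsmFdrThreshold(p, 0.0035)
  expect_equal(nrow(r$accepted), 3L)
  expect_equal(r$fdr, 0)
  ## 1000 targets and 3 decoys above threshold: FDR 0.003 passes 0.0035
  p2 <- psmTable(c(rep(10, 1000), rep(10, 3), rep(1, 500)),
                 c(rep(FALSE, 1000), rep(TRUE, 3), rep(TRUE, 500)))
  r2 <- estimatePsmFdrThreshold(p2, 0.0035)
  expect_equal(r2$fdr, 3 / 1000)
  expect_equal(nrow(r2$accepted), 1000L)
})

test_that("FDR threshold equals the exhaustive-scan oracle", {
  set.seed(7)
  for (i in 1:20) {
    n <- 200
    dec <- runif(n) < 0.4
    sc <- ifelse(dec, rnorm(n, 8, 3), rnorm(n, 12, 3))
    p <- psmTable(sc, dec)
    for (target in c(0.01, 0.05, 0.2)) {
      want <- oracleFdrThreshold(sc, dec, target)
      if (is.infinite(want)) {
        expect_warning(r <- estimatePsmFdrThreshold(p, target))
        expect_equal(nrow(r$accepted), 0L)
      } else {
        r <- estimatePsmFdrThreshold(p, target)
        expect_equal(r$threshold, want)
      }
    }
  }
})

test_that("accepted set is monotone in the target FDR", {
  set.seed(8)
  dec <- runif(500) < 0.3
  sc <- ifelse(dec, rnorm(500, 8, 3), rnorm(500, 13, 3))
  p <- psmTable(sc, dec)
  sizes <- vapply(c(0.5, 0.2, 0.1, 0.05, 0.02, 0.01),
                  function(q) nrow(estimatePsmFdrThreshold(p, q)$accepted),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("FDR estimation requires decoys and targets", {
  expect_error(estimatePsmFdrThreshold(psmTable(1:3, rep(FALSE, 3)), 0.01),
               "decoy")
  expect_error(estimatePsmFdrThreshold(psmTable(1:3, rep(TRUE, 3)), 0.01),
               "target")
})

test_that("protein inference applies the two-peptide/three-PSM rule", {
  prot <- c(A = "MKWWHDYQAKRAAADDDK", B = "MKQQQEEEKRTTTVVVK")
  classes <- classifyPeptides(c("WWHDYQAK", "AAADDDK", "QQQEEEK"), prot)
  ## one distinct peptide seen three times -> identified (PSM rule)
  acc <- psmTable(rep(30, 3), rep(FALSE, 3), peptide = rep("WWHDYQAK", 3))
  id <- inferProteins(acc, classes, "microoxic")
  expect_identical(identifiedProteins(id), "A")
  ## one peptide, one PSM -> not identified
  acc1 <- psmTable(30, FALSE, peptide = "WWHDYQAK")
  expect_length(identifiedProteins(inferProteins(acc1, classes, "microoxic")), 0)
  ## two distinct peptides -> identified (peptide rule)
  acc2 <- psmTable(c(30, 30), c(FALSE, FALSE),
                   peptide = c("WWHDYQAK", "AAADDDK"))
  expect_identical(identifiedProteins(inferProteins(acc2, classes, "microoxic")),
                   "A")
  ## absent condition -> warning and empty set
  expect_warning(id0 <- inferProteins(acc, classes, "oxic"), "no accepted")
  expect_length(identifiedProteins(id0), 0)
})

test_that("ambiguous peptide evidence never identifies a protein", {
  set.seed(9)
  seqs <- setNames(vapply(rep(40, 8), randomAA, character(1)),
                   paste0("P", 1:8))
  motif <- "HHWWDDYQNC"
  seqs["P1"] <- paste0(motif, seqs["P1"])
  seqs["P2"] <- paste0(seqs["P2"], motif)
  classes <- classifyPeptides(motif, seqs)
  expect_identical(classes$class, "ambiguous")
  acc <- psmTable(rep(30, 10), rep(FALSE, 10), peptide = rep(motif, 10))
  expect_length(identifiedProteins(inferProteins(acc, classes, "microoxic")), 0)
})

test_that("3a groups are reported once, keyed by the sorted id set", {
  seqs <- c(Z2 = "MKWWHDYQAKAAADDDKX", Z1 = "MKWWHDYQAKAAADDDKX")
  classes <- classifyPeptides(c("WWHDYQAK", "AAADDDKX"), seqs)
  acc <- psmTable(c(30, 30), c(FALSE, FALSE),
                  peptide = c("WWHDYQAK", "AAADDDKX"))
  id <- inferProteins(acc, classes, "microoxic")
  expect_identical(identifiedProteins(id), "Z1;Z2")
})

test_that("identification is invariant to PSM input order", {
  set.seed(10)
  seqs <- setNames(vapply(rep(60, 6), randomAA, character(1)),
                   paste0("P", 1:6))
  peps <- unlist(lapply(seqs, digest, missedCleavages = 0,
                        minLen = 7, maxLen = 45))
  classes <- classifyPeptides(peps, seqs)
  acc <- psmTable(rnorm(40, 30), rep(FALSE, 40),
                  peptide = sample(peps, 40, replace = TRUE))
  a <- inferProteins(acc, classes, "microoxic")
  b <- inferProteins(acc[sample.int(40), ], classes, "microoxic")
  expect_setequal(identifiedProteins(a), identifiedProteins(b))
})

test_that("protein FDR is the decoy/target identification ratio", {
  mk <- function(n, cond = "microoxic") {
    new("IdentificationSet", condition = cond,
        proteins = paste0("p", seq_len(n)),
        evidence = data.frame(protein = paste0("p", seq_len(n)),
                              n_peptides = 2L, n_psms = 3L,
                              identified = TRUE))
  }
  empty <- new("IdentificationSet", condition = "decoy",
               proteins = character(),
               evidence = data.frame(protein = character(),
                                     n_peptides = integer(),
                                     n_psms = integer(),
                                     identified = logical()))
  expect_equal(estimateProteinFdr(mk(300), empty), 0)
  expect_equal(estimateProteinFdr(mk(400), mk(2, "decoy")), 0.005)
  expect_warning(r <- estimateProteinFdr(empty, empty), "undefined")
  expect_true(is.na(r))
})

test_that("Venn accounting matches brute-force set algebra", {
  set.seed(12)
  for (i in 1:10) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    v <- conditionVenn(a, b)
    expect_equal(v$shared, length(intersect(a, b)))
    expect_equal(v$only_a, length(setdiff(a, b)))
    expect_equal(v$only_b, length(setdiff(b, a)))
    expect_equal(v$union, length(union(a, b)))
    expect_equal(v$only_a + v$shared, length(unique(a)))
  }
  v <- conditionVenn(letters[1:5], letters[1:5])
  expect_equal(v$only_a, 0)
  expect_equal(v$only_b, 0)
})
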