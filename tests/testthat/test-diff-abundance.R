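nbMatrix <- function(n, muOx, muMic, disp, nRep = 3, seed = 1) {
  set.seed(seed)
  muOx <- rep(muOx, length.out = n)
  muMic <- rep(muMic, length.out = n)
  draw <- function(mu) rnbinom(n, mu = mu, size = 1 / disp)
  m <- cbind(sapply(seq_len(nRep), function(i) draw(muOx)),
             sapply(seq_len(nRep), function(i) draw(muMic)))
  dimnames(m) <- list(paste0("prot", seq_len(n)),
                      c(paste0("ox", seq_len(nRep)),
                        paste0("mi", seq_len(nRep))))
  m
}
cond6 <- rep(c("oxic", "microoxic"), each = 3)

test_that("size factors recover known column scalings", {
  m <- matrix(rpois(600, 100), nrow = 100)
  m2 <- cbind(m, m[, 1] * 2)
  f <- countSizeFactors(m2)
  expect_equal(unname(f[7] / f[1]), 2, tolerance = 0.05)
  ## identical columns -> all factors 1
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(countSizeFactors(same)), rep(1, 3))
  ## scaling the whole matrix leaves factors unchanged
  expect_equal(countSizeFactors(m * 10), countSizeFactors(m))
  ## geometric mean of factors is 1
  expect_equal(exp(mean(log(countSizeFactors(m2)))), 1)
})

test_that("size factors fall back to totals when no row is all-positive", {
  m <- rbind(c(10, 0, 5), c(0, 8, 4))
  expect_warning(f <- countSizeFactors(m), "total-count")
  expect_length(f, 3)
  expect_true(all(f > 0))
})

test_that("dispersion estimates track the generating model", {
  ## Poisson counts: dispersion near zero as counts grow
  m <- nbMatrix(300, 500, 500, disp = 1e-9, seed = 2)
  d <- countDispersions(m, rep(1, 6), cond6, shrink = 0)
  expect_lt(median(d), 0.01)
  ## NB alpha = 0.1 with 50 replicates per condition: recovered
  set.seed(3)
  m2 <- nbMatrix(300, 100, 100, disp = 0.1, nRep = 50, seed = 3)
  d2 <- countDispersions(m2, rep(1, 100),
                         rep(c("oxic", "microoxic"), each = 50))
  expect_gte(median(d2), 0.05)
  expect_lte(median(d2), 0.2)
  ## constant row sits at the floor
  m3 <- matrix(50, nrow = 2, ncol = 6)
  d3 <- countDispersions(m3, rep(1, 6), cond6, shrink = 0)
  expect_equal(unname(d3), rep(1e-8, 2))
})

test_that("single-replicate designs fall back to the prior", {
  m <- matrix(rpois(20, 50), ncol = 2)
  expect_warning(
    d <- countDispersions(m, c(1, 1), c("oxic", "microoxic"), prior = 0.07),
    "prior")
  expect_equal(unname(d), rep(0.07, 10))
})

test_that("the Wald test is null-centred on identical counts", {
  m <- matrix(1000, nrow = 3, ncol = 6,
              dimnames = list(paste0("p", 1:3), NULL))
  res <- nbWaldTest(m, rep(1, 6), rep(0.01, 3), cond6)
  expect_true(all(abs(res$log2fc) < 0.01))
  expect_true(all(res$p > 0.5))
})

test_that("all-zero rows are reported as missing", {
  m <- rbind(p1 = rep(0L, 6), p2 = rpois(6, 50))
  res <- nbWaldTest(m, rep(1, 6), c(0.05, 0.05), cond6)
  expect_equal(res$log2fc[1], 0)
  expect_true(is.na(res$p[1]))
  expect_false(is.na(res$p[2]))
})

test_that("swapping condition labels negates fold changes", {
  m <- nbMatrix(50, 80, 160, disp = 0.05, seed = 4)
  res1 <- nbWaldTest(m, rep(1, 6), rep(0.05, 50), cond6)
  res2 <- nbWaldTest(m, rep(1, 6), rep(0.05, 50), rev(cond6))
  expect_equal(res1$log2fc, -res2$log2fc, tolerance = 1e-8)
  expect_equal(res1$p, res2$p, tolerance = 1e-8)
})

test_that("results are invariant to sample column order", {
  m <- nbMatrix(40, 60, 120, disp = 0.05, seed = 5)
  perm <- c(4, 1, 6, 2, 3, 5)
  res1 <- nbWaldTest(m, rep(1, 6), rep(0.05, 40), cond6)
  res2 <- nbWaldTest(m[, perm], rep(1, 6), rep(0.05, 40), cond6[perm])
  expect_equal(res1$log2fc, res2$log2fc, tolerance = 1e-10)
  expect_equal(res1$p, res2$p, tolerance = 1e-10)
})

test_that("at the large-count Poisson limit the Wald p matches a rate test", {
  y1 <- c(100000, 100100, 99900)
  y2 <- c(110000, 110200, 109800)
  m <- matrix(c(y1, y2), nrow = 1)
  res <- nbWaldTest(m, rep(1, 6), 1e-12, cond6)
  s1 <- sum(y1)
  s2 <- sum(y2)
  z <- (log(s2) - log(s1)) / sqrt(1 / s1 + 1 / s2)
  pOracle <- 2 * pnorm(-abs(z))
  expect_equal(res$p[1], pOracle, tolerance = 1e-3)
})

test_that("fold-change recovery agrees with an established NB implementation", {
  set.seed(6)
  m <- nbMatrix(60, 50, c(rep(50, 30), rep(200, 30)), disp = 0.05, seed = 6)
  storage.mode(m) <- "integer"
  res <- nbWaldTest(m, condition = cond6)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, S4Vectors::DataFrame(condition = factor(cond6,
                                               levels = c("oxic",
                                                          "microoxic"))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  keep <- !is.na(ref$padj) & !is.na(res$padj)
  expect_gt(cor(res$log2fc[keep], ref$log2FoldChange[keep]), 0.98)
  ## the two routes agree on which proteins are strongly induced
  expect_setequal(res$protein[keep][res$padj[keep] < 0.01 & res$log2fc[keep] > 1],
                  rownames(ref)[keep][ref$padj[keep] < 0.01 &
                                        ref$log2FoldChange[keep] > 1])
})

test_that("BH adjustment follows the hand-applied definition", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  p <- runif(50)
  expect_equal(bhAdjust(p), oracleBH(p))
  expect_true(all(bhAdjust(p) >= p))
  ## NA passthrough
  got <- bhAdjust(c(0.01, NA, 0.5))
  expect_true(is.na(got[2]))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("set selection applies the padj and fold-change thresholds", {
  res <- data.frame(protein = paste0("p", 1:6),
                    log2fc = c(2, -1.5, 0.5, 1.2, -0.2, 3),
                    p = c(0.001, 0.002, 0.2, 0.3, 0.01, NA),
                    padj = c(0.01, 0.05, 0.4, 0.6, 0.15, NA))
  s <- selectSets(res)
  expect_setequal(s$core_up, c("p1"))
  expect_setequal(s$core_down, c("p2", "p5"))
  expect_setequal(s$relaxed_up, c("p1", "p4"))
  s0 <- selectSets(res[0, ])
  expect_length(s0$core_up, 0)
  expect_length(s0$relaxed_up, 0)
})

test_that("core selection recovers planted induced proteins", {
  ## 50 induced (log2FC 3, mean 200) among 100 nulls; averaged over seeds
  hits <- falses <- numeric(5)
  for (s in 1:5) {
    m <- rbind(nbMatrix(50, 200, 1600, disp = 0.05, seed = 100 + s),
               nbMatrix(100, 50, 50, disp = 0.05, seed = 200 + s))
    rownames(m) <- paste0(rep(c("ind", "null"), c(50, 100)),
                          c(1:50, 1:100))
    res <- nbWaldTest(m, countSizeFactors(m),
                      condition = cond6)
    s2 <- selectSets(res)
    hits[s] <- sum(grepl("^ind", s2$core_up))
    falses[s] <- sum(grepl("^null", s2$core_up))
  }
  expect_gte(mean(hits), 45)
  expect_lte(mean(falses), 5)
})

test_that("count matrix text round trip preserves counts and conditions", {
  m <- matrix(rpois(30, 20), nrow = 5,
              dimnames = list(paste0("p", 1:5),
                              c(paste0("o", 1:3), paste0("m", 1:3))))
  se <- psmCountSet(m, cond6)
  f <- tempfile(fileext = ".tsv")
  writeCountMatrix(se, f)
  back <- readCountMatrix(f)
  expect_equal(unname(SummarizedExperiment::assay(back, "counts")),
               unname(m))
  expect_equal(SummarizedExperiment::colData(back)$condition, cond6)
})
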