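mkSE <- function(mat, class, nM = 2, nF = 2, start = NULL) {
  colnames(mat) <- c(paste0("M", seq_len(nM)), paste0("F", seq_len(nF)))
  rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  info <- data.frame(gene = rownames(mat), chrom = ifelse(
    class == "autosome", "chr1", "chrXY"),
    start = start %||% seq(0, by = 1e4, length.out = nrow(mat)),
    end = (start %||% seq(0, by = 1e4,
                          length.out = nrow(mat))) + 1000,
    class = class, stringsAsFactors = FALSE)
  sexes <- data.frame(sample = colnames(mat),
                      sex = rep(c("M", "F"), c(nM, nF)))
  makeExpressionSE(mat, info, sexes)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the expression filter requires support in both sexes", {
  mat <- rbind(c(5, 5, 5, 5),
               c(0, 0, 0, 0),    # silent everywhere
               c(5, 5, 0, 0),    # male-only
               c(5, 0, 5, 5))    # expressed in >= half of each sex
  se <- mkSE(mat, rep("autosome", 4))
  kept <- rownames(filterExpressed(se, minExpr = 1))
  expect_setequal(kept, c("g1", "g4"))
  # brute-force recomputation on random data
  set.seed(3)
  mat2 <- matrix(rexp(200, 1 / 3), ncol = 4)
  se2 <- mkSE(mat2, rep("autosome", 50))
  kept2 <- rownames(filterExpressed(se2))
  want <- rowSums(mat2[, 1:2] >= 1) >= 1 & rowSums(mat2[, 3:4] >= 1) >= 1
  expect_setequal(kept2, paste0("g", which(want)))
})

test_that("per-gene log2 M:F ratios behave and negate under sex swap", {
  mat <- rbind(c(10, 10, 10, 10), c(5, 5, 10, 10))
  se <- mkSE(mat, rep("autosome", 2))
  r <- mfLog2PerGene(se)
  expect_equal(unname(r), c(0, -1))
  swapped <- mkSE(mat[, c(3, 4, 1, 2)], rep("autosome", 2))
  expect_equal(unname(mfLog2PerGene(swapped)), c(0, 1))
})

test_that("signed-rank and rank-sum tests match exact enumeration", {
  set.seed(9)
  n <- 10
  m <- matrix(rexp(4 * n, 1 / 10), ncol = 4)
  se <- mkSE(m, rep("young", n))
  got <- testMFX(se)
  mMeans <- rowMeans(m[, 1:2])
  fMeans <- rowMeans(m[, 3:4])
  want <- oracleSignedRank(mMeans, fMeans)
  expect_equal(got$statistic, want$V)
  expect_equal(got$pValue, want$p, tolerance = 1e-10)

  m2 <- matrix(rexp(4 * 13, 1 / 10), ncol = 4)
  se2 <- mkSE(m2, rep(c("young", "autosome"), c(6, 7)))
  got2 <- testXvsAutosomes(se2, "M")
  want2 <- oracleRankSum(rowMeans(m2[1:6, 1:2]),
                         rowMeans(m2[7:13, 1:2]))
  expect_equal(got2$statistic, want2$W)
  expect_equal(got2$pValue, want2$p, tolerance = 1e-10)
})

test_that("degenerate inputs of the paired X test are flagged", {
  mat <- matrix(5, nrow = 8, ncol = 4)
  se <- mkSE(mat, rep("old", 8))
  r <- testMFX(se)
  expect_true(r$allZero)
  expect_equal(r$pValue, 1)
  # a clean 2-fold shift over 100 genes is overwhelmingly significant
  set.seed(12)
  f <- rexp(100, 1 / 10) + 1
  mat2 <- cbind(f / 2, f / 2, f, f)
  se2 <- mkSE(mat2, rep("old", 100))
  expect_lt(testMFX(se2)$pValue, 1e-10)
})

test_that("ASE-gene ratio contrast detects shifts and degenerates safely", {
  set.seed(15)
  a <- rexp(60, 1 / 10) + 1
  x <- rexp(20, 1 / 10) + 1
  mat <- rbind(cbind(a, a, a, a), cbind(x / 2, x / 2, x, x))
  se <- mkSE(mat, rep(c("autosome", "old"), c(60, 20)))
  aseGenes <- paste0("g", 61:80)
  r <- testAseGeneRatios(se, aseGenes)
  expect_true(r$applicable)
  expect_lt(r$pValue, 1e-6)
  expect_equal(r$medianAseX, -1)
  none <- testAseGeneRatios(se, character(0))
  expect_false(none$applicable)
  expect_true(is.na(none$pValue))
})

test_that("sex-bias classes detect injected male-biased genes", {
  # 8 replicates per sex: the rank-sum floor at 3v3 precludes
  # significance, so bias classification needs this many samples
  set.seed(19)
  nA <- 300; nX <- 80; nM <- 8; nF <- 8
  base <- rexp(nA + nX, 1 / 20) + 1
  noise <- function(n) matrix(2^rnorm(n * (nM + nF), sd = 0.25),
                              ncol = nM + nF)
  mat <- base * noise(nA + nX)
  biased <- 1:30  # autosomal, male-biased 4-fold
  mat[biased, 1:nM] <- mat[biased, 1:nM] * 4
  se <- mkSE(mat, rep(c("autosome", "old"), c(nA, nX)), nM = nM,
             nF = nF)
  res <- sexBiasClasses(se)
  found <- which(res$classes == "male_biased")
  expect_gt(length(intersect(found, biased)), 24)
  expect_lt(length(setdiff(found, biased)), 6)
  # no-difference input: everything unbiased, chi-square zero
  flat <- mkSE(matrix(5, 20, nM + nF),
               rep(c("autosome", "old"), c(15, 5)), nM = nM, nF = nF)
  resFlat <- sexBiasClasses(flat)
  expect_true(all(resFlat$classes == "unbiased"))
  expect_equal(resFlat$chisq, 0)
})

test_that("the expression track recomputes per-window gene means", {
  win <- tileWindows(c(chrXY = 5e4), 1e4)
  mat <- rbind(c(10, 10, 10, 10),
               c(5, 5, 10, 10),
               c(20, 20, 10, 10))
  se <- mkSE(mat, rep("old", 3), start = c(1000, 2000, 25000))
  tr <- expressionTrack(se, win, span = 1)
  expect_equal(tr$meanMFLog2, c(mean(c(0, -1)), NA, 1, NA, NA))
  # uniform expression gives a flat zero track
  se2 <- mkSE(matrix(7, 4, 4), rep("old", 4),
              start = c(0, 11000, 21000, 31000))
  # the empty 5th window borrows its smoothed value from neighbors
  expect_equal(expressionTrack(se2, win, span = 3)$smooth,
               c(0, 0, 0, 0, 0))
  expect_equal(expressionTrack(se2, win, span = 3)$meanMFLog2,
               c(0, 0, 0, 0, NA))
})

test_that("the verdict rule codifies the three regimes", {
  expect_equal(dosageVerdict(0.5, 0.8, 0.02), "COMPLETE")
  expect_equal(dosageVerdict(1e-6, 1e-5, -0.97), "ABSENT")
  expect_equal(dosageVerdict(0.5, 1e-5, -0.5), "PARTIAL")
  expect_equal(dosageVerdict(0.5, 0.8, -0.6), "PARTIAL")
  expect_equal(dosageVerdict(0.5, 0.8, 0.02,
                             hasDegenerateStratum = FALSE),
               "NOT_APPLICABLE")
  expect_error(dosageVerdict(NA, 0.5, 0), "missing")
})

test_that("compensated and uncompensated simulations get the right verdict", {
  for (comp in c(TRUE, FALSE)) {
    cfg <- presetConfig("picta", sexChromLength = 4e6, nAutosomes = 1,
                        chromLength = 2e6, nGenesPerChrom = 150,
                        windowSize = 5e4, seed = 311 + comp,
                        compensation = comp)
    tr <- simTruth(cfg)
    rna <- simulateRna(cfg, tr)
    rep <- dosageReport(rna$expression)
    expect_equal(verdict(rep), if (comp) "COMPLETE" else "ABSENT")
    expect_lt(abs(rep@medianXRatio - if (comp) 0 else -1), 0.25)
  }
})
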