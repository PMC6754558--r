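siteRow <- function(gene, sample, a, b, chrom = "chr1", pos = 0L) {
  data.frame(gene = gene, chrom = chrom, pos = pos, sample = sample,
             countA = a, countB = b, stringsAsFactors = FALSE)
}

test_that("het-site calling rejects monoallelic and shallow sites", {
  counts <- rbind(siteRow("g1", "M1", 20, 0),   # hemizygous-like
                  siteRow("g2", "M1", 12, 8),   # genuine het
                  siteRow("g3", "M1", 4, 3),    # too shallow
                  siteRow("g4", "M1", 9, 1))    # minor too rare
  res <- callHetSites(counts, minDepth = 10, minMinor = 2)
  expect_equal(res$sites$gene, "g2")
  expect_equal(res$genesWithHet$gene, "g2")
  expect_setequal(res$genesWithoutHet$gene, c("g1", "g3", "g4"))
})

test_that("major allele frequency pools sites by per-site major allele", {
  expect_equal(geneMajorAlleleFreq(siteRow("g", "s", 10, 10))
               $majorAlleleFreq, 0.5)
  expect_equal(geneMajorAlleleFreq(siteRow("g", "s", 30, 10))
               $majorAlleleFreq, 0.75)
  # pooling is by allele identity: opposite imbalances cancel
  two <- rbind(siteRow("g", "s", 30, 10), siteRow("g", "s", 10, 30))
  maf <- geneMajorAlleleFreq(two)
  expect_equal(maf$nSites, 2L)
  expect_equal(maf$totalA, 40)
  expect_equal(maf$totalMajor, 40)
  expect_equal(maf$majorAlleleFreq, 0.5)
  # consistent imbalance accumulates
  same <- rbind(siteRow("g", "s", 30, 10), siteRow("g", "s", 28, 12))
  expect_equal(geneMajorAlleleFreq(same)$majorAlleleFreq, 58 / 80)
  expect_true(all(geneMajorAlleleFreq(two)$majorAlleleFreq >= 0.5))
})

test_that("the exact binomial ASE test matches closed forms", {
  even <- aseTest(geneMajorAlleleFreq(siteRow("g", "s", 50, 50)))
  expect_equal(even$pValue, 1)
  extreme <- aseTest(geneMajorAlleleFreq(siteRow("g", "s", 40, 0)))
  expect_equal(extreme$pValue, 2 * 0.5^40, tolerance = 1e-12)
  expect_error(aseTest(geneMajorAlleleFreq(siteRow("g", "s", 5, 5)),
                       nullP = 1.5), "nullP")
})

test_that("sampling alone pushes major allele frequency above 0.5", {
  set.seed(17)
  n <- 1000
  sites <- do.call(rbind, lapply(seq_len(n), function(i) {
    depth <- rpois(5, 40)
    a <- rbinom(5, depth, 0.5)
    data.frame(gene = paste0("g", i), chrom = "chr1",
               pos = seq_len(5), sample = "s", countA = a,
               countB = depth - a, stringsAsFactors = FALSE)
  }))
  maf <- geneMajorAlleleFreq(sites)
  med <- median(maf$majorAlleleFreq)
  # folded-normal oracle: ~200 pooled reads per gene, SE = sqrt(.25/200)
  # = 0.035, median of |N(0, SE)| = 0.674 * SE = 0.024 above one half
  expect_gt(med, 0.51)
  expect_lt(med, 0.54)
})

test_that("the null rejection rate of the ASE test is near alpha", {
  set.seed(23)
  nGenes <- 2000
  depth <- rpois(nGenes * 5, 40)
  a <- rbinom(nGenes * 5, depth, 0.5)
  sites <- data.frame(gene = rep(paste0("g", seq_len(nGenes)), each = 5),
                      chrom = "chr1", pos = rep(1:5, nGenes),
                      sample = "s", countA = a, countB = depth - a,
                      stringsAsFactors = FALSE)
  res <- aseTest(geneMajorAlleleFreq(sites))
  rate <- mean(res$pValue < 0.05)
  # the exact test is slightly conservative by discreteness; the
  # attainable size at these depths sits just below the nominal 0.05
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.065)
})

test_that("chi-square enrichment equals the textbook 2x2 formula", {
  # equal proportions 30/100 in both groups
  eq <- aseEnrichment(rep(c(TRUE, FALSE, TRUE, FALSE),
                          c(30, 70, 30, 70)),
                      rep(c(TRUE, FALSE), times = c(100, 100)))
  expect_equal(eq$chisq, 0, tolerance = 1e-12)
  tab <- aseEnrichment(
    c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 90)),
    rep(c(TRUE, FALSE), times = c(100, 100)))
  expect_equal(tab$chisq, 12.5, tolerance = 1e-12)
  expect_equal(tab$df, 1)
  # random tables with margins <= 100 match the closed form
  set.seed(31)
  for (i in 1:25) {
    a <- sample(1:50, 1); b <- sample(1:50, 1)
    c2 <- sample(1:50, 1); d <- sample(1:50, 1)
    isAse <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c2, d))
    isX <- rep(c(TRUE, FALSE), c(a + b, c2 + d))
    expect_equal(aseEnrichment(isAse, isX)$chisq,
                 oracleChisq2x2(a, b, c2, d), tolerance = 1e-10)
  }
  expect_error(aseEnrichment(rep(FALSE, 10), rep(c(TRUE, FALSE), 5)),
               "margin")
})

test_that("rank-sum comparison of MAF distributions matches enumeration", {
  idn <- compareMafDistributions(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(idn$pValue, 1)
  sep <- compareMafDistributions(c(0.9, 0.9, 0.9), c(0.5, 0.5, 0.5))
  expect_equal(sep$medianSexLinked, 0.9)
  expect_equal(sep$medianAutosomal, 0.5)
  expect_lte(sep$pValue, 0.15)  # exact two-sided floor at n = 3 vs 3
  set.seed(37)
  x <- runif(8, 0.5, 1)
  y <- runif(9, 0.5, 1)
  got <- compareMafDistributions(x, y)
  want <- oracleRankSum(x, y)
  expect_equal(got$statistic, want$W)
  expect_equal(got$pValue, want$p, tolerance = 1e-10)
  expect_error(compareMafDistributions(0.5, c(0.5, 0.6)), "2 values")
})

test_that("male het-site retention matches the Y survival fraction", {
  cfg <- simConfig(seed = 71, nAutosomes = 0, sexChromLength = 3e6,
                   strata = stratumSpec(0, 3e6, "old",
                                        xyDivergence = 0.005,
                                        yLoss = 0.5,
                                        ySilencedFraction = 0.5),
                   nGenesPerChrom = 300, windowSize = 5e4)
  tr <- simTruth(cfg)
  rna <- simulateRna(cfg, tr)
  het <- callHetSites(rna$alleleCounts)
  sx <- sampleSexes(cfg)
  males <- sx$sample[sx$sex == "M"]
  withHet <- unique(het$genesWithHet$gene[
    het$genesWithHet$sample %in% males])
  frac <- length(withHet) / 300
  # expected retention 1 - (yLoss + (1 - yLoss) * ySilenced) = 0.25
  expect_lt(abs(frac - 0.25), 0.08)
  # surviving genes with decayed Y activity are enriched in ASE
  maf <- aseTest(geneMajorAlleleFreq(
    het$sites[het$sites$sample %in% males, ]))
  genes <- truthGenes(tr)
  aseTruth <- genes$gene[genes$isASE]
  sig <- maf$gene[maf$isASE]
  expect_gt(mean(unique(sig) %in% aseTruth), 0.9)
})
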