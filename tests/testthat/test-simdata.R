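test_that("configuration validation rejects malformed inputs", {
  expect_error(
    simConfig(sexChromLength = 1e5,
              strata = rbind(stratumSpec(0, 6e4, "PAR"),
                             stratumSpec(5e4, 1e5, "young",
                                         xyDivergence = 0.01))),
    "tile")
  expect_error(
    simConfig(sexChromLength = 1e5,
              strata = stratumSpec(0, 1e5, "PAR", yLoss = 0.5)),
    "PAR")
  expect_error(
    simConfig(sexChromLength = 1e5,
              strata = stratumSpec(0, 5e4, "PAR")),
    "end at sexChromLength")
  expect_error(simConfig(nMales = 0), "male")
  expect_error(simConfig(haploidDepth = -1), "haploidDepth")
})

test_that("truth window labels exactly tile the sex chromosome", {
  cfg <- simConfig(seed = 5, nAutosomes = 1, chromLength = 1e6,
                   sexChromLength = 3e6, windowSize = 5e4)
  tr <- simTruth(cfg)
  w <- truthWindows(tr)
  expect_equal(sum(BiocGenerics::width(w)), 3e6)
  expect_false(is.unsorted(BiocGenerics::start(w)))
  expect_true(all(BiocGenerics::start(w)[-1] ==
                    BiocGenerics::end(w)[-length(w)] + 1L))
  expect_false(anyNA(w$label))
  # labels agree with the stratum tiling (thirds)
  expect_equal(unique(w$label[1:20]), "UNDIFF_PAR")
  expect_equal(unique(w$label[21:40]), "YOUNG")
  expect_equal(unique(w$label[41:60]), "OLD_DEGENERATE")
})

test_that("an all-PAR sex chromosome yields Y identical to X", {
  cfg <- simConfig(seed = 9, nAutosomes = 1, chromLength = 1e4,
                   sexChromLength = 2e4,
                   strata = stratumSpec(0, 2e4, "PAR"),
                   windowSize = 5e3, nGenesPerChrom = 5)
  gen <- simulateGenomes(cfg)
  expect_identical(as.character(gen$sequences[["chrY"]]),
                   as.character(gen$sequences[["chrX"]]))
})

test_that("total Y loss removes the old-stratum sequence", {
  cfg <- simConfig(seed = 9, nAutosomes = 1, chromLength = 1e4,
                   sexChromLength = 3e4,
                   strata = rbind(stratumSpec(0, 1e4, "PAR"),
                                  stratumSpec(1e4, 3e4, "old",
                                              yLoss = 1)),
                   windowSize = 5e3, nGenesPerChrom = 5)
  gen <- simulateGenomes(cfg)
  x <- as.character(gen$sequences[["chrX"]])
  y <- as.character(gen$sequences[["chrY"]])
  expect_equal(nchar(y), 1e4)
  expect_identical(y, substring(x, 1, 1e4))
})

test_that("X-Y divergence matches the binomial oracle", {
  len <- 1e6
  d <- 0.01
  cfg <- simConfig(seed = 13, nAutosomes = 1, chromLength = 1e4,
                   sexChromLength = len,
                   strata = stratumSpec(0, len, "young",
                                        xyDivergence = d),
                   windowSize = 5e4, nGenesPerChrom = 5)
  gen <- simulateGenomes(cfg)
  x <- strsplit(as.character(gen$sequences[["chrX"]]), "")[[1]]
  y <- strsplit(as.character(gen$sequences[["chrY"]]), "")[[1]]
  mism <- sum(x != y)
  expect_equal(mism, length(gen$truth@xyDivergentSites))
  # Binomial(1e6, 0.01): mean 1e4, sd ~99.5; 3 SD check
  expect_lt(abs(mism - len * d), 3 * sqrt(len * d * (1 - d)))
})

test_that("coverage means follow the hemizygosity model", {
  cfg <- simConfig(seed = 21, nAutosomes = 1, chromLength = 5e6,
                   sexChromLength = 5e6,
                   strata = rbind(stratumSpec(0, 2.5e6, "PAR"),
                                  stratumSpec(2.5e6, 5e6, "old",
                                              yLoss = 1)),
                   windowSize = 5e4, nGenesPerChrom = 10)
  tr <- simTruth(cfg)
  cov <- simulateCoverage(cfg, tr)
  sx <- sampleSexes(cfg)
  males <- sx$sample[sx$sex == "M"]
  onSex <- cov$chrom == "chrXY"
  par <- onSex & cov$end <= 2.5e6
  old <- onSex & cov$start >= 2.5e6
  mPar <- mean(cov$depth[par & cov$sample %in% males])
  fPar <- mean(cov$depth[par & !cov$sample %in% males])
  mOld <- mean(cov$depth[old & cov$sample %in% males])
  fOld <- mean(cov$depth[old & !cov$sample %in% males])
  # lambda = 20: both sexes 2*lambda in the PAR; 150 draws of
  # NB(mu = 40, size = 10) put the mean within ~3.5 (3 SD)
  expect_lt(abs(mPar - 40), 3.5)
  expect_lt(abs(fPar - 40), 3.5)
  expect_lt(abs(mOld - 20), 2.5)  # X-hemizygous: males halve
  expect_lt(abs(fOld - 40), 3.5)
  # determinism: identical draw under the same seed
  cov2 <- simulateCoverage(cfg, tr)
  expect_identical(cov, cov2)
  cov3 <- simulateCoverage(cfg, tr, seed = 999)
  expect_false(identical(cov$depth, cov3$depth))
})

test_that("SNP densities follow pi, pi + d, and hemizygous thinning", {
  d <- 0.005
  cfg <- simConfig(seed = 31, nAutosomes = 1, chromLength = 2e6,
                   sexChromLength = 6e6, windowSize = 5e4,
                   nGenesPerChrom = 10)
  tr <- simTruth(cfg)
  sites <- simulateSnps(cfg, tr)
  sx <- sampleSexes(cfg)
  males <- sx$sample[sx$sex == "M"]
  denOf <- function(sel, samples, bp) {
    sum(sel & sites$sample %in% samples) / length(samples) / bp
  }
  onSex <- sites$chrom == "chrXY"
  young <- onSex & sites$pos >= 2e6 & sites$pos < 4e6
  old <- onSex & sites$pos >= 4e6
  par <- onSex & sites$pos < 2e6
  females <- setdiff(sx$sample, males)
  expect_lt(abs(denOf(par, males, 2e6) - 0.001), 2e-4)
  expect_lt(abs(denOf(par, females, 2e6) - 0.001), 2e-4)
  expect_lt(abs(denOf(young, males, 2e6) - (0.001 + d)), 5e-4)
  expect_lt(abs(denOf(young, females, 2e6) - 0.001), 2e-4)
  # old stratum, yLoss = 0.9: male density ~ 0.1 * (pi + d)
  expect_lt(abs(denOf(old, males, 2e6) - 0.1 * (0.001 + d)), 3e-4)
  expect_lt(abs(denOf(old, females, 2e6) - 0.001), 2e-4)
})

test_that("emitted reads are deterministic and cover every k-mer", {
  cfg <- simConfig(seed = 41, nAutosomes = 1, chromLength = 1e4,
                   sexChromLength = 1e4,
                   strata = stratumSpec(0, 1e4, "PAR"),
                   windowSize = 5e3, nGenesPerChrom = 2)
  gen <- simulateGenomes(cfg)
  genome <- gen$sequences[["chrX"]]
  r1 <- emitReads(setNames(as.character(genome), "chrX"), depth = 30,
                  errorRate = 0, seed = 7)
  r2 <- emitReads(setNames(as.character(genome), "chrX"), depth = 30,
                  errorRate = 0, seed = 7)
  expect_identical(as.character(r1), as.character(r2))
  # total bases within 5% of depth * genome length (Poisson-scale check)
  expect_lt(abs(sum(BiocGenerics::width(r1)) - 3e5), 0.05 * 3e5)
  # every genomic k-mer recovered from error-free reads
  genomeKmers <- oracleGenomeKmers(as.character(genome), k = 31)
  readKmers <- kmers(countKmers(r1, k = 31, minCount = 1))
  expect_true(all(genomeKmers %in% readKmers))
})

test_that("silenced and deleted Y copies yield monoallelic male RNA", {
  cfg <- presetConfig("picta", sexChromLength = 2e6, nAutosomes = 1,
                      chromLength = 1e6, nGenesPerChrom = 150,
                      windowSize = 5e4, seed = 55)
  tr <- simTruth(cfg)
  rna <- simulateRna(cfg, tr)
  ac <- rna$alleleCounts
  sx <- sampleSexes(cfg)
  males <- sx$sample[sx$sex == "M"]
  genes <- truthGenes(tr)
  mono <- genes$gene[genes$yDeleted | genes$ySilenced]
  sel <- ac$sample %in% males & ac$gene %in% mono
  expect_true(any(sel))
  expect_true(all(ac$countB[sel] == 0))
  # female counts at the same genes stay balanced on average
  selF <- !ac$sample %in% males & ac$gene %in% mono
  frac <- sum(ac$countA[selF]) / sum(ac$countA[selF] + ac$countB[selF])
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("the full simulation bundle is deterministic given the seed", {
  cfg <- simConfig(seed = 77, nAutosomes = 1, chromLength = 1e6,
                   sexChromLength = 1.5e6, nGenesPerChrom = 30,
                   windowSize = 5e4)
  s1 <- simulateXYData(cfg)
  s2 <- simulateXYData(cfg)
  expect_identical(s1$coverage, s2$coverage)
  expect_identical(s1$hetSites, s2$hetSites)
  expect_identical(s1$alleleCounts, s2$alleleCounts)
  expect_identical(SummarizedExperiment::assay(s1$expression),
                   SummarizedExperiment::assay(s2$expression))
})
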