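library(GenomicRanges)

twoWindows <- tileWindows(c(chr1 = 2e4), 1e4)

test_that("window coverage averages per-sex sample means", {
  sexes <- data.frame(sample = c("M1", "M2", "F1"),
                      sex = c("M", "M", "F"))
  depth <- rbind(flatDepth(twoWindows, "M1", 10),
                 flatDepth(twoWindows, "M2", 30),
                 flatDepth(twoWindows, "F1", 10))
  cov <- windowCoverage(depth, twoWindows, sexes, normalize = FALSE)
  expect_equal(cov$maleCov, c(20, 20))
  expect_equal(cov$femaleCov, c(10, 10))
  expect_error(
    windowCoverage(rbind(depth, flatDepth(twoWindows, "X9", 5)),
                   twoWindows, sexes, normalize = FALSE),
    "without a sex label")
})

test_that("window means match brute-force recomputation on ragged input", {
  set.seed(42)
  win <- tileWindows(c(chr1 = 1e4), 2.5e3)
  # ragged depth segments of random length, not aligned to windows
  mk <- function(sample) {
    brk <- sort(sample(1:9999, 40))
    st <- c(0, brk)
    en <- c(brk, 10000)
    data.frame(chrom = "chr1", start = st, end = en, sample = sample,
               depth = rpois(length(st), 30), stringsAsFactors = FALSE)
  }
  depth <- rbind(mk("M1"), mk("F1"))
  got <- perSampleWindowDepth(depth, win)
  want <- oracleWindowMeans(depth, win)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("normalization is scale-invariant and idempotent", {
  win <- tileWindows(c(chr1 = 4e4), 1e4)
  sexes <- data.frame(sample = c("M1", "F1"), sex = c("M", "F"))
  depth <- rbind(flatDepth(win, "M1", 20), flatDepth(win, "F1", 40))
  mat <- perSampleWindowDepth(depth, win)
  norm <- normalizeSamples(mat, rep(TRUE, 4))
  expect_true(all(norm == 1))
  set.seed(1)
  mat2 <- matrix(rpois(40, 30) + 1, nrow = 10)
  colnames(mat2) <- c("a", "b", "c", "d")
  n1 <- normalizeSamples(mat2, rep(TRUE, 10))
  expect_equal(normalizeSamples(n1, rep(TRUE, 10)), n1)
  expect_error(normalizeSamples(mat2 * 0, rep(TRUE, 10)), "zero")
})

test_that("SNP density counts per kb per individual", {
  win <- tileWindows(c(chr1 = 2e4), 1e4)
  sexes <- data.frame(sample = c("M1", "F1"), sex = c("M", "F"))
  expect_equal(snpDensity(emptyHetSites(), win, sexes)$maleSnpDen,
               c(0, 0))
  sites <- data.frame(chrom = "chr1", pos = seq(0, 9000, by = 1000),
                      sample = "M1", stringsAsFactors = FALSE)
  den <- snpDensity(sites, win, sexes)
  expect_equal(den$maleSnpDen, c(1, 0))
  expect_equal(den$femaleSnpDen, c(0, 0))
})

test_that("moving average shrinks at edges and preserves length", {
  expect_equal(movingAverage(c(5, 1, 4), span = 1), c(5, 1, 4))
  expect_equal(movingAverage(rep(2, 7), span = 5), rep(2, 7))
  expect_equal(movingAverage(c(0, 0, 3, 0, 0), span = 3),
               c(0, 1, 1, 1, 0))
  expect_error(movingAverage(1:5, span = 2), "odd")
  expect_error(movingAverage(1:5, span = 0), "odd")
  # NA handling: averages over available neighbors only
  expect_equal(movingAverage(c(1, NA, 3), span = 3), c(1, 2, 3))
})

test_that("bootstrap interval degenerates correctly and is seeded", {
  ci <- bootstrapAutosomalCI(rep(3.5, 50), nBoot = 200, seed = 1)
  expect_equal(ci@lower, 3.5)
  expect_equal(ci@upper, 3.5)
  expect_equal(ci@center, 3.5)
  set.seed(99)
  v <- rnorm(500)
  a <- bootstrapAutosomalCI(v, nBoot = 500, seed = 42)
  b <- bootstrapAutosomalCI(v, nBoot = 500, seed = 42)
  expect_identical(c(a@lower, a@upper), c(b@lower, b@upper))
  expect_true(a@lower <= a@center && a@center <= a@upper)
  expect_error(bootstrapAutosomalCI(v, level = 1.2), "level")
  expect_error(bootstrapAutosomalCI(numeric(0)), "at least 2")
})

test_that("statistics negate under sex-label swap and ZW orientation", {
  win <- tileWindows(c(chr1 = 4e4, chrZ = 2e4), 1e4)
  sexes <- data.frame(sample = c("M1", "F1"), sex = c("M", "F"))
  swapped <- data.frame(sample = c("M1", "F1"), sex = c("F", "M"))
  set.seed(3)
  depth <- rbind(flatDepth(win, "M1", rpois(6, 30) + 1),
                 flatDepth(win, "F1", rpois(6, 30) + 1))
  sites <- data.frame(chrom = "chrZ", pos = c(100, 5000, 15000),
                      sample = c("M1", "M1", "F1"),
                      stringsAsFactors = FALSE)
  a <- windowStats(depth, sites, win, sexes, sexChrom = "chrZ")
  b <- windowStats(depth, sites, win, swapped, sexChrom = "chrZ")
  expect_equal(mcols(a)$log2MFCov, -mcols(b)$log2MFCov)
  expect_equal(mcols(a)$mfSnpDiff, -mcols(b)$mfSnpDiff)
  zw <- windowStats(depth, sites, win, sexes, sexChrom = "chrZ",
                    orientation = "ZW")
  expect_equal(mcols(zw)$log2MFCov, mcols(b)$log2MFCov)
})

test_that("window statistics equal brute-force recomputation on simulation", {
  cfg <- simConfig(seed = 8, nAutosomes = 1, chromLength = 5e5,
                   sexChromLength = 5e5, windowSize = 5e4,
                   nGenesPerChrom = 5)
  sim <- simulateXYData(cfg)
  ws <- windowStats(sim$coverage, sim$hetSites, sim$windows, sim$sexes,
                    sexChrom = "chrXY", normalize = FALSE)
  mat <- oracleWindowMeans(sim$coverage, sim$windows)
  sx <- sim$sexes
  male <- rowMeans(mat[, sx$sample[sx$sex == "M"]])
  female <- rowMeans(mat[, sx$sample[sx$sex == "F"]])
  expect_equal(mcols(ws)$maleCov, unname(male))
  expect_equal(mcols(ws)$femaleCov, unname(female))
  expect_equal(mcols(ws)$log2MFCov, unname(log2(male / female)))
})
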