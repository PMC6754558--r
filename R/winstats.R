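#' @importFrom data.table as.data.table
NULL

depthToGRanges <- function(depth) {
  assertColumns(depth, c("chrom", "start", "end", "sample", "depth"),
                "depth")
  GRanges(depth$chrom, IRanges(depth$start + 1, depth$end))
}

#' Per-sample mean depth in analysis windows
#'
#' Aggregates a depth table (arbitrary non-overlapping intervals per
#' sample: per-base, bedGraph-style runs, or pre-windowed) into the
#' overlap-weighted mean depth of each analysis window. Windows with no
#' covered bases for a sample are `NA` (flagged missing).
#'
#' @param depth data.frame: `chrom`, `start`, `end` (0-based
#'   half-open), `sample`, `depth`.
#' @param windows GRanges of analysis windows.
#' @return numeric matrix, windows x samples.
#' @export
perSampleWindowDepth <- function(depth, windows) {
  gr <- depthToGRanges(depth)
  ov <- findOverlaps(gr, windows)
  w <- width(pintersect(gr[queryHits(ov)], windows[subjectHits(ov)]))
  dt <- data.table(
    win = subjectHits(ov),
    sample = depth$sample[queryHits(ov)],
    wsum = w * depth$depth[queryHits(ov)],
    w = w)
  agg <- dt[, list(d = sum(wsum) / sum(w)), by = c("win", "sample")]
  samples <- sort(unique(depth$sample))
  mat <- matrix(NA_real_, nrow = length(windows), ncol = length(samples),
                dimnames = list(NULL, samples))
  mat[cbind(agg$win, match(agg$sample, samples))] <- agg$d
  mat
}

#' Normalize samples to unit autosomal median depth
#'
#' Scales each sample so its median depth over autosomal windows equals
#' 1, removing sequencing-effort differences that would otherwise mimic
#' sex linkage. Within-sample structure is preserved; normalization is
#' idempotent.
#'
#' @param mat windows x samples depth matrix
#'   (see [perSampleWindowDepth()]).
#' @param autosomal logical vector marking autosomal windows (rows).
#' @return matrix of the same shape.
#' @export
normalizeSamples <- function(mat, autosomal) {
  if (length(autosomal) != nrow(mat)) {
    stop("'autosomal' must have one entry per window")
  }
  if (!any(autosomal)) stop("no autosomal windows identified")
  med <- apply(mat[autosomal, , drop = FALSE], 2L, median, na.rm = TRUE)
  if (any(!is.finite(med) | med == 0)) {
    stop("autosomal median depth is zero (or undefined) for sample(s): ",
         paste(colnames(mat)[!is.finite(med) | med == 0], collapse = ", "))
  }
  sweep(mat, 2L, med, "/")
}

sexOf <- function(samples, sexes, orientation = "XY") {
  assertColumns(sexes, c("sample", "sex"), "sexes")
  sx <- sexes$sex[match(samples, sexes$sample)]
  if (anyNA(sx)) {
    stop("sample(s) without a sex label: ",
         paste(samples[is.na(sx)], collapse = ", "))
  }
  if (!all(sx %in% c("M", "F"))) stop("sex labels must be 'M' or 'F'")
  if (orientation == "ZW") sx <- c(M = "F", F = "M")[sx]
  sx
}

#' Per-window per-sex mean coverage
#'
#' The per-sex value is the mean over individuals of that sex of the
#' per-sample window mean depth, optionally normalized to unit
#' autosomal median per sample first.
#'
#' @inheritParams perSampleWindowDepth
#' @param sexes data.frame with columns `sample`, `sex` (`"M"`/`"F"`).
#' @param sexChrom name(s) of candidate sex chromosome(s); all other
#'   chromosomes are treated as autosomal for normalization.
#' @param normalize normalize samples to unit autosomal median depth?
#' @param orientation `"XY"` (statistics are male vs female) or `"ZW"`
#'   (sex roles flipped, so the heterogametic sex is always the
#'   numerator).
#' @return data.frame with columns `maleCov`, `femaleCov`, one row per
#'   window.
#' @export
windowCoverage <- function(depth, windows, sexes, sexChrom = NULL,
                           normalize = TRUE, orientation = c("XY", "ZW")) {
  orientation <- match.arg(orientation)
  mat <- perSampleWindowDepth(depth, windows)
  if (normalize) {
    autosomal <- !(as.character(seqnames(windows)) %in% sexChrom)
    mat <- normalizeSamples(mat, autosomal)
  }
  sx <- sexOf(colnames(mat), sexes, orientation)
  data.frame(
    maleCov = rowMeans(mat[, sx == "M", drop = FALSE], na.rm = FALSE),
    femaleCov = rowMeans(mat[, sx == "F", drop = FALSE], na.rm = FALSE))
}

#' Per-window per-sex heterozygous SNP density
#'
#' Density is the heterozygous-site count per kb, averaged over the
#' individuals of each sex (individuals without sites in a window
#' contribute zeros).
#'
#' @param sites data.frame of heterozygous sites: `chrom`, `pos`
#'   (0-based), `sample` (from [simulateSnps()] or [readVcfHets()]).
#' @inheritParams windowCoverage
#' @return data.frame with columns `maleSnpDen`, `femaleSnpDen`
#'   (sites/kb/individual), one row per window.
#' @export
snpDensity <- function(sites, windows, sexes,
                       orientation = c("XY", "ZW")) {
  orientation <- match.arg(orientation)
  if (length(windows) == 0L) stop("window set is empty")
  assertColumns(sites, c("chrom", "pos", "sample"), "sites")
  samples <- sexes$sample
  sx <- sexOf(samples, sexes, orientation)
  counts <- matrix(0, nrow = length(windows), ncol = length(samples),
                   dimnames = list(NULL, samples))
  if (nrow(sites)) {
    if (!all(sites$sample %in% samples)) {
      stop("sites contain sample(s) without a sex label")
    }
    gr <- GRanges(sites$chrom, IRanges(sites$pos + 1, width = 1L))
    ov <- findOverlaps(gr, windows)
    dt <- data.table(win = subjectHits(ov),
                     sample = sites$sample[queryHits(ov)])
    agg <- dt[, list(n = .N), by = c("win", "sample")]
    counts[cbind(agg$win, match(agg$sample, samples))] <- agg$n
  }
  dens <- counts / (width(windows) / 1000)
  data.frame(
    maleSnpDen = rowMeans(dens[, sx == "M", drop = FALSE]),
    femaleSnpDen = rowMeans(dens[, sx == "F", drop = FALSE]))
}

#' Centered moving average with shrinking edges
#'
#' Mean over the `span` windows centered on each position; at series
#' edges the window shrinks to the available neighbors, so the output
#' has the same length as the input. `NA`s are ignored within each
#' window.
#'
#' @param values numeric series ordered by genomic position.
#' @param span odd integer >= 1.
#' @return numeric vector of the same length.
#' @examples
#' movingAverage(c(0, 0, 3, 0, 0), span = 3)
#' @export
movingAverage <- function(values, span = 11L) {
  if (span < 1 || span %% 2 == 0) stop("span must be an odd integer >= 1")
  n <- length(values)
  if (n == 0L) return(numeric(0))
  h <- (span - 1L) / 2L
  ok <- !is.na(values)
  cs <- cumsum(ifelse(ok, values, 0))
  cn <- cumsum(ok)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sums <- cs[hi] - c(0, cs)[lo]
  cnts <- cn[hi] - c(0, cn)[lo]
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Percentile bootstrap null interval from autosomal windows
#'
#' Resamples the autosomal window statistics with replacement `nBoot`
#' times; each replicate yields the `(1-level)/2` and `1-(1-level)/2`
#' percentiles of the resampled distribution, and the interval reported
#' is the bootstrap mean of each bound. Windows of a focal chromosome
#' falling outside the interval deviate significantly from the
#' autosomal background at the stated level.
#'
#' @param values numeric vector of the statistic over autosomal windows
#'   (`NA`s dropped).
#' @param statistic statistic name recorded in the result.
#' @param nBoot number of bootstrap replicates.
#' @param level confidence level in (0, 1).
#' @param seed RNG seed for reproducible intervals.
#' @return An [AutosomalNull-class].
#' @export
bootstrapAutosomalCI <- function(values, statistic = "log2MFCov",
                                 nBoot = 1000L, level = 0.95,
                                 seed = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("need at least 2 finite autosomal window values")
  }
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  withSeed(seed, {
    bounds <- vapply(seq_len(nBoot), function(i) {
      quantile(sample(values, replace = TRUE), probs, names = FALSE)
    }, numeric(2L))
  })
  new("AutosomalNull", statistic = statistic,
      lower = mean(bounds[1L, ]), upper = mean(bounds[2L, ]),
      level = level, nBoot = as.integer(nBoot),
      center = median(values))
}

#' Assemble per-window male/female scan statistics
#'
#' Combines coverage and SNP-density summaries into a
#' [WindowStats-class] object: normalized per-sex mean depth, the log2
#' male:female coverage ratio (NA where either sex has zero or missing
#' coverage), per-sex heterozygous SNP densities, and their
#' male-minus-female difference.
#'
#' @inheritParams windowCoverage
#' @param sites heterozygous-site data.frame (see [snpDensity()]).
#' @return A [WindowStats-class] (GRanges with statistic columns).
#' @export
windowStats <- function(depth, sites, windows, sexes, sexChrom = NULL,
                        normalize = TRUE, orientation = c("XY", "ZW")) {
  orientation <- match.arg(orientation)
  cov <- windowCoverage(depth, windows, sexes, sexChrom = sexChrom,
                        normalize = normalize, orientation = orientation)
  den <- snpDensity(sites, windows, sexes, orientation = orientation)
  l2 <- log2(cov$maleCov / cov$femaleCov)
  l2[!is.finite(l2)] <- NA_real_
  gr <- granges(windows)
  mcols(gr) <- DataFrame(
    maleCov = cov$maleCov, femaleCov = cov$femaleCov, log2MFCov = l2,
    maleSnpDen = den$maleSnpDen, femaleSnpDen = den$femaleSnpDen,
    mfSnpDiff = den$maleSnpDen - den$femaleSnpDen)
  new("WindowStats", gr)
}

#' Export window statistics as a data.frame
#'
#' @param ws a [WindowStats-class].
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and the six statistic columns.
#' @export
windowStatsTable <- function(ws) {
  data.frame(chrom = as.character(seqnames(ws)), start = start(ws) - 1L,
             end = end(ws), as.data.frame(mcols(ws)))
}
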