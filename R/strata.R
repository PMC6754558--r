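#' Classify windows into stratum states against autosomal nulls
#'
#' Applies the joint coverage/SNP decision rule to (smoothed) window
#' statistics: a window is `OLD_DEGENERATE` when its smoothed log2
#' male:female coverage ratio falls below the lower bound of the
#' coverage null (males halve their depth over X-hemizygous regions);
#' otherwise `YOUNG` when its smoothed male-minus-female SNP-density
#' difference exceeds the upper bound of the SNP null (Y reads carrying
#' Y-specific alleles map to the homologous X); otherwise
#' `UNDIFF_PAR`. Coverage takes precedence over the SNP signal. A
#' reduced male SNP density co-occurring with reduced coverage is
#' annotated as corroborating Y degeneration.
#'
#' The nulls must be built from autosomal values of the *same*
#' statistics, smoothed with the same span (see [callStrata()], which
#' wires this up).
#'
#' @param ws a [WindowStats-class] restricted to one chromosome,
#'   ordered by position.
#' @param covNull [AutosomalNull-class] for `log2MFCov`.
#' @param snpNull [AutosomalNull-class] for `mfSnpDiff`.
#' @param span odd smoothing span in windows (1 = no smoothing).
#' @return GRanges of the windows with metadata columns `label`,
#'   `smoothCov`, `smoothSnp`, `corroborated`.
#' @export
classifyWindows <- function(ws, covNull, snpNull, span = 3L) {
  if (covNull@statistic != "log2MFCov" || snpNull@statistic != "mfSnpDiff") {
    stop("null/statistic mismatch: covNull must be 'log2MFCov', ",
         "snpNull 'mfSnpDiff'")
  }
  if (length(unique(as.character(seqnames(ws)))) > 1L) {
    stop("classifyWindows expects windows of a single chromosome")
  }
  o <- order(start(ws))
  ws <- ws[o]
  sc <- movingAverage(mcols(ws)$log2MFCov, span)
  ss <- movingAverage(mcols(ws)$mfSnpDiff, span)
  label <- rep(NA_character_, length(ws))
  ok <- is.finite(sc) & is.finite(ss)
  label[ok] <- ifelse(sc[ok] < covNull@lower, "OLD_DEGENERATE",
                      ifelse(ss[ok] > snpNull@upper, "YOUNG",
                             "UNDIFF_PAR"))
  out <- granges(ws)
  mcols(out) <- DataFrame(
    label = label, smoothCov = sc, smoothSnp = ss,
    rawCov = mcols(ws)$log2MFCov, rawSnp = mcols(ws)$mfSnpDiff,
    corroborated = ok & label == "OLD_DEGENERATE" & ss < snpNull@lower)
  out
}

#' Refine call boundaries on the unsmoothed statistic
#'
#' Smoothing blurs stratum transitions by up to `(span - 1) / 2`
#' windows. For each boundary between adjacent calls, this re-places
#' the cut within a `span + 2`-window neighborhood at the position
#' minimizing the squared deviation of the *raw* per-window statistic
#' from each call's median (the coverage ratio when either side is an
#' old degenerate stratum, the SNP-density difference otherwise).
#'
#' @param calls merged stratum calls (see [mergeCalls()]).
#' @param labeled labeled windows from [classifyWindows()] (must carry
#'   `rawCov`/`rawSnp` columns).
#' @param span the smoothing span used for classification.
#' @return the calls with adjusted boundaries and recomputed support.
#' @export
refineBoundaries <- function(calls, labeled, span = 3L) {
  if (length(calls) < 2L) return(calls)
  labeled <- labeled[order(start(labeled))]
  reach <- span + 2L
  for (j in seq_len(length(calls) - 1L)) {
    a <- calls[j]
    b <- calls[j + 1L]
    col <- if (a$label == "OLD_DEGENERATE" ||
                 b$label == "OLD_DEGENERATE") "rawCov" else "rawSnp"
    x <- mcols(labeled)[[col]]
    ia <- which(start(labeled) >= start(a) & start(labeled) < end(a))
    ib <- which(start(labeled) >= start(b) & start(labeled) < end(b))
    if (length(ia) < 2L || length(ib) < 2L) next
    medA <- median(x[ia], na.rm = TRUE)
    medB <- median(x[ib], na.rm = TRUE)
    c0 <- ib[1L]
    lo <- max(min(ia) + 1L, c0 - reach)
    hi <- min(max(ib), c0 + reach)
    seg <- min(ia):max(ib)
    cost <- vapply(lo:hi, function(k) {
      left <- seg[seg < k]
      right <- seg[seg >= k]
      sum((x[left] - medA)^2, na.rm = TRUE) +
        sum((x[right] - medB)^2, na.rm = TRUE)
    }, numeric(1L))
    k <- (lo:hi)[which.min(cost)]
    end(calls)[j] <- end(labeled)[k - 1L]
    start(calls)[j + 1L] <- start(labeled)[k]
  }
  calls$support <- vapply(seq_along(calls), function(j) {
    i <- which(start(labeled) >= start(calls)[j] &
                 start(labeled) < end(calls)[j])
    mean(labeled$label[i] == calls$label[j], na.rm = TRUE)
  }, numeric(1L))
  calls
}

labelRuns <- function(labels, minRun) {
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < minRun)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    leftLen <- if (i > 1L) r$lengths[i - 1L] else -1L
    rightLen <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    take <- if (leftLen >= rightLen) r$values[i - 1L] else r$values[i + 1L]
    labels[starts[i]:ends[i]] <- take
  }
  labels
}

#' Merge per-window labels into contiguous stratum calls
#'
#' Maximal runs of identical labels are merged into calls; runs shorter
#' than `minRun` windows are iteratively absorbed into the larger
#' flanking run (ties break to the preceding run), suppressing isolated
#' misclassified windows. Boundaries are reported at window resolution.
#'
#' @param labeled GRanges of ordered windows with a `label` metadata
#'   column (from [classifyWindows()]); `NA` labels are dropped first.
#' @param minRun minimum run length in windows.
#' @return GRanges of stratum calls with metadata columns `label` and
#'   `support` (fraction of member windows whose individual label
#'   matches the call).
#' @export
mergeCalls <- function(labeled, minRun = 5L) {
  keep <- !is.na(labeled$label)
  labeled <- labeled[keep]
  if (!length(labeled)) return(GRanges())
  o <- order(start(labeled))
  labeled <- labeled[o]
  orig <- labeled$label
  merged <- labelRuns(orig, minRun)
  r <- rle(merged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  calls <- GRanges(
    as.character(seqnames(labeled))[starts],
    IRanges(start(labeled)[starts], end(labeled)[ends]))
  calls$label <- r$values
  calls$support <- vapply(seq_along(starts), function(i) {
    mean(orig[starts[i]:ends[i]] == r$values[i])
  }, numeric(1L))
  calls
}

#' Scan a chromosome for evolutionary strata
#'
#' End-to-end stratum inference on one candidate chromosome: smooths
#' the per-window coverage and SNP statistics, builds percentile
#' bootstrap nulls from the identically smoothed autosomal windows,
#' classifies each candidate window (coverage loss = old degenerate
#' stratum, elevated male SNP density without coverage loss = young
#' stratum, otherwise undifferentiated/PAR), merges labels into
#' contiguous calls, and refines each call boundary on the unsmoothed
#' statistic ([refineBoundaries()]).
#'
#' @param ws a [WindowStats-class] over all chromosomes.
#' @param sexChrom name of the candidate sex chromosome.
#' @param span odd smoothing span in windows.
#' @param nBoot bootstrap replicates for the autosomal nulls.
#' @param level confidence level of the nulls.
#' @param minRun minimum run length for [mergeCalls()]. The default,
#'   `max(2 * span + 1, 15)` windows, encodes that strata are Mb-scale
#'   features (15 windows = 750 kb at the default 50 kb windows): it
#'   absorbs both the footprint of single outlying windows (which
#'   smoothing spreads over `span` values) and short chance runs of
#'   misclassified windows inside a stratum. Lower it for small
#'   demonstration chromosomes.
#' @param seed RNG seed for the bootstrap.
#' @return list: `calls` (merged stratum GRanges), `windows` (labeled
#'   candidate windows), `covNull`, `snpNull`.
#' @examples
#' cfg <- simConfig(seed = 2, nAutosomes = 1, chromLength = 2e6,
#'                  sexChromLength = 3e6, windowSize = 5e4)
#' sim <- simulateXYData(cfg)
#' ws <- windowStats(sim$coverage, sim$hetSites, sim$windows, sim$sexes,
#'                   sexChrom = "chrXY")
#' res <- callStrata(ws, "chrXY", seed = 1)
#' res$calls
#' @export
callStrata <- function(ws, sexChrom, span = 3L, nBoot = 1000L,
                       level = 0.95, minRun = NULL, seed = NULL) {
  if (is.null(minRun)) minRun <- max(2L * span + 1L, 15L)
  isSex <- as.character(seqnames(ws)) == sexChrom
  if (!any(isSex)) stop("no windows on chromosome ", sexChrom)
  if (!any(!isSex)) stop("no autosomal windows to build the null from")
  auto <- ws[!isSex]
  # smooth autosomal statistics chromosome-wise with the same span
  smoothAuto <- function(col) {
    unlist(lapply(split(seq_along(auto), as.character(seqnames(auto))),
                  function(i) {
                    i <- i[order(start(auto)[i])]
                    movingAverage(mcols(auto)[[col]][i], span)
                  }), use.names = FALSE)
  }
  covNull <- bootstrapAutosomalCI(smoothAuto("log2MFCov"),
                                  statistic = "log2MFCov", nBoot = nBoot,
                                  level = level,
                                  seed = if (is.null(seed)) NULL
                                         else subSeed(seed, 11L))
  snpNull <- bootstrapAutosomalCI(smoothAuto("mfSnpDiff"),
                                  statistic = "mfSnpDiff", nBoot = nBoot,
                                  level = level,
                                  seed = if (is.null(seed)) NULL
                                         else subSeed(seed, 12L))
  labeled <- classifyWindows(ws[isSex], covNull, snpNull, span = span)
  calls <- refineBoundaries(mergeCalls(labeled, minRun = minRun),
                            labeled, span = span)
  list(calls = calls, windows = labeled,
       covNull = covNull, snpNull = snpNull)
}
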