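#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData
NULL

#' Assemble an expression SummarizedExperiment
#'
#' @param mat genes x samples matrix of normalized (TPM-like)
#'   expression values.
#' @param geneInfo data.frame with one row per gene: `gene`, `chrom`,
#'   `start`, `end`, `class` (one of `autosome`, `PAR`, `young`,
#'   `old`).
#' @param sexes data.frame `sample`, `sex` covering the matrix columns.
#' @return [SummarizedExperiment::SummarizedExperiment] with assay
#'   `expr`.
#' @export
makeExpressionSE <- function(mat, geneInfo, sexes) {
  assertColumns(geneInfo, c("gene", "chrom", "class"), "geneInfo")
  if (nrow(geneInfo) != nrow(mat)) {
    stop("geneInfo must have one row per matrix row")
  }
  sx <- sexOf(colnames(mat), sexes)
  SummarizedExperiment(
    assays = list(expr = as.matrix(mat)),
    rowData = S4Vectors::DataFrame(geneInfo, row.names = geneInfo$gene),
    colData = S4Vectors::DataFrame(sample = colnames(mat), sex = sx,
                                   row.names = colnames(mat)))
}

exprMatrix <- function(se) {
  if (!"expr" %in% SummarizedExperiment::assayNames(se)) {
    stop("expected an assay named 'expr'")
  }
  assay(se, "expr")
}

geneClass <- function(se) as.character(rowData(se)$class)

isNonrecombining <- function(se) geneClass(se) %in% c("young", "old")

sexCols <- function(se, sex) which(colData(se)$sex == sex)

#' Filter to genes expressed in both sexes
#'
#' Retains genes with expression `>= minExpr` in at least half the
#' samples of *each* sex, the floor applied before any ratio
#' statistics; genes expressed in only one sex would otherwise produce
#' unbounded log ratios.
#'
#' @param se expression [SummarizedExperiment::SummarizedExperiment]
#'   (see [makeExpressionSE()]).
#' @param minExpr expression floor (default 1 normalized unit).
#' @return the filtered SummarizedExperiment.
#' @export
filterExpressed <- function(se, minExpr = 1) {
  mat <- exprMatrix(se)
  mCols <- sexCols(se, "M")
  fCols <- sexCols(se, "F")
  okM <- rowSums(mat[, mCols, drop = FALSE] >= minExpr) >=
    length(mCols) / 2
  okF <- rowSums(mat[, fCols, drop = FALSE] >= minExpr) >=
    length(fCols) / 2
  keep <- okM & okF
  if (!any(keep)) stop("no genes pass the expression filter")
  se[keep, ]
}

#' Per-gene log2 male:female expression ratio
#'
#' `log2(mean over male samples / mean over female samples)` per gene;
#' genes with a zero mean in either sex are dropped with a message.
#'
#' @inheritParams filterExpressed
#' @return named numeric vector over the retained genes.
#' @export
mfLog2PerGene <- function(se) {
  mat <- exprMatrix(se)
  m <- rowMeans(mat[, sexCols(se, "M"), drop = FALSE])
  f <- rowMeans(mat[, sexCols(se, "F"), drop = FALSE])
  bad <- m == 0 | f == 0
  if (any(bad)) {
    message("dropping ", sum(bad), " gene(s) with zero mean in one sex")
  }
  setNames(log2(m / f), rownames(se))[!bad]
}

#' Male vs female expression on the nonrecombining X (signed rank)
#'
#' Two-sided Wilcoxon signed-rank test over gene pairs (per-gene male
#' mean vs female mean) restricted to genes of the nonrecombining
#' region (young + old strata). If every difference is zero the test is
#' undefined; p = 1 is returned with a flag.
#'
#' @inheritParams filterExpressed
#' @return list: `statistic` (V), `pValue`, `n`, `allZero`.
#' @export
testMFX <- function(se) {
  sel <- isNonrecombining(se)
  if (sum(sel) < 6L) stop("need >= 6 nonrecombining X genes")
  mat <- exprMatrix(se[sel, ])
  m <- rowMeans(mat[, sexCols(se, "M"), drop = FALSE])
  f <- rowMeans(mat[, sexCols(se, "F"), drop = FALSE])
  if (all(m == f)) {
    return(list(statistic = NA_real_, pValue = 1, n = sum(sel),
                allZero = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(m, f, paired = TRUE))
  list(statistic = unname(wt$statistic), pValue = wt$p.value,
       n = sum(sel), allZero = FALSE)
}

#' X vs autosome expression within one sex (rank sum)
#'
#' Two-sided Wilcoxon rank-sum test comparing per-gene mean expression
#' of nonrecombining X genes against autosomal genes within the stated
#' sex.
#'
#' @inheritParams filterExpressed
#' @param sex `"M"` or `"F"`.
#' @return list: `statistic` (W), `pValue`, `nX`, `nA`, `medianX`,
#'   `medianA`.
#' @export
testXvsAutosomes <- function(se, sex = c("M", "F")) {
  sex <- match.arg(sex)
  mat <- exprMatrix(se)
  means <- rowMeans(mat[, sexCols(se, sex), drop = FALSE])
  x <- means[isNonrecombining(se)]
  a <- means[geneClass(se) == "autosome"]
  if (length(x) < 2L || length(a) < 2L) {
    stop("need >= 2 genes in each group")
  }
  wt <- suppressWarnings(wilcox.test(x, a))
  list(statistic = unname(wt$statistic), pValue = wt$p.value,
       nX = length(x), nA = length(a),
       medianX = median(x), medianA = median(a))
}

#' M:F ratios of X-linked ASE genes vs autosomal genes (rank sum)
#'
#' Compares the per-gene log2 male:female expression ratios of
#' sex-linked genes with a male ASE pattern against autosomal genes.
#'
#' @inheritParams filterExpressed
#' @param aseGenes character vector of gene ids with significant male
#'   ASE (from [aseTest()]).
#' @return list: `statistic`, `pValue`, `nAseX`, `nA`, `medianAseX`,
#'   `medianA`; all NA (with `applicable = FALSE`) when no ASE gene is
#'   present in the matrix.
#' @export
testAseGeneRatios <- function(se, aseGenes) {
  ratios <- mfLog2PerGene(se)
  cls <- geneClass(se)[match(names(ratios), rownames(se))]
  xAse <- ratios[names(ratios) %in% aseGenes &
                   cls %in% c("PAR", "young", "old")]
  a <- ratios[cls == "autosome"]
  if (length(xAse) < 2L) {
    return(list(statistic = NA_real_, pValue = NA_real_,
                nAseX = length(xAse), nA = length(a),
                medianAseX = NA_real_, medianA = median(a),
                applicable = FALSE))
  }
  wt <- suppressWarnings(wilcox.test(xAse, a))
  list(statistic = unname(wt$statistic), pValue = wt$p.value,
       nAseX = length(xAse), nA = length(a),
       medianAseX = median(xAse), medianA = median(a),
       applicable = TRUE)
}

#' Classify genes as male-biased, female-biased, or unbiased
#'
#' A gene is sex-biased when `|log2(M/F)| >= lfc` and its per-gene
#' Wilcoxon rank-sum test (male vs female samples) is significant after
#' BH correction (`q < alpha`). Counts are tabulated for the
#' nonrecombining X and the autosomes and compared with a 2x3
#' chi-square homogeneity test. Note the rank-sum p floor at 3 vs 3
#' samples is 0.1, so meaningful classification needs more replicates.
#'
#' @inheritParams filterExpressed
#' @param lfc absolute log2 fold-change threshold.
#' @param alpha BH-corrected significance threshold.
#' @return list: `classes` (per-gene factor), `table` (2x3 counts,
#'   X vs autosomes), `chisq`, `df`, `pValue`.
#' @export
sexBiasClasses <- function(se, lfc = 1, alpha = 0.05) {
  mat <- exprMatrix(se)
  mCols <- sexCols(se, "M")
  fCols <- sexCols(se, "F")
  if (length(mCols) < 2L || length(fCols) < 2L) {
    stop("need >= 2 replicates per sex")
  }
  l2 <- log2(rowMeans(mat[, mCols, drop = FALSE]) /
               rowMeans(mat[, fCols, drop = FALSE]))
  p <- vapply(seq_len(nrow(mat)), function(i) {
    suppressWarnings(wilcox.test(mat[i, mCols], mat[i, fCols]))$p.value
  }, numeric(1L))
  q <- p.adjust(p, method = "BH")
  cls <- rep("unbiased", nrow(mat))
  cls[q < alpha & l2 >= lfc] <- "male_biased"
  cls[q < alpha & l2 <= -lfc] <- "female_biased"
  cls <- factor(cls, levels = c("male_biased", "unbiased",
                                "female_biased"))
  grp <- ifelse(isNonrecombining(se), "X", "autosome")
  tab <- table(factor(grp, levels = c("X", "autosome")), cls)
  if (any(rowSums(tab) == 0)) {
    stop("degenerate table margins: a gene group is empty")
  }
  if (sum(colSums(tab) > 0) < 2L) {
    # single class everywhere: the distributions are trivially identical
    ct <- list(statistic = 0, parameter = 0, p.value = 1)
  } else {
    ct <- suppressWarnings(chisq.test(tab[, colSums(tab) > 0,
                                          drop = FALSE],
                                      correct = FALSE))
  }
  list(classes = setNames(cls, rownames(se)), table = tab,
       chisq = unname(ct$statistic), df = unname(ct$parameter),
       pValue = ct$p.value)
}

#' Along-chromosome expression-ratio track
#'
#' Per-window mean of per-gene log2 male:female expression ratios,
#' smoothed with [movingAverage()]; windows containing no genes are
#' `NA`, not zero.
#'
#' @inheritParams filterExpressed
#' @param windows GRanges of windows over the chromosome(s) of
#'   interest.
#' @param span odd smoothing span in windows.
#' @return GRanges of the windows with columns `meanMFLog2` (raw) and
#'   `smooth` (moving average, computed per chromosome).
#' @export
expressionTrack <- function(se, windows, span = 11L) {
  ratios <- mfLog2PerGene(se)
  rd <- rowData(se)[match(names(ratios), rownames(se)), ]
  genes <- GRanges(rd$chrom, IRanges(rd$start + 1, width = 1L))
  ov <- findOverlaps(genes, windows)
  raw <- rep(NA_real_, length(windows))
  agg <- tapply(ratios[queryHits(ov)], subjectHits(ov), mean)
  raw[as.integer(names(agg))] <- agg
  sm <- rep(NA_real_, length(windows))
  for (chr in unique(as.character(seqnames(windows)))) {
    i <- which(as.character(seqnames(windows)) == chr)
    i <- i[order(start(windows)[i])]
    sm[i] <- movingAverage(raw[i], span)
  }
  out <- granges(windows)
  mcols(out) <- DataFrame(meanMFLog2 = raw, smooth = sm)
  out
}

#' Dosage-compensation verdict from the three tests
#'
#' Codifies the chromosome-wide inference: `COMPLETE` when neither the
#' male-vs-female X contrast nor the X-vs-autosome male contrast is
#' significant *and* the median X log2(M/F) sits within `tol` of 0;
#' `ABSENT` when the median sits within `tol` of -1 (the uncompensated
#' X-hemizygous expectation) with both tests significant; `PARTIAL`
#' otherwise; `NOT_APPLICABLE` when the chromosome has no degenerate
#' stratum to compensate.
#'
#' @param pMFX,pXvsAMale,medianXRatio test outputs (see [testMFX()],
#'   [testXvsAutosomes()], [mfLog2PerGene()]).
#' @param hasDegenerateStratum logical.
#' @param alpha significance threshold of the rule.
#' @param tol log2 tolerance around the 0 / -1 regimes.
#' @return character verdict.
#' @export
dosageVerdict <- function(pMFX, pXvsAMale, medianXRatio,
                          hasDegenerateStratum = TRUE, alpha = 0.01,
                          tol = 0.25) {
  if (!hasDegenerateStratum) return("NOT_APPLICABLE")
  if (any(is.na(c(pMFX, pXvsAMale, medianXRatio)))) {
    stop("missing test inputs")
  }
  nonsig <- pMFX > alpha && pXvsAMale > alpha
  sig <- pMFX <= alpha && pXvsAMale <= alpha
  if (nonsig && abs(medianXRatio) <= tol) "COMPLETE"
  else if (sig && abs(medianXRatio + 1) <= tol) "ABSENT"
  else "PARTIAL"
}

#' Full dosage-compensation report for one chromosome
#'
#' Runs the expression filter, the three contrasts and the verdict rule
#' and returns a [DosageReport-class].
#'
#' @inheritParams filterExpressed
#' @param aseGenes gene ids with male ASE (may be empty).
#' @param hasDegenerateStratum does the candidate chromosome carry an
#'   old degenerate stratum (from [callStrata()] or truth)?
#' @param minExpr expression floor.
#' @param alpha,tol verdict rule parameters (see [dosageVerdict()]).
#' @return A [DosageReport-class].
#' @export
dosageReport <- function(se, aseGenes = character(0),
                         hasDegenerateStratum = TRUE, minExpr = 1,
                         alpha = 0.01, tol = 0.25) {
  se <- filterExpressed(se, minExpr)
  mat <- exprMatrix(se)
  mMeans <- rowMeans(mat[, sexCols(se, "M"), drop = FALSE])
  fMeans <- rowMeans(mat[, sexCols(se, "F"), drop = FALSE])
  nonrec <- isNonrecombining(se)
  autos <- geneClass(se) == "autosome"
  medians <- c(maleX = median(log2(mMeans[nonrec])),
               femaleX = median(log2(fMeans[nonrec])),
               maleA = median(log2(mMeans[autos])),
               femaleA = median(log2(fMeans[autos])))
  ratios <- mfLog2PerGene(se)
  cls <- geneClass(se)[match(names(ratios), rownames(se))]
  medX <- median(ratios[cls %in% c("young", "old")])
  mfx <- testMFX(se)
  xa <- testXvsAutosomes(se, "M")
  ar <- testAseGeneRatios(se, aseGenes)
  v <- dosageVerdict(mfx$pValue, xa$pValue, medX,
                     hasDegenerateStratum = hasDegenerateStratum,
                     alpha = alpha, tol = tol)
  new("DosageReport", medians = medians, medianXRatio = medX,
      pMFX = mfx$pValue, pXvsAMale = xa$pValue,
      pAseRatio = ar$pValue %||% NA_real_,
      verdict = v, alpha = alpha, tol = tol)
}
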