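#' Call usable heterozygous sites from allele counts
#'
#' Retains sites with total depth `>= minDepth` and minor-allele count
#' `>= minMinor` in the supplied evidence (DNA counts where available,
#' otherwise the RNA counts themselves). Sites with a zero minor allele
#' look hemizygous or monoallelically silenced and are rejected, which
#' is exactly how Y-deleted and Y-silenced genes drop out of the male
#' ASE analysis.
#'
#' @param counts data.frame of per-site allele counts: `gene`, `chrom`,
#'   `pos`, `sample`, `countA`, `countB` (from [simulateRna()] or
#'   [readAlleleCounts()]).
#' @param minDepth minimum `countA + countB`.
#' @param minMinor minimum `min(countA, countB)`.
#' @return list: `sites` (the retained rows), `genesWithHet` /
#'   `genesWithoutHet` (per sample, data.frame `sample`, `gene`).
#' @export
callHetSites <- function(counts, minDepth = 10L, minMinor = 2L) {
  assertColumns(counts, c("gene", "sample", "countA", "countB"), "counts")
  tot <- counts$countA + counts$countB
  minor <- pmin(counts$countA, counts$countB)
  keep <- tot >= minDepth & minor >= minMinor
  sites <- counts[keep, , drop = FALSE]
  all <- unique(counts[, c("sample", "gene")])
  het <- unique(sites[, c("sample", "gene")])
  hetKey <- paste(het$sample, het$gene)
  noHet <- all[!paste(all$sample, all$gene) %in% hetKey, , drop = FALSE]
  list(sites = sites, genesWithHet = het, genesWithoutHet = noHet)
}

#' Per-gene pooled major allele frequency
#'
#' Within each gene and sample, the two allele columns are summed over
#' the gene's retained sites (allele A is the same physical allele at
#' every site of a gene, e.g. the reference/X allele of the counting
#' step); the major allele is then the larger *pooled* total, so the
#' major allele frequency `pooled major / (major + minor)` lies in
#' `[0.5, 1]`. Taking the major after pooling keeps the frequency
#' unbiased-to-first-order under balanced expression (the alternative,
#' pooling per-site majors, inflates it by the folded per-site sampling
#' noise and destroys the calibration of the downstream binomial
#' test).
#'
#' @param sites retained heterozygous sites (see [callHetSites()]).
#' @return data.frame, one row per gene x sample: `gene`, `chrom`,
#'   `sample`, `nSites`, `totalA`, `totalB`, `totalMajor`,
#'   `totalMinor`, `majorAlleleFreq`. Gene/sample pairs with zero
#'   pooled counts are dropped with a message.
#' @export
geneMajorAlleleFreq <- function(sites) {
  assertColumns(sites, c("gene", "sample", "countA", "countB"), "sites")
  dt <- as.data.table(sites)
  byCols <- intersect(c("gene", "chrom", "sample"), names(dt))
  agg <- dt[, list(nSites = .N, totalA = sum(countA),
                   totalB = sum(countB)), by = byCols]
  zero <- agg$totalA + agg$totalB == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " gene/sample pair(s) with zero counts")
    agg <- agg[!zero]
  }
  agg[, `:=`(totalMajor = pmax(totalA, totalB),
             totalMinor = pmin(totalA, totalB))]
  agg[, majorAlleleFreq := totalMajor / (totalMajor + totalMinor)]
  setDF(agg)
}

#' Exact binomial ASE test per gene with BH correction
#'
#' Tests each gene's pooled major/minor counts against equal
#' transcription of the two alleles (two-sided exact binomial test,
#' null probability 0.5 unless overridden), then applies
#' Benjamini-Hochberg FDR correction across the tested genes within
#' each sample. A gene is flagged `isASE` when `q < alpha`.
#'
#' @param maf per-gene pooled counts from [geneMajorAlleleFreq()].
#' @param nullP null major-allele probability, in (0, 1).
#' @param alpha FDR threshold for the `isASE` flag.
#' @return `maf` with columns `pValue`, `qValue`, `isASE` appended.
#' @export
aseTest <- function(maf, nullP = 0.5, alpha = 0.05) {
  if (nullP <= 0 || nullP >= 1) stop("nullP must lie in (0, 1)")
  assertColumns(maf, c("sample", "totalMajor", "totalMinor"), "maf")
  n <- maf$totalMajor + maf$totalMinor
  p <- vapply(seq_len(nrow(maf)), function(i) {
    binom.test(maf$totalMajor[i], n[i], p = nullP)$p.value
  }, numeric(1L))
  maf$pValue <- p
  maf$qValue <- ave(p, maf$sample,
                    FUN = function(x) p.adjust(x, method = "BH"))
  maf$isASE <- maf$qValue < alpha
  maf
}

#' Per-site binomial ASE test with BH correction
#'
#' Site-level analogue of [aseTest()]: each heterozygous site's allele
#' counts are tested against 0.5 and BH-corrected within sample. This
#' is the unit in which sex-chromosome ASE enrichment is reported by
#' default.
#'
#' @param sites retained heterozygous sites (see [callHetSites()]).
#' @inheritParams aseTest
#' @return `sites` with `pValue`, `qValue`, `isASE` appended.
#' @export
aseSiteTest <- function(sites, nullP = 0.5, alpha = 0.05) {
  if (nullP <= 0 || nullP >= 1) stop("nullP must lie in (0, 1)")
  n <- sites$countA + sites$countB
  p <- vapply(seq_len(nrow(sites)), function(i) {
    binom.test(max(sites$countA[i], sites$countB[i]), n[i],
               p = nullP)$p.value
  }, numeric(1L))
  sites$pValue <- p
  sites$qValue <- ave(p, sites$sample,
                      FUN = function(x) p.adjust(x, method = "BH"))
  sites$isASE <- sites$qValue < alpha
  sites
}

#' Chi-square enrichment of ASE on the sex chromosome
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table
#' of `(ASE, non-ASE) x (sex-linked, autosomal)` tested units (sites by
#' default, genes if aggregated upstream).
#'
#' @param isASE logical vector over tested units.
#' @param isSexLinked logical vector of the same length.
#' @return list: `chisq`, `df`, `pValue`, `table` (the 2x2 table).
#' @export
aseEnrichment <- function(isASE, isSexLinked) {
  if (length(isASE) != length(isSexLinked)) {
    stop("isASE and isSexLinked must have equal length")
  }
  if (!any(isSexLinked) || all(isSexLinked)) {
    stop("both sex-linked and autosomal units are required")
  }
  tab <- table(factor(isSexLinked, levels = c(TRUE, FALSE)),
               factor(isASE, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a margin total is zero")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       pValue = ct$p.value, table = tab)
}

#' Compare major-allele-frequency distributions between gene groups
#'
#' Two-sided Wilcoxon rank-sum test of the per-gene major allele
#' frequencies of sex-linked vs autosomal genes, with group medians
#' (ties handled by midranks; the test is exact for small untied
#' samples and uses the normal approximation otherwise).
#'
#' @param sexLinked,autosomal numeric vectors of major allele
#'   frequencies (>= 2 values each).
#' @return list: `statistic` (rank-sum W), `pValue`,
#'   `medianSexLinked`, `medianAutosomal`.
#' @export
compareMafDistributions <- function(sexLinked, autosomal) {
  if (length(sexLinked) < 2L || length(autosomal) < 2L) {
    stop("each group needs at least 2 values")
  }
  wt <- suppressWarnings(wilcox.test(sexLinked, autosomal,
                                     alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied groups: no evidence of a shift
  list(statistic = unname(wt$statistic), pValue = p,
       medianSexLinked = median(sexLinked),
       medianAutosomal = median(autosomal))
}
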