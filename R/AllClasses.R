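#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

STRATUM_KINDS <- c("PAR", "young", "old")
WINDOW_LABELS <- c("UNDIFF_PAR", "YOUNG", "OLD_DEGENERATE")
DOSAGE_VERDICTS <- c("COMPLETE", "PARTIAL", "ABSENT", "NOT_APPLICABLE")

#' SimConfig: parameters of the synthetic XY-system simulator
#'
#' Holds every data-generating assumption of the simulator: genome
#' geometry, the stratum layout of the sex chromosome, sequencing depth
#' and its overdispersion, polymorphism rate, RNA-seq depth, and the
#' dosage-compensation switch. Construct with [simConfig()].
#'
#' @slot seed master RNG seed (integer).
#' @slot nAutosomes number of autosomes.
#' @slot chromLength autosome length in bp.
#' @slot sexChromLength sex-chromosome length in bp.
#' @slot strata data.frame with columns `start`, `end` (0-based
#'   half-open bp), `kind` (PAR/young/old), `xyDivergence` (fixed X-Y
#'   differences per bp), `yLoss` (fraction of Y sequence/genes lost,
#'   old only), `ySilencedFraction` (fraction of surviving Y copies
#'   transcriptionally silent, old only). Must tile
#'   `[0, sexChromLength)`.
#' @slot haploidDepth mean reads per base per haploid copy (lambda).
#' @slot depthDispersion negative-binomial size parameter of window
#'   depth counts.
#' @slot polymorphismRate heterozygous sites per bp per diploid
#'   individual (pi).
#' @slot nMales,nFemales sample sizes per sex.
#' @slot nGenesPerChrom genes placed per chromosome.
#' @slot rnaDepth mean RNA-seq reads per heterozygous site.
#' @slot meanHetSites mean heterozygous sites per gene.
#' @slot aseTheta X-allele read fraction for old-stratum genes whose Y
#'   copy is transcribed at a decayed level (0.5 = balanced, 1 =
#'   X-only).
#' @slot compensation logical; chromosome-wide dosage compensation.
#' @slot kmerErrorRate per-base sequencing error for read emission.
#' @slot windowSize analysis window size in bp.
#' @exportClass SimConfig
setClass("SimConfig", slots = c(
  seed = "integer",
  nAutosomes = "integer",
  chromLength = "numeric",
  sexChromLength = "numeric",
  strata = "data.frame",
  haploidDepth = "numeric",
  depthDispersion = "numeric",
  polymorphismRate = "numeric",
  nMales = "integer",
  nFemales = "integer",
  nGenesPerChrom = "integer",
  rnaDepth = "numeric",
  meanHetSites = "numeric",
  aseTheta = "numeric",
  compensation = "logical",
  kmerErrorRate = "numeric",
  windowSize = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  s <- object@strata
  need <- c("start", "end", "kind", "xyDivergence", "yLoss",
            "ySilencedFraction")
  if (!all(need %in% names(s))) {
    return(paste("strata must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(s) == 0L) msg <- c(msg, "strata must contain at least one row")
  if (nrow(s) > 0L) {
    if (is.unsorted(s$start)) msg <- c(msg, "strata must be sorted by start")
    if (any(s$end <= s$start)) msg <- c(msg, "stratum end must exceed start")
    if (s$start[1L] != 0) msg <- c(msg, "strata must start at 0")
    if (nrow(s) > 1L && any(s$start[-1L] != s$end[-nrow(s)])) {
      msg <- c(msg, "strata must be disjoint and tile the sex chromosome")
    }
    if (s$end[nrow(s)] != object@sexChromLength) {
      msg <- c(msg, "strata must end at sexChromLength")
    }
    if (!all(s$kind %in% STRATUM_KINDS)) {
      msg <- c(msg, "stratum kind must be PAR, young or old")
    }
    rates <- c(s$xyDivergence, s$yLoss, s$ySilencedFraction)
    if (any(rates < 0 | rates > 1)) {
      msg <- c(msg, "xyDivergence, yLoss, ySilencedFraction must lie in [0, 1]")
    }
    par <- s$kind == "PAR"
    if (any(s$xyDivergence[par] != 0) || any(s$yLoss[par] != 0)) {
      msg <- c(msg, "PAR strata must have xyDivergence = yLoss = 0")
    }
    if (any(s$yLoss[s$kind == "young"] != 0)) {
      msg <- c(msg, "young strata must have yLoss = 0")
    }
  }
  if (object@nMales < 1L || object@nFemales < 1L) {
    msg <- c(msg, "need at least one male and one female")
  }
  if (object@haploidDepth <= 0) msg <- c(msg, "haploidDepth must be positive")
  if (object@depthDispersion <= 0) {
    msg <- c(msg, "depthDispersion must be positive")
  }
  if (object@polymorphismRate < 0) {
    msg <- c(msg, "polymorphismRate must be non-negative")
  }
  if (object@rnaDepth <= 0) msg <- c(msg, "rnaDepth must be positive")
  if (object@aseTheta < 0.5 || object@aseTheta > 1) {
    msg <- c(msg, "aseTheta must lie in [0.5, 1]")
  }
  if (object@kmerErrorRate < 0 || object@kmerErrorRate > 1) {
    msg <- c(msg, "kmerErrorRate must lie in [0, 1]")
  }
  if (object@windowSize < 1) msg <- c(msg, "windowSize must be >= 1 bp")
  if (length(msg)) msg else TRUE
})

#' SimTruth: ground truth emitted by the simulator
#'
#' @slot windows GRanges tiling the sex chromosome, with metadata column
#'   `label` in `UNDIFF_PAR`/`YOUNG`/`OLD_DEGENERATE`.
#' @slot genes GRanges of simulated genes with columns `gene`, `class`
#'   (autosomal/PAR/young/old), `yDeleted`, `ySilenced`, `isASE`.
#' @slot xyDivergentSites integer positions (0-based) of fixed X-Y
#'   differences on the sex chromosome.
#' @slot yLostIntervals GRanges of deleted Y segments (sex-chromosome
#'   coordinates).
#' @slot compensation logical dosage-compensation flag.
#' @exportClass SimTruth
setClass("SimTruth", slots = c(
  windows = "GRanges",
  genes = "GRanges",
  xyDivergentSites = "integer",
  yLostIntervals = "GRanges",
  compensation = "logical"
))

#' WindowStats: per-window male/female coverage and SNP statistics
#'
#' A `GRanges` subclass whose metadata columns carry, per genomic
#' window: normalized per-sex mean depth (`maleCov`, `femaleCov`), the
#' log2 male:female coverage ratio (`log2MFCov`), per-sex heterozygous
#' SNP densities in sites/kb/individual (`maleSnpDen`, `femaleSnpDen`)
#' and their male-minus-female difference (`mfSnpDiff`).
#'
#' @exportClass WindowStats
setClass("WindowStats", contains = "GRanges")

setValidity("WindowStats", function(object) {
  need <- c("maleCov", "femaleCov", "log2MFCov", "maleSnpDen",
            "femaleSnpDen", "mfSnpDiff")
  miss <- setdiff(need, names(mcols(object)))
  if (length(miss)) {
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  }
  dens <- c(mcols(object)$maleSnpDen, mcols(object)$femaleSnpDen)
  if (any(dens < 0, na.rm = TRUE)) return("SNP densities must be >= 0")
  TRUE
})

#' AutosomalNull: bootstrap null interval for a window statistic
#'
#' Percentile bootstrap interval of the distribution of a per-window
#' statistic over autosomal windows; windows of the focal chromosome
#' falling outside it deviate significantly from the autosomal
#' background.
#'
#' @slot statistic name of the statistic (`log2MFCov` or `mfSnpDiff`).
#' @slot lower,upper interval bounds.
#' @slot level confidence level in (0, 1).
#' @slot nBoot bootstrap replicates.
#' @slot center autosomal median of the statistic.
#' @exportClass AutosomalNull
setClass("AutosomalNull", slots = c(
  statistic = "character",
  lower = "numeric",
  upper = "numeric",
  level = "numeric",
  nBoot = "integer",
  center = "numeric"
))

setValidity("AutosomalNull", function(object) {
  msg <- character(0)
  if (object@level <= 0 || object@level >= 1) {
    msg <- c(msg, "level must lie in (0, 1)")
  }
  if (object@lower > object@center || object@center > object@upper) {
    msg <- c(msg, "must satisfy lower <= center <= upper")
  }
  if (length(msg)) msg else TRUE
})

#' KmerSet: canonical k-mers of one sample
#'
#' @slot sample sample identifier.
#' @slot sex `"M"` or `"F"`.
#' @slot k k-mer length (odd).
#' @slot minCount minimum multiplicity retained.
#' @slot kmers sorted character vector of canonical k-mers.
#' @exportClass KmerSet
setClass("KmerSet", slots = c(
  sample = "character",
  sex = "character",
  k = "integer",
  minCount = "integer",
  kmers = "character"
))

setValidity("KmerSet", function(object) {
  msg <- character(0)
  if (object@k %% 2L == 0L) msg <- c(msg, "k must be odd")
  if (length(object@kmers) &&
      !all(nchar(object@kmers) == object@k)) {
    msg <- c(msg, "all k-mers must have length k")
  }
  if (!object@sex %in% c("M", "F")) msg <- c(msg, "sex must be 'M' or 'F'")
  if (length(msg)) msg else TRUE
})

#' SexSpecificResult: male-unique (Y-mer) and female-unique k-mers
#'
#' Y-mers are k-mers present in every male and absent from every
#' female of a species; female-unique k-mers are the converse.
#'
#' @slot species species identifier.
#' @slot k k-mer length.
#' @slot yMers character vector of Y-mers.
#' @slot femaleUnique character vector of female-unique k-mers.
#' @exportClass SexSpecificResult
setClass("SexSpecificResult", slots = c(
  species = "character",
  k = "integer",
  yMers = "character",
  femaleUnique = "character"
))

setValidity("SexSpecificResult", function(object) {
  if (length(intersect(object@yMers, object@femaleUnique))) {
    return("yMers and femaleUnique must be disjoint")
  }
  TRUE
})

#' DosageReport: chromosome-wide dosage-compensation assessment
#'
#' @slot medians named numeric: median per-gene mean expression for
#'   male X, female X, male autosomes, female autosomes.
#' @slot medianXRatio median log2 male:female ratio over nonrecombining
#'   X genes.
#' @slot pMFX Wilcoxon signed-rank p, male vs female X expression.
#' @slot pXvsAMale Wilcoxon rank-sum p, X vs autosomes in males.
#' @slot pAseRatio Wilcoxon rank-sum p, M:F log2 ratios of X ASE genes
#'   vs autosomal genes (NA if no ASE genes supplied).
#' @slot verdict one of COMPLETE, PARTIAL, ABSENT, NOT_APPLICABLE.
#' @slot alpha significance threshold used by the verdict rule.
#' @slot tol log2 tolerance around 0 (and -1) used by the verdict rule.
#' @exportClass DosageReport
setClass("DosageReport", slots = c(
  medians = "numeric",
  medianXRatio = "numeric",
  pMFX = "numeric",
  pXvsAMale = "numeric",
  pAseRatio = "numeric",
  verdict = "character",
  alpha = "numeric",
  tol = "numeric"
))

setValidity("DosageReport", function(object) {
  if (!object@verdict %in% DOSAGE_VERDICTS) {
    return(paste("verdict must be one of:",
                 paste(DOSAGE_VERDICTS, collapse = ", ")))
  }
  TRUE
})
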