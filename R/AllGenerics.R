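#' @importFrom methods show
NULL

#' Accessors for simulator and scan objects
#'
#' Small accessor generics: `kmers()` returns the canonical k-mer set
#' of a [KmerSet-class]; `yMers()` and `femaleUnique()` the two
#' sex-specific sets of a [SexSpecificResult-class]; `verdict()` the
#' categorical outcome of a [DosageReport-class]; `truthWindows()` and
#' `truthGenes()` the labeled windows and genes of a
#' [SimTruth-class].
#'
#' @param x the object.
#' @return The slot contents (character vector, GRanges, ...).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("kmers", function(x) standardGeneric("kmers"))
#' @rdname accessors
#' @export
setMethod("kmers", "KmerSet", function(x) x@kmers)

#' @rdname accessors
#' @export
setGeneric("yMers", function(x) standardGeneric("yMers"))
#' @rdname accessors
#' @export
setMethod("yMers", "SexSpecificResult", function(x) x@yMers)

#' @rdname accessors
#' @export
setGeneric("femaleUnique", function(x) standardGeneric("femaleUnique"))
#' @rdname accessors
#' @export
setMethod("femaleUnique", "SexSpecificResult", function(x) x@femaleUnique)

#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @rdname accessors
#' @export
setMethod("verdict", "DosageReport", function(x) x@verdict)

#' @rdname accessors
#' @export
setGeneric("truthWindows", function(x) standardGeneric("truthWindows"))
#' @rdname accessors
#' @export
setMethod("truthWindows", "SimTruth", function(x) x@windows)

#' @rdname accessors
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))
#' @rdname accessors
#' @export
setMethod("truthGenes", "SimTruth", function(x) x@genes)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nAutosomes, "autosome(s) of",
      format(object@chromLength, big.mark = ","), "bp +",
      "sex chromosome of",
      format(object@sexChromLength, big.mark = ","), "bp\n")
  cat("  strata:", paste(sprintf("%s[%g,%g)", object@strata$kind,
                                 object@strata$start, object@strata$end),
                         collapse = " "), "\n")
  cat(sprintf("  lambda=%g, dispersion=%g, pi=%g, %dM/%dF, compensation=%s\n",
              object@haploidDepth, object@depthDispersion,
              object@polymorphismRate, object@nMales, object@nFemales,
              object@compensation))
})

setMethod("show", "SimTruth", function(object) {
  tab <- table(object@windows$label)
  cat("SimTruth:", length(object@windows), "sex-chromosome windows (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat(" ", length(object@genes), "genes;",
      sum(object@genes$yDeleted), "Y-deleted,",
      sum(object@genes$ySilenced), "Y-silenced;",
      "compensation =", object@compensation, "\n")
})

setMethod("show", "AutosomalNull", function(object) {
  cat(sprintf("AutosomalNull '%s': %.0f%% interval [%.4g, %.4g], center %.4g (%d bootstraps)\n",
              object@statistic, 100 * object@level, object@lower,
              object@upper, object@center, object@nBoot))
})

setMethod("show", "KmerSet", function(object) {
  cat(sprintf("KmerSet %s (%s): %d canonical %d-mers (minCount=%d)\n",
              object@sample, object@sex, length(object@kmers), object@k,
              object@minCount))
})

setMethod("show", "SexSpecificResult", function(object) {
  cat(sprintf("SexSpecificResult %s: %d Y-mers, %d female-unique (k=%d)\n",
              object@species, length(object@yMers),
              length(object@femaleUnique), object@k))
})

setMethod("show", "DosageReport", function(object) {
  cat("DosageReport:", object@verdict, "\n")
  cat(sprintf("  median log2(M/F) on X: %.3f\n", object@medianXRatio))
  cat(sprintf("  p(M vs F on X, signed rank)    = %.3g\n", object@pMFX))
  cat(sprintf("  p(X vs A in males, rank sum)   = %.3g\n", object@pXvsAMale))
  cat(sprintf("  p(ASE-X vs A M:F ratios)       = %.3g\n", object@pAseRatio))
})
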