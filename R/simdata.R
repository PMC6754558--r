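#' @importFrom Biostrings DNAStringSet reverseComplement
#' @importFrom data.table data.table rbindlist setDF setkey :=
NULL

#' Specify one stratum of the simulated sex chromosome
#'
#' A stratum is a contiguous block of the sex chromosome with a shared
#' recombination history: `PAR` (still recombining, X and Y identical),
#' `young` (recently non-recombining; Y intact but diverged from X at
#' density `xyDivergence`), or `old` (anciently non-recombining; a
#' fraction `yLoss` of the Y copy deleted, a fraction
#' `ySilencedFraction` of the surviving Y gene copies transcriptionally
#' silent).
#'
#' @param start,end 0-based half-open coordinates in bp.
#' @param kind `"PAR"`, `"young"`, or `"old"`.
#' @param xyDivergence fixed X-Y differences per bp (young/old).
#' @param yLoss fraction of Y sequence/genes lost (old only).
#' @param ySilencedFraction fraction of surviving Y gene copies silent
#'   (old only).
#' @return One-row data.frame suitable for the `strata` argument of
#'   [simConfig()].
#' @examples
#' stratumSpec(0, 1e6, "young", xyDivergence = 0.005)
#' @export
stratumSpec <- function(start, end, kind = c("PAR", "young", "old"),
                        xyDivergence = 0, yLoss = 0,
                        ySilencedFraction = 0) {
  kind <- match.arg(kind)
  data.frame(start = start, end = end, kind = kind,
             xyDivergence = xyDivergence, yLoss = yLoss,
             ySilencedFraction = ySilencedFraction,
             stringsAsFactors = FALSE)
}

defaultStrata <- function(sexChromLength, xyDivergence = 0.005,
                          yLoss = 0.9, ySilencedFraction = 0.5) {
  b <- round(c(0, 1 / 3, 2 / 3, 1) * sexChromLength)
  rbind(
    stratumSpec(b[1L], b[2L], "PAR"),
    stratumSpec(b[2L], b[3L], "young", xyDivergence = xyDivergence),
    stratumSpec(b[3L], b[4L], "old", xyDivergence = xyDivergence,
                yLoss = yLoss, ySilencedFraction = ySilencedFraction)
  )
}

#' Build a simulator configuration
#'
#' Defaults describe the study conditions exercised throughout the
#' package: three autosomes of 20 Mb, a 50 Mb sex chromosome split into
#' equal PAR / young / old thirds (X-Y divergence 0.005/bp in the
#' non-recombining strata, 90% Y loss and 50% residual silencing in the
#' old stratum), haploid depth 20x with negative-binomial dispersion 10,
#' heterozygosity 0.001/bp, three individuals per sex, 200 genes per
#' chromosome with on average 5 heterozygous sites at RNA depth 40, and
#' chromosome-wide dosage compensation switched on.
#'
#' @param seed master RNG seed.
#' @param nAutosomes,chromLength,sexChromLength genome geometry.
#' @param strata data.frame of [stratumSpec()] rows tiling
#'   `[0, sexChromLength)`.
#' @param haploidDepth mean reads/base per haploid copy (lambda).
#' @param depthDispersion negative-binomial size of window depths.
#' @param polymorphismRate heterozygous sites per bp per individual.
#' @param nMales,nFemales sample sizes.
#' @param nGenesPerChrom genes per chromosome.
#' @param rnaDepth mean RNA reads per heterozygous site.
#' @param meanHetSites mean heterozygous sites per gene.
#' @param aseTheta X-allele read fraction in males for old-stratum
#'   genes with a transcriptionally decayed (but active) Y copy; these
#'   are the genes expected to show significant allele-specific
#'   expression. 0.5 means no decay.
#' @param compensation chromosome-wide dosage compensation on/off.
#' @param kmerErrorRate per-base error rate for read emission.
#' @param windowSize analysis window size in bp.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1, nAutosomes = 1, chromLength = 1e6,
#'                  sexChromLength = 1.5e6)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nAutosomes = 3L,
                      chromLength = 2e7,
                      sexChromLength = 5e7,
                      strata = defaultStrata(sexChromLength),
                      haploidDepth = 20,
                      depthDispersion = 10,
                      polymorphismRate = 0.001,
                      nMales = 3L,
                      nFemales = 3L,
                      nGenesPerChrom = 200L,
                      rnaDepth = 40,
                      meanHetSites = 5,
                      aseTheta = 0.9,
                      compensation = TRUE,
                      kmerErrorRate = 0,
                      windowSize = 5e4) {
  new("SimConfig",
      seed = as.integer(seed), nAutosomes = as.integer(nAutosomes),
      chromLength = as.numeric(chromLength),
      sexChromLength = as.numeric(sexChromLength),
      strata = as.data.frame(strata),
      haploidDepth = haploidDepth, depthDispersion = depthDispersion,
      polymorphismRate = polymorphismRate,
      nMales = as.integer(nMales), nFemales = as.integer(nFemales),
      nGenesPerChrom = as.integer(nGenesPerChrom),
      rnaDepth = rnaDepth, meanHetSites = meanHetSites,
      aseTheta = aseTheta, compensation = compensation,
      kmerErrorRate = kmerErrorRate, windowSize = windowSize)
}

sexChromName <- function(config) "chrXY"

chromLengths <- function(config) {
  n <- config@nAutosomes
  auto <- setNames(rep(config@chromLength, n),
                   if (n > 0L) paste0("chr", seq_len(n)) else character(0))
  c(auto, setNames(config@sexChromLength, sexChromName(config)))
}

#' Sample sheet of the simulated individuals
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns `sample`, `sex` (`"M"`/`"F"`).
#' @export
sampleSexes <- function(config) {
  data.frame(
    sample = c(paste0("M", seq_len(config@nMales)),
               paste0("F", seq_len(config@nFemales))),
    sex = c(rep("M", config@nMales), rep("F", config@nFemales)),
    stringsAsFactors = FALSE)
}

#' Tile chromosomes into non-overlapping analysis windows
#'
#' @param lengths named numeric vector of chromosome lengths, or a
#'   [SimConfig-class].
#' @param windowSize window size in bp (last window of a chromosome may
#'   be shorter).
#' @return GRanges of windows, 0-based half-open convention externally
#'   (GRanges stores 1-based starts internally).
#' @examples
#' tileWindows(c(chr1 = 250000), 1e5)
#' @export
tileWindows <- function(lengths, windowSize = 5e4) {
  if (is(lengths, "SimConfig")) {
    windowSize <- lengths@windowSize
    lengths <- chromLengths(lengths)
  }
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("'lengths' must be a named vector of chromosome lengths")
  }
  grl <- lapply(names(lengths), function(chr) {
    len <- lengths[[chr]]
    starts <- seq(0, len - 1, by = windowSize)
    ends <- pmin(starts + windowSize, len)
    GRanges(chr, IRanges(start = starts + 1, end = ends))
  })
  gr <- suppressWarnings(do.call(c, grl))
  seqlengths(gr) <- lengths[seqlevels(gr)]
  gr
}

kindToLabel <- function(kind) {
  c(PAR = "UNDIFF_PAR", young = "YOUNG", old = "OLD_DEGENERATE")[kind]
}

strataGRanges <- function(config) {
  s <- config@strata
  GRanges(sexChromName(config),
          IRanges(start = s$start + 1, end = s$end),
          kind = s$kind, xyDivergence = s$xyDivergence,
          yLoss = s$yLoss, ySilencedFraction = s$ySilencedFraction)
}

#' Generate the structural ground truth of a simulated XY system
#'
#' Draws everything downstream simulators condition on: window labels
#' tiling the sex chromosome, the deleted Y segments of old strata
#' (dispersed 1-kb tiles, an exact `yLoss` fraction per stratum), the
#' fixed X-Y divergent sites of non-recombining strata, and gene
#' placements with per-gene Y-deletion / Y-silencing status.
#'
#' @param config a [SimConfig-class].
#' @param seed RNG seed (defaults to a seed derived from
#'   `config@seed`).
#' @return A [SimTruth-class].
#' @export
simTruth <- function(config, seed = subSeed(config@seed, 1L)) {
  validObject(config)
  withSeed(seed, {
    s <- config@strata
    xyName <- sexChromName(config)

    windows <- tileWindows(setNames(config@sexChromLength, xyName),
                           config@windowSize)
    sg <- strataGRanges(config)
    ov <- findOverlaps(windows, sg)
    w <- width(pintersect(windows[queryHits(ov)], sg[subjectHits(ov)]))
    best <- tapply(seq_along(queryHits(ov)), queryHits(ov),
                   function(i) subjectHits(ov)[i][which.max(w[i])])
    windows$label <- unname(kindToLabel(sg$kind[unlist(best)]))

    # dispersed Y loss: an exact yLoss fraction of 1-kb tiles per stratum
    tileSize <- min(1000, config@windowSize)
    lost <- GRanges()
    for (i in which(s$kind == "old" & s$yLoss > 0)) {
      starts <- seq(s$start[i], s$end[i] - 1, by = tileSize)
      ends <- pmin(starts + tileSize, s$end[i])
      nLost <- round(s$yLoss[i] * length(starts))
      pick <- sort(sample.int(length(starts), nLost))
      lost <- c(lost, GRanges(xyName, IRanges(starts[pick] + 1, ends[pick])))
    }
    lost <- reduce(lost)

    divergent <- integer(0)
    for (i in which(s$kind != "PAR" & s$xyDivergence > 0)) {
      len <- s$end[i] - s$start[i]
      n <- rbinom(1L, len, s$xyDivergence[i])
      divergent <- c(divergent,
                     s$start[i] + sort(sample.int(len, n)) - 1L)
    }

    # gene placement: uniform, fixed count per chromosome
    lens <- chromLengths(config)
    geneWidth <- 1000
    genes <- GRanges()
    for (chr in names(lens)) {
      n <- config@nGenesPerChrom
      if (n == 0L) next
      starts <- sort(round(runif(n, 0, lens[[chr]] - geneWidth)))
      g <- GRanges(chr, IRanges(starts + 1, width = geneWidth))
      g$gene <- sprintf("%s_g%04d", chr, seq_len(n))
      genes <- suppressWarnings(c(genes, g))
    }
    isSex <- as.character(seqnames(genes)) == xyName
    cls <- rep("autosome", length(genes))
    if (any(isSex)) {
      idx <- findOverlaps(resize(genes[isSex], 1L), sg, select = "first")
      cls[isSex] <- sg$kind[idx]
    }
    genes$class <- cls
    old <- which(genes$class == "old")
    yl <- sg$yLoss[match("old", sg$kind)] %||% 0
    ys <- sg$ySilencedFraction[match("old", sg$kind)] %||% 0
    if (length(old)) {
      sidx <- findOverlaps(resize(genes[old], 1L), sg, select = "first")
      yl <- sg$yLoss[sidx]
      ys <- sg$ySilencedFraction[sidx]
    }
    genes$yDeleted <- logical(length(genes))
    genes$ySilenced <- logical(length(genes))
    if (length(old)) {
      genes$yDeleted[old] <- runif(length(old)) < yl
      genes$ySilenced[old] <- !genes$yDeleted[old] &
        runif(length(old)) < ys
    }
    # genes expected to show significant male ASE: surviving old-stratum
    # genes whose Y copy is transcribed at a decayed level (theta > 0.5)
    genes$isASE <- genes$class == "old" & !genes$yDeleted &
      !genes$ySilenced & config@aseTheta > 0.5

    new("SimTruth", windows = windows, genes = genes,
        xyDivergentSites = as.integer(divergent), yLostIntervals = lost,
        compensation = config@compensation)
  })
}

randomDNA <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

substituteAt <- function(seq, pos0) {
  # pos0: 0-based positions; substitute with a different random base
  if (!length(pos0)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  old <- ch[pos0 + 1L]
  alt <- vapply(old, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1L), USE.NAMES = FALSE)
  ch[pos0 + 1L] <- alt
  paste(ch, collapse = "")
}

deleteIntervals <- function(seq, lost) {
  # lost: GRanges in sequence coordinates (1-based); keep the complement
  if (!length(lost)) return(seq)
  lost <- reduce(lost)
  keepStart <- c(1L, end(lost) + 1L)
  keepEnd <- c(start(lost) - 1L, nchar(seq))
  ok <- keepEnd >= keepStart
  paste(substring(seq, keepStart[ok], keepEnd[ok]), collapse = "")
}

#' Simulate haplotype sequences of the XY system
#'
#' Emits one haplotype pair per autosome (the second haplotype carries
#' background heterozygosity at rate pi), one X and one Y. The Y equals
#' the X except for substitutions at the X-Y divergent sites of
#' non-recombining strata and deletion of the lost Y segments of old
#' strata.
#'
#' @param config a [SimConfig-class]. Sequence simulation is intended
#'   for small (kb-Mb) configurations; window-level simulators do not
#'   need it.
#' @param truth optional [SimTruth-class] (generated if missing).
#' @param seed RNG seed.
#' @return list with `sequences` (named [Biostrings::DNAStringSet]:
#'   `<chrom>_hap1/2`, `chrX`, `chrY`) and `truth`.
#' @export
simulateGenomes <- function(config, truth = NULL,
                            seed = subSeed(config@seed, 5L)) {
  validObject(config)
  if (is.null(truth)) truth <- simTruth(config)
  withSeed(seed, {
    seqs <- character(0)
    for (chr in paste0("chr", seq_len(config@nAutosomes))) {
      hap1 <- randomDNA(config@chromLength)
      nHet <- rpois(1L, config@chromLength * config@polymorphismRate)
      hetPos <- sort(sample.int(config@chromLength, nHet)) - 1L
      hap2 <- substituteAt(hap1, hetPos)
      seqs[paste0(chr, "_hap1")] <- hap1
      seqs[paste0(chr, "_hap2")] <- hap2
    }
    x <- randomDNA(config@sexChromLength)
    y <- substituteAt(x, truth@xyDivergentSites)
    y <- deleteIntervals(y, truth@yLostIntervals)
    seqs[["chrX"]] <- x
    seqs[["chrY"]] <- y
    list(sequences = DNAStringSet(seqs), truth = truth)
  })
}

#' Simulate per-window DNA-seq depth for all samples
#'
#' Window depths are negative-binomial with size `depthDispersion`.
#' Females have mean `2 * lambda` everywhere. Males have mean
#' `lambda * (1 + m)` where `m = 1` on autosomes, the PAR and young
#' strata (Y reads co-map to the homologous X) and `m = 1 - yLoss` over
#' old strata, so a fully deleted Y yields the 2-fold male coverage
#' reduction expected under X-hemizygosity.
#'
#' @param config a [SimConfig-class].
#' @param truth a [SimTruth-class].
#' @param windows optional GRanges of windows (defaults to tiling all
#'   chromosomes at `config@windowSize`).
#' @param seed RNG seed.
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `sample`, `depth`.
#' @export
simulateCoverage <- function(config, truth, windows = NULL,
                             seed = subSeed(config@seed, 2L)) {
  validObject(config)
  if (config@haploidDepth <= 0) stop("haploidDepth must be positive")
  if (is.null(windows)) windows <- tileWindows(config)
  withSeed(seed, {
    xyName <- sexChromName(config)
    m <- rep(1, length(windows))
    onSex <- as.character(seqnames(windows)) == xyName
    if (length(truth@yLostIntervals) && any(onSex)) {
      sel <- which(onSex)
      ov <- findOverlaps(windows[sel], truth@yLostIntervals)
      w <- width(pintersect(windows[sel][queryHits(ov)],
                            truth@yLostIntervals[subjectHits(ov)]))
      lostBp <- rep(0, length(sel))
      agg <- tapply(w, queryHits(ov), sum)
      lostBp[as.integer(names(agg))] <- agg
      m[sel] <- 1 - lostBp / width(windows[sel])
    }
    sexes <- sampleSexes(config)
    lam <- config@haploidDepth
    out <- lapply(seq_len(nrow(sexes)), function(i) {
      mu <- if (sexes$sex[i] == "F") rep(2 * lam, length(windows))
            else lam * (1 + m)
      data.table(
        chrom = as.character(seqnames(windows)),
        start = start(windows) - 1L, end = end(windows),
        sample = sexes$sample[i],
        depth = rnbinom(length(windows), size = config@depthDispersion,
                        mu = mu))
    })
    setDF(rbindlist(out))
  })
}

uniformInComplement <- function(n, regionStart, regionEnd, lost) {
  # n uniform 0-based positions in [regionStart, regionEnd) \ lost
  if (n == 0L) return(integer(0))
  if (!length(lost)) {
    return(regionStart + sort(sample.int(regionEnd - regionStart, n,
                                         replace = TRUE)) - 1L)
  }
  keep <- setdiff(IRanges(regionStart + 1, regionEnd), ranges(lost))
  if (!length(keep) || sum(width(keep)) == 0L) return(integer(0))
  seg <- sample.int(length(keep), n, replace = TRUE,
                    prob = width(keep) / sum(width(keep)))
  off <- floor(runif(n) * width(keep)[seg])
  sort(as.integer(start(keep)[seg] - 1L + off))
}

#' Simulate heterozygous SNP sites for all samples
#'
#' Every individual carries background heterozygosity at rate pi. Males
#' are additionally heterozygous at the shared X-Y divergent sites of
#' young (and surviving old) strata, because Y reads carrying Y-specific
#' alleles map onto the homologous X. Over deleted Y segments of old
#' strata males are hemizygous and carry no heterozygous sites.
#'
#' @inheritParams simulateCoverage
#' @return data.frame of heterozygous sites: `chrom`, `pos` (0-based),
#'   `sample`, `ref`, `alt`.
#' @export
simulateSnps <- function(config, truth, seed = subSeed(config@seed, 3L)) {
  validObject(config)
  withSeed(seed, {
    xyName <- sexChromName(config)
    lens <- chromLengths(config)
    sexes <- sampleSexes(config)
    pi0 <- config@polymorphismRate
    lost <- truth@yLostIntervals
    out <- list()
    for (i in seq_len(nrow(sexes))) {
      smp <- sexes$sample[i]
      male <- sexes$sex[i] == "M"
      for (chr in names(lens)) {
        len <- lens[[chr]]
        if (male && chr == xyName) {
          effLen <- len - sum(width(lost))
          n <- rpois(1L, effLen * pi0)
          pos <- uniformInComplement(n, 0L, len, lost)
          div <- truth@xyDivergentSites
          if (length(lost) && length(div)) {
            inLost <- overlapsAny(GRanges(xyName, IRanges(div + 1, width = 1)),
                                  lost)
            div <- div[!inLost]
          }
          pos <- sort(unique(c(pos, div)))
        } else {
          n <- rpois(1L, len * pi0)
          pos <- sort(sample.int(len, n, replace = TRUE)) - 1L
        }
        if (length(pos)) {
          out[[length(out) + 1L]] <- data.table(
            chrom = chr, pos = as.integer(pos), sample = smp)
        }
      }
    }
    sites <- rbindlist(out)
    if (nrow(sites)) {
      key <- paste(sites$chrom, sites$pos)
      uk <- !duplicated(key)
      bases <- c("A", "C", "G", "T")
      refs <- sample(bases, sum(uk), replace = TRUE)
      alts <- vapply(refs, function(b) sample(setdiff(bases, b), 1L),
                     character(1L), USE.NAMES = FALSE)
      sites$ref <- refs[match(key, key[uk])]
      sites$alt <- alts[match(key, key[uk])]
      setkey(sites, chrom, pos)
    } else {
      sites$ref <- character(0)
      sites$alt <- character(0)
    }
    setDF(sites)
  })
}

#' Simulate RNA-seq allele counts and an expression matrix
#'
#' At each heterozygous site of a gene, allele counts are
#' `Binomial(n, theta)` with read depth `n ~ Poisson(rnaDepth)`:
#' `theta = 0.5` when both alleles (X and Y) are transcribed equally,
#' `theta = aseTheta` in males for old-stratum genes with a decayed but
#' active Y copy (the allele-specific-expression signal), and
#' `theta = 1` (X allele only) in males for genes whose Y copy is
#' deleted or silenced. The expression matrix is log-normal around a
#' per-gene baseline; without dosage compensation, male expression of
#' degenerate sex-linked genes is halved relative to females, with
#' compensation it matches the female level.
#'
#' @inheritParams simulateCoverage
#' @return list with `alleleCounts` (data.frame: `gene`, `chrom`,
#'   `pos`, `sample`, `countA` (X allele), `countB`) and `expression`
#'   (a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `expr`, gene metadata in `rowData`, sex in `colData`).
#' @export
simulateRna <- function(config, truth, seed = subSeed(config@seed, 4L)) {
  validObject(config)
  if (config@rnaDepth <= 0) stop("rnaDepth must be positive")
  withSeed(seed, {
    genes <- truth@genes
    sexes <- sampleSexes(config)
    nG <- length(genes)
    nSites <- 1L + rpois(nG, max(config@meanHetSites - 1, 0))
    siteGene <- rep(seq_len(nG), nSites)
    siteOff <- unlist(lapply(nSites, seq_len))
    sitePos <- start(genes)[siteGene] - 1L + siteOff * 10L

    degenerate <- genes$yDeleted | genes$ySilenced
    grid <- data.table(
      geneIdx = rep(siteGene, times = nrow(sexes)),
      pos = rep(sitePos, times = nrow(sexes)),
      sample = rep(sexes$sample, each = length(siteGene)),
      sex = rep(sexes$sex, each = length(siteGene)))
    theta <- rep(0.5, nrow(grid))
    male <- grid$sex == "M"
    theta[male & degenerate[grid$geneIdx]] <- 1           # X-only
    theta[male & genes$isASE[grid$geneIdx]] <- config@aseTheta
    grid[, `:=`(
      gene = genes$gene[grid$geneIdx],
      chrom = as.character(seqnames(genes))[grid$geneIdx],
      theta = theta)]
    depth <- rpois(nrow(grid), config@rnaDepth)
    countA <- rbinom(nrow(grid), depth, grid$theta)
    grid[, `:=`(countA = countA, countB = depth - countA)]
    alleleCounts <- setDF(grid[, c("gene", "chrom", "pos", "sample",
                                   "countA", "countB")])

    base <- rnorm(nG, mean = 5, sd = 1.5)
    mat <- matrix(0, nrow = nG, ncol = nrow(sexes),
                  dimnames = list(genes$gene, sexes$sample))
    for (j in seq_len(nrow(sexes))) {
      fac <- rep(1, nG)
      if (sexes$sex[j] == "M" && !config@compensation) {
        fac[degenerate] <- 0.5
      }
      mat[, j] <- fac * 2^(base + rnorm(nG, sd = 0.4))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = mat),
      rowData = S4Vectors::DataFrame(
        gene = genes$gene, chrom = as.character(seqnames(genes)),
        start = start(genes) - 1L, end = end(genes),
        class = genes$class, yDeleted = genes$yDeleted,
        ySilenced = genes$ySilenced, isASE = genes$isASE),
      colData = S4Vectors::DataFrame(sample = sexes$sample,
                                     sex = sexes$sex,
                                     row.names = sexes$sample))
    list(alleleCounts = alleleCounts, expression = se)
  })
}

#' Emit error-injected sequencing reads at uniform coverage
#'
#' Read starts are uniform over each sequence, except that one read is
#' anchored at each terminus so error-free read sets contain every
#' genomic k-mer (k up to the read length).
#'
#' @param sequences named character vector or
#'   [Biostrings::DNAStringSet].
#' @param depth target mean coverage (> 0).
#' @param errorRate per-base substitution error probability.
#' @param readLength read length in bp.
#' @param seed RNG seed; reads are deterministic given the seed.
#' @return [Biostrings::DNAStringSet] of reads (random strand).
#' @export
emitReads <- function(sequences, depth, errorRate = 0, readLength = 100L,
                      seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  if (errorRate < 0 || errorRate > 1) stop("errorRate must lie in [0, 1]")
  seqs <- as.character(sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    allReads <- character(0)
    for (nm in names(seqs)) {
      s <- seqs[[nm]]
      len <- nchar(s)
      rl <- min(readLength, len)
      nReads <- max(2L, round(depth * len / rl))
      # one read is anchored at each terminus: purely uniform starts
      # systematically undersample the first and last read-length of
      # sequence, which would drop terminal k-mers from read sets
      starts <- c(1L, len - rl + 1L,
                  sample.int(len - rl + 1L, nReads - 2L, replace = TRUE))
      reads <- substring(s, starts, starts + rl - 1L)
      if (errorRate > 0) {
        nErr <- rbinom(nReads, rl, errorRate)
        hit <- which(nErr > 0L)
        for (i in hit) {
          p <- sample.int(rl, nErr[i])
          ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
          ch[p] <- vapply(ch[p], function(b) sample(setdiff(bases, b), 1L),
                          character(1L), USE.NAMES = FALSE)
          reads[i] <- paste(ch, collapse = "")
        }
      }
      flip <- runif(nReads) < 0.5
      if (any(flip)) {
        reads[flip] <- as.character(reverseComplement(DNAStringSet(reads[flip])))
      }
      names(reads) <- sprintf("%s_read%06d", nm, seq_len(nReads))
      allReads <- c(allReads, reads)
    }
    DNAStringSet(allReads)
  })
}

#' Preset configurations emulating the three observed XY states
#'
#' Desk-scale layouts of the three qualitative sex-chromosome states
#' observed in poeciliids:
#' \describe{
#'   \item{reticulata}{largely homomorphic: recombining PAR over most
#'     of the chromosome plus a young non-recombining stratum, no Y
#'     degeneration.}
#'   \item{wingei}{non-recombining along the whole chromosome: a large
#'     young stratum plus a small old degenerate stratum at the distal
#'     end.}
#'   \item{picta}{profoundly degenerate: an old stratum with
#'     large-scale Y loss spanning nearly the whole chromosome, a
#'     small residual PAR at the far end; dosage compensation present
#'     by default.}
#' }
#'
#' @param species `"reticulata"`, `"wingei"`, or `"picta"`.
#' @param sexChromLength sex-chromosome length in bp (layouts scale
#'   proportionally).
#' @param compensation dosage compensation flag (defaults: TRUE for
#'   `picta`, irrelevant-but-TRUE otherwise).
#' @param ... further arguments to [simConfig()].
#' @return A [SimConfig-class].
#' @examples
#' presetConfig("picta", sexChromLength = 6e6, nAutosomes = 1,
#'              chromLength = 3e6)
#' @export
presetConfig <- function(species = c("picta", "wingei", "reticulata"),
                         sexChromLength = 2e7, compensation = TRUE,
                         ...) {
  species <- match.arg(species)
  L <- sexChromLength
  strata <- switch(species,
    reticulata = rbind(
      stratumSpec(0, round(0.75 * L), "PAR"),
      stratumSpec(round(0.75 * L), L, "young", xyDivergence = 0.005)),
    wingei = rbind(
      stratumSpec(0, round(0.85 * L), "young", xyDivergence = 0.005),
      stratumSpec(round(0.85 * L), round(0.97 * L), "old",
                  xyDivergence = 0.005, yLoss = 0.9,
                  ySilencedFraction = 0.5),
      stratumSpec(round(0.97 * L), L, "PAR")),
    picta = rbind(
      stratumSpec(0, round(0.95 * L), "old", xyDivergence = 0.005,
                  yLoss = 0.9, ySilencedFraction = 0.5),
      stratumSpec(round(0.95 * L), L, "PAR")))
  simConfig(sexChromLength = L, strata = strata,
            compensation = compensation, ...)
}

#' Simulate a complete XY-system dataset with ground truth
#'
#' Runs the structural truth generator and the coverage, SNP and RNA
#' simulators under seeds derived from `config@seed`; optionally also
#' emits haplotype sequences and reads (intended for small
#' configurations only).
#'
#' @param config a [SimConfig-class].
#' @param sequences emit haplotype FASTA sequences?
#' @param reads emit FASTQ-style reads (implies `sequences`)?
#' @return list: `config`, `truth`, `windows`, `sexes`, `coverage`,
#'   `hetSites`, `alleleCounts`, `expression`, and optionally
#'   `sequences`, `reads`.
#' @examples
#' cfg <- simConfig(seed = 7, nAutosomes = 1, chromLength = 5e5,
#'                  sexChromLength = 6e5, nGenesPerChrom = 20,
#'                  windowSize = 2.5e4)
#' sim <- simulateXYData(cfg)
#' head(sim$coverage)
#' @export
simulateXYData <- function(config, sequences = FALSE, reads = FALSE) {
  validObject(config)
  truth <- simTruth(config)
  windows <- tileWindows(config)
  coverage <- simulateCoverage(config, truth, windows)
  hetSites <- simulateSnps(config, truth)
  rna <- simulateRna(config, truth)
  out <- list(config = config, truth = truth, windows = windows,
              sexes = sampleSexes(config), coverage = coverage,
              hetSites = hetSites, alleleCounts = rna$alleleCounts,
              expression = rna$expression)
  if (sequences || reads) {
    gen <- simulateGenomes(config, truth)
    out$sequences <- gen$sequences
    if (reads) {
      out$reads <- emitReads(gen$sequences, depth = 2 * config@haploidDepth,
                             errorRate = config@kmerErrorRate,
                             seed = subSeed(config@seed, 6L))
    }
  }
  out
}
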