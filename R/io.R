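#' @importFrom data.table fread fwrite
#' @importFrom Biostrings writeXStringSet BStringSet
#' @importFrom jsonlite write_json read_json toJSON
#' @importFrom utils read.delim write.table
NULL

isGz <- function(path) grepl("\\.gz$", path)

readTsv <- function(path) {
  if (isGz(path)) {
    read.delim(gzfile(path), stringsAsFactors = FALSE)
  } else {
    setDF(fread(path, sep = "\t", header = TRUE, data.table = TRUE))
  }
}

writeTsv <- function(df, path) {
  fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Depth, sample-sex, allele-count and window-statistic tables
#'
#' Plain TSV readers/writers for the pipeline's tabular interchange
#' formats. All coordinates are 0-based half-open. Gzip input is
#' supported by the readers. `readDepthTable` also accepts 4-column
#' bedGraph-style files (chrom/start/end/depth) if a `sample` name is
#' supplied.
#'
#' @param path file path.
#' @param df,sample the table to write / sample name for bedGraph
#'   input.
#' @return the table as a data.frame (readers) or the path, invisibly
#'   (writers).
#' @name tables
NULL

#' @rdname tables
#' @export
readDepthTable <- function(path, sample = NULL) {
  df <- readTsv(path)
  if (ncol(df) == 4L && !is.null(sample)) {
    names(df) <- c("chrom", "start", "end", "depth")
    df$sample <- sample
    df <- df[, c("chrom", "start", "end", "sample", "depth")]
  }
  assertColumns(df, c("chrom", "start", "end", "sample", "depth"),
                basename(path))
  df
}

#' @rdname tables
#' @export
writeDepthTable <- function(df, path) {
  assertColumns(df, c("chrom", "start", "end", "sample", "depth"), "df")
  writeTsv(df, path)
}

#' @rdname tables
#' @export
readSampleSexes <- function(path) {
  df <- readTsv(path)
  assertColumns(df, c("sample", "sex"), basename(path))
  df
}

#' @rdname tables
#' @export
writeSampleSexes <- function(df, path) writeTsv(df, path)

#' @rdname tables
#' @export
readAlleleCounts <- function(path) {
  df <- readTsv(path)
  assertColumns(df, c("gene", "chrom", "pos", "sample", "countA",
                      "countB"), basename(path))
  df
}

#' @rdname tables
#' @export
writeAlleleCounts <- function(df, path) writeTsv(df, path)

#' @rdname tables
#' @export
writeWindowStats <- function(ws, path) writeTsv(windowStatsTable(ws), path)

#' @rdname tables
#' @export
readWindowStats <- function(path) {
  df <- readTsv(path)
  gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
  mcols(gr) <- DataFrame(df[, c("maleCov", "femaleCov", "log2MFCov",
                                "maleSnpDen", "femaleSnpDen",
                                "mfSnpDiff")])
  new("WindowStats", gr)
}

#' BED import/export of windows and stratum calls
#'
#' Thin wrappers over [rtracklayer::import.bed()]/`export.bed()`; BED
#' is 0-based half-open on disk and converted to/from GRanges
#' conventions automatically. Stratum calls are written with
#' `name = label` and `score = round(1000 * support)`.
#'
#' @param path BED path.
#' @param gr GRanges (for export); stratum calls need `label` and
#'   `support` columns.
#' @return GRanges (import) or the path, invisibly (export).
#' @name bed
NULL

#' @rdname bed
#' @export
readBed <- function(path) rtracklayer::import(path, format = "BED")

#' @rdname bed
#' @export
writeStrataBed <- function(gr, path) {
  out <- granges(gr)
  mcols(out) <- DataFrame(name = gr$label,
                          score = round(1000 * gr$support))
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' @rdname bed
#' @export
writeGenesBed <- function(gr, path) {
  out <- granges(gr)
  mcols(out) <- DataFrame(name = gr$gene)
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Write heterozygous sites as a multi-sample VCF
#'
#' Emits a minimal but standard-conformant VCF 4.2: biallelic SNVs,
#' `GT:DP:GQ` per sample, heterozygous (`0/1`) for samples carrying
#' the site and homozygous reference otherwise. Positions are converted
#' from the internal 0-based convention to VCF's 1-based.
#'
#' @param sites data.frame: `chrom`, `pos` (0-based), `sample`, `ref`,
#'   `alt` (see [simulateSnps()]).
#' @param samples character vector fixing the sample-column order.
#' @param path output path (`.vcf`).
#' @param dp,gq depth/genotype-quality values written for simulated
#'   genotypes.
#' @return the path, invisibly.
#' @export
writeSnpVcf <- function(sites, samples, path, dp = 40L, gq = 99L) {
  assertColumns(sites, c("chrom", "pos", "sample", "ref", "alt"),
                "sites")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=strataXY",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  dt <- as.data.table(sites)
  key <- dt[, list(ref = ref[1L], alt = alt[1L],
                   carriers = list(unique(sample))),
            by = c("chrom", "pos")]
  setkey(key, chrom, pos)
  gtFor <- function(carriers) {
    ifelse(samples %in% carriers[[1L]],
           sprintf("0/1:%d:%d", dp, gq), sprintf("0/0:%d:%d", dp, gq))
  }
  body <- vapply(seq_len(nrow(key)), function(i) {
    paste(c(key$chrom[i], key$pos[i] + 1L, ".", key$ref[i], key$alt[i],
            ".", "PASS", ".", "GT:DP:GQ", gtFor(key$carriers[i])),
          collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read heterozygous sites from a VCF
#'
#' Parses a VCF with [VariantAnnotation::readVcf()], keeps biallelic
#' SNVs, and returns the heterozygous genotypes passing depth and
#' genotype-quality filters (filters are skipped when the VCF lacks the
#' corresponding FORMAT field). Positions are returned 0-based.
#'
#' @param path VCF path (plain or bgzip).
#' @param minDepth minimum per-genotype DP.
#' @param minGQ minimum per-genotype GQ.
#' @return data.frame: `chrom`, `pos` (0-based), `sample`.
#' @export
readVcfHets <- function(path, minDepth = 10L, minGQ = 20L) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altL <- rr$ALT
  biallelic <- lengths(altL) == 1L
  alt <- rep(NA_character_, length(rr))
  alt[biallelic] <- as.character(unlist(altL[biallelic]))
  snv <- biallelic & nchar(ref) == 1L & !is.na(alt) &
    alt %in% c("A", "C", "G", "T")
  gt <- VariantAnnotation::geno(vcf)$GT[snv, , drop = FALSE]
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  dim(het) <- dim(gt)
  genoFields <- names(VariantAnnotation::geno(vcf))
  if ("DP" %in% genoFields) {
    dpm <- VariantAnnotation::geno(vcf)$DP[snv, , drop = FALSE]
    het <- het & !is.na(dpm) & dpm >= minDepth
  }
  if ("GQ" %in% genoFields) {
    gqm <- VariantAnnotation::geno(vcf)$GQ[snv, , drop = FALSE]
    het <- het & !is.na(gqm) & gqm >= minGQ
  }
  idx <- which(het, arr.ind = TRUE)
  pos <- start(rr)[snv]
  chrom <- as.character(seqnames(rr))[snv]
  data.frame(chrom = chrom[idx[, 1L]],
             pos = pos[idx[, 1L]] - 1L,
             sample = colnames(gt)[idx[, 2L]],
             stringsAsFactors = FALSE)[order(idx[, 1L], idx[, 2L]), ,
                                       drop = FALSE]
}

#' FASTA/FASTQ sequence output
#'
#' @param x a [Biostrings::DNAStringSet].
#' @param path output path.
#' @return the path, invisibly.
#' @name seqio
NULL

#' @rdname seqio
#' @export
writeFasta <- function(x, path) {
  writeXStringSet(x, path)
  invisible(path)
}

#' @rdname seqio
#' @export
writeFastq <- function(x, path) {
  quals <- BStringSet(vapply(width(x), function(w) {
    paste(rep("I", w), collapse = "")
  }, character(1L)))
  writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' K-mer set text files
#'
#' Sorted text, one canonical k-mer per line.
#'
#' @param x a [KmerSet-class] (write) or path (read).
#' @param path output path.
#' @param sample,sex,minCount metadata for the re-read set.
#' @return the path (write) or a [KmerSet-class] (read).
#' @name kmerio
NULL

#' @rdname kmerio
#' @export
writeKmerSet <- function(x, path) {
  writeLines(sort(kmers(x)), path)
  invisible(path)
}

#' @rdname kmerio
#' @export
readKmerSet <- function(path, sample = "sample", sex = "M",
                        minCount = 1L) {
  km <- readLines(path)
  km <- km[nzchar(km)]
  k <- if (length(km)) nchar(km[1L]) else 31L
  new("KmerSet", sample = sample, sex = sex, k = as.integer(k),
      minCount = as.integer(minCount), kmers = sort(km))
}

#' JSON export of a bootstrap null
#'
#' @param null an [AutosomalNull-class] (write) or path (read).
#' @param path file path.
#' @return path (write) / [AutosomalNull-class] (read).
#' @name nulljson
NULL

#' @rdname nulljson
#' @export
writeNullJson <- function(null, path) {
  write_json(list(statistic = null@statistic, lower = null@lower,
                  upper = null@upper, level = null@level,
                  nBoot = null@nBoot, center = null@center),
             path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nulljson
#' @export
readNullJson <- function(path) {
  x <- read_json(path, simplifyVector = TRUE)
  new("AutosomalNull", statistic = x$statistic, lower = x$lower,
      upper = x$upper, level = x$level, nBoot = as.integer(x$nBoot),
      center = x$center)
}

#' Expression matrix TSV (self-contained)
#'
#' One row per gene with annotation columns (`gene`, `chrom`, `start`,
#' `end`, `class`) followed by one column per sample.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `expr` (write) or path (read).
#' @param path file path.
#' @param sexes data.frame `sample`, `sex` for reading.
#' @return path (write) / SummarizedExperiment (read).
#' @name exprio
NULL

#' @rdname exprio
#' @export
writeExpressionTsv <- function(se, path) {
  rd <- as.data.frame(rowData(se)[, c("gene", "chrom", "start", "end",
                                      "class")])
  writeTsv(cbind(rd, as.data.frame(exprMatrix(se))), path)
}

#' @rdname exprio
#' @export
readExpressionTsv <- function(path, sexes) {
  df <- readTsv(path)
  annCols <- c("gene", "chrom", "start", "end", "class")
  assertColumns(df, annCols, basename(path))
  mat <- as.matrix(df[, setdiff(names(df), annCols), drop = FALSE])
  rownames(mat) <- df$gene
  makeExpressionSE(mat, df[, annCols], sexes)
}

#' Serialize a simulator configuration to/from YAML
#'
#' @param config a [SimConfig-class] (write) or path (read).
#' @param path YAML path.
#' @return path (write) / [SimConfig-class] (read).
#' @name configio
NULL

#' @rdname configio
#' @export
writeSimConfigYaml <- function(config, path) {
  x <- list(
    seed = config@seed, nAutosomes = config@nAutosomes,
    chromLength = config@chromLength,
    sexChromLength = config@sexChromLength,
    strata = lapply(seq_len(nrow(config@strata)), function(i) {
      as.list(config@strata[i, ])
    }),
    haploidDepth = config@haploidDepth,
    depthDispersion = config@depthDispersion,
    polymorphismRate = config@polymorphismRate,
    nMales = config@nMales, nFemales = config@nFemales,
    nGenesPerChrom = config@nGenesPerChrom,
    rnaDepth = config@rnaDepth, meanHetSites = config@meanHetSites,
    aseTheta = config@aseTheta,
    compensation = config@compensation,
    kmerErrorRate = config@kmerErrorRate,
    windowSize = config@windowSize)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname configio
#' @export
readSimConfigYaml <- function(path) {
  x <- yaml::read_yaml(path)
  strata <- do.call(rbind, lapply(x$strata, function(s) {
    stratumSpec(as.numeric(s$start), as.numeric(s$end), s$kind,
                xyDivergence = as.numeric(s$xyDivergence %||% 0),
                yLoss = as.numeric(s$yLoss %||% 0),
                ySilencedFraction = as.numeric(s$ySilencedFraction %||% 0))
  }))
  simConfig(seed = x$seed %||% 1L, nAutosomes = x$nAutosomes,
            chromLength = x$chromLength,
            sexChromLength = x$sexChromLength, strata = strata,
            haploidDepth = x$haploidDepth %||% 20,
            depthDispersion = x$depthDispersion %||% 10,
            polymorphismRate = x$polymorphismRate %||% 0.001,
            nMales = x$nMales %||% 3L, nFemales = x$nFemales %||% 3L,
            nGenesPerChrom = x$nGenesPerChrom %||% 200L,
            rnaDepth = x$rnaDepth %||% 40,
            meanHetSites = x$meanHetSites %||% 5,
            aseTheta = x$aseTheta %||% 0.9,
            compensation = x$compensation %||% TRUE,
            kmerErrorRate = x$kmerErrorRate %||% 0,
            windowSize = x$windowSize %||% 5e4)
}
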