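#' @importFrom Biostrings readDNAStringSet
NULL

kmerizeOne <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

#' Canonicalize k-mers (strand collapse)
#'
#' Maps each k-mer to the lexicographic minimum of itself and its
#' reverse complement, so counts are independent of read strand.
#'
#' @param x character vector of k-mers (A/C/G/T only).
#' @return character vector of canonical k-mers.
#' @export
canonicalKmers <- function(x) {
  if (!length(x)) return(character(0))
  rc <- as.character(reverseComplement(DNAStringSet(x)))
  ifelse(x <= rc, x, rc)
}

#' Count canonical k-mers of one sample
#'
#' Enumerates all k-length substrings of the input sequences (reads or
#' assembly contigs), drops k-mers containing ambiguous bases,
#' canonicalizes by strand, and retains those seen at least `minCount`
#' times. Counting is in-memory and intended for desk-scale inputs
#' (up to ~1e7 distinct k-mers).
#'
#' @param x sequences: a [Biostrings::DNAStringSet], a character
#'   vector, or the path to a FASTA/FASTQ file (gzip allowed).
#' @param k odd k-mer length (values in 11-63 are typical; an even `k`
#'   is an error because canonicalization would be ambiguous for
#'   palindromes).
#' @param minCount minimum multiplicity (default 2 suppresses isolated
#'   sequencing errors in read data; use 1 for assemblies).
#' @param sample,sex sample metadata recorded in the result.
#' @return A [KmerSet-class].
#' @examples
#' kmers(countKmers("ACGTACGT", k = 5, minCount = 1))
#' @export
countKmers <- function(x, k = 31L, minCount = 2L, sample = "sample",
                       sex = c("M", "F")) {
  sex <- match.arg(sex)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd (unambiguous canonicalization)")
  if (k < 3L) stop("k must be >= 3")
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x, ignore.case = TRUE))
      "fastq" else "fasta"
    x <- readDNAStringSet(x, format = fmt)
  }
  seqs <- toupper(as.character(x))
  km <- unlist(lapply(seqs, kmerizeOne, k = k), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  km <- canonicalKmers(km)
  if (length(km)) {
    r <- rle(sort(km))
    km <- r$values[r$lengths >= minCount]
  }
  new("KmerSet", sample = sample, sex = sex, k = k,
      minCount = as.integer(minCount), kmers = km)
}

checkSameK <- function(sets) {
  ks <- vapply(sets, function(s) s@k, integer(1L))
  if (length(unique(ks)) != 1L) stop("all KmerSets must share the same k")
  ks[1L]
}

#' Sex-specific k-mers of one species
#'
#' Y-mers are the k-mers present in *every* male sample and absent from
#' *every* female sample; female-unique k-mers are the converse. This
#' is the strictest reading of "male-unique": intersection across the
#' carrying sex, subtraction of the union of the other sex.
#'
#' @param males,females lists of [KmerSet-class] (at least one each),
#'   all with the same k.
#' @param species species identifier recorded in the result.
#' @return A [SexSpecificResult-class].
#' @export
sexSpecificKmers <- function(males, females, species = "species") {
  if (is(males, "KmerSet")) males <- list(males)
  if (is(females, "KmerSet")) females <- list(females)
  if (!length(males) || !length(females)) {
    stop("need at least one KmerSet per sex")
  }
  k <- checkSameK(c(males, females))
  mInt <- Reduce(intersect, lapply(males, kmers))
  fInt <- Reduce(intersect, lapply(females, kmers))
  mUni <- Reduce(union, lapply(males, kmers))
  fUni <- Reduce(union, lapply(females, kmers))
  new("SexSpecificResult", species = species, k = k,
      yMers = sort(setdiff(mInt, fUni)),
      femaleUnique = sort(setdiff(fInt, mUni)))
}

#' Venn partition of sex-specific k-mers across species
#'
#' For every non-empty subset of species, counts the k-mers present in
#' the sex-specific set of exactly the species in that subset. The
#' partition counts sum to the size of the union.
#'
#' @param sets named list (>= 2 entries) of per-species k-mer sets:
#'   either character vectors or [SexSpecificResult-class] objects
#'   (`which` selects the set used).
#' @param which for `SexSpecificResult` input, `"yMers"` or
#'   `"femaleUnique"`.
#' @return data.frame: `species` (subset as `+`-joined names),
#'   `nSpecies`, `count`; one row per non-empty subset, including
#'   zero counts.
#' @examples
#' crossSpeciesShared(list(s1 = c("A", "B"), s2 = c("B", "C"),
#'                         s3 = "B"))
#' @export
crossSpeciesShared <- function(sets, which = c("yMers", "femaleUnique")) {
  which <- match.arg(which)
  if (length(sets) < 2L) stop("need at least 2 species")
  sets <- lapply(sets, function(s) {
    if (is(s, "SexSpecificResult")) slot(s, which) else as.character(s)
  })
  if (is.null(names(sets))) names(sets) <- paste0("sp", seq_along(sets))
  uni <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) uni %in% s,
                   logical(length(uni)))
  if (length(uni) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, names(sets)))
  nSp <- length(sets)
  subsets <- lapply(seq_len(2^nSp - 1L), function(code) {
    as.logical(bitwAnd(code, 2^(seq_len(nSp) - 1L)))
  })
  counts <- vapply(subsets, function(sub) {
    if (length(uni) == 0L) return(0L)
    sum(apply(member, 1L, function(row) all(row == sub)))
  }, integer(1L))
  data.frame(
    species = vapply(subsets, function(sub) {
      paste(names(sets)[sub], collapse = "+")
    }, character(1L)),
    nSpecies = vapply(subsets, sum, integer(1L)),
    count = counts, stringsAsFactors = FALSE)
}

#' Female-unique to Y-mer burden ratio
#'
#' An excess of female-unique over male-unique k-mers is the signature
#' of large-scale Y loss: much of the X has no surviving Y homolog, so
#' X-derived k-mers have nothing to pair with in males, while the lost
#' Y contributes no male-unique sequence.
#'
#' @param result a [SexSpecificResult-class].
#' @param threshold ratio above which the Y-loss flag is raised.
#' @return list: `ratio` (female-unique count / Y-mer count; `Inf` when
#'   there are no Y-mers), `nYmers`, `nFemaleUnique`, `yLossSignature`
#'   (logical flag).
#' @export
kmerBurdenRatio <- function(result, threshold = 1.5) {
  nY <- length(result@yMers)
  nF <- length(result@femaleUnique)
  ratio <- if (nY == 0L) Inf else nF / nY
  list(ratio = ratio, nYmers = nY, nFemaleUnique = nF,
       yLossSignature = is.infinite(ratio) || ratio > threshold)
}
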