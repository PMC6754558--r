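# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (enumeration, direct recomputation) and must stay
# independent of the package code paths they check.

# all distinct canonical k-mers of a set of sequences, by enumeration
oracleGenomeKmers <- function(seqs, k) {
  km <- unlist(lapply(as.character(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), k:n)
  }), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  sort(unique(ifelse(km <= rc, km, rc)))
}

# Pearson chi-square on a 2x2 table by the textbook closed form
oracleChisq2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# exact two-sided rank-sum test by complete enumeration (no ties)
oracleRankSum <- function(x, y) {
  r <- rank(c(x, y))
  n <- length(x)
  N <- length(r)
  obs <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  cs <- utils::combn(N, n)
  stats <- apply(cs, 2L, function(i) sum(r[i]))
  list(W = obs - n * (n + 1) / 2,
       p = mean(abs(stats - mu) >= abs(obs - mu) - 1e-12))
}

# exact two-sided signed-rank test over all 2^n sign assignments
oracleSignedRank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  stats <- as.matrix(signs) %*% r
  list(V = obs, p = mean(abs(stats - mu) >= abs(obs - mu) - 1e-12))
}

# per-window per-sample mean depth by direct looping
oracleWindowMeans <- function(depth, windows) {
  samples <- sort(unique(depth$sample))
  out <- matrix(NA_real_, length(windows), length(samples),
                dimnames = list(NULL, samples))
  wChrom <- as.character(GenomeInfoDb::seqnames(windows))
  wStart <- BiocGenerics::start(windows) - 1L
  wEnd <- BiocGenerics::end(windows)
  for (i in seq_along(windows)) {
    for (s in samples) {
      rows <- depth[depth$sample == s & depth$chrom == wChrom[i] &
                      depth$end > wStart[i] & depth$start < wEnd[i], ,
                    drop = FALSE]
      if (!nrow(rows)) next
      w <- pmin(rows$end, wEnd[i]) - pmax(rows$start, wStart[i])
      out[i, s] <- sum(w * rows$depth) / sum(w)
    }
  }
  out
}

emptyHetSites <- function() {
  data.frame(chrom = character(0), pos = integer(0),
             sample = character(0), stringsAsFactors = FALSE)
}

# small flat depth table builder: every listed window at given depth
flatDepth <- function(windows, sample, depth) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(windows)),
             start = BiocGenerics::start(windows) - 1L,
             end = BiocGenerics::end(windows),
             sample = sample, depth = depth,
             stringsAsFactors = FALSE)
}
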