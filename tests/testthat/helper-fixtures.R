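suppressMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## deterministic random genome for small fixtures
toy_genome <- function(lengths, seed = 1, gc = 0.4) {
  set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  g <- DNAStringSet(vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1)))
  names(g) <- names(lengths)
  g
}

## O(n * m) counting oracle mirroring the fractional-overlap strand rule
brute_force_counts <- function(reads, regions, strand_mode = "any",
                               min_overlap_fraction = 0.5) {
  out <- numeric(length(regions))
  for (j in seq_along(regions)) {
    for (i in seq_along(reads)) {
      if (as.character(seqnames(reads))[i] != as.character(seqnames(regions))[j])
        next
      ov <- min(end(reads)[i], end(regions)[j]) -
        max(start(reads)[i], start(regions)[j]) + 1
      if (ov < min_overlap_fraction * width(reads)[i]) next
      same <- as.character(strand(reads))[i] == as.character(strand(regions))[j]
      if (strand_mode == "same" && !same) next
      if (strand_mode == "opposite" && same) next
      out[j] <- out[j] + 1
    }
  }
  out
}

## independent direct-summation power oracle: explicit accumulation of the
## complex exponential sum, term by term
oracle_power <- function(x, periods_bins) {
  N <- length(x)
  xt <- x - mean(x)
  vapply(periods_bins, function(p) {
    re <- 0; im <- 0
    for (n in 0:(N - 1)) {
      re <- re + xt[n + 1] * cos(2 * pi * n / p)
      im <- im - xt[n + 1] * sin(2 * pi * n / p)
    }
    (re^2 + im^2) / N
  }, numeric(1))
}

## sorted dinucleotide multiset signature of a sequence
dinuc_multiset <- function(s) {
  paste(sort(substring(s, seq_len(nchar(s) - 1), 2:nchar(s))), collapse = ",")
}
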