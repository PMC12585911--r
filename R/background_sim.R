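## Dinucleotide-composition machinery for the background read simulator.
## A read's k-mer "key" is the multiset of its overlapping k-mers (k = 2:
## the 16 dinucleotide counts), encoded as a complex number whose real and
## imaginary parts pack the counts of categories 1-8 and 9-16 in base 64
## (exact in doubles for reads up to 64 nt).

BASES <- c("A", "C", "G", "T")
DINUCS <- as.vector(t(outer(BASES, BASES, paste0)))

## integer codes 1..16 of overlapping dinucleotides of a chromosome (0 where
## either base is not ACGT)
dinuc_codes <- function(chrseq) {
  b <- match(strsplit(as.character(chrseq), "")[[1]], BASES)  # NA for N
  n <- length(b)
  code <- (b[-n] - 1L) * 4L + b[-1L]
  code[is.na(code)] <- 0L
  code
}

## zero-padded cumulative count matrix: row i+1 holds counts of categories
## 1..16 (and valid dinucleotides, col 17) over code[1..i]
dinuc_cummat <- function(code) {
  m <- matrix(0L, length(code) + 1L, 17L)
  for (cat in seq_len(16L)) m[-1L, cat] <- cumsum(code == cat)
  m[-1L, 17L] <- cumsum(code != 0L)
  m
}

## dinucleotide counts (rows, 16 cols) + valid-count (col 17) for windows of
## `w` dinucleotides starting at `starts`
window_counts <- function(cm, starts, w) {
  cm[starts + w, , drop = FALSE] - cm[starts, , drop = FALSE]
}

counts_key <- function(m) {
  k1 <- as.numeric(m[, 1:8, drop = FALSE] %*% 64^(0:7))
  k2 <- as.numeric(m[, 9:16, drop = FALSE] %*% 64^(0:7))
  complex(real = k1, imaginary = k2)
}

## dinucleotide count matrix (16 cols) for read sequences of a shared length
seq_dinuc_counts <- function(seqs) {
  L <- nchar(seqs)
  if (length(unique(L)) != 1) stop("sequences must share a length")
  W <- L[1] - 1L
  m <- matrix(0L, length(seqs), 16L)
  colnames(m) <- DINUCS
  for (i in seq_len(W)) {
    mer <- substring(seqs, i, i + 1L)
    j <- match(mer, DINUCS)
    ok <- !is.na(j)
    idx <- cbind(which(ok), j[ok])
    m[idx] <- m[idx] + 1L
  }
  m
}

## per-read dinucleotide counts, handling mixed lengths
seq_dinuc_counts_bylen <- function(seqs) {
  L <- nchar(seqs)
  m <- matrix(0L, length(seqs), 16L)
  for (len in unique(L)) {
    i <- which(L == len)
    m[i, ] <- seq_dinuc_counts(seqs[i])
  }
  m
}

revcomp_str <- function(seqs) {
  as.character(reverseComplement(DNAStringSet(seqs)))
}

#' Simulate background pseudo-reads preserving dinucleotide composition
#'
#' Emits exactly one pseudo-read per input read, of the same length, at a
#' random genomic position and strand whose sequence has exactly the same
#' multiset of overlapping k-mers (k = 2: dinucleotides) as the input read.
#' The resulting read set reflects the signal expected from sequence
#' composition alone and is the denominator of the simulation-normalization
#' steps of damage/repair profiles.
#'
#' Sampling: for each read, up to `sens` candidates are drawn (chromosome
#' proportional to length, start uniform, strand uniform; windows containing N
#' or falling off a chromosome are redrawn without consuming an attempt) and
#' the first whose dinucleotide multiset matches is accepted. For reads still
#' unmatched after `sens` attempts, a position is drawn uniformly at random
#' from the precomputed set of all genomic windows (either strand) with a
#' matching multiset, so the per-read composition identity still holds
#' exactly. Only when the read's multiset occurs nowhere in the genome is the
#' last random candidate emitted and flagged. Deterministic under `seed`.
#'
#' @param reads `GRanges` of input reads (lengths 2-64 nt).
#' @param genome `DNAStringSet`.
#' @param kmer k-mer size (only `2`, the dinucleotide simulator, is
#'   implemented).
#' @param sens maximum random sampling attempts per read before falling back to
#'   indexed sampling (default 20).
#' @param seed RNG seed.
#' @param sequences optional read sequences (defaults to extraction from
#'   `genome`).
#' @return `GRanges` of pseudo-reads, parallel to `reads`, with metadata
#'   columns `flagged` (TRUE = no genomic window matches; composition identity
#'   not guaranteed) and `sample`. The flagged fraction is reported in a
#'   message when nonzero.
#' @export
simulate_background_reads <- function(reads, genome, kmer = 2, sens = 20,
                                      seed = 1L, sequences = NULL) {
  if (kmer != 2) stop("only kmer = 2 is implemented")
  if (sens < 1) stop("sens must be >= 1")
  n <- length(reads)
  if (n == 0)
    return(GRanges(flagged = logical(0), sample = character(0)))
  chrlen <- setNames(width(genome), names(genome))
  lens <- width(reads)
  if (any(lens > max(chrlen)))
    stop("read(s) longer than every chromosome")
  if (any(lens < 2) || any(lens > 64))
    stop("read lengths must be in [2, 64] nt")
  if (is.null(sequences)) sequences <- read_sequences(reads, genome)

  set.seed(seed)
  cms <- lapply(as.list(genome), function(s) dinuc_cummat(dinuc_codes(s)))
  chrs <- names(genome)

  target_fwd <- seq_dinuc_counts_bylen(sequences)          # read-strand counts
  target_rev <- seq_dinuc_counts_bylen(revcomp_str(sequences))
  key_fwd <- counts_key(target_fwd)
  key_rev <- counts_key(target_rev)

  out_chr <- character(n); out_start <- numeric(n)
  out_strand <- character(n)
  flagged <- logical(n)

  pending <- seq_len(n)
  for (attempt in seq_len(sens)) {
    if (!length(pending)) break
    drawn <- draw_valid_candidates(cms, chrs, chrlen, lens[pending])
    cand <- drawn$cand
    ck <- drawn$keys
    tgt <- ifelse(cand$strand == "+", key_fwd[pending], key_rev[pending])
    hit <- ck == tgt
    hi <- pending[hit]
    out_chr[hi] <- cand$chr[hit]
    out_start[hi] <- cand$start[hit]
    out_strand[hi] <- cand$strand[hit]
    if (attempt == sens) {
      rest <- !hit  # last candidate kept as the flagged fallback of last resort
      ri <- pending[rest]
      out_chr[ri] <- cand$chr[rest]
      out_start[ri] <- cand$start[rest]
      out_strand[ri] <- cand$strand[rest]
    }
    pending <- pending[!hit]
  }

  if (length(pending)) {
    ## indexed exact sampling for reads the blind attempts missed
    for (L in sort(unique(lens[pending]))) {
      sel <- pending[lens[pending] == L]
      keys <- unique(c(key_fwd[sel], key_rev[sel]))
      index <- genome_key_index(cms, chrlen, L, keys)
      jf <- match(key_fwd[sel], keys)
      jr <- match(key_rev[sel], keys)
      for (ii in seq_along(sel)) {
        pf <- index[[jf[ii]]]  # matching (chrom idx, start) for a + pseudo-read
        pr <- index[[jr[ii]]]  # for a - pseudo-read
        nf <- if (is.null(pf)) 0L else nrow(pf)
        nr <- if (is.null(pr)) 0L else nrow(pr)
        if (nf + nr == 0L) { flagged[sel[ii]] <- TRUE; next }
        pick <- sample.int(nf + nr, 1L)
        if (pick <= nf) {
          out_chr[sel[ii]] <- chrs[pf[pick, 1L]]
          out_start[sel[ii]] <- pf[pick, 2L]
          out_strand[sel[ii]] <- "+"
        } else {
          out_chr[sel[ii]] <- chrs[pr[pick - nf, 1L]]
          out_start[sel[ii]] <- pr[pick - nf, 2L]
          out_strand[sel[ii]] <- "-"
        }
      }
    }
    nfl <- sum(flagged)
    if (nfl > 0)
      message(nfl, " read(s) flagged (", signif(nfl / n, 3),
              " of total): no genomic window matches their composition")
  }
  GRanges(out_chr, IRanges(out_start, width = lens), strand = out_strand,
          flagged = flagged, sample = "background_sim")
}

## uniform candidate windows: chromosome ~ length, start uniform, strand
## uniform; windows containing N (or on too-short chromosomes) are redrawn
## without consuming a sampling attempt; returns their composition keys
draw_valid_candidates <- function(cms, chrs, chrlen, lens) {
  np <- length(lens)
  chr <- character(np); start <- numeric(np)
  strand <- sample(c("+", "-"), np, replace = TRUE)
  keys <- complex(np)
  todo <- seq_len(np)
  for (guard in 1:50) {
    if (!length(todo)) break
    ci <- sample.int(length(chrs), length(todo), replace = TRUE, prob = chrlen)
    maxs <- chrlen[ci] - lens[todo] + 1
    ok_chr <- maxs >= 1
    s <- floor(runif(length(todo)) * pmax(maxs, 1)) + 1
    chr[todo] <- chrs[ci]
    start[todo] <- s
    has_n <- logical(length(todo))
    for (u in unique(ci)) {
      i <- which(ci == u)
      cnt <- window_counts(cms[[u]], s[i], lens[todo][i] - 1L)
      keys[todo[i]] <- counts_key(cnt)
      has_n[i] <- cnt[, 17L] != lens[todo][i] - 1L
    }
    todo <- todo[!ok_chr | has_n]
  }
  list(cand = list(chr = chr, start = start, strand = strand), keys = keys)
}

## all genomic windows of read length L whose composition key is in `keys`:
## list parallel to `keys` of (chrom index, start) matrices
genome_key_index <- function(cms, chrlen, L, keys) {
  W <- L - 1L
  res <- vector("list", length(keys))
  for (ci in seq_along(cms)) {
    nstart <- chrlen[ci] - L + 1L
    if (nstart < 1) next
    starts <- seq_len(nstart)
    cnt <- window_counts(cms[[ci]], starts, W)
    full <- cnt[, 17L] == W  # windows without N
    gk <- counts_key(cnt)
    mi <- match(gk, keys)
    mi[!full] <- NA_integer_
    ok <- which(!is.na(mi))
    if (!length(ok)) next
    grp <- split(ok, mi[ok])
    for (key_j in names(grp)) {
      j <- as.integer(key_j)
      res[[j]] <- rbind(res[[j]],
                        cbind(rep(ci, length(grp[[key_j]])), grp[[key_j]]))
    }
  }
  res
}
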