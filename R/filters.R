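#' Post-alignment filter for XR-seq reads
#'
#' Keeps reads with mapping quality strictly greater than `mapq_min`, mapped to
#' an allowed chromosome, and with aligned length inside `length_range`
#' (inclusive). These are the standard post-alignment criteria for excised
#' oligonucleotide (XR-seq) libraries: the excision products informative for
#' repair mapping are 21-28 nt. Order is preserved and the filter is
#' idempotent.
#'
#' @param reads `GRanges` of reads with a `mapq` metadata column.
#' @param mapq_min reads must satisfy `mapq > mapq_min` (default 20).
#' @param allowed_chroms character vector of chromosomes to keep; defaults to
#'   all chromosomes present. An empty vector is a configuration error.
#' @param length_range inclusive `(low, high)` bounds on aligned length.
#' @return the retained reads, in input order.
#' @examples
#' r <- alignments(c("I", "I"), c(100, 100), c(123, 119), "+", mapq = 30)
#' length(filter_xr_reads(r))  # the 20-nt read is dropped
#' @export
filter_xr_reads <- function(reads, mapq_min = 20L,
                            allowed_chroms = seqlevels(reads),
                            length_range = c(21L, 28L)) {
  if (length(allowed_chroms) == 0) stop("allowed_chroms must be non-empty")
  if (length(length_range) != 2 || length_range[1] > length_range[2])
    stop("length_range must be (low, high) with low <= high")
  if (is.null(reads$mapq)) stop("reads lack a 'mapq' metadata column")
  keep <- reads$mapq > mapq_min &
    as.character(seqnames(reads)) %in% allowed_chroms &
    width(reads) >= length_range[1] & width(reads) <= length_range[2]
  reads[keep]
}

#' Post-alignment filter for paired-end RNA-seq reads
#'
#' Retains reads that satisfy all six criteria used for high-confidence
#' expression quantification: MAPQ >= 30; properly paired with the mate on the
#' same chromosome; insert size <= 500 kb with forward/reverse (-> <-)
#' orientation; a CIGAR string containing at least one aligned (`M`) segment;
#' at most 10 reported alignment locations (`NH` tag); and not mapped to the
#' mitochondrial genome.
#'
#' @param reads `GRanges` with metadata columns `mapq`, `proper_pair`,
#'   `same_chrom`, `insert_size`, `fr_orientation`, `cigar`, `nh`. A missing
#'   column is an error naming the field.
#' @param mito chromosome names treated as mitochondrial.
#' @return the retained reads, in input order.
#' @export
filter_rnaseq_pairs <- function(reads, mito = c("MT", "chrM", "M")) {
  need <- c("mapq", "proper_pair", "same_chrom", "insert_size",
            "fr_orientation", "cigar", "nh")
  missing <- setdiff(need, colnames(mcols(reads)))
  if (length(missing))
    stop("reads lack required metadata field(s): ", paste(missing, collapse = ", "))
  keep <- reads$mapq >= 30 &
    reads$proper_pair & reads$same_chrom &
    abs(reads$insert_size) <= 5e5 & reads$fr_orientation &
    grepl("M", reads$cigar, fixed = TRUE) &
    reads$nh <= 10 &
    !as.character(seqnames(reads)) %in% mito
  reads[keep]
}

#' Collapse PCR duplicates to a single alignment
#'
#' At most one read is kept per (chromosome, start, end, strand) key; the first
#' occurrence survives. Idempotent and order-stable.
#'
#' @param reads `GRanges` of reads.
#' @return deduplicated reads in input order.
#' @export
deduplicate_alignments <- function(reads) {
  reads[!duplicated(granges(reads))]
}

#' Positional nucleotide or dinucleotide composition of reads
#'
#' Computes per-position base (`k = 1`) or overlapping-dinucleotide (`k = 2`)
#' frequencies over reads of exactly `read_length` nt, the standard damage
#' fingerprint plot for XR-seq/Damage-seq libraries (24-nt XR-seq reads of UV
#' libraries carry a dipyrimidine 6 nt from the 3' end). Rows are positions and
#' sum to 1; positions containing `N` are excluded from the denominator.
#'
#' @param seqs character vector (or `DNAStringSet`) of read sequences in read
#'   orientation; only those of length `read_length` are used.
#' @param k 1 (mononucleotide) or 2 (overlapping dinucleotide).
#' @param read_length read length to select.
#' @param from_3prime if `TRUE`, rows are labelled by negative offsets from the
#'   3' end (the last base or dinucleotide start is position -1).
#' @return frequency matrix: `read_length` x 4 for `k = 1`,
#'   `(read_length - 1)` x 16 for `k = 2`.
#' @examples
#' m <- positional_composition(c("TTAG", "TTCC"), k = 2, read_length = 4)
#' m["1", "TT"]
#' @export
positional_composition <- function(seqs, k = c(1, 2), read_length,
                                   from_3prime = FALSE) {
  k <- as.integer(k[1])
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2")
  seqs <- as.character(seqs)
  seqs <- seqs[nchar(seqs) == read_length]
  if (length(seqs) == 0)
    stop("no reads of length ", read_length, " in input")
  bases <- c("A", "C", "G", "T")
  cols <- if (k == 1) bases else
    as.vector(t(outer(bases, bases, paste0)))
  npos <- read_length - k + 1L
  out <- matrix(0, npos, length(cols), dimnames = list(seq_len(npos), cols))
  for (i in seq_len(npos)) {
    mer <- substring(seqs, i, i + k - 1L)
    tab <- table(factor(mer, levels = cols))
    tot <- sum(tab)
    if (tot > 0) out[i, ] <- as.numeric(tab) / tot
  }
  ## 3'-offset convention: a dinucleotide labelled -6 occupies 0-based read
  ## indices (L-7, L-6); the 3'-most base (k = 1) is labelled -1
  if (from_3prime)
    rownames(out) <- as.character(seq_len(npos) - read_length - (2L - k))
  out
}
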