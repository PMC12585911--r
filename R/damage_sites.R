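#' Remove undamaged-strand reads by adaptor content
#'
#' In Damage-seq libraries the undamaged strand is captured with a known
#' adaptor; any raw read containing that adaptor as a substring originates from
#' the undamaged strand and is discarded before alignment.
#'
#' @param seqs character vector of raw (unaligned) read sequences.
#' @param adaptor adaptor sequence; the default is the 33-mer used for
#'   undamaged-strand capture in UV Damage-seq libraries.
#' @return the reads that do not contain the adaptor, in input order.
#' @export
remove_undamaged_strand_reads <- function(
    seqs, adaptor = "GACTGGTTCCAATTGAAAGTGCTCTTCCGATCT") {
  if (!is.character(adaptor) || length(adaptor) != 1 || nchar(adaptor) == 0)
    stop("adaptor must be a non-empty DNA string")
  seqs[!grepl(adaptor, seqs, fixed = TRUE)]
}

#' Infer 10-nt damage windows from Damage-seq alignments
#'
#' The lesion dinucleotide sits two nucleotides upstream of each read's 5' end
#' (in read orientation): reads are conceptually trimmed to their first 4 nt
#' and extended 6 nt upstream, giving a 10-nt window whose middle two bases
#' (oriented positions 5-6) are the damaged dinucleotide. For a `+` read
#' starting at 1-based position S the window is `[S-6, S+3]` and the
#' dinucleotide `[S-2, S-1]`; for a `-` read ending at E the window is
#' `[E-3, E+6]` and the dinucleotide `[E+1, E+2]`.
#'
#' Under the default `convention = "opposite"` the lesion is placed on the
#' strand opposite the mapped read (the sequenced extension product is
#' complementary to the damaged strand); `convention = "read"` books the lesion
#' on the read strand. The window coordinates are identical under both; only
#' the strand label and hence the orientation of `oriented_seq` change. Reads
#' whose window would fall off the chromosome are dropped and counted, not
#' clipped.
#'
#' @param reads deduplicated `GRanges` of aligned Damage-seq reads.
#' @param genome `DNAStringSet`.
#' @param convention `"opposite"` (default) or `"read"`.
#' @return `GRanges` of width-10 windows with strand = damage strand and
#'   metadata columns `dinuc_start` (1-based start of the lesion dinucleotide),
#'   `read_strand` and `oriented_seq` (the damaged strand's 10-mer, 5'->3').
#'   The number of boundary-skipped reads is in `metadata()$n_skipped`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(I = paste(rep("ACGT", 60), collapse = "")))
#' r <- alignments("I", 101, 126, "+", mapq = 30)
#' infer_damage_windows(r, g)
#' @export
infer_damage_windows <- function(reads, genome,
                                 convention = c("opposite", "read")) {
  convention <- match.arg(convention)
  if (length(reads) == 0) {
    out <- GRanges()
    metadata(out)$n_skipped <- 0L
    return(out)
  }
  chrlen <- setNames(width(genome), names(genome))
  chr <- as.character(seqnames(reads))
  if (!all(chr %in% names(chrlen)))
    stop("reads on chromosomes absent from genome")
  plus <- as.character(strand(reads)) == "+"
  ## 5'-anchored window arithmetic (1-based, closed)
  win_start <- ifelse(plus, start(reads) - 6L, end(reads) - 3L)
  win_end <- win_start + 9L
  dinuc_start <- ifelse(plus, start(reads) - 2L, end(reads) + 1L)
  ok <- win_start >= 1L & win_end <= chrlen[chr]
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message(n_skipped, " read(s) skipped: damage window off chromosome bounds")
  idx <- which(ok)
  read_strand <- ifelse(plus, "+", "-")[idx]
  damage_strand <- if (convention == "opposite")
    ifelse(read_strand == "+", "-", "+") else read_strand
  win <- GRanges(chr[idx], IRanges(win_start[idx], win_end[idx]),
                 strand = damage_strand)
  win$dinuc_start <- dinuc_start[idx]
  win$read_strand <- read_strand
  win$oriented_seq <- extract_oriented(win, genome)
  if (!is.null(reads$lesion_id)) win$lesion_id <- reads$lesion_id[idx]
  metadata(win)$n_skipped <- n_skipped
  win
}

#' Lesion dinucleotide intervals of damage windows
#'
#' @param windows output of [infer_damage_windows()].
#' @return width-2 `GRanges` (strand = damage strand) of lesion dinucleotides.
#' @export
damage_dinucs <- function(windows) {
  out <- GRanges(seqnames(windows),
                 IRanges(windows$dinuc_start, width = 2L),
                 strand = strand(windows))
  mcols(out) <- mcols(windows)
  out
}

#' Dipyrimidine filter for damage windows
#'
#' UV photolesions form between adjacent pyrimidines, so only windows whose
#' oriented positions 5-6 (the inferred lesion dinucleotide, read on the
#' damaged strand) are both C or T are plausible damage sites. Windows with
#' `N` at those positions are rejected.
#'
#' @param windows output of [infer_damage_windows()].
#' @return the retained windows, in input order.
#' @export
dipyrimidine_filter <- function(windows) {
  if (length(windows) == 0) return(windows)
  mid <- substr(windows$oriented_seq, 5L, 6L)
  keep <- grepl("^[CT][CT]$", mid)
  windows[keep]
}
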