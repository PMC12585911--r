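#' Construct read alignments
#'
#' Builds the `GRanges` representation of aligned reads used throughout the
#' package: an ungapped interval per read (1-based, closed; BED input is
#' converted on read) with strand, mapping quality and a sample label. Read
#' length equals the aligned span.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 1-based inclusive interval per read.
#' @param strand `"+"` or `"-"` per read.
#' @param mapq integer mapping qualities (>= 0).
#' @param sample optional sample label (recycled).
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A `GRanges` with metadata columns `mapq` and `sample`.
#' @examples
#' alignments("I", 101, 126, "+", mapq = 30)
#' @export
alignments <- function(chrom, start, end, strand = "+", mapq = 0L,
                       sample = NA_character_, seqlengths = NULL) {
  if (any(mapq < 0)) stop("mapq must be >= 0")
  gr <- GRanges(chrom, IRanges(start, end), strand = strand,
                mapq = as.integer(mapq), sample = sample)
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  gr
}

#' Read aligned reads from a BED6 file
#'
#' The BED score column is interpreted as mapping quality and the name column
#' as the sample label, mirroring [write_reads_bed()].
#'
#' @param path BED6 file.
#' @return `GRanges` with `mapq` and `sample` metadata columns.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  mapq <- if (!is.null(gr$score)) as.integer(gr$score) else 0L
  nm <- if (!is.null(gr$name)) gr$name else NA_character_
  mcols(gr) <- DataFrame(mapq = mapq, sample = nm)
  gr
}

#' Write aligned reads to a BED6 file
#'
#' @param reads `GRanges` of reads; `mapq` is written to the score column and
#'   `sample` (if present) to the name column.
#' @param path output file.
#' @export
write_reads_bed <- function(reads, path) {
  out <- granges(reads)
  out$name <- if (!is.null(reads$sample)) reads$sample else "."
  out$score <- if (!is.null(reads$mapq)) as.numeric(reads$mapq) else 0
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Uppercase [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file (1-based inclusive coordinates, converted to `GRanges`
#' natively by rtracklayer) and keeps `gene`-type features. The transcription
#' start site is the 5' end of the interval in strand orientation.
#'
#' @param path GFF3 file.
#' @return `GRanges` with a `gene_id` metadata column.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  id <- gr$ID
  if (is.null(id)) id <- gr$Name
  mcols(gr) <- DataFrame(gene_id = as.character(id))
  gr
}

#' Write gene models to GFF3
#'
#' @param genes `GRanges` with `gene_id`.
#' @param path output file.
#' @export
write_genes_gff3 <- function(genes, path) {
  out <- granges(genes)
  out$source <- "repairscape"
  out$type <- "gene"
  out$ID <- genes$gene_id
  rtracklayer::export(out, path, format = "GFF3")
  invisible(path)
}

#' TSS and TES positions of gene models
#'
#' For a `+` gene the TSS is the leftmost base and the TES the rightmost; for a
#' `-` gene the reverse.
#'
#' @param genes stranded `GRanges`.
#' @return data.frame with `gene_id`, `tss`, `tes` (1-based positions).
#' @export
gene_anchors <- function(genes) {
  plus <- as.character(strand(genes)) != "-"
  data.frame(
    gene_id = if (!is.null(genes$gene_id)) genes$gene_id else as.character(seq_along(genes)),
    tss = ifelse(plus, start(genes), end(genes)),
    tes = ifelse(plus, end(genes), start(genes))
  )
}

#' Extract read sequences from a genome
#'
#' Returns each read's sequence in its own 5'->3' orientation (reverse
#' complement of the reference for minus-strand reads).
#'
#' @param reads `GRanges` of reads.
#' @param genome `DNAStringSet`.
#' @return character vector of sequences, one per read.
#' @export
read_sequences <- function(reads, genome) {
  extract_oriented(reads, genome)
}

## shared oriented extraction; `gr` strand "-" => reverse complement
extract_oriented <- function(gr, genome) {
  out <- character(length(gr))
  for (chr in unique(as.character(seqnames(gr)))) {
    if (!chr %in% names(genome)) stop("chromosome absent from genome: ", chr)
    i <- which(as.character(seqnames(gr)) == chr)
    seqs <- extractAt(genome[[chr]], IRanges(start(gr)[i], end(gr)[i]))
    neg <- as.character(strand(gr))[i] == "-"
    if (any(neg)) seqs[neg] <- reverseComplement(seqs[neg])
    out[i] <- as.character(seqs)
  }
  out
}

#' Read/write an expression table
#'
#' Two-column TSV of `gene_id` and `tpm` (or raw counts).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_expression_tsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_expression_tsv
#' @param x data.frame to write.
#' @export
write_expression_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a binned profile as bedGraph
#'
#' @param bins `GRanges` of bins.
#' @param values numeric per bin.
#' @param path output file.
#' @export
write_bedgraph <- function(bins, values, path) {
  out <- granges(bins)
  strand(out) <- "*"
  out$score <- as.numeric(values)
  rtracklayer::export(out, path, format = "bedGraph")
  invisible(path)
}
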