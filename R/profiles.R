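#' Tile chromosomes into fixed-width bins
#'
#' Consecutive non-overlapping bins per chromosome; the terminal partial bin is
#' retained. 2-kb bins are the unit for genome-wide repair-signal clustering
#' and chromatin-tertile stratification.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param width bin width, bp.
#' @return `GRanges` of bins.
#' @examples
#' length(genome_bins(c(I = 10500), 2000))  # 6 bins, last of width 500
#' @export
genome_bins <- function(chrom_sizes, width = 2000) {
  if (width <= 0) stop("width must be positive")
  tiles <- GenomicRanges::tileGenome(chrom_sizes, tilewidth = width,
                                     cut.last.tile.in.chrom = TRUE)
  tiles
}

#' Count reads in regions with a minimum-overlap and strand rule
#'
#' A read is assigned to a region when at least `min_overlap_fraction` of the
#' read lies inside the region (inclusive boundary: a 24-nt read with exactly
#' 12 nt inside is counted). `strand_mode = "opposite"` counts reads whose
#' strand differs from the region's - the transcribed strand (TS) for
#' repair/damage reads over genes, since reads lie on the damaged strand -
#' and `"same"` counts matching strands (NTS). Regions may overlap; a read is
#' then counted in every qualifying region.
#'
#' @param reads `GRanges` of reads.
#' @param regions `GRanges` of bins/genes/windows.
#' @param strand_mode `"any"`, `"same"` or `"opposite"`.
#' @param min_overlap_fraction required fraction of the read inside the region.
#' @param normalize `"raw"` counts or `"RPM"` (reads per million mapped).
#' @param library_size total mapped reads for RPM (defaults to
#'   `length(reads)`).
#' @return numeric vector of counts (or RPM), one per region.
#' @export
count_in_bins <- function(reads, regions,
                          strand_mode = c("any", "same", "opposite"),
                          min_overlap_fraction = 0.5,
                          normalize = c("raw", "RPM"),
                          library_size = length(reads)) {
  strand_mode <- match.arg(strand_mode)
  normalize <- match.arg(normalize)
  if (strand_mode != "any" && any(as.character(strand(regions)) == "*"))
    stop("strand_mode '", strand_mode, "' requires stranded regions")
  counts <- numeric(length(regions))
  if (length(reads) > 0 && length(regions) > 0) {
    hits <- findOverlaps(reads, regions, ignore.strand = TRUE)
    q <- queryHits(hits); s <- subjectHits(hits)
    ov <- width(pintersect(granges(reads)[q], granges(regions)[s],
                           ignore.strand = TRUE))
    keep <- ov >= min_overlap_fraction * width(reads)[q]
    if (strand_mode != "any") {
      same <- as.character(strand(reads))[q] == as.character(strand(regions))[s]
      keep <- keep & if (strand_mode == "same") same else !same
    }
    counts <- tabulate(s[keep], nbins = length(regions))
  }
  if (normalize == "RPM") {
    if (library_size <= 0) stop("library_size must be positive for RPM")
    counts <- counts * 1e6 / library_size
  }
  counts
}

#' Count matrix over regions for several samples
#'
#' @param read_list named list of `GRanges` read sets.
#' @param regions `GRanges`.
#' @param ... passed to [count_in_bins()].
#' @return regions x samples matrix; per-sample library sizes in
#'   `attr(, "library_sizes")`.
#' @export
count_matrix <- function(read_list, regions, ...) {
  m <- vapply(read_list, count_in_bins, numeric(length(regions)),
              regions = regions, ...)
  attr(m, "library_sizes") <- vapply(read_list, length, integer(1))
  m
}

#' Hierarchical clustering of samples by genome-wide signal similarity
#'
#' Pairwise Spearman correlation over per-bin values, distance 1 - rho, Ward
#' linkage. Rank-based correlation makes the result invariant to monotone
#' per-sample rescaling.
#'
#' @param mat bins x samples numeric matrix (e.g. RPM over 2-kb bins).
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust`, `dist`, `correlation`, and `labels` (if `k`
#'   given).
#' @export
cluster_samples <- function(mat, k = NULL) {
  if (ncol(mat) < 2) stop("need at least 2 samples")
  if (nrow(mat) < 3) stop("need at least 3 bins")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  rho <- stats::cor(mat, method = "spearman")
  d <- as.dist(1 - rho)
  hc <- hclust(d, method = "ward.D2")
  out <- list(hclust = hc, dist = d, correlation = rho)
  if (!is.null(k)) out$labels <- cutree(hc, k = k)
  out
}

#' Select long, isolated genes for strand-specific metaprofiles
#'
#' Retains genes strictly longer than `min_length` whose distance to the
#' nearest other gene (either strand) is at least `min_gap`, so that TSS/TES
#' windows do not bleed into neighbouring transcription units.
#'
#' @param genes `GRanges`.
#' @param min_length genes must satisfy `width > min_length` (bp).
#' @param min_gap minimum distance to the nearest other gene (bp).
#' @return the retained genes.
#' @export
select_genes <- function(genes, min_length = 2000, min_gap = 500) {
  if (length(genes) == 0) return(genes)
  long <- width(genes) > min_length
  if (length(genes) == 1) return(genes[long])
  nn <- distanceToNearest(genes, ignore.strand = TRUE)
  dist <- rep(Inf, length(genes))  # genes alone on a chromosome have no neighbour
  dist[queryHits(nn)] <- mcols(nn)$distance
  genes[long & dist >= min_gap]
}

#' Rank-stratify items into near-equal groups
#'
#' Ranks items by `key_values` ascending (ties broken by item id, for
#' determinism) after optionally dropping zero-key items and trimming the top
#' `trim_top_fraction` (outlier control), then splits into `n_groups` groups
#' whose sizes differ by at most one. Quartile labels run low to high.
#'
#' @param ids item identifiers.
#' @param key_values numeric ranking key (e.g. TPM, mean ChIP signal).
#' @param n_groups number of groups (4 for quartiles, 3 for tertiles).
#' @param exclude_zero drop items with key 0 before ranking.
#' @param trim_top_fraction fraction of top-keyed items to drop (e.g. 0.005).
#' @return data.frame `id`, `key`, `group` (ordered factor, low to high).
#' @export
stratify <- function(ids, key_values, n_groups, exclude_zero = FALSE,
                     trim_top_fraction = 0) {
  stopifnot(length(ids) == length(key_values))
  keep <- rep(TRUE, length(ids))
  if (exclude_zero) keep <- key_values != 0
  ids <- ids[keep]; key_values <- key_values[keep]
  if (trim_top_fraction > 0) {
    n_trim <- floor(length(ids) * trim_top_fraction)
    if (n_trim > 0) {
      ord <- order(key_values, ids, decreasing = TRUE)
      drop <- ord[seq_len(n_trim)]
      ids <- ids[-drop]; key_values <- key_values[-drop]
    }
  }
  n <- length(ids)
  if (n < n_groups) stop("fewer items (", n, ") than groups (", n_groups, ")")
  ord <- order(key_values, ids)
  grp_sorted <- ceiling(seq_len(n) * n_groups / n)
  labels <- if (n_groups == 3) c("low", "medium", "high")
            else paste0("Q", seq_len(n_groups))
  out <- data.frame(id = ids[ord], key = key_values[ord],
                    group = factor(labels[grp_sorted], levels = labels,
                                   ordered = TRUE))
  out[order(match(out$id, ids)), , drop = FALSE]
}

#' TPM from counts and gene lengths
#'
#' `rate_i = counts_i / length_i(kb)`; `TPM_i = rate_i * 1e6 / sum(rate)`.
#' TPM always sums to 1e6 for non-degenerate input.
#'
#' @param counts per-gene read counts.
#' @param lengths gene lengths, bp.
#' @return TPM vector.
#' @export
tpm_from_counts <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / (lengths / 1000)
  tot <- sum(rate)
  if (tot == 0) {
    warning("all counts are zero; returning all-zero TPM")
    return(rate)
  }
  rate * 1e6 / tot
}

#' RPKM from counts, lengths and library size
#'
#' `RPKM = (count / length(kb)) / (library_size / 1e6)`.
#'
#' @param counts per-gene read counts.
#' @param lengths gene lengths, bp.
#' @param library_size total mapped reads.
#' @return RPKM vector.
#' @export
rpkm <- function(counts, lengths, library_size) {
  (counts / (lengths / 1000)) / (library_size / 1e6)
}

#' Strand-specific gene metaprofile
#'
#' For each gene, the window from `upstream` bp before to `downstream` bp after
#' the anchor (TSS or TES), oriented 5'->3' in transcription direction, is
#' divided into `n_bins` equal bins and reads are counted per bin under the
#' given strand rule (`"opposite"` = TS, `"same"` = NTS). Genes whose window
#' leaves the chromosome are skipped and counted.
#'
#' @param reads `GRanges` of reads.
#' @param genes stranded `GRanges`.
#' @param anchor `"TSS"` or `"TES"`.
#' @param upstream,downstream window extent around the anchor, bp (the window
#'   spans `upstream + downstream` bp; defaults follow the 1 kb upstream /
#'   500 bp downstream convention for TSS profiles).
#' @param n_bins number of bins (window span must be divisible by it).
#' @param strand_mode as in [count_in_bins()].
#' @param min_overlap_fraction as in [count_in_bins()].
#' @param library_size for RPM scaling of the mean profile; `NULL` leaves raw
#'   counts.
#' @return list with `matrix` (genes x bins, transcription direction left to
#'   right), `mean`, `ci_lower`, `ci_upper` (95% CI = mean +/- 1.96 SEM),
#'   `offsets` (bin-start bp relative to the anchor) and `n_skipped`.
#' @export
gene_metaprofile <- function(reads, genes, anchor = c("TSS", "TES"),
                             upstream = 1000, downstream = 500, n_bins = 100,
                             strand_mode = c("opposite", "same", "any"),
                             min_overlap_fraction = 0.5,
                             library_size = NULL) {
  anchor <- match.arg(anchor)
  strand_mode <- match.arg(strand_mode)
  span <- upstream + downstream
  if (span %% n_bins != 0)
    stop("window span (", span, ") must be divisible by n_bins")
  bw <- span / n_bins
  plus <- as.character(strand(genes)) != "-"
  apos <- if (anchor == "TSS") ifelse(plus, start(genes), end(genes))
          else ifelse(plus, end(genes), start(genes))
  win_start <- ifelse(plus, apos - upstream, apos - downstream + 1)
  win_end <- win_start + span - 1
  sl <- seqlengths(genes)[as.character(seqnames(genes))]
  ok <- win_start >= 1 & (is.na(sl) | win_end <= sl)
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message(n_skipped, " gene(s) skipped: metaprofile window off chromosome")
  genes <- genes[ok]; win_start <- win_start[ok]; plus <- plus[ok]
  ng <- length(genes)
  if (ng == 0) stop("no genes with valid windows")
  ## per-gene bin ranges; bin index j counts along transcription direction
  bin_no <- rep(seq_len(n_bins), ng)
  gidx <- rep(seq_len(ng), each = n_bins)
  left_index <- ifelse(plus[gidx], bin_no, n_bins - bin_no + 1)
  bstart <- win_start[gidx] + (left_index - 1) * bw
  bins <- GRanges(rep(as.character(seqnames(genes)), each = n_bins),
                  IRanges(bstart, width = bw),
                  strand = rep(as.character(strand(genes)), each = n_bins))
  counts <- count_in_bins(reads, bins, strand_mode = strand_mode,
                          min_overlap_fraction = min_overlap_fraction)
  m <- matrix(counts, nrow = ng, ncol = n_bins, byrow = TRUE)
  rownames(m) <- genes$gene_id %||% as.character(seq_len(ng))
  if (!is.null(library_size)) m <- m * 1e6 / library_size
  mu <- colMeans(m)
  sem <- apply(m, 2, stats::sd) / sqrt(ng)
  list(matrix = m, mean = mu,
       ci_lower = mu - 1.96 * sem, ci_upper = mu + 1.96 * sem,
       offsets = seq(-upstream, downstream - bw, by = bw),
       n_skipped = n_skipped)
}

#' Paired TS/NTS strand-asymmetry statistics per expression group
#'
#' Per group: the transcribed-strand fraction TS/(TS+NTS) per gene (genes with
#' TS+NTS = 0 are excluded and counted), a two-sided paired Wilcoxon
#' signed-rank test of TS vs NTS, and Benjamini-Hochberg adjustment across the
#' groups of the invocation.
#'
#' @param ts,nts per-gene TS and NTS values (e.g. RPKM), aligned.
#' @param groups factor of expression groups per gene (a single group if
#'   omitted).
#' @return data.frame per group: `n`, `n_excluded`, `mean_fraction`,
#'   `median_fraction`, `p`, `q`.
#' @export
compare_strands <- function(ts, nts, groups = NULL) {
  stopifnot(length(ts) == length(nts))
  if (is.null(groups)) groups <- factor(rep("all", length(ts)))
  groups <- droplevels(as.factor(groups))
  res <- lapply(levels(groups), function(g) {
    i <- which(groups == g)
    tot <- ts[i] + nts[i]
    inf <- tot > 0
    frac <- ts[i][inf] / tot[inf]
    d <- ts[i] - nts[i]
    nz <- d != 0  # zero differences carry no sign-rank information
    p <- if (sum(inf) < 2) NA_real_
         else if (!any(nz)) 1
         else suppressWarnings(
           wilcox.test(ts[i][nz], nts[i][nz], paired = TRUE,
                       alternative = "two.sided")$p.value)
    data.frame(group = g, n = sum(inf), n_excluded = sum(!inf),
               mean_fraction = if (sum(inf)) mean(frac) else NA_real_,
               median_fraction = if (sum(inf)) stats::median(frac) else NA_real_,
               p = p)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Classify peaks as genic or intergenic
#'
#' A peak is genic when it overlaps any gene body extended `upstream` bp
#' upstream of its TSS (strand-aware extension); otherwise intergenic.
#'
#' @param peaks `GRanges`.
#' @param genes stranded `GRanges`.
#' @param upstream promoter extension past the TSS, bp (default 200).
#' @return character vector `"genic"`/`"intergenic"`, one per peak.
#' @export
classify_peaks <- function(peaks, genes, upstream = 200) {
  ext <- suppressWarnings(resize(genes, width(genes) + upstream, fix = "end"))
  ext <- trim(ext)
  genic <- overlapsAny(peaks, ext, ignore.strand = TRUE)
  ifelse(genic, "genic", "intergenic")
}
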