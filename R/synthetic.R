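#' Configuration for the synthetic UV damage/repair data generator
#'
#' Defines the study conditions the generator emulates: an L1-larva-like
#' experiment with strand-biased XR-seq reads peaking at 24 nt and carrying a
#' dipyrimidine 6 nt from the 3' end, Damage-seq reads whose 5' ends sit two
#' nucleotides past a planted lesion dinucleotide, expression-dependent
#' transcribed-strand repair bias, time-decaying damage with
#' linker-preferential repair, and 10-bp (helical) plus 160-bp (nucleosome
#' repeat) periodic modulation of lesion density around dyads and accessible
#' peaks.
#'
#' @param genome_length bp per chromosome.
#' @param n_chroms number of chromosomes (named I, II, ...).
#' @param gc_content GC fraction of the iid toy genome (default 0.36,
#'   nematode-like).
#' @param n_genes number of non-overlapping genes to place.
#' @param gene_length_range inclusive bp bounds for gene lengths.
#' @param min_gene_gap minimum gap between adjacent genes, bp.
#' @param expression_meanlog,expression_sdlog log-normal law for TPM of
#'   expressed genes.
#' @param zero_expression_fraction fraction of genes with TPM 0.
#' @param ts_bias_by_quartile expected TS/(TS+NTS) per expression quartile,
#'   low to high.
#' @param xr_lengths,xr_length_prob discrete XR read-length law (default
#'   10-32 nt peaking at 24 nt).
#' @param damage_motif_offset dipyrimidine offset from the XR read 3' end: the
#'   default 6 places the dinucleotide at 0-based read indices (L-7, L-6),
#'   matching dual incisions 16 nt 5' and 6 nt 3' of the lesion.
#' @param n_reads reads (XR) or lesions (Damage) per sample.
#' @param damage_read_length aligned length of Damage-seq reads, bp.
#' @param n_peaks,peak_flank accessible-chromatin peak summits and profiled
#'   half-width, bp.
#' @param n_dyads,dyad_flank nucleosome dyad centres and profiled half-width.
#' @param periodic_amplitudes named numeric: cosine amplitude of lesion-density
#'   modulation per period in bp (names), e.g. `c("160" = 0.5, "10" = 0.4)`;
#'   the 160-bp term applies around peak summits, the 10-bp term around dyads.
#'   Amplitudes must lie in [0, 1] (larger would imply negative densities).
#' @param peak_center_dip_depth fractional depletion of lesion density at peak
#'   summits (protein-bound DNA forms fewer lesions); Gaussian dip of
#'   `peak_center_dip_sd` bp.
#' @param peak_center_dip_sd width of the central dip, bp.
#' @param timepoint_decay named survival fractions per timepoint (damage
#'   remaining), e.g. `c("0h" = 1, "48h" = .08)`.
#' @param linker_repair_factor amplitude of the 160-bp cosine modulating lesion
#'   survival near peaks at later timepoints: nucleosome-wrapped lesions
#'   survive more, linker lesions are preferentially repaired.
#' @param noise_lesion_fraction fraction of planted lesions placed at
#'   non-dipyrimidine sites (to exercise the dipyrimidine filter).
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6,
                       n_chroms = 1,
                       gc_content = 0.36,
                       n_genes = 120,
                       gene_length_range = c(2200, 6000),
                       min_gene_gap = 600,
                       expression_meanlog = 2,
                       expression_sdlog = 1.5,
                       zero_expression_fraction = 0.1,
                       ts_bias_by_quartile = c(0.5, 0.55, 0.65, 0.75),
                       xr_lengths = 10:32,
                       xr_length_prob = NULL,
                       damage_motif_offset = 6,
                       n_reads = 50000,
                       damage_read_length = 50,
                       n_peaks = 40,
                       peak_flank = 1000,
                       n_dyads = 200,
                       dyad_flank = 80,
                       periodic_amplitudes = c("160" = 0.5, "10" = 0.4),
                       peak_center_dip_depth = 0.4,
                       peak_center_dip_sd = 75,
                       timepoint_decay = c("0h" = 1, "8h" = 0.5,
                                           "24h" = 0.2, "48h" = 0.08),
                       linker_repair_factor = 0.3,
                       noise_lesion_fraction = 0,
                       seed = 1L) {
  if (is.null(xr_length_prob)) {
    xr_length_prob <- stats::dnorm(xr_lengths, mean = 24, sd = 2.5)
    xr_length_prob <- xr_length_prob / sum(xr_length_prob)
  }
  cfg <- list(genome_length = genome_length, n_chroms = n_chroms,
              gc_content = gc_content, n_genes = n_genes,
              gene_length_range = gene_length_range,
              min_gene_gap = min_gene_gap,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              zero_expression_fraction = zero_expression_fraction,
              ts_bias_by_quartile = ts_bias_by_quartile,
              xr_lengths = xr_lengths, xr_length_prob = xr_length_prob,
              damage_motif_offset = damage_motif_offset,
              n_reads = n_reads, damage_read_length = damage_read_length,
              n_peaks = n_peaks, peak_flank = peak_flank,
              n_dyads = n_dyads, dyad_flank = dyad_flank,
              periodic_amplitudes = periodic_amplitudes,
              peak_center_dip_depth = peak_center_dip_depth,
              peak_center_dip_sd = peak_center_dip_sd,
              timepoint_decay = timepoint_decay,
              linker_repair_factor = linker_repair_factor,
              noise_lesion_fraction = noise_lesion_fraction,
              seed = as.integer(seed))
  fr <- c(cfg$gc_content, cfg$zero_expression_fraction,
          cfg$ts_bias_by_quartile, cfg$noise_lesion_fraction,
          cfg$timepoint_decay, cfg$peak_center_dip_depth)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (any(cfg$periodic_amplitudes > 1) || any(cfg$periodic_amplitudes < 0))
    stop("periodic amplitudes must lie in [0, 1] (negative densities otherwise)")
  if (abs(sum(cfg$xr_length_prob) - 1) > 1e-8 || any(cfg$xr_length_prob < 0))
    stop("xr_length_prob must be a probability vector")
  if (length(cfg$ts_bias_by_quartile) != 4)
    stop("ts_bias_by_quartile must have 4 entries")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chroms, "chromosome(s) x", x$genome_length, "bp,",
      x$n_genes, "genes,", x$n_reads, "reads/sample, seed", x$seed, "\n")
  invisible(x)
}

chrom_names <- function(n) {
  as.character(utils::as.roman(seq_len(n)))
}

#' Build a toy genome with annotation, peaks, dyads and expression
#'
#' Generates an iid-base genome at the configured GC content, places
#' non-overlapping genes respecting the minimum gap, assigns log-normal TPM
#' values (with a configurable zero-expression fraction), and scatters peak
#' summits and nucleosome dyad centres with enough clearance from chromosome
#' ends for profiling. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `genes` (`GRanges` with
#'   `gene_id`), `expression` (data.frame `gene_id`, `tpm`), `peaks` and
#'   `dyads` (width-1 `GRanges` summit/dyad positions; peaks carry an
#'   `enrichment` score), and the `config`.
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gc <- config$gc_content
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chroms <- chrom_names(config$n_chroms)
  genome <- DNAStringSet(vapply(chroms, function(chr) {
    paste(sample(c("A", "C", "G", "T"), config$genome_length,
                 replace = TRUE, prob = probs), collapse = "")
  }, character(1)))
  names(genome) <- chroms

  genes <- GRanges()
  if (config$n_genes > 0) {
    per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
    glist <- list()
    for (ci in seq_along(chroms)) {
      ng <- per_chrom[ci]
      if (ng == 0) next
      lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                     ng, replace = TRUE)
      slack <- config$genome_length - sum(lens) - (ng + 1) * config$min_gene_gap
      if (slack < 0)
        stop("genes do not fit: need ", sum(lens) + (ng + 1) * config$min_gene_gap,
             " bp, have ", config$genome_length)
      ## distribute the slack over the ng + 1 inter-gene gaps at random
      cuts <- sort(runif(ng))
      extra <- floor(diff(c(0, cuts, 1)) * slack)
      gaps <- config$min_gene_gap + extra  # gap before each gene (+ terminal)
      starts <- cumsum(gaps[seq_len(ng)]) + cumsum(c(0, lens[-ng])) + 1
      glist[[ci]] <- GRanges(chroms[ci], IRanges(starts, width = lens),
                             strand = sample(c("+", "-"), ng, replace = TRUE))
    }
    genes <- do.call(c, glist)
    genes$gene_id <- sprintf("g%04d", seq_along(genes))
  }

  tpm <- numeric(length(genes))
  if (length(genes)) {
    expressed <- runif(length(genes)) >= config$zero_expression_fraction
    tpm[expressed] <- rlnorm(sum(expressed), config$expression_meanlog,
                             config$expression_sdlog)
  }
  expression <- data.frame(gene_id = genes$gene_id %||% character(0),
                           tpm = tpm)

  clear_pk <- config$peak_flank + 50
  peaks <- GRanges()
  if (config$n_peaks > 0) {
    pos <- scatter_positions(config$n_peaks, config$genome_length, clear_pk,
                             min_sep = 2 * config$peak_flank + 100)
    chr <- sample(chroms, config$n_peaks, replace = TRUE)
    peaks <- GRanges(chr, IRanges(pos, width = 1), strand = "*",
                     enrichment = round(rlnorm(config$n_peaks, 3, 0.8), 2))
  }
  clear_dy <- config$dyad_flank + 20
  dyads <- GRanges()
  if (config$n_dyads > 0) {
    pos <- scatter_positions(config$n_dyads, config$genome_length, clear_dy,
                             min_sep = 2 * config$dyad_flank + 40)
    chr <- sample(chroms, config$n_dyads, replace = TRUE)
    dyads <- GRanges(chr, IRanges(pos, width = 1), strand = "*")
  }
  sl <- setNames(rep(config$genome_length, config$n_chroms), chroms)
  for (nm in c("genes", "peaks", "dyads")) {
    gr <- get(nm)
    if (length(gr)) {
      seqlevels(gr) <- chroms
      seqlengths(gr) <- sl
      assign(nm, gr)
    }
  }
  ## sorted dipyrimidine-site catalogues (1-based dinucleotide starts), cached
  ## so repeated read simulations on the same genome skip the sequence scan
  site_catalog <- lapply(as.list(genome), function(s)
    list(pyr = dinuc_positions(s, "pyr"), pur = dinuc_positions(s, "pur")))
  list(genome = genome, genes = genes, expression = expression,
       peaks = peaks, dyads = dyads, site_catalog = site_catalog,
       config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## n positions in [clear+1, L-clear] at pairwise separation >= min_sep
scatter_positions <- function(n, L, clear, min_sep) {
  lo <- clear + 1
  hi <- L - clear
  span <- hi - lo - (n - 1) * min_sep
  if (span < 0) stop("cannot place ", n, " anchors at separation ", min_sep)
  offs <- sort(sample.int(span + 1, n, replace = TRUE)) - 1L
  lo + offs + (seq_len(n) - 1L) * min_sep
}

#' Write the toy dataset to standard formats
#'
#' Emits FASTA (genome), GFF3 (genes), BED (peaks, dyads) and TSV (expression)
#' files under `dir`.
#'
#' @param sim output of [build_toy_genome()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_toy_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.gff3"),
             peaks = file.path(dir, "peaks.bed"),
             dyads = file.path(dir, "dyads.bed"),
             expression = file.path(dir, "expression.tsv"))
  writeXStringSet(sim$genome, paths["genome"])
  write_genes_gff3(sim$genes, paths["genes"])
  pk <- granges(sim$peaks)
  pk$score <- sim$peaks$enrichment
  rtracklayer::export(pk, paths["peaks"], format = "BED")
  rtracklayer::export(granges(sim$dyads), paths["dyads"], format = "BED")
  write_expression_tsv(sim$expression, paths["expression"])
  invisible(paths)
}

## 1-based start positions of forward-strand dinucleotides matching `kind`
## kind "pyr": both bases C/T (a plus-strand dipyrimidine)
## kind "pur": both bases A/G (reverse complement is a minus-strand dipyrimidine)
dinuc_positions <- function(chrseq, kind = c("pyr", "pur")) {
  kind <- match.arg(kind)
  s <- strsplit(as.character(chrseq), "")[[1]]
  is_y <- if (kind == "pyr") s %in% c("C", "T") else s %in% c("A", "G")
  which(is_y[-length(is_y)] & is_y[-1])
}

#' Simulate XR-seq reads with expression-dependent strand bias
#'
#' Reads are sampled over gene bodies of expressed genes (gene picked with
#' probability proportional to gene length). Each read's strand is the
#' transcribed strand (opposite the gene's annotated strand, since XR-seq reads
#' are the excised damaged-strand oligonucleotides) with probability equal to
#' the gene's expression-quartile TS bias. Lengths follow the configured law,
#' and read start positions are chosen so that the read carries a dipyrimidine
#' at `damage_motif_offset` nt from its 3' end.
#'
#' @param sim output of [build_toy_genome()].
#' @param config optional [sim_config()] override (defaults to `sim$config`).
#' @param n_reads optional read count override.
#' @return list with `reads` (`GRanges`, mcols `mapq`, `sample`) and `truth`
#'   (data.frame per read: `gene_id`, `quartile`, `is_ts`).
#' @export
simulate_xr_reads <- function(sim, config = sim$config, n_reads = config$n_reads) {
  set.seed(config$seed + 1L)
  expr <- sim$expression
  genes <- sim$genes
  keep <- expr$tpm > 0
  if (!any(keep)) stop("no expressed genes to sample reads from")
  genes <- genes[keep]
  expr <- expr[keep, ]
  if (n_reads == 0) {
    return(list(reads = GRanges(seqlengths = seqlengths(sim$genes)),
                truth = data.frame(gene_id = character(0),
                                   quartile = integer(0), is_ts = logical(0))))
  }
  strat <- stratify(expr$gene_id, expr$tpm, n_groups = 4)
  quart <- as.integer(strat$group[match(expr$gene_id, strat$id)])

  ## dipyrimidine position catalogues per chromosome and strand sense
  catalog <- sim$site_catalog %||% lapply(as.list(sim$genome), function(s)
    list(pyr = dinuc_positions(s, "pyr"), pur = dinuc_positions(s, "pur")))
  pyr <- lapply(catalog, `[[`, "pyr")
  pur <- lapply(catalog, `[[`, "pur")

  gi <- sample.int(length(genes), n_reads, replace = TRUE,
                   prob = width(genes))
  bias <- config$ts_bias_by_quartile[quart[gi]]
  is_ts <- runif(n_reads) < bias
  gene_strand <- as.character(strand(genes))[gi]
  ## TS read lies opposite the gene strand
  read_strand <- ifelse(is_ts, ifelse(gene_strand == "+", "-", "+"), gene_strand)
  len <- sample(config$xr_lengths, n_reads, replace = TRUE,
                prob = config$xr_length_prob)

  ## Placement: a + read of length L starting at S carries its read-orientation
  ## dinucleotide at forward start D = S + L - o - 1 (a pyrimidine pair); a
  ## - read at D = S + o - 1 (a purine pair on the forward strand). Group
  ## reads by (gene, strand, length), locate each group's admissible catalogue
  ## slice with two batched binary searches, then sample starts per group.
  o <- config$damage_motif_offset
  starts <- integer(n_reads)
  okv <- logical(n_reads)
  gene_chr <- as.character(seqnames(genes))
  gene_start <- start(genes); gene_end <- end(genes)
  key <- paste0(gi, "_", read_strand, "_", len)
  grp <- split(seq_len(n_reads), key)
  rep_i <- vapply(grp, `[`, integer(1), 1L)
  g_gi <- gi[rep_i]; g_str <- read_strand[rep_i]; g_len <- len[rep_i]
  g_chr <- gene_chr[g_gi]
  g_dlo <- ifelse(g_str == "+", gene_start[g_gi] + g_len - o - 1L,
                  gene_start[g_gi] + o - 1L)
  g_dhi <- ifelse(g_str == "+", gene_end[g_gi] - o,
                  gene_end[g_gi] - g_len + o)
  g_i1 <- integer(length(grp)); g_i2 <- integer(length(grp))
  for (chr in unique(g_chr)) {
    for (kind in c("+", "-")) {
      sel <- which(g_chr == chr & g_str == kind)
      if (!length(sel)) next
      cand <- if (kind == "+") pyr[[chr]] else pur[[chr]]
      g_i1[sel] <- findInterval(g_dlo[sel] - 1L, cand) + 1L
      g_i2[sel] <- findInterval(g_dhi[sel], cand)
    }
  }
  for (k in seq_along(grp)) {
    if (g_i2[k] < g_i1[k]) next
    g <- grp[[k]]
    cand <- if (g_str[k] == "+") pyr[[g_chr[k]]] else pur[[g_chr[k]]]
    D <- cand[g_i1[k] - 1L +
                sample.int(g_i2[k] - g_i1[k] + 1L, length(g), replace = TRUE)]
    starts[g] <- if (g_str[k] == "+") D - g_len[k] + o + 1L else D - o + 1L
    okv[g] <- TRUE
  }
  if (!any(okv))
    stop("no dipyrimidine placement sites available in the gene set")
  reads <- GRanges(as.character(seqnames(genes))[gi[okv]],
                   IRanges(starts[okv], width = len[okv]),
                   strand = read_strand[okv],
                   mapq = 42L, sample = "xr_sim",
                   seqlengths = seqlengths(sim$genes))
  truth <- data.frame(gene_id = genes$gene_id[gi[okv]],
                      quartile = quart[gi[okv]],
                      is_ts = is_ts[okv])
  list(reads = reads, truth = truth)
}

#' Simulate Damage-seq reads with planted lesions and periodic structure
#'
#' Plants `n_reads` lesions at dipyrimidine dinucleotides (both strands) with
#' site probabilities modulated multiplicatively by (i) a cosine of the
#' configured 160-bp amplitude around peak summits, (ii) a cosine of the 10-bp
#' amplitude around dyad centres, and (iii) a Gaussian dip at peak summits.
#' Each surviving lesion emits one read whose 5' end sits exactly two
#' nucleotides past the lesion dinucleotide in read orientation - the exact
#' inverse of [infer_damage_windows()] geometry, under the same strand
#' `convention`. Later timepoints keep each lesion with probability
#' `survival * (1 + linker_repair_factor * cos(2 pi d / 160))` near peaks
#' (nucleosome-wrapped lesions persist; linker lesions are repaired first) and
#' `survival` elsewhere. Mock (uniform genomic) and naked-DNA (dipyrimidine
#' density only, no chromatin modulation) control read sets are also emitted.
#'
#' @param sim output of [build_toy_genome()].
#' @param config optional [sim_config()] override.
#' @param convention lesion strand bookkeeping, as in [infer_damage_windows()].
#' @return list with `reads` (named list of `GRanges` per timepoint, each read
#'   carrying `lesion_id`), `naked`, `mock` (`GRanges`), and `truth`
#'   (data.frame per planted lesion: `lesion_id`, `chrom`, `dinuc_start`,
#'   `damage_strand`, `is_dipyrimidine`, plus one logical survival column per
#'   timepoint).
#' @export
simulate_damage_reads <- function(sim, config = sim$config,
                                  convention = c("opposite", "read")) {
  convention <- match.arg(convention)
  set.seed(config$seed + 2L)
  amp <- config$periodic_amplitudes
  a160 <- unname(amp[names(amp) == "160"]) %||% 0
  a10 <- unname(amp[names(amp) == "10"]) %||% 0
  if (length(a160) == 0) a160 <- 0
  if (length(a10) == 0) a10 <- 0
  if ((a160 > 0 || a10 > 0) && length(sim$peaks) + length(sim$dyads) == 0)
    stop("periodic amplitudes set but no peaks/dyads defined")

  L <- config$damage_read_length
  catalog <- sim$site_catalog %||% lapply(as.list(sim$genome), function(s)
    list(pyr = dinuc_positions(s, "pyr"), pur = dinuc_positions(s, "pur")))
  site_chr <- character(0); site_pos <- integer(0); site_strand <- character(0)
  site_dipyr <- logical(0)
  for (chr in names(sim$genome)) {
    p1 <- catalog[[chr]]$pyr  # lesion on + strand
    p2 <- catalog[[chr]]$pur  # lesion on - strand
    site_chr <- c(site_chr, rep(chr, length(p1) + length(p2)))
    site_pos <- c(site_pos, p1, p2)
    site_strand <- c(site_strand, rep("+", length(p1)), rep("-", length(p2)))
    site_dipyr <- c(site_dipyr, rep(TRUE, length(p1) + length(p2)))
    if (config$noise_lesion_fraction > 0) {
      ## non-dipyrimidine candidate sites (mixed dinucleotides), both strands
      all_pos <- seq_len(length(sim$genome[[chr]]) - 1L)
      bad <- setdiff(setdiff(all_pos, p1), p2)
      site_chr <- c(site_chr, rep(chr, 2 * length(bad)))
      site_pos <- c(site_pos, bad, bad)
      site_strand <- c(site_strand, rep("+", length(bad)), rep("-", length(bad)))
      site_dipyr <- c(site_dipyr, rep(FALSE, 2 * length(bad)))
    }
  }
  ## clearance so the read and its inferred window stay on-chromosome
  ok <- site_pos > L + 8L & site_pos < width(sim$genome)[match(site_chr, names(sim$genome))] - L - 8L
  site_chr <- site_chr[ok]; site_pos <- site_pos[ok]
  site_strand <- site_strand[ok]; site_dipyr <- site_dipyr[ok]
  ## sort by (chrom, position) so anchors can slice by binary search
  ord <- order(site_chr, site_pos)
  site_chr <- site_chr[ord]; site_pos <- site_pos[ord]
  site_strand <- site_strand[ord]; site_dipyr <- site_dipyr[ord]
  chr_idx <- split(seq_along(site_pos), site_chr)

  ## chromatin weights: cosine terms around anchors plus the summit dip
  wts <- rep(1, length(site_pos))
  phase160 <- rep(NA_real_, length(site_pos))  # distance to nearest peak summit
  add_modulation <- function(anchors, flank, fn) {
    for (i in seq_along(anchors)) {
      chr <- as.character(seqnames(anchors))[i]
      a <- start(anchors)[i]
      v <- chr_idx[[chr]]
      if (is.null(v)) next
      pos <- site_pos[v]
      i1 <- findInterval(a - flank - 1L, pos) + 1L
      i2 <- findInterval(a + flank, pos)
      if (i2 >= i1) {
        j <- v[i1:i2]
        fn(j, site_pos[j] - a)
      }
    }
  }
  if (length(sim$peaks)) {
    add_modulation(sim$peaks, config$peak_flank, function(j, d) {
      w <- 1 + a160 * cos(2 * pi * d / 160)
      w <- w * (1 - config$peak_center_dip_depth *
                  exp(-d^2 / (2 * config$peak_center_dip_sd^2)))
      wts[j] <<- wts[j] * w
      phase160[j] <<- d
    })
  }
  if (length(sim$dyads)) {
    add_modulation(sim$dyads, config$dyad_flank, function(j, d) {
      wts[j] <<- wts[j] * (1 + a10 * cos(2 * pi * d / 10))
    })
  }

  nles <- config$n_reads
  base_w <- ifelse(site_dipyr, 1, 0)
  nf <- config$noise_lesion_fraction
  if (nf > 0) {
    ## noise lesions get total mass nf / (1 - nf) relative to dipyrimidines
    n_true <- sum(site_dipyr); n_noise <- sum(!site_dipyr)
    base_w[!site_dipyr] <- (nf / (1 - nf)) * n_true / n_noise
  }
  les <- sample.int(length(site_pos), nles, replace = TRUE,
                    prob = base_w * wts)
  truth <- data.frame(lesion_id = seq_len(nles),
                      chrom = site_chr[les],
                      dinuc_start = site_pos[les],
                      damage_strand = site_strand[les],
                      is_dipyrimidine = site_dipyr[les],
                      stringsAsFactors = FALSE)
  d160 <- phase160[les]

  tps <- names(config$timepoint_decay)
  reads <- vector("list", length(tps)); names(reads) <- tps
  for (k in seq_along(tps)) {
    s <- config$timepoint_decay[k]
    p <- rep(s, nles)
    near <- !is.na(d160)
    if (s < 1 && config$linker_repair_factor > 0) {
      p[near] <- pmin(1, pmax(0, s * (1 + config$linker_repair_factor *
                                        cos(2 * pi * d160[near] / 160))))
    }
    surv <- if (s >= 1) rep(TRUE, nles) else runif(nles) < p
    truth[[paste0("survives_", tps[k])]] <- surv
    reads[[k]] <- lesions_to_reads(truth[surv, ], L, convention,
                                   seqlengths(sim$genes), sample_id = tps[k])
  }
  naked_sites <- sample.int(length(site_pos), nles, replace = TRUE,
                            prob = base_w)
  naked_truth <- data.frame(lesion_id = seq_len(nles),
                            chrom = site_chr[naked_sites],
                            dinuc_start = site_pos[naked_sites],
                            damage_strand = site_strand[naked_sites])
  naked <- lesions_to_reads(naked_truth, L, convention,
                            seqlengths(sim$genes), sample_id = "naked")
  ## mock control: no UV, uniform genomic background
  mock_chr <- sample(names(sim$genome), nles, replace = TRUE,
                     prob = width(sim$genome))
  mock_start <- floor(runif(nles, 10, width(sim$genome)[
    match(mock_chr, names(sim$genome))] - L - 10))
  mock <- GRanges(mock_chr, IRanges(mock_start, width = L),
                  strand = sample(c("+", "-"), nles, replace = TRUE),
                  mapq = 40L, sample = "mock",
                  seqlengths = seqlengths(sim$genes))
  list(reads = reads, naked = naked, mock = mock, truth = truth)
}

## inverse of infer_damage_windows geometry
lesions_to_reads <- function(truth, read_length, convention, seqlens,
                             sample_id = "damage") {
  read_strand <- if (convention == "opposite")
    ifelse(truth$damage_strand == "+", "-", "+") else truth$damage_strand
  D <- truth$dinuc_start
  start <- ifelse(read_strand == "+", D + 2L, D - read_length)
  GRanges(truth$chrom, IRanges(start, width = read_length),
          strand = read_strand, mapq = 40L, sample = sample_id,
          lesion_id = truth$lesion_id, seqlengths = seqlens)
}

#' Simulate binned signal tracks from class profiles
#'
#' Emits one signal vector per sample: its class profile plus iid Gaussian
#' noise. A fixture generator for clustering and tertile-stratification tests.
#'
#' @param class_profiles list (or matrix columns) of per-bin class mean
#'   profiles, all the same length.
#' @param n_samples samples per class.
#' @param noise_sd iid Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return matrix bins x samples; column names `<class>_<replicate>`, class
#'   labels in `attr(, "class_labels")`.
#' @export
simulate_signal_tracks <- function(class_profiles, n_samples, noise_sd, seed = 1L) {
  if (is.matrix(class_profiles))
    class_profiles <- lapply(seq_len(ncol(class_profiles)),
                             function(j) class_profiles[, j])
  nb <- unique(lengths(class_profiles))
  if (length(nb) != 1) stop("class profiles must share a length")
  set.seed(seed)
  ncl <- length(class_profiles)
  out <- matrix(0, nb, ncl * n_samples)
  labs <- character(ncl * n_samples)
  k <- 0
  for (c in seq_len(ncl)) {
    for (s in seq_len(n_samples)) {
      k <- k + 1
      out[, k] <- class_profiles[[c]] + rnorm(nb, 0, noise_sd)
      labs[k] <- as.character(c)
    }
  }
  colnames(out) <- paste0("class", labs, "_", rep(seq_len(n_samples), ncl))
  attr(out, "class_labels") <- labs
  out
}
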