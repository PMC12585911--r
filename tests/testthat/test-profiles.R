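test_that("genome bins tile chromosomes and keep the terminal partial bin", {
  b1 <- genome_bins(c(I = 10000), 2000)
  expect_equal(length(b1), 5)
  expect_true(all(width(b1) == 2000))
  b2 <- genome_bins(c(I = 10500), 2000)
  expect_equal(length(b2), 6)
  expect_equal(width(b2)[6], 500)
  sizes <- c(I = 10500, II = 4000, III = 999)
  expect_equal(length(genome_bins(sizes, 2000)), sum(ceiling(sizes / 2000)))
})

test_that("fractional-overlap counting matches the brute-force oracle", {
  ## inclusive boundary: a 24-nt read with exactly 12 nt inside is counted
  bin <- GRanges("I", IRanges(1001, 2000), strand = "+")
  half_in <- alignments("I", 1989, 2012, "+", mapq = 30)   # 12 nt inside
  expect_equal(count_in_bins(half_in, bin), 1)
  eleven_in <- alignments("I", 1990, 2013, "+", mapq = 30) # 11 nt inside
  expect_equal(count_in_bins(eleven_in, bin), 0)

  ## a + read over a + gene is NTS: not counted under strand_mode = opposite
  gene <- GRanges("I", IRanges(1000, 3000), strand = "+")
  plus_read <- alignments("I", 1500, 1523, "+", mapq = 30)
  expect_equal(count_in_bins(plus_read, gene, strand_mode = "opposite"), 0)
  expect_equal(count_in_bins(plus_read, gene, strand_mode = "same"), 1)

  ## random fixture vs O(n*m) enumeration, all strand modes
  set.seed(8)
  reads <- alignments(sample(c("I", "II"), 300, TRUE),
                      st <- sample(9000, 300, TRUE),
                      st + sample(15:40, 300, TRUE),
                      sample(c("+", "-"), 300, TRUE), mapq = 30)
  regions <- GRanges(sample(c("I", "II"), 30, TRUE),
                     IRanges(rs <- sample(9000, 30, TRUE),
                             rs + sample(50:500, 30, TRUE)),
                     strand = sample(c("+", "-"), 30, TRUE))
  for (m in c("any", "same", "opposite")) {
    expect_equal(count_in_bins(reads, regions, strand_mode = m),
                 brute_force_counts(reads, regions, strand_mode = m),
                 info = m)
  }

  ## strand-swap symmetry: flipping read strands swaps TS and NTS exactly
  flipped <- reads
  strand(flipped) <- ifelse(as.character(strand(reads)) == "+", "-", "+")
  expect_equal(count_in_bins(reads, regions, strand_mode = "same"),
               count_in_bins(flipped, regions, strand_mode = "opposite"))

  expect_error(count_in_bins(reads, GRanges("I", IRanges(1, 100)),
                             strand_mode = "same"), "stranded")
})

test_that("RPM normalization is the printed formula and scale-invariant", {
  bins <- genome_bins(c(I = 10000), 1000)
  reads <- alignments("I", c(100, 150, 5000), c(123, 173, 5023), "+", mapq = 30)
  rpm <- count_in_bins(reads, bins, normalize = "RPM")
  expect_equal(rpm[1], 2 * 1e6 / 3)
  ## 10x library replication leaves RPM bit-identical
  reads10 <- rep(reads, 10)
  expect_identical(count_in_bins(reads10, bins, normalize = "RPM"),
                   count_in_bins(reads, bins, normalize = "RPM"))
})

test_that("sample clustering is rank-based, Ward-linked and recovers classes", {
  set.seed(10)
  prof <- list(rep(c(1, 5), 100), rep(c(4, 2), 100))
  mat <- simulate_signal_tracks(prof, n_samples = 5, noise_sd = 0.3, seed = 3)
  cl <- cluster_samples(mat, k = 2)
  expect_equal(length(unique(cl$labels[1:5])), 1)
  expect_equal(length(unique(cl$labels[6:10])), 1)
  expect_true(cl$labels[1] != cl$labels[6])

  ## duplicated sample: distance 0
  dup <- cbind(mat, mat[, 1])
  d <- cluster_samples(dup)$dist
  expect_equal(as.matrix(d)[1, 11], 0)

  ## Spearman: invariant to monotone rescaling of one sample
  resc <- mat
  resc[, 2] <- exp(resc[, 2] / 2)
  expect_equal(as.matrix(cluster_samples(mat)$dist),
               as.matrix(cluster_samples(resc)$dist))

  const <- mat
  const[, 3] <- 1
  colnames(const)[3] <- "flat"
  expect_error(cluster_samples(const), "flat")
})

test_that("gene selection enforces strict length and neighbour-gap rules", {
  ## single short gene: 1999 bp is not > 2000
  g1 <- GRanges("I", IRanges(1000, 2998), strand = "+", gene_id = "a")
  expect_equal(length(select_genes(g1)), 0)
  g2 <- GRanges("I", IRanges(1000, 2999), strand = "+", gene_id = "a")
  expect_equal(length(select_genes(g2)), 0)   # exactly 2000 bp: strict >
  g3 <- GRanges("I", IRanges(1000, 3000), strand = "+", gene_id = "a")
  expect_equal(length(select_genes(g3)), 1)   # 2001 bp kept

  ## brute-force oracle on a random annotation
  set.seed(12)
  st <- sort(sample(1e5, 30))
  genes <- GRanges("I", IRanges(st, st + sample(1500:4000, 30, TRUE)),
                   strand = sample(c("+", "-"), 30, TRUE),
                   gene_id = sprintf("g%02d", 1:30))
  got <- select_genes(genes, min_length = 2000, min_gap = 500)
  keep <- vapply(seq_along(genes), function(i) {
    if (width(genes)[i] <= 2000) return(FALSE)
    dmin <- min(vapply(seq_along(genes)[-i], function(j) {
      gap <- max(start(genes)[i], start(genes)[j]) -
        min(end(genes)[i], end(genes)[j]) - 1
      max(gap, 0)
    }, numeric(1)))
    dmin >= 500
  }, logical(1))
  expect_equal(got$gene_id, genes$gene_id[keep])
})

test_that("stratification splits ranked items into near-equal deterministic groups", {
  s <- stratify(letters[1:8], c(5, 1, 7, 3, 8, 2, 6, 4), n_groups = 4)
  expect_equal(as.vector(table(s$group)), c(2, 2, 2, 2))
  expect_equal(s$group[s$id == "b"], s$group[s$id == "f"])  # keys 1 and 2: Q1

  s2 <- stratify(sprintf("i%04d", 1:1000), runif(1000), n_groups = 4,
                 trim_top_fraction = 0.005)
  expect_equal(nrow(s2), 995)

  ## all-tied keys: grouping equals the id-order split
  s3 <- stratify(c("d", "b", "a", "c"), rep(1, 4), n_groups = 2)
  expect_equal(s3$group[match(c("a", "b"), s3$id)],
               factor(c("Q1", "Q1"), levels = c("Q1", "Q2"), ordered = TRUE))
  expect_equal(as.character(s3$group[match(c("c", "d"), s3$id)]), c("Q2", "Q2"))

  ## zero exclusion and group-count guard
  s4 <- stratify(letters[1:6], c(0, 0, 1, 2, 3, 4), n_groups = 2,
                 exclude_zero = TRUE)
  expect_equal(nrow(s4), 4)
  expect_error(stratify(letters[1:3], 1:3, n_groups = 4), "fewer items")
})

test_that("TPM and RPKM follow the printed formulas", {
  expect_equal(tpm_from_counts(10, 500), 1e6)
  expect_equal(tpm_from_counts(c(10, 10), c(1000, 2000)),
               c(2e6 / 3, 1e6 / 3))
  set.seed(3)
  tpm <- tpm_from_counts(rpois(50, 100), sample(500:5000, 50))
  expect_equal(sum(tpm), 1e6, tolerance = 1e-9)
  expect_warning(z <- tpm_from_counts(c(0, 0), c(1000, 2000)), "zero")
  expect_equal(z, c(0, 0))
  ## RPKM = (reads / length kb) / (total reads / 1e6)
  expect_equal(rpkm(20, 2000, 2e6), (20 / 2) / 2)
})

test_that("gene metaprofiles are oriented along transcription", {
  gn <- GRanges("I", IRanges(5000, 9000), strand = "+", gene_id = "gp",
                seqlengths = c(I = 20000))
  ## reads (minus strand = TS for a + gene) in the first 15 bp of the
  ## 1.5-kb/100-bin TSS window => all counts in bin 1
  reads <- alignments("I", rep(4000, 10), rep(4014, 10), "-", mapq = 30)
  prof <- gene_metaprofile(reads, gn, anchor = "TSS", strand_mode = "opposite")
  expect_equal(sum(prof$matrix), 10)
  expect_equal(unname(prof$matrix[1, 1]), 10)
  expect_equal(prof$offsets[1], -1000)

  ## mirror: same geometry on a - gene lands in bin 1 after orientation
  gm <- GRanges("I", IRanges(5000, 9000), strand = "-", gene_id = "gm",
                seqlengths = c(I = 20000))
  reads_m <- alignments("I", rep(9986, 10), rep(10000, 10), "+", mapq = 30)
  prof_m <- gene_metaprofile(reads_m, gm, anchor = "TSS",
                             strand_mode = "opposite")
  expect_equal(unname(prof_m$matrix[1, 1]), 10)

  ## genes whose window leaves the chromosome are skipped and counted
  edge <- GRanges("I", IRanges(c(500, 5000), c(3000, 9000)), strand = "+",
                  gene_id = c("e", "gp"), seqlengths = c(I = 20000))
  expect_message(pe <- gene_metaprofile(reads, edge, anchor = "TSS"), "skipped")
  expect_equal(pe$n_skipped, 1)
  expect_equal(nrow(pe$matrix), 1)
})

test_that("strand comparison reports fractions, Wilcoxon p and BH q", {
  expect_equal(compare_strands(3, 1)$mean_fraction, 0.75)
  ## TS identical to NTS: no nonzero differences, p = 1
  expect_equal(compare_strands(rep(2, 10), rep(2, 10))$p, 1)
  ## zero totals are excluded and counted
  r <- compare_strands(c(0, 3, 5), c(0, 1, 5))
  expect_equal(r$n, 2)
  expect_equal(r$n_excluded, 1)
  ## grouped: q is BH over the group family
  set.seed(2)
  ts <- c(rnorm(40, 10), rnorm(40, 10))
  nts <- c(rnorm(40, 5), rnorm(40, 10))
  g <- rep(c("hi", "null"), each = 40)
  out <- compare_strands(ts, nts, g)
  expect_equal(out$q, stats::p.adjust(out$p, "BH"))
  expect_lt(out$p[out$group == "hi"], 1e-6)
})

test_that("peak classification honours the 200-bp promoter extension", {
  gene <- GRanges("I", IRanges(5000, 8000), strand = "+", gene_id = "g")
  near <- GRanges("I", IRanges(4850, 4860))    # 150 bp upstream of the TSS
  far <- GRanges("I", IRanges(4700, 4799))     # ends 201 bp upstream
  expect_equal(classify_peaks(near, gene), "genic")
  expect_equal(classify_peaks(far, gene), "intergenic")

  ## minus-strand gene: extension goes right of the end
  gm <- GRanges("I", IRanges(5000, 8000), strand = "-", gene_id = "g")
  nearm <- GRanges("I", IRanges(8150, 8160))
  expect_equal(classify_peaks(nearm, gm), "genic")

  ## brute-force check over random peaks and genes
  set.seed(4)
  genes <- GRanges("I", IRanges(gs <- sample(5e4, 3) + 2000, gs + 3000),
                   strand = sample(c("+", "-"), 3, TRUE),
                   gene_id = paste0("g", 1:3))
  peaks <- GRanges("I", IRanges(ps <- sample(6e4, 10), ps + 200))
  lab <- classify_peaks(peaks, genes)
  manual <- vapply(seq_along(peaks), function(i) {
    any(vapply(seq_along(genes), function(j) {
      s <- start(genes)[j]; e <- end(genes)[j]
      if (as.character(strand(genes))[j] == "+") s <- s - 200 else e <- e + 200
      start(peaks)[i] <= e && end(peaks)[i] >= s
    }, logical(1)))
  }, logical(1))
  expect_equal(lab, ifelse(manual, "genic", "intergenic"))
})
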