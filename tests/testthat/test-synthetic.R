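test_that("toy genome generation is deterministic and respects the gene layout", {
  cfg <- sim_config(genome_length = 2e5, n_genes = 20,
                    gene_length_range = c(2200, 4000), min_gene_gap = 500,
                    n_peaks = 5, n_dyads = 10, seed = 42)
  a <- build_toy_genome(cfg)
  b <- build_toy_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$expression, b$expression)
  expect_equal(length(a$genes), 20)

  g <- sort(a$genes, ignore.strand = TRUE)
  gaps <- start(g)[-1] - end(g)[-length(g)] - 1
  expect_true(all(gaps >= 500))
  expect_true(all(end(g) <= 2e5))
  expect_true(all(width(g) >= 2200 & width(g) <= 4000))

  empty <- build_toy_genome(sim_config(genome_length = 5e4, n_genes = 0,
                                       n_peaks = 0, n_dyads = 0, seed = 1))
  expect_equal(length(empty$genes), 0)

  expect_error(build_toy_genome(
    sim_config(genome_length = 3e4, n_genes = 20, seed = 1)),
    "do not fit")
})

test_that("toy dataset round-trips through standard file formats", {
  cfg <- sim_config(genome_length = 5e4, n_genes = 5,
                    gene_length_range = c(2200, 4000), n_peaks = 3,
                    n_dyads = 4, seed = 2)
  sim <- build_toy_genome(cfg)
  dir <- withr::local_tempdir()
  paths <- write_toy_genome(sim, dir)
  g2 <- read_genome_fasta(paths["genome"])
  expect_identical(as.character(g2), as.character(sim$genome))
  genes2 <- read_genes_gff3(paths["genes"])
  expect_equal(start(genes2), start(sim$genes))
  expect_equal(genes2$gene_id, sim$genes$gene_id)
  expr2 <- read_expression_tsv(paths["expression"])
  expect_equal(expr2$tpm, sim$expression$tpm, tolerance = 1e-6)
})

test_that("simulated XR reads carry the planted strand bias and 3' dipyrimidine", {
  cfg <- sim_config(genome_length = 4e5, n_genes = 40,
                    gene_length_range = c(2200, 4000),
                    ts_bias_by_quartile = rep(0.5, 4), seed = 11)
  sim <- build_toy_genome(cfg)
  xr <- simulate_xr_reads(sim, n_reads = 50000)
  ## binomial 3 sigma around 0.5 at n = 50 000
  ts_frac <- mean(xr$truth$is_ts)
  expect_lt(abs(ts_frac - 0.5), 3 * sqrt(0.25 / 50000))

  ## every read of the modal length carries a read-orientation dipyrimidine
  ## at the configured 3' offset
  seqs <- read_sequences(xr$reads, sim$genome)
  s24 <- seqs[nchar(seqs) == 24]
  mid <- substr(s24, 18, 19)  # offset 6 => 0-based indices (17, 18)
  expect_true(all(grepl("^[CT][CT]$", mid)))

  empty <- simulate_xr_reads(sim, n_reads = 0)
  expect_equal(length(empty$reads), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("damage lesions are uniform over dipyrimidine sites when unmodulated", {
  cfg <- sim_config(genome_length = 2e5, n_genes = 10, n_reads = 40000,
                    periodic_amplitudes = c("160" = 0, "10" = 0),
                    peak_center_dip_depth = 0, seed = 13)
  sim <- build_toy_genome(cfg)
  dm <- simulate_damage_reads(sim, cfg)
  ## survival 1 at t0: one read per planted lesion
  expect_equal(length(dm$reads[["0h"]]), nrow(dm$truth))
  ## chi-square goodness of fit across 50 position bins; expected counts
  ## proportional to dipyrimidine-site density per bin is ~uniform for an
  ## iid genome, so test positions directly against uniformity of site index
  pos <- dm$truth$dinuc_start
  ## expected bin mass proportional to the candidate dipyrimidine-site count
  ## per bin (computed independently by direct sequence scan, both strands)
  s <- strsplit(as.character(sim$genome[["I"]]), "")[[1]]
  pyr <- s %in% c("C", "T"); pur <- s %in% c("A", "G")
  sites <- c(which(pyr[-length(s)] & pyr[-1]), which(pur[-length(s)] & pur[-1]))
  br <- seq(min(sites), max(sites) + 1, length.out = 51)
  exp_mass <- table(cut(sites, br, include.lowest = TRUE))
  ct <- table(cut(pos, br, include.lowest = TRUE))
  p <- stats::chisq.test(ct, p = as.numeric(exp_mass) / sum(exp_mass))$p.value
  expect_gt(p, 0.001)

  expect_error(sim_config(periodic_amplitudes = c("160" = 1.5)), "amplitudes")
})

test_that("later damage timepoints subsample lesions and decay monotonically", {
  cfg <- sim_config(genome_length = 2e5, n_genes = 10, n_reads = 20000,
                    n_peaks = 10, n_dyads = 20, seed = 17)
  sim <- build_toy_genome(cfg)
  dm <- simulate_damage_reads(sim, cfg)
  counts <- vapply(dm$reads, length, integer(1))
  expect_true(all(diff(counts) < 0))
  expect_equal(unname(counts["0h"]), 20000)
  ## surviving read sets are subsets of the planted lesions
  expect_true(all(dm$reads[["48h"]]$lesion_id %in% dm$truth$lesion_id))
  ## controls have the same depth
  expect_equal(length(dm$naked), 20000)
  expect_equal(length(dm$mock), 20000)
})

test_that("signal track simulator reproduces class profiles", {
  prof <- list(sin(seq(0, 3, length.out = 50)), cos(seq(0, 3, length.out = 50)))
  noiseless <- simulate_signal_tracks(prof, n_samples = 3, noise_sd = 0, seed = 1)
  expect_equal(noiseless[, 1], prof[[1]])
  expect_equal(noiseless[, 4], prof[[2]])
  a <- simulate_signal_tracks(prof, 3, 0.1, seed = 5)
  b <- simulate_signal_tracks(prof, 3, 0.1, seed = 5)
  expect_identical(a, b)
  ## law of large numbers on the matrix mean, 3 sigma
  big <- simulate_signal_tracks(prof, 200, 0.5, seed = 2)
  mu_true <- mean(unlist(prof))
  expect_lt(abs(mean(big) - mu_true), 3 * 0.5 / sqrt(length(big)))
})
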