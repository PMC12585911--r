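test_that("fixed-bp peak windows put the centre bin over the anchor", {
  ## anchor at 0-based 5000 (1-based 5001), +/-1 kb, 201 x 10-bp bins:
  ## bin 101 spans 0-based [4995, 5005)
  anchor <- GRanges("I", IRanges(5001, 5001))
  reads_in <- alignments("I", rep(4996, 3), rep(5005, 3), "+", mapq = 30)
  pp <- peak_profile(reads_in, anchor, flank = 1000, n_bins = 201)
  expect_equal(pp$plus[1, 101], 3)
  expect_equal(sum(pp$plus), 3)
  expect_equal(pp$bin_size, 10)
  expect_equal(pp$offset_start, -1005)

  ## a read just left of the centre bin falls in bin 100
  left <- alignments("I", 4986, 4995, "+", mapq = 30)
  pl <- peak_profile(left, anchor, flank = 1000, n_bins = 201)
  expect_equal(pl$plus[1, 100], 1)

  expect_warning(peak_profile(reads_in, anchor, flank = 1000, n_bins = 126),
                 "centre")
})

test_that("plus-strand reorientation reverses bin order and is an involution", {
  anchor <- GRanges("I", IRanges(5001, 5001))
  reads <- alignments("I", c(4101, 5896), c(4110, 5905), c("+", "-"), mapq = 30)
  plain <- peak_profile(reads, anchor, flank = 1000, n_bins = 201)
  oriented <- peak_profile(reads, anchor, flank = 1000, n_bins = 201,
                           orient = TRUE)
  expect_equal(oriented$plus, reverse_plus_bins(plain$plus))
  expect_equal(oriented$minus, plain$minus)          # minus order unchanged
  expect_equal(reverse_plus_bins(reverse_plus_bins(plain$plus)), plain$plus)
  expect_equal(reverse_plus_bins(c(1, 2, 3)), c(3, 2, 1))

  ## a symmetric read layout (mirrored around the window midpoint) gives
  ## mirror-equal oriented strand profiles
  sym <- c(alignments("I", c(4201, 4501), c(4210, 4510), "+", mapq = 30),
           alignments("I", c(5491, 5791), c(5500, 5800), "-", mapq = 30))
  po <- peak_profile(sym, anchor, flank = 1000, n_bins = 201, orient = TRUE)
  expect_equal(po$plus, po$minus)
})

test_that("scale-region mode bins slopped intervals of variable width", {
  anchors <- GRanges("I", IRanges(c(2001, 10001), c(2400, 11000)))
  ## reads at the same *relative* position (5% into the slopped window)
  reads <- alignments("I", c(1571, 9626), c(1580, 9635), "+", mapq = 30)
  pp <- peak_profile(reads, anchors, flank = 500, n_bins = 40,
                     mode = "scale_region")
  expect_equal(dim(pp$plus), c(2, 40))
  expect_equal(which(pp$plus[1, ] > 0), which(pp$plus[2, ] > 0))
})

test_that("rolling mean truncates at the edges and skips missing bins", {
  x <- c(1, 2, 3, 4, 5)
  sm <- rolling_mean(x, window = 3)
  expect_equal(sm, c(1.5, 2, 3, 4, 4.5))
  xna <- c(1, NA, 3, NA, NA)
  expect_equal(rolling_mean(xna, 3), c(1, 2, 3, 3, NA))
})

test_that("normalization chain identities hold", {
  ones <- rep(1, 50)
  out <- normalize_chain(ones, mock = ones, naked = ones, sim = ones,
                         mode = "damage_full")
  expect_true(all(out == 0))                     # log2(1) everywhere
  expect_equal(attr(out, "n_masked"), 0)

  ## planted 2x enrichment over sim: interior of the run is exactly 1 after
  ## log2; smoothing shrinks only the run edges
  x <- rep(1, 100); x[50:60] <- 2
  out2 <- normalize_chain(x, sim = rep(1, 100), mode = "xr_sim",
                          smooth_window = 11)
  expect_equal(out2[55], 1)
  expect_true(all(out2[c(45, 65)] < 1 & out2[c(45, 65)] > 0))
  raw2 <- normalize_chain(x, sim = rep(1, 100), mode = "xr_sim",
                          smooth_window = 1)
  expect_equal(raw2[50:60], rep(1, 11))
  expect_equal(raw2[1:49], rep(0, 49))

  ## nonpositive denominators are masked and counted
  sim <- rep(1, 100); sim[3] <- 0
  outm <- normalize_chain(x, sim = sim, mode = "xr_sim", smooth_window = 1)
  expect_equal(attr(outm, "n_masked"), 1)
  expect_true(is.na(outm[3]))
  expect_error(normalize_chain(x, sim = rep(0, 100), mode = "xr_sim"),
               "all-zero")

  ## xr_sim_damage divides by the damage landscape
  dmg <- rep(2, 100)
  out3 <- normalize_chain(rep(4, 100), sim = rep(1, 100), damage = dmg,
                          mode = "xr_sim_damage", smooth_window = 1)
  expect_true(all(out3 == 1))

  ## binned_signal inputs keep their class and metadata
  bs <- binned_signal(x, bin_size = 10, offset_start = -500)
  ob <- normalize_chain(bs, sim = rep(1, 100), mode = "xr_sim")
  expect_s3_class(ob, "binned_signal")
  expect_equal(ob$bin_size, 10)
})

test_that("tertile box statistics use interpolated percentiles and BH-corrected Wilcoxon", {
  ## 12.5th percentile of 1..8 under linear interpolation = 1.875
  m <- cbind(t0 = 1:8, t1 = 1:8 + 0.5)
  tb <- tertile_boxstats(m, tertiles = rep("low", 8))
  expect_equal(tb$stats$whisker_low[1], 1.875)
  expect_equal(tb$stats$whisker_high[1], 7.125)
  expect_equal(tb$stats$median[1], 4.5)

  ## shifting one tertile far away yields small adjusted p at n = 200 bins
  set.seed(6)
  vals <- matrix(rnorm(600), ncol = 2)
  tert <- rep(c("low", "medium", "high"), each = 100)
  vals[tert == "high", ] <- vals[tert == "high", ] + 10
  out <- tertile_boxstats(vals, tert)
  hi <- out$tests$type == "between_tertiles" &
    grepl("high", out$tests$tertile)
  expect_true(all(out$tests$q[hi] < 0.05))
  expect_equal(out$tests$q, stats::p.adjust(out$tests$p, "BH"))

  ## tertiles with < 2 usable bins give NA statistics, not errors
  m2 <- cbind(t0 = c(1, NA), t1 = c(2, NA))
  tb2 <- tertile_boxstats(m2, tertiles = c("low", "high"))
  expect_true(all(is.na(tb2$stats$median[tb2$stats$tertile == "high"])))
})
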