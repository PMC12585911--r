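#' Binned signal container
#'
#' A per-region (or aggregated) vector of bin values with its bin size and the
#' bp offset of the first bin start relative to the anchor point. This is the
#' substrate of profile plots and periodicity analysis.
#'
#' @param values numeric vector of bin values (NA = masked bin).
#' @param bin_size bin width, bp.
#' @param offset_start bp of the first bin's start relative to the anchor
#'   (anchor at bp 0); `NA` for unanchored signals.
#' @return object of class `binned_signal`.
#' @export
binned_signal <- function(values, bin_size = 1, offset_start = NA_real_) {
  if (length(values) < 1 || bin_size <= 0)
    stop("need >= 1 bin and positive bin_size")
  structure(list(values = as.numeric(values), bin_size = bin_size,
                 offset_start = offset_start),
            class = "binned_signal")
}

#' @export
print.binned_signal <- function(x, ...) {
  cat("binned_signal:", length(x$values), "bins of", x$bin_size, "bp",
      if (!is.na(x$offset_start))
        paste0("(first bin starts at ", x$offset_start, " bp from anchor)"),
      "\n")
  invisible(x)
}

## bp of each bin start relative to the anchor
bin_offsets <- function(x) x$offset_start + (seq_along(x$values) - 1) * x$bin_size

#' Stranded profiles centred on peaks or dyads
#'
#' In `fixed_bp` mode, anchors are points (peak summits, dyad centres) and the
#' window of `2 * flank` bp is covered by `n_bins` bins of width
#' `2 * flank / (n_bins - 1)`, arranged so the central bin straddles the anchor
#' (201 x 10-bp bins for +/-1 kb ATAC windows; 41 x 2-bp bins for +/-80 bp dyad
#' windows). In `scale_region` mode anchors are intervals, extended by `flank`
#' on both sides and divided into `n_bins` equal parts (variable bin size).
#'
#' With `orient = TRUE` the bin order of the plus-strand counts is reversed
#' (the last bin plotted first) while the minus strand is unchanged, so
#' transcription reads left to right on both strands.
#'
#' @param reads `GRanges` of reads or damage sites.
#' @param anchors `GRanges`: width-1 points (`fixed_bp`) or intervals
#'   (`scale_region`).
#' @param flank half-window (or slop), bp.
#' @param n_bins number of bins; an even count in `fixed_bp` mode has no exact
#'   centre bin and triggers a warning.
#' @param mode `"fixed_bp"` or `"scale_region"`.
#' @param orient reverse plus-strand bin order.
#' @param min_overlap_fraction as in [count_in_bins()].
#' @param library_size if given, counts are scaled to RPM.
#' @return list with `plus`, `minus`, `combined` (anchors x bins matrices),
#'   `bin_size` (bp; `NA` in scale_region mode), `offset_start`, and `mean_*`
#'   aggregated [binned_signal]s.
#' @export
peak_profile <- function(reads, anchors, flank = 1000, n_bins = 201,
                         mode = c("fixed_bp", "scale_region"), orient = FALSE,
                         min_overlap_fraction = 0.5, library_size = NULL) {
  mode <- match.arg(mode)
  na <- length(anchors)
  if (na == 0) stop("no anchors")
  chr <- as.character(seqnames(anchors))
  if (mode == "fixed_bp") {
    if (any(width(anchors) != 1))
      stop("fixed_bp mode expects width-1 anchor points")
    if (n_bins %% 2 == 0)
      warning("even n_bins: no exact centre bin over the anchor")
    bin_size <- 2 * flank / (n_bins - 1)
    if (bin_size != round(bin_size))
      stop("2 * flank / (n_bins - 1) must be an integer bin size")
    ## centre bin straddles the anchor: first bin starts flank + bin_size/2
    ## upstream of it
    first0 <- (start(anchors) - 1) - flank - bin_size / 2
    bstart <- rep(first0, each = n_bins) +
      (rep(seq_len(n_bins), na) - 1) * bin_size + 1
    bins <- GRanges(rep(chr, each = n_bins),
                    IRanges(floor(bstart), width = bin_size))
    offset_start <- -flank - bin_size / 2
  } else {
    lo <- start(anchors) - flank
    hi <- end(anchors) + flank
    w <- (hi - lo + 1) / n_bins
    gidx <- rep(seq_len(na), each = n_bins)
    j <- rep(seq_len(n_bins), na)
    bs <- lo[gidx] + round((j - 1) * w[gidx])
    be <- lo[gidx] + round(j * w[gidx]) - 1
    bins <- GRanges(chr[gidx], IRanges(bs, pmax(bs, be)))
    bin_size <- NA_real_
    offset_start <- NA_real_
  }
  count_strand <- function(str) {
    r <- reads[as.character(strand(reads)) == str]
    cnt <- count_in_bins(r, bins, strand_mode = "any",
                         min_overlap_fraction = min_overlap_fraction)
    m <- matrix(cnt, nrow = na, ncol = n_bins, byrow = TRUE)
    if (!is.null(library_size)) m <- m * 1e6 / library_size
    m
  }
  plus <- count_strand("+")
  minus <- count_strand("-")
  if (orient) plus <- plus[, rev(seq_len(n_bins)), drop = FALSE]
  combined <- plus + minus
  mk <- function(m) binned_signal(colMeans(m),
                                  if (is.na(bin_size)) 1 else bin_size,
                                  offset_start)
  list(plus = plus, minus = minus, combined = combined,
       bin_size = bin_size, offset_start = offset_start,
       mean_plus = mk(plus), mean_minus = mk(minus),
       mean_combined = mk(combined))
}

#' Reverse plus-strand bin order
#'
#' The reorientation used to display transcription left-to-right on both
#' strands; applying it twice is the identity.
#'
#' @param m matrix (regions x bins) or numeric vector.
#' @return the column-reversed input.
#' @export
reverse_plus_bins <- function(m) {
  if (is.matrix(m)) m[, rev(seq_len(ncol(m))), drop = FALSE] else rev(m)
}

#' Centred rolling mean, truncated at the edges
#'
#' NA bins are excluded from each window mean (all-NA windows stay NA); no
#' padding is invented at the profile boundaries.
#'
#' @param x numeric vector.
#' @param window odd window width in bins (default 11).
#' @return smoothed vector, same length.
#' @export
rolling_mean <- function(x, window = 11) {
  n <- length(x)
  half <- floor(window / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    v <- x[j]
    out[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

#' Control/simulation normalization chain for binned profiles
#'
#' Implements the normalization chains used for chromatin-context profiles
#' (all inputs RPM-scaled, same binning):
#' \describe{
#'   \item{`damage_full`}{`x / mock`, then divided by `mean(naked)`, then
#'     `/ sim`, smoothed with a centred 11-bin rolling window, log2.}
#'   \item{`xr_sim`}{`x / sim`, smoothed, log2.}
#'   \item{`xr_sim_damage`}{`x / sim`, further divided by the
#'     simulation-normalized damage profile (`damage`), smoothed, log2 -
#'     repair efficiency relative to the local damage landscape.}
#' }
#' Bins with nonpositive denominators are masked (NA), propagate through the
#' smoother as missing, and are counted in `attr(, "n_masked")`.
#'
#' @param x profile to normalize (numeric or [binned_signal]).
#' @param mock,naked,sim,damage control profiles as required by `mode`.
#' @param smooth_window rolling-mean width in bins; 1 disables smoothing.
#' @param mode `"damage_full"`, `"xr_sim"` or `"xr_sim_damage"`.
#' @return log2 profile (same class as `x`), masked-bin count in
#'   `attr(, "n_masked")`.
#' @export
normalize_chain <- function(x, mock = NULL, naked = NULL, sim = NULL,
                            damage = NULL, smooth_window = 11,
                            mode = c("damage_full", "xr_sim", "xr_sim_damage")) {
  mode <- match.arg(mode)
  as_bs <- inherits(x, "binned_signal")
  v <- if (as_bs) x$values else as.numeric(x)
  val <- function(p) if (inherits(p, "binned_signal")) p$values else as.numeric(p)
  divide <- function(num, den) {
    if (length(den) != length(num)) stop("profiles must share binning")
    if (all(den <= 0, na.rm = TRUE)) stop("all-zero denominator profile")
    out <- ifelse(is.na(den) | den <= 0, NA_real_, num / den)
    out
  }
  if (mode == "damage_full") {
    if (is.null(mock) || is.null(naked) || is.null(sim))
      stop("damage_full requires mock, naked and sim profiles")
    v <- divide(v, val(mock))
    nm <- mean(val(naked), na.rm = TRUE)
    if (nm <= 0) stop("all-zero denominator profile")
    v <- v / nm
    v <- divide(v, val(sim))
  } else {
    if (is.null(sim)) stop(mode, " requires a sim profile")
    v <- divide(v, val(sim))
    if (mode == "xr_sim_damage") {
      if (is.null(damage)) stop("xr_sim_damage requires a damage profile")
      v <- divide(v, val(damage))
    }
  }
  n_masked <- sum(is.na(v))
  if (smooth_window > 1) v <- rolling_mean(v, smooth_window)
  v <- ifelse(is.na(v) | v <= 0, NA_real_, log2(v))
  out <- if (as_bs) binned_signal(v, x$bin_size, x$offset_start) else v
  attr(out, "n_masked") <- n_masked
  out
}

#' Box statistics and Wilcoxon tests across chromatin tertiles and timepoints
#'
#' For bins stratified into tertiles of a chromatin mark, summarizes a
#' normalized signal per tertile and timepoint (median, IQR, whiskers at the
#' 12.5th/87.5th percentiles, linear interpolation between closest ranks) and
#' tests: paired Wilcoxon of each timepoint against the reference within a
#' tertile, unpaired Wilcoxon between tertiles within each timepoint, with
#' Benjamini-Hochberg correction across all tests of the invocation.
#'
#' @param mat bins x timepoints numeric matrix (NA bins dropped per test).
#' @param tertiles factor of tertile labels per bin (see [stratify()]).
#' @param reference reference timepoint (column name or index, default first).
#' @return list with `stats` (per tertile x timepoint summary) and `tests`
#'   (`type`, `tertile`/pair, `timepoint`, `p`, `q`). Cells with fewer than 2
#'   usable bins yield NA statistics.
#' @export
tertile_boxstats <- function(mat, tertiles, reference = 1) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("t", seq_len(ncol(mat)))
  tertiles <- droplevels(as.factor(tertiles))
  stopifnot(length(tertiles) == nrow(mat))
  ref <- if (is.character(reference)) match(reference, colnames(mat)) else reference
  tps <- colnames(mat)
  levs <- levels(tertiles)
  qs <- c(0.125, 0.25, 0.5, 0.75, 0.875)
  stats_rows <- list(); test_rows <- list()
  for (g in levs) {
    rows <- which(tertiles == g)
    for (j in seq_along(tps)) {
      v <- mat[rows, j]; v <- v[!is.na(v)]
      if (length(v) >= 2) {
        qv <- stats::quantile(v, qs, type = 7, names = FALSE)
      } else qv <- rep(NA_real_, 5)
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        tertile = g, timepoint = tps[j], n = length(v),
        whisker_low = qv[1], q25 = qv[2], median = qv[3], q75 = qv[4],
        whisker_high = qv[5])
      if (j != ref) {
        a <- mat[rows, j]; b <- mat[rows, ref]
        use <- !is.na(a) & !is.na(b)
        p <- if (sum(use) < 2 || all(a[use] == b[use])) NA_real_
             else suppressWarnings(wilcox.test(a[use], b[use], paired = TRUE,
                                               exact = FALSE)$p.value)
        test_rows[[length(test_rows) + 1]] <- data.frame(
          type = "timepoint_vs_reference", tertile = g, timepoint = tps[j],
          p = p)
      }
    }
  }
  if (length(levs) >= 2) {
    prs <- utils::combn(levs, 2, simplify = FALSE)
    for (j in seq_along(tps)) {
      for (pr in prs) {
        a <- mat[tertiles == pr[1], j]; b <- mat[tertiles == pr[2], j]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        p <- if (length(a) < 2 || length(b) < 2) NA_real_
             else suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
        test_rows[[length(test_rows) + 1]] <- data.frame(
          type = "between_tertiles", tertile = paste(pr, collapse = " vs "),
          timepoint = tps[j], p = p)
      }
    }
  }
  tests <- do.call(rbind, test_rows)
  if (!is.null(tests)) tests$q <- p.adjust(tests$p, method = "BH")
  list(stats = do.call(rbind, stats_rows), tests = tests)
}
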