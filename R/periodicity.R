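#' Fourier power at candidate periods
#'
#' Mean-centres the binned signal and, for each candidate period P (bp,
#' converted to bin units p = P / bin_size), computes the squared magnitude of
#' the sum of signal values weighted by complex exponentials of that period,
#' normalized by the signal length:
#' `raw_power(p) = |sum_n x~_n exp(-2 pi i n / p)|^2 / N`.
#' Relative power divides by the mean over the candidate set, a dimensionless
#' measure comparable across timepoints and genotypes. Candidate periods need
#' not be integer multiples of the bin size (160 bp on 10-bp bins is 16 bins;
#' 10 bp on 2-bp bins is 5), but must exceed 2 bins (Nyquist guard). Missing
#' bins are mean-imputed (count reported) so N stays fixed.
#'
#' @param signal numeric vector or [binned_signal()] of bin values.
#' @param candidate_periods_bp candidate periods in bp. Defaults: 100-250 bp in
#'   steps of 5 for nucleosome-repeat analyses; use `seq(5, 20, 0.5)` for
#'   10-bp helical-turn analyses.
#' @param bin_size bp per bin (taken from a `binned_signal` input).
#' @return `power_spectrum` object: `period_bp`, `period_bins`, `raw_power`,
#'   `relative_power`, `n`, `bin_size`, `n_imputed`.
#' @examples
#' ps <- power_spectrum(cos(2 * pi * (0:200) / 16),
#'                      candidate_periods_bp = seq(100, 250, 5), bin_size = 10)
#' ps$period_bp[which.max(ps$raw_power)]  # 160
#' @export
power_spectrum <- function(signal, candidate_periods_bp = seq(100, 250, by = 5),
                           bin_size = NULL) {
  if (inherits(signal, "binned_signal")) {
    if (is.null(bin_size)) bin_size <- signal$bin_size
    signal <- signal$values
  }
  if (is.null(bin_size)) bin_size <- 1
  x <- as.numeric(signal)
  N <- length(x)
  if (N < 4) stop("need at least 4 bins")
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    if (n_imputed == N) stop("all bins missing")
    x[is.na(x)] <- mean(x, na.rm = TRUE)
  }
  p_bins <- candidate_periods_bp / bin_size
  if (any(p_bins <= 2))
    stop("candidate periods must exceed 2 bins (sub-Nyquist)")
  xt <- x - mean(x)
  E <- exp(-2i * pi * outer(0:(N - 1), 1 / p_bins))
  raw <- Mod(colSums(xt * E))^2 / N
  rel <- if (all(raw == 0)) raw else raw / mean(raw)
  structure(list(period_bp = candidate_periods_bp, period_bins = p_bins,
                 raw_power = raw, relative_power = rel, n = N,
                 bin_size = bin_size, n_imputed = n_imputed),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  top <- which.max(x$raw_power)
  cat("power_spectrum over", length(x$period_bp), "candidate periods (",
      min(x$period_bp), "-", max(x$period_bp), "bp ), N =", x$n, "bins of",
      x$bin_size, "bp\n  peak:", x$period_bp[top], "bp, relative power",
      signif(x$relative_power[top], 4), "\n")
  invisible(x)
}

#' Signal-to-noise ratio at a target period
#'
#' Power at the target period divided by the mean power across all other
#' candidate periods (160 bp for nucleosome-repeat analyses, 10 bp for
#' dyad-centred analyses). Identical whether raw or relative power is used.
#'
#' @param spectrum a [power_spectrum()].
#' @param target_period_bp target period, bp; must be in the candidate set.
#' @return the SNR (possibly `Inf`, with a warning, if all off-target power is
#'   zero).
#' @export
snr <- function(spectrum, target_period_bp) {
  i <- which(abs(spectrum$period_bp - target_period_bp) < 1e-8)
  if (length(i) != 1)
    stop("target period ", target_period_bp, " bp not in the candidate set")
  if (length(spectrum$period_bp) < 2) stop("need at least 2 candidate periods")
  off <- mean(spectrum$raw_power[-i])
  if (off == 0) {
    warning("zero off-target power; SNR reported as Inf")
    return(Inf)
  }
  spectrum$raw_power[i] / off
}

#' Permutation test of periodicity strength
#'
#' Shuffles the bins of the signal uniformly at random `n_perm` times (missing
#' bins are shuffled along with the values, then mean-imputed), recomputes the
#' SNR for each shuffle, and reports the empirical p-value as the proportion of
#' permuted SNR values strictly exceeding the observed SNR. The positively
#' biased `(k + 1) / (n + 1)` estimate is reported alongside. A constant signal
#' has undefined SNR and yields p = 1 by convention.
#'
#' @param signal numeric vector or [binned_signal()].
#' @param target_period_bp target period, bp.
#' @param candidate_periods_bp candidate set (must contain the target).
#' @param bin_size bp per bin.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed (dedicated to the permutation stream).
#' @return `periodicity_test` object: `target_period_bp`, `snr`, `empirical_p`,
#'   `p_plus1`, `n_perm`, `seed`.
#' @export
permutation_pvalue <- function(signal, target_period_bp,
                               candidate_periods_bp = seq(100, 250, by = 5),
                               bin_size = NULL, n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(signal, "binned_signal")) {
    if (is.null(bin_size)) bin_size <- signal$bin_size
    signal <- signal$values
  }
  if (is.null(bin_size)) bin_size <- 1
  x <- as.numeric(signal)
  if (sum(!is.na(x)) < 4) stop("need at least 4 non-missing bins")
  if (stats::sd(x, na.rm = TRUE) == 0) {
    message("constant signal: SNR undefined, p = 1 by convention")
    return(structure(list(target_period_bp = target_period_bp, snr = NA_real_,
                          empirical_p = 1, p_plus1 = 1, n_perm = n_perm,
                          seed = seed),
                     class = "periodicity_test"))
  }
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  N <- length(x)
  p_bins <- candidate_periods_bp / bin_size
  if (any(p_bins <= 2)) stop("candidate periods must exceed 2 bins")
  ti <- which(abs(candidate_periods_bp - target_period_bp) < 1e-8)
  if (length(ti) != 1) stop("target period not in the candidate set")
  E <- exp(-2i * pi * outer(0:(N - 1), 1 / p_bins))
  pw <- function(M) {
    ## columns of M are signals; returns candidate x column raw power
    Mt <- M - rep(colMeans(M), each = N)
    Mod(crossprod(E, Mt))^2 / N
  }
  obs_raw <- pw(matrix(x, ncol = 1))[, 1]
  off <- mean(obs_raw[-ti])
  snr_obs <- if (off == 0) Inf else obs_raw[ti] / off
  set.seed(seed)
  perm <- matrix(0, N, n_perm)
  for (j in seq_len(n_perm)) perm[, j] <- x[sample.int(N)]
  raw_p <- pw(perm)
  snr_perm <- raw_p[ti, ] / colMeans(raw_p[-ti, , drop = FALSE])
  k <- sum(snr_perm > snr_obs)
  structure(list(target_period_bp = target_period_bp, snr = snr_obs,
                 empirical_p = k / n_perm, p_plus1 = (k + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "periodicity_test")
}

#' @export
print.periodicity_test <- function(x, ...) {
  cat("periodicity_test: target", x$target_period_bp, "bp, SNR",
      signif(x$snr, 4), ", empirical p =", x$empirical_p,
      paste0("(", x$n_perm, " permutations)"), "\n")
  invisible(x)
}

#' Restrict an anchored profile to its downstream portion
#'
#' Keeps the bins whose start lies at or past `start_offset_bp` downstream of
#' the anchor (bp 0), preserving bin boundaries - the region restriction used
#' to capture transcription-driven asymmetric periodicity (+250 bp for
#' accessibility-peak windows, +20 bp for dyad windows).
#'
#' @param profile a [binned_signal()] with a defined anchor offset.
#' @param start_offset_bp bp offset from the anchor.
#' @return the restricted `binned_signal`.
#' @export
restrict_downstream <- function(profile, start_offset_bp) {
  stopifnot(inherits(profile, "binned_signal"))
  if (is.na(profile$offset_start))
    stop("profile has no anchor offset; cannot restrict")
  offs <- bin_offsets(profile)
  keep <- offs >= start_offset_bp
  if (!any(keep))
    stop("offset ", start_offset_bp, " bp is beyond the profiled window")
  binned_signal(profile$values[keep], profile$bin_size, offs[which(keep)[1]])
}
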