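#' Percent amplitude of fluctuation of a time series
#'
#' PerAF is the mean absolute deviation of a series from its mean,
#' expressed as a percentage of that mean:
#' \deqn{\mathrm{PerAF} = \frac{1}{n}\sum_{i=1}^{n}
#'   \left|\frac{x_i - \mu}{\mu}\right| \times 100\%,\qquad
#'   \mu = \frac{1}{n}\sum_{i=1}^{n} x_i.}
#' It is invariant under positive rescaling of the series (unlike ALFF,
#' which is homogeneous of degree 1) but not under additive offsets,
#' since the offset changes \eqn{\mu}.
#'
#' @param x Numeric vector of BOLD intensities, length >= 2, strictly
#'   positive mean.
#' @return PerAF in percent (non-negative scalar; 0 iff `x` is constant).
#' @examples
#' peraf_series(c(90, 110, 90, 110))  # 10
#' @export
peraf_series <- function(x) {
  if (length(x) < 2) stop("PerAF needs at least 2 timepoints")
  if (any(!is.finite(x))) stop("non-finite values in series")
  mu <- mean(x)
  if (mu <= 0)
    stop(sprintf("series mean must be positive for PerAF (got %.6g)", mu))
  100 * mean(abs(x - mu)) / mu
}

#' Voxelwise PerAF map of a 4D BOLD image
#'
#' Applies [peraf_series()] to every masked voxel. Voxels whose series
#' mean is non-positive (or negligible relative to the image's intensity
#' scale) cannot support the percent normalisation; they are dropped from
#' the output mask and counted in `meta$voxels_dropped`.
#'
#' @param bold A [bold_image()] (already preprocessed: volumes discarded,
#'   nuisance regressed).
#' @param mask Logical 3D array matching the spatial grid.
#' @param mean_epsilon Relative tolerance: voxels with mean below
#'   `mean_epsilon` times the grand within-mask mean are dropped.
#' @return An [amplitude_map()] with `metric = "PerAF"`, units percent.
#' @export
peraf_map <- function(bold, mask, mean_epsilon = 1e-6) {
  stopifnot(inherits(bold, "bold_image"))
  d <- dim(bold$data)
  mask <- as_mask(mask, d[1:3])
  if (!any(mask)) stop("mask is empty")
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])[as.vector(mask), ,
                                                           drop = FALSE]
  mu <- rowMeans(m)
  grand <- mean(mu)
  ok <- mu > max(0, mean_epsilon * grand)
  per <- rep(NA_real_, nrow(m))
  per[ok] <- 100 * rowMeans(abs(m[ok, , drop = FALSE] - mu[ok])) / mu[ok]
  vals <- array(0, dim = d[1:3])
  keep <- mask
  keep[mask] <- ok
  vals[keep] <- per[ok]
  amplitude_map(vals, "PerAF", keep, bold$voxel_size_mm, bold$affine,
                meta = list(voxels_dropped = sum(!ok)))
}

#' Scale a map by its within-mask mean
#'
#' Divides every voxel by the global mean over the mask, so the output
#' has within-mask mean exactly 1 ("mPerAF"-style standardisation used
#' before group comparison of average regional values).
#'
#' @param map An [amplitude_map()].
#' @param mask Optional logical 3D array; defaults to the map's own mask.
#' @return An [amplitude_map()] with `metric = "mPerAF"` when the input
#'   was PerAF, otherwise the input metric is kept.
#' @export
mean_scale_map <- function(map, mask = NULL) {
  stopifnot(inherits(map, "amplitude_map"))
  if (is.null(mask)) mask <- map$mask else mask <- as_mask(mask, dim(map$values))
  g <- mean(map$values[mask])
  if (!is.finite(g) || g <= 0)
    stop(sprintf("within-mask mean must be positive to scale (got %.6g)", g))
  vals <- map$values / g
  metric <- if (map$metric == "PerAF") "mPerAF" else map$metric
  amplitude_map(vals, metric, mask, map$voxel_size_mm, map$affine,
                meta = c(map$meta, list(scaled_by = g)))
}

# Single-sided amplitude spectrum of a series: frequencies k/(n*tr) for
# k = 1..floor(n/2), amplitudes from the plain (untapered) periodogram.
amplitude_spectrum <- function(x, tr_s) {
  n <- length(x)
  kmax <- floor(n / 2)
  co <- stats::fft(x)[seq_len(kmax) + 1L]
  amp <- 2 * Mod(co) / n
  if (n %% 2 == 0) amp[kmax] <- Mod(co[kmax]) / n  # Nyquist bin unpaired
  list(freq = seq_len(kmax) / (n * tr_s), amp = amp)
}

#' Amplitude of low-frequency fluctuations (ALFF) of a series
#'
#' Mean of the single-sided amplitude spectrum (square root of
#' periodogram power, scaled to sinusoid amplitude) over the frequency
#' bins inside `band`. A pure in-band sinusoid of amplitude A on a grid
#' frequency contributes A at its bin; ALFF scales linearly with the
#' signal (`alff(c x) = c alff(x)`), in contrast to PerAF's scale
#' invariance.
#'
#' @param x Numeric vector, length >= 4.
#' @param tr_s Sampling interval (repetition time), seconds.
#' @param band Length-2 numeric, (low, high) Hz; default the 0.01-0.08 Hz
#'   resting-state convention.
#' @return Non-negative scalar in the units of `x`.
#' @export
alff_series <- function(x, tr_s, band = c(0.01, 0.08)) {
  if (length(x) < 4) stop("ALFF needs at least 4 timepoints")
  if (any(!is.finite(x))) stop("non-finite values in series")
  if (band[1] < 0 || band[2] <= band[1] || band[1] > 1 / (2 * tr_s))
    stop("invalid frequency band")
  sp <- amplitude_spectrum(x, tr_s)
  inband <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(inband))
    stop(sprintf("no frequency bins in [%.4g, %.4g] Hz; grid spacing is %.4g Hz",
                 band[1], band[2], sp$freq[1]))
  mean(sp$amp[inband])
}

#' Fractional ALFF (fALFF) of a series
#'
#' Ratio of the summed in-band amplitude to the total amplitude over all
#' nonzero frequencies; lies in [0, 1] and, like PerAF, is invariant
#' under positive rescaling. A constant series has no fluctuation energy
#' at all and is rejected rather than returning 0/0.
#'
#' @inheritParams alff_series
#' @return Scalar in [0, 1].
#' @export
falff_series <- function(x, tr_s, band = c(0.01, 0.08)) {
  if (length(x) < 4) stop("fALFF needs at least 4 timepoints")
  if (any(!is.finite(x))) stop("non-finite values in series")
  sp <- amplitude_spectrum(x, tr_s)
  total <- sum(sp$amp)
  # guard against numerically-constant series (fft leaves ~1e-14 residue)
  if (total <= 1e-10 * mean(abs(x)))
    stop("constant series: total fluctuation amplitude is zero, fALFF undefined")
  inband <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(inband))
    stop(sprintf("no frequency bins in [%.4g, %.4g] Hz", band[1], band[2]))
  sum(sp$amp[inband]) / total
}

#' Voxelwise ALFF map of a 4D BOLD image
#'
#' @inheritParams peraf_map
#' @param band Frequency band in Hz.
#' @return An [amplitude_map()] with `metric = "ALFF"`.
#' @export
alff_map <- function(bold, mask, band = c(0.01, 0.08)) {
  stopifnot(inherits(bold, "bold_image"))
  d <- dim(bold$data)
  mask <- as_mask(mask, d[1:3])
  if (!any(mask)) stop("mask is empty")
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])[as.vector(mask), ,
                                                           drop = FALSE]
  n <- d[4]
  kmax <- floor(n / 2)
  freq <- seq_len(kmax) / (n * bold$tr_s)
  co <- stats::mvfft(t(m))[seq_len(kmax) + 1L, , drop = FALSE]
  amp <- 2 * Mod(co) / n
  if (n %% 2 == 0) amp[kmax, ] <- Mod(co[kmax, ]) / n
  inband <- freq >= band[1] & freq <= band[2]
  if (!any(inband)) stop("no frequency bins inside the band")
  vals3 <- array(0, dim = d[1:3])
  vals3[mask] <- colMeans(amp[inband, , drop = FALSE])
  amplitude_map(vals3, "ALFF", mask, bold$voxel_size_mm, bold$affine,
                meta = list(band_hz = band))
}
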