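#' Discard initial volumes of a 4D image
#'
#' Removes the first `k` timepoints, the conventional guard against
#' pre-steady-state magnetisation: the default of 15 volumes leaves 230
#' of a 245-volume acquisition.
#'
#' @param bold A [bold_image()].
#' @param k Number of leading volumes to drop (default 15).
#' @return A [bold_image()] with `k` fewer timepoints.
#' @export
discard_initial_volumes <- function(bold, k = 15L) {
  stopifnot(inherits(bold, "bold_image"))
  nt <- dim(bold$data)[4]
  if (k < 0) stop("`k` must be non-negative")
  if (k >= nt)
    stop(sprintf("cannot discard %d volumes from a %d-timepoint image", k, nt))
  if (k == 0) return(bold)
  out <- bold
  out$data <- bold$data[, , , -(seq_len(k)), drop = FALSE]
  out$meta$volumes_discarded <- k
  out
}

#' Motion-based subject exclusion rule
#'
#' A subject is excluded when any translation exceeds
#' `max_translation_mm` in absolute value on any axis at any timepoint,
#' or any rotation exceeds `max_rotation_deg`. Both comparisons are
#' strict (a displacement of exactly 1.5 mm is kept under the default
#' "> 1.5 mm" rule). The returned reason names the first violation.
#'
#' @param trace A `motion_trace` data.frame (see
#'   [generate_motion_trace()] / [read_motion_trace()]).
#' @param max_translation_mm Translation threshold, mm (default 1.5).
#' @param max_rotation_deg Rotation threshold, degrees (default 1.5).
#' @return A list: `exclude` (logical), `reason` (character or NA),
#'   `axis`, `timepoint`.
#' @export
motion_exclusion <- function(trace, max_translation_mm = 1.5,
                             max_rotation_deg = 1.5) {
  if (nrow(trace) < 1) stop("empty motion trace")
  cols <- c(trans_x = "trans_x", trans_y = "trans_y", trans_z = "trans_z",
            rot_x = "rot_x", rot_y = "rot_y", rot_z = "rot_z")
  lim <- c(rep(max_translation_mm, 3), rep(max_rotation_deg, 3))
  for (j in seq_along(cols)) {
    v <- abs(trace[[cols[j]]])
    hit <- which(v > lim[j])
    if (length(hit) > 0) {
      tp <- hit[1]
      unit <- if (j <= 3) "mm" else "deg"
      reason <- sprintf("%s = %.3f %s at timepoint %d exceeds %.3g %s",
                        cols[j], trace[[cols[j]]][tp], unit, tp, lim[j], unit)
      return(list(exclude = TRUE, reason = reason, axis = names(cols)[j],
                  timepoint = tp))
    }
  }
  list(exclude = FALSE, reason = NA_character_, axis = NA_character_,
       timepoint = NA_integer_)
}

#' Nuisance regression of ROI mean signals
#'
#' Regresses each voxel's time series on an intercept plus the mean
#' series of each regressor mask (conventionally central white matter and
#' the ventricles) by ordinary least squares, and returns the residuals
#' with the voxel's original mean added back. Restoring the mean keeps
#' the series strictly positive so the PerAF denominator stays
#' well-defined; the de-meaned output is orthogonal to every regressor.
#'
#' @param bold A [bold_image()].
#' @param regressor_masks Named or unnamed list of logical 3D arrays.
#' @return A [bold_image()] of the same shape; `meta$nuisance_regressors`
#'   records the regressor names.
#' @export
nuisance_regression <- function(bold, regressor_masks) {
  stopifnot(inherits(bold, "bold_image"))
  if (length(regressor_masks) == 0) stop("no regressor masks supplied")
  d <- dim(bold$data)
  nvox <- prod(d[1:3]); nt <- d[4]
  nm <- names(regressor_masks)
  if (is.null(nm)) nm <- sprintf("regressor_%d", seq_along(regressor_masks))
  Y <- t(matrix(bold$data, nrow = nvox, ncol = nt))  # time x voxels
  X <- matrix(1, nrow = nt, ncol = 1 + length(regressor_masks))
  for (j in seq_along(regressor_masks)) {
    msk <- as_mask(regressor_masks[[j]], d[1:3])
    if (!any(msk)) stop(sprintf("regressor mask '%s' is empty", nm[j]))
    r <- rowMeans(Y[, as.vector(msk), drop = FALSE])
    if (stats::sd(r) == 0)
      stop(sprintf("regressor '%s' is constant", nm[j]))
    X[, j + 1] <- r
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop1 <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop(sprintf("collinear nuisance regressors: %s",
                 paste(c("intercept", nm)[drop1], collapse = ", ")))
  }
  resid <- Y - X %*% qr.coef(qrX, Y)
  mu <- colMeans(Y)
  out <- bold
  out$data <- array(t(resid + rep(mu, each = nt)), dim = d)
  out$meta$nuisance_regressors <- nm
  out
}

#' Remove a linear trend, preserving the mean
#'
#' Fits and subtracts a least-squares line per series, then restores the
#' original mean (so amplitude metrics keep their positive denominator).
#' Works on a numeric vector or voxelwise on a [bold_image()].
#'
#' @param x Numeric vector (length >= 3) or [bold_image()].
#' @return Same type as the input.
#' @export
linear_detrend <- function(x) {
  if (inherits(x, "bold_image")) {
    d <- dim(x$data)
    nt <- d[4]
    Y <- t(matrix(x$data, nrow = prod(d[1:3]), ncol = nt))
    X <- cbind(1, seq_len(nt))
    resid <- Y - X %*% qr.coef(qr(X), Y)
    out <- x
    out$data <- array(t(resid + rep(colMeans(Y), each = nt)), dim = d)
    out$meta$detrended <- TRUE
    return(out)
  }
  if (length(x) < 3) stop("detrending needs at least 3 timepoints")
  t_ <- seq_along(x)
  fit <- stats::lm.fit(cbind(1, t_), x)
  fit$residuals + mean(x)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Reflective-boundary 1D Gaussian convolution matrix of size n, sigma in
# sample units. Rows sum to 1 (constant fields are fixed points).
conv_matrix_1d <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  off <- (-r):r
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    # reflect indices about the edges (half-sample symmetric)
    j <- ifelse(j < 1, 2 - j, j)
    j <- ifelse(j > n, 2 * n - j, j)
    j <- pmin(pmax(j, 1L), n)
    for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + w[t]
  }
  K
}

# Separable 3D Gaussian smoothing, sigma in voxels (scalar or length 3).
gaussian_smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  s <- rep(sigma_vox, length.out = 3)
  if (all(s <= 0)) return(arr)
  K1 <- conv_matrix_1d(d[1], s[1])
  K2 <- conv_matrix_1d(d[2], s[2])
  K3 <- conv_matrix_1d(d[3], s[3])
  x <- array(K1 %*% matrix(arr, d[1], d[2] * d[3]), dim = d)
  x <- aperm(array(K2 %*% matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3]),
                   dim = d[c(2, 1, 3)]), c(2, 1, 3))
  x <- aperm(array(K3 %*% matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2]),
                   dim = d[c(3, 1, 2)]), c(2, 3, 1))
  x
}

#' Gaussian smoothing of a 3D map
#'
#' Separable 3D Gaussian filter with
#' \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})} per axis, specified in
#' mm and converted to voxels via the map's voxel size. Boundaries are
#' handled by reflection, which preserves the mean of interior regions
#' and leaves constant maps unchanged. `fwhm_mm = 0` is the identity.
#'
#' @param map An [amplitude_map()].
#' @param fwhm_mm Full width at half maximum of the kernel, mm (>= 0).
#' @return A smoothed [amplitude_map()] on the same mask.
#' @export
gaussian_smooth_map <- function(map, fwhm_mm) {
  stopifnot(inherits(map, "amplitude_map"))
  if (fwhm_mm < 0) stop("`fwhm_mm` must be non-negative")
  if (fwhm_mm == 0) return(map)
  sig <- fwhm_to_sigma(fwhm_mm) / map$voxel_size_mm
  vals <- gaussian_smooth3d(map$values, sig)
  amplitude_map(vals, map$metric, map$mask, map$voxel_size_mm, map$affine,
                meta = c(map$meta, list(smoothed_fwhm_mm = fwhm_mm)))
}

#' Subject-level temporal preprocessing
#'
#' Runs the fixed temporal pipeline on one subject: discard the first
#' `k_discard` volumes, check the motion trace against the exclusion
#' thresholds, regress out the nuisance ROI mean signals, and remove the
#' linear trend (the voxel mean is restored after both regression
#' steps). Returns the processed image together with a per-subject
#' report; excluded subjects return `bold = NULL` and the rule that
#' excluded them.
#'
#' @param bold A [bold_image()].
#' @param motion Optional `motion_trace`; `NULL` skips motion QC.
#' @param regressor_masks Optional list of nuisance masks; `NULL` skips
#'   nuisance regression.
#' @param k_discard Leading volumes to drop (default 15).
#' @param max_translation_mm,max_rotation_deg Motion thresholds.
#' @param detrend Remove the linear trend (default TRUE).
#' @return A list: `bold` (processed [bold_image()] or `NULL`),
#'   `report` (list: subject_id, volumes_discarded, excluded,
#'   exclusion_reason, nuisance_regressors).
#' @export
preprocess_subject <- function(bold, motion = NULL, regressor_masks = NULL,
                               k_discard = 15L, max_translation_mm = 1.5,
                               max_rotation_deg = 1.5, detrend = TRUE) {
  stopifnot(inherits(bold, "bold_image"))
  report <- list(subject_id = bold$meta$subject_id %||% NA_character_,
                 volumes_discarded = k_discard,
                 excluded = FALSE, exclusion_reason = NA_character_,
                 nuisance_regressors = character(0))
  if (!is.null(motion)) {
    qc <- motion_exclusion(motion, max_translation_mm, max_rotation_deg)
    if (qc$exclude) {
      report$excluded <- TRUE
      report$exclusion_reason <- qc$reason
      return(list(bold = NULL, report = report))
    }
  }
  out <- discard_initial_volumes(bold, k_discard)
  if (!is.null(regressor_masks) && length(regressor_masks) > 0) {
    out <- nuisance_regression(out, regressor_masks)
    report$nuisance_regressors <- out$meta$nuisance_regressors
  }
  if (detrend) out <- linear_detrend(out)
  list(bold = out, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
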