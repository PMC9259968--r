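#' Configuration for a synthetic two-group BOLD cohort
#'
#' Describes everything needed to simulate a resting-state cohort with a
#' planted regional amplitude effect: the grid and timing, the
#' band-limited fluctuation process, the effect regions and their
#' attenuation factor, and the master seed. The defaults emulate a
#' desk-scale version of a typical 3 T resting scan: TR 2 s, 245 volumes
#' (so 230 remain after the conventional 15-volume discard), positive
#' baseline intensity far above the fluctuation scale, and fluctuations
#' confined to the 0.01-0.08 Hz resting-state band.
#'
#' The group effect is a *reduction* of fluctuation amplitude: inside each
#' effect ROI, patient-group signal amplitude is multiplied by
#' `effect_factor` (1 = no effect, groups exchangeable).
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param voxel_size_mm Positive scalar, mm.
#' @param tr_s Repetition time, seconds.
#' @param n_timepoints Timepoints per subject, before any discard.
#' @param n_per_group Subjects per group.
#' @param baseline_intensity Mean BOLD level (arbitrary scanner units).
#' @param fluct_amplitude Standard deviation of the band-limited signal
#'   component, same units as the baseline.
#' @param fluct_band_hz Length-2 numeric, (low, high) band edges in Hz.
#' @param effect_rois List of `list(center = c(i, j, k), radius = r)`
#'   spheres (1-based voxel indices, radius in voxels).
#' @param effect_factor Multiplier in (0, 1] applied to the fluctuation
#'   amplitude inside effect ROIs for the patient group.
#' @param noise_sd White measurement noise standard deviation.
#' @param spatial_fwhm_mm Non-negative; FWHM of optional 3D smoothing of
#'   the signal component (0 = none).
#' @param seed Master integer seed; per-subject seeds are derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(24L, 24L, 24L),
                       voxel_size_mm = 3,
                       tr_s = 2,
                       n_timepoints = 245L,
                       n_per_group = 18L,
                       baseline_intensity = 1000,
                       fluct_amplitude = 20,
                       fluct_band_hz = c(0.01, 0.08),
                       effect_rois = list(
                         list(center = c(8L, 8L, 16L), radius = 3),
                         list(center = c(17L, 17L, 8L), radius = 3)),
                       effect_factor = 0.5,
                       noise_sd = 10,
                       spatial_fwhm_mm = 0,
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (baseline_intensity <= 0) stop("`baseline_intensity` must be positive")
  if (fluct_amplitude < 0) stop("`fluct_amplitude` must be non-negative")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (spatial_fwhm_mm < 0) stop("`spatial_fwhm_mm` must be non-negative")
  if (length(fluct_band_hz) != 2L || fluct_band_hz[1] <= 0 ||
      fluct_band_hz[2] <= fluct_band_hz[1])
    stop("`fluct_band_hz` must satisfy 0 < low < high")
  if (fluct_band_hz[2] > 1 / (2 * tr_s))
    stop(sprintf("band high edge %.4g Hz exceeds Nyquist %.4g Hz for TR %.3g s",
                 fluct_band_hz[2], 1 / (2 * tr_s), tr_s))
  if (effect_factor <= 0 || effect_factor > 1)
    stop("`effect_factor` must lie in (0, 1]")
  for (roi in effect_rois) {
    ctr <- roi$center; r <- roi$radius
    if (any(ctr - r < 1) || any(ctr + r > grid_shape))
      stop("effect ROI sphere extends outside the grid")
  }
  if (n_per_group < 1) stop("`n_per_group` must be >= 1")
  if (n_timepoints < 2) stop("`n_timepoints` must be >= 2")
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
         n_timepoints = as.integer(n_timepoints),
         n_per_group = as.integer(n_per_group),
         baseline_intensity = baseline_intensity,
         fluct_amplitude = fluct_amplitude,
         fluct_band_hz = fluct_band_hz,
         effect_rois = effect_rois, effect_factor = effect_factor,
         noise_sd = noise_sd, spatial_fwhm_mm = spatial_fwhm_mm,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> grid %s, TR %.3g s, %d tp, %d+%d subjects, effect_factor %.3g in %d ROI(s), seed %d\n",
              paste(x$grid_shape, collapse = "x"), x$tr_s, x$n_timepoints,
              x$n_per_group, x$n_per_group, x$effect_factor,
              length(x$effect_rois), x$seed))
  invisible(x)
}

#' Spherical binary mask on a voxel grid
#'
#' Includes every voxel whose Euclidean distance (in voxel units) from
#' `center` is at most `radius`. The sphere is clipped at grid edges but
#' always contains at least the centre voxel.
#'
#' @param grid_shape Integer triple.
#' @param center 1-based voxel index triple; must lie inside the grid.
#' @param radius Non-negative radius in voxels.
#' @return Logical 3D array.
#' @export
make_sphere_mask <- function(grid_shape, center, radius) {
  grid_shape <- as.integer(grid_shape)
  if (radius < 0) stop("`radius` must be non-negative")
  if (any(center < 1) || any(center > grid_shape))
    stop("`center` must lie inside the grid")
  dx2 <- (seq_len(grid_shape[1]) - center[1])^2
  dy2 <- (seq_len(grid_shape[2]) - center[2])^2
  dz2 <- (seq_len(grid_shape[3]) - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(d2 <= radius^2 + 1e-12, dim = grid_shape)
}

# Derive a per-subject seed from the master seed and subject index.
# Simple multiplicative mix kept strictly below 2^31.
subject_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 7919 + as.double(index) * 104729) %%
               2147483647)
}

#' Simulate one subject's 4D BOLD image
#'
#' Every voxel time series is `baseline + band-limited Gaussian signal +
#' white noise`. The signal is synthesised in the frequency domain:
#' independent complex-Gaussian Fourier coefficients on the grid
#' frequencies inside `fluct_band_hz` (Hermitian-symmetrised), scaled so
#' the signal's population standard deviation is exactly
#' `fluct_amplitude`. For the patient group, amplitude inside each effect
#' ROI is multiplied by `effect_factor`. If any resulting intensity is
#' non-positive the whole image is shifted up to a minimum of 1 and the
#' shift recorded in `meta$positivity_shift` (with the defaults,
#' baseline >= 10 * (amplitude + noise), no shift ever occurs).
#'
#' @param config A [sim_config()].
#' @param group `"patient"` or `"control"`.
#' @param subject_seed Integer seed for this subject's draws.
#' @return A [bold_image()] of shape `grid_shape x n_timepoints`.
#' @export
generate_subject_bold <- function(config, group = c("control", "patient"),
                                  subject_seed) {
  stopifnot(inherits(config, "sim_config"))
  group <- match.arg(group)
  nt <- config$n_timepoints
  nvox <- prod(config$grid_shape)
  # grid frequencies k/(nt * tr); band bins (excluding DC and Nyquist
  # asymmetry concerns: only k < nt/2 carry a conjugate pair)
  kmax <- floor((nt - 1) / 2)
  freqs <- seq_len(kmax) / (nt * config$tr_s)
  band <- which(freqs >= config$fluct_band_hz[1] &
                  freqs <= config$fluct_band_hz[2])
  set.seed(subject_seed)
  if (config$fluct_amplitude > 0 && length(band) > 0) {
    m <- length(band)
    co <- matrix(0 + 0i, nrow = nt, ncol = nvox)
    re <- matrix(stats::rnorm(m * nvox), m, nvox)
    im <- matrix(stats::rnorm(m * nvox), m, nvox)
    co[band + 1L, ] <- complex(real = re, imaginary = im)
    co[nt - band + 1L, ] <- Conj(co[band + 1L, , drop = FALSE])
    # x_t = Re(sum_k C_k e^{2pi i k t / nt}); each band bin contributes
    # variance 4 (unit-variance real and imaginary parts), total 4m
    signal <- Re(stats::mvfft(co, inverse = TRUE)) *
      (config$fluct_amplitude / (2 * sqrt(m)))
    signal <- t(signal)  # voxels x time
    if (group == "patient" && config$effect_factor < 1) {
      for (roi in config$effect_rois) {
        msk <- make_sphere_mask(config$grid_shape, roi$center, roi$radius)
        signal[as.vector(msk), ] <- signal[as.vector(msk), ] * config$effect_factor
      }
    }
  } else {
    signal <- matrix(0, nrow = nvox, ncol = nt)
  }
  arr <- array(signal, dim = c(config$grid_shape, nt))
  if (config$spatial_fwhm_mm > 0) {
    sig_vox <- fwhm_to_sigma(config$spatial_fwhm_mm) / config$voxel_size_mm
    for (t in seq_len(nt))
      arr[, , , t] <- gaussian_smooth3d(arr[, , , t], sig_vox)
  }
  arr <- arr + config$baseline_intensity
  if (config$noise_sd > 0)
    arr <- arr + array(stats::rnorm(length(arr), sd = config$noise_sd), dim = dim(arr))
  meta <- list(group = group, subject_seed = subject_seed,
               positivity_shift = 0)
  mn <- min(arr)
  if (mn <= 0) {
    shift <- 1 - mn
    arr <- arr + shift
    meta$positivity_shift <- shift
  }
  bold_image(arr, config$voxel_size_mm, config$tr_s, meta = meta)
}

#' Simulate a two-group cohort with ground truth
#'
#' Generates `2 * n_per_group` subjects (controls first, then patients),
#' each from a seed derived deterministically from the master seed, and
#' returns the images together with the ground truth: the effect ROI
#' masks, the expected patient/control amplitude ratio inside them, and
#' the group labels. Optionally writes the cohort to disk as NIfTI images
#' plus a labels TSV, ROI masks and a JSON copy of the configuration.
#'
#' @param config A [sim_config()].
#' @param output_dir Optional directory; when given, files are written.
#' @return A list with elements `images` (list of [bold_image()]),
#'   `labels` (data.frame: subject_id, group) and `ground_truth` (list:
#'   `roi_masks`, `true_amplitude_ratio`, `labels`).
#' @export
generate_cohort <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_per_group
  groups <- rep(c("control", "patient"), each = n)
  ids <- sprintf("sub-%02d", seq_len(2 * n))
  images <- vector("list", 2 * n)
  for (i in seq_len(2 * n)) {
    images[[i]] <- generate_subject_bold(config, groups[i],
                                         subject_seed(config$seed, i))
    images[[i]]$meta$subject_id <- ids[i]
  }
  roi_masks <- lapply(config$effect_rois, function(roi)
    make_sphere_mask(config$grid_shape, roi$center, roi$radius))
  labels <- data.frame(subject_id = ids, group = groups,
                       stringsAsFactors = FALSE)
  gt <- list(roi_masks = roi_masks,
             true_amplitude_ratio = config$effect_factor,
             labels = labels)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir))
      dir.create(output_dir, recursive = TRUE)
    for (i in seq_len(2 * n)) {
      p <- file.path(output_dir, paste0(ids[i], "_bold.nii.gz"))
      ok <- try(write_volume(images[[i]], p), silent = TRUE)
      if (inherits(ok, "try-error"))
        stop(sprintf("failed to write %s: %s", p, as.character(ok)))
    }
    utils::write.table(labels, file.path(output_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (r in seq_along(roi_masks))
      write_volume(roi_masks[[r]],
                   file.path(output_dir, sprintf("roi-%02d_mask.nii.gz", r)),
                   voxel_size_mm = config$voxel_size_mm)
    cfg <- unclass(config)
    jsonlite::write_json(cfg, file.path(output_dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(images = images, labels = labels, ground_truth = gt)
}

#' Simulate a rigid-body head-motion trace
#'
#' Produces per-timepoint x/y/z translations (mm) and rotations (degrees)
#' as bounded Gaussian random walks, in the 6-column realignment-parameter
#' convention. When `max_disp_mm` is finite it acts as a hard cap on the
#' absolute translations (the walk is clamped); pass `max_disp_mm = Inf`
#' to generate unconstrained traces, e.g. deliberate threshold
#' violations.
#'
#' @param n_timepoints Number of rows (>= 1).
#' @param max_disp_mm Hard cap on |translation| per axis (mm); `Inf`
#'   disables the cap. `0` yields an all-zero trace.
#' @param seed Integer seed.
#' @param step_sd_mm Random-walk step SD for translations, mm.
#' @param step_sd_deg Random-walk step SD for rotations, degrees.
#' @return A data.frame of class `motion_trace` with columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`.
#' @export
generate_motion_trace <- function(n_timepoints, max_disp_mm = 1.0, seed = 1L,
                                  step_sd_mm = 0.05, step_sd_deg = 0.05) {
  if (n_timepoints < 1) stop("`n_timepoints` must be >= 1")
  set.seed(seed)
  walk <- function(sd, cap) {
    if (cap == 0) return(rep(0, n_timepoints))
    w <- cumsum(stats::rnorm(n_timepoints, sd = sd))
    if (is.finite(cap)) w <- pmin(pmax(w, -cap), cap)
    w
  }
  out <- data.frame(
    trans_x = walk(step_sd_mm, max_disp_mm),
    trans_y = walk(step_sd_mm, max_disp_mm),
    trans_z = walk(step_sd_mm, max_disp_mm),
    rot_x = walk(step_sd_deg, Inf),
    rot_y = walk(step_sd_deg, Inf),
    rot_z = walk(step_sd_deg, Inf))
  class(out) <- c("motion_trace", "data.frame")
  out
}

#' Read a 6-column realignment-parameter motion trace
#'
#' @param path Whitespace-delimited text file, 6 columns: three
#'   translations (mm) then three rotations (degrees).
#' @return A `motion_trace` data.frame.
#' @export
read_motion_trace <- function(path) {
  m <- utils::read.table(path, header = FALSE)
  if (ncol(m) != 6)
    stop(sprintf("motion file %s has %d columns, expected 6", path, ncol(m)))
  names(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  class(m) <- c("motion_trace", "data.frame")
  m
}
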