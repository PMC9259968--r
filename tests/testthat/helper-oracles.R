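# Independent oracles and shared fixtures, kept deliberately naive so
# they stay independent of the implementation paths they check.

# Literal loop transcription of the PerAF definition.
naive_peraf <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  acc <- 0
  for (i in seq_len(n)) acc <- acc + abs((x[i] - mu) / mu)
  100 * acc / n
}

# AUC by exhaustive pair counting (Mann-Whitney), ties counted one half.
# `pos`/`neg` are the feature values for the two classes, oriented so
# that larger values are more "positive".
pair_count_auc <- function(pos, neg) {
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + if (p > q) 1 else if (p == q) 0.5 else 0
  conc / (length(pos) * length(neg))
}

# Normal-equations OLS residuals (solve(t(X) X) t(X) y), independent of
# the QR route used in the package.
normal_eq_residuals <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# Direct (non-separable) 3D Gaussian convolution with reflective
# boundaries, as a smoothing oracle on tiny grids.
direct_gauss3d <- function(arr, sigma) {
  d <- dim(arr)
  r <- max(1L, ceiling(4 * sigma))
  off <- (-r):r
  w1 <- exp(-off^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  refl <- function(j, n) {
    j <- ifelse(j < 1, 2 - j, j)
    j <- ifelse(j > n, 2 * n - j, j)
    pmin(pmax(j, 1L), n)
  }
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s <- 0
    for (a in seq_along(off)) for (b in seq_along(off)) for (cc in seq_along(off))
      s <- s + w1[a] * w1[b] * w1[cc] *
        arr[refl(i + off[a], d[1]), refl(j + off[b], d[2]),
            refl(k + off[cc], d[3])]
    out[i, j, k] <- s
  }
  out
}

# Desk-scale cohort configuration with two planted spherical ROIs and a
# halved fluctuation amplitude in patients; used across the group-level
# tests so all of them see the same study conditions.
test_cohort_config <- function(seed = 1L, n_per_group = 18L,
                               effect_factor = 0.5) {
  sim_config(grid_shape = c(16L, 16L, 16L), voxel_size_mm = 3, tr_s = 2,
             n_timepoints = 115L, n_per_group = n_per_group,
             baseline_intensity = 1000, fluct_amplitude = 20,
             fluct_band_hz = c(0.01, 0.08),
             effect_rois = list(list(center = c(5L, 5L, 11L), radius = 3),
                                list(center = c(12L, 12L, 5L), radius = 3)),
             effect_factor = effect_factor, noise_sd = 10,
             spatial_fwhm_mm = 0, seed = seed)
}

# Wrap a plain 3D array as a PerAF-metric amplitude map (positive shift
# keeps the values legal for mean scaling in the tests that need it).
as_test_map <- function(arr, voxel_size_mm = 1, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(arr))
  amplitude_map(arr, "PerAF", mask, voxel_size_mm)
}

# Tiny preprocessed bold image from an explicit voxel x time matrix.
bold_from_matrix <- function(m, grid, voxel_size_mm = 3, tr_s = 2) {
  bold_image(array(m, dim = c(grid, ncol(m))), voxel_size_mm, tr_s)
}
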