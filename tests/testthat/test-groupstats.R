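make_maps <- function(arrs, voxel_size_mm = 1) {
  lapply(arrs, as_test_map, voxel_size_mm = voxel_size_mm)
}

test_that("voxelwise t is antisymmetric under group swap and 0 for identical groups", {
  set.seed(21)
  d <- c(5L, 5L, 5L)
  ga <- make_maps(lapply(1:4, function(i) array(rnorm(prod(d), 5), d)))
  gb <- make_maps(lapply(1:4, function(i) array(rnorm(prod(d), 5), d)))
  st <- voxelwise_ttest(ga, gb)
  sw <- voxelwise_ttest(gb, ga)
  expect_identical(st$t, -sw$t)
  expect_equal(st$df, 6L)
  same <- voxelwise_ttest(ga, ga)
  expect_true(all(same$t == 0))
})

test_that("voxelwise t matches stats::t.test on extracted voxel vectors", {
  set.seed(22)
  d <- c(4L, 3L, 2L)
  ga <- make_maps(lapply(1:5, function(i) array(rnorm(prod(d), 3, 2), d)))
  gb <- make_maps(lapply(1:7, function(i) array(rnorm(prod(d), 4, 2), d)))
  st <- voxelwise_ttest(ga, gb)
  for (v in sample(prod(d), 6)) {
    ijk <- arrayInd(v, d)
    a <- vapply(ga, function(m) m$values[ijk], 0)
    b <- vapply(gb, function(m) m$values[ijk], 0)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(st$t[ijk], unname(ref$statistic), tolerance = 1e-10)
  }
  expect_equal(st$df, 10L)
})

test_that("zero-variance voxels are flagged, not infinite", {
  d <- c(3L, 3L, 3L)
  ga <- make_maps(lapply(1:3, function(i) array(1, d)))
  gb <- make_maps(lapply(1:3, function(i) array(2, d)))
  st <- voxelwise_ttest(ga, gb)
  expect_true(all(is.finite(st$t)))
  expect_equal(st$meta$zero_variance_voxels, prod(d))
  expect_error(voxelwise_ttest(ga[1], gb), "at least 2")
})

test_that("connected components respect 6/18/26 connectivity", {
  d <- c(7L, 7L, 7L)
  m <- array(FALSE, d)
  # two voxels sharing a face: one cluster at any connectivity
  m[2, 2, 2] <- m[3, 2, 2] <- TRUE
  expect_equal(max(label_components(m, 6)), 1)
  # an edge-diagonal pair: separate at 6, joined at 18
  m2 <- array(FALSE, d); m2[2, 2, 2] <- m2[3, 3, 2] <- TRUE
  expect_equal(max(label_components(m2, 6)), 2)
  expect_equal(max(label_components(m2, 18)), 1)
  # a corner-diagonal pair: separate at 18, joined at 26
  m3 <- array(FALSE, d); m3[2, 2, 2] <- m3[3, 3, 3] <- TRUE
  expect_equal(max(label_components(m3, 18)), 2)
  expect_equal(max(label_components(m3, 26)), 1)
  expect_error(label_components(m3, 10), "6, 18 or 26")
})

test_that("cluster extraction conserves suprathreshold voxel counts per tail", {
  set.seed(23)
  d <- c(10L, 10L, 10L)
  ga <- make_maps(lapply(1:6, function(i) array(rnorm(prod(d)), d)))
  gb <- make_maps(lapply(1:6, function(i) array(rnorm(prod(d)), d)))
  st <- voxelwise_ttest(ga, gb)
  tab <- extract_clusters(st, voxel_p = 0.2, connectivity = 18)
  tcrit <- qt(1 - 0.2 / 2, df = st$df)
  expect_equal(sum(tab$size[tab$direction == "pos"]), sum(st$t > tcrit))
  expect_equal(sum(tab$size[tab$direction == "neg"]), sum(st$t < -tcrit))
  # sizes sorted descending; each peak |t| is the cluster maximum
  expect_true(all(diff(tab$size) <= 0))
  la <- attr(tab, "label_array")
  for (r in seq_len(nrow(tab))) {
    code <- if (tab$direction[r] == "pos") tab$label[r] else -tab$label[r]
    expect_equal(max(abs(st$t[la == code])), abs(tab$peak_t[r]))
  }
  # an all-zero map yields an empty table, not an error
  z <- voxelwise_ttest(ga, ga)
  expect_equal(nrow(extract_clusters(z, 0.01)), 0)
})

test_that("peak coordinates are reported in mm through the affine", {
  d <- c(9L, 9L, 9L)
  arr0 <- array(0, d)
  pos <- arr0; pos[3, 4, 5] <- 1
  ga <- make_maps(list(pos + 0.01, pos + 0.02, pos - 0.01), voxel_size_mm = 2)
  gb <- make_maps(list(arr0, arr0 + 0.001, arr0 - 0.001), voxel_size_mm = 2)
  st <- voxelwise_ttest(ga, gb)
  tab <- extract_clusters(st, voxel_p = 0.01)
  big <- tab[which.max(abs(tab$peak_t)), ]
  expect_equal(c(big$peak_i, big$peak_j, big$peak_k), c(3, 4, 5))
  # centred affine: voxel (5,5,5) of a 9-grid is 0 mm; (3,4,5) -> (-4,-2,0)
  expect_equal(c(big$peak_x_mm, big$peak_y_mm, big$peak_z_mm), c(-4, -2, 0))
})

test_that("fixed-size correction applies the strict >40 rule", {
  tab <- data.frame(label = 1:3, direction = "neg", size = c(40L, 41L, 12L),
                    peak_t = c(-5, -6, -4))
  class(tab) <- c("cluster_table", "data.frame")
  spec <- correction_spec(min_cluster_voxels = 40L)
  out <- significant_clusters(tab, spec)
  expect_identical(out$significant, c(FALSE, TRUE, FALSE))
  empty <- tab[0, ]
  expect_equal(nrow(significant_clusters(empty, spec)), 0)
  expect_error(correction_spec(min_cluster_voxels = NULL, monte_carlo = NULL),
               "either")
})

test_that("monte carlo threshold is deterministic and voxel-p monotone", {
  mask <- array(TRUE, c(12L, 12L, 12L))
  m1 <- monte_carlo_cluster_threshold(mask, fwhm_mm = 2, voxel_size_mm = 1,
                                      voxel_p = 0.01, n_iterations = 200,
                                      seed = 31)
  m2 <- monte_carlo_cluster_threshold(mask, fwhm_mm = 2, voxel_size_mm = 1,
                                      voxel_p = 0.01, n_iterations = 200,
                                      seed = 31)
  expect_identical(as.integer(m1), as.integer(m2))
  expect_gte(m1, 1)
  # stricter voxel threshold cannot need larger clusters
  m_strict <- monte_carlo_cluster_threshold(mask, fwhm_mm = 2,
                                            voxel_size_mm = 1,
                                            voxel_p = 0.001,
                                            n_iterations = 200, seed = 31)
  expect_lte(m_strict, m1)
  # unsmoothed noise at a very strict threshold: isolated voxels only
  m_iso <- monte_carlo_cluster_threshold(mask, fwhm_mm = 0, voxel_size_mm = 1,
                                         voxel_p = 1e-6, n_iterations = 200,
                                         seed = 31)
  expect_equal(as.integer(m_iso), 1L)
  expect_error(monte_carlo_cluster_threshold(array(FALSE, c(3, 3, 3)), 2, 1),
               "empty")
})

test_that("a strong planted effect yields exactly the two ground-truth clusters", {
  cfg <- test_cohort_config(seed = 41L, n_per_group = 6L, effect_factor = 0.3)
  coh <- generate_cohort(cfg)
  mask <- array(TRUE, cfg$grid_shape)
  maps <- lapply(coh$images, function(b) {
    m <- peraf_map(discard_initial_volumes(b, 15), mask)
    gaussian_smooth_map(m, 6)
  })
  st <- voxelwise_ttest(maps[coh$labels$group == "patient"],
                        maps[coh$labels$group == "control"], mask)
  tab <- extract_clusters(st, voxel_p = 0.01)
  spec <- correction_spec(min_cluster_voxels = 40L)
  out <- significant_clusters(tab, spec)
  sig <- out[out$significant, ]
  expect_equal(nrow(sig), 2)
  expect_true(all(sig$direction == "neg"))
  la <- attr(out, "label_array")
  gt <- coh$ground_truth$roi_masks
  dice <- sapply(seq_len(nrow(sig)), function(r) {
    cm <- la == -sig$label[r]
    max(dice_coefficient(cm, gt[[1]]), dice_coefficient(cm, gt[[2]]))
  })
  expect_true(all(dice > 0.5))
})
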