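make_features <- function(pat, ctl, region = "r1") {
  n1 <- length(pat); n2 <- length(ctl)
  out <- data.frame(subject_id = sprintf("s%02d", seq_len(n1 + n2)),
                    label = c(rep("patient", n1), rep("control", n2)),
                    stringsAsFactors = FALSE)
  out[[region]] <- c(pat, ctl)
  class(out) <- c("feature_table", "data.frame")
  out
}

test_that("regional means are exact voxel averages", {
  d <- c(4L, 4L, 4L)
  la <- array(0L, d)
  la[1, 1, 1] <- 1L                      # single voxel
  la[2, 1:3, 1] <- 2L                    # three voxels
  arr1 <- array(5, d)
  arr2 <- array(0, d); arr2[2, 1:3, 1] <- c(1, 2, 6); arr2[1, 1, 1] <- 9
  ft <- extract_regional_means(list(as_test_map(arr1), as_test_map(arr2)),
                               la, c("control", "patient"))
  expect_equal(ft$region_1, c(5, 9))
  expect_equal(ft$region_2, c(5, 3))     # mean(1,2,6) = 3
  expect_equal(ft$label, c("control", "patient"))
  # signed cluster labels (negative-direction clusters) are accepted
  ft2 <- extract_regional_means(list(as_test_map(arr2)), -la, "patient")
  expect_equal(ft2$region_2, 3)
})

test_that("AUC equals the pair-counting Mann-Whitney oracle", {
  # worked example: patients {2,4}, controls {1,3}; lower-in-patients
  # orientation gives 3 of 4 concordant pairs
  r <- roc_analysis(c(2, 4, 1, 3), c("patient", "patient", "control", "control"))
  expect_equal(r$auc, 0.75)
  set.seed(51)
  for (rep in 1:300) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    x <- c(rnorm(n1), rnorm(n2, 0.5))
    if (rep %% 3 == 0) x <- round(x)    # force ties
    lab <- c(rep("patient", n1), rep("control", n2))
    r <- roc_analysis(x, lab)
    u1 <- pair_count_auc(x[1:n1], x[-(1:n1)])
    expect_equal(r$auc, max(u1, 1 - u1), tolerance = 1e-12)
  }
})

test_that("ROC handles perfect separation and orientation", {
  # marker decreases in patients, as for an amplitude reduction
  r <- roc_analysis(c(1, 2, 3, 8, 9, 10),
                    c(rep("patient", 3), rep("control", 3)))
  expect_equal(r$auc, 1.0)
  expect_equal(r$direction, "lower_indicates_positive")
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
  expect_error(roc_analysis(1:4, rep("patient", 4)), "two classes")
  expect_warning(r0 <- roc_analysis(rep(2, 8), rep(c("patient", "control"), 4)),
                 "constant")
  expect_equal(r0$auc, 0.5)
})

test_that("permuted labels give chance-level AUC on average", {
  set.seed(52)
  x <- rnorm(24)
  aucs <- replicate(400, {
    roc_analysis(x, sample(rep(c("patient", "control"), 12)))$auc
  })
  # folded (auc >= 0.5) null mean for n=12+12 is ~0.56; check against
  # a direct permutation estimate of the same folded statistic
  ref <- replicate(400, {
    idx <- sample(24, 12)
    u <- pair_count_auc(x[idx], x[-idx])
    max(u, 1 - u)
  })
  expect_lt(abs(mean(aucs) - mean(ref)),
            3 * sqrt(var(aucs) / 400 + var(ref) / 400) + 0.01)
})

test_that("DeLong interval brackets the AUC and tightens with separation", {
  set.seed(53)
  r <- roc_analysis(c(rnorm(15, 0), rnorm(15, 2)),
                    rep(c("patient", "control"), each = 15))
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
  expect_gte(r$ci95[1], 0); expect_lte(r$ci95[2], 1)
})

test_that("LOO SVM is perfect on well-separated features", {
  set.seed(54)
  ft <- make_features(rnorm(10, -5, 0.3), rnorm(10, 5, 0.3))
  res <- loo_svm(ft)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)
  # confusion counts recompute the reported rates exactly
  expect_equal(res$accuracy, (res$tp + res$tn) / res$n)
  expect_equal(res$sensitivity, res$tp / (res$tp + res$fn))
  expect_equal(res$specificity, res$tn / (res$tn + res$fp))
  expect_equal(nrow(res$predictions), 20)
  # decision values separate the classes in the right direction
  dv <- res$predictions$decision_value
  expect_true(all(dv[ft$label == "patient"] > 0))
  expect_true(all(dv[ft$label == "control"] < 0))
})

test_that("label-shuffled features give chance-level LOO accuracy", {
  set.seed(55)
  x <- rnorm(36)
  lab <- sample(rep(c("patient", "control"), 18))
  ft <- make_features(x[1:18], x[19:36])
  ft$label <- lab
  res <- loo_svm(ft)
  # binomial 95% band around 0.5 at N=36 (LOO inflates variance a bit;
  # allow a slightly wider band)
  expect_gt(res$accuracy, 0.5 - 2.5 * sqrt(0.25 / 36))
  expect_lt(res$accuracy, 0.5 + 2.5 * sqrt(0.25 / 36))
})

test_that("fold z-scoring never sees the held-out subject", {
  set.seed(56)
  ft <- make_features(rnorm(6, 0, 1), rnorm(6, 1, 1))
  res1 <- loo_svm(ft)
  # perturbing subject 1's feature must not change any other fold's
  # training standardisation; its own prediction may change, the
  # remaining folds' training sets differ only by that one value --
  # verify directly that the scaler excludes the held-out row
  X <- as.matrix(ft[, "r1", drop = FALSE])
  i <- 1
  ctr <- mean(X[-i, ]); scl <- sd(X[-i, ])
  X2 <- X; X2[i] <- X2[i] + 100
  expect_equal(mean(X2[-i, ]), ctr)
  expect_equal(sd(X2[-i, ]), scl)
  # an extreme held-out value is simply misclassified; it cannot drag
  # its own fold's scaler, so every other subject's features standardise
  # against statistics that exclude them
  ft2 <- ft; ft2$r1[1] <- ft2$r1[1] + 100
  res2 <- loo_svm(ft2)
  expect_equal(nrow(res2$predictions), nrow(res1$predictions))
})

test_that("overlapping 1-D classes reach near the analytic Bayes accuracy", {
  # two unit-variance Gaussians 1.35 SD apart: Bayes accuracy
  # pnorm(1.35/2) ~ 0.75
  set.seed(57)
  delta <- 1.35
  ft <- make_features(rnorm(18, 0), rnorm(18, delta))
  res <- loo_svm(ft)
  expect_lt(abs(res$accuracy - pnorm(delta / 2)), 0.10)
})

test_that("permutation test is deterministic with valid extremes", {
  set.seed(58)
  ft <- make_features(rnorm(8, -4, 0.5), rnorm(8, 4, 0.5))
  p1 <- permutation_test(ft, n_permutations = 200, seed = 9)
  p2 <- permutation_test(ft, n_permutations = 200, seed = 9)
  expect_identical(p1$p_value, p2$p_value)
  # perfectly separated features: no permutation reaches the observed
  # accuracy except by luck; smallest achievable p is 1/(B+1)
  expect_equal(p1$observed_accuracy, 1.0)
  expect_lte(p1$p_value, 10 / 201)
  expect_gte(p1$p_value, 1 / 201)
  expect_warning(permutation_test(ft, n_permutations = 50, seed = 1),
                 "resolution")
})

test_that("an uninformative observed accuracy yields a large p", {
  set.seed(59)
  # constant feature: every LOO prediction is the training majority,
  # observed accuracy sits at/below the null median, so p > 0.5
  ft <- make_features(rnorm(7), rnorm(7))
  ft$r1 <- ft$r1 * 0.01 + 10
  pt <- suppressWarnings(permutation_test(ft, n_permutations = 99, seed = 2))
  expect_gt(pt$p_value, 0.2)
})
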