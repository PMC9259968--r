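#' Regional mean amplitude features
#'
#' For each subject map and each labelled region, the mean map value over
#' the region's voxels — the per-region "average PerAF" features used for
#' ROC and SVM evaluation.
#'
#' @param maps List of [amplitude_map()]s, one per subject.
#' @param label_array Integer 3D array: 0 = background, each nonzero
#'   value (by absolute value, so signed cluster labels work) a region.
#' @param labels Character/factor vector of group labels, one per map.
#' @param subject_ids Optional subject identifiers.
#' @param region_names Optional names for the regions (defaults to
#'   `region_1`, ...).
#' @return A `feature_table` data.frame: `subject_id`, `label`, one
#'   numeric column per region.
#' @export
extract_regional_means <- function(maps, label_array, labels,
                                   subject_ids = NULL, region_names = NULL) {
  if (length(maps) != length(labels))
    stop("`maps` and `labels` lengths differ")
  la <- abs(label_array)
  regs <- sort(unique(la[la > 0]))
  if (length(regs) == 0) stop("label array contains no regions")
  if (is.null(region_names))
    region_names <- sprintf("region_%d", regs)
  if (is.null(subject_ids))
    subject_ids <- vapply(seq_along(maps), function(i)
      maps[[i]]$meta$subject_id %||% sprintf("sub-%02d", i), character(1))
  feat <- matrix(NA_real_, nrow = length(maps), ncol = length(regs),
                 dimnames = list(NULL, region_names))
  for (r in seq_along(regs)) {
    vox <- which(la == regs[r])
    if (length(vox) == 0) stop(sprintf("region %d is empty", regs[r]))
    for (i in seq_along(maps)) {
      if (!identical(dim(maps[[i]]$values), dim(la)))
        stop("map and label array grids differ")
      feat[i, r] <- mean(maps[[i]]$values[vox])
    }
  }
  out <- data.frame(subject_id = subject_ids,
                    label = as.character(labels),
                    feat, stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_columns <- function(features) {
  setdiff(names(features), c("subject_id", "label"))
}

#' ROC analysis of one regional feature
#'
#' Empirical ROC curve over all thresholds with trapezoid AUC (equal to
#' the normalised Mann-Whitney U statistic, ties counted one half),
#' DeLong 95% confidence interval, and the Youden-optimal operating
#' point (ties broken toward higher specificity). The curve is oriented
#' so AUC >= 0.5; `direction` records whether lower feature values
#' indicate the positive (patient) class, as for an amplitude marker
#' that decreases in disease.
#'
#' @param x Numeric feature vector.
#' @param labels Group labels, two levels.
#' @param positive Label of the "disease" class (default `"patient"` if
#'   present, else the rarer level).
#' @return A `roc_result` list: `auc`, `ci95`, `direction`
#'   (`"lower_indicates_positive"` or `"higher_indicates_positive"`),
#'   `cutoff`, `sensitivity`, `specificity`, `curve` (data.frame of
#'   sensitivity/specificity points), `n_positive`, `n_negative`.
#' @export
roc_analysis <- function(x, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must have exactly two classes")
  if (is.null(positive))
    positive <- if ("patient" %in% lev) "patient" else
      lev[which.min(table(labels)[lev])]
  negative <- setdiff(lev, positive)
  if (min(table(labels)) < 2)
    stop("need at least 2 subjects per class")
  if (stats::sd(x) == 0) {
    warning("constant feature: degenerate ROC curve, AUC 0.5")
    return(structure(list(
      auc = 0.5, ci95 = c(0, 1), direction = "higher_indicates_positive",
      cutoff = x[1], sensitivity = NA_real_, specificity = NA_real_,
      curve = data.frame(sensitivity = c(0, 1), specificity = c(1, 0)),
      n_positive = sum(labels == positive),
      n_negative = sum(labels == negative)), class = "roc_result"))
  }
  # orient explicitly so the reported AUC is >= 0.5: "<" means higher
  # values are more positive; flip when the marker decreases in patients
  r <- pROC::roc(response = factor(labels, levels = c(negative, positive)),
                 predictor = x, direction = "<", quiet = TRUE)
  if (as.numeric(pROC::auc(r)) < 0.5)
    r <- pROC::roc(response = factor(labels, levels = c(negative, positive)),
                   predictor = x, direction = ">", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  co <- pROC::coords(r, x = "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  co <- co[order(-co$specificity), , drop = FALSE][1, ]  # tie -> higher spec
  structure(list(
    auc = as.numeric(pROC::auc(r)),
    ci95 = c(max(0, ci[1]), min(1, ci[3])),
    direction = if (r$direction == ">") "lower_indicates_positive"
                else "higher_indicates_positive",
    cutoff = co$threshold,
    sensitivity = co$sensitivity, specificity = co$specificity,
    curve = data.frame(sensitivity = r$sensitivities,
                       specificity = r$specificities),
    n_positive = sum(labels == positive),
    n_negative = sum(labels == negative)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), sens %.3f / spec %.3f at cutoff %.4g (%s)\n",
              x$auc, x$ci95[1], x$ci95[2], x$sensitivity, x$specificity,
              x$cutoff, x$direction))
  invisible(x)
}

# z-score columns with supplied centre/scale; zero-SD columns pass
# through centred only (scale 1) so degenerate features cannot produce NaN.
fold_zscore <- function(m, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(m, 2, center), 2, scale, "/")
}

#' Leave-one-out linear SVM evaluation
#'
#' For each subject in turn: z-score the features using the training
#' fold's mean and SD only (no leakage from the held-out subject), fit a
#' linear soft-margin SVM on the remaining N - 1 subjects, and predict
#' the held-out subject. Confusion counts over the N held-out
#' predictions give sensitivity, specificity and accuracy; decision
#' values are retained so an ROC of the classifier output can be drawn.
#'
#' @param features A `feature_table` (or data.frame with `label` plus
#'   numeric feature columns).
#' @param cost Soft-margin cost C (default 1).
#' @param positive Positive-class label (default `"patient"` if present).
#' @return An `svm_result` list: `predictions` (data.frame: subject_id,
#'   label, predicted, decision_value), `tp`/`tn`/`fp`/`fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `n`, `positive`.
#' @export
loo_svm <- function(features, cost = 1, positive = NULL) {
  labels <- as.character(features$label)
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must have exactly two classes")
  if (is.null(positive))
    positive <- if ("patient" %in% lev) "patient" else lev[1]
  negative <- setdiff(lev, positive)
  X <- as.matrix(features[, feature_columns(features), drop = FALSE])
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects")
  if (any(table(labels) < 2))
    stop("each class needs at least 2 subjects so every training fold has both")
  pred <- character(n)
  dval <- numeric(n)
  yf <- factor(labels, levels = c(negative, positive))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    Xtr <- fold_zscore(X[tr, , drop = FALSE], ctr, scl)
    Xte <- fold_zscore(X[i, , drop = FALSE], ctr, scl)
    fit <- e1071::svm(Xtr, yf[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    p <- stats::predict(fit, Xte, decision.values = TRUE)
    pred[i] <- as.character(p)
    dv <- as.numeric(attr(p, "decision.values"))
    # orient the decision value so positive class -> positive sign
    if (colnames(attr(p, "decision.values"))[1] ==
        paste(positive, negative, sep = "/")) dval[i] <- dv else dval[i] <- -dv
  }
  tp <- sum(pred == positive & labels == positive)
  tn <- sum(pred == negative & labels == negative)
  fp <- sum(pred == positive & labels == negative)
  fn <- sum(pred == negative & labels == positive)
  structure(list(
    predictions = data.frame(
      subject_id = features$subject_id %||% seq_len(n),
      label = labels, predicted = pred, decision_value = dval,
      stringsAsFactors = FALSE),
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / n, n = n, positive = positive),
    class = "svm_result")
}

#' @export
print.svm_result <- function(x, ...) {
  cat(sprintf("<svm_result> N = %d: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              x$n, 100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Permutation test of leave-one-out SVM accuracy
#'
#' Builds the null distribution of global accuracy by shuffling the
#' group labels and re-running the entire leave-one-out procedure
#' (including fold-wise z-scoring) for each permutation. The p-value is
#' \eqn{(1 + \#\{\mathrm{null} \ge \mathrm{observed}\}) /
#' (1 + n_\mathrm{permutations})}, so it can never be exactly zero.
#'
#' @param features A `feature_table`.
#' @param n_permutations Number of label shuffles (default 1000; values
#'   below 100 warn about resolution).
#' @param seed Integer seed (deterministic given it).
#' @param cost,positive Passed to [loo_svm()].
#' @return A `permutation_result` list: `p_value`, `observed_accuracy`,
#'   `null_accuracies`, `n_permutations`, `observed` (the full
#'   [loo_svm()] result).
#' @export
permutation_test <- function(features, n_permutations = 1000L, seed = 1L,
                             cost = 1, positive = NULL) {
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")
  if (n_permutations < 100)
    warning("fewer than 100 permutations gives coarse p-value resolution")
  obs <- loo_svm(features, cost = cost, positive = positive)
  set.seed(seed)
  nullacc <- numeric(n_permutations)
  perm_feat <- features
  for (b in seq_len(n_permutations)) {
    perm_feat$label <- sample(features$label)
    nullacc[b] <- loo_svm(perm_feat, cost = cost,
                          positive = positive)$accuracy
  }
  p <- (1 + sum(nullacc >= obs$accuracy)) / (1 + n_permutations)
  structure(list(p_value = p, observed_accuracy = obs$accuracy,
                 null_accuracies = nullacc,
                 n_permutations = n_permutations, observed = obs),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed accuracy %.3f, p = %.4g (%d permutations; null mean %.3f)\n",
              x$observed_accuracy, x$p_value, x$n_permutations,
              mean(x$null_accuracies)))
  invisible(x)
}

#' Write a feature table as TSV
#'
#' @param features A `feature_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(as.data.frame(features), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
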