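#' Full pipeline configuration
#'
#' Aggregates every tunable of the analysis into one serialisable list:
#' simulation (or input paths), temporal preprocessing, the amplitude
#' metric, map smoothing, cluster correction, and discrimination
#' parameters. `paper_preset = TRUE` pins the replication parameter set:
#' discard 15 volumes, 1.5 mm motion threshold, voxel p 0.01, fixed
#' cluster-size rule > 40 voxels at alpha 0.05, and 10,000 SVM
#' permutations.
#'
#' @param sim A [sim_config()] (used when the cohort is simulated).
#' @param k_discard Leading volumes to drop.
#' @param max_translation_mm,max_rotation_deg Motion QC thresholds.
#' @param metric `"PerAF"` or `"ALFF"`.
#' @param smooth_fwhm_mm Map smoothing FWHM, mm.
#' @param correction A [correction_spec()]; default Monte-Carlo mode with
#'   the map-smoothing FWHM and 1000 iterations.
#' @param svm_cost Linear SVM cost.
#' @param n_permutations SVM permutation count.
#' @param seed Master seed for the stochastic stages (cluster simulation
#'   and the permutation test).
#' @param paper_preset Apply the pinned replication parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            k_discard = 15L,
                            max_translation_mm = 1.5,
                            max_rotation_deg = 1.5,
                            metric = c("PerAF", "ALFF"),
                            smooth_fwhm_mm = 6,
                            correction = NULL,
                            svm_cost = 1,
                            n_permutations = 1000L,
                            seed = 1L,
                            paper_preset = FALSE) {
  metric <- match.arg(metric)
  if (is.null(correction))
    correction <- correction_spec(
      voxel_p = 0.01, cluster_alpha = 0.05, min_cluster_voxels = NULL,
      monte_carlo = list(n_iterations = 1000L, fwhm_mm = smooth_fwhm_mm,
                         seed = seed))
  cfg <- list(sim = sim, k_discard = as.integer(k_discard),
              max_translation_mm = max_translation_mm,
              max_rotation_deg = max_rotation_deg,
              metric = metric, smooth_fwhm_mm = smooth_fwhm_mm,
              correction = correction, svm_cost = svm_cost,
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed), paper_preset = paper_preset)
  if (paper_preset) {
    cfg$k_discard <- 15L
    cfg$max_translation_mm <- 1.5
    cfg$correction <- correction_spec(voxel_p = 0.01, cluster_alpha = 0.05,
                                      min_cluster_voxels = 40L,
                                      connectivity = cfg$correction$connectivity)
    cfg$n_permutations <- 10000L
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  mode <- if (!is.null(x$correction$min_cluster_voxels))
    sprintf("fixed > %d voxels", x$correction$min_cluster_voxels)
  else sprintf("Monte-Carlo (%d iter)", x$correction$monte_carlo$n_iterations)
  cat(sprintf("<pipeline_config> metric %s, discard %d, smooth %.3g mm, voxel p %.3g, correction %s, %d permutations, seed %d%s\n",
              x$metric, x$k_discard, x$smooth_fwhm_mm,
              x$correction$voxel_p, mode, x$n_permutations, x$seed,
              if (x$paper_preset) " [paper preset]" else ""))
  invisible(x)
}

#' Run the full amplitude-analysis pipeline on a cohort
#'
#' Executes: simulate (or accept) the cohort, temporal preprocessing,
#' voxelwise amplitude maps, map smoothing, the two-group t-map
#' (patient - control), cluster extraction and extent correction,
#' regional mean features from the significant clusters, per-region ROC,
#' and the leave-one-out SVM with its permutation null. When no cluster
#' survives correction, the discrimination stages are marked not
#' applicable rather than failing. Deterministic stages are bit-stable
#' under rerun; stochastic stages are reproducible given
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built cohort (as from [generate_cohort()]);
#'   by default one is simulated from `config$sim`.
#' @param motion_traces Optional list of `motion_trace` objects, one per
#'   subject, for the motion-exclusion rule.
#' @param mask Optional analysis mask (defaults to the full grid).
#' @param output_dir Optional directory for TSV/JSON artifacts.
#' @return A `pipeline_result` list: `config`, `labels`,
#'   `preprocess_reports`, `maps`, `stat_map`, `clusters` (with
#'   `significant` column), `size_threshold`, `features`, `roc` (named
#'   list of `roc_result`), `svm`, `permutation`, `ground_truth`.
#' @export
run_pipeline <- function(config, cohort = NULL, motion_traces = NULL,
                         mask = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$sim)
  images <- cohort$images
  labels <- cohort$labels
  n <- length(images)
  if (!is.null(motion_traces) && length(motion_traces) != n)
    stop("`motion_traces` length must equal the number of subjects")
  grid <- dim(images[[1]]$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = grid) else
    mask <- as_mask(mask, grid)

  # --- preprocessing + QC ---------------------------------------------
  reports <- vector("list", n)
  kept <- logical(n)
  proc <- vector("list", n)
  for (i in seq_len(n)) {
    pp <- preprocess_subject(images[[i]],
                             motion = if (is.null(motion_traces)) NULL
                                      else motion_traces[[i]],
                             k_discard = config$k_discard,
                             max_translation_mm = config$max_translation_mm,
                             max_rotation_deg = config$max_rotation_deg)
    reports[[i]] <- pp$report
    kept[i] <- !pp$report$excluded
    proc[[i]] <- pp$bold
  }
  if (sum(kept & labels$group == "patient") < 2 ||
      sum(kept & labels$group == "control") < 2)
    stop("fewer than 2 subjects per group remain after motion QC")

  # --- amplitude maps --------------------------------------------------
  maps <- vector("list", n)
  for (i in which(kept)) {
    maps[[i]] <- if (config$metric == "PerAF")
      peraf_map(proc[[i]], mask) else alff_map(proc[[i]], mask)
    if (config$smooth_fwhm_mm > 0)
      maps[[i]] <- gaussian_smooth_map(maps[[i]], config$smooth_fwhm_mm)
    maps[[i]]$meta$subject_id <- labels$subject_id[i]
  }

  # --- group statistics ------------------------------------------------
  pat <- maps[kept & labels$group == "patient"]
  ctl <- maps[kept & labels$group == "control"]
  stat <- voxelwise_ttest(pat, ctl, mask)
  clusters <- extract_clusters(stat, voxel_p = config$correction$voxel_p,
                               connectivity = config$correction$connectivity)
  mc_thr <- NULL
  if (is.null(config$correction$min_cluster_voxels)) {
    mc <- config$correction$monte_carlo
    mc_thr <- monte_carlo_cluster_threshold(
      mask, mc$fwhm_mm, images[[1]]$voxel_size_mm,
      voxel_p = config$correction$voxel_p,
      cluster_alpha = config$correction$cluster_alpha,
      n_iterations = mc$n_iterations, seed = mc$seed %||% config$seed,
      connectivity = config$correction$connectivity,
      group_sizes = c(length(pat), length(ctl)))
  }
  clusters <- significant_clusters(clusters, config$correction,
                                   mask = mask,
                                   voxel_size_mm = images[[1]]$voxel_size_mm,
                                   mc_threshold = mc_thr)

  # --- discrimination --------------------------------------------------
  roc <- NULL; svm <- NULL; perm <- NULL; features <- NULL
  sig <- clusters[clusters$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    lab_arr <- attr(clusters, "label_array")
    keep_arr <- array(0L, dim = dim(lab_arr))
    region_names <- character(nrow(sig))
    for (r in seq_len(nrow(sig))) {
      code <- if (sig$direction[r] == "pos") sig$label[r] else -sig$label[r]
      keep_arr[lab_arr == code] <- r
      region_names[r] <- sprintf("cluster_%s_%d", sig$direction[r], sig$label[r])
    }
    features <- extract_regional_means(
      maps[kept], keep_arr, labels$group[kept],
      subject_ids = labels$subject_id[kept], region_names = region_names)
    roc <- lapply(region_names, function(rn)
      roc_analysis(features[[rn]], features$label))
    names(roc) <- region_names
    svm <- loo_svm(features, cost = config$svm_cost)
    perm <- permutation_test(features, n_permutations = config$n_permutations,
                             seed = config$seed, cost = config$svm_cost)
  }

  res <- structure(
    list(config = config, labels = labels,
         preprocess_reports = reports, maps = maps, stat_map = stat,
         clusters = clusters,
         size_threshold = attr(clusters, "size_threshold"),
         features = features, roc = roc, svm = svm, permutation = perm,
         ground_truth = cohort$ground_truth),
    class = "pipeline_result")
  if (!is.null(output_dir)) make_report(res, output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  nsig <- sum(x$clusters$significant)
  cat(sprintf("<pipeline_result> %d subjects, %d cluster(s) significant (size threshold %s)\n",
              nrow(x$labels), nsig, x$size_threshold))
  if (!is.null(x$svm))
    cat(sprintf("  SVM accuracy %.2f%%, permutation p = %.4g\n",
                100 * x$svm$accuracy, x$permutation$p_value))
  invisible(x)
}

#' Write a report bundle for a pipeline run
#'
#' Emits the cohort summary (group sizes, Welch t on any numeric
#' covariates), the cluster table TSV, per-region ROC JSON + curve TSVs,
#' the SVM/permutation JSON, the resolved configuration, and a short
#' markdown summary.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param output_dir Directory to write into (created if needed).
#' @param covariates Optional data.frame of per-subject numeric
#'   covariates (rows aligned with `result$labels`).
#' @return `output_dir`, invisibly.
#' @export
make_report <- function(result, output_dir, covariates = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  labels <- result$labels
  grp <- table(labels$group)

  cohort <- data.frame(group = names(grp), n = as.integer(grp))
  cov_rows <- NULL
  if (!is.null(covariates)) {
    for (v in names(covariates)) {
      a <- covariates[[v]][labels$group == "patient"]
      b <- covariates[[v]][labels$group == "control"]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        # degenerate: constant within both groups
        tt <- if (mean(a) == mean(b)) list(statistic = 0, p.value = 1)
              else list(statistic = NA_real_, p.value = NA_real_)
      } else {
        tt <- stats::t.test(a, b)  # Welch
      }
      cov_rows <- rbind(cov_rows, data.frame(
        covariate = v,
        patient_mean = mean(a), patient_sd = stats::sd(a),
        control_mean = mean(b), control_sd = stats::sd(b),
        t = as.numeric(tt$statistic), p = tt$p.value))
    }
    utils::write.table(cov_rows, file.path(output_dir, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort, file.path(output_dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_cluster_table(result$clusters, file.path(output_dir, "clusters.tsv"))

  cfg <- result$config
  cfg$sim <- unclass(cfg$sim)
  cfg$correction <- unclass(cfg$correction)
  jsonlite::write_json(unclass(cfg), file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  applicable <- !is.null(result$svm)
  if (applicable) {
    write_feature_table(result$features,
                        file.path(output_dir, "features.tsv"))
    roc_json <- lapply(result$roc, function(r)
      list(auc = r$auc, ci95_low = r$ci95[1], ci95_high = r$ci95[2],
           direction = r$direction, cutoff = r$cutoff,
           sensitivity = r$sensitivity, specificity = r$specificity,
           n_positive = r$n_positive, n_negative = r$n_negative))
    jsonlite::write_json(roc_json, file.path(output_dir, "roc.json"),
                         auto_unbox = TRUE, digits = NA)
    for (rn in names(result$roc))
      utils::write.table(result$roc[[rn]]$curve,
                         file.path(output_dir, paste0("roc_", rn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    svm_json <- list(
      n = result$svm$n, accuracy = result$svm$accuracy,
      sensitivity = result$svm$sensitivity,
      specificity = result$svm$specificity,
      tp = result$svm$tp, tn = result$svm$tn, fp = result$svm$fp,
      fn = result$svm$fn,
      permutation_p = result$permutation$p_value,
      n_permutations = result$permutation$n_permutations,
      null_accuracy_mean = mean(result$permutation$null_accuracies),
      null_accuracy_q95 = as.numeric(stats::quantile(
        result$permutation$null_accuracies, 0.95)))
    jsonlite::write_json(svm_json, file.path(output_dir, "svm.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  md <- c("# Amplitude analysis report", "",
          sprintf("- Subjects: %s", paste(sprintf("%s n=%d", cohort$group,
                                                  cohort$n), collapse = ", ")),
          sprintf("- Metric: %s, smoothing %.3g mm", cfg$metric,
                  cfg$smooth_fwhm_mm),
          sprintf("- Cluster size threshold in force: %s",
                  result$size_threshold),
          sprintf("- Significant clusters: %d",
                  sum(result$clusters$significant)), "")
  if (applicable) {
    md <- c(md,
            sprintf("- Regional AUCs: %s",
                    paste(sprintf("%s %.3f", names(result$roc),
                                  vapply(result$roc, `[[`, 0, "auc")),
                          collapse = ", ")),
            sprintf("- SVM: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%% (N = %d)",
                    100 * result$svm$accuracy, 100 * result$svm$sensitivity,
                    100 * result$svm$specificity, result$svm$n),
            sprintf("- Permutation p = %.4g (%d permutations)",
                    result$permutation$p_value,
                    result$permutation$n_permutations))
  } else {
    md <- c(md, "- ROC and SVM: not applicable (no significant clusters)")
  }
  writeLines(md, file.path(output_dir, "summary.md"))
  invisible(output_dir)
}

#' Dice overlap between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; used to score recovery of planted
#' effect regions by significant clusters.
#'
#' @param a,b Logical 3D arrays of equal dimension.
#' @return Scalar in [0, 1] (0 when both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b, dim(a))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
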