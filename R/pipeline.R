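# End-to-end orchestration: synthesize -> segment -> extract -> merge
# blood work -> select -> model, with every artifact written to a run
# directory and the full configuration embedded in the summary.

#' Build a pipeline run configuration
#'
#' All thresholds default to the study's published values: CT lung window
#' 800--1200 (air-near-zero offset scale), ANOVA screen at p <= 0.1,
#' Pearson pruning at |r| <= 0.5, 64 gray levels, co-occurrence distances
#' 1--4, ridge 1e-3.
#'
#' @param cohort_seed,split_seed RNG seeds for cohort generation and the
#'   cross-validation split.
#' @param n_low,n_high Cohort group sizes.
#' @param tabular_only Skip the imaging arm and model the planted tabular
#'   biomarkers directly.
#' @param seg_low,seg_high,min_component_voxels CT segmentation window and
#'   component filter.
#' @param p_threshold,r_cutoff Feature-selection thresholds.
#' @param n_levels,glcm_distances Radiomics quantization and offsets.
#' @param lambda Ridge penalty for the logistic fits.
#' @param ct_phantom,mri_phantom Optional [phantom_spec] overrides.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(cohort_seed = 1, split_seed = 1,
                       n_low = 7, n_high = 8, tabular_only = FALSE,
                       seg_low = 800, seg_high = 1200,
                       min_component_voxels = 50,
                       p_threshold = 0.1, r_cutoff = 0.5,
                       n_levels = 64, glcm_distances = 1:4,
                       lambda = 1e-3,
                       ct_phantom = NULL, mri_phantom = NULL) {
  structure(list(cohort_seed = cohort_seed, split_seed = split_seed,
                 n_low = n_low, n_high = n_high, tabular_only = tabular_only,
                 seg_low = seg_low, seg_high = seg_high,
                 min_component_voxels = min_component_voxels,
                 p_threshold = p_threshold, r_cutoff = r_cutoff,
                 n_levels = n_levels, glcm_distances = glcm_distances,
                 lambda = lambda,
                 ct_phantom = ct_phantom, mri_phantom = mri_phantom),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  assert_that(length(unknown) == 0,
              paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

# aliases from extracted feature names to the published model's
# feature vocabulary
alias_model_columns <- function(df) {
  al <- c(ct_average_gray = "ct_fo_mean",
          ct_hist_kurtosis = "ct_fo_kurtosis",
          ct_cooc_entropy = "ct_glcm_d1_entropy",
          mr_hist_kurtosis = "mr_fo_kurtosis")
  for (k in names(al)) if (al[[k]] %in% names(df)) df[[k]] <- df[[al[[k]]]]
  df
}

#' Run the full analysis pipeline
#'
#' Stages: (1) synthesize the cohort (tabular, or tabular + CT/MRI phantom
#' volumes); (2) segment the CT lungs by thresholding (MRI masks are taken
#' as given, mirroring a manually contoured input); (3) extract the
#' 92-feature radiomics vector per modality; (4) derive blood-count ratios
#' and merge; (5) dichotomize CD45 at the median, ANOVA-screen and
#' correlation-prune the candidate features; (6) fit and cross-validate
#' the CT and MRI models. Existing stage outputs in `out_dir` (cohort
#' files, `features.csv`) are reused, so deleting a downstream artifact
#' and re-running regenerates it from the cached upstream ones. Identical
#' configuration and seeds give an identical summary.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory for artifacts (created if needed).
#' @return Invisibly, the summary list (also written as `summary.json`):
#'   configuration, kept features, per-model fold/mean/averaged-curve AUCs.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  cfg_plain <- lapply(unclass(config), function(x)
    if (inherits(x, "phantom_spec")) unclass(x) else x)
  logf("config: %s", jsonlite::toJSON(cfg_plain, auto_unbox = TRUE,
                                      null = "null"))
  spec <- cohort_spec(n_low = config$n_low, n_high = config$n_high,
                      seed = config$cohort_seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_pr(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }

  if (config$tabular_only) {
    cohort_path <- file.path(out_dir, "cohort.csv")
    merged <- stage("synthesize", {
      if (!file.exists(cohort_path)) {
        cohort <- generate_tabular_cohort(spec)
        write.csv(cohort, cohort_path, row.names = FALSE)
        logf("synthesized tabular cohort: %d subjects", nrow(cohort))
      } else logf("reusing %s", cohort_path)
      read_cohort_csv(cohort_path, check_bounds = FALSE)
    })
    merged <- cbind(merged, derive_ratios(merged))
  } else {
    synth_dir <- file.path(out_dir, "cohort_data")
    manifest_path <- file.path(synth_dir, "manifest.csv")
    stage("synthesize", {
      if (!file.exists(manifest_path)) {
        ct <- config$ct_phantom %||% phantom_spec("CT")
        mri <- config$mri_phantom %||% phantom_spec("MRI")
        generate_imaging_cohort(spec, ct, mri, synth_dir)
        logf("synthesized imaging cohort under %s", synth_dir)
      } else logf("reusing %s", synth_dir)
    })
    manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
    cohort <- read_cohort_csv(file.path(synth_dir, "cohort.csv"),
                              check_bounds = FALSE)

    feats_path <- file.path(out_dir, "features.csv")
    feats <- stage("segment+extract", {
      if (!file.exists(feats_path)) {
        # CT masks from the threshold segmenter; MRI masks as provided
        for (r in which(manifest$modality == "CT")) {
          vol <- read_volume(manifest$volume[r], "CT")
          m <- segment_lungs_ct(vol, config$seg_low, config$seg_high,
                                config$min_component_voxels)
          seg_path <- sub("_mask\\.nii", "_segmask.nii", manifest$mask[r])
          write_mask(m, seg_path)
          manifest$mask[r] <- seg_path
        }
        logf("segmented %d CT volumes (window %g-%g)",
             sum(manifest$modality == "CT"), config$seg_low, config$seg_high)
        fe <- extract_cohort_features(
          manifest, config = list(n_levels = config$n_levels,
                                  glcm_distances = config$glcm_distances))
        write.csv(fe, feats_path, row.names = FALSE)
        logf("extracted %d feature columns", ncol(fe) - 1L)
        fe
      } else {
        logf("reusing %s", feats_path)
        read.csv(feats_path, stringsAsFactors = FALSE)
      }
    })
    # imaging features replace the generator's planted radiomics columns
    planted <- grep("^(ct|mr)_", names(cohort), value = TRUE)
    cohort <- cohort[, setdiff(names(cohort), planted)]
    merged <- merge(cohort, feats, by = "subject_id", sort = TRUE)
    merged <- cbind(merged, derive_ratios(merged))
  }

  sel <- stage("select", {
    labels <- dichotomize_by_median(merged$cd45)
    candidates <- setdiff(names(merged)[vapply(merged, is.numeric, logical(1))],
                          c("cd45"))
    select_features(merged, candidates, labels,
                    p_threshold = config$p_threshold,
                    r_cutoff = config$r_cutoff)
  })
  jsonlite::write_json(
    list(kept = sel$kept,
         table = sel$table,
         p_threshold = sel$p_threshold, r_cutoff = sel$r_cutoff),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  logf("selection: %d kept of %d candidates", length(sel$kept),
       nrow(sel$table))

  models_summary <- NULL
  if (length(sel$kept) == 0) {
    logf("no features survived the screen at p <= %g; models skipped",
         config$p_threshold)
    models_summary <- list(skipped = TRUE,
                           reason = sprintf("empty kept set at p <= %g",
                                            config$p_threshold))
  } else {
    reports <- stage("model", {
      # expose the published models' vocabulary (ct_average_gray etc.) as
      # aliases of the corresponding extracted feature columns
      run_models(alias_model_columns(merged), seed = config$split_seed,
                 lambda = config$lambda)
    })
    for (m in names(reports)) {
      rep <- reports[[m]]
      jsonlite::write_json(
        list(features = rep$features,
             coefficients = as.list(coef(rep$fit)),
             separation = rep$fit$separation,
             lambda = rep$fit$lambda_used,
             fold_aucs = rep$cv$fold_aucs,
             mean_auc = rep$cv$mean_auc,
             average_curve_auc = rep$cv$average_curve_auc),
        file.path(out_dir, paste0("model_", m, ".json")),
        auto_unbox = TRUE, digits = NA)
      roc_df <- do.call(rbind, c(
        lapply(1:2, function(k) data.frame(curve = paste0("fold", k),
                                           fpr = rep$cv$fold_rocs[[k]]$fpr,
                                           tpr = rep$cv$fold_rocs[[k]]$tpr)),
        list(data.frame(curve = "average", fpr = rep$cv$average_roc$fpr,
                        tpr = rep$cv$average_roc$tpr))))
      write.csv(roc_df, file.path(out_dir, paste0("roc_", m, ".csv")),
                row.names = FALSE)
      logf("%s model: fold AUCs %.3f/%.3f, mean %.3f", toupper(m),
           rep$cv$fold_aucs[1], rep$cv$fold_aucs[2], rep$cv$mean_auc)
    }
    models_summary <- lapply(reports, function(rep)
      list(features = rep$features, fold_aucs = rep$cv$fold_aucs,
           mean_auc = rep$cv$mean_auc,
           average_curve_auc = rep$cv$average_curve_auc,
           separation = rep$fit$separation))
  }

  summary <- list(config = cfg_plain,
                  n_subjects = nrow(merged),
                  kept_features = sel$kept,
                  models = models_summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}
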