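# End-to-end orchestration: simulate -> prep -> features -> classify ->
# report, with a single global seed fanned out deterministically to every
# stage.

#' Pipeline configuration
#'
#' @param n_scar,n_healthy cohort composition (default 80/80).
#' @param phantom [phantom_config()] template for the cohort.
#' @param registration [registration_config()] for LGE-to-cine alignment
#'   (the pipeline default trims the iteration budget relative to the
#'   standalone default: alignment QC does not need the last fraction of a
#'   pixel).
#' @param flow a [flow_config()].
#' @param radiomics a [radiomics_config()].
#' @param feature_sets list of character subsets of
#'   `c("flow", "area", "radiomics")`; the default runs the three
#'   combinations (flow+area, flow+area+radiomics, area+radiomics).
#' @param split_fractions train/test fractions (default `c(0.8, 0.2)`).
#' @param pca_components flow-PCA components per displacement map
#'   (default 8).
#' @param qc_threshold alignment QC pass threshold.
#' @param cv_folds folds for the cross-validated ROC (default 10).
#' @param importance_repeats permutation-importance shuffles (default 10).
#' @param seed global seed; every stage derives its own stream from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_scar = 80L, n_healthy = 80L,
                            phantom = phantom_config(),
                            registration = registration_config(max_iterations = 300),
                            flow = flow_config(),
                            radiomics = radiomics_config(),
                            feature_sets = list(
                              c("flow", "area"),
                              c("flow", "area", "radiomics"),
                              c("area", "radiomics")),
                            split_fractions = c(0.8, 0.2),
                            pca_components = 8L,
                            qc_threshold = 0.5,
                            cv_folds = 10L,
                            importance_repeats = 10L,
                            seed = 1L) {
  for (fs in feature_sets) {
    if (!all(fs %in% c("flow", "area", "radiomics"))) {
      stopf("feature sets must be subsets of {flow, area, radiomics}")
    }
  }
  structure(list(n_scar = as.integer(n_scar), n_healthy = as.integer(n_healthy),
                 phantom = phantom, registration = registration,
                 flow = flow, radiomics = radiomics,
                 feature_sets = feature_sets,
                 split_fractions = split_fractions,
                 pca_components = as.integer(pca_components),
                 qc_threshold = qc_threshold,
                 cv_folds = as.integer(cv_folds),
                 importance_repeats = as.integer(importance_repeats),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Displacement maps (px) for the canonical frame pairs of one cine sequence.
compute_flow_maps <- function(cine, cfg_flow) {
  n <- length(cine$frames)
  pairs <- enumerate_frame_pairs(n, cfg_flow$skip_interval)
  tt <- cine$trigger_times_ms
  maps <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1] + 1L; j <- pairs[p, 2] + 1L
    fl <- lucas_kanade_flow(cine$frames[[i]], cine$frames[[j]], cfg_flow)
    elapsed <- tt[j] - tt[i]
    steps <- j - i
    # velocities per ms, then r = v * k * dt over the actual elapsed time
    field <- list(vx = fl$vx / elapsed, vy = fl$vy / elapsed,
                  confident = fl$confident)
    maps[[p]] <- displacement_magnitude(field, dt_ms = elapsed / steps,
                                        k = steps,
                                        magnitude = cfg_flow$magnitude)$r
  }
  maps
}

# Small stable hash of a config (manifest stamping).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), force = TRUE, auto_unbox = TRUE)
  chars <- utf8ToInt(s)
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full contrast-free scar-prediction pipeline on phantoms
#'
#' Simulates a phantom cohort, runs ground-truth preparation per study
#' (trigger-time frame matching, mutual-information affine registration of
#' the LGE image, 32-frame stacking, alignment QC), extracts the engineered
#' features (flow-PCA, area-change rates, radiomics with redundancy and
#' significance filtering fitted on the training split only), trains and
#' evaluates the SVM and decision-tree classifiers for each configured
#' feature-set combination, and assembles per-configuration reports
#' (confusion matrix, precision/recall/F1/accuracy, held-out AUC,
#' cross-validated ROC, permutation importance for the full set).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, the feature table
#'   (CSV), per-configuration reports (JSON), QC overlays (PNG) and a
#'   manifest (JSON) are written.
#' @param verbose print stage progress.
#' @return List with `feature_table`, `splits`, `selection` (radiomics
#'   filter reports), `reports` (per feature set and model), `prep`
#'   (per-study QC and registration summary), `labels`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(fmt, ...) if (verbose) {
    message(sprintf("[%s +%.1fs seed=%d] %s", format(Sys.time(), "%H:%M:%S"),
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    config$seed, sprintf(fmt, ...)))
  }
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list(), files = character(0))

  say("simulate: %d scar + %d healthy studies", config$n_scar, config$n_healthy)
  cohort <- generate_cohort(config$n_scar, config$n_healthy, config$phantom,
                            seed = derive_seed(config$seed, "simulate"))
  n <- length(cohort$studies)
  labels <- cohort$labels
  manifest$stages$simulate <- list(n_studies = n, seed = derive_seed(config$seed, "simulate"))

  say("prep: trigger-time matching, registration, QC")
  prep_rows <- vector("list", n)
  for (s in seq_len(n)) {
    study <- cohort$studies[[s]]
    mi <- match_frame_by_trigger_time(study$cine, study$lge$trigger_time_ms)
    reg_cfg <- config$registration
    reg_cfg$seed <- derive_seed(config$seed, paste0("register-", s))
    reg <- register_affine_mi(study$cine$frames[[mi]], study$lge$image, reg_cfg)
    mask_reg <- apply_affine(study$lge$true_mask, reg$params, "nearest")
    qc <- qc_alignment(study$cine$frames[[mi]], reg$resampled,
                       mask_reg == 1L,  # scar excluded: enhancement is not misalignment
                       threshold = config$qc_threshold)
    err <- registration_error(reg$params, study$lge$true_misalignment,
                              dim(study$lge$image))
    prep_rows[[s]] <- data.frame(
      study = study$id, matched_frame = mi,
      mi_before = reg$mi_before, mi_after = reg$mi_after,
      qc_score = qc$qc_score, qc_pass = qc$qc_pass,
      reg_translation_err_px = err$translation_px,
      reg_rotation_err_deg = err$rotation_deg)
    cohort$studies[[s]]$prep <- list(matched_frame = mi, params = reg$params,
                                     mask_registered = mask_reg, qc = qc,
                                     stack = stack_to_fixed_length(study$cine$frames, 32L))
  }
  prep_df <- do.call(rbind, prep_rows)
  manifest$stages$prep <- list(qc_pass_rate = mean(prep_df$qc_pass))

  say("split: stratified %s", paste(config$split_fractions, collapse = "/"))
  splits <- split_dataset(n, config$split_fractions,
                          seed = derive_seed(config$seed, "split"),
                          labels = labels)

  say("features: optical flow + PCA")
  all_maps <- vector("list", n)
  for (s in seq_len(n)) {
    all_maps[[s]] <- compute_flow_maps(cohort$studies[[s]]$cine, config$flow)
  }
  projector <- fit_flow_pca(all_maps[splits$train], config$pca_components)
  flow_rows <- t(vapply(all_maps, function(m) flow_feature_vector(m, projector),
                        flow_feature_vector(all_maps[[1]], projector)))

  say("features: area-change rates and radiomics")
  area_rows <- t(vapply(seq_len(n), function(s) {
    st <- cohort$studies[[s]]
    area_change_series(st$masks, st$cine$trigger_times_ms,
                       k = config$flow$skip_interval,
                       spacing_mm = st$cine$pixel_spacing_mm)$values
  }, area_change_series(cohort$studies[[1]]$masks,
                        cohort$studies[[1]]$cine$trigger_times_ms,
                        k = config$flow$skip_interval,
                        spacing_mm = cohort$studies[[1]]$cine$pixel_spacing_mm)$values))
  radio_rows <- t(vapply(seq_len(n), function(s) {
    st <- cohort$studies[[s]]
    extract_radiomics(st$cine$frames, st$masks, st$cine$pixel_spacing_mm,
                      config$radiomics)
  }, extract_radiomics(cohort$studies[[1]]$cine$frames,
                       cohort$studies[[1]]$masks,
                       cohort$studies[[1]]$cine$pixel_spacing_mm,
                       config$radiomics)))

  say("features: radiomics redundancy + significance filtering (train only)")
  red <- redundancy_filter(radio_rows[splits$train, , drop = FALSE],
                           r_threshold = 0.9)
  sig <- significance_filter(
    radio_rows[splits$train, red$kept_names, drop = FALSE],
    labels[splits$train], alpha = 0.001)
  radio_kept <- radio_rows[, sig$kept_names, drop = FALSE]

  feature_table <- data.frame(flow_rows, area_rows, radio_kept,
                              check.names = FALSE)
  feature_table$label <- labels
  col_groups <- list(
    flow = colnames(flow_rows),
    area = colnames(area_rows),
    radiomics = colnames(radio_kept))

  say("classify: SVM and decision tree per feature set")
  reports <- list()
  full_set <- c("flow", "area", "radiomics")
  for (fs in config$feature_sets) {
    set_name <- paste(fs, collapse = "+")
    cols <- unlist(col_groups[fs])
    X <- as.matrix(feature_table[, cols, drop = FALSE])
    Xtr <- X[splits$train, , drop = FALSE]; ytr <- labels[splits$train]
    Xte <- X[splits$test, , drop = FALSE]; yte <- labels[splits$test]
    std <- fit_standardizer(Xtr)
    Ztr <- apply_standardizer(std, Xtr); Zte <- apply_standardizer(std, Xte)
    Zall <- apply_standardizer(std, X)
    model_seed <- derive_seed(config$seed, paste0("model-", set_name))
    models <- list(
      svm = train_svm_rbf(Ztr, ytr, seed = model_seed),
      dt = train_decision_tree(Xtr, ytr, seed = model_seed))
    specs <- list(svm = svm_model_spec(seed = model_seed),
                  dt = tree_model_spec(seed = model_seed))
    eval_X <- list(svm = Zte, dt = Xte)
    cv_X <- list(svm = Zall, dt = X)
    for (mn in names(models)) {
      m <- models[[mn]]
      pred <- m$predict(eval_X[[mn]])
      scores <- m$scores(eval_X[[mn]])
      rep_cls <- classification_report(yte, pred)
      roc <- pROC::roc(yte, scores, quiet = TRUE, direction = "<",
                       levels = c(0, 1))
      cv <- cv_roc_auc(cv_X[[mn]], labels, specs[[mn]],
                       n_folds = config$cv_folds,
                       seed = derive_seed(config$seed, paste0("cv-", set_name, "-", mn)))
      imp <- NULL
      if (setequal(fs, full_set)) {
        imp <- permutation_importance(m, eval_X[[mn]], yte,
                                      n_repeats = config$importance_repeats,
                                      seed = derive_seed(config$seed, paste0("imp-", set_name, "-", mn)))
      }
      reports[[set_name]][[mn]] <- list(
        feature_set = fs, model = mn,
        classification = rep_cls,
        test_auc = as.numeric(pROC::auc(roc)),
        cv = cv[c("fold_auc", "mean_auc", "sd_auc", "fpr_grid",
                  "mean_tpr", "sd_tpr", "n_folds")],
        importance = if (!is.null(imp)) imp$importance else NULL)
    }
  }

  result <- list(feature_table = feature_table, splits = splits,
                 selection = list(redundancy = red, significance = sig),
                 reports = reports, prep = prep_df, labels = labels,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    result$manifest <- write_pipeline_outputs(result, cohort, config, out_dir, say)
  }
  say("done")
  result
}

write_pipeline_outputs <- function(result, cohort, config, out_dir, say) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- result$manifest
  add_file <- function(path) manifest$files <<- c(manifest$files, path)

  feat_path <- file.path(out_dir, "features.csv")
  utils::write.csv(result$feature_table, feat_path, row.names = FALSE)
  add_file(feat_path)

  for (set_name in names(result$reports)) {
    for (mn in names(result$reports[[set_name]])) {
      rp <- result$reports[[set_name]][[mn]]
      path <- file.path(out_dir, sprintf("report_%s_%s.json",
                                         gsub("\\+", "-", set_name), mn))
      jsonlite::write_json(list(
        feature_set = rp$feature_set, model = mn,
        confusion = as.data.frame(rp$classification$confusion),
        precision = rp$classification$precision,
        recall = rp$classification$recall,
        f1 = rp$classification$f1,
        accuracy = rp$classification$accuracy,
        test_auc = rp$test_auc,
        cv_mean_auc = rp$cv$mean_auc, cv_sd_auc = rp$cv$sd_auc,
        importance = rp$importance),
        path, auto_unbox = TRUE, digits = NA)
      add_file(path)
      curve_path <- file.path(out_dir, sprintf("roc_%s_%s.csv",
                                               gsub("\\+", "-", set_name), mn))
      utils::write.csv(data.frame(fpr = rp$cv$fpr_grid, tpr = rp$cv$mean_tpr,
                                  sd = rp$cv$sd_tpr),
                       curve_path, row.names = FALSE)
      add_file(curve_path)
      png_path <- sub("\\.csv$", ".png", curve_path)
      grDevices::png(png_path, width = 480, height = 480)
      lo <- pmax(rp$cv$mean_tpr - rp$cv$sd_tpr, 0)
      hi <- pmin(rp$cv$mean_tpr + rp$cv$sd_tpr, 1)
      graphics::plot(rp$cv$fpr_grid, rp$cv$mean_tpr, type = "n",
                     xlab = "False positive rate", ylab = "True positive rate",
                     main = sprintf("%s %s: AUC %.2f +/- %.2f (%d-fold CV)",
                                    set_name, toupper(mn), rp$cv$mean_auc,
                                    rp$cv$sd_auc, rp$cv$n_folds))
      graphics::polygon(c(rp$cv$fpr_grid, rev(rp$cv$fpr_grid)), c(lo, rev(hi)),
                        col = "grey85", border = NA)
      graphics::lines(rp$cv$fpr_grid, rp$cv$mean_tpr, lwd = 2)
      graphics::abline(0, 1, lty = 2, col = "grey50")
      grDevices::dev.off()
      add_file(png_path)
    }
  }

  # QC overlay per study: cine frame with the registered myocardium contour
  qc_dir <- file.path(out_dir, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  for (s in seq_along(cohort$studies)) {
    st <- cohort$studies[[s]]
    path <- file.path(qc_dir, sprintf("%s_qc.png", st$id))
    grDevices::png(path, width = 320, height = 320)
    op <- graphics::par(mar = c(0, 0, 1, 0))
    frame <- st$cine$frames[[st$prep$matched_frame]]
    graphics::image(frame, col = grDevices::gray.colors(128), axes = FALSE,
                    main = sprintf("%s qc=%.2f", st$id,
                                   st$prep$qc$qc_score %||% NA))
    myo <- (st$prep$mask_registered == 1L | st$prep$mask_registered == 3L) * 1
    graphics::contour(myo, levels = 0.5, add = TRUE, drawlabels = FALSE,
                      col = "red")
    graphics::par(op)
    grDevices::dev.off()
    add_file(path)
  }

  manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  say("outputs written to %s", out_dir)
  manifest
}
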