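#' Assemble a full pipeline run configuration
#'
#' Nested stage configurations with the published analysis settings as
#' defaults: 5 discarded volumes, 2 mm / 2 degree motion screen, global
#' signal preserved, 0.01-0.08 Hz band, 8 mm FWHM smoothing, GRF voxel
#' p < 0.001 and cluster p < 0.01, and an RBF-SVM over powers-of-two grids.
#'
#' @param seed global seed; every stage seed derives from it.
#' @param out_dir output root directory.
#' @param cohort a [cohort_spec] (its own seed is overridden by `seed`).
#' @param preprocess a [preprocess_config].
#' @param n_components,z_threshold group-ICA model order and mask threshold.
#' @param voxel_p,cluster_p,connectivity group-stats thresholds.
#' @param c_grid,gamma_grid,cv_scheme SVM settings.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "nethom_run",
                       cohort = cohort_spec(seed = seed),
                       preprocess = preprocess_config(),
                       n_components = 20L, z_threshold = 1.5,
                       voxel_p = 0.001, cluster_p = 0.01, connectivity = 26,
                       c_grid = 2^seq(-5, 15, 2),
                       gamma_grid = 2^seq(-15, 3, 2),
                       cv_scheme = "loocv") {
  cohort$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 cohort = cohort, preprocess = preprocess,
                 n_components = as.integer(n_components),
                 z_threshold = z_threshold, voxel_p = voxel_p,
                 cluster_p = cluster_p, connectivity = connectivity,
                 c_grid = c_grid, gamma_grid = gamma_grid,
                 cv_scheme = cv_scheme),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The file representation round-trips losslessly through [run_config()].
#'
#' @param path YAML file path.
#' @param config a `run_config` (for writing).
#' @return for `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  rois <- if (!is.null(y$cohort$dmn_roi_set)) {
    lapply(y$cohort$dmn_roi_set, function(r)
      box_roi(r$label, r$x[1]:r$x[2], r$y[1]:r$y[2], r$z[1]:r$z[2]))
  } else default_dmn_rois()
  effects <- if (!is.null(y$cohort$effect_rois)) y$cohort$effect_rois else
    formals(cohort_spec)$effect_rois
  co <- y$cohort
  cohort <- cohort_spec(
    n_patients = co$n_patients %||% 43, n_controls = co$n_controls %||% 42,
    grid_shape = co$grid_shape %||% c(30, 36, 30),
    voxel_size_mm = co$voxel_size_mm %||% c(3, 3, 3),
    n_volumes = co$n_volumes %||% 240, tr_seconds = co$tr_seconds %||% 2,
    dmn_roi_set = rois, effect_rois = effects,
    base_coupling = co$base_coupling %||% 0.5,
    ar1_coefficient = co$ar1_coefficient %||% 0.5,
    drift_amplitude = co$drift_amplitude %||% 0.5,
    motion_sigma_mm = co$motion_sigma_mm %||% 0.05,
    regional_sigma = co$regional_sigma %||% 0.8,
    coupling_jitter = co$coupling_jitter %||% 0.07,
    nuisance_leak = co$nuisance_leak %||% 0.1,
    seed = y$seed %||% 1)
  pp <- y$preprocess %||% list()
  prep <- preprocess_config(
    n_discard = pp$n_discard %||% 5, max_translation_mm = pp$max_translation_mm %||% 2,
    max_rotation_deg = pp$max_rotation_deg %||% 2,
    band = unlist(pp$band %||% c(0.01, 0.08)), fwhm_mm = pp$fwhm_mm %||% 8)
  run_config(seed = y$seed %||% 1, out_dir = y$out_dir %||% "nethom_run",
             cohort = cohort, preprocess = prep,
             n_components = y$n_components %||% 20,
             z_threshold = y$z_threshold %||% 1.5,
             voxel_p = y$voxel_p %||% 0.001, cluster_p = y$cluster_p %||% 0.01,
             connectivity = y$connectivity %||% 26,
             c_grid = unlist(y$c_grid %||% 2^seq(-5, 15, 2)),
             gamma_grid = unlist(y$gamma_grid %||% 2^seq(-15, 3, 2)),
             cv_scheme = y$cv_scheme %||% "loocv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  rois <- lapply(config$cohort$dmn_roi_set, function(r) {
    v <- r$voxels
    list(label = r$label, x = range(v[, 1]), y = range(v[, 2]),
         z = range(v[, 3]))
  })
  y <- list(seed = config$seed, out_dir = config$out_dir,
            cohort = list(
              n_patients = config$cohort$n_patients,
              n_controls = config$cohort$n_controls,
              grid_shape = config$cohort$grid_shape,
              voxel_size_mm = config$cohort$voxel_size_mm,
              n_volumes = config$cohort$n_volumes,
              tr_seconds = config$cohort$tr_seconds,
              dmn_roi_set = rois,
              effect_rois = config$cohort$effect_rois,
              base_coupling = config$cohort$base_coupling,
              ar1_coefficient = config$cohort$ar1_coefficient,
              drift_amplitude = config$cohort$drift_amplitude,
              motion_sigma_mm = config$cohort$motion_sigma_mm,
              regional_sigma = config$cohort$regional_sigma,
              coupling_jitter = config$cohort$coupling_jitter,
              nuisance_leak = config$cohort$nuisance_leak),
            preprocess = unclass(config$preprocess),
            n_components = config$n_components,
            z_threshold = config$z_threshold,
            voxel_p = config$voxel_p, cluster_p = config$cluster_p,
            connectivity = config$connectivity,
            c_grid = config$c_grid, gamma_grid = config$gamma_grid,
            cv_scheme = config$cv_scheme)
  yaml::write_yaml(y, path)
  invisible(path)
}

config_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 16807) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> DMN extraction -> NH -> group
#' statistics -> classification under one seed, writing stage outputs and a
#' run manifest under `config$out_dir`. The simulation stage is skipped when
#' its outputs already exist with a matching configuration digest
#' (resumability); deterministic stages reproduce identical outputs given
#' the same configuration.
#'
#' @param config a [run_config()].
#' @param keep_images write preprocessed 4-D images to disk (default FALSE;
#'   they are held in memory only, NH maps and masks are always written).
#' @return a list (the run manifest): stage timings, rejection list, mask
#'   provenance, cluster table, demographics, correlations, classification.
#' @export
run_pipeline <- function(config, keep_images = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, config_digest = config_digest(
    unclass(config)[setdiff(names(config), "out_dir")]), stages = list())
  manifest_path <- file.path(out, "manifest.json")
  tic <- function() proc.time()[["elapsed"]]
  save_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE, pretty = TRUE)
  }

  # --- simulate ---------------------------------------------------------
  t0 <- tic()
  cohort_dir <- file.path(out, "cohort")
  spec <- config$cohort
  sim_digest <- config_digest(unclass(spec))
  marker <- file.path(cohort_dir, "spec_digest.txt")
  if (file.exists(marker) && readLines(marker)[1] == sim_digest) {
    pheno <- read.table(file.path(cohort_dir, "phenotype.tsv"),
                        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    imgs <- file.path(cohort_dir, paste0(pheno$subject_id, "_bold.nii"))
    gz <- !file.exists(imgs)
    imgs[gz] <- paste0(imgs[gz], ".gz")
    cohort <- list(phenotype = pheno, dir = cohort_dir, images = imgs,
                   motion = file.path(cohort_dir, paste0(pheno$subject_id, "_motion.txt")))
    skipped <- TRUE
  } else {
    cohort <- generate_cohort(spec, cohort_dir, force = TRUE, compress = FALSE)
    writeLines(sim_digest, marker)
    skipped <- FALSE
  }
  manifest$stages$simulate <- list(
    seconds = tic() - t0, skipped = skipped, digest = sim_digest,
    n_subjects = nrow(cohort$phenotype))
  save_manifest()

  # --- preprocess + NH (streamed per subject) ---------------------------
  t0 <- tic()
  nuis <- nuisance_rois(spec)
  rejections <- data.frame(subject_id = character(), axis = integer(),
                           peak = numeric())
  preproc <- list()
  for (i in seq_len(nrow(cohort$phenotype))) {
    img <- read_ts_image(cohort$images[i], tr = spec$tr_seconds)
    trace <- as.matrix(read.table(cohort$motion[i]))
    res <- preprocess_subject(img, trace, config$preprocess,
                              wm_roi = nuis$wm, csf_roi = nuis$csf)
    if (res$status == "rejected") {
      rejections <- rbind(rejections, data.frame(
        subject_id = cohort$phenotype$subject_id[i],
        axis = res$screen$axis, peak = res$screen$peak))
      next
    }
    if (keep_images) {
      ppdir <- file.path(out, "preproc")
      dir.create(ppdir, showWarnings = FALSE)
      write_ts_image(res$image, file.path(
        ppdir, paste0(cohort$phenotype$subject_id[i], "_preproc.nii.gz")))
    }
    preproc[[cohort$phenotype$subject_id[i]]] <- res$image
  }
  write.table(rejections, file.path(out, "rejections.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$preprocess <- list(
    seconds = tic() - t0, accepted = length(preproc),
    rejected = nrow(rejections),
    rejected_ids = rejections$subject_id)
  save_manifest()

  pheno <- cohort$phenotype[cohort$phenotype$subject_id %in% names(preproc), ]
  if (sum(pheno$group == "control") < 2L || sum(pheno$group == "patient") < 2L)
    stop("stage preprocess: fewer than 2 accepted subjects in a group")

  # --- DMN extraction (controls only) -----------------------------------
  t0 <- tic()
  ctrl_ids <- pheno$subject_id[pheno$group == "control"]
  template <- dmn_truth_mask(spec)
  ica_notes <- character()
  mask <- withCallingHandlers(
    extract_dmn_mask(preproc[ctrl_ids], template,
                     n_components = config$n_components,
                     z_threshold = config$z_threshold,
                     seed = derive_seed(config$seed, 1L)),
    warning = function(w) {
      ica_notes <<- c(ica_notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write_volume(mask, file.path(out, "dmn_mask.nii.gz"))
  prov <- attr(mask, "provenance")
  jsonlite::write_json(prov, file.path(out, "dmn_selection.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$dmn <- c(list(seconds = tic() - t0,
                                mask_voxels = sum(mask$data),
                                notes = ica_notes), prov)
  save_manifest()

  # --- NH maps ----------------------------------------------------------
  t0 <- tic()
  nhdir <- file.path(out, "nh")
  dir.create(nhdir, showWarnings = FALSE)
  nh_maps <- list()
  for (id in pheno$subject_id) {
    z <- compute_nh_map(preproc[[id]], mask, subject_id = id)
    zs <- standardize_nh_map(z)
    write_volume(zs, file.path(nhdir, paste0(id, "_nh.nii.gz")))
    nh_maps[[id]] <- zs
  }
  manifest$stages$nh <- list(seconds = tic() - t0, n_maps = length(nh_maps))
  save_manifest()

  # --- group statistics --------------------------------------------------
  t0 <- tic()
  pat_ids <- pheno$subject_id[pheno$group == "patient"]
  cmp <- nh_group_comparison(nh_maps[pat_ids], nh_maps[ctrl_ids], mask,
                             voxel_p = config$voxel_p,
                             cluster_p = config$cluster_p,
                             connectivity = config$connectivity)
  write.table(cmp$clusters, file.path(out, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  demo <- demographics_table(pheno)
  write.table(demo, file.path(out, "demographics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # clinical correlations in the patient group, per surviving cluster
  comps <- attr(cmp$clusters, "clusters")
  correlations <- data.frame()
  if (length(comps)) {
    pats <- pheno[pheno$group == "patient", ]
    for (ci in seq_along(comps)) {
      feat <- extract_cluster_means(nh_maps[pat_ids], comps[[ci]])
      for (v in c("reaction_time", "illness_duration", "onset_age")) {
        if (!v %in% names(pats)) next
        ok <- is.finite(pats[[v]])
        if (sum(ok) < 3L) next
        pc <- pearson_corr(feat[ok], pats[[v]][ok])
        correlations <- rbind(correlations, data.frame(
          cluster = ci, direction = cmp$clusters$direction[ci],
          variable = v, r = pc$r, n = pc$n, p = pc$p))
      }
    }
  }
  write.table(correlations, file.path(out, "correlations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$stats <- list(
    seconds = tic() - t0, n_clusters = nrow(cmp$clusters),
    fwhm_mm = cmp$smoothness$fwhm_mm, resels = cmp$smoothness$resels)
  save_manifest()

  # --- classification ----------------------------------------------------
  t0 <- tic()
  classification <- NULL
  pos <- which(cmp$clusters$direction == "A>B")
  feat_idx <- if (length(pos)) pos else seq_len(nrow(cmp$clusters))
  if (length(feat_idx) >= 1L) {
    feats <- comps[feat_idx]
    names(feats) <- sprintf("cluster%d_%s", feat_idx,
                            gsub("[<>]", "", cmp$clusters$direction[feat_idx]))
    ftab <- build_feature_table(nh_maps, feats, pheno)
    write.table(ftab, file.path(out, "features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    classification <- cv_svm_grid(ftab, config$c_grid, config$gamma_grid,
                                  scheme = config$cv_scheme)
    jsonlite::write_json(
      classification[c("accuracy", "sensitivity", "specificity", "counts",
                       "best_c", "best_gamma", "scheme")],
      file.path(out, "classification.json"), auto_unbox = TRUE, digits = NA)
    write.table(classification$grid, file.path(out, "svm_grid.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$stages$classify <- list(
    seconds = tic() - t0,
    performed = !is.null(classification),
    accuracy = if (!is.null(classification)) classification$accuracy else NA)
  save_manifest()

  manifest$rejections <- rejections
  manifest$clusters <- cmp$clusters
  manifest$demographics <- demo
  manifest$correlations <- correlations
  manifest$classification <- classification
  manifest$mask <- mask
  manifest$nh_maps <- nh_maps
  manifest$tmap <- cmp$tmap
  manifest$smoothness <- cmp$smoothness
  invisible(manifest)
}
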