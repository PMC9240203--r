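# Monte-Carlo drivers shared by the long-running statistical checks.

# null two-group cohort: ~2000-voxel box mask (inset from the volume edge,
# as a brain mask would be), no injected effect
null_cohort_spec <- function(seed) {
  cohort_spec(n_patients = 10, n_controls = 10, grid_shape = c(15, 15, 14),
              n_volumes = 120,
              dmn_roi_set = list(box_roi("NET", 2:14, 2:14, 2:13)),
              effect_rois = list(), seed = seed)
}

# generate -> preprocess -> NH -> group stats for one cohort; returns the
# cluster table plus what is needed for recovery scoring
simulate_group_analysis <- function(spec, cfg = preprocess_config(),
                                    use_nuisance = TRUE) {
  mask <- dmn_truth_mask(spec)
  nuis <- if (use_nuisance) nethom:::nuisance_rois(spec) else
    list(wm = NULL, csf = NULL)
  ids <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  maps <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- generate_subject(spec, ids[i],
                            subject_seed = nethom:::subject_seed_for(spec$seed, i))
    res <- preprocess_subject(sub$image,
                              if (use_nuisance) sub$motion else NULL,
                              cfg, nuis$wm, nuis$csf)
    maps[[i]] <- standardize_nh_map(
      compute_nh_map(res$image, mask, paste0(ids[i], i)))
  }
  cmp <- nh_group_comparison(maps[ids == "patient"], maps[ids == "control"],
                             mask)
  list(spec = spec, mask = mask, cmp = cmp)
}

# Dice of detected voxels (clusters of the matching direction, pooled)
# against each injected effect ROI
effect_recovery_dice <- function(sim) {
  cl <- sim$cmp$clusters
  comps <- attr(cl, "clusters")
  rois <- setNames(sim$spec$dmn_roi_set,
                   vapply(sim$spec$dmn_roi_set, `[[`, "", "label"))
  vapply(sim$spec$effect_rois, function(ef) {
    tv <- nethom:::vox_linear_index(rois[[ef$label]]$voxels,
                                    sim$spec$grid_shape)
    dir <- if (ef$direction == "increase") "A>B" else "A<B"
    det <- unlist(lapply(comps[cl$direction == dir], `[[`, "voxels"))
    2 * length(intersect(tv, det)) / (length(tv) + length(det))
  }, 1)
}
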