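# End-to-end pipeline: phantom (or ingested data) -> cleaning ->
# parcellation -> seed contrasts -> brain-behavior correlation, with a
# machine-readable run report.

#' Pipeline configuration
#'
#' Nested stage configurations plus a global seed from which every stage's
#' seed is derived deterministically (stage seeds are `rng_seed + fixed
#' offsets`, so one integer reproduces the whole run).
#'
#' @param rng_seed Global integer seed.
#' @param output_dir Where `run_pipeline()` writes its outputs.
#' @param phantom A [phantom_config()] (its `rng_seed` is overridden).
#' @param cleaning A [cleaning_config()].
#' @param parcellation A [parcellation_config()] (seed overridden).
#' @param inference An [inference_config()] (seed overridden).
#' @param fingerprint_fwhm_mm,contrast_fwhm_mm Smoothing for the
#'   fingerprint-target thread and the group-comparison thread (the ROI
#'   voxel series are never smoothed).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(rng_seed = 1L, output_dir = tempfile("longaxis"),
                            phantom = phantom_config(),
                            cleaning = cleaning_config(),
                            parcellation = parcellation_config(),
                            inference = inference_config(),
                            fingerprint_fwhm_mm = 4,
                            contrast_fwhm_mm = 8) {
  rng_seed <- as.integer(rng_seed)
  phantom$rng_seed <- rng_seed
  parcellation$rng_seed <- rng_seed + 1000L
  inference$rng_seed <- rng_seed + 2000L
  structure(list(rng_seed = rng_seed, output_dir = output_dir,
                 phantom = phantom, cleaning = cleaning,
                 parcellation = parcellation, inference = inference,
                 fingerprint_fwhm_mm = fingerprint_fwhm_mm,
                 contrast_fwhm_mm = contrast_fwhm_mm),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of any stage block may be set; unset fields keep their
#' defaults.
#'
#' @param path YAML file with optional blocks `phantom`, `cleaning`,
#'   `parcellation`, `inference` and top-level `rng_seed`, `output_dir`,
#'   `fingerprint_fwhm_mm`, `contrast_fwhm_mm`.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fun, block) {
    args <- y[[block]]
    if (is.null(args)) return(fun())
    if (block == "phantom") {
      for (f in c("n_per_group", "anterior_coupling", "posterior_coupling"))
        if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
    }
    do.call(fun, args)
  }
  args <- list(phantom = build(phantom_config, "phantom"),
               cleaning = build(cleaning_config, "cleaning"),
               parcellation = build(parcellation_config, "parcellation"),
               inference = build(inference_config, "inference"))
  for (f in c("rng_seed", "output_dir", "fingerprint_fwhm_mm",
              "contrast_fwhm_mm"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(pipeline_config, args)
}

roi_series_of <- function(run, roi_mask) {
  run$data[roi_mask[run$mask], , drop = FALSE]
}

#' Run the full analysis pipeline on a phantom study
#'
#' Generates (or accepts) a phantom study, cleans every run, parcellates the
#' left and right ROI on the first (reference) group, contrasts seed
#' connectivity of each parcel between the reference group and every other
#' group, computes parcel-to-hub connectivity and correlates it with the
#' behavior score. Outputs (label volumes, cluster tables, behavior tables,
#' run report with file checksums) are written under `config$output_dir`.
#'
#' @param config A [pipeline_config()].
#' @param study Optional pre-generated `phantom_study` (bypasses phantom
#'   generation; its grid and tables are used as-is).
#' @return A `pipeline_result` list: `study`, `labelings`, `contrasts`,
#'   `behavior`, `report` (tibble of output files and checksums),
#'   `output_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  t0 <- Sys.time()

  if (is.null(study)) study <- generate_phantom(config$phantom)
  stages$phantom <- list(subjects = nrow(study$subjects))

  grid <- study$grid
  groups <- unique(study$subjects$group)
  ref_group <- groups[1]

  # cleaning: one unsmoothed thread (fingerprints / parcel seeds) and one
  # smoothed thread for voxelwise group comparisons
  cleaned <- lapply(names(study$runs), function(sid)
    clean_run(study$runs[[sid]], study$noise_mask, study$motion[[sid]],
              config$cleaning))
  names(cleaned) <- names(study$runs)
  smoothed_fp <- lapply(cleaned, gaussian_smooth,
                        fwhm_mm = config$fingerprint_fwhm_mm)
  smoothed_con <- lapply(cleaned, gaussian_smooth,
                         fwhm_mm = config$contrast_fwhm_mm)
  stages$cleaning <- list(
    flagged = vapply(cleaned, function(r)
      length(attr(r, "flagged_volumes")), integer(1)))

  # parcellation per ROI on the reference group
  ref_ids <- study$subjects$subject[study$subjects$group == ref_group]
  gm_not_roi <- study$gm_mask & !study$roi_mask_left & !study$roi_mask_right
  labelings <- list()
  for (side in c("left", "right")) {
    roi_mask <- study[[paste0("roi_mask_", side)]]
    runs_roi <- lapply(cleaned[ref_ids], roi_series_of, roi_mask)
    runs_tgt <- lapply(smoothed_fp[ref_ids], roi_series_of, gm_not_roi)
    labelings[[side]] <- parcellate_roi(runs_roi, runs_tgt, roi_mask, grid,
                                        config$parcellation)
    write_volume(labels_to_volume(labelings[[side]], roi_mask, grid),
                 file.path(config$output_dir,
                           paste0("labels_", side, ".nii.gz")), grid)
  }
  stages$parcellation <- list(
    pruned = vapply(labelings, function(l) length(l$pruned_voxels),
                    integer(1)))

  # seed contrasts: reference group vs each other group, per parcel
  contrasts <- list()
  seed_series <- function(sid, side, lab_value) {
    roi_mask <- study[[paste0("roi_mask_", side)]]
    lab <- labelings[[side]]
    kept <- lab$kept_voxels %||% seq_along(lab$labels)
    sel <- kept[lab$labels == lab_value]
    colMeans(roi_series_of(cleaned[[sid]], roi_mask)[sel, , drop = FALSE])
  }
  search_mask <- gm_not_roi
  for (side in c("left", "right")) {
    for (parcel in 1:2) {
      pname <- c("anterior", "posterior")[parcel]
      maps <- lapply(names(cleaned), function(sid)
        seed_to_voxel_map(seed_series(sid, side, parcel),
                          roi_series_of(smoothed_con[[sid]], search_mask),
                          subject = sid,
                          seed_name = paste(side, pname)))
      names(maps) <- names(cleaned)
      for (g in setdiff(groups, ref_group)) {
        ids_g <- study$subjects$subject[study$subjects$group == g]
        covar <- study$subjects$education[
          match(c(ref_ids, ids_g), study$subjects$subject)]
        ci <- permutation_cluster_inference(
          maps[ref_ids], maps[ids_g], covariates = covar,
          mask = search_mask, grid = grid, config = config$inference)
        key <- paste(side, pname, g, sep = "_")
        contrasts[[key]] <- ci
        utils::write.csv(ci$clusters,
                         file.path(config$output_dir,
                                   paste0("clusters_", key, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  stages$contrasts <- list(
    significant = vapply(contrasts, function(ci)
      sum(ci$clusters$significant), integer(1)))

  # parcel-to-hub connectivity and brain-behavior correlation
  hub_for <- list(anterior = "mPFC-like", posterior = "PCC-like")
  beh <- list()
  for (side in c("left", "right")) {
    for (pname in c("anterior", "posterior")) {
      hub_mask <- study$hub_masks[[hub_for[[pname]]]]
      z <- vapply(names(cleaned), function(sid) {
        s1 <- seed_series(sid, side, match(pname, c("anterior", "posterior")))
        s2 <- colMeans(roi_series_of(cleaned[[sid]], hub_mask))
        roi_to_roi_connectivity(s1, s2)
      }, numeric(1))
      beh[[paste(side, pname, sep = "_")]] <- tibble::tibble(
        subject = names(cleaned),
        connection = paste0(side, "_", pname, "_to_", hub_for[[pname]]),
        z = z)
    }
  }
  beh_tbl <- dplyr::bind_rows(beh)
  beh_wide <- dplyr::left_join(study$subjects, beh_tbl, by = "subject")
  correlations <- dplyr::group_by(beh_wide, .data$group, .data$connection)
  correlations <- dplyr::group_modify(correlations, function(d, key)
    behavior_correlation(d$z, d$behavior))
  correlations <- dplyr::ungroup(correlations)
  utils::write.csv(correlations,
                   file.path(config$output_dir, "behavior_correlations.csv"),
                   row.names = FALSE)
  stages$behavior <- list(rows = nrow(correlations))

  files <- list.files(config$output_dir, full.names = TRUE)
  report <- tibble::tibble(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
  report_meta <- list(rng_seed = config$rng_seed,
                      elapsed_seconds =
                        as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      stages = stages)
  jsonlite::write_json(c(report_meta,
                         list(files = as.list(stats::setNames(report$md5,
                                                              report$file)))),
                       file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(study = study, labelings = labelings,
                 contrasts = contrasts, behavior = correlations,
                 behavior_values = beh_wide,
                 report = report, output_dir = config$output_dir,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$study$runs), " subjects; ",
      length(x$contrasts), " contrasts; outputs in ", x$output_dir, "\n",
      sep = "")
  invisible(x)
}
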