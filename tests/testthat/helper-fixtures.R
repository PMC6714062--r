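# Shared fixtures: small phantom configurations and independent oracles
# used across test files. Everything is generated in code at test time.

small_phantom_config <- function(rng_seed = 1L, ...) {
  args <- list(grid_shape = c(14, 12, 8),
               n_per_group = c(control = 3, patient = 3),
               rng_seed = rng_seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_config, args)
}

# strong-signal configuration under which parcellation must recover truth
recovery_config <- function(rng_seed = 1L, n = 20, ...) {
  args <- list(n_per_group = c(control = n),
               anterior_coupling = c(control = 0.9),
               posterior_coupling = c(control = 0.9),
               gradient_sharpness = 20, noise_sd = 0.7,
               rng_seed = rng_seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_config, args)
}

# run cleaning + fingerprint smoothing and parcellate one ROI of a study
parcellate_study <- function(study, side = "left", fwhm = 4,
                             config = parcellation_config(rng_seed = 7)) {
  cleaned <- lapply(names(study$runs), function(sid)
    clean_run(study$runs[[sid]], study$noise_mask, study$motion[[sid]]))
  names(cleaned) <- names(study$runs)
  smoothed <- lapply(cleaned, gaussian_smooth, fwhm_mm = fwhm)
  gm_not_roi <- study$gm_mask & !study$roi_mask_left & !study$roi_mask_right
  roi <- study[[paste0("roi_mask_", side)]]
  parcellate_roi(
    lapply(cleaned, function(r) r$data[roi[r$mask], , drop = FALSE]),
    lapply(smoothed, function(r) r$data[gm_not_roi[r$mask], , drop = FALSE]),
    roi, study$grid, config)
}

truth_labels_for <- function(study, side = "left") {
  tl <- study$truth$roi_labels
  tl$label[tl$roi == side]
}

# independent Pearson correlation oracle (textbook formula, no cor())
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# exhaustive minimum-inertia 2-partition of the rows of x
brute_force_two_partition <- function(x) {
  n <- nrow(x)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(lab)) < 2) next
    inertia <- 0
    for (j in 1:2) {
      rows <- x[lab == j, , drop = FALSE]
      ctr <- colMeans(rows)
      inertia <- inertia + sum(sweep(rows, 2, ctr)^2)
    }
    if (is.null(best) || inertia < best$inertia)
      best <- list(labels = lab, inertia = inertia)
  }
  best
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
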