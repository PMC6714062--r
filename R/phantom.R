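# Multi-subject resting-state phantom generator.
#
# The phantom emulates the statistical structure the analysis assumes: two
# band-limited latent network signals (an "anterior" and a "posterior"
# network), an elongated ROI whose voxels mix the two signals along a
# sigmoid gradient over the long (y) axis, hub regions carrying each signal,
# group-dependent coupling attenuation, slow drift, a shared physiological
# signal concentrated in a noise compartment, whole-volume spike artifacts
# with matching motion traces, and a behavior score linearly coupled to each
# subject's true ROI-hub coupling. Ground truth is retained for every
# planted feature so downstream stages can be tested against it.

#' Configuration of a phantom study
#'
#' Defaults encode the acquisition this generator emulates: 180 volumes at
#' TR = 2 s, with network signals confined to the 0.008-0.09 Hz band used by
#' the cleaning stage.
#'
#' @param grid_shape Voxels per axis (x, y, z); the ROI long axis runs along y.
#' @param voxel_size_mm Isotropic voxel edge, mm.
#' @param n_volumes Time points per run.
#' @param tr_seconds Repetition time, seconds.
#' @param n_per_group Named integer vector, subjects per group.
#' @param anterior_coupling,posterior_coupling Named numeric vectors in
#'   \[0,1\] (one entry per group): mixing weight of the anterior / posterior
#'   network signal into the corresponding ROI compartment.
#' @param coupling_sd Between-subject SD of the coupling weights around the
#'   group value (truncated to \[0,1\]); gives the within-group connectivity
#'   variance that brain-behavior correlation requires.
#' @param gradient_sharpness Slope of the sigmoid switching anterior weight
#'   to posterior weight along the ROI y-axis (per normalized half-length);
#'   large values give an abrupt two-compartment split.
#' @param noise_sd SD of additive white voxel noise.
#' @param drift_amplitude Amplitude of the slow (< 0.008 Hz) cosine drift.
#' @param physio_amplitude Amplitude of the shared physiological signal in
#'   the noise compartment; gray matter receives `physio_gm_weight` of it.
#' @param physio_gm_weight Fraction of the physiological signal leaking into
#'   gray matter.
#' @param spike_rate Fraction of volumes carrying a planted spike artifact.
#' @param spike_amplitude Additive offset of a spike, in units of `noise_sd`.
#' @param behavior_slope,behavior_noise_sd Linear coupling of the behavior
#'   score to the subject's true anterior ROI-hub coupling, and its noise SD.
#' @param rng_seed Integer seed; the study is fully reproducible given it.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(18, 14, 12),
                           voxel_size_mm = 3,
                           n_volumes = 180,
                           tr_seconds = 2,
                           n_per_group = c(control = 20, patient = 20),
                           anterior_coupling = c(control = 0.8, patient = 0.8),
                           posterior_coupling = c(control = 0.8, patient = 0.8),
                           coupling_sd = 0.12,
                           gradient_sharpness = 8,
                           noise_sd = 1,
                           drift_amplitude = 1,
                           physio_amplitude = 1.5,
                           physio_gm_weight = 0.25,
                           spike_rate = 0.03,
                           spike_amplitude = 8,
                           behavior_slope = 1,
                           behavior_noise_sd = 0.15,
                           rng_seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm, n_volumes = as.integer(n_volumes),
              tr_seconds = tr_seconds, n_per_group = n_per_group,
              anterior_coupling = anterior_coupling,
              posterior_coupling = posterior_coupling,
              coupling_sd = coupling_sd,
              gradient_sharpness = gradient_sharpness, noise_sd = noise_sd,
              drift_amplitude = drift_amplitude,
              physio_amplitude = physio_amplitude,
              physio_gm_weight = physio_gm_weight,
              spike_rate = spike_rate, spike_amplitude = spike_amplitude,
              behavior_slope = behavior_slope,
              behavior_noise_sd = behavior_noise_sd,
              rng_seed = as.integer(rng_seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
              voxel_size_mm > 0, n_volumes >= 2, tr_seconds > 0,
              all(n_per_group >= 1), gradient_sharpness >= 0,
              noise_sd > 0, drift_amplitude >= 0,
              spike_rate >= 0, spike_rate < 1, coupling_sd >= 0)
    groups <- names(n_per_group)
    if (is.null(groups) || anyDuplicated(groups))
      stop("n_per_group must carry unique group names", call. = FALSE)
    for (w in list(anterior_coupling, posterior_coupling)) {
      if (!all(groups %in% names(w)))
        stop("coupling weights must name every group", call. = FALSE)
      if (any(w < 0 | w > 1))
        stop("coupling weights must lie in [0, 1]", call. = FALSE)
    }
    # leave headroom for the nuisance design estimated downstream:
    # intercept + 5 CompCor components + expected spike columns
    n_nuis <- 1 + 5 + ceiling(spike_rate * n_volumes)
    if (n_volumes < 2 * n_nuis)
      stop("n_volumes (", n_volumes, ") < 2 x expected nuisance regressors (",
           n_nuis, ")", call. = FALSE)
  })
  invisible(cfg)
}

# ellipsoid mask, 0-based centre/semi-axes in voxels
ellipsoid_mask <- function(grid, center, semi) {
  idx <- voxel_indices(grid)
  d <- ((idx[, 1] - center[1]) / semi[1])^2 +
    ((idx[, 2] - center[2]) / semi[2])^2 +
    ((idx[, 3] - center[3]) / semi[3])^2
  array(d <= 1, dim = grid$shape)
}

block_mask <- function(grid, lo, hi) {
  idx <- voxel_indices(grid)
  inb <- idx[, 1] >= lo[1] & idx[, 1] <= hi[1] &
    idx[, 2] >= lo[2] & idx[, 2] <= hi[2] &
    idx[, 3] >= lo[3] & idx[, 3] <= hi[3]
  array(inb, dim = grid$shape)
}

# Fourier bins of an n_volumes-long run that fall inside [low, high] Hz
inband_bins <- function(n_volumes, tr, low = 0.008, high = 0.09) {
  k <- seq_len(n_volumes %/% 2 - 1)
  k[k / (n_volumes * tr) >= low & k / (n_volumes * tr) <= high]
}

# Band-limited signal: sum of sinusoids with random phases at the given
# Fourier-bin frequencies, scaled to unit SD. Sampling frequencies on the
# run's Fourier bins makes the band limit exact over the acquisition window
# and makes signals built from disjoint bins exactly orthogonal.
bandlimited_signal <- function(n_volumes, tr, bins) {
  t <- (seq_len(n_volumes) - 1) * tr
  f <- bins / (n_volumes * tr)
  ph <- stats::runif(length(bins), 0, 2 * pi)
  s <- rowSums(vapply(seq_along(f),
                      function(i) cos(2 * pi * f[i] * t + ph[i]),
                      numeric(n_volumes)))
  s <- s - mean(s)
  s / stats::sd(s)
}

phantom_geometry <- function(cfg) {
  grid <- volume_grid(cfg$grid_shape, voxel_size_mm = cfg$voxel_size_mm)
  sh <- cfg$grid_shape
  if (any(sh < c(12, 10, 6)))
    stop("grid too small to contain disjoint ROI, hub and noise masks; ",
         "need at least 12 x 10 x 6 voxels (offending mask: roi)",
         call. = FALSE)
  zc <- round(sh[3] * 0.55)
  yc <- (sh[2] - 1) / 2
  semi <- c(max(1.6, sh[1] * 0.12), max(3, sh[2] * 0.36), max(1.4, sh[3] * 0.18))
  roi_left <- ellipsoid_mask(grid, c(round(sh[1] * 0.27), yc, zc), semi)
  roi_right <- ellipsoid_mask(grid, c(round(sh[1] * 0.73), yc, zc), semi)
  hub <- function(cx, cy, cz)
    block_mask(grid, pmax(c(cx, cy, cz) - 1, 0),
               pmin(c(cx, cy, cz) + 1, sh - 1))
  mid_x <- round((sh[1] - 1) / 2)
  hub_masks <- list(
    # anterior-network hubs sit at high y, posterior at low y
    "mPFC-like" = hub(mid_x, sh[2] - 2, zc),
    "anterior-network" = hub(mid_x, sh[2] - 2, max(1, zc - 4)),
    "PCC-like" = hub(mid_x, 1, zc),
    "posterior-network" = hub(mid_x, 1, max(1, zc - 4))
  )
  noise_mask <- block_mask(grid, c(0, round(yc) - 1, 0),
                           c(2, round(yc) + 1, 2))
  for (nm in names(hub_masks)) {
    if (any(hub_masks[[nm]] & (roi_left | roi_right)))
      stop("grid too small: hub mask '", nm, "' overlaps an ROI",
           call. = FALSE)
    if (any(hub_masks[[nm]] & noise_mask))
      stop("grid too small: hub mask '", nm, "' overlaps the noise mask",
           call. = FALSE)
  }
  if (any(noise_mask & (roi_left | roi_right)))
    stop("grid too small: noise mask overlaps an ROI", call. = FALSE)
  gm_mask <- array(TRUE, dim = sh)
  gm_mask[noise_mask] <- FALSE
  list(grid = grid, gm_mask = gm_mask, roi_mask_left = roi_left,
       roi_mask_right = roi_right, noise_mask = noise_mask,
       hub_masks = hub_masks)
}

# sigmoid anterior weight along the ROI long (y) axis
anterior_weight <- function(y_mm, sharpness) {
  yc <- (min(y_mm) + max(y_mm)) / 2
  half <- max((max(y_mm) - min(y_mm)) / 2, .Machine$double.eps)
  1 / (1 + exp(-sharpness * (y_mm - yc) / half))
}

#' Generate a phantom study
#'
#' Builds the masks, per-subject 4D time series, subject table, behavior
#' scores and ground-truth records described in [phantom_config()]. The
#' result is bit-reproducible given `rng_seed`.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_study`: `grid`, `runs` (named list of
#'   [bold_run()]), masks (`gm_mask`, `roi_mask_left`, `roi_mask_right`,
#'   `noise_mask`, `hub_masks`), `motion` (named list of T x 6 matrices),
#'   `global_signal` (named list), `subjects` (tibble), and `truth` (list
#'   with `roi_labels` tibble, `couplings` tibble, `spikes` tibble,
#'   `signals` per-subject latent signals).
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  geo <- phantom_geometry(config)
  grid <- geo$grid
  Tn <- config$n_volumes
  groups <- names(config$n_per_group)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)

  brain_mask <- geo$gm_mask | geo$noise_mask
  vi_brain <- which(brain_mask)
  n_brain <- length(vi_brain)
  # per-voxel role lookups in brain-mask canonical order
  in_roi_l <- geo$roi_mask_left[brain_mask]
  in_roi_r <- geo$roi_mask_right[brain_mask]
  in_noise <- geo$noise_mask[brain_mask]
  in_gm <- geo$gm_mask[brain_mask]
  hub_ant <- (geo$hub_masks[["mPFC-like"]] |
                geo$hub_masks[["anterior-network"]])[brain_mask]
  hub_post <- (geo$hub_masks[["PCC-like"]] |
                 geo$hub_masks[["posterior-network"]])[brain_mask]

  mm_brain <- voxel_to_mm(voxel_indices(grid, brain_mask), grid)

  # anterior weight per ROI voxel, shared across subjects (the geometry is
  # the ROI's, not the subject's)
  truth_labels <- list()
  w_ant <- numeric(n_brain)
  for (side in c("left", "right")) {
    sel <- if (side == "left") in_roi_l else in_roi_r
    y <- mm_brain[sel, "y"]
    w <- anterior_weight(y, config$gradient_sharpness)
    w_ant[sel] <- w
    idx <- voxel_indices(grid, if (side == "left") geo$roi_mask_left
                         else geo$roi_mask_right)
    truth_labels[[side]] <- tibble::tibble(
      roi = side, i = idx[, 1], j = idx[, 2], k = idx[, 3],
      anterior_weight = w,
      label = ifelse(w > 0.5, "anterior", "posterior"))
  }
  truth_labels <- dplyr::bind_rows(truth_labels)

  subj_ids <- character(0)
  subj_group <- character(0)
  for (g in groups) {
    n <- config$n_per_group[[g]]
    subj_ids <- c(subj_ids, sprintf("%s%02d", substr(g, 1, 3), seq_len(n)))
    subj_group <- c(subj_group, rep(g, n))
  }
  n_subj <- length(subj_ids)
  n_spike <- round(config$spike_rate * Tn)

  runs <- list(); motion <- list(); gsig <- list()
  couplings <- vector("list", n_subj); spikes <- vector("list", n_subj)
  signals <- list()
  behavior <- numeric(n_subj)
  mts <- rep(NA, n_subj); education <- numeric(n_subj)
  sex <- character(n_subj); language <- character(n_subj)

  clamp01 <- function(x) pmin(1, pmax(0, x))
  for (s in seq_len(n_subj)) {
    g <- subj_group[s]
    c_ant <- clamp01(config$anterior_coupling[[g]] +
                       stats::rnorm(1, 0, config$coupling_sd))
    c_post <- clamp01(config$posterior_coupling[[g]] +
                        stats::rnorm(1, 0, config$coupling_sd))
    # disjoint in-band Fourier bins make the three latent signals exactly
    # uncorrelated over the run
    bins <- inband_bins(Tn, config$tr_seconds)
    n_sin <- min(6L, length(bins) %/% 3)
    if (n_sin < 1)
      stop("run too short: no in-band Fourier bins for latent signals",
           call. = FALSE)
    pick <- sample(bins, 3 * n_sin)
    A <- bandlimited_signal(Tn, config$tr_seconds, pick[seq_len(n_sin)])
    P <- bandlimited_signal(Tn, config$tr_seconds, pick[n_sin + seq_len(n_sin)])
    physio <- bandlimited_signal(Tn, config$tr_seconds,
                                 pick[2 * n_sin + seq_len(n_sin)])
    tsec <- (seq_len(Tn) - 1) * config$tr_seconds
    drift_f <- stats::runif(1, 0.001, 0.004)
    drift <- config$drift_amplitude *
      cos(2 * pi * drift_f * tsec + stats::runif(1, 0, 2 * pi))

    # mixing weights per voxel (n_brain x 4: A, P, physio, drift)
    wA <- numeric(n_brain); wP <- numeric(n_brain)
    wA[hub_ant] <- 1; wP[hub_post] <- 1
    roi <- in_roi_l | in_roi_r
    wA[roi] <- c_ant * w_ant[roi]
    wP[roi] <- c_post * (1 - w_ant[roi])
    wPh <- ifelse(in_noise, config$physio_amplitude,
                  config$physio_amplitude * config$physio_gm_weight)
    wDr <- stats::runif(n_brain, 0.5, 1.5)

    X <- cbind(wA, wP, wPh, wDr) %*% rbind(A, P, physio, drift)
    X <- X + matrix(stats::rnorm(n_brain * Tn, 0, config$noise_sd),
                    n_brain, Tn)

    spike_vols <- sort(sample(2:Tn, n_spike))
    if (n_spike > 0)
      X[, spike_vols] <- X[, spike_vols] +
        config$spike_amplitude * config$noise_sd

    # motion traces: near-zero wander plus >1 mm translation steps at the
    # planted spike volumes (axis cycles x, y, z per spike)
    mo <- matrix(stats::rnorm(Tn * 6, 0, 0.01), Tn, 6)
    mo <- apply(mo, 2, cumsum)
    for (q in seq_along(spike_vols)) {
      ax <- ((q - 1) %% 3) + 1
      mo[spike_vols[q]:Tn, ax] <- mo[spike_vols[q]:Tn, ax] + 1.5
    }
    behavior[s] <- config$behavior_slope * c_ant +
      stats::rnorm(1, 0, config$behavior_noise_sd)
    mts[s] <- if (g == groups[1]) NA else stats::runif(1) < 0.6
    education[s] <- round(stats::rnorm(1, if (g == groups[1]) 18 else 14, 2))
    sex[s] <- sample(c("M", "F"), 1)
    language[s] <- sample(c("left", "right", "bilateral"), 1,
                          prob = c(0.85, 0.05, 0.10))

    runs[[subj_ids[s]]] <- bold_run(X, brain_mask, grid,
                                    config$tr_seconds, subj_ids[s])
    motion[[subj_ids[s]]] <- mo
    gsig[[subj_ids[s]]] <- colMeans(X)
    couplings[[s]] <- tibble::tibble(subject = subj_ids[s], group = g,
                                     anterior_coupling = c_ant,
                                     posterior_coupling = c_post)
    spikes[[s]] <- if (n_spike > 0)
      tibble::tibble(subject = subj_ids[s], volume = spike_vols)
    else tibble::tibble(subject = character(0), volume = integer(0))
    signals[[subj_ids[s]]] <- list(anterior = A, posterior = P,
                                   physio = physio, drift = drift)
  }

  subjects <- tibble::tibble(subject = subj_ids, group = subj_group,
                             mts = mts, sex = sex, education = education,
                             language = language, behavior = behavior)
  structure(list(
    grid = grid, runs = runs, gm_mask = geo$gm_mask,
    roi_mask_left = geo$roi_mask_left, roi_mask_right = geo$roi_mask_right,
    noise_mask = geo$noise_mask, hub_masks = geo$hub_masks,
    motion = motion, global_signal = gsig, subjects = subjects,
    truth = list(roi_labels = truth_labels,
                 couplings = dplyr::bind_rows(couplings),
                 spikes = dplyr::bind_rows(spikes),
                 signals = signals),
    config = config), class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat("<phantom_study> ", length(x$runs), " subjects (",
      paste(sprintf("%s: %d", names(x$config$n_per_group),
                    x$config$n_per_group), collapse = ", "),
      "), ", format(x$grid), ", T = ", x$config$n_volumes,
      ", TR = ", x$config$tr_seconds, " s\n", sep = "")
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a phantom study to disk
#'
#' 4D runs and 3D masks go out as NIfTI, the subject table, truth tables and
#' motion traces as delimited text, plus a manifest listing every file with
#' its MD5 checksum.
#'
#' @param study A `phantom_study`.
#' @param dir Output directory (created if needed).
#' @return Tibble manifest (file, md5), invisibly written to
#'   `manifest.txt` as well.
#' @export
write_phantom <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0)
    stop("directory not writable: ", dir, call. = FALSE)
  paths <- character(0)
  wv <- function(data, name, ...) {
    p <- file.path(dir, name)
    write_volume(data, p, study$grid, ...)
    paths <<- c(paths, p)
  }
  for (nm in c("gm_mask", "roi_mask_left", "roi_mask_right", "noise_mask"))
    wv(study[[nm]] * 1L, paste0(nm, ".nii.gz"))
  for (nm in names(study$hub_masks))
    wv(study$hub_masks[[nm]] * 1L,
       paste0("hub_", gsub("[^A-Za-z0-9]+", "_", nm), ".nii.gz"))
  for (sid in names(study$runs)) {
    run <- study$runs[[sid]]
    wv(unmask(run$data, run$mask), paste0("bold_", sid, ".nii.gz"),
       tr_seconds = run$tr_seconds, datatype = "double")
    p <- file.path(dir, paste0("motion_", sid, ".txt"))
    utils::write.table(study$motion[[sid]], p, row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(study$subjects, "subjects.csv")
  wt(study$truth$roi_labels, "truth_roi_labels.csv")
  wt(study$truth$couplings, "truth_couplings.csv")
  wt(study$truth$spikes, "truth_spikes.csv")
  manifest <- tibble::tibble(file = basename(paths),
                             md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(dir, "manifest.txt"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read back a phantom study written by [write_phantom()]
#'
#' @param dir Directory produced by [write_phantom()].
#' @return A list with the same volumes and tables (the in-memory truth
#'   signal traces are not round-tripped).
#' @export
read_phantom <- function(dir) {
  rv <- function(name) read_volume(file.path(dir, name))
  gm <- rv("gm_mask.nii.gz")
  grid <- gm$grid
  masks <- list(gm_mask = gm$data > 0)
  for (nm in c("roi_mask_left", "roi_mask_right", "noise_mask"))
    masks[[nm]] <- read_volume(file.path(dir, paste0(nm, ".nii.gz")),
                               grid)$data > 0
  hub_files <- list.files(dir, pattern = "^hub_.*\\.nii\\.gz$")
  hubs <- lapply(hub_files, function(f) read_volume(file.path(dir, f),
                                                    grid)$data > 0)
  names(hubs) <- sub("^hub_(.*)\\.nii\\.gz$", "\\1", hub_files)
  subjects <- tibble::as_tibble(utils::read.csv(file.path(dir,
                                                          "subjects.csv")))
  brain <- masks$gm_mask | masks$noise_mask
  runs <- list(); motion <- list()
  for (sid in subjects$subject) {
    v <- read_volume(file.path(dir, paste0("bold_", sid, ".nii.gz")), grid)
    runs[[sid]] <- bold_run(v$data, brain, grid, v$tr_seconds, sid)
    motion[[sid]] <- as.matrix(utils::read.table(
      file.path(dir, paste0("motion_", sid, ".txt"))))
  }
  truth <- list(
    roi_labels = tibble::as_tibble(
      utils::read.csv(file.path(dir, "truth_roi_labels.csv"))),
    couplings = tibble::as_tibble(
      utils::read.csv(file.path(dir, "truth_couplings.csv"))),
    spikes = tibble::as_tibble(
      utils::read.csv(file.path(dir, "truth_spikes.csv"))))
  c(list(grid = grid, runs = runs, motion = motion, subjects = subjects,
         truth = truth, hub_masks = hubs), masks)
}
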