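# Temporal cleaning of BOLD runs: band-pass filtering, CompCor-style
# nuisance extraction from a noise compartment, artifact spike regressors,
# joint nuisance regression, and mask-normalized Gaussian smoothing.

#' Cleaning configuration
#'
#' Defaults follow common resting-state practice: a 0.008-0.09 Hz pass band,
#' the top five noise-compartment principal components, spike flagging at
#' |global-signal z| > 3, > 1 mm translation or > 0.05 rad rotation between
#' consecutive volumes.
#'
#' @param low_cut_hz,high_cut_hz Pass-band edges in Hz.
#' @param n_compcor Number of noise-compartment principal components.
#' @param global_sd_threshold Global-signal z-score threshold for spikes.
#' @param translation_mm_threshold Volume-to-volume translation threshold, mm.
#' @param rotation_rad_threshold Volume-to-volume rotation threshold, rad
#'   (applied per rotation axis, no conversion to mm).
#' @param smooth_fwhm_mm Gaussian smoothing FWHM in mm; 0 disables smoothing.
#' @param filter_order Butterworth order before the forward-backward pass
#'   doubles the effective order.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(low_cut_hz = 0.008, high_cut_hz = 0.09,
                            n_compcor = 5, global_sd_threshold = 3,
                            translation_mm_threshold = 1,
                            rotation_rad_threshold = 0.05,
                            smooth_fwhm_mm = 0, filter_order = 4) {
  stopifnot(low_cut_hz > 0, high_cut_hz > low_cut_hz, n_compcor >= 0,
            smooth_fwhm_mm >= 0, filter_order >= 1)
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 n_compcor = n_compcor,
                 global_sd_threshold = global_sd_threshold,
                 translation_mm_threshold = translation_mm_threshold,
                 rotation_rad_threshold = rotation_rad_threshold,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 filter_order = filter_order),
            class = "cleaning_config")
}

# ---- band-pass ------------------------------------------------------------

# Squared-magnitude response of the (b, a) filter at digital angular
# frequencies w (radians/sample); this is the gain of a transient-free
# forward-backward pass.
iir_gain2 <- function(w, b, a) {
  H <- vapply(w, function(wi) {
    zb <- exp(-1i * wi * (seq_along(b) - 1))
    za <- exp(-1i * wi * (seq_along(a) - 1))
    abs(sum(b * zb) / sum(a * za))
  }, numeric(1))
  H^2
}

# Zero-phase filtering down the columns: each column is symmetrically
# extended (even reflection, doubling its length) and its spectrum is
# multiplied by the squared-magnitude Butterworth response |H|^2 — the exact
# transfer function of a transient-free forward-backward pass. The gain is
# real and even, so the output is exactly zero-phase and exactly
# equivariant under time reversal.
filtfilt_cols <- function(x, b, a) {
  x <- as.matrix(x)
  n <- nrow(x)
  ext <- rbind(x, x[n:1, , drop = FALSE])
  m <- 2L * n
  g <- iir_gain2(2 * pi * seq(0, m - 1) / m, b, a)
  Y <- stats::mvfft(ext) * g
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / m
  y[seq_len(n), , drop = FALSE]
}

bandpass_coefs <- function(tr_seconds, config) {
  nyq <- 1 / (2 * tr_seconds)
  if (config$high_cut_hz >= nyq)
    stop("high cut ", config$high_cut_hz, " Hz is not below the Nyquist ",
         "frequency ", nyq, " Hz for TR = ", tr_seconds, " s", call. = FALSE)
  bf <- signal::butter(config$filter_order,
                       c(config$low_cut_hz, config$high_cut_hz) / nyq,
                       type = "pass")
  list(b = bf$b, a = bf$a)
}

#' Band-pass filter voxel time series
#'
#' Zero-phase Butterworth band-pass applied to each voxel's demeaned
#' series: the squared-magnitude response of the order-`filter_order`
#' Butterworth (the transfer function of a transient-free forward-backward
#' pass) is applied spectrally on a symmetric extension of the series.
#' Attenuates fluctuations below `low_cut_hz` and above `high_cut_hz`
#' while preserving length.
#'
#' @param series V x T numeric matrix (voxels by time).
#' @param tr_seconds Repetition time in seconds.
#' @param config A [cleaning_config()].
#' @return V x T filtered matrix.
#' @export
bandpass_filter <- function(series, tr_seconds, config = cleaning_config()) {
  series <- as.matrix(series)
  if (ncol(series) < 8) stop("need at least 8 volumes to filter",
                             call. = FALSE)
  if (!all(is.finite(series))) stop("series contains non-finite values",
                                    call. = FALSE)
  co <- bandpass_coefs(tr_seconds, config)
  x <- t(series - rowMeans(series))          # T x V
  t(filtfilt_cols(x, co$b, co$a))
}

#' Squared-magnitude frequency response of the band-pass filter
#'
#' The forward-backward pass applies the filter twice, so the effective
#' amplitude response at frequency `f_hz` is `|H(f)|^2`.
#'
#' @param f_hz Frequencies in Hz.
#' @inheritParams bandpass_filter
#' @return Amplitude response (gain) at each frequency.
#' @export
bandpass_response <- function(f_hz, tr_seconds, config = cleaning_config()) {
  co <- bandpass_coefs(tr_seconds, config)
  iir_gain2(2 * pi * f_hz * tr_seconds, co$b, co$a)
}

# ---- CompCor --------------------------------------------------------------

#' Principal-component nuisance time courses from a noise compartment
#'
#' Demeans each noise-mask voxel series and returns the first `n` principal
#' component time courses (unit variance, mutually orthogonal, ordered by
#' explained variance).
#'
#' @param series V x T matrix of noise-compartment voxel series, or a
#'   [bold_run()] together with `noise_mask`.
#' @param noise_mask Logical array selecting the noise compartment (only
#'   used when `series` is a `bold_run`).
#' @param n Number of components.
#' @return T x n matrix of component time courses with an
#'   `explained_variance` attribute.
#' @export
compcor_components <- function(series, noise_mask = NULL, n = 5) {
  if (inherits(series, "bold_run")) {
    stopifnot(!is.null(noise_mask))
    check_mask(noise_mask, series$grid)
    sel <- noise_mask[series$mask]
    series <- series$data[sel, , drop = FALSE]
  }
  series <- as.matrix(series)
  if (nrow(series) == 0) stop("noise mask is empty", call. = FALSE)
  x <- t(series - rowMeans(series))          # T x V, column = voxel
  sv <- svd(x, nu = min(dim(x)), nv = 0)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (n > rank)
    stop("requested ", n, " components but the noise series have rank ",
         rank, call. = FALSE)
  comp <- sv$u[, seq_len(n), drop = FALSE]
  comp <- matrix(scale(comp), nrow(comp), n)  # unit variance, zero mean
  colnames(comp) <- paste0("compcor-", seq_len(n))
  attr(comp, "explained_variance") <-
    (sv$d[seq_len(n)]^2) / sum(sv$d^2)
  comp
}

# ---- spike regressors -----------------------------------------------------

#' Artifact spike regressors from global signal and motion
#'
#' A volume is flagged when the within-run z-score of the global signal
#' exceeds `global_sd_threshold` in magnitude, or when any volume-to-volume
#' translation change exceeds `translation_mm_threshold`, or any rotation
#' change exceeds `rotation_rad_threshold` (per axis). Each flagged volume
#' contributes one one-hot regressor column.
#'
#' @param global_signal Length-T numeric vector (mean in-brain intensity per
#'   volume).
#' @param motion T x 6 matrix: three translations (mm) then three rotations
#'   (rad).
#' @param config A [cleaning_config()].
#' @return T x m 0/1 matrix (m = number of flagged volumes; m = 0 gives a
#'   T x 0 matrix) with columns named `spike-<volume>` and an attribute
#'   `flagged` listing the volumes.
#' @export
spike_regressors <- function(global_signal, motion,
                             config = cleaning_config()) {
  Tn <- length(global_signal)
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == Tn, ncol(motion) == 6)
  gs_sd <- stats::sd(global_signal)
  z <- if (gs_sd == 0) rep(0, Tn)
  else (global_signal - mean(global_signal)) / gs_sd
  flag_g <- abs(z) > config$global_sd_threshold
  d <- abs(diff(motion))
  flag_t <- c(FALSE, apply(d[, 1:3, drop = FALSE] >
                             config$translation_mm_threshold, 1, any))
  flag_r <- c(FALSE, apply(d[, 4:6, drop = FALSE] >
                             config$rotation_rad_threshold, 1, any))
  flagged <- which(flag_g | flag_t | flag_r)
  out <- matrix(0, Tn, length(flagged))
  for (i in seq_along(flagged)) out[flagged[i], i] <- 1
  colnames(out) <- if (length(flagged)) paste0("spike-", flagged)
  else character(0)
  attr(out, "flagged") <- flagged
  out
}

# ---- nuisance regression --------------------------------------------------

#' Regress a nuisance design out of voxel time series
#'
#' Least-squares residuals of every voxel series on an intercept plus the
#' design columns; residuals are numerically orthogonal to every column.
#'
#' @param series V x T matrix.
#' @param design T x m numeric matrix (m may be 0, giving plain demeaning).
#' @return V x T residual matrix.
#' @export
regress_nuisance <- function(series, design) {
  series <- as.matrix(series)
  Tn <- ncol(series)
  design <- if (is.null(design)) matrix(0, Tn, 0) else as.matrix(design)
  stopifnot(nrow(design) == Tn)
  if (Tn <= ncol(design) + 1)
    stop("need more volumes (", Tn, ") than design columns + 1 (",
         ncol(design) + 1, ")", call. = FALSE)
  X <- cbind(`(intercept)` = 1, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  t(qr.resid(qrX, t(series)))
}

# ---- Gaussian smoothing ---------------------------------------------------

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve a 3D array along one axis with a symmetric kernel (zero padding),
# implemented as a banded-matrix product for speed
conv_axis <- function(arr, k, axis) {
  if (length(k) == 1) return(arr)
  d <- dim(arr)
  n <- d[axis]
  r <- (length(k) - 1) / 2
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    src <- idx + o
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[o + r + 1]
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m <- K %*% matrix(m, nrow = n)
  m <- array(m, dm)
  aperm(m, order(perm))
}

#' Mask-normalized Gaussian smoothing
#'
#' Smooths each volume with a separable 3D Gaussian of the given FWHM
#' (sigma = FWHM / (2 sqrt(2 ln 2)) per axis, converted from mm to voxels
#' through the grid). Values outside the mask are excluded from the
#' convolution and restored afterwards, and the in-mask kernel mass is
#' renormalized so constant regions are preserved exactly.
#'
#' @param data 3D array, 4D array, or [bold_run()].
#' @param fwhm_mm Full width at half maximum in mm; 0 returns the input.
#' @param grid A `volume_grid` (taken from the run if `data` is one).
#' @param mask Logical array; defaults to everywhere (or the run's mask).
#' @return Same container as the input, smoothed within the mask.
#' @export
gaussian_smooth <- function(data, fwhm_mm, grid = NULL, mask = NULL) {
  if (inherits(data, "bold_run")) {
    run <- data
    sm <- gaussian_smooth(unmask(run$data, run$mask), fwhm_mm, run$grid,
                          run$mask)
    out <- run
    flat <- matrix(sm, nrow = prod(run$grid$shape))
    out$data <- flat[which(run$mask), , drop = FALSE]
    return(out)
  }
  stopifnot(fwhm_mm >= 0, !is.null(grid))
  if (fwhm_mm == 0) return(data)
  if (is.null(mask)) mask <- array(TRUE, dim = grid$shape)
  check_mask(mask, grid)
  vox_mm <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / vox_mm
  ks <- lapply(sigma_vox, gaussian_kernel_1d)
  smooth3 <- function(v) {
    num <- conv_axis(conv_axis(conv_axis(v * mask, ks[[1]], 1),
                               ks[[2]], 2), ks[[3]], 3)
    num
  }
  den <- smooth3(array(1, dim = grid$shape))
  den[den == 0] <- 1
  if (length(dim(data)) == 3) {
    out <- smooth3(data) / den
    out[!mask] <- data[!mask]
    return(out)
  }
  # 4D: convolve all volumes at once (conv_axis reshapes generically, and
  # the 3D mask/denominator recycle along the time axis)
  masked <- data * as.vector(mask)
  num <- conv_axis(conv_axis(conv_axis(masked, ks[[1]], 1),
                             ks[[2]], 2), ks[[3]], 3)
  out <- num / as.vector(den)
  outside <- rep(!mask, dim(data)[4])
  out[outside] <- data[outside]
  out
}

# ---- full cleaning of one run --------------------------------------------

#' Clean one BOLD run
#'
#' Applies the temporal pipeline in one pass: spike regressors are built
#' from the raw global signal and motion; the data and the continuous
#' nuisance regressors (noise-compartment principal components) are
#' band-pass filtered; then filtered components and one-hot spike columns
#' are regressed out jointly, so residuals are in-band and orthogonal to the
#' design. Optional mask-normalized smoothing comes last.
#'
#' @param run A [bold_run()].
#' @param noise_mask Logical array, the noise compartment for CompCor.
#' @param motion T x 6 motion-parameter matrix (or `NULL` to skip spike
#'   flagging from motion).
#' @param config A [cleaning_config()].
#' @return A cleaned `bold_run`; the nuisance design and flagged volumes are
#'   attached as attributes `design` and `flagged_volumes`.
#' @export
clean_run <- function(run, noise_mask, motion = NULL,
                      config = cleaning_config()) {
  stopifnot(inherits(run, "bold_run"))
  gsignal <- colMeans(run$data)
  spikes <- if (is.null(motion))
    spike_regressors(gsignal, matrix(0, ncol(run$data), 6), config)
  else spike_regressors(gsignal, motion, config)
  cc <- if (config$n_compcor > 0)
    compcor_components(run, noise_mask, config$n_compcor)
  else matrix(0, ncol(run$data), 0)
  # the data are filtered before regression, so every regressor is passed
  # through the same filter: spike one-hots become the exact ringing
  # pattern a filtered impulse leaves in the data, and the components stay
  # matched to the filtered noise-compartment series
  co <- bandpass_coefs(run$tr_seconds, config)
  design <- cbind(cc, spikes)
  design_f <- if (ncol(design) > 0)
    filtfilt_cols(scale(design, scale = FALSE), co$b, co$a)
  else design
  colnames(design_f) <- colnames(design)
  filtered <- bandpass_filter(run$data, run$tr_seconds, config)
  resid <- regress_nuisance(filtered, design_f)
  out <- run
  out$data <- resid
  if (config$smooth_fwhm_mm > 0)
    out <- gaussian_smooth(out, config$smooth_fwhm_mm)
  attr(out, "design") <- design_f
  attr(out, "flagged_volumes") <- attr(spikes, "flagged")
  out
}
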