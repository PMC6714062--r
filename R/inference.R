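# Seed-based connectivity maps and group inference.
#
# Per subject, the mean seed time course is correlated with every
# gray-matter voxel and Fisher z transformed. Group contrasts fit, per
# voxel, a linear model with intercept, group indicator and covariates; the
# group t map is thresholded at a cluster-defining p, suprathreshold voxels
# are clustered (positive and negative separately), and cluster sizes are
# referred to a permutation null built by relabeling group membership.
# Benjamini-Hochberg FDR across observed clusters marks significance.

#' Inference configuration
#'
#' @param n_permutations Number of group relabelings (if fewer distinct
#'   relabelings exist, all of them are used exactly and the count recorded).
#' @param cluster_defining_p Voxelwise two-sided p threshold forming
#'   clusters.
#' @param fdr_q FDR level across observed clusters.
#' @param two_sided Test both directions (positive and negative
#'   suprathreshold sets are clustered separately).
#' @param cluster_connectivity 6, 18 or 26.
#' @param null_type `"max"` (per-permutation maximum cluster size; the
#'   default) or `"pooled"` (all suprathreshold cluster sizes of every
#'   permutation, ranked against their total count).
#' @param rng_seed Integer seed for the permutation draw.
#' @return A list of class `inference_config`.
#' @export
inference_config <- function(n_permutations = 5000,
                             cluster_defining_p = 0.005, fdr_q = 0.05,
                             two_sided = TRUE, cluster_connectivity = 26,
                             null_type = c("max", "pooled"),
                             rng_seed = 1L) {
  stopifnot(cluster_defining_p > 0, cluster_defining_p < 1,
            n_permutations >= 100, fdr_q > 0, fdr_q <= 1,
            cluster_connectivity %in% c(6, 18, 26))
  structure(list(n_permutations = as.integer(n_permutations),
                 cluster_defining_p = cluster_defining_p, fdr_q = fdr_q,
                 two_sided = isTRUE(two_sided),
                 cluster_connectivity = cluster_connectivity,
                 null_type = match.arg(null_type),
                 rng_seed = as.integer(rng_seed)),
            class = "inference_config")
}

#' Fisher z transformation
#'
#' `atanh(r)`: variance-stabilizing transform of a Pearson correlation.
#'
#' @param r Correlations, all strictly inside (-1, 1).
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("Fisher z is defined for |r| < 1; mask boundary correlations ",
         "upstream", call. = FALSE)
  atanh(r)
}

#' Seed-to-voxel connectivity map
#'
#' Pearson correlation of the seed time course with every voxel series,
#' Fisher z transformed. Voxels with undefined or boundary correlations
#' (constant series, |r| >= 1) are masked out and recorded.
#'
#' @param seed_series Length-T numeric vector (mean seed time course).
#' @param brain_series V x T matrix of voxel series.
#' @param subject Optional subject id carried into the result.
#' @param seed_name Optional seed name.
#' @return A `seed_map`: list with `z` (length V, `NA` at masked voxels),
#'   `masked` (indices), `subject`, `seed_name`.
#' @export
seed_to_voxel_map <- function(seed_series, brain_series,
                              subject = NA_character_,
                              seed_name = NA_character_) {
  brain_series <- as.matrix(brain_series)
  stopifnot(length(seed_series) == ncol(brain_series))
  if (stats::sd(seed_series) == 0)
    stop("seed series is constant", call. = FALSE)
  r <- as.vector(stats::cor(seed_series, t(brain_series)))
  bad <- !is.finite(r) | abs(r) >= 1 - 1e-12
  z <- rep(NA_real_, length(r))
  z[!bad] <- atanh(r[!bad])
  structure(list(z = z, masked = which(bad), subject = subject,
                 seed_name = seed_name), class = "seed_map")
}

seed_map_matrix <- function(maps) {
  z <- do.call(rbind, lapply(maps, function(m)
    if (inherits(m, "seed_map")) m$z else as.numeric(m)))
  rownames(z) <- vapply(maps, function(m)
    if (inherits(m, "seed_map")) m$subject else NA_character_, character(1))
  z
}

# per-voxel t statistic for the group column of [1 | group | covariates]
tmap_fit <- function(Y, group, covariates = NULL) {
  n <- nrow(Y)
  X <- cbind(1, group)
  if (!is.null(covariates) && NCOL(covariates) > 0)
    X <- cbind(X, as.matrix(covariates))
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("singular design: a covariate is collinear with the group ",
         "indicator or intercept", call. = FALSE)
  XtXi <- chol2inv(qr.R(qrX))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXi[2, 2])
  t <- as.vector(B[2, ] / se)
  t[se == 0] <- 0
  list(t = t, df = df)
}

#' Voxelwise two-group contrast
#'
#' Per voxel, the t statistic of the group indicator in a linear model with
#' intercept, group and covariates of no interest. With no covariates this
#' equals the pooled-variance two-sample t test (group a minus group b).
#'
#' @param maps_a,maps_b Lists of `seed_map` (or numeric z vectors), one per
#'   subject.
#' @param covariates Optional data frame / matrix of per-subject covariates,
#'   rows ordered as `c(maps_a, maps_b)`.
#' @return List with `t` (length V; `NA` where any subject is masked), `df`,
#'   `group` (indicator used), `n_a`, `n_b`.
#' @export
group_contrast <- function(maps_a, maps_b, covariates = NULL) {
  stopifnot(length(maps_a) >= 2, length(maps_b) >= 2)
  Y <- seed_map_matrix(c(maps_a, maps_b))
  group <- rep(c(1, 0), c(length(maps_a), length(maps_b)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(Y))
    if (anyNA(covariates)) stop("covariates contain missing values",
                                call. = FALSE)
  }
  ok <- !apply(is.na(Y), 2, any)
  fit <- tmap_fit(Y[, ok, drop = FALSE], group, covariates)
  t_full <- rep(NA_real_, ncol(Y))
  t_full[ok] <- fit$t
  list(t = t_full, df = fit$df, group = group,
       n_a = length(maps_a), n_b = length(maps_b))
}

# suprathreshold clusters of a t map over mask voxels; returns a list of
# integer index vectors (into the voxel order), with sign attached
supra_clusters <- function(t, tcrit, coords, connectivity, two_sided) {
  out <- list()
  signs <- if (two_sided) c(1, -1) else 1
  for (s in signs) {
    sel <- which(!is.na(t) & s * t > tcrit)
    if (!length(sel)) next
    cc <- connected_components(coords[sel, , drop = FALSE], connectivity)
    for (c in seq_len(max(cc))) {
      ix <- sel[cc == c]
      out[[length(out) + 1]] <- structure(
        ix, sign = s, mass = sum(abs(t[ix]) - tcrit))
    }
  }
  out
}

# Clusters are ordered lexicographically: larger extent wins; equal extents
# are ordered by suprathreshold excess mass. The continuous mass component
# breaks the heavy integer ties among small clusters, so null p-values are
# continuously distributed while extent stays the primary statistic.
cluster_exceeds <- function(null_size, null_mass, size, mass) {
  null_size > size | (null_size == size & null_mass >= mass)
}

# Map-level ordering for calibration: maximal cluster by (extent, mass),
# with the map's peak |t| as a final continuous key so maps without any
# suprathreshold cluster are ranked among themselves too.
map_exceeds <- function(ns, nm, np, s, m, pk) {
  ns > s | (ns == s & nm > m) | (ns == s & nm == m & np >= pk)
}

# all distinct assignments of n_a "group a" slots among n subjects, as a
# matrix of indicator columns; used when exhaustive enumeration is smaller
# than the requested permutation count
distinct_relabelings <- function(n, n_a) {
  cmb <- utils::combn(n, n_a)
  ind <- matrix(0, n, ncol(cmb))
  for (i in seq_len(ncol(cmb))) ind[cmb[, i], i] <- 1
  ind
}

#' Permutation cluster-extent inference on a group contrast
#'
#' Thresholds the observed t map at the two-sided t quantile for
#' `cluster_defining_p`, forms suprathreshold clusters, and compares each
#' observed cluster's extent with a permutation null obtained by relabeling
#' group membership (covariates stay bound to their subjects). Clusters are
#' ordered by extent with suprathreshold excess mass as a continuous
#' tie-break; the uncorrected cluster p is
#' `(1 + #{null clusters >= observed}) / (1 + n_null)` under that order;
#' Benjamini-Hochberg across observed clusters at `fdr_q` marks
#' significance. Deterministic given `rng_seed`.
#'
#' @inheritParams group_contrast
#' @param mask Logical array over the grid giving the search space (the
#'   voxel order of the maps must be this mask's canonical order).
#' @param grid A `volume_grid` (for peak mm coordinates).
#' @param config An [inference_config()].
#' @return A `cluster_inference` object; `clusters` is a tibble with one
#'   row per observed cluster (sign, size, mass, peak coordinates, peak t,
#'   p_uncorrected, p_fdr, significant). `p_map` is the map-level p-value
#'   of the maximal cluster statistic under an (extent, mass, peak |t|)
#'   ordering, defined even when no voxel is suprathreshold.
#' @export
permutation_cluster_inference <- function(maps_a, maps_b, covariates = NULL,
                                          mask, grid,
                                          config = inference_config()) {
  check_mask(mask, grid)
  Y <- seed_map_matrix(c(maps_a, maps_b))
  stopifnot(ncol(Y) == sum(mask))
  n_a <- length(maps_a); n <- nrow(Y)
  group <- rep(c(1, 0), c(n_a, n - n_a))
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)

  ok <- !apply(is.na(Y), 2, any)
  Yok <- Y[, ok, drop = FALSE]
  coords_all <- voxel_indices(grid, mask)
  coords <- coords_all[ok, , drop = FALSE]

  obs <- tmap_fit(Yok, group, covm)
  tcrit <- stats::qt(1 - config$cluster_defining_p / 2, obs$df)
  obs_cl <- supra_clusters(obs$t, tcrit, coords,
                           config$cluster_connectivity, config$two_sided)

  # permutation null of cluster sizes
  n_distinct <- choose(n, n_a)
  exhaustive <- is.finite(n_distinct) && n_distinct <= config$n_permutations
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)
  perms <- if (exhaustive) {
    distinct_relabelings(n, n_a)
  } else {
    vapply(seq_len(config$n_permutations), function(i) {
      g <- rep(0, n); g[sample.int(n, n_a)] <- 1; g
    }, numeric(n))
  }
  n_perm <- ncol(perms)
  null_sizes <- vector("list", n_perm)
  null_masses <- vector("list", n_perm)
  null_peaks <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    fit <- tmap_fit(Yok, perms[, i], covm)
    cl <- supra_clusters(fit$t, tcrit, coords,
                         config$cluster_connectivity, config$two_sided)
    null_sizes[[i]] <- lengths(cl)
    null_masses[[i]] <- vapply(cl, attr, numeric(1), "mass")
    null_peaks[i] <- max(abs(fit$t))
  }

  # map-level p: the maximal cluster under (extent, mass, peak |t|)
  # ordering, defined even for maps with no suprathreshold cluster --
  # exactly (discretely) uniform under the null, which the calibration
  # suite exploits
  nm_size <- numeric(n_perm); nm_mass <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    si <- null_sizes[[i]]; mi <- null_masses[[i]]
    if (length(si)) {
      j <- order(si, mi, decreasing = TRUE)[1]
      nm_size[i] <- si[j]; nm_mass[i] <- mi[j]
    }
  }
  obs_sizes <- lengths(obs_cl)
  obs_masses <- vapply(obs_cl, attr, numeric(1), "mass")
  if (length(obs_cl)) {
    j <- order(obs_sizes, obs_masses, decreasing = TRUE)[1]
    obs_max <- c(obs_sizes[j], obs_masses[j])
  } else obs_max <- c(0, 0)
  obs_peak <- max(abs(obs$t), na.rm = TRUE)
  p_map <- (1 + sum(map_exceeds(nm_size, nm_mass, null_peaks,
                                obs_max[1], obs_max[2], obs_peak))) /
    (1 + n_perm)

  if (length(obs_cl)) {
    sizes <- obs_sizes
    masses <- obs_masses
    if (config$null_type == "max") {
      p_unc <- vapply(seq_along(sizes), function(k)
        (1 + sum(cluster_exceeds(nm_size, nm_mass, sizes[k], masses[k]))) /
          (1 + n_perm), numeric(1))
    } else {
      pool_s <- unlist(null_sizes); pool_m <- unlist(null_masses)
      p_unc <- vapply(seq_along(sizes), function(k)
        (1 + sum(cluster_exceeds(pool_s, pool_m, sizes[k], masses[k]))) /
          (1 + length(pool_s)), numeric(1))
    }
    p_fdr <- stats::p.adjust(p_unc, "BH")
    peaks <- lapply(obs_cl, function(ix) {
      tt <- obs$t[ix]
      pk <- ix[order(-abs(tt))[1]]
      list(peak_t = obs$t[pk], peak = voxel_to_mm(coords[pk, , drop = FALSE],
                                                  grid))
    })
    clusters <- tibble::tibble(
      cluster = seq_along(obs_cl),
      sign = vapply(obs_cl, attr, numeric(1), "sign"),
      size = as.integer(sizes),
      mass = masses,
      peak_x = vapply(peaks, function(p) p$peak[1, 1], numeric(1)),
      peak_y = vapply(peaks, function(p) p$peak[1, 2], numeric(1)),
      peak_z = vapply(peaks, function(p) p$peak[1, 3], numeric(1)),
      peak_t = vapply(peaks, function(p) p$peak_t, numeric(1)),
      p_uncorrected = p_unc,
      p_fdr = pmax(p_fdr, p_unc),
      significant = p_fdr <= config$fdr_q)
    clusters <- dplyr::arrange(clusters, .data$p_uncorrected,
                               dplyr::desc(.data$size))
    clusters$cluster <- seq_len(nrow(clusters))
  } else {
    clusters <- tibble::tibble(
      cluster = integer(0), sign = numeric(0), size = integer(0),
      mass = numeric(0), peak_x = numeric(0), peak_y = numeric(0), peak_z = numeric(0),
      peak_t = numeric(0), p_uncorrected = numeric(0), p_fdr = numeric(0),
      significant = logical(0))
  }
  t_full <- rep(NA_real_, sum(mask))
  t_full[ok] <- obs$t
  structure(list(
    clusters = clusters, t_map = t_full, df = obs$df, tcrit = tcrit,
    cluster_voxels = lapply(obs_cl, function(ix) which(ok)[ix]),
    null_sizes = null_sizes, null_masses = null_masses,
    p_map = p_map, n_permutations_used = n_perm,
    exhaustive = exhaustive, mask = mask, grid = grid, config = config,
    maps = Y, group = group, covariates = covm),
    class = "cluster_inference")
}

#' @export
print.cluster_inference <- function(x, ...) {
  cat("<cluster_inference> ", nrow(x$clusters), " cluster(s), df = ", x$df,
      ", |t| threshold ", signif(x$tcrit, 4), ", ",
      x$n_permutations_used,
      if (x$exhaustive) " exhaustive relabelings\n" else " permutations\n",
      sep = "")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Small-volume correction
#'
#' Recomputes the entire inference (thresholding, clustering, permutation
#' null) with the search space restricted to `svc_mask`.
#'
#' @param result A `cluster_inference`.
#' @param svc_mask Logical array; intersected with the original search mask.
#' @param config Optional replacement [inference_config()].
#' @return A `cluster_inference` restricted to the small volume.
#' @export
small_volume_correct <- function(result, svc_mask, config = NULL) {
  stopifnot(inherits(result, "cluster_inference"))
  check_mask(svc_mask, result$grid, "svc_mask")
  if (!any(svc_mask)) stop("small-volume mask is empty", call. = FALSE)
  keep <- svc_mask[result$mask]
  newmask <- result$mask & svc_mask
  Y <- result$maps[, keep, drop = FALSE]
  n_a <- sum(result$group == 1)
  maps_a <- lapply(seq_len(n_a), function(i) Y[i, ])
  maps_b <- lapply(seq(n_a + 1, nrow(Y)), function(i) Y[i, ])
  permutation_cluster_inference(maps_a, maps_b, result$covariates,
                                newmask, result$grid,
                                config %||% result$config)
}

#' Per-subject connectivity at a cluster's peak voxel
#'
#' @param maps List of `seed_map` (or numeric z vectors), one per subject,
#'   over the same voxel order as the inference mask.
#' @param result A `cluster_inference`.
#' @param cluster Cluster number (row of `result$clusters`).
#' @return Tibble (subject, value); a subject whose peak voxel is masked is
#'   recorded with `NA`.
#' @export
extract_peak_values <- function(maps, result, cluster = 1) {
  stopifnot(cluster %in% result$clusters$cluster)
  row <- result$clusters[result$clusters$cluster == cluster, ]
  vox <- result$cluster_voxels[[cluster]]
  Y <- seed_map_matrix(maps)
  tt <- result$t_map[vox]
  pk <- vox[order(-abs(tt))[1]]
  tibble::tibble(
    subject = rownames(Y) %||% as.character(seq_len(nrow(Y))),
    value = Y[, pk])
}

#' Permutation two-sample t test on scalar values
#'
#' Pooled-variance two-sample t with a two-sided permutation p-value from
#' random group relabelings (`+1` correction); when fewer distinct
#' relabelings exist than requested, all of them are enumerated exactly.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param n_permutations Requested number of relabelings.
#' @param rng_seed Integer seed.
#' @return Tibble with `t`, `p`, `n_permutations_used`, `exhaustive`,
#'   `degenerate` (TRUE when both groups had zero variance, in which case
#'   p = 1).
#' @export
subgroup_permutation_ttest <- function(a, b, n_permutations = 5000,
                                       rng_seed = 1L) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
      (nx + ny - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  vals <- c(a, b)
  n <- length(vals); n_a <- length(a)
  if (stats::var(vals) == 0)
    return(tibble::tibble(t = 0, p = 1, n_permutations_used = 0L,
                          exhaustive = TRUE, degenerate = TRUE))
  t_obs <- pooled_t(a, b)
  n_distinct <- choose(n, n_a)
  exhaustive <- n_distinct <= n_permutations
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  draw <- if (exhaustive) {
    cmb <- utils::combn(n, n_a)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  } else {
    lapply(seq_len(n_permutations), function(i) sample.int(n, n_a))
  }
  t_null <- vapply(draw, function(ix)
    pooled_t(vals[ix], vals[-ix]), numeric(1))
  t_null[!is.finite(t_null)] <- 0
  if (exhaustive) {
    # the observed labeling is one of the enumerated relabelings
    p <- sum(abs(t_null) >= abs(t_obs) - 1e-12) / length(t_null)
  } else {
    p <- (1 + sum(abs(t_null) >= abs(t_obs) - 1e-12)) / (1 + length(t_null))
  }
  tibble::tibble(t = t_obs, p = p,
                 n_permutations_used = length(t_null),
                 exhaustive = exhaustive, degenerate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
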