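test_that("Fisher z closed forms and symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("seed maps mask boundary voxels and have the z sampling spread", {
  set.seed(20)
  Tn <- 180
  seed <- rnorm(Tn)
  brain <- rbind(seed, matrix(rnorm(500 * Tn), 500, Tn))
  m <- seed_to_voxel_map(seed, brain)
  expect_equal(m$masked, 1)     # the seed's own copy hits |r| = 1
  expect_true(is.na(m$z[1]))
  z <- m$z[-1]
  # Fisher z of null correlations: SD ~ 1/sqrt(T - 3)
  expect_equal(mean(z), 0, tolerance = 0.02)
  expect_equal(sd(z), 1 / sqrt(Tn - 3), tolerance = 0.15)
  expect_error(seed_to_voxel_map(rep(1, Tn), brain), "constant")
})

test_that("hub z separation grows with planted coupling", {
  zgap <- vapply(c(0.3, 0.9), function(cpl) {
    st <- generate_phantom(small_phantom_config(
      rng_seed = 61, n_per_group = c(control = 6),
      anterior_coupling = c(control = cpl),
      posterior_coupling = c(control = cpl), coupling_sd = 0))
    gaps <- vapply(names(st$runs), function(sid) {
      run <- clean_run(st$runs[[sid]], st$noise_mask, st$motion[[sid]])
      ant <- truth_labels_for(st, "left") == "anterior"
      roi <- run$data[st$roi_mask_left[run$mask], , drop = FALSE]
      m <- seed_to_voxel_map(colMeans(roi[ant, ]), run$data)
      hub <- st$hub_masks[["mPFC-like"]][run$mask]
      mean(m$z[hub], na.rm = TRUE) - mean(m$z[!hub], na.rm = TRUE)
    }, numeric(1))
    mean(gaps)
  }, numeric(1))
  expect_true(all(zgap > 0))
  expect_gt(zgap[2], zgap[1])
})

test_that("group contrast equals the pooled two-sample t without covariates", {
  set.seed(21)
  V <- 40
  za <- lapply(1:7, function(i) rnorm(V))
  zb <- lapply(1:9, function(i) rnorm(V, 0.3))
  gc <- group_contrast(za, zb)
  Ya <- do.call(rbind, za); Yb <- do.call(rbind, zb)
  tref <- vapply(seq_len(V), function(v)
    unname(t.test(Ya[, v], Yb[, v], var.equal = TRUE)$statistic), numeric(1))
  expect_equal(gc$t, tref, tolerance = 1e-10)
  expect_equal(gc$df, 14)
  # identical groups give t ~ 0
  gc0 <- group_contrast(za, za)
  expect_lt(max(abs(gc0$t)), 1e-8)
  # covariate collinear with group is an error
  expect_error(group_contrast(za, zb, covariates = rep(c(1, 0), c(7, 9))),
               "singular")
  # covariates reduce the df accordingly
  gc2 <- group_contrast(za, zb, covariates = rnorm(16))
  expect_equal(gc2$df, 13)
})

test_that("permutation inference is deterministic and finds the planted cluster", {
  set.seed(22)
  g <- volume_grid(c(8, 8, 8), voxel_size_mm = 3)
  mask <- array(TRUE, c(8, 8, 8))
  eff <- array(0, c(8, 8, 8)); eff[3:5, 3:5, 3:5] <- 1
  ma <- lapply(1:10, function(i) rnorm(512) + 2.5 * as.vector(eff))
  mb <- lapply(1:10, function(i) rnorm(512))
  cfg <- inference_config(n_permutations = 200, rng_seed = 5)
  ci1 <- permutation_cluster_inference(ma, mb, NULL, mask, g, cfg)
  ci2 <- permutation_cluster_inference(ma, mb, NULL, mask, g, cfg)
  expect_identical(ci1$clusters, ci2$clusters)
  top <- ci1$clusters[1, ]
  expect_true(top$significant)
  expect_gte(top$size, 15)
  expect_equal(top$sign, 1)
  # planted voxels dominate the top cluster
  planted <- which(as.vector(eff) == 1)
  expect_gt(length(intersect(ci1$cluster_voxels[[1]], planted)) /
              length(planted), 0.5)
  # corrected p never smaller than uncorrected
  expect_true(all(ci1$clusters$p_fdr >= ci1$clusters$p_uncorrected))
})

test_that("a cluster beating every permutation gets the extreme-rank p", {
  set.seed(23)
  g <- volume_grid(c(6, 6, 6), voxel_size_mm = 3)
  mask <- array(TRUE, c(6, 6, 6))
  eff <- array(0, c(6, 6, 6)); eff[2:5, 2:5, 2:5] <- 1
  ma <- lapply(1:8, function(i) rnorm(216) + 4 * as.vector(eff))
  mb <- lapply(1:8, function(i) rnorm(216))
  cfg <- inference_config(n_permutations = 150, rng_seed = 9)
  ci <- permutation_cluster_inference(ma, mb, NULL, mask, g, cfg)
  null_max <- vapply(ci$null_sizes, function(s)
    if (length(s)) max(s) else 0, numeric(1))
  top <- ci$clusters[1, ]
  if (top$size > max(null_max)) {
    expect_equal(top$p_uncorrected, 1 / (ci$n_permutations_used + 1))
  }
  expect_gte(top$size, max(null_max))  # the planted effect is overwhelming
})

test_that("permutations relabel groups but keep covariates bound to subjects", {
  set.seed(24)
  g <- volume_grid(c(5, 5, 5), voxel_size_mm = 3)
  mask <- array(TRUE, c(5, 5, 5))
  ma <- lapply(1:5, function(i) rnorm(125))
  mb <- lapply(1:5, function(i) rnorm(125))
  covar <- rnorm(10)
  ci <- permutation_cluster_inference(ma, mb, covar, mask, g,
                                      inference_config(n_permutations = 100,
                                                       rng_seed = 2))
  expect_identical(ci$covariates, as.matrix(covar))
  expect_equal(sum(ci$group), 5)
  expect_equal(ci$df, 10 - 3)
})

test_that("small-volume correction with the full mask reproduces the result", {
  set.seed(25)
  g <- volume_grid(c(6, 6, 6), voxel_size_mm = 3)
  mask <- array(TRUE, c(6, 6, 6))
  eff <- array(0, c(6, 6, 6)); eff[2:4, 2:4, 2:4] <- 1
  ma <- lapply(1:8, function(i) rnorm(216) + 1.2 * as.vector(eff))
  mb <- lapply(1:8, function(i) rnorm(216))
  cfg <- inference_config(n_permutations = 120, rng_seed = 3)
  ci <- permutation_cluster_inference(ma, mb, NULL, mask, g, cfg)
  svc_full <- small_volume_correct(ci, mask)
  expect_equal(svc_full$clusters, ci$clusters)
  # disjoint mask -> zero clusters
  far <- array(FALSE, c(6, 6, 6)); far[6, 6, 6] <- TRUE
  svc_far <- small_volume_correct(ci, far)
  expect_equal(nrow(svc_far$clusters), 0)
  # a weak effect can reach significance when the search space shrinks
  eff_mask <- array(as.logical(eff), c(6, 6, 6))
  svc_eff <- small_volume_correct(ci, eff_mask)
  expect_gte(nrow(svc_eff$clusters), 1)
})

test_that("subgroup permutation t test matches exhaustive enumeration", {
  a <- c(2.1, 3.3, 1.8, 2.9)
  b <- c(4.0, 5.1, 4.4, 3.9)
  res <- subgroup_permutation_ttest(a, b, n_permutations = 5000,
                                    rng_seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations_used, 70)
  # independent oracle: enumerate all 70 relabelings directly
  vals <- c(a, b)
  tstat <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  }
  t_all <- apply(combn(8, 4), 2, function(ix)
    tstat(vals[ix], vals[-ix]))
  p_oracle <- mean(abs(t_all) >= abs(tstat(a, b)) - 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  # identical groups: p ~ 1
  same <- subgroup_permutation_ttest(c(1, 2, 3), c(1, 2, 3), 1000, 1)
  expect_gt(same$p, 0.9)
  # large shift hits the resolution floor of the enumeration
  shift <- subgroup_permutation_ttest(c(1, 1.1, 0.9, 1.05),
                                      c(9, 9.1, 8.9, 9.05), 5000, 1)
  expect_equal(shift$p, 2 / 70)  # the labeling and its mirror image
  # zero variance in both groups is flagged, not an error
  degen <- subgroup_permutation_ttest(c(1, 1), c(1, 1), 100, 1)
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
})

test_that("peak value extraction returns each subject's z at the peak", {
  set.seed(26)
  g <- volume_grid(c(5, 5, 5), voxel_size_mm = 3)
  mask <- array(TRUE, c(5, 5, 5))
  eff <- array(0, c(5, 5, 5)); eff[2:3, 2:3, 2:3] <- 2
  ma <- lapply(1:6, function(i) rnorm(125) + as.vector(eff))
  mb <- lapply(1:6, function(i) rnorm(125))
  ci <- permutation_cluster_inference(ma, mb, NULL, mask, g,
                                      inference_config(n_permutations = 100,
                                                       rng_seed = 4))
  expect_gte(nrow(ci$clusters), 1)
  pv <- extract_peak_values(c(ma, mb), ci, cluster = 1)
  expect_equal(nrow(pv), 12)
  vox <- ci$cluster_voxels[[1]]
  pk <- vox[which.max(abs(ci$t_map[vox]))]
  expect_equal(pv$value, vapply(c(ma, mb), function(m) m[pk], numeric(1)),
               ignore_attr = TRUE)
})
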