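test_that("fingerprints match a brute-force correlation oracle", {
  # hand-built series: 2 ROI voxels x 3 target voxels, length 5
  roi <- rbind(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
  tgt <- rbind(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1), c(1, 3, 2, 5, 4))
  fp <- compute_fingerprints(roi, tgt)
  for (i in 1:2) for (j in 1:3)
    expect_equal(fp$values[i, j], pearson_oracle(roi[i, ], tgt[j, ]),
                 tolerance = 1e-12)
  expect_equal(fp$values[1, 1], 1)       # identical series
  expect_equal(fp$values[1, 2], -1)      # reversed series
})

test_that("fingerprints of independent noise have the expected spread", {
  set.seed(10)
  roi <- matrix(rnorm(10 * 180), 10, 180)
  tgt <- matrix(rnorm(100 * 180), 100, 180)
  fp <- compute_fingerprints(roi, tgt)
  expect_lt(mean(abs(fp$values)), 0.1)
  expect_equal(sd(fp$values), 1 / sqrt(179), tolerance = 0.15)
})

test_that("zero-variance series are dropped with a record, not silently", {
  roi <- rbind(rnorm(20), rep(1, 20))
  tgt <- rbind(rnorm(20), rnorm(20))
  expect_warning(fp <- compute_fingerprints(roi, tgt), "zero-variance")
  expect_equal(fp$dropped_roi, 2)
  expect_equal(nrow(fp$values), 1)
})

test_that("second-order matrix is symmetric, unit diagonal, block structured", {
  set.seed(11)
  # two orthogonal row blocks
  base1 <- rnorm(50); base2 <- rnorm(50)
  fp <- rbind(t(replicate(4, base1 + rnorm(50, 0, 0.01))),
              t(replicate(4, base2 + rnorm(50, 0, 0.01))))
  so <- second_order(fp)
  expect_equal(so$values, t(so$values))
  expect_equal(diag(so$values), rep(1, 8))
  within <- c(so$values[1:4, 1:4][upper.tri(diag(4))],
              so$values[5:8, 5:8][upper.tri(diag(4))])
  between <- as.vector(so$values[1:4, 5:8])
  expect_gt(min(within), 0.99)
  expect_lt(max(abs(between)), 0.2)
  # identical fingerprint rows correlate at exactly 1
  so2 <- second_order(rbind(base1, base1, base2))
  expect_equal(so2$values[1, 2], 1)
})

test_that("group averaging equals the element-wise mean and checks dims", {
  set.seed(12)
  ms <- lapply(1:3, function(i) {
    m <- matrix(rnorm(36), 6); m <- (m + t(m)) / 2; diag(m) <- 1; m
  })
  avg <- group_average(ms)
  expect_equal(avg$values, (ms[[1]] + ms[[2]] + ms[[3]]) / 3,
               tolerance = 1e-12)
  expect_equal(group_average(ms[1])$values, ms[[1]])
  # M and -M off-diagonals cancel
  m2 <- -ms[[1]]; diag(m2) <- 1
  canc <- group_average(list(ms[[1]], m2))$values
  expect_equal(canc, diag(6), ignore_attr = TRUE)
  expect_error(group_average(list(ms[[1]], matrix(0, 5, 5))), "dimension")
})

test_that("k-means matches exhaustive minimum-inertia 2-partitioning", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    m <- matrix(rnorm(n * n), n); m <- (m + t(m)) / 2; diag(m) <- 1
    fit <- kmeans_parcellate(m, parcellation_config(rng_seed = rep))
    oracle <- brute_force_two_partition(m)
    expect_equal(fit$inertia, oracle$inertia, tolerance = 1e-10)
    expect_equal(ari(fit$labels, oracle$labels), 1)
  }
})

test_that("k-means is deterministic given the seed and separates blocks", {
  set.seed(14)
  so <- matrix(0.02 * rnorm(400), 20)
  so[1:8, 1:8] <- so[1:8, 1:8] + 0.9
  so[9:20, 9:20] <- so[9:20, 9:20] + 0.9
  so <- (so + t(so)) / 2; diag(so) <- 1
  f1 <- kmeans_parcellate(so, parcellation_config(rng_seed = 3))
  f2 <- kmeans_parcellate(so, parcellation_config(rng_seed = 3))
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$inertia, f2$inertia)
  expect_equal(ari(f1$labels, rep(1:2, c(8, 12))), 1)
  # independent route: stats::kmeans with many restarts finds the same
  # minimum inertia
  km <- stats::kmeans(so, 2, nstart = 50)
  expect_equal(f1$inertia, km$tot.withinss, tolerance = 1e-8)
})

test_that("relabeling puts the anterior cluster first regardless of input numbering", {
  g <- volume_grid(c(5, 9, 5), voxel_size_mm = 2)
  coords <- rbind(cbind(2, 7:8, 2), cbind(2, 0:3, 2))
  lab <- structure(list(labels = rep(c(1L, 2L), c(2, 4)), k = 2L,
                        inertia = 0, pruned_voxels = integer(0)),
                   class = "parcel_labeling")
  out <- relabel_by_axis(lab, coords, g)
  expect_equal(out$labels, rep(c(1L, 2L), c(2, 4)))
  expect_equal(out$canonical_names, c("anterior", "posterior"))
  # swap the numbering: canonical result is unchanged
  lab2 <- lab; lab2$labels <- 3L - lab$labels
  out2 <- relabel_by_axis(lab2, coords, g)
  expect_equal(out2$labels, out$labels)
})

test_that("pruning removes exactly the planted satellite", {
  g <- volume_grid(c(30, 30, 6), voxel_size_mm = 2)
  # two big slabs plus a 2-voxel satellite of label 1 inside label 2 land
  main1 <- as.matrix(expand.grid(i = 0:9, j = 0:9, k = 1:2))
  main2 <- as.matrix(expand.grid(i = 15:24, j = 15:24, k = 1:2))
  sat <- rbind(c(20, 20, 4), c(20, 21, 4))
  coords <- rbind(main1, sat, main2)
  labels <- c(rep(1L, nrow(main1)), 1L, 1L, rep(2L, nrow(main2)))
  lab <- structure(list(labels = labels, k = 2L, inertia = 0,
                        pruned_voxels = integer(0)),
                   class = "parcel_labeling")
  out <- prune_isolated(lab, coords, parcellation_config())
  expect_equal(out$pruned_voxels, nrow(main1) + 1:2)
  expect_equal(length(out$labels), nrow(coords) - 2)
  # contiguous labeling is untouched
  lab0 <- structure(list(labels = c(rep(1L, nrow(main1)),
                                    rep(2L, nrow(main2))),
                         k = 2L, inertia = 0, pruned_voxels = integer(0)),
                    class = "parcel_labeling")
  out0 <- prune_isolated(lab0, rbind(main1, main2), parcellation_config())
  expect_equal(out0$pruned_voxels, integer(0))
  # pruning may never empty a cluster
  labE <- structure(list(labels = c(rep(1L, nrow(main1)), 2L), k = 2L,
                         inertia = 0, pruned_voxels = integer(0)),
                    class = "parcel_labeling")
  expect_error(prune_isolated(labE, rbind(main1, c(0, 0, 5)),
                              parcellation_config()), "empty")
})

test_that("label volumes round trip through the voxel mask", {
  st <- generate_phantom(small_phantom_config(rng_seed = 31))
  lab <- parcellate_study(st, "left")
  vol <- labels_to_volume(lab, st$roi_mask_left, st$grid)
  expect_setequal(unique(as.vector(vol)), c(0L, 1L, 2L))
  back <- volume_to_labels(vol, st$roi_mask_left)
  full <- integer(sum(st$roi_mask_left))
  full[lab$kept_voxels] <- lab$labels
  expect_identical(back, full)
  expect_error(labels_to_volume(lab, st$gm_mask, st$grid), "mask has")
})

test_that("permuting voxel order permutes fingerprints and second order identically", {
  set.seed(15)
  roi <- matrix(rnorm(6 * 60), 6, 60)
  tgt <- matrix(rnorm(40 * 60), 40, 60)
  perm <- sample(6)
  fp <- compute_fingerprints(roi, tgt)$values
  fp_p <- compute_fingerprints(roi[perm, ], tgt)$values
  expect_equal(fp_p, fp[perm, ], tolerance = 1e-12)
  so <- second_order(fp)$values
  so_p <- second_order(fp[perm, ])$values
  expect_equal(so_p, so[perm, perm], tolerance = 1e-12)
})

test_that("parcellation recovers planted labels on a strong phantom", {
  st <- generate_phantom(recovery_config(rng_seed = 41, n = 8))
  lab <- parcellate_study(st, "left")
  truth <- truth_labels_for(st, "left")
  expect_gte(ari(lab$labels, truth[lab$kept_voxels]), 0.9)
  # canonical names agree with planted anterior/posterior when recovered
  d <- tidy(lab)
  agree <- mean(d$parcel == truth[lab$kept_voxels])
  expect_gt(max(agree, 1 - agree), 0.95)
})

test_that("the unsmoothed-ROI thread feeds parcellation (wiring contract)", {
  st <- generate_phantom(small_phantom_config(rng_seed = 51,
                                              n_per_group = c(control = 2)))
  run <- st$runs[[1]]
  cleaned <- clean_run(run, st$noise_mask, st$motion[[1]])
  sm <- gaussian_smooth(cleaned, 4)
  roi_sel <- st$roi_mask_left[run$mask]
  roi_clean <- cleaned$data[roi_sel, , drop = FALSE]
  roi_smooth <- sm$data[roi_sel, , drop = FALSE]
  # smoothing changes ROI voxel series, so the thread choice matters...
  expect_gt(max(abs(roi_clean - roi_smooth)), 1e-3)
  # ...and the pipeline's ROI extraction takes the unsmoothed cleaned run
  expect_identical(longaxis:::roi_series_of(cleaned, st$roi_mask_left),
                   roi_clean)
})
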