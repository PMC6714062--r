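test_that("factor scores are the oriented z-scored projection", {
  L <- matrix(0, 8, 3)
  L[1, 1] <- 1; L[2, 2] <- 1; L[3, 3] <- 1
  mod <- factor_model(L, means = 1:8, sds = rep(2, 8))
  raw <- tibble::tibble(viq = 1, piq = 2, rmf = 3, rvdl = 4, cal = 5,
                        rmw = 6, ravlt_tot = 7, ravlt_ret = 8)
  sc <- factor_scores(raw, mod)
  expect_equal(unlist(sc[c("IQ", "VSM", "VM")]), c(IQ = 0, VSM = 0, VM = 0))
  # 2-test hand example: loading column (1,1,0,...)/sqrt(2), unit SDs
  L2 <- matrix(0, 8, 3); L2[1:2, 1] <- 1 / sqrt(2)
  mod2 <- factor_model(L2)
  raw2 <- raw; raw2$viq <- 3; raw2$piq <- 5
  sc2 <- factor_scores(raw2, mod2)
  expect_equal(sc2$IQ, (3 + 5) / sqrt(2))
  # doubling a loading column doubles the factor
  mod3 <- factor_model(2 * L2)
  expect_equal(factor_scores(raw2, mod3)$IQ, 2 * sc2$IQ)
  # orientation flips the contribution of inverted tests
  mod4 <- factor_model(L2, orientations = c(-1, rep(1, 7)))
  expect_equal(factor_scores(raw2, mod4)$IQ, (-3 + 5) / sqrt(2))
})

test_that("subjects with missing tests are excluded with a record", {
  L <- diag(1, 8, 3)
  mod <- factor_model(L)
  raw <- tibble::as_tibble(matrix(rnorm(24), 3, 8,
                                  dimnames = list(NULL, mod$test_names)))
  raw$viq[2] <- NA
  sc <- factor_scores(raw, mod)
  expect_equal(nrow(sc), 2)
  expect_equal(attr(sc, "excluded"), 2)
  expect_error(factor_model(L, sds = c(0, rep(1, 7))), "positive")
})

test_that("ROI-to-ROI connectivity is atanh(r) with boundary errors", {
  set.seed(30)
  t <- seq_len(200)
  a <- sin(0.3 * t) + rnorm(200, 0, 0.2)
  b <- sin(0.3 * t) + rnorm(200, 0, 0.2)
  expect_equal(roi_to_roi_connectivity(a, b), atanh(cor(a, b)))
  expect_error(roi_to_roi_connectivity(a, a), "boundary")
  expect_error(roi_to_roi_connectivity(rep(1, 200), b), "constant")
  # orthogonal sinusoids: z ~ 0
  s1 <- sin(2 * pi * 5 * t / 200); s2 <- cos(2 * pi * 5 * t / 200)
  expect_lt(abs(roi_to_roi_connectivity(s1, s2)), 1e-8)
})

test_that("behavior correlation matches cor.test and flips sign exactly", {
  set.seed(31)
  z <- rnorm(20); s <- 0.6 * z + rnorm(20, 0, 0.5)
  bc <- behavior_correlation(z, s)
  ct <- cor.test(z, s)
  expect_equal(bc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(bc$p, ct$p.value, tolerance = 1e-12)
  expect_equal(bc$df, 18)
  bc_neg <- behavior_correlation(z, -s)
  expect_equal(bc_neg$r, -bc$r, tolerance = 1e-12)
  # perfect agreement
  expect_equal(behavior_correlation(z, z)$r, 1)
  # one-sided option
  bc_g <- behavior_correlation(z, s, alternative = "greater")
  expect_equal(bc_g$p, bc$p / 2, tolerance = 1e-12)
})

test_that("chi-square reproduces the cohort contingency statistics", {
  # sex distribution between the two patient groups
  sex <- matrix(c(17, 6, 7, 16), 2, byrow = TRUE)
  res_sex <- chi_square_test(sex)
  expect_equal(round(res_sex$statistic, 1), 8.7)
  expect_equal(res_sex$df, 1)
  expect_equal(res_sex$n, 46)
  expect_lt(res_sex$p, 0.005)
  # presence of mesial temporal sclerosis
  mts <- matrix(c(15, 8, 13, 10), 2, byrow = TRUE)
  expect_equal(round(chi_square_test(mts)$statistic, 2), 0.37)
  # presence of other lesions
  les <- matrix(c(3, 20, 1, 22), 2, byrow = TRUE)
  expect_equal(round(chi_square_test(les)$statistic, 1), 1.1)
})

test_that("chi-square equals the textbook sum((O-E)^2/E) on random tables", {
  set.seed(32)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 10) + 1, 2, 3)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    oracle <- sum((tab - E)^2 / E)
    res <- chi_square_test(tab)
    expect_equal(res$statistic, oracle, tolerance = 1e-12)
    expect_equal(res$df, 2)
  }
  # identical rows are exactly independent
  expect_equal(chi_square_test(rbind(c(5, 10), c(5, 10)))$statistic, 0)
  expect_error(chi_square_test(rbind(c(0, 0), c(5, 10))), "marginal")
})

test_that("Fisher exact matches hypergeometric enumeration on 2x2 tables", {
  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  # oracle: enumerate all tables with the same margins
  r1 <- 10; c1 <- 12; n <- 24
  probs <- vapply(max(0, c1 - (n - r1)):min(r1, c1), function(a)
    dhyper(a, r1, n - r1, c1), numeric(1))
  p_obs <- dhyper(1, r1, n - r1, c1)
  oracle <- sum(probs[probs <= p_obs + 1e-12])
  expect_equal(fisher_exact_test(tab), oracle, tolerance = 1e-10)
  # zero row degenerates to p = 1
  expect_equal(fisher_exact_test(rbind(c(0, 0), c(3, 4))), 1)
  # 2x3 language-dominance style table returns a valid p
  lang <- rbind(c(0, 23, 0), c(1, 20, 2))
  p <- fisher_exact_test(lang)
  expect_gt(p, 0); expect_lte(p, 1)
})

test_that("one-way ANOVA matches the hand-computed decomposition", {
  g1 <- c(1, 2, 3); g2 <- c(2, 3, 4); g3 <- c(5, 6, 7)
  res <- oneway_anova(list(g1, g2, g3))
  all_v <- c(g1, g2, g3); gm <- mean(all_v)
  ssb <- 3 * sum((c(mean(g1), mean(g2), mean(g3)) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  expect_equal(res$F, (ssb / 2) / (ssw / 6), tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(2, 6))
  expect_equal(res$p, pf(res$F, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(oneway_anova(list(c(1, 1), c(2, 2))), "undefined")
})

test_that("ANOVA p-values are calibrated under the null", {
  set.seed(33)
  ps <- vapply(1:200, function(i)
    oneway_anova(list(rnorm(8), rnorm(8), rnorm(8)))$p, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("two-sample t matches the pooled formula and is antisymmetric", {
  a <- c(1.2, 2.4, 0.8); b <- c(2.0, 3.1, 2.6, 1.9)
  res <- two_sample_ttest(a, b)
  sp2 <- (2 * var(a) + 3 * var(b)) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 4))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 5)
  expect_equal(two_sample_ttest(b, a)$t, -res$t, tolerance = 1e-12)
  expect_equal(two_sample_ttest(a, a)$t, 0)
  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "undefined|variance")
})

test_that("correlation tables filter subjects and apply Bonferroni", {
  set.seed(34)
  d <- tibble::tibble(z1 = rnorm(30), z2 = rnorm(30),
                      VM = rnorm(30), language = rep(c("left", "right"),
                                                     c(24, 6)))
  d$VM <- d$VM + 0.8 * d$z1
  tbl <- behavior_correlation_table(d, c("z1", "z2"), "VM",
                                    filter = c(language = "left"),
                                    bonferroni_family = 4)
  expect_equal(nrow(tbl), 2)
  expect_true(all(tbl$n == 24))
  expect_equal(tbl$p_bonferroni, pmin(1, tbl$p * 4))
  ref <- behavior_correlation(d$z1[d$language == "left"],
                              d$VM[d$language == "left"])
  expect_equal(tbl$r[tbl$connection == "z1"], ref$r)
})

test_that("phantom brain-behavior coupling is recovered with the planted sign", {
  st <- generate_phantom(small_phantom_config(
    rng_seed = 35, n_per_group = c(control = 20), coupling_sd = 0.15,
    behavior_slope = 1.5, behavior_noise_sd = 0.1, spike_rate = 0))
  z <- vapply(names(st$runs), function(sid) {
    run <- clean_run(st$runs[[sid]], st$noise_mask, st$motion[[sid]])
    ant <- truth_labels_for(st, "left") == "anterior"
    roi <- run$data[st$roi_mask_left[run$mask], , drop = FALSE]
    hub <- colMeans(run$data[st$hub_masks[["mPFC-like"]][run$mask], ,
                             drop = FALSE])
    roi_to_roi_connectivity(colMeans(roi[ant, , drop = FALSE]), hub)
  }, numeric(1))
  bc <- behavior_correlation(z, st$subjects$behavior)
  expect_gt(bc$r, 0)
})
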