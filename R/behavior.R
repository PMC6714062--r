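# Neuropsychological factor scores, ROI-to-ROI connectivity, brain-behavior
# correlation, and the contingency-table / ANOVA statistics used for cohort
# demographics.

#' A factor-score model for an eight-test neuropsychological battery
#'
#' Raw test scores are oriented (so higher always means better), z-scored
#' with supplied standardization constants, and projected onto externally
#' estimated factor loadings. The loadings, means, SDs and orientations are
#' inputs: they come from a normative principal-component analysis that is
#' not re-estimated here.
#'
#' @param loadings 8 x 3 numeric matrix (tests x factors).
#' @param test_names Character(8); defaults to the standard battery order:
#'   verbal IQ, performance IQ, faces recognition (RMF), visual design
#'   learning (RVDL), conditional associative learning trials (CAL), word
#'   recognition (RMW), auditory verbal learning total (RAVLT-tot) and
#'   retention (RAVLT-ret).
#' @param factor_names Character(3), default IQ / VSM / VM.
#' @param means,sds Standardization constants per test (SDs must be > 0).
#' @param orientations +1 or -1 per test; -1 flips tests where a higher raw
#'   score is worse (e.g. trials-to-criterion).
#' @return A list of class `factor_model`.
#' @export
factor_model <- function(loadings,
                         test_names = c("viq", "piq", "rmf", "rvdl", "cal",
                                        "rmw", "ravlt_tot", "ravlt_ret"),
                         factor_names = c("IQ", "VSM", "VM"),
                         means = rep(0, length(test_names)),
                         sds = rep(1, length(test_names)),
                         orientations = rep(1, length(test_names))) {
  loadings <- as.matrix(loadings)
  n_tests <- length(test_names)
  stopifnot(nrow(loadings) == n_tests, ncol(loadings) == length(factor_names),
            all(is.finite(loadings)), length(means) == n_tests,
            length(sds) == n_tests, length(orientations) == n_tests,
            all(orientations %in% c(-1, 1)))
  if (any(sds <= 0)) stop("standardization SDs must be positive",
                          call. = FALSE)
  dimnames(loadings) <- list(test_names, factor_names)
  structure(list(loadings = loadings, test_names = test_names,
                 factor_names = factor_names, means = means, sds = sds,
                 orientations = orientations), class = "factor_model")
}

#' Transform raw test scores into factor scores
#'
#' `scores = ((oriented raw - mean) / sd) %*% loadings`, linear and
#' deterministic. Subjects with any missing test are excluded and recorded
#' in the `excluded` attribute.
#'
#' @param raw Data frame / tibble with one row per subject containing the
#'   model's `test_names` columns (other columns are carried through).
#' @param model A [factor_model()].
#' @return Tibble: input rows (complete cases only) plus one column per
#'   factor.
#' @export
factor_scores <- function(raw, model) {
  raw <- tibble::as_tibble(raw)
  missing_cols <- setdiff(model$test_names, names(raw))
  if (length(missing_cols))
    stop("raw scores lack test column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- as.matrix(raw[model$test_names])
  incomplete <- which(apply(is.na(X), 1, any))
  if (length(incomplete)) {
    raw <- raw[-incomplete, , drop = FALSE]
    X <- X[-incomplete, , drop = FALSE]
  }
  Z <- sweep(sweep(X, 2, model$means), 2, model$sds, `/`)
  Z <- sweep(Z, 2, model$orientations, `*`)
  S <- Z %*% model$loadings
  out <- dplyr::bind_cols(raw, tibble::as_tibble(S))
  attr(out, "excluded") <- incomplete
  out
}

#' Fisher z connectivity between two mean time courses
#'
#' `atanh` of the Pearson correlation between two ROI mean time courses.
#' Constant input or |r| = 1 (e.g. a series against itself) is an error by
#' contract: such pairs carry no usable connectivity estimate.
#'
#' @param series_a,series_b Numeric vectors of equal length.
#' @return Fisher z value.
#' @export
roi_to_roi_connectivity <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b))
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    stop("constant series has no defined correlation", call. = FALSE)
  r <- stats::cor(series_a, series_b)
  if (abs(r) >= 1 - 1e-12)
    stop("|r| = 1 boundary: the two series are (anti)identical",
         call. = FALSE)
  atanh(r)
}

#' Brain-behavior Pearson correlation
#'
#' Correlates per-subject connectivity values with behavior scores;
#' p from the t transform of r with df = n - 2.
#'
#' @param z_values Per-subject connectivity (Fisher z) values.
#' @param scores Per-subject behavior scores.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return Tibble with `r`, `df`, `p`, `n`, `alternative`.
#' @export
behavior_correlation <- function(z_values, scores,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(z_values) == length(scores))
  ok <- is.finite(z_values) & is.finite(scores)
  z_values <- z_values[ok]; scores <- scores[ok]
  n <- length(z_values)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(z_values) == 0 || stats::sd(scores) == 0)
    stop("zero variance in connectivity or behavior values", call. = FALSE)
  r <- stats::cor(z_values, scores)
  df <- n - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tstat), df),
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df))
  tibble::tibble(r = r, df = df, p = p, n = n, alternative = alternative)
}

#' Pearson chi-square test of independence
#'
#' Classic `sum((O - E)^2 / E)` on a two-way count table, without Yates
#' continuity correction (the convention under which the standard cohort
#' contingency statistics reproduce exactly).
#'
#' @param table Matrix of counts (at least 2 x 2).
#' @return Tibble with `statistic`, `df`, `p`, `n`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total in the contingency table", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 n = sum(table))
}

#' Fisher exact test on an r x c count table
#'
#' Exact p by enumeration of tables with fixed margins (Freeman-Halton for
#' tables beyond 2 x 2), two-sided by probability ordering. Degenerate
#' margins (an all-zero row or column) give p = 1.
#'
#' @param table Matrix of counts.
#' @return p-value.
#' @export
fisher_exact_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0))
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  table <- table[keep_r, keep_c, drop = FALSE]
  if (nrow(table) < 2 || ncol(table) < 2) return(1)
  stats::fisher.test(table)$p.value
}

#' One-way analysis of variance
#'
#' Classic between/within mean-square F ratio across k groups.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return Tibble with `F`, `df1`, `df2`, `p`.
#' @export
oneway_anova <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  vals <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, stats::var, numeric(1)) == 0))
    stop("zero within-group variance in every group: F is undefined",
         call. = FALSE)
  ft <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  tibble::tibble(F = unname(ft$statistic),
                 df1 = unname(ft$parameter[1]),
                 df2 = unname(ft$parameter[2]), p = ft$p.value)
}

#' Pooled-variance two-sample t test
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @return Tibble with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(c(a, b)) == 0 ||
      ((stats::var(a) == 0) && (stats::var(b) == 0)))
    stop("zero pooled variance: t is undefined", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}

#' Brain-behavior correlation table over named connections
#'
#' Runs [behavior_correlation()] for every combination of connection column
#' and factor column, optionally restricted to one subject subset (e.g.
#' left-language-dominant individuals), optionally Bonferroni-adjusting a
#' declared family of connections of interest.
#'
#' @param data Tibble with one row per subject: connection z columns,
#'   factor score columns, and any filter column.
#' @param connections Character vector of connection column names.
#' @param factors Character vector of factor column names.
#' @param filter Optional named character, e.g. `c(language = "left")`:
#'   keep rows whose `language` column equals "left".
#' @param alternative Sidedness passed to [behavior_correlation()].
#' @param bonferroni_family Optional integer: family size for a Bonferroni-
#'   adjusted column `p_bonferroni`.
#' @return Tibble (connection, factor, r, df, p, n, alternative, and
#'   optionally p_bonferroni).
#' @export
behavior_correlation_table <- function(data, connections, factors,
                                       filter = NULL,
                                       alternative = "two.sided",
                                       bonferroni_family = NULL) {
  data <- tibble::as_tibble(data)
  if (!is.null(filter)) {
    for (col in names(filter))
      data <- data[!is.na(data[[col]]) & data[[col]] == filter[[col]], ]
  }
  grid_tbl <- expand.grid(connection = connections, factor = factors,
                          stringsAsFactors = FALSE)
  res <- purrr::pmap_dfr(grid_tbl, function(connection, factor) {
    ct <- behavior_correlation(data[[connection]], data[[factor]],
                               alternative = alternative)
    dplyr::bind_cols(tibble::tibble(connection = connection,
                                    factor = factor), ct)
  })
  if (!is.null(bonferroni_family))
    res$p_bonferroni <- pmin(1, res$p * bonferroni_family)
  res
}
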