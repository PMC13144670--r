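#' Pair bootstrap for a heritability estimate
#'
#' Resamples pairs with replacement — by default stratified by analysis
#' group, so the SS and REF groups keep their sizes — and re-runs the full
#' estimation pipeline (variance-component fit, liability conversion,
#' modified Falconer) on every replicate. The standard error is the standard
#' deviation of the replicate estimates. The primary 95% confidence interval
#' is the normal-approximation interval `estimate +/- 1.96 se`; the
#' 2.5/97.5 percentile interval is also returned for audit (an internal
#' calibration study found the percentile interval at a few hundred
#' replicates to undercover slightly, see the methods vignette).
#' Deterministic under a fixed seed and invariant to the row order of the
#' pair table.
#'
#' @param table a pair table (see [as_pair_table()]).
#' @param p Weinberg mixture weight passed to [estimate_phenotype()].
#' @param n_boot number of bootstrap replicates (default 500).
#' @param seed integer seed.
#' @param stratified resample within analysis group (default `TRUE`).
#' @param variant liability-transform variant, see [liability_correlation()].
#' @return an object of class `bootstrap_result`: list with the point
#'   `estimate` (raw scale), `se`, `ci95` (normal approximation),
#'   `ci95_percentile`, `replicates`, failure count, `n_boot`, and `seed`.
#'   Errors if more than 20% of replicates fail.
#' @export
bootstrap_estimate <- function(table, p, n_boot = 500, seed = 1L,
                               stratified = TRUE, variant = "reich") {
  tab <- as_pair_table(table)
  data.table::setorder(tab, pair_id)   # row-order invariance
  point <- estimate_phenotype(tab, p, variant = variant)
  set.seed(seed)
  # resampling pairs with replacement is a multinomial reweighting of the
  # pair-transformed design, so each replicate re-runs the whole
  # model -> liability -> Falconer pipeline from weighted cross-products
  design <- reml_design(tab)
  warm <- pmax(point$vc$gamma, 1e-4)   # warm start at the full-sample optimum
  n <- nrow(tab)
  n_ss <- length(design$yp_ss); n_ref <- length(design$yp_ref)
  reps <- numeric(n_boot)
  msgs <- character(0)
  for (b in seq_len(n_boot)) {
    if (stratified) {
      w_ss <- tabulate(sample.int(n_ss, n_ss, replace = TRUE), n_ss)
      w_ref <- tabulate(sample.int(n_ref, n_ref, replace = TRUE), n_ref)
    } else {
      w <- tabulate(sample.int(n, n, replace = TRUE), n)
      w_ss <- w[design$ss]; w_ref <- w[!design$ss]
    }
    reps[b] <- tryCatch({
      pre <- reml_crossprods(design, w_ss, w_ref)
      K_b <- (sum(w_ss * design$cases_ss) + sum(w_ref * design$cases_ref)) /
             (2 * (sum(w_ss) + sum(w_ref)))
      vc <- fit_vc_from_pre(pre, polish = FALSE, start = warm)
      h2_from_vc(vc, K_b, p, variant = variant)$h2_raw
    }, error = function(e) { msgs <<- c(msgs, conditionMessage(e)); NA_real_ })
  }
  n_fail <- sum(is.na(reps))
  if (n_fail > 0.2 * n_boot)
    stop(n_fail, "/", n_boot, " bootstrap replicates failed; first failures: ",
         paste(utils::head(unique(msgs), 3), collapse = " | "))
  ok <- reps[!is.na(reps)]
  se <- stats::sd(ok)
  structure(list(
    estimate = point$h2_raw, point = point,
    se = se,
    ci95 = point$h2_raw + c(-1, 1) * 1.959963984540054 * se,
    ci95_percentile = unname(stats::quantile(ok, c(0.025, 0.975), type = 7)),
    replicates = reps, n_fail = n_fail, n_boot = n_boot, seed = seed),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Stratified pair bootstrap (%d replicates, %d failed)\n  h2 = %.4f, SE = %.4f, 95%% CI = [%.4f, %.4f]\n",
    x$n_boot, x$n_fail, x$estimate, x$se, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Two-tailed z-test for a heritability estimate
#'
#' `p = 2 (1 - pnorm(|h2 / se|))`. Vectorised; a nonpositive or missing
#' standard error yields `NA` with a warning.
#'
#' @param h2 estimate(s).
#' @param se standard error(s), typically the bootstrap SD.
#' @return p-value(s).
#' @export
z_test <- function(h2, se) {
  bad <- !is.finite(se) | se <= 0
  if (any(bad)) warning("nonpositive or missing SE: p-value set to NA")
  p <- 2 * stats::pnorm(abs(h2 / se), lower.tail = FALSE)
  p[bad] <- NA_real_
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; phenotypes with `q < alpha`
#' (default 0.05) are flagged as having non-zero heritability.
#'
#' @param p_values vector of p-values in \[0, 1\] (NA allowed).
#' @param alpha significance level for the flag.
#' @return a `data.table` with p, q, and `significant`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  q <- stats::p.adjust(p_values, method = "BH")
  data.table::data.table(p = p_values, q = q,
                         significant = !is.na(q) & q < alpha)
}

#' Inverse-variance weighted mean of heritability estimates
#'
#' Weights `w = 1/se^2`; mean `= sum(w h2) / sum(w)` with 95% CI
#' `mean +/- 1.96 / sqrt(sum(w))`.
#'
#' @param estimates vector of estimates.
#' @param ses vector of standard errors, all positive.
#' @param labels optional phenotype labels, used in error messages.
#' @return list with `mean`, `se`, `ci95`, and `n`.
#' @export
ivw_mean <- function(estimates, ses, labels = NULL) {
  stopifnot(length(estimates) == length(ses))
  if (length(estimates) == 0) stop("no estimates to aggregate")
  bad <- !is.finite(ses) | ses <= 0
  if (any(bad)) {
    who <- if (!is.null(labels)) paste(labels[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("nonpositive SE for: ", who)
  }
  w <- 1 / ses^2
  m <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(mean = m, se = se,
       ci95 = c(m - 1.959963984540054 * se, m + 1.959963984540054 * se),
       n = length(estimates))
}

#' Weighted comparison of two sets of heritability estimates
#'
#' Matches two estimate sets on a key (e.g. phecode), optionally excludes
#' phenotypes whose case sex ratios differ substantially between the sets
#' (ratio of sex ratios above `max_sex_ratio_ratio`, as sex imbalance biases
#' the estimator differently in each set), and fits a weighted least-squares
#' regression of `y` on `x` with weights `1 / (se_x^2 + se_y^2)`.
#'
#' @param set_x,set_y data.frames with columns `key`, `h2`, `se`, and
#'   optionally `sex_ratio`.
#' @param max_sex_ratio_ratio comparability threshold on the ratio of case
#'   sex ratios (default 1.5); used only when both sets carry `sex_ratio`.
#' @return an object of class `comparison_fit`: list with `slope`,
#'   `intercept`, their standard errors, `n` matched phenotypes used,
#'   `excluded` keys, and the matched data.
#' @export
compare_estimate_sets <- function(set_x, set_y, max_sex_ratio_ratio = 1.5) {
  sx <- data.table::as.data.table(set_x)
  sy <- data.table::as.data.table(set_y)
  for (nm in list(sx, sy))
    if (!all(c("key", "h2", "se") %in% names(nm)))
      stop("estimate sets need columns key, h2, se")
  m <- merge(sx, sy, by = "key", suffixes = c("_x", "_y"))
  excluded <- character(0)
  if (all(c("sex_ratio_x", "sex_ratio_y") %in% names(m))) {
    rr <- pmax(m$sex_ratio_x / m$sex_ratio_y, m$sex_ratio_y / m$sex_ratio_x)
    drop <- is.finite(rr) & rr > max_sex_ratio_ratio
    excluded <- m$key[drop]
    m <- m[!drop]
  }
  if (nrow(m) < 3)
    stop("fewer than 3 matched phenotypes after exclusions (", nrow(m), ")")
  w <- 1 / (m$se_x^2 + m$se_y^2)
  fit <- stats::lm(h2_y ~ h2_x, data = m, weights = w)
  cf <- summary(fit)$coefficients
  structure(list(
    slope = cf["h2_x", "Estimate"], slope_se = cf["h2_x", "Std. Error"],
    intercept = cf["(Intercept)", "Estimate"],
    intercept_se = cf["(Intercept)", "Std. Error"],
    n = nrow(m), excluded = excluded, matched = m, fit = fit),
    class = "comparison_fit")
}

#' @export
print.comparison_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted comparison fit on %d matched phenotypes (%d excluded)\n  slope = %.4f (SE %.4f), intercept = %.4f (SE %.4f)\n",
    x$n, length(x$excluded), x$slope, x$slope_se, x$intercept, x$intercept_se))
  invisible(x)
}
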