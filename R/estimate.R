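# liability conversion + modified Falconer from fitted components
h2_from_vc <- function(vc, K, p, variant = "reich") {
  r_ss_liab <- liability_correlation(vc$v_ss, K, variant = variant)
  r_os_liab <- liability_correlation(vc$v_os, K, variant = variant)
  h2 <- falconer_modified(r_ss_liab, r_os_liab, p)
  list(h2_raw = h2$h2_raw, h2_report = h2$h2_report,
       r_ss_liab = r_ss_liab, r_os_liab = r_os_liab)
}

#' Point heritability estimate for one phenotype
#'
#' Runs the full estimation pipeline on a single phenotype pair table: the
#' two-variance-component REML fit, observed-scale within-group covariances
#' (`V_SS`, `V_OS`), conversion of each to the liability scale at the table's
#' prevalence, and the modified Falconer estimator `(2/p)(r_SS - r_OS)`.
#'
#' @param table a pair table (see [as_pair_table()]) holding a single
#'   phecode.
#' @param p probability that a same-sex twin pair is monozygotic (Weinberg
#'   mixture weight), typically `mz_probability(...)$p`.
#' @param variant liability-transform variant, see [liability_correlation()].
#' @return an object of class `heritability_estimate`: list with `h2_raw`,
#'   `h2_report` (truncated to \[0, 1\]), the prevalence `K`, all
#'   intermediates (`vc`, `r_ss_obs`, `r_os_obs`, `r_ss_liab`, `r_os_liab`,
#'   `p`), and counts (`n_pairs`, `n_ss`, `n_ref`, `n_cases`).
#' @export
estimate_phenotype <- function(table, p, variant = "reich") {
  tab <- as_pair_table(table)
  phecode <- NA_character_
  if ("phecode" %in% names(tab)) {
    codes <- unique(as.character(tab$phecode))
    if (length(codes) > 1)
      stop("pair table mixes ", length(codes), " phecodes (",
           paste(utils::head(codes, 3), collapse = ", "),
           ", ...); estimate one phecode at a time")
    phecode <- codes
  }
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("phecode ", phecode, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  K <- pair_prevalence(tab)
  vc <- wrap(fit_variance_components(tab))
  if (vc$degenerate)
    stop("phecode ", phecode, ": outcome constant, no variance to decompose")
  robs <- wrap(observed_correlations(vc))
  h2 <- wrap(h2_from_vc(vc, K, p, variant = variant))
  structure(list(
    phecode = phecode,
    h2_raw = h2$h2_raw, h2_report = h2$h2_report,
    K = K, p = p, vc = vc,
    r_ss_obs = robs$r_ss_obs, r_os_obs = robs$r_os_obs,
    r_ss_liab = h2$r_ss_liab, r_os_liab = h2$r_os_liab,
    n_pairs = vc$n_pairs, n_ss = vc$n_ss, n_ref = vc$n_ref,
    n_cases = sum(tab$y1) + sum(tab$y2)),
    class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf(
    "Liability-scale heritability%s\n  h2 = %.4f (reported %.4f), K = %.4f, p(MZ|SS) = %.4f\n  r_SS = %.4f, r_OS = %.4f (liability scale); %d pairs, %d cases\n",
    if (is.na(x$phecode)) "" else paste0(" [phecode ", x$phecode, "]"),
    x$h2_raw, x$h2_report, x$K, x$p, x$r_ss_liab, x$r_os_liab,
    x$n_pairs, x$n_cases))
  invisible(x)
}
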