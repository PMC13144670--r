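#' Validate and normalise a phenotype pair table
#'
#' The canonical analysis unit is one row per pair:
#' `pair_id`, `group` (`"SS"` = same-sex twin pair, `"REF"` = opposite-sex
#' twin pair or, in the sibling design, any non-twin sibling pair),
#' `y1`, `y2` (0/1 outcomes ordered by birth), `sex1`, `sex2` (`"M"`/`"F"`),
#' `byear1`, `byear2` (birth years, used as the age fixed effect).
#'
#' @param x a data.frame or data.table with the columns above (an optional
#'   `phecode` column is carried along).
#' @return a `data.table` with validated columns.
#' @export
as_pair_table <- function(x) {
  if (isTRUE(attr(x, "pair_table_validated"))) return(x)
  dt <- data.table::as.data.table(x)
  need <- c("pair_id", "group", "y1", "y2", "sex1", "sex2", "byear1", "byear2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("pair table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(dt$group %in% c("SS", "REF")))
    stop("group must be 'SS' or 'REF'")
  yy <- unlist(dt[, c("y1", "y2")])
  if (!is.numeric(yy) || anyNA(yy) || any(!is.finite(yy)))
    stop("y1/y2 must be finite numeric outcomes")
  if (!all(unlist(dt[, c("sex1", "sex2")]) %in% c("M", "F")))
    stop("sex1/sex2 must be 'M' or 'F'")
  data.table::setattr(dt, "pair_table_validated", TRUE)
  dt
}

#' Pair prevalence
#'
#' Prevalence `K` of the phenotype among all individuals in a pair table,
#' `K = sum(y) / (2 n_pairs)`.
#'
#' @param table a pair table (see [as_pair_table()]).
#' @return the prevalence.
#' @export
pair_prevalence <- function(table) {
  (sum(table$y1) + sum(table$y2)) / (2 * nrow(table))
}

# Pair-transformed design. Each 2x2 pair covariance sigma^2 * V_j has
# eigenvectors (1,1)/sqrt(2) and (1,-1)/sqrt(2); transforming each pair into
# its sum and difference components diagonalises the model, with eigenvalues
# constant within four strata (SS-sum, SS-diff, REF-sum, REF-diff). All REML
# quantities then reduce to weighted stratum cross-products, so a likelihood
# evaluation is O(1) after one O(n) pass, and a pair bootstrap replicate is
# a multinomial reweighting of the same design.
reml_design <- function(table) {
  tab <- as_pair_table(table)
  n_pairs <- nrow(tab)
  ss <- tab$group == "SS"
  if (!any(ss)) stop("singular design: no SS pairs in table")
  if (!any(!ss)) stop("singular design: no REF pairs in table")

  by_all <- c(tab$byear1, tab$byear2)
  mu <- mean(by_all); sdv <- stats::sd(by_all)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  X1 <- cbind(1, as.numeric(tab$sex1 == "M"), (tab$byear1 - mu) / sdv)
  X2 <- cbind(1, as.numeric(tab$sex2 == "M"), (tab$byear2 - mu) / sdv)
  colnames(X1) <- colnames(X2) <- c("(Intercept)", "sexM", "byear")

  # drop aliased columns; rank detection on the 3x3 Gram matrix
  qrx <- qr(crossprod(X1) + crossprod(X2))
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  X1 <- X1[, keep, drop = FALSE]
  X2 <- X2[, keep, drop = FALSE]

  s2 <- sqrt(2)
  Xp <- (X1 + X2) / s2; Xm <- (X1 - X2) / s2
  yp <- (tab$y1 + tab$y2) / s2; ym <- (tab$y1 - tab$y2) / s2
  list(Xp_ss = Xp[ss, , drop = FALSE], Xm_ss = Xm[ss, , drop = FALSE],
       Xp_ref = Xp[!ss, , drop = FALSE], Xm_ref = Xm[!ss, , drop = FALSE],
       yp_ss = yp[ss], ym_ss = ym[ss], yp_ref = yp[!ss], ym_ref = ym[!ss],
       cases_ss = (tab$y1 + tab$y2)[ss], cases_ref = (tab$y1 + tab$y2)[!ss],
       ss = ss, n_pairs = n_pairs, p = length(keep), terms = colnames(X1))
}

# stratum cross-products, optionally with nonnegative pair weights (bootstrap
# resample counts, split by stratum); NULL weights mean unit weights
reml_crossprods <- function(design, w_ss = NULL, w_ref = NULL) {
  strat <- function(X, y, w) {
    if (is.null(w))
      list(A = crossprod(X), b = crossprod(X, y), c = sum(y^2), n = nrow(X))
    else
      list(A = crossprod(X, X * w), b = crossprod(X, y * w),
           c = sum(y^2 * w), n = sum(w))
  }
  n_ss <- if (is.null(w_ss)) length(design$yp_ss) else sum(w_ss)
  n_ref <- if (is.null(w_ref)) length(design$yp_ref) else sum(w_ref)
  list(
    groups = list(
      ssp  = strat(design$Xp_ss, design$yp_ss, w_ss),
      ssm  = strat(design$Xm_ss, design$ym_ss, w_ss),
      refp = strat(design$Xp_ref, design$yp_ref, w_ref),
      refm = strat(design$Xm_ref, design$ym_ref, w_ref)
    ),
    n_obs = 2 * (n_ss + n_ref), p = design$p, terms = design$terms,
    n_pairs = n_ss + n_ref, n_ss = n_ss, n_ref = n_ref
  )
}

reml_precompute <- function(table) reml_crossprods(reml_design(table))

# -2 * profiled REML log-likelihood (up to an additive constant) at variance
# ratios gamma = (v_pair, v_only_ss) / v_e
reml_neg2loglik <- function(gamma, pre) {
  gp <- gamma[1]; gs <- gamma[2]
  lam_ssp <- 1 + 2 * gp + 2 * gs
  lam_refp <- 1 + gs + 2 * gp
  lam_refm <- 1 + gs
  g <- pre$groups
  M <- g$ssp$A / lam_ssp + g$ssm$A + g$refp$A / lam_refp + g$refm$A / lam_refm
  v <- g$ssp$b / lam_ssp + g$ssm$b + g$refp$b / lam_refp + g$refm$b / lam_refm
  cc <- g$ssp$c / lam_ssp + g$ssm$c + g$refp$c / lam_refp + g$refm$c / lam_refm
  beta <- tryCatch(solve(M, v), error = function(e) NULL)
  if (is.null(beta)) return(.Machine$double.xmax)
  rss <- cc - sum(beta * v)
  if (!is.finite(rss) || rss <= 0) return(.Machine$double.xmax)
  sumlog <- g$ssp$n * log(lam_ssp) + g$refp$n * log(lam_refp) +
            g$refm$n * log(lam_refm)
  ldM <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  (pre$n_obs - pre$p) * log(rss) + sumlog + ldM
}

# moment-based starting values from OLS residual covariances, computed from
# the stratum cross-products: for OLS residuals, the sum of within-pair
# products in a stratum equals (RSS_sum - RSS_diff) / 2 of the transformed
# residuals
reml_start <- function(pre) {
  g <- pre$groups
  A <- g$ssp$A + g$ssm$A + g$refp$A + g$refm$A
  b <- g$ssp$b + g$ssm$b + g$refp$b + g$refm$b
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(c(1e-3, 1e-3))
  rss_g <- function(s) max(s$c - 2 * sum(beta * s$b) +
                           drop(crossprod(beta, s$A %*% beta)), 0)
  c_ss <- (rss_g(g$ssp) - rss_g(g$ssm)) / (2 * max(pre$n_ss, 1))
  c_ref <- (rss_g(g$refp) - rss_g(g$refm)) / (2 * max(pre$n_ref, 1))
  vt <- (rss_g(g$ssp) + rss_g(g$ssm) + rss_g(g$refp) + rss_g(g$refm)) / pre$n_obs
  if (vt <= 0) return(c(1e-3, 1e-3))
  v_pair <- max(c_ref, 0)
  v_only <- max(c_ss - c_ref, 0)
  v_e <- max(vt - v_pair - v_only, 0.05 * vt)
  c(v_pair, v_only) / v_e
}

# core optimisation given precomputed cross-products; polish tightens the
# optimum with a projected finite-difference Newton so independent
# optimisations of the same criterion agree to ~1e-8 on the ratios
fit_vc_from_pre <- function(pre, polish = TRUE, start = NULL) {
  if (is.null(start)) start <- pmax(reml_start(pre), 1e-4)
  fit <- stats::nlminb(start, reml_neg2loglik, pre = pre,
                       lower = c(0, 0), upper = c(1e6, 1e6),
                       control = list(eval.max = 2000, iter.max = 1000,
                                      rel.tol = 1e-14, x.tol = 1e-12))
  gamma <- fit$par
  obj <- fit$objective
  if (!is.finite(obj) || obj >= .Machine$double.xmax)
    stop("REML fit failed: likelihood not finite at optimum")
  if (polish) {
    cand <- polish_reml(gamma, pre)
    cobj <- reml_neg2loglik(cand, pre)
    if (cobj <= obj) { gamma <- cand; obj <- cobj }
  }

  gp <- gamma[1]; gs <- gamma[2]
  lam_ssp <- 1 + 2 * gp + 2 * gs
  lam_refp <- 1 + gs + 2 * gp
  lam_refm <- 1 + gs
  g <- pre$groups
  M <- g$ssp$A / lam_ssp + g$ssm$A + g$refp$A / lam_refp + g$refm$A / lam_refm
  v <- g$ssp$b / lam_ssp + g$ssm$b + g$refp$b / lam_refp + g$refm$b / lam_refm
  cc <- g$ssp$c / lam_ssp + g$ssm$c + g$refp$c / lam_refp + g$refm$c / lam_refm
  beta <- drop(solve(M, v))
  names(beta) <- pre$terms
  sigma2 <- max(cc - sum(beta * v), 0) / (pre$n_obs - pre$p)

  structure(list(
    v_pair = sigma2 * gp, v_only_ss = sigma2 * gs, v_e = sigma2,
    v_ss = sigma2 * (gp + gs), v_os = sigma2 * gp,
    v_total = sigma2 * (1 + gp + gs),
    beta = beta, gamma = gamma, neg2reml = obj,
    n_pairs = pre$n_pairs, n_ss = pre$n_ss, n_ref = pre$n_ref,
    degenerate = FALSE, convergence = fit$convergence),
    class = "variance_components")
}

#' Fit the two-variance-component mixed model on paired binary outcomes
#'
#' Fits `y = X beta + u_pair + u_onlySS + e` by restricted maximum
#' likelihood, where `y` is the 0/1 phenotype of each pair member, the fixed
#' effects are sex and birth year, `u_pair` is a random intercept shared by
#' the two members of every pair, and `u_onlySS` is a random intercept shared
#' only within same-sex twin pairs (independent across individuals of
#' reference-group pairs, so every individual carries the same total
#' variance). The within-pair covariance is therefore
#' `V_pair + V_onlySS` for an SS pair and `V_pair` for a REF pair, with
#' `V_total = V_pair + V_onlySS + V_e`.
#'
#' The outcome is modelled linearly (a linear probability model); the
#' correction from the observed 0/1 scale to the liability scale is applied
#' downstream by [liability_correlation()]. The pair-diagonalised likelihood
#' is evaluated in closed form from stratum cross-products, so the fit cost
#' is one O(n) pass plus a two-parameter bounded quasi-Newton optimisation;
#' components on the nonnegativity boundary are reported as 0.
#'
#' @param table a pair table (see [as_pair_table()]) containing both SS and
#'   REF pairs.
#' @param polish run a finite-difference Newton refinement of the optimum
#'   (default `TRUE`).
#' @return an object of class `variance_components`: list with `v_pair`,
#'   `v_only_ss`, `v_e`, `v_ss`, `v_os`, `v_total`, fixed-effect estimates
#'   `beta`, variance ratios `gamma`, the optimised restricted deviance
#'   `neg2reml`, pair counts, a `degenerate` flag (constant outcome), and
#'   the optimiser `convergence` code.
#' @export
fit_variance_components <- function(table, polish = TRUE) {
  tab <- as_pair_table(table)
  if (stats::var(c(tab$y1, tab$y2)) == 0) {
    return(structure(list(
      v_pair = 0, v_only_ss = 0, v_e = 0, v_ss = 0, v_os = 0, v_total = 0,
      beta = NULL, gamma = c(NA_real_, NA_real_), neg2reml = NA_real_,
      n_pairs = nrow(tab), n_ss = sum(tab$group == "SS"),
      n_ref = sum(tab$group == "REF"), degenerate = TRUE, convergence = 0L),
      class = "variance_components"))
  }
  fit_vc_from_pre(reml_precompute(tab), polish = polish)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# projected-Newton polish with central finite differences
polish_reml <- function(gamma, pre, iters = 12L) {
  h <- 1e-6
  f <- function(x) reml_neg2loglik(pmax(x, 0), pre)
  for (it in seq_len(iters)) {
    g <- numeric(2); H <- matrix(0, 2, 2)
    f0 <- f(gamma)
    hs <- h * pmax(1, abs(gamma))
    for (k in 1:2) {
      ek <- c(0, 0); ek[k] <- hs[k]
      fp <- f(gamma + ek); fm <- f(gamma - ek)
      g[k] <- (fp - fm) / (2 * hs[k])
      H[k, k] <- (fp - 2 * f0 + fm) / hs[k]^2
    }
    e1 <- c(hs[1], 0); e2 <- c(0, hs[2])
    H[1, 2] <- H[2, 1] <-
      (f(gamma + e1 + e2) - f(gamma + e1 - e2) -
       f(gamma - e1 + e2) + f(gamma - e1 - e2)) / (4 * hs[1] * hs[2])
    act <- gamma <= 0 & g > 0    # pinned at the nonnegativity boundary
    if (all(act)) break
    free <- which(!act)
    step <- tryCatch(-solve(H[free, free, drop = FALSE], g[free]),
                     error = function(e) NULL)
    if (is.null(step)) break
    cand <- gamma
    cand[free] <- pmax(gamma[free] + step, 0)
    cand[act] <- 0
    if (f(cand) <= f0) {
      moved <- max(abs(cand - gamma))
      gamma <- cand
      if (moved < 1e-12 * max(1, max(abs(gamma)))) break
    } else break
  }
  pmax(gamma, 0)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Two-component REML fit on paired 0/1 outcomes\n")
  cat(sprintf("  pairs: %d (SS %d, REF %d)\n", x$n_pairs, x$n_ss, x$n_ref))
  if (x$degenerate) {
    cat("  outcome constant: all components 0 (degenerate)\n")
  } else {
    cat(sprintf("  V_pair = %.6g, V_onlySS = %.6g, V_e = %.6g\n",
                x$v_pair, x$v_only_ss, x$v_e))
    cat(sprintf("  V_SS = %.6g, V_OS = %.6g, V_total = %.6g\n",
                x$v_ss, x$v_os, x$v_total))
  }
  invisible(x)
}
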