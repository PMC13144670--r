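# Independent oracles, deliberately written against the model definition
# rather than the package's internals.

# Exact bivariate-normal upper-quadrant probability P(X > T, Y > T) at
# correlation rho, by one-dimensional quadrature.
quadrant_prob <- function(rho, T) {
  if (abs(rho) >= 1) return(pnorm(T, lower.tail = FALSE) * (rho > 0))
  stats::integrate(function(x)
    dnorm(x) * pnorm((rho * x - T) / sqrt(1 - rho^2)),
    lower = T, upper = Inf, rel.tol = 1e-12)$value
}

# -2 restricted log-likelihood of the two-component pair model, computed the
# pedestrian way: per-pair 2x2 covariance blocks, generic inverses and
# determinants, GLS for beta. gamma = (v_pair, v_only_ss) / v_e.
neg2reml_dense <- function(gamma, tab) {
  gp <- gamma[1]; gs <- gamma[2]
  if (gp < 0 || gs < 0) return(.Machine$double.xmax)
  n <- nrow(tab)
  by_all <- c(tab$byear1, tab$byear2)
  mu <- mean(by_all); sdv <- sd(by_all); if (!is.finite(sdv) || sdv == 0) sdv <- 1
  p <- 3
  XtVX <- matrix(0, p, p); XtVy <- numeric(p); ytVy <- 0; logdetV <- 0
  for (j in seq_len(n)) {
    Vj <- if (tab$group[j] == "SS")
      matrix(c(1 + gp + gs, gp + gs, gp + gs, 1 + gp + gs), 2)
    else
      matrix(c(1 + gp + gs, gp, gp, 1 + gp + gs), 2)
    Xj <- rbind(c(1, as.numeric(tab$sex1[j] == "M"), (tab$byear1[j] - mu) / sdv),
                c(1, as.numeric(tab$sex2[j] == "M"), (tab$byear2[j] - mu) / sdv))
    yj <- c(tab$y1[j], tab$y2[j])
    Vinv <- solve(Vj)
    XtVX <- XtVX + t(Xj) %*% Vinv %*% Xj
    XtVy <- XtVy + t(Xj) %*% Vinv %*% yj
    ytVy <- ytVy + drop(t(yj) %*% Vinv %*% yj)
    logdetV <- logdetV + determinant(Vj, logarithm = TRUE)$modulus
  }
  beta <- solve(XtVX, XtVy)
  rss <- ytVy - drop(crossprod(beta, XtVy))
  if (!is.finite(rss) || rss <= 0) return(.Machine$double.xmax)
  (2 * n - p) * log(rss) + as.numeric(logdetV) +
    as.numeric(determinant(XtVX, logarithm = TRUE)$modulus)
}

# brute-force REML optimum: multi-start bounded quasi-Newton on the dense
# criterion, followed by a coordinate-wise golden-section refinement
brute_reml_optimum <- function(tab, starts = list(c(0.02, 0.02),
                                                  c(0.2, 0.1),
                                                  c(0.6, 0.3))) {
  f <- function(g) neg2reml_dense(g, tab)
  best <- NULL
  for (s in starts) {
    o <- optim(s, f, method = "L-BFGS-B", lower = c(0, 0),
               control = list(factr = 10, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  g <- best$par
  for (it in 1:3) {
    for (k in 1:2) {
      lo <- max(g[k] - 0.01 / it^2, 0); hi <- g[k] + 0.01 / it^2
      opt <- optimize(function(x) { gg <- g; gg[k] <- x; f(gg) },
                      c(lo, hi), tol = 1e-10)
      if (opt$objective <= f(g)) g[k] <- opt$minimum
    }
  }
  list(gamma = pmax(g, 0), value = f(g))
}

# step-up Benjamini-Hochberg q-values straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- m / seq_len(m) * p[ord]
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}
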