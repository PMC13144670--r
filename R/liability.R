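#' Liability threshold for a given prevalence
#'
#' Under the liability-threshold model a binary trait with lifetime prevalence
#' `K` corresponds to a standard-normal liability exceeding
#' `T = qnorm(1 - K)`.
#'
#' @param K prevalence in (0, 1).
#' @return the threshold `T`.
#' @export
liability_threshold <- function(K) {
  stopifnot(all(K > 0 & K < 1))
  stats::qnorm(1 - K)
}

#' Mean liability of affected individuals
#'
#' `i = phi(T) / K`, the mean of a standard normal truncated to the affected
#' tail above `T = qnorm(1 - K)`.
#'
#' @inheritParams liability_threshold
#' @return the selection intensity `i`.
#' @export
mean_liability_affected <- function(K) {
  T <- liability_threshold(K)
  stats::dnorm(T) / K
}

#' Convert an observed-scale within-pair covariance to a liability correlation
#'
#' Binary 0/1 outcomes understate the correlation of the latent liabilities.
#' Given the observed-scale covariance `cov_obs` between pair members and the
#' prevalence `K`, the recurrence risk in the co-member of an affected
#' individual is `q_R = K + cov_obs / K`, with group-specific threshold
#' `T_G = qnorm(1 - q_R)`. The liability correlation is then obtained from the
#' Reich--James--Morris threshold-model approximation
#'
#' \deqn{r = \frac{T - T_G \sqrt{1 - (T^2 - T_G^2)(1 - T/i)}}{i + T_G^2 (i - T)}}
#'
#' with `T = qnorm(1 - K)` and `i = dnorm(T)/K`. This transform is strictly
#' increasing in `cov_obs` and maps 0 to 0 for every `K`. `variant =
#' "printed"` selects an alternative algebraic arrangement (square root
#' multiplying the threshold difference, plus sign inside the group-threshold
#' argument) that circulates in the applied literature; it is retained only
#' for audit, as it is not monotone in the required direction and does not
#' recover the generating correlation in simulation.
#'
#' @param cov_obs observed-scale within-pair covariance; must satisfy
#'   `-K^2 < cov_obs < K (1 - K)` so the implied recurrence risk lies in
#'   (0, 1).
#' @param K prevalence in (0, 1).
#' @param variant `"reich"` (default) or `"printed"`.
#' @return the liability-scale correlation.
#' @examples
#' liability_correlation(0, 0.1)      # 0: no covariance, no correlation
#' liability_correlation(0.02, 0.1)
#' @export
liability_correlation <- function(cov_obs, K, variant = c("reich", "printed")) {
  variant <- match.arg(variant)
  stopifnot(length(K) == 1, K > 0, K < 1, length(cov_obs) == 1)
  T <- liability_threshold(K)
  i <- mean_liability_affected(K)
  arg <- if (variant == "reich") 1 - K - cov_obs / K else 1 - K + cov_obs / K
  if (is.na(arg) || arg <= 0 || arg >= 1)
    stop("covariance incompatible with prevalence: implied recurrence risk ",
         "outside (0, 1) (cov_obs = ", format(cov_obs), ", K = ", K, ")")
  Tg <- stats::qnorm(arg)
  disc <- 1 - (T^2 - Tg^2) * (1 - T / i)
  if (disc < 0)
    stop("covariance incompatible with prevalence: negative discriminant in ",
         "liability transform")
  if (variant == "reich") {
    (T - Tg * sqrt(disc)) / (i + Tg^2 * (i - T))
  } else {
    (T - Tg) * sqrt(disc) / (i + Tg^2 * (i - T))
  }
}

#' Observed-scale within-group correlations from fitted variance components
#'
#' `r_SS = (V_pair + V_onlySS) / V_total` and `r_OS = V_pair / V_total`.
#'
#' @param vc a `variance_components` object from [fit_variance_components()],
#'   or any list with elements `v_pair`, `v_only_ss`, `v_e`.
#' @return list with `r_ss_obs` and `r_os_obs`.
#' @export
observed_correlations <- function(vc) {
  v_total <- vc$v_pair + vc$v_only_ss + vc$v_e
  if (!is.finite(v_total) || v_total <= 0)
    stop("total variance is zero: outcome is constant")
  list(r_ss_obs = (vc$v_pair + vc$v_only_ss) / v_total,
       r_os_obs = vc$v_pair / v_total)
}
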