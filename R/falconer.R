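#' Probability that a same-sex twin pair is monozygotic (Weinberg's rule)
#'
#' Under Weinberg's differential rule a dizygotic twin pair is same-sex with
#' probability 1/2, so the monozygotic fraction of all pairs can be estimated
#' from the opposite-sex pair count alone: `p(MZ) = 1 - 2 N_OS / N_all`.
#' Conditioning on being same-sex gives the mixture weight used by the
#' modified Falconer estimator: `p = p(MZ) / p(SS)` with `p(SS) = N_SS / N_all`.
#'
#' @param n_all total number of twin pairs.
#' @param n_ss number of same-sex pairs.
#' @param n_os number of opposite-sex pairs.
#' @return An object of class `mz_probability`: a list with `p` (the
#'   probability that a same-sex pair is monozygotic), `p_mz`, `p_ss`, `p_os`,
#'   and the input counts.
#' @examples
#' mz_probability(100, 75, 25)  # p(MZ) = 0.5, p(SS) = 0.75, p = 2/3
#' @export
mz_probability <- function(n_all, n_ss, n_os) {
  stopifnot(length(n_all) == 1, length(n_ss) == 1, length(n_os) == 1)
  if (n_all <= 0) stop("n_all must be positive")
  if (n_ss < 0 || n_os < 0) stop("pair counts must be nonnegative")
  if (n_ss + n_os != n_all)
    stop("n_ss + n_os must equal n_all (got ", n_ss, " + ", n_os,
         " != ", n_all, ")")
  p_os <- n_os / n_all
  p_mz <- 1 - 2 * p_os
  if (p_mz < 0)
    stop("Weinberg violation: negative MZ fraction (more than half of pairs ",
         "are opposite-sex)")
  p_ss <- n_ss / n_all
  structure(
    list(p = p_mz / p_ss, p_mz = p_mz, p_ss = p_ss, p_os = p_os,
         n_all = n_all, n_ss = n_ss, n_os = n_os),
    class = "mz_probability"
  )
}

#' @export
print.mz_probability <- function(x, ...) {
  cat(sprintf(
    "Weinberg zygosity mixture: p(MZ|SS) = %.4f\n  pairs: %d total, %d same-sex, %d opposite-sex\n  p(MZ) = %.4f, p(SS) = %.4f\n",
    x$p, x$n_all, x$n_ss, x$n_os, x$p_mz, x$p_ss))
  invisible(x)
}

#' Classic Falconer heritability from MZ/DZ correlations
#'
#' `h2 = 2 (r_MZ - r_DZ)`. Returns the raw value together with a copy
#' truncated to `[0, 1]` for reporting.
#'
#' @param r_mz,r_dz liability-scale correlations for monozygotic and dizygotic
#'   pairs, each in `[-1, 1]`.
#' @return list with `h2_raw` and `h2_report` (truncated to `[0, 1]`).
#' @export
falconer_classic <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  raw <- 2 * (r_mz - r_dz)
  list(h2_raw = raw, h2_report = min(max(raw, 0), 1))
}

#' Modified Falconer heritability from same-sex/opposite-sex correlations
#'
#' When zygosity is unknown the same-sex group is an MZ/DZ mixture with MZ
#' weight `p`, giving `h2 = (2 / p) (r_SS - r_OS)`. With `p = 1` this reduces
#' exactly to [falconer_classic()].
#'
#' @param r_ss,r_os liability-scale correlations of the same-sex and of the
#'   reference (opposite-sex, or opposite-sex plus non-twin sibling) group.
#' @param p probability that a same-sex pair is monozygotic, in `(0, 1]`;
#'   typically `mz_probability(...)$p`.
#' @return list with `h2_raw` and `h2_report` (truncated to `[0, 1]`).
#' @export
falconer_modified <- function(r_ss, r_os, p) {
  stopifnot(abs(r_ss) <= 1, abs(r_os) <= 1)
  if (length(p) != 1 || is.na(p) || p <= 0 || p > 1)
    stop("no monozygotic information: p must lie in (0, 1]")
  raw <- (2 / p) * (r_ss - r_os)
  list(h2_raw = raw, h2_report = min(max(raw, 0), 1))
}
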