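#' Specify a simulated phenotype
#'
#' Describes one binary phenotype generated under the liability-threshold
#' model with an additive-genetic / shared-environment / unique-environment
#' decomposition. The latent liability of individual `i` in a pair is
#' `l_i = g_i + c + e_i` with `Var(g) = h2`, `cor(g1, g2) = 1` for
#' monozygotic twins and `0.5` for dizygotic twins and full siblings,
#' `Var(c) = c2_twin` (twin pairs) or `c2_sib` (non-twin sibling pairs)
#' shared within the pair, and independent `e` making the total variance 1.
#' The individual is affected iff `l + sex_effect * 1[male] > qnorm(1 - K)`.
#'
#' @param phecode phenotype identifier (dotted-decimal string, e.g. "345.1").
#' @param h2 true additive-genetic variance fraction in \[0, 1\].
#' @param c2_twin twin-shared environment variance fraction.
#' @param c2_sib sibling-shared environment variance fraction (defaults to
#'   `c2_twin`; must not exceed it).
#' @param prevalence lifetime prevalence `K` in (0, 1).
#' @param sex_effect additive liability shift applied to males (0 = balanced
#'   sexes).
#' @param onset_mean,onset_sd mean and standard deviation (years) of the
#'   log-normal age-at-onset distribution. The defaults describe a
#'   childhood-onset phenotype, matching the follow-up structure of a birth
#'   cohort observed from birth.
#' @return a `phenotype_spec` list.
#' @export
phenotype_spec <- function(phecode, h2, c2_twin = 0, c2_sib = c2_twin,
                           prevalence = 0.1, sex_effect = 0,
                           onset_mean = 8, onset_sd = 4) {
  stopifnot(h2 >= 0, h2 <= 1, c2_twin >= 0, c2_sib >= 0,
            onset_mean > 0, onset_sd > 0)
  if (c2_sib > c2_twin)
    stop("c2_sib must not exceed c2_twin")
  if (h2 + c2_twin > 1 || h2 + c2_sib > 1)
    stop("h2 + c2 must not exceed 1")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  structure(list(phecode = as.character(phecode), h2 = h2,
                 c2_twin = c2_twin, c2_sib = c2_sib,
                 prevalence = prevalence, sex_effect = sex_effect,
                 onset_mean = onset_mean, onset_sd = onset_sd),
            class = "phenotype_spec")
}

#' Parameters of a synthetic registry simulation
#'
#' Each family contributes either a twin pair (with probability
#' `twin_fraction`; monozygotic with probability `p_mz`) or a non-twin
#' sibling pair. Sexes of dizygotic twins and siblings are i.i.d.
#' Bernoulli(1/2) per member (Weinberg's rule, no sex-ratio-at-birth
#' adjustment); monozygotic pairs share one sex draw. Twins share birth date
#' and birthplace; non-twin siblings are born 11 months to 4 years apart.
#' Death and emigration act as independent constant annual hazards from
#' birth, and a diagnosis is recorded only if onset falls on or after the
#' 1st of January of `registry_start_year` and no later than the person's
#' censoring date (death, emigration, or study end) — which is how the
#' generator expresses left truncation of diagnostic information.
#'
#' The defaults emulate a birth cohort followed from birth within the
#' registry era (births 1977-2000, registry opening in 1977, study end 2021)
#' with a twin birth fraction and a monozygotic fraction typical of a
#' European register population.
#'
#' @param n_families number of families (>= 1); each contributes one pair.
#' @param phenotypes a single [phenotype_spec()] or list of them.
#' @param twin_fraction probability a family contributes a twin pair.
#' @param p_mz probability a twin pair is monozygotic.
#' @param registry_start_year diagnoses before the 1st of January of this
#'   year are unobservable.
#' @param study_end_year last calendar year of follow-up.
#' @param birth_year_range integer vector `c(min, max)` for first-born birth
#'   years.
#' @param mortality_rate,emigration_rate constant annual hazards.
#' @param seed integer seed; identical parameters and seed reproduce the
#'   tables byte-for-byte.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_families, phenotypes,
                       twin_fraction = 0.06, p_mz = 0.28,
                       registry_start_year = 1977, study_end_year = 2021,
                       birth_year_range = c(1977, 2000),
                       mortality_rate = 0.001, emigration_rate = 0.001,
                       seed = 1L) {
  stopifnot(n_families >= 1, twin_fraction >= 0, twin_fraction <= 1,
            p_mz >= 0, p_mz <= 1, length(birth_year_range) == 2,
            birth_year_range[1] <= birth_year_range[2],
            mortality_rate >= 0, emigration_rate >= 0)
  if (inherits(phenotypes, "phenotype_spec")) phenotypes <- list(phenotypes)
  stopifnot(length(phenotypes) >= 1,
            all(vapply(phenotypes, inherits, TRUE, "phenotype_spec")))
  structure(list(n_families = as.integer(n_families),
                 twin_fraction = twin_fraction, p_mz = p_mz,
                 phenotypes = phenotypes,
                 registry_start_year = as.integer(registry_start_year),
                 study_end_year = as.integer(study_end_year),
                 birth_year_range = as.integer(birth_year_range),
                 mortality_rate = mortality_rate,
                 emigration_rate = emigration_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a synthetic person/diagnosis registry
#'
#' Generates the person and diagnosis tables consumed by the cohort builder,
#' plus ground-truth tables, under the generative model described in
#' [sim_params()] and [phenotype_spec()].
#'
#' @param params a [sim_params()] object.
#' @return list with `persons` (person_id, sex, birth_date, birthplace,
#'   mother_id, father_id, death_date, emigration_date), `diagnoses`
#'   (person_id, code, code_system = "phecode", date), `truth_pairs`
#'   (pair_id, person_id1, person_id2, zygosity in MZ/DZ/SIB, relationship),
#'   and `truth_phenotypes` (the generating parameters per phecode).
#' @export
simulate_registry <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  nF <- params$n_families
  study_end <- as.Date(sprintf("%d-12-31", params$study_end_year))
  registry_start <- as.Date(sprintf("%d-01-01", params$registry_start_year))

  is_twin <- stats::runif(nF) < params$twin_fraction
  is_mz <- is_twin & (stats::runif(nF) < params$p_mz)

  # sexes: one draw per member; MZ pairs copy member 1
  sex1 <- ifelse(stats::runif(nF) < 0.5, "M", "F")
  sex2 <- ifelse(stats::runif(nF) < 0.5, "M", "F")
  sex2[is_mz] <- sex1[is_mz]

  yr_lo <- params$birth_year_range[1]
  yr_hi <- params$birth_year_range[2]
  byear1 <- sample(yr_lo:yr_hi, nF, replace = TRUE)
  bdate1 <- as.Date(sprintf("%d-01-01", byear1)) + sample.int(365, nF, replace = TRUE) - 1L
  gap_days <- sample(334:1461, nF, replace = TRUE)
  bdate2 <- data.table::fifelse(is_twin, bdate1, bdate1 + gap_days)

  birthplace <- sprintf("BP%03d", sample.int(250, nF, replace = TRUE))

  person_id1 <- sprintf("P%08d", seq_len(nF) * 2L - 1L)
  person_id2 <- sprintf("P%08d", seq_len(nF) * 2L)
  mother_id <- sprintf("M%07d", seq_len(nF))
  father_id <- sprintf("F%07d", seq_len(nF))

  censor_dates <- function(bdate, rate) {
    if (rate <= 0) return(as.Date(rep(NA, length(bdate))))
    t_yr <- stats::rexp(length(bdate), rate = rate)
    d <- bdate + round(365.25 * t_yr)
    d[d > study_end] <- NA
    d
  }
  death1 <- censor_dates(bdate1, params$mortality_rate)
  death2 <- censor_dates(bdate2, params$mortality_rate)
  emig1 <- censor_dates(bdate1, params$emigration_rate)
  emig2 <- censor_dates(bdate2, params$emigration_rate)

  persons <- data.table::data.table(
    person_id = c(person_id1, person_id2),
    sex = c(sex1, sex2),
    birth_date = c(bdate1, bdate2),
    birthplace = c(birthplace, birthplace),
    mother_id = c(mother_id, mother_id),
    father_id = c(father_id, father_id),
    death_date = c(death1, death2),
    emigration_date = c(emig1, emig2)
  )
  data.table::setorder(persons, person_id)

  g_corr <- data.table::fifelse(is_mz, 1, 0.5)
  c2 <- function(ph) data.table::fifelse(is_twin, ph$c2_twin, ph$c2_sib)

  diag_list <- vector("list", length(params$phenotypes))
  for (k in seq_along(params$phenotypes)) {
    ph <- params$phenotypes[[k]]
    z0 <- stats::rnorm(nF); z1 <- stats::rnorm(nF)
    g1 <- z0
    g2 <- g_corr * z0 + sqrt(1 - g_corr^2) * z1
    cshare <- stats::rnorm(nF)
    c2v <- c2(ph)
    e_var <- 1 - ph$h2 - c2v
    l1 <- sqrt(ph$h2) * g1 + sqrt(c2v) * cshare + sqrt(e_var) * stats::rnorm(nF)
    l2 <- sqrt(ph$h2) * g2 + sqrt(c2v) * cshare + sqrt(e_var) * stats::rnorm(nF)
    T <- liability_threshold(ph$prevalence)
    aff1 <- (l1 + ph$sex_effect * (sex1 == "M")) > T
    aff2 <- (l2 + ph$sex_effect * (sex2 == "M")) > T

    sdlog <- sqrt(log(1 + (ph$onset_sd / ph$onset_mean)^2))
    meanlog <- log(ph$onset_mean) - sdlog^2 / 2
    onset1 <- bdate1 + round(365.25 * stats::rlnorm(nF, meanlog, sdlog))
    onset2 <- bdate2 + round(365.25 * stats::rlnorm(nF, meanlog, sdlog))

    cens1 <- pmin(death1, emig1, study_end, na.rm = TRUE)
    cens2 <- pmin(death2, emig2, study_end, na.rm = TRUE)
    obs1 <- aff1 & onset1 >= registry_start & onset1 <= cens1
    obs2 <- aff2 & onset2 >= registry_start & onset2 <= cens2

    diag_list[[k]] <- data.table::data.table(
      person_id = c(person_id1[obs1], person_id2[obs2]),
      code = ph$phecode,
      code_system = "phecode",
      date = c(onset1[obs1], onset2[obs2])
    )
  }
  diagnoses <- data.table::rbindlist(diag_list)
  data.table::setorder(diagnoses, person_id, code, date)

  truth_pairs <- data.table::data.table(
    pair_id = sprintf("FAM%07d", seq_len(nF)),
    person_id1 = person_id1, person_id2 = person_id2,
    zygosity = data.table::fifelse(is_mz, "MZ",
               data.table::fifelse(is_twin, "DZ", "SIB")),
    relationship = data.table::fifelse(is_twin, "twin", "nontwin_sibling")
  )
  truth_phenotypes <- data.table::rbindlist(lapply(params$phenotypes, function(ph)
    data.table::data.table(phecode = ph$phecode, h2_true = ph$h2,
                           c2_twin = ph$c2_twin, c2_sib = ph$c2_sib,
                           prevalence = ph$prevalence,
                           sex_effect = ph$sex_effect)))

  list(persons = persons, diagnoses = diagnoses,
       truth_pairs = truth_pairs, truth_phenotypes = truth_phenotypes)
}

#' Expected liability-scale group correlations under the generative model
#'
#' Closed-form expectations of the same-sex and reference-group liability
#' correlations implied by a [phenotype_spec()] and the family-structure
#' parameters, used as an analytic oracle for the simulator and estimator.
#' For the twin design: `r_OS = 0.5 h2 + c2_twin` and
#' `r_SS = p (h2 + c2_twin) + (1 - p)(0.5 h2 + c2_twin)` where
#' `p = p_mz / (p_mz + (1 - p_mz)/2)` is the Weinberg mixture weight. For
#' the sibling design the reference group mixes opposite-sex twin pairs and
#' all non-twin sibling pairs by their expected proportions.
#'
#' @param params a [sim_params()] object (family-structure parameters).
#' @param phenotype a [phenotype_spec()].
#' @param design `"twin"` or `"sibling"`.
#' @return list with `r_ss`, `r_os`, and the mixture weight `p`.
#' @export
expected_group_correlations <- function(params, phenotype,
                                        design = c("twin", "sibling")) {
  design <- match.arg(design)
  stopifnot(inherits(params, "sim_params"), inherits(phenotype, "phenotype_spec"))
  p_mz <- params$p_mz
  p <- p_mz / (p_mz + (1 - p_mz) / 2)
  r_mz <- phenotype$h2 + phenotype$c2_twin
  r_dz <- 0.5 * phenotype$h2 + phenotype$c2_twin
  r_sib <- 0.5 * phenotype$h2 + phenotype$c2_sib
  r_ss <- p * r_mz + (1 - p) * r_dz
  if (design == "twin") {
    r_os <- r_dz
  } else {
    w_os_twin <- params$twin_fraction * (1 - p_mz) / 2
    w_sib <- 1 - params$twin_fraction
    if (w_os_twin + w_sib <= 0)
      stop("sibling design requires opposite-sex twin or sibling pairs")
    r_os <- (w_os_twin * r_dz + w_sib * r_sib) / (w_os_twin + w_sib)
  }
  list(r_ss = r_ss, r_os = r_os, p = p)
}
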