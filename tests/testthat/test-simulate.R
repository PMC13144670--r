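ph_default <- phenotype_spec("008", h2 = 0.5, c2_twin = 0.2, c2_sib = 0.1,
                             prevalence = 0.1)

test_that("phenotype and simulation parameters are validated", {
  expect_error(phenotype_spec("1", h2 = 0.9, c2_twin = 0.2), "exceed 1")
  expect_error(phenotype_spec("1", h2 = 0.5, c2_twin = 0.1, c2_sib = 0.2),
               "c2_sib")
  expect_error(phenotype_spec("1", h2 = 0.5, prevalence = 0), "prevalence")
  expect_error(phenotype_spec("1", h2 = 0.5, prevalence = 1), "prevalence")
  expect_error(sim_params(0, ph_default), "n_families")
  expect_error(sim_params(10, ph_default, twin_fraction = 1.5), "twin_fraction")
})

test_that("identical seed and parameters reproduce the registry byte-for-byte", {
  pm <- sim_params(2000, ph_default, twin_fraction = 0.5, seed = 99)
  a <- simulate_registry(pm)
  b <- simulate_registry(pm)
  expect_identical(serialize(a$persons, NULL), serialize(b$persons, NULL))
  expect_identical(serialize(a$diagnoses, NULL), serialize(b$diagnoses, NULL))
  c <- simulate_registry(sim_params(2000, ph_default, twin_fraction = 0.5,
                                    seed = 100))
  expect_false(identical(a$persons, c$persons))
})

test_that("simulated family structure obeys Weinberg's rule and pairing rules", {
  pm <- sim_params(40000, ph_default, twin_fraction = 0.5, p_mz = 0.3, seed = 5)
  reg <- simulate_registry(pm)
  per <- reg$persons
  tp <- reg$truth_pairs
  sex <- setNames(per$sex, per$person_id)
  same_sex <- sex[tp$person_id1] == sex[tp$person_id2]

  # MZ pairs always same-sex
  expect_true(all(same_sex[tp$zygosity == "MZ"]))
  # DZ twins same-sex with probability 1/2 (4-sigma binomial band)
  dz <- tp$zygosity == "DZ"
  expect_equal(mean(same_sex[dz]), 0.5, tolerance = 4 * 0.5 / sqrt(sum(dz)))

  # twins share birth date and birthplace; siblings 334-1461 days apart
  bd <- setNames(per$birth_date, per$person_id)
  bp <- setNames(per$birthplace, per$person_id)
  tw <- tp$relationship == "twin"
  expect_true(all(bd[tp$person_id1[tw]] == bd[tp$person_id2[tw]]))
  expect_true(all(bp[tp$person_id1[tw]] == bp[tp$person_id2[tw]]))
  gaps <- as.integer(bd[tp$person_id2[!tw]] - bd[tp$person_id1[!tw]])
  expect_true(all(gaps >= 334 & gaps <= 1461))
})

test_that("case fraction matches the prevalence when censoring is disabled", {
  ph <- phenotype_spec("010", h2 = 0.4, c2_twin = 0.1, prevalence = 0.15,
                       onset_mean = 5, onset_sd = 2)
  pm <- sim_params(30000, ph, twin_fraction = 1, seed = 6,
                   mortality_rate = 0, emigration_rate = 0,
                   birth_year_range = c(1980, 1995))
  reg <- simulate_registry(pm)
  frac <- nrow(reg$diagnoses) / nrow(reg$persons)
  expect_equal(frac, 0.15, tolerance = 4 * sqrt(0.15 * 0.85 / 60000) / 0.15)
})

test_that("independence and perfect-correlation edge cases behave", {
  # h2 = c2 = 0: within-pair outcomes uncorrelated
  ph0 <- phenotype_spec("000", h2 = 0, c2_twin = 0, prevalence = 0.3,
                        onset_mean = 5, onset_sd = 2)
  pm0 <- sim_params(30000, ph0, twin_fraction = 1, seed = 7,
                    mortality_rate = 0, emigration_rate = 0,
                    birth_year_range = c(1980, 1995))
  reg0 <- simulate_registry(pm0)
  tw <- identify_twin_pairs(reg0$persons)
  tab <- build_phenotype_tables(tw, map_codes(reg0$diagnoses))
  expect_lt(abs(cor(tab$y1, tab$y2)), 4 / sqrt(nrow(tab)))

  # h2 = 1, MZ only: liabilities identical, concordance complete
  ph1 <- phenotype_spec("001", h2 = 1, c2_twin = 0, prevalence = 0.5,
                        onset_mean = 5, onset_sd = 2)
  pm1 <- sim_params(5000, ph1, twin_fraction = 1, p_mz = 1, seed = 8,
                    mortality_rate = 0, emigration_rate = 0,
                    birth_year_range = c(1980, 1995))
  reg1 <- simulate_registry(pm1)
  tw1 <- identify_twin_pairs(reg1$persons)
  tab1 <- build_phenotype_tables(tw1, map_codes(reg1$diagnoses))
  expect_true(all(tab1$y1 == tab1$y2))
})

test_that("empirical group correlations match the closed-form expectations", {
  ph <- phenotype_spec("020", h2 = 0.5, c2_twin = 0.2, c2_sib = 0.1,
                       prevalence = 0.1, onset_mean = 5, onset_sd = 2)
  pm <- sim_params(150000, ph, twin_fraction = 1, p_mz = 0.28, seed = 9,
                   mortality_rate = 0, emigration_rate = 0,
                   birth_year_range = c(1980, 1995))
  reg <- simulate_registry(pm)
  tw <- identify_twin_pairs(reg$persons)
  tab <- build_phenotype_tables(tw, map_codes(reg$diagnoses))
  K <- pair_prevalence(tab)
  ss <- tab[group == "SS"]; rf <- tab[group == "REF"]
  r_ss <- liability_correlation(cov(ss$y1, ss$y2), K)
  r_os <- liability_correlation(cov(rf$y1, rf$y2), K)
  exp_r <- expected_group_correlations(pm, ph, "twin")
  expect_equal(r_ss, exp_r$r_ss, tolerance = 0.05 / exp_r$r_ss)
  expect_equal(r_os, exp_r$r_os, tolerance = 0.05 / exp_r$r_os)
})

test_that("raising h2 raises the same-sex/opposite-sex correlation gap", {
  gap <- function(h2, seed) {
    ph <- phenotype_spec("030", h2 = h2, c2_twin = 0.15, prevalence = 0.2,
                         onset_mean = 5, onset_sd = 2)
    pm <- sim_params(60000, ph, twin_fraction = 1, p_mz = 0.3, seed = seed,
                     mortality_rate = 0, emigration_rate = 0,
                     birth_year_range = c(1980, 1995))
    reg <- simulate_registry(pm)
    tw <- identify_twin_pairs(reg$persons)
    tab <- build_phenotype_tables(tw, map_codes(reg$diagnoses))
    ss <- tab[group == "SS"]; rf <- tab[group == "REF"]
    cov(ss$y1, ss$y2) - cov(rf$y1, rf$y2)
  }
  expect_lt(gap(0.2, 10), gap(0.6, 10))
})

test_that("expected correlations close the Falconer algebra exactly", {
  # p_mz = 1/3 gives mixture weight p = 0.5
  ph <- phenotype_spec("040", h2 = 0.4, c2_twin = 0.2, prevalence = 0.1)
  pm <- sim_params(10, ph, twin_fraction = 1, p_mz = 1 / 3)
  e <- expected_group_correlations(pm, ph, "twin")
  expect_equal(e$p, 0.5)
  expect_equal(e$r_ss, 0.5 * 0.6 + 0.5 * 0.4)
  expect_equal(e$r_os, 0.4)
  # c2 cancels: the estimator recovers h2 exactly in expectation
  expect_equal(falconer_modified(e$r_ss, e$r_os, e$p)$h2_raw, 0.4)

  # h2 = 0: both groups correlate only through shared environment
  ph0 <- phenotype_spec("041", h2 = 0, c2_twin = 0.3, prevalence = 0.1)
  e0 <- expected_group_correlations(pm, ph0, "twin")
  expect_equal(e0$r_ss, 0.3)
  expect_equal(e0$r_os, 0.3)

  # sibling design with c2_sib < c2_twin inflates the estimand by
  # (2/p) * w_sib * (c2_twin - c2_sib)
  ph2 <- phenotype_spec("042", h2 = 0.4, c2_twin = 0.2, c2_sib = 0.05,
                        prevalence = 0.1)
  pm2 <- sim_params(10, ph2, twin_fraction = 0.3, p_mz = 1 / 3)
  e2 <- expected_group_correlations(pm2, ph2, "sibling")
  w_os <- 0.3 * (2 / 3) / 2; w_sib <- 0.7
  infl <- (2 / e2$p) * (w_sib / (w_os + w_sib)) * (0.2 - 0.05)
  expect_equal(falconer_modified(e2$r_ss, e2$r_os, e2$p)$h2_raw, 0.4 + infl,
               tolerance = 1e-12)
})
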