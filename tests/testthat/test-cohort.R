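twin_family <- function(id1 = "A", id2 = "B", birth1 = "2000-05-01",
                        birth2 = "2000-05-01", place1 = "X", place2 = "X",
                        mother = "M1", father = "F1",
                        sex1 = "M", sex2 = "F") {
  persons_table(
    person_row(id1, sex1, birth1, place1, mother, father),
    person_row(id2, sex2, birth2, place2, mother, father))
}

test_that("twin identification follows the 1-day/same-birthplace/first-pair rules", {
  expect_equal(nrow(identify_twin_pairs(twin_family())), 1)
  # one day apart still counts; two days does not
  expect_equal(nrow(identify_twin_pairs(
    twin_family(birth2 = "2000-05-02"))), 1)
  expect_equal(nrow(identify_twin_pairs(
    twin_family(birth2 = "2000-05-03"))), 0)
  # birthplaces must match
  expect_equal(nrow(identify_twin_pairs(twin_family(place2 = "Y"))), 0)
  # different fathers: not a pair
  p <- twin_family(); p$father_id <- c("F1", "F2")
  expect_equal(nrow(identify_twin_pairs(p)), 0)

  # two twin pairs of one couple: only the earlier pair is kept
  p2 <- rbind(twin_family("A", "B", "2000-05-01", "2000-05-01"),
              twin_family("C", "D", "2003-02-01", "2003-02-01"))
  tw <- identify_twin_pairs(p2)
  expect_equal(nrow(tw), 1)
  expect_setequal(c(tw$person_id1, tw$person_id2), c("A", "B"))

  # born before 1955: outside the registry window
  expect_equal(nrow(identify_twin_pairs(
    twin_family(birth1 = "1950-01-01", birth2 = "1950-01-01"))), 0)

  expect_error(identify_twin_pairs(rbind(twin_family(), twin_family())),
               "duplicate")
})

test_that("twin analysis group reflects sex composition", {
  tw <- identify_twin_pairs(twin_family(sex1 = "M", sex2 = "M"))
  expect_equal(tw$analysis_group, "SS")
  tw2 <- identify_twin_pairs(twin_family(sex1 = "M", sex2 = "F"))
  expect_equal(tw2$analysis_group, "REF")
})

test_that("sibling identification picks the closest gap within 11 months-4 years", {
  p <- persons_table(
    person_row("A", birth = "2000-01-01"),
    person_row("B", birth = "2002-01-01"),
    person_row("C", birth = "2005-01-01"))
  sib <- identify_sibling_pairs(p)
  expect_equal(nrow(sib), 1)
  expect_setequal(c(sib$person_id1, sib$person_id2), c("A", "B"))
  expect_equal(sib$analysis_group, "REF")

  # 6 years apart: no pair; 10 months apart: no pair
  expect_equal(nrow(identify_sibling_pairs(persons_table(
    person_row("A", birth = "2000-01-01"),
    person_row("B", birth = "2006-01-01")))), 0)
  expect_equal(nrow(identify_sibling_pairs(persons_table(
    person_row("A", birth = "2000-01-01"),
    person_row("B", birth = "2000-11-01")))), 0)

  # twins are never re-used as non-twin siblings
  fam <- persons_table(
    person_row("A", birth = "2000-01-01"),
    person_row("B", birth = "2000-01-01"),
    person_row("C", birth = "2002-01-01"),
    person_row("D", birth = "2004-06-01"))
  tw <- identify_twin_pairs(fam)
  sib <- identify_sibling_pairs(fam, twin_pairs = tw)
  expect_setequal(c(sib$person_id1, sib$person_id2), c("C", "D"))
  expect_equal(nrow(sibling_cohort(tw, sib)), nrow(tw) + nrow(sib))
})

test_that("birth-cohort restriction applies the alive-in-1977 and birth-window rules", {
  p <- persons_table(
    person_row("A", birth = "1960-03-01", death = "1976-01-01"),
    person_row("B", birth = "1960-03-01"),
    person_row("C", birth = "1980-01-01"), person_row("D", birth = "1980-01-01"),
    person_row("E", birth = "1960-03-01", mother = "M2", father = "F2"),
    person_row("G", birth = "1960-03-01", mother = "M2", father = "F2"))
  pairs <- identify_twin_pairs(rbind(
    p[1:2], p[3:4][, `:=`(mother_id = "M3", father_id = "F3")], p[5:6]))
  expect_equal(nrow(pairs), 3)
  # member died 1976: excluded from the 1955 cohort
  r55 <- restrict_birth_cohort(pairs, p, "1955")
  expect_false(any(grepl("A", r55$pair_id)))
  expect_true(any(grepl("E", r55$pair_id)))   # born 1960, alive 1977
  expect_true(any(grepl("C", r55$pair_id)))   # born 1980: in both cohorts
  r77 <- restrict_birth_cohort(pairs, p, "1977")
  expect_equal(nrow(r77), 1)
  expect_true(grepl("C", r77$pair_id))
  expect_error(restrict_birth_cohort(pairs, p, "1960"))
})

test_that("phecode hierarchy closure and two-step code mapping", {
  expect_equal(phecode_ancestors("345.12"), c("345.1", "345"))
  expect_equal(phecode_ancestors("345"), character(0))

  ev <- data.table::data.table(
    person_id = "A", code = "345.12", code_system = "phecode",
    date = as.Date("2010-01-01"))
  mapped <- map_codes(ev)
  expect_setequal(mapped$phecode, c("345.12", "345.1", "345"))

  # ICD-8 -> ICD-10 -> phecode composition
  i8 <- data.table::data.table(icd8 = "345.09", icd10 = "G40.9")
  i10 <- data.table::data.table(icd10 = "G40.9", phecode = "345.1")
  ev8 <- data.table::data.table(
    person_id = "A", code = "345.09", code_system = "ICD-8",
    date = as.Date("1990-01-01"))
  m8 <- map_codes(ev8, i8, i10)
  expect_setequal(m8$phecode, c("345.1", "345"))

  # unmapped ICD-10 code: zero events, one warning
  ev10 <- data.table::data.table(
    person_id = "A", code = "Z99.9", code_system = "ICD-10",
    date = as.Date("2010-01-01"))
  expect_warning(m10 <- map_codes(ev10, i8, i10), "unmapped")
  expect_equal(nrow(m10), 0)

  expect_error(map_codes(data.table::data.table(
    person_id = "A", code = "x", code_system = "ICD-9",
    date = as.Date("2010-01-01"))), "unknown code system")
})

test_that("malformed map files are rejected with a line number", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("icd10,phecode", "G40.9,345.1", "E10,", "E11,250.1"), f)
  expect_error(read_code_map(f), "line 3")
  writeLines(c("a,b,c", "1,2,3"), f)
  expect_error(read_code_map(f), "2 columns")
})

test_that("phenotype tables honour follow-up windows and censoring", {
  p <- twin_family()
  p$emigration_date[2] <- as.Date("2010-06-01")
  tw <- identify_twin_pairs(p)
  ev_in <- data.table::data.table(person_id = c("A", "B"), phecode = "008",
                                  date = as.Date("2009-01-01"))
  tab <- build_phenotype_tables(tw, ev_in)
  expect_equal(tab$y1 + tab$y2, 2)  # both inside follow-up: concordant

  # event after the pair's follow-up end (co-twin emigrated): y = 0
  ev_late <- data.table::data.table(person_id = "A", phecode = "008",
                                    date = as.Date("2012-01-01"))
  tab2 <- build_phenotype_tables(tw, ev_late)
  expect_equal(nrow(tab2), 0)  # no observable event at all

  # event before registry start is unobservable
  ev_early <- data.table::data.table(person_id = "A", phecode = "008",
                                     date = as.Date("1976-01-01"))
  expect_equal(nrow(build_phenotype_tables(tw, ev_early)), 0)

  # event for an unknown person: warn and drop
  ev_unknown <- data.table::data.table(person_id = c("A", "ZZ"),
                                       phecode = "008",
                                       date = as.Date("2009-01-01"))
  expect_warning(tab3 <- build_phenotype_tables(tw, ev_unknown), "outside")
  expect_equal(sum(tab3$y1 + tab3$y2), 1)
})

test_that("onset classification uses the 10% by age 18 boundary inclusively", {
  mk <- function(n_early, n_late) {
    per <- persons_table(person_row(sprintf("P%03d", 1:(n_early + n_late)),
                                    birth = "2000-01-01"))
    ev <- data.table::data.table(
      person_id = sprintf("P%03d", 1:(n_early + n_late)), phecode = "100",
      date = as.Date("2000-01-01") +
        round(365.25 * c(rep(10, n_early), rep(40, n_late))))
    classify_onset(ev, per)
  }
  expect_equal(mk(100, 0)$onset_class, "early")
  expect_equal(mk(0, 100)$onset_class, "late")
  expect_equal(mk(9, 91)$onset_class, "late")    # 9% just below threshold
  expect_equal(mk(10, 90)$onset_class, "early")  # exactly 10% counts
})

test_that("phecode filters apply in order and propagate sex-ratio exclusions", {
  mk_tab <- function(code, n, n_conc_ss, n_conc_ref, n_f, n_m) {
    # concordant pairs first, then discordant female/male singleton cases
    y_ss <- rbind(matrix(1L, n_conc_ss, 2), matrix(0L, n - n_conc_ss, 2))
    y_ref <- rbind(matrix(1L, n_conc_ref, 2), matrix(0L, n - n_conc_ref, 2))
    tab <- toy_pair_table(y_ss, y_ref)
    tab$phecode <- code
    extra_f <- min(n_f, n - n_conc_ss)
    tab[tab$group == "SS", "sex1"] <- "F"; tab[tab$group == "SS", "sex2"] <- "F"
    if (extra_f > 0)
      tab[which(tab$group == "SS")[n_conc_ss + seq_len(extra_f)], "y1"] <- 1L
    if (n_m > 0)
      tab[which(tab$group == "REF")[n_conc_ref + seq_len(n_m)], "y1"] <- 1L
    tab
  }
  cfg <- filter_config(min_prevalence = 0.005, min_cases = 5,
                       min_concordant_pairs = 5, max_sex_ratio = 5)

  # rare phenotype: excluded for prevalence
  rare <- mk_tab("100", 1000, 1, 1, 0, 0)
  f1 <- filter_phecodes(rare, cfg, twin_cohort = FALSE)
  expect_equal(f1$exclusions$reason, "prevalence")

  # 4 concordant SS pairs: below the 5-pair floor
  conc <- mk_tab("200", 200, 4, 6, 10, 10)
  f2 <- filter_phecodes(conc, cfg, twin_cohort = FALSE)
  expect_equal(f2$exclusions[phecode == "200", reason], "concordant_pairs")

  # sex ratio 6: excluded, and the parent phecode goes with it
  imb <- rbind(mk_tab("751.11", 300, 6, 6, 48, 0),
               mk_tab("751.1", 300, 6, 6, 20, 21))
  # 751.11: concordant SS pairs are all-female too -> 60 F vs 12 M cases
  f3 <- filter_phecodes(imb, cfg, twin_cohort = FALSE)
  expect_equal(f3$exclusions[phecode == "751.11", reason], "sex_ratio")
  expect_equal(f3$exclusions[phecode == "751.1", reason],
               "sex_ratio_descendant")

  # eligible and excluded partition the phecode universe
  all_tabs <- rbind(rare, conc, imb)
  f4 <- filter_phecodes(all_tabs, cfg, twin_cohort = FALSE)
  expect_setequal(c(f4$eligible, f4$exclusions$phecode),
                  unique(all_tabs$phecode))

  # the 400-case rule only binds twin-cohort runs
  small <- mk_tab("300", 2000, 40, 40, 50, 50)
  f5t <- filter_phecodes(small, filter_config(min_cases = 400), twin_cohort = TRUE)
  expect_equal(f5t$exclusions[phecode == "300", reason], "min_cases")
  f5s <- filter_phecodes(small, filter_config(min_cases = 400), twin_cohort = FALSE)
  expect_true("300" %in% f5s$eligible)
})

test_that("pairing is exclusive on simulated families", {
  reg <- simulate_registry(sim_params(
    3000, phenotype_spec("008", 0.5, 0.2, prevalence = 0.2),
    twin_fraction = 0.4, seed = 12))
  tw <- identify_twin_pairs(reg$persons)
  sib <- identify_sibling_pairs(reg$persons, twin_pairs = tw)
  ids_tw <- c(tw$person_id1, tw$person_id2)
  ids_sib <- c(sib$person_id1, sib$person_id2)
  expect_equal(anyDuplicated(ids_tw), 0)
  expect_equal(anyDuplicated(ids_sib), 0)
  expect_length(intersect(ids_tw, ids_sib), 0)
  # one pair per parent couple in each relationship class
  expect_equal(anyDuplicated(tw$pair_id), 0)
})
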