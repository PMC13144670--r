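#' @import data.table
NULL

REGISTRY_BASE_DATE <- as.Date("1955-01-01")

validate_persons <- function(persons) {
  dt <- data.table::as.data.table(persons)
  need <- c("person_id", "sex", "birth_date", "birthplace",
            "mother_id", "father_id")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("person table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(dt$person_id))
    stop("duplicate person ids in person table")
  if (!"death_date" %in% names(dt)) dt[, death_date := as.Date(NA)]
  if (!"emigration_date" %in% names(dt)) dt[, emigration_date := as.Date(NA)]
  dt[, birth_date := as.Date(birth_date)]
  dt[, death_date := as.Date(death_date)]
  dt[, emigration_date := as.Date(emigration_date)]
  dt
}

# assemble PairRecord rows from two person-row tables (member order fixed by
# birth date, then person id)
make_pair_records <- function(p1, p2, relationship, study_end) {
  swap <- p2$birth_date < p1$birth_date |
    (p2$birth_date == p1$birth_date & p2$person_id < p1$person_id)
  a <- data.table::copy(p1); b <- data.table::copy(p2)
  for (col in names(a)) {
    tmp <- a[[col]][swap]
    data.table::set(a, which(swap), col, b[[col]][swap])
    data.table::set(b, which(swap), col, tmp)
  }
  followup_end <- pmin(a$death_date, a$emigration_date,
                       b$death_date, b$emigration_date,
                       study_end, na.rm = TRUE)
  data.table::data.table(
    pair_id = paste(a$person_id, b$person_id, sep = "_"),
    person_id1 = a$person_id, person_id2 = b$person_id,
    relationship = relationship,
    analysis_group = if (relationship == "twin")
      data.table::fifelse(a$sex == b$sex, "SS", "REF") else "REF",
    sex1 = a$sex, sex2 = b$sex,
    birth_date1 = a$birth_date, birth_date2 = b$birth_date,
    byear1 = as.integer(format(a$birth_date, "%Y")),
    byear2 = as.integer(format(b$birth_date, "%Y")),
    age_gap = as.numeric(b$birth_date - a$birth_date) / 365.25,
    followup_end = followup_end
  )
}

#' Identify twin pairs from person records
#'
#' A twin pair is two children of the same mother and father with birth dates
#' at most one calendar day apart and identical places of birth, born on or
#' after the 1st of January 1955. At most one twin pair is kept per parent
#' couple: the earliest-born eligible pair. Same-sex pairs get
#' `analysis_group = "SS"`, opposite-sex pairs `"REF"`.
#'
#' @param persons person table with columns person_id, sex, birth_date,
#'   birthplace, mother_id, father_id, and optional death_date /
#'   emigration_date.
#' @param study_end end of follow-up (Date); follow-up for a pair ends at the
#'   first member's death or emigration, or at `study_end`.
#' @return a `data.table` of pair records (see [as_pair_table()] for the
#'   analysis columns; also carries birth dates, age gap and follow-up end).
#' @export
identify_twin_pairs <- function(persons, study_end = as.Date("2021-12-31")) {
  dt <- validate_persons(persons)
  dt <- dt[!is.na(mother_id) & !is.na(father_id)]
  data.table::setorder(dt, mother_id, father_id, birth_date, person_id)
  dt[, fam__ := .GRP, by = .(mother_id, father_id)]
  nxt <- dt[, data.table::shift(.SD, -1),
            .SDcols = c("person_id", "birth_date", "birthplace"), by = fam__]
  data.table::setnames(nxt, c("fam__", "n_id", "n_bd", "n_bp"))
  cand_idx <- which(!is.na(nxt$n_id) &
                    abs(as.integer(nxt$n_bd - dt$birth_date)) <= 1L &
                    dt$birthplace == nxt$n_bp &
                    dt$birth_date >= REGISTRY_BASE_DATE)
  if (!length(cand_idx)) return(make_pair_records(dt[0], dt[0], "twin", study_end))
  # earliest eligible pair per parent couple
  first <- cand_idx[!duplicated(dt$fam__[cand_idx])]
  p1 <- dt[first]
  p2 <- dt[data.table::chmatch(nxt$n_id[first], dt$person_id)]
  make_pair_records(p1, p2, "twin", study_end)
}

#' Identify non-twin sibling pairs from person records
#'
#' A non-twin sibling pair is two children of the same mother and father born
#' between 11 months (334 days) and 4 years (1461 days) apart. When a parent
#' couple has more than two eligible children, only the pair born closest
#' together is kept (ties broken by earliest first-born birth date, then
#' lexicographic person id). Persons already belonging to a twin pair are
#' never re-used as non-twin siblings. All non-twin pairs get
#' `analysis_group = "REF"` regardless of sex, since full siblings are as
#' genetically similar as dizygotic twins.
#'
#' @inheritParams identify_twin_pairs
#' @param twin_pairs optionally, the output of [identify_twin_pairs()] on the
#'   same persons; its members are excluded from sibling pairing.
#' @return a `data.table` of pair records.
#' @export
identify_sibling_pairs <- function(persons, twin_pairs = NULL,
                                   study_end = as.Date("2021-12-31")) {
  dt <- validate_persons(persons)
  dt <- dt[!is.na(mother_id) & !is.na(father_id)]
  if (!is.null(twin_pairs) && nrow(twin_pairs))
    dt <- dt[!person_id %in% c(twin_pairs$person_id1, twin_pairs$person_id2)]
  data.table::setorder(dt, mother_id, father_id, birth_date, person_id)
  dt[, fam__ := .GRP, by = .(mother_id, father_id)]
  nxt <- dt[, data.table::shift(.SD, -1),
            .SDcols = c("person_id", "birth_date"), by = fam__]
  data.table::setnames(nxt, c("fam__", "n_id", "n_bd"))
  gap <- as.integer(nxt$n_bd - dt$birth_date)
  ok <- !is.na(nxt$n_id) & gap >= 334L & gap <= 1461L
  if (!any(ok)) return(make_pair_records(dt[0], dt[0], "nontwin_sibling", study_end))
  cand <- data.table::data.table(idx = which(ok), fam__ = dt$fam__[ok],
                                 gap = gap[ok], bd = dt$birth_date[ok],
                                 id = dt$person_id[ok])
  data.table::setorder(cand, fam__, gap, bd, id)
  best <- cand[!duplicated(fam__)]
  p1 <- dt[best$idx]
  p2 <- dt[data.table::chmatch(nxt$n_id[best$idx], dt$person_id)]
  make_pair_records(p1, p2, "nontwin_sibling", study_end)
}

#' Assemble the sibling cohort
#'
#' The sibling cohort contains both the twin pairs and the non-twin sibling
#' pairs, so the same-sex group is identical in the twin and sibling designs
#' while the reference group gains all non-twin pairs.
#'
#' @param twin_pairs,nontwin_pairs outputs of [identify_twin_pairs()] and
#'   [identify_sibling_pairs()].
#' @return a combined pair `data.table`.
#' @export
sibling_cohort <- function(twin_pairs, nontwin_pairs) {
  data.table::rbindlist(list(twin_pairs, nontwin_pairs), use.names = TRUE)
}

#' Restrict pairs to a birth cohort
#'
#' The `"1955"` cohort keeps pairs where both members were born 1955-2021
#' and both were alive on the 1st of January 1977 (so that some diagnostic
#' follow-up exists for them); the `"1977"` cohort keeps pairs with both
#' members born 1977-2021, who are followed from birth.
#'
#' @param pairs a pair table from the identification functions.
#' @param persons the person table (for death dates).
#' @param cohort `"1955"` or `"1977"`.
#' @return the filtered pair table.
#' @export
restrict_birth_cohort <- function(pairs, persons, cohort = c("1955", "1977")) {
  cohort <- match.arg(as.character(cohort), c("1955", "1977"))
  dt <- data.table::as.data.table(pairs)
  per <- validate_persons(persons)
  death <- per$death_date[match(c(dt$person_id1, dt$person_id2), per$person_id)]
  n <- nrow(dt)
  d1 <- death[seq_len(n)]; d2 <- death[n + seq_len(n)]
  end <- as.Date("2021-12-31")
  if (cohort == "1955") {
    lo <- as.Date("1955-01-01"); npr <- as.Date("1977-01-01")
    keep <- dt$birth_date1 >= lo & dt$birth_date1 <= end &
            dt$birth_date2 >= lo & dt$birth_date2 <= end &
            (is.na(d1) | d1 >= npr) & (is.na(d2) | d2 >= npr)
  } else {
    lo <- as.Date("1977-01-01")
    keep <- dt$birth_date1 >= lo & dt$birth_date1 <= end &
            dt$birth_date2 >= lo & dt$birth_date2 <= end
  }
  dt[keep]
}
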