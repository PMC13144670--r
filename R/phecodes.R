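#' Ancestors of a phecode in the dotted-decimal hierarchy
#'
#' Phecodes form a hierarchy by decimal truncation: `751.11` is a child of
#' `751.1`, which is a child of `751`. Returns the ancestors of a code from
#' nearest to root, excluding the code itself.
#'
#' @param code a single phecode string.
#' @return character vector of ancestor codes (possibly empty).
#' @examples
#' phecode_ancestors("345.12")  # "345.1", "345"
#' @export
phecode_ancestors <- function(code) {
  code <- as.character(code)
  stopifnot(length(code) == 1)
  parts <- strsplit(code, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(character(0))
  dec <- parts[2]
  anc <- character(0)
  for (k in rev(seq_len(nchar(dec) - 1)))
    anc <- c(anc, paste0(parts[1], ".", substr(dec, 1, k)))
  c(anc, parts[1])
}

#' Read a two-column code-mapping file
#'
#' @param path delimited text file with two columns (source code, target
#'   code); a header row is expected.
#' @param from,to names to assign to the columns.
#' @return a `data.table` with the two columns.
#' @export
read_code_map <- function(path, from = "from", to = "to") {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  if (ncol(dt) != 2)
    stop("malformed map file '", path, "': expected 2 columns, found ", ncol(dt))
  bad <- which(is.na(dt[[1]]) | dt[[1]] == "" | is.na(dt[[2]]) | dt[[2]] == "")
  if (length(bad))
    stop("malformed map file '", path, "': empty field at line ", bad[1] + 1)
  data.table::setnames(dt, c(from, to))
  dt
}

#' Map diagnosis events to phecodes with hierarchy closure
#'
#' ICD-8 events are first converted to ICD-10 (only ICD-9/ICD-10 to phecode
#' maps exist), then ICD-10 events to phecodes; events whose code system is
#' already `"phecode"` pass through. Every mapped event is propagated to all
#' ancestor phecodes in the dotted-decimal hierarchy. Unmapped codes are
#' counted and reported with a warning; they are not fatal.
#'
#' @param diagnoses event table with columns person_id, code, code_system
#'   (one of `"ICD-8"`, `"ICD-10"`, `"phecode"`), date.
#' @param icd8_to_icd10 optional two-column mapping (ICD-8 code, ICD-10
#'   code), e.g. from [read_code_map()].
#' @param icd10_to_phecode optional two-column mapping (ICD-10 code,
#'   phecode).
#' @return a `data.table` with columns person_id, phecode, date, including
#'   the ancestor-closure events.
#' @export
map_codes <- function(diagnoses, icd8_to_icd10 = NULL, icd10_to_phecode = NULL) {
  dt <- data.table::as.data.table(diagnoses)
  need <- c("person_id", "code", "code_system", "date")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("diagnosis table missing columns: ",
                         paste(miss, collapse = ", "))
  unknown <- setdiff(unique(dt$code_system), c("ICD-8", "ICD-10", "phecode"))
  if (length(unknown)) stop("unknown code system(s): ",
                            paste(unknown, collapse = ", "))
  dt <- data.table::copy(dt)
  dt[, date := as.Date(date)]
  n_unmapped <- 0L

  i8 <- dt[code_system == "ICD-8"]
  if (nrow(i8)) {
    if (is.null(icd8_to_icd10))
      stop("ICD-8 events present but no icd8_to_icd10 map supplied")
    m <- stats::setNames(icd8_to_icd10[[2]], icd8_to_icd10[[1]])
    i8[, code := unname(m[code])]
    n_unmapped <- n_unmapped + sum(is.na(i8$code))
    i8 <- i8[!is.na(code)][, code_system := "ICD-10"]
  }
  i10 <- data.table::rbindlist(list(dt[code_system == "ICD-10"], i8))
  if (nrow(i10)) {
    if (is.null(icd10_to_phecode))
      stop("ICD-10 events present but no icd10_to_phecode map supplied")
    m <- stats::setNames(icd10_to_phecode[[2]], icd10_to_phecode[[1]])
    i10[, code := unname(m[code])]
    n_unmapped <- n_unmapped + sum(is.na(i10$code))
    i10 <- i10[!is.na(code)]
  }
  ev <- data.table::rbindlist(list(dt[code_system == "phecode"], i10))
  ev <- ev[, .(person_id, phecode = code, date)]
  if (n_unmapped > 0)
    warning(n_unmapped, " diagnosis event(s) with unmapped codes were dropped")

  # ancestor closure
  codes <- unique(ev$phecode)
  anc <- data.table::rbindlist(lapply(codes, function(cd) {
    a <- phecode_ancestors(cd)
    if (!length(a)) return(NULL)
    data.table::data.table(phecode = cd, ancestor = a)
  }))
  if (nrow(anc)) {
    extra <- merge(ev, anc, by = "phecode", allow.cartesian = TRUE)
    extra <- extra[, .(person_id, phecode = ancestor, date)]
    ev <- data.table::rbindlist(list(ev, extra))
  }
  data.table::setorder(ev, person_id, phecode, date)
  ev[]
}

#' Build per-phecode phenotype pair tables
#'
#' For every phecode present in the mapped events, assigns each pair member
#' `y = 1` iff the person has at least one event for that phecode dated
#' within the observation window `[registry_start, followup_end]` of the
#' pair, and returns the long-format table of analyzable pairs.
#'
#' @param pairs a pair table (from the identification functions, possibly
#'   cohort-restricted).
#' @param events mapped events from [map_codes()].
#' @param registry_start first date at which diagnoses are observable.
#' @return a `data.table` with columns phecode, pair_id, group, y1, y2,
#'   sex1, sex2, byear1, byear2 (one block of all pairs per phecode). Events
#'   for persons not in any pair are dropped with a warning.
#' @export
build_phenotype_tables <- function(pairs, events,
                                   registry_start = as.Date("1977-01-01")) {
  pr <- data.table::as.data.table(pairs)
  ev <- data.table::as.data.table(events)
  members <- data.table::rbindlist(list(
    pr[, .(pair_id, person_id = person_id1, slot = 1L, followup_end)],
    pr[, .(pair_id, person_id = person_id2, slot = 2L, followup_end)]))
  known <- ev$person_id %in% members$person_id
  if (!all(known)) {
    warning(sum(!known), " event(s) for persons outside the pair cohort dropped")
    ev <- ev[known]
  }
  ev <- merge(ev, members, by = "person_id", allow.cartesian = TRUE)
  ev <- ev[date >= registry_start & date <= followup_end]
  aff <- unique(ev[, .(phecode, pair_id, slot)])

  skel <- pr[, .(pair_id, group = analysis_group, sex1, sex2, byear1, byear2)]
  out <- data.table::rbindlist(lapply(sort(unique(aff$phecode)), function(cd) {
    s <- data.table::copy(skel)
    a <- aff[phecode == cd]
    s[, `:=`(phecode = cd,
             y1 = as.integer(pair_id %in% a[slot == 1L, pair_id]),
             y2 = as.integer(pair_id %in% a[slot == 2L, pair_id]))]
    s
  }))
  if (is.null(out) || !nrow(out))
    return(data.table::data.table(phecode = character(), pair_id = character(),
                                  group = character(), y1 = integer(),
                                  y2 = integer(), sex1 = character(),
                                  sex2 = character(), byear1 = integer(),
                                  byear2 = integer()))
  data.table::setcolorder(out, c("phecode", "pair_id", "group", "y1", "y2",
                                 "sex1", "sex2", "byear1", "byear2"))
  out[]
}

#' Classify phenotype onset as early or late
#'
#' A phecode is early-onset iff the fraction of cases whose first event
#' occurred at age `early_onset_age` or younger is at least
#' `early_onset_threshold` (the case-denominator reading of a cumulative
#' incidence of 10% by age 18). Phecodes with zero cases are labelled
#' `"undefined"`.
#'
#' @param events mapped events from [map_codes()].
#' @param persons person table (for birth dates).
#' @param early_onset_age age cutoff in years (default 18).
#' @param early_onset_threshold minimum early-case fraction (default 0.10).
#' @return a `data.table` with phecode, n_cases, frac_early, onset_class.
#' @export
classify_onset <- function(events, persons, early_onset_age = 18,
                           early_onset_threshold = 0.10) {
  ev <- data.table::as.data.table(events)
  per <- validate_persons(persons)
  first <- ev[, .(date = min(date)), by = .(person_id, phecode)]
  first[, birth := per$birth_date[match(person_id, per$person_id)]]
  first <- first[!is.na(birth)]
  first[, age := as.numeric(date - birth) / 365.25]
  res <- first[, .(n_cases = .N,
                   frac_early = mean(age <= early_onset_age)), by = phecode]
  res[, onset_class := data.table::fifelse(n_cases == 0, "undefined",
        data.table::fifelse(frac_early >= early_onset_threshold, "early", "late"))]
  data.table::setorder(res, phecode)
  res[]
}

#' Eligibility thresholds for phecode filtering
#'
#' @param min_prevalence minimum cohort prevalence (default 0.005).
#' @param min_cases minimum case count, applied in twin-cohort runs only
#'   (default 400).
#' @param min_concordant_pairs minimum concordant pairs required in the SS
#'   and in the REF group (default 5).
#' @param max_sex_ratio maximum female-to-male or male-to-female case ratio
#'   (default 5).
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param early_onset_threshold,early_onset_age onset-classification
#'   parameters (defaults 0.10 and 18).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_prevalence = 0.005, min_cases = 400,
                          min_concordant_pairs = 5, max_sex_ratio = 5,
                          fdr_alpha = 0.05, early_onset_threshold = 0.10,
                          early_onset_age = 18) {
  stopifnot(min_prevalence > 0, min_cases > 0, min_concordant_pairs > 0,
            max_sex_ratio > 0, fdr_alpha > 0, early_onset_threshold > 0,
            early_onset_age > 0)
  structure(list(min_prevalence = min_prevalence, min_cases = min_cases,
                 min_concordant_pairs = min_concordant_pairs,
                 max_sex_ratio = max_sex_ratio, fdr_alpha = fdr_alpha,
                 early_onset_threshold = early_onset_threshold,
                 early_onset_age = early_onset_age),
            class = "filter_config")
}

#' Apply the phecode eligibility filters
#'
#' A phecode is eligible iff its prevalence is at least `min_prevalence`,
#' (for twin-cohort runs) its case count is at least `min_cases`, both the
#' SS and the REF group contain at least `min_concordant_pairs` concordant
#' pairs, and the case sex ratio (computed among case individuals) does not
#' exceed `max_sex_ratio`. A phecode excluded by the sex-ratio rule also
#' removes all its hierarchical ancestors, since an ancestor can appear
#' sex-balanced while aggregating imbalanced children. The exclusion ledger
#' records the first failing rule per excluded phecode.
#'
#' @param tables long phenotype table from [build_phenotype_tables()].
#' @param config a [filter_config()].
#' @param twin_cohort logical; if `TRUE` the `min_cases` rule is applied
#'   (it is a twin-analysis requirement), otherwise only the prevalence rule.
#' @return list with `eligible` (character vector of phecodes), `exclusions`
#'   (`data.table` phecode, reason), and `stats` (per-phecode summary).
#' @export
filter_phecodes <- function(tables, config = filter_config(),
                            twin_cohort = TRUE) {
  dt <- data.table::as.data.table(tables)
  stats <- dt[, {
    n_pairs <- .N
    n_cases <- sum(y1) + sum(y2)
    female <- sum((y1 == 1) * (sex1 == "F")) + sum((y2 == 1) * (sex2 == "F"))
    male <- n_cases - female
    list(n_pairs = n_pairs, n_cases = n_cases,
         K = n_cases / (2 * n_pairs),
         conc_ss = sum(y1 == 1 & y2 == 1 & group == "SS"),
         conc_ref = sum(y1 == 1 & y2 == 1 & group == "REF"),
         n_female = female, n_male = male,
         sex_ratio = if (n_cases == 0) NA_real_
                     else max(female, male) / max(min(female, male), 0))
  }, by = phecode]

  reason <- rep(NA_character_, nrow(stats))
  reason[is.na(reason) & stats$K < config$min_prevalence] <- "prevalence"
  if (twin_cohort)
    reason[is.na(reason) & stats$n_cases < config$min_cases] <- "min_cases"
  reason[is.na(reason) &
         (stats$conc_ss < config$min_concordant_pairs |
          stats$conc_ref < config$min_concordant_pairs)] <- "concordant_pairs"
  sex_fail <- !is.na(stats$sex_ratio) & stats$sex_ratio > config$max_sex_ratio
  reason[is.na(reason) & sex_fail] <- "sex_ratio"

  # sex-ratio exclusions propagate to all hierarchical ancestors
  sex_excluded <- stats$phecode[sex_fail]
  if (length(sex_excluded)) {
    anc <- unique(unlist(lapply(sex_excluded, phecode_ancestors)))
    hit <- stats$phecode %in% anc & is.na(reason)
    reason[hit] <- "sex_ratio_descendant"
  }

  exclusions <- data.table::data.table(phecode = stats$phecode,
                                       reason = reason)[!is.na(reason)]
  list(eligible = stats$phecode[is.na(reason)],
       exclusions = exclusions,
       stats = stats)
}
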