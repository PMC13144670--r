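#' Assemble a run configuration
#'
#' A run configuration drives the four pipeline stages ([run_simulate()],
#' [run_build()], [run_estimate()], [run_aggregate()]) and is fully
#' serialisable to YAML, so a stored configuration file reproduces a run
#' deterministically (up to floating-point determinism of the platform).
#'
#' @param output_dir directory receiving all stage outputs and manifests.
#' @param cohort `"1955"` or `"1977"` birth cohort.
#' @param design `"twin"` or `"sibling"`.
#' @param seed master integer seed for simulation and bootstrap.
#' @param simulation optional list of [sim_params()] arguments (without
#'   `seed`), used by [run_simulate()].
#' @param persons,diagnoses optional explicit paths to input tables; default
#'   to the simulate-stage outputs inside `output_dir`.
#' @param icd8_map,icd10_map optional paths to code-mapping files.
#' @param domain_map optional path to a two-column phecode-to-domain table
#'   used by [run_aggregate()].
#' @param filter a [filter_config()] or list of its arguments.
#' @param n_boot,stratified bootstrap settings.
#' @param registry_start_year first year with observable diagnoses.
#' @return a `run_config` list.
#' @export
run_config <- function(output_dir, cohort = "1977", design = "twin",
                       seed = 1L, simulation = NULL,
                       persons = NULL, diagnoses = NULL,
                       icd8_map = NULL, icd10_map = NULL, domain_map = NULL,
                       filter = filter_config(), n_boot = 500,
                       stratified = TRUE, registry_start_year = 1977) {
  cohort <- match.arg(as.character(cohort), c("1955", "1977"))
  design <- match.arg(design, c("twin", "sibling"))
  if (is.list(filter) && !inherits(filter, "filter_config"))
    filter <- do.call(filter_config, filter)
  structure(list(output_dir = output_dir, cohort = cohort, design = design,
                 seed = as.integer(seed), simulation = simulation,
                 persons = persons, diagnoses = diagnoses,
                 icd8_map = icd8_map, icd10_map = icd10_map,
                 domain_map = domain_map, filter = filter,
                 n_boot = as.integer(n_boot), stratified = isTRUE(stratified),
                 registry_start_year = as.integer(registry_start_year)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

stage_path <- function(config, file) file.path(config$output_dir, file)

require_upstream <- function(config, files, stage) {
  paths <- vapply(files, function(f) stage_path(config, f), "")
  missing <- files[!file.exists(paths)]
  if (length(missing))
    stop("stage '", stage, "' requires upstream output(s) not found in ",
         config$output_dir, ": ", paste(missing, collapse = ", "))
}

write_stage <- function(config, stage, tables, inputs = character(0)) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- character(0)
  for (nm in names(tables)) {
    f <- stage_path(config, paste0(nm, ".tsv"))
    data.table::fwrite(tables[[nm]], f, sep = "\t", quote = FALSE)
    outs <- c(outs, f)
  }
  manifest <- list(
    stage = stage,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package = "regherit",
    version = as.character(utils::packageVersion("regherit")),
    seed = config$seed,
    config = unclass(config[!vapply(config, is.null, TRUE)]),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outs))
  )
  jsonlite::write_json(manifest, stage_path(config, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(outs)
}

#' Run the simulate stage
#'
#' Generates a synthetic registry from `config$simulation` and writes
#' `persons.tsv`, `diagnoses.tsv`, `truth_pairs.tsv`,
#' `truth_phenotypes.tsv` and a manifest to the output directory.
#'
#' @param config a [run_config()] with a `simulation` entry.
#' @return (invisibly) the simulated tables.
#' @export
run_simulate <- function(config) {
  if (is.null(config$simulation))
    stop("config key 'simulation' is required for run_simulate")
  simargs <- config$simulation
  if (!is.null(simargs$phenotypes) && is.list(simargs$phenotypes[[1]]))
    simargs$phenotypes <- lapply(simargs$phenotypes,
                                 function(x) do.call(phenotype_spec, x))
  simargs$seed <- config$seed
  params <- do.call(sim_params, simargs)
  reg <- simulate_registry(params)
  write_stage(config, "simulate", reg)
  message(sprintf("simulate: %d persons, %d diagnosis events",
                  nrow(reg$persons), nrow(reg$diagnoses)))
  invisible(reg)
}

#' Run the cohort-build stage
#'
#' Reads person and diagnosis tables, identifies twin (and for the sibling
#' design non-twin sibling) pairs, restricts to the configured birth cohort,
#' maps diagnosis codes to phecodes with hierarchy closure, builds the
#' per-phecode pair tables and applies the eligibility filters. Writes
#' `pairs.tsv`, `phenotypes.tsv`, `exclusions.tsv`, `filter_stats.tsv`.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with pairs, tables, and the filter result.
#' @export
run_build <- function(config) {
  ppath <- config$persons %||% stage_path(config, "persons.tsv")
  dpath <- config$diagnoses %||% stage_path(config, "diagnoses.tsv")
  for (f in c(ppath, dpath))
    if (!file.exists(f))
      stop("stage 'build' requires input table not found: ", f)
  persons <- data.table::fread(ppath, colClasses = list(character = "person_id"))
  diagnoses <- data.table::fread(dpath)

  twins <- identify_twin_pairs(persons)
  message(sprintf("build: %d twin pairs identified", nrow(twins)))
  pairs <- if (config$design == "sibling") {
    sibs <- identify_sibling_pairs(persons, twin_pairs = twins)
    message(sprintf("build: %d non-twin sibling pairs identified", nrow(sibs)))
    sibling_cohort(twins, sibs)
  } else twins
  pairs <- restrict_birth_cohort(pairs, persons, config$cohort)
  message(sprintf("build: %d pairs in the %s birth cohort",
                  nrow(pairs), config$cohort))

  i8 <- if (!is.null(config$icd8_map))
    read_code_map(config$icd8_map, "icd8", "icd10")
  i10 <- if (!is.null(config$icd10_map))
    read_code_map(config$icd10_map, "icd10", "phecode")
  events <- map_codes(diagnoses, icd8_to_icd10 = i8, icd10_to_phecode = i10)

  registry_start <- as.Date(sprintf("%d-01-01", config$registry_start_year))
  tables <- build_phenotype_tables(pairs, events, registry_start)
  filt <- filter_phecodes(tables, config$filter,
                          twin_cohort = config$design == "twin")
  message(sprintf("build: %d phecodes with events, %d eligible after filters",
                  length(unique(tables$phecode)), length(filt$eligible)))
  onset <- classify_onset(events, persons,
                          early_onset_age = config$filter$early_onset_age,
                          early_onset_threshold = config$filter$early_onset_threshold)
  write_stage(config, "build",
              list(pairs = pairs, phenotypes = tables,
                   exclusions = filt$exclusions, filter_stats = filt$stats,
                   onset = onset),
              inputs = c(ppath, dpath))
  invisible(list(pairs = pairs, tables = tables, filter = filt, onset = onset))
}

#' Run the estimate stage
#'
#' For every phecode that passed the filters: fits the variance-component
#' model, converts to the liability scale, applies the modified Falconer
#' estimator with the Weinberg mixture weight computed from the cohort's
#' twin pairs, bootstraps the standard error and 95% CI, and computes
#' z-test p-values with Benjamini-Hochberg q-values across the run. Writes
#' `estimates.tsv` with all intermediates.
#'
#' @param config a [run_config()].
#' @return (invisibly) the estimates `data.table`.
#' @export
run_estimate <- function(config) {
  require_upstream(config, c("pairs.tsv", "phenotypes.tsv", "exclusions.tsv"),
                   "estimate")
  pairs <- data.table::fread(stage_path(config, "pairs.tsv"))
  tables <- data.table::fread(stage_path(config, "phenotypes.tsv"),
                              colClasses = list(character = "phecode"))
  excl <- data.table::fread(stage_path(config, "exclusions.tsv"),
                            colClasses = "character")
  eligible <- setdiff(unique(tables$phecode), excl$phecode)
  if (!length(eligible)) stop("no eligible phecodes to estimate")

  tw <- pairs[relationship == "twin"]
  mz <- mz_probability(nrow(tw), sum(tw$analysis_group == "SS"),
                       sum(tw$analysis_group == "REF"))
  message(sprintf("estimate: p(MZ|SS) = %.4f from %d twin pairs",
                  mz$p, mz$n_all))

  rows <- lapply(seq_along(eligible), function(k) {
    cd <- eligible[k]
    tab <- tables[phecode == cd]
    boot <- tryCatch(
      bootstrap_estimate(tab, mz$p, n_boot = config$n_boot,
                         seed = (config$seed + k) %% .Machine$integer.max,
                         stratified = config$stratified),
      error = function(e) {
        warning("phecode ", cd, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(boot)) return(NULL)
    pt <- boot$point
    data.table::data.table(
      phecode = cd, cohort = config$cohort, design = config$design,
      h2_raw = pt$h2_raw, h2_report = pt$h2_report,
      se_boot = boot$se, ci_lo = boot$ci95[1], ci_hi = boot$ci95[2],
      ci_lo_pct = boot$ci95_percentile[1], ci_hi_pct = boot$ci95_percentile[2],
      v_pair = pt$vc$v_pair, v_only_ss = pt$vc$v_only_ss, v_e = pt$vc$v_e,
      r_ss_obs = pt$r_ss_obs, r_os_obs = pt$r_os_obs,
      r_ss_liab = pt$r_ss_liab, r_os_liab = pt$r_os_liab,
      p_mzss = mz$p, K = pt$K, n_pairs = pt$n_pairs, n_ss = pt$n_ss,
      n_ref = pt$n_ref, n_cases = pt$n_cases)
  })
  est <- data.table::rbindlist(rows)
  if (!nrow(est)) stop("all phecode estimates failed")
  est[, p_value := z_test(h2_raw, se_boot)]
  fdr <- bh_fdr(est$p_value, alpha = config$filter$fdr_alpha)
  est[, q_value := fdr$q]
  est[, significant := fdr$significant]
  write_stage(config, "estimate", list(estimates = est),
              inputs = vapply(c("pairs.tsv", "phenotypes.tsv"),
                              function(f) stage_path(config, f), ""))
  message(sprintf("estimate: %d phecodes estimated, %d with q < %.2f",
                  nrow(est), sum(est$significant), config$filter$fdr_alpha))
  invisible(est)
}

#' Run the aggregate stage
#'
#' Computes inverse-variance-weighted mean heritabilities per functional
#' domain (from `config$domain_map`, a two-column phecode-to-domain file;
#' phecodes without a domain fall into `"all"`) over the FDR-significant
#' estimates, and writes `ivw.tsv`.
#'
#' @param config a [run_config()].
#' @return (invisibly) the IVW summary `data.table`.
#' @export
run_aggregate <- function(config) {
  require_upstream(config, "estimates.tsv", "aggregate")
  est <- data.table::fread(stage_path(config, "estimates.tsv"),
                           colClasses = list(character = "phecode"))
  est <- est[is.finite(se_boot) & se_boot > 0]
  dom <- if (!is.null(config$domain_map)) {
    dm <- read_code_map(config$domain_map, "phecode", "domain")
    dm$domain[match(est$phecode, dm$phecode)]
  } else rep(NA_character_, nrow(est))
  est[, domain := data.table::fifelse(is.na(dom), "all", dom)]
  sig <- est[significant == TRUE]
  if (!nrow(sig)) stop("no FDR-significant estimates to aggregate")
  ivw <- sig[, {
    s <- ivw_mean(h2_raw, se_boot, labels = phecode)
    list(ivw_mean = s$mean, ivw_se = s$se,
         ci_lo = s$ci95[1], ci_hi = s$ci95[2], n_phecodes = s$n)
  }, by = .(domain, cohort, design)]
  write_stage(config, "aggregate", list(ivw = ivw),
              inputs = stage_path(config, "estimates.tsv"))
  invisible(ivw)
}
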