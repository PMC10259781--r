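# Pipeline orchestration. Each stage is a pure function of (inputs,
# config): it reads the tables named in the config, runs the analysis, and
# writes delimited + JSON outputs into the output directory, logging the
# case counts at every filter step. Re-running never mutates inputs.

#' Pipeline configuration
#'
#' Collects every setting the pipeline stages need: table paths and column
#' mappings, the term-list path, the study drug, covariate drug lists, band
#' edges, the analysis window, and the output directory. Can also be read
#' from a YAML file with [read_pipeline_config()].
#'
#' @param tables named list of file paths (`demo`, `drug`, `reac`, `hist`).
#' @param mapping named list of column mappings per table kind (defaults to
#'   the normalized names; see [jader_default_mapping()]).
#' @param delim,encoding table file dialect.
#' @param term_list path to the SMQ term-list file.
#' @param drug study drug generic name.
#' @param antipsychotics,antiepileptics paths to drug-list files (bundled
#'   defaults).
#' @param lithium_drugs,fluvoxamine_drugs name vectors.
#' @param dose_breaks,lithium_break band edges, mg/day.
#' @param dose_rule multi-record dose rule.
#' @param sex_reference reference sex level in the model.
#' @param window_days time-to-onset analysis window.
#' @param day_convention onset day-counting convention.
#' @param quartile_type quantile algorithm for the median/IQR.
#' @param hist_bin_width histogram bin width, days.
#' @param out_dir output directory.
#' @param seed seed for [run_simulate()].
#' @param n_cases number of cases for [run_simulate()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(tables = list(),
                            mapping = NULL,
                            delim = ",", encoding = "UTF-8",
                            term_list = jaderpv_example("smq_convulsions_demo.txt"),
                            drug = "clozapine",
                            antipsychotics = jaderpv_example("antipsychotics.txt"),
                            antiepileptics = jaderpv_example("antiepileptics.txt"),
                            lithium_drugs = c("lithium carbonate", "lithium"),
                            fluvoxamine_drugs = "fluvoxamine",
                            dose_breaks = c(200, 400),
                            lithium_break = 600,
                            dose_rule = "max",
                            sex_reference = "male",
                            window_days = 1095,
                            day_convention = "plus1",
                            quartile_type = 7,
                            hist_bin_width = 30,
                            out_dir = ".",
                            seed = NULL,
                            n_cases = 2000) {
  stopifnot(dose_breaks[1] > 0, dose_breaks[1] < dose_breaks[2],
            lithium_break > 0, window_days > 0)
  structure(list(tables = tables, mapping = mapping, delim = delim,
                 encoding = encoding, term_list = term_list, drug = drug,
                 antipsychotics = antipsychotics,
                 antiepileptics = antiepileptics,
                 lithium_drugs = lithium_drugs,
                 fluvoxamine_drugs = fluvoxamine_drugs,
                 dose_breaks = dose_breaks, lithium_break = lithium_break,
                 dose_rule = dose_rule, sex_reference = sex_reference,
                 window_days = window_days, day_convention = day_convention,
                 quartile_type = quartile_type,
                 hist_bin_width = hist_bin_width,
                 out_dir = out_dir, seed = seed, n_cases = n_cases),
            class = "pipeline_config")
}

#' @describeIn pipeline_config read settings from a YAML file; entries not
#'   present fall back to the defaults.
#' @param path path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

# read the four tables and join them, logging counts
.load_cases <- function(config) {
  mp <- config$mapping
  tab <- function(kind) {
    key <- tolower(kind)
    if (is.null(config$tables[[key]])) {
      stop("config$tables$", key, " is not set", call. = FALSE)
    }
    read_jader_table(config$tables[[key]], kind,
                     mapping = if (!is.null(mp)) mp[[kind]] else NULL,
                     delim = config$delim, encoding = config$encoding)
  }
  cases <- build_cases(tab("DEMO"), tab("DRUG"), tab("REAC"), tab("HIST"))
  message("loaded ", n_cases(cases), " cases (",
          sum(vapply(cases$orphans, nrow, integer(1))), " orphan rows)")
  cases
}

.cohort_config_from <- function(config) {
  cohort_config(drug = config$drug,
                antipsychotics = read_drug_list(config$antipsychotics),
                antiepileptics = read_drug_list(config$antiepileptics),
                lithium_drugs = config$lithium_drugs,
                fluvoxamine_drugs = config$fluvoxamine_drugs,
                dose_breaks = config$dose_breaks,
                lithium_break = config$lithium_break,
                dose_rule = config$dose_rule)
}

#' Run the simulation stage
#'
#' Generates a synthetic four-table dump (see [simulate_jader()]) and
#' writes it, with its ground truth, under the configured output directory.
#'
#' @param config a [pipeline_config()] with `seed` (and optionally
#'   `n_cases`) set.
#' @param sim_args further arguments passed to [sim_config()].
#' @return the `jader_sim` object, invisibly.
#' @export
run_simulate <- function(config, sim_args = list()) {
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  sc <- do.call(sim_config, c(list(n_cases = config$n_cases,
                                   seed = config$seed), sim_args))
  sim <- simulate_jader(sc)
  paths <- write_jader_tables(sim, config$out_dir, delim = config$delim)
  message("simulated ", sim$config$n_cases, " cases -> ", config$out_dir)
  invisible(sim)
}

#' Run the reporting-odds profile stage
#'
#' Loads the four tables, restricts to the study drug, flags cases against
#' the term list, builds the cohort with its exclusion ledger, fits the
#' adjusted reporting-odds model and writes `cohort.csv`, `ledger.json`,
#' `effects.csv` and `effects.json`.
#'
#' @param config a [pipeline_config()].
#' @return list with `cohort`, `ledger`, `effects`, `fit`, invisibly.
#' @export
run_profile <- function(config) {
  cases <- .load_cases(config)
  cases <- filter_drug_cases(cases, config$drug)
  message(n_cases(cases), " cases report ", config$drug)
  q <- read_term_list(config$term_list)
  flags <- flag_cases(cases, q)
  built <- build_cohort(cases, flags, .cohort_config_from(config))
  message(built$ledger$n_retained, " of ", built$ledger$n_input,
          " cases retained after exclusions (",
          paste(names(built$ledger$exclusions), built$ledger$exclusions,
                sep = "=", collapse = ", "), ")")
  ar <- adjusted_ror(built$cohort, sex_reference = config$sex_reference)
  if (!ar$fit$converged) {
    stop("logistic model did not converge; no effect table written",
         call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(built$cohort, file.path(config$out_dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_input = built$ledger$n_input,
         n_retained = built$ledger$n_retained,
         exclusions = as.list(built$ledger$exclusions),
         seed = config$seed),
    file.path(config$out_dir, "ledger.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(ar$effects, file.path(config$out_dir, "effects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(ar$effects, file.path(config$out_dir, "effects.json"),
                       dataframe = "rows", digits = NA)
  invisible(list(cohort = built$cohort, ledger = built$ledger,
                 effects = ar$effects, fit = ar$fit))
}

#' Run the time-to-onset stage
#'
#' Loads the tables, computes the onset-day sample for target-event cases
#' of the study drug, summarizes it (median, IQR, within-window
#' proportions), fits the Weibull law and classifies the hazard, and writes
#' `tto_summary.json` and `tto_histogram.csv`.
#'
#' @param config a [pipeline_config()].
#' @return list with `sample`, `summary`, `fit`, `histogram`, invisibly.
#' @export
run_tto <- function(config) {
  cases <- .load_cases(config)
  cases <- filter_drug_cases(cases, config$drug)
  q <- read_term_list(config$term_list)
  flags <- flag_cases(cases, q)
  smp <- onset_days(cases, flags, drug_name = config$drug,
                    window_days = config$window_days,
                    convention = config$day_convention)
  message(length(smp$days), " onset times (",
          smp$n_excluded_missing_dates, " missing dates, ",
          smp$n_excluded_beyond_window, " beyond window)")
  if (length(smp$days) == 0L) stop("empty onset sample", call. = FALSE)
  if (length(smp$days) < 3L) {
    stop("fewer than 3 onset times; cannot fit", call. = FALSE)
  }
  s <- onset_summary(smp, quartile_type = config$quartile_type)
  fit <- fit_weibull(smp)
  hg <- onset_histogram(smp, bin_width_days = config$hist_bin_width)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n = s$n, median_days = s$median, q1_days = s$q1, q3_days = s$q3,
         proportion_within_365 = proportion_within(smp, 365),
         weibull = list(alpha = fit$alpha, alpha_ci = fit$alpha_ci,
                        beta = fit$beta, beta_ci = fit$beta_ci,
                        loglik = fit$loglik,
                        failure_type = fit$failure_type),
         n_excluded_missing_dates = smp$n_excluded_missing_dates,
         n_excluded_beyond_window = smp$n_excluded_beyond_window,
         window_days = smp$window_days, seed = config$seed),
    file.path(config$out_dir, "tto_summary.json"),
    auto_unbox = TRUE, digits = NA)
  utils::write.csv(hg, file.path(config$out_dir, "tto_histogram.csv"),
                   row.names = FALSE)
  invisible(list(sample = smp, summary = s, fit = fit, histogram = hg))
}

#' @describeIn run_profile run simulate (when `seed` is set and table paths
#'   are not), profile and time-to-onset in sequence.
#' @export
run_all <- function(config) {
  if (!length(config$tables)) {
    run_simulate(config)
    config$mapping <- sim_table_mapping()
    config$tables <- list(demo = file.path(config$out_dir, "demo.csv"),
                          drug = file.path(config$out_dir, "drug.csv"),
                          reac = file.path(config$out_dir, "reac.csv"),
                          hist = file.path(config$out_dir, "hist.csv"))
  }
  profile <- run_profile(config)
  tto <- run_tto(config)
  invisible(list(profile = profile, tto = tto))
}
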