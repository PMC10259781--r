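# Cohort construction: reduce each study-drug case to an outcome flag plus
# a complete covariate vector, excluding cases with unknown sex, age,
# study-drug dose or lithium dose, in that fixed order, and keeping an
# auditable ledger of the exclusion counts.

age_levels <- c("le29", "30s", "40s", "50s", "ge60")
dose_levels <- c("low", "medium", "high")
lithium_levels <- c("none", "low", "high")

#' Categorize decade-banded age strings
#'
#' Spontaneous-report databases band ages in 10-year increments (e.g.
#' `"20s"`). Bands below 30 form the reference group (29 and younger);
#' 30s/40s/50s are kept; 60s and above collapse to a single 60+ group.
#' Non-numeric labels (`"adult"`, `"child"`, `"elderly"`) and blanks map to
#' `NA`, which excludes the case downstream. A trailing non-digit band
#' suffix after the leading digits is tolerated (so `"20s"`, `"20"` and
#' banded labels in other scripts all parse).
#'
#' @param age_raw character vector of age strings as reported.
#' @return factor with levels le29, 30s, 40s, 50s, ge60; `NA` where the age
#'   is missing or non-numeric.
#' @export
#' @examples
#' categorize_age(c("20s", "30s", "70s", "adult", ""))
categorize_age <- function(age_raw) {
  x <- trimws(as.character(age_raw))
  num <- grepl("^\\d{1,3}\\D*$", x)
  v <- rep(NA_real_, length(x))
  v[num] <- as.numeric(sub("^(\\d{1,3})\\D*$", "\\1", x[num]))
  out <- rep(NA_character_, length(x))
  out[!is.na(v) & v < 30] <- "le29"
  out[!is.na(v) & v >= 30 & v < 40] <- "30s"
  out[!is.na(v) & v >= 40 & v < 50] <- "40s"
  out[!is.na(v) & v >= 50 & v < 60] <- "50s"
  out[!is.na(v) & v >= 60] <- "ge60"
  factor(out, levels = age_levels)
}

#' Categorize a daily dose into low / medium / high bands
#'
#' Default band edges follow the study-drug convention for clozapine:
#' low < 200 mg, medium 200-400 mg (closed interval: both edges are
#' medium), high > 400 mg. Missing doses map to `NA`.
#'
#' @param dose_mg_per_day numeric vector (mg/day).
#' @param breaks two ascending edges `c(low_upper, medium_upper)`.
#' @return factor with levels low, medium, high; `NA` for missing dose.
#' @export
#' @examples
#' categorize_cloz_dose(c(199.9, 200, 400, 600, NA))
categorize_cloz_dose <- function(dose_mg_per_day, breaks = c(200, 400)) {
  stopifnot(length(breaks) == 2L, breaks[1] < breaks[2], breaks[1] > 0)
  d <- as.numeric(dose_mg_per_day)
  out <- rep(NA_character_, length(d))
  out[!is.na(d) & d < breaks[1]] <- "low"
  out[!is.na(d) & d >= breaks[1] & d <= breaks[2]] <- "medium"
  out[!is.na(d) & d > breaks[2]] <- "high"
  factor(out, levels = dose_levels)
}

#' Resolve one dose per case for a given drug
#'
#' A case can carry several records of the same drug (dose changes,
#' re-reports). The default rule takes the maximum non-missing dose —
#' peak exposure; `"first"` takes the first non-missing record in table
#' order and `"mean"` averages the non-missing doses.
#'
#' @param cases a `jader_cases` object.
#' @param drug_name normalized generic name to match.
#' @param rule reconciliation rule.
#' @return named numeric vector over all case ids (DEMO order); `NA` where
#'   the case has no record of the drug or only missing doses.
#' @export
resolve_drug_dose <- function(cases, drug_name, rule = c("max", "first", "mean")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cases, "jader_cases"))
  target <- normalize_name(drug_name)
  ids <- cases$demo$case_id
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  rows <- cases$drug[cases$drug$drug_name %in% target &
                       !is.na(cases$drug$dose_mg_per_day), , drop = FALSE]
  if (nrow(rows)) {
    agg <- switch(rule,
                  max = tapply(rows$dose_mg_per_day, rows$case_id, max),
                  first = tapply(rows$dose_mg_per_day, rows$case_id,
                                 function(v) v[1L]),
                  mean = tapply(rows$dose_mg_per_day, rows$case_id, mean))
    out[names(agg)] <- unname(agg)
  }
  out
}

#' Categorize lithium exposure
#'
#' Three levels against the no-use reference: no lithium record at all ->
#' `none`; lithium with a resolved dose of at most the band edge (600 mg)
#' -> `low`; above it -> `high`. A case with lithium records but no usable
#' dose is `NA` (excluded downstream as unknown lithium dose) — the
#' unknown-dose exclusion applies only to lithium users.
#'
#' @param cases a `jader_cases` object.
#' @param lithium_drugs normalized names counted as lithium.
#' @param break_mg band edge in mg/day.
#' @param rule dose reconciliation rule, as in [resolve_drug_dose()].
#' @return factor over all case ids with levels none, low, high; `NA` for
#'   lithium users with unknown dose.
#' @export
categorize_lithium <- function(cases,
                               lithium_drugs = c("lithium carbonate", "lithium"),
                               break_mg = 600, rule = "max") {
  stopifnot(inherits(cases, "jader_cases"), break_mg > 0)
  target <- normalize_name(lithium_drugs)
  ids <- cases$demo$case_id
  has_li <- ids %in% cases$drug$case_id[cases$drug$drug_name %in% target]
  rows <- cases$drug[cases$drug$drug_name %in% target, , drop = FALSE]
  dose <- stats::setNames(rep(NA_real_, length(ids)), ids)
  usable <- rows[!is.na(rows$dose_mg_per_day), , drop = FALSE]
  if (nrow(usable)) {
    agg <- switch(rule,
                  max = tapply(usable$dose_mg_per_day, usable$case_id, max),
                  first = tapply(usable$dose_mg_per_day, usable$case_id,
                                 function(v) v[1L]),
                  mean = tapply(usable$dose_mg_per_day, usable$case_id, mean))
    dose[names(agg)] <- unname(agg)
  }
  out <- rep(NA_character_, length(ids))
  out[!has_li] <- "none"
  out[has_li & !is.na(dose) & dose <= break_mg] <- "low"
  out[has_li & !is.na(dose) & dose > break_mg] <- "high"
  factor(out, levels = lithium_levels)
}

#' Flag antipsychotic polypharmacy
#'
#' `TRUE` when a case has at least one drug record whose name is on the
#' antipsychotic list and differs from the study drug itself.
#'
#' @param cases a `jader_cases` object.
#' @param antipsychotics character vector of antipsychotic generic names
#'   (defaults to the bundled list of approved antipsychotics).
#' @param drug_name the study drug, excluded from the match.
#' @return logical vector over all case ids (DEMO order).
#' @export
flag_polypharmacy <- function(cases,
                              antipsychotics = read_drug_list(
                                jaderpv_example("antipsychotics.txt")),
                              drug_name = "clozapine") {
  stopifnot(inherits(cases, "jader_cases"))
  set <- setdiff(normalize_name(antipsychotics), normalize_name(drug_name))
  ids <- cases$demo$case_id
  ids %in% cases$drug$case_id[cases$drug$drug_name %in% set]
}

#' @describeIn flag_polypharmacy flag any concomitant drug from a name list
#'   (e.g. fluvoxamine), without the self-exclusion.
#' @param drugs character vector of names to match.
#' @export
flag_drug_use <- function(cases, drugs) {
  stopifnot(inherits(cases, "jader_cases"))
  cases$demo$case_id %in%
    cases$drug$case_id[cases$drug$drug_name %in% normalize_name(drugs)]
}

#' Flag concomitant antiepileptic use with the temporal rule
#'
#' A case counts as using antiepileptics when it has a record of any listed
#' agent, except that for a target-event case with a complete event onset
#' date, agents started strictly after the onset are non-concomitant: the
#' flag is `FALSE` only if every matching record has a complete start date
#' later than the onset. Records with missing or partial start dates count
#' as concomitant (no evidence of post-onset initiation).
#'
#' @param cases a `jader_cases` object.
#' @param flags output of [flag_cases()] for the same cases.
#' @param antiepileptics agent names (defaults to the bundled five-agent
#'   list: valproate, carbamazepine, lamotrigine, clonazepam, diazepam).
#' @return logical vector over all case ids (DEMO order).
#' @export
flag_antiepileptic <- function(cases, flags,
                               antiepileptics = read_drug_list(
                                 jaderpv_example("antiepileptics.txt"))) {
  stopifnot(inherits(cases, "jader_cases"))
  set <- normalize_name(antiepileptics)
  ids <- cases$demo$case_id
  rows <- cases$drug[cases$drug$drug_name %in% set, , drop = FALSE]
  has_ae <- ids %in% rows$case_id
  out <- has_ae
  fl <- flags[match(ids, flags$case_id), , drop = FALSE]
  judge <- which(has_ae & fl$is_seizure_case & !is.na(fl$seizure_onset_date))
  if (length(judge)) {
    rj <- rows[rows$case_id %in% ids[judge], , drop = FALSE]
    s <- parse_complete_date(rj$start_date)
    onset <- fl$seizure_onset_date[match(rj$case_id, ids)]
    # concomitant unless every record is known to start after onset
    all_after <- tapply(!is.na(s) & s > onset, rj$case_id, all)
    out[judge] <- !unname(all_after[match(ids[judge], names(all_after))])
  }
  out
}

#' Read a plain-text drug list
#'
#' One generic name per line; `#` comments allowed. Names are normalized.
#'
#' @param path path to the list file.
#' @return character vector of normalized names.
#' @export
read_drug_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  normalize_name(lines[nzchar(lines)])
}

#' Cohort construction settings
#'
#' @param drug study drug generic name.
#' @param antipsychotics,antiepileptics drug-name vectors (bundled defaults).
#' @param lithium_drugs names counted as lithium.
#' @param fluvoxamine_drugs names counted as fluvoxamine.
#' @param dose_breaks study-drug band edges, mg/day.
#' @param lithium_break lithium band edge, mg/day.
#' @param dose_rule multi-record dose reconciliation rule.
#' @return a list of settings for [build_cohort()].
#' @export
cohort_config <- function(drug = "clozapine",
                          antipsychotics = read_drug_list(
                            jaderpv_example("antipsychotics.txt")),
                          antiepileptics = read_drug_list(
                            jaderpv_example("antiepileptics.txt")),
                          lithium_drugs = c("lithium carbonate", "lithium"),
                          fluvoxamine_drugs = "fluvoxamine",
                          dose_breaks = c(200, 400),
                          lithium_break = 600,
                          dose_rule = "max") {
  list(drug = drug, antipsychotics = antipsychotics,
       antiepileptics = antiepileptics, lithium_drugs = lithium_drugs,
       fluvoxamine_drugs = fluvoxamine_drugs, dose_breaks = dose_breaks,
       lithium_break = lithium_break, dose_rule = dose_rule)
}

#' Build the analyzable cohort and its exclusion ledger
#'
#' Applies the exclusion rules in a fixed order — unknown sex, unknown or
#' non-numeric age, unknown study-drug dose, unknown lithium dose (lithium
#' users only) — attributing each excluded case to the first failing rule,
#' and reduces every retained case to one complete row: outcome flag plus
#' the ten-covariate vector of the reporting-odds model.
#'
#' @param cases a `jader_cases` object already restricted to the study drug
#'   (see [filter_drug_cases()]).
#' @param flags output of [flag_cases()] for the same cases.
#' @param config settings from [cohort_config()].
#' @return a list with `cohort` (data.frame, one row per retained case) and
#'   `ledger` (class `exclusion_ledger`).
#' @export
build_cohort <- function(cases, flags, config = cohort_config()) {
  stopifnot(inherits(cases, "jader_cases"))
  ids <- cases$demo$case_id
  fl <- flags[match(ids, flags$case_id), , drop = FALSE]

  sex <- cases$demo$sex
  age <- categorize_age(cases$demo$age_raw)
  dose <- resolve_drug_dose(cases, config$drug, rule = config$dose_rule)
  dose_cat <- categorize_cloz_dose(dose, breaks = config$dose_breaks)
  lith <- categorize_lithium(cases, lithium_drugs = config$lithium_drugs,
                             break_mg = config$lithium_break,
                             rule = config$dose_rule)

  reason <- rep(NA_character_, length(ids))
  reason[is.na(reason) & !(sex %in% c("male", "female"))] <- "unknown_sex"
  reason[is.na(reason) & is.na(age)] <- "unknown_age_or_nonnumeric"
  reason[is.na(reason) & is.na(dose_cat)] <- "unknown_cloz_dose"
  reason[is.na(reason) & is.na(lith)] <- "unknown_lithium_dose"
  keep <- is.na(reason)

  poly <- flag_polypharmacy(cases, config$antipsychotics, config$drug)
  fluvo <- flag_drug_use(cases, config$fluvoxamine_drugs)
  antiep <- flag_antiepileptic(cases, fl, config$antiepileptics)

  cohort <- data.frame(
    case_id = ids[keep],
    outcome_seizure = fl$is_seizure_case[keep],
    sex = factor(sex[keep], levels = c("male", "female")),
    age_cat = age[keep],
    cloz_dose_cat = dose_cat[keep],
    polypharmacy = poly[keep],
    lithium_cat = lith[keep],
    fluvoxamine = fluvo[keep],
    antiepileptic = antiep[keep],
    convulsive_history = fl$has_convulsive_history[keep],
    stringsAsFactors = FALSE)

  reasons <- c("unknown_sex", "unknown_age_or_nonnumeric",
               "unknown_cloz_dose", "unknown_lithium_dose")
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  ledger <- structure(list(n_input = length(ids),
                           n_retained = sum(keep),
                           exclusions = counts),
                      class = "exclusion_ledger")
  stopifnot(ledger$n_input == ledger$n_retained + sum(ledger$exclusions))
  list(cohort = cohort, ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("<exclusion_ledger> ", x$n_input, " cases in, ",
      x$n_retained, " retained\n", sep = "")
  for (r in names(x$exclusions)) {
    cat(sprintf("  %-26s %d\n", r, x$exclusions[[r]]))
  }
  invisible(x)
}
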