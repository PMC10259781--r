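# Seeded simulator of four-table spontaneous-report dumps with known ground
# truth. The generator is the oracle for every pipeline stage: covariates
# are drawn from stated prevalences, the seizure outcome from a logistic
# model at planted log odds ratios, onset times from a Weibull law, and
# missingness is applied MCAR after outcome generation, so the analyzable
# truth is known exactly.

.nonseizure_pts <- c("Nausea", "Agranulocytosis", "Constipation",
                     "Somnolence", "Pyrexia", "Weight increased",
                     "Neutropenia", "Myocarditis",
                     "Salivary hypersecretion")
.benign_hist_pts <- c("Diabetes mellitus", "Hypertension",
                      "Dyslipidaemia", "Insomnia")
.background_drugs <- c("olanzapine", "sertraline", "donepezil",
                       "metformin", "amlodipine", "warfarin")

#' Default planted log odds for the seizure outcome model
#'
#' Named in the fixed dummy-coding order (male/age<=29/low-dose/no-lithium
#' reference). The non-intercept entries are the natural logs of the
#' adjusted reporting odds ratios the simulator is designed to emulate; the
#' intercept -3.0 puts the marginal seizure-report fraction near 11% of
#' study-drug reports under the default prevalences.
#'
#' @return named numeric vector of length 14.
#' @export
default_true_beta <- function() {
  c("(Intercept)" = -3.0,
    sex = log(0.9),
    age_30s = log(0.45), age_40s = log(0.40),
    age_50s = log(0.35), age_ge60 = log(0.30),
    dose_medium = log(3.05), dose_high = log(9.81),
    polypharmacy = log(1.68),
    lithium_low = log(1.63), lithium_high = log(1.66),
    fluvoxamine = log(2.79),
    antiepileptic = log(0.49),
    convulsive_history = log(8.49))
}

#' Simulation settings
#'
#' Defines the generating process for a four-table dump: number of reports,
#' fraction on the study drug, covariate prevalences, planted log odds for
#' the seizure outcome, dose values per band, the Weibull onset law, and
#' MCAR missingness rates applied after outcome generation.
#'
#' @param n_cases number of reports (DEMO rows).
#' @param seed RNG seed (mandatory; the run is reproducible given it).
#' @param p_clozapine fraction of reports involving the study drug.
#' @param p_female,age_probs,dose_probs,p_polypharmacy,lithium_probs,p_fluvoxamine,p_antiepileptic,p_history
#'   covariate prevalences among study-drug reports.
#' @param beta named planted log-odds vector, see [default_true_beta()].
#' @param weibull_alpha,weibull_beta onset-law scale (days) and shape.
#' @param missingness named list of MCAR rates: `sex`, `age` (blank),
#'   `age_nonnumeric` (adult/child/elderly label), `cloz_dose`,
#'   `lithium_dose`, `start_date`, `onset_date`.
#' @param p_partial_date probability that a non-missing date is truncated
#'   to year-month (or year) precision.
#' @param date_start,date_end report registration window.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 2000,
                       seed,
                       p_clozapine = 0.25,
                       p_female = 0.43,
                       age_probs = c(le29 = 0.22, "30s" = 0.28, "40s" = 0.25,
                                     "50s" = 0.15, ge60 = 0.10),
                       dose_probs = c(low = 0.35, medium = 0.40, high = 0.25),
                       p_polypharmacy = 0.40,
                       lithium_probs = c(none = 0.84, low = 0.11, high = 0.05),
                       p_fluvoxamine = 0.03,
                       p_antiepileptic = 0.30,
                       p_history = 0.04,
                       beta = default_true_beta(),
                       weibull_alpha = 193,
                       weibull_beta = 1.0,
                       missingness = list(sex = 0.02, age = 0.03,
                                          age_nonnumeric = 0.03,
                                          cloz_dose = 0.25,
                                          lithium_dose = 0.05,
                                          start_date = 0.04,
                                          onset_date = 0.03),
                       p_partial_date = 0.03,
                       date_start = "2004-04-01",
                       date_end = "2021-11-30") {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  probs <- c(p_clozapine, p_female, age_probs, dose_probs, p_polypharmacy,
             lithium_probs, p_fluvoxamine, p_antiepileptic, p_history,
             unlist(missingness), p_partial_date)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(age_probs) - 1) > 1e-8 || abs(sum(dose_probs) - 1) > 1e-8 ||
      abs(sum(lithium_probs) - 1) > 1e-8) {
    stop("category probabilities must sum to 1", call. = FALSE)
  }
  if (weibull_alpha <= 0 || weibull_beta <= 0) {
    stop("Weibull parameters must be positive", call. = FALSE)
  }
  stopifnot(n_cases >= 1, length(beta) == 14L)
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 p_clozapine = p_clozapine, p_female = p_female,
                 age_probs = age_probs, dose_probs = dose_probs,
                 p_polypharmacy = p_polypharmacy,
                 lithium_probs = lithium_probs,
                 p_fluvoxamine = p_fluvoxamine,
                 p_antiepileptic = p_antiepileptic,
                 p_history = p_history, beta = beta,
                 weibull_alpha = weibull_alpha, weibull_beta = weibull_beta,
                 missingness = missingness, p_partial_date = p_partial_date,
                 date_start = as.Date(date_start),
                 date_end = as.Date(date_end)),
            class = "sim_config")
}

#' @describeIn sim_config settings emulating the published clozapine-seizure
#'   profile: every report involves the study drug, effects at the reported
#'   adjusted RORs, onset scale 193 days with shape 1 (median onset about
#'   134 days, constant hazard).
#' @export
paperlike_config <- function(n_cases = 2000, seed, ...) {
  sim_config(n_cases = n_cases, seed = seed, p_clozapine = 1, ...)
}

# truncate complete ISO dates to year-month or year precision
.truncate_date <- function(x, to_year) {
  ifelse(to_year, substr(x, 1, 4), substr(x, 1, 7))
}

#' Simulate a four-table dump with ground truth
#'
#' Draws reports per [sim_config()]: study-drug reports get latent
#' covariates, a seizure outcome from the logistic model at the planted log
#' odds, and — for seizure cases — an onset day drawn from the Weibull law
#' (rounded up to keep positivity) anchoring the event date to the drug
#' start date. Missingness is applied after outcome generation (MCAR), and
#' the per-case exclusion fate implied by the applied masks is recorded in
#' the ground truth by construction, independent of the analysis code.
#'
#' @param config a [sim_config()].
#' @return list of class `jader_sim`: `tables` (demo/drug/reac/hist
#'   data.frames in the generator's column layout), `truth` (one row per
#'   case), `mapping` (column mappings for [read_jader_table()]),
#'   `term_query` (the demo term set used for seizure events), `config`.
#' @export
simulate_jader <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  q <- read_term_list(jaderpv_example("smq_convulsions_demo.txt"))
  with_seed(config$seed, {
    n <- config$n_cases
    id <- sprintf("C%07d", seq_len(n))
    cloz <- stats::runif(n) < config$p_clozapine

    # latent covariates (drawn for everyone; only meaningful where cloz)
    female <- stats::runif(n) < config$p_female
    age_cat <- sample(names(config$age_probs), n, TRUE, config$age_probs)
    dose_cat <- sample(names(config$dose_probs), n, TRUE, config$dose_probs)
    poly <- stats::runif(n) < config$p_polypharmacy
    lith_cat <- sample(names(config$lithium_probs), n, TRUE,
                       config$lithium_probs)
    fluvo <- stats::runif(n) < config$p_fluvoxamine
    antiep <- stats::runif(n) < config$p_antiepileptic
    hx <- stats::runif(n) < config$p_history

    b <- config$beta
    eta <- b[["(Intercept)"]] + b[["sex"]] * female +
      b[["age_30s"]] * (age_cat == "30s") +
      b[["age_40s"]] * (age_cat == "40s") +
      b[["age_50s"]] * (age_cat == "50s") +
      b[["age_ge60"]] * (age_cat == "ge60") +
      b[["dose_medium"]] * (dose_cat == "medium") +
      b[["dose_high"]] * (dose_cat == "high") +
      b[["polypharmacy"]] * poly +
      b[["lithium_low"]] * (lith_cat == "low") +
      b[["lithium_high"]] * (lith_cat == "high") +
      b[["fluvoxamine"]] * fluvo +
      b[["antiepileptic"]] * antiep +
      b[["convulsive_history"]] * hx
    y <- cloz & (stats::runif(n) < stats::plogis(eta))

    onset_day <- rep(NA_real_, n)
    onset_day[y] <- ceiling(stats::rweibull(sum(y),
                                            shape = config$weibull_beta,
                                            scale = config$weibull_alpha))

    # dose values within bands (mg/day, 25 mg steps for the study drug)
    dose_mg <- rep(NA_real_, n)
    dose_mg[dose_cat == "low"] <- sample(seq(25, 175, 25),
                                         sum(dose_cat == "low"), TRUE)
    dose_mg[dose_cat == "medium"] <- sample(seq(200, 400, 25),
                                            sum(dose_cat == "medium"), TRUE)
    dose_mg[dose_cat == "high"] <- sample(seq(425, 600, 25),
                                          sum(dose_cat == "high"), TRUE)
    lith_mg <- rep(NA_real_, n)
    lith_mg[lith_cat == "low"] <- sample(seq(200, 600, 100),
                                         sum(lith_cat == "low"), TRUE)
    lith_mg[lith_cat == "high"] <- sample(seq(700, 1200, 100),
                                          sum(lith_cat == "high"), TRUE)

    span <- as.numeric(config$date_end - config$date_start) - 400
    start_date <- config$date_start + sample.int(max(span, 1L), n, TRUE)

    # missingness masks (MCAR, drawn after outcomes)
    mr <- config$missingness
    m_sex <- stats::runif(n) < mr$sex
    u <- stats::runif(n)
    m_age <- u < mr$age
    m_age_lab <- !m_age & (u < mr$age + mr$age_nonnumeric)
    m_dose <- stats::runif(n) < mr$cloz_dose
    m_lith <- stats::runif(n) < mr$lithium_dose
    m_start <- stats::runif(n) < mr$start_date
    p_start <- !m_start & (stats::runif(n) < config$p_partial_date)
    p_start_year <- stats::runif(n) < 0.5
    m_onset <- stats::runif(n) < mr$onset_date
    p_onset <- !m_onset & (stats::runif(n) < config$p_partial_date)
    p_onset_year <- stats::runif(n) < 0.5

    ## DEMO -----------------------------------------------------------
    age_emit <- age_cat
    age_emit[age_cat == "le29"] <- sample(c("10s", "20s"),
                                          sum(age_cat == "le29"), TRUE,
                                          prob = c(0.15, 0.85))
    age_emit[age_cat == "ge60"] <- sample(c("60s", "70s", "80s"),
                                          sum(age_cat == "ge60"), TRUE,
                                          prob = c(0.6, 0.3, 0.1))
    sex_emit <- ifelse(female, "female", "male")
    sex_emit[m_sex] <- ""
    age_emit[m_age] <- ""
    age_emit[m_age_lab] <- sample(c("adult", "child", "elderly"),
                                  sum(m_age_lab), TRUE,
                                  prob = c(0.7, 0.1, 0.2))
    demo <- data.frame(case_id = id, sex = sex_emit, age = age_emit,
                       stringsAsFactors = FALSE)

    ## DRUG -----------------------------------------------------------
    start_emit <- format(start_date, "%Y-%m-%d")
    start_emit[p_start] <- .truncate_date(start_emit[p_start],
                                          p_start_year[p_start])
    start_emit[m_start] <- ""
    drug_blocks <- list()
    ci <- which(cloz)
    drug_blocks$cloz <- data.frame(
      case_id = id[ci], drug = "clozapine", involvement = "suspected",
      dose = ifelse(m_dose[ci], NA_real_, dose_mg[ci]),
      start_date = start_emit[ci], stringsAsFactors = FALSE)
    pi_ <- which(cloz & poly)
    if (length(pi_)) {
      drug_blocks$poly <- data.frame(
        case_id = id[pi_],
        drug = sample(c("risperidone", "olanzapine", "quetiapine",
                        "aripiprazole", "haloperidol"),
                      length(pi_), TRUE),
        involvement = "concomitant",
        dose = NA_real_, start_date = start_emit[pi_],
        stringsAsFactors = FALSE)
    }
    li <- which(cloz & lith_cat != "none")
    if (length(li)) {
      drug_blocks$lithium <- data.frame(
        case_id = id[li], drug = "lithium carbonate",
        involvement = "concomitant",
        dose = ifelse(m_lith[li], NA_real_, lith_mg[li]),
        start_date = start_emit[li], stringsAsFactors = FALSE)
    }
    fi <- which(cloz & fluvo)
    if (length(fi)) {
      drug_blocks$fluvo <- data.frame(
        case_id = id[fi], drug = "fluvoxamine",
        involvement = sample(c("concomitant", "interaction"),
                             length(fi), TRUE, prob = c(0.8, 0.2)),
        dose = NA_real_, start_date = start_emit[fi],
        stringsAsFactors = FALSE)
    }
    ai <- which(cloz & antiep)
    if (length(ai)) {
      drug_blocks$antiep <- data.frame(
        case_id = id[ai],
        drug = sample(c("valproate sodium", "carbamazepine", "lamotrigine",
                        "clonazepam", "diazepam"), length(ai), TRUE),
        involvement = "concomitant",
        dose = NA_real_, start_date = start_emit[ai],
        stringsAsFactors = FALSE)
    }
    bi <- which(!cloz)
    if (length(bi)) {
      drug_blocks$background <- data.frame(
        case_id = id[bi],
        drug = sample(.background_drugs, length(bi), TRUE),
        involvement = sample(c("suspected", "concomitant"),
                             length(bi), TRUE, prob = c(0.7, 0.3)),
        dose = NA_real_, start_date = start_emit[bi],
        stringsAsFactors = FALSE)
    }
    drug <- do.call(rbind, unname(drug_blocks))

    ## REAC -----------------------------------------------------------
    onset_date <- start_date + ifelse(y, onset_day - 1,
                                      sample.int(400L, n, TRUE))
    onset_emit <- format(onset_date, "%Y-%m-%d")
    onset_emit[p_onset] <- .truncate_date(onset_emit[p_onset],
                                          p_onset_year[p_onset])
    onset_emit[m_onset] <- ""
    pt <- character(n)
    pt[y] <- sample(q$terms, sum(y), TRUE)
    bg_seiz <- !y & !cloz & stats::runif(n) < 0.05
    pt[bg_seiz] <- sample(q$terms, sum(bg_seiz), TRUE)
    rest <- !y & !bg_seiz
    pt[rest] <- sample(.nonseizure_pts, sum(rest), TRUE)
    reac <- data.frame(case_id = id, pt = pt, onset_date = onset_emit,
                       stringsAsFactors = FALSE)

    ## HIST -----------------------------------------------------------
    hi <- which(cloz & hx)
    hist_blocks <- list()
    if (length(hi)) {
      hist_blocks$conv <- data.frame(
        case_id = id[hi],
        disease_pt = sample(c("Epilepsy", "Seizure"), length(hi), TRUE),
        stringsAsFactors = FALSE)
    }
    oi <- which(!(cloz & hx) & stats::runif(n) < 0.3)
    if (length(oi)) {
      hist_blocks$other <- data.frame(
        case_id = id[oi],
        disease_pt = sample(.benign_hist_pts, length(oi), TRUE),
        stringsAsFactors = FALSE)
    }
    hist <- if (length(hist_blocks)) do.call(rbind, unname(hist_blocks))
            else data.frame(case_id = character(0),
                            disease_pt = character(0),
                            stringsAsFactors = FALSE)

    ## ground truth, by construction from the masks ---------------------
    fate <- rep("background", n)
    fate[cloz] <- "retained"
    fate[cloz & m_sex] <- "unknown_sex"
    f_open <- cloz & !m_sex
    fate[f_open & (m_age | m_age_lab)] <- "unknown_age_or_nonnumeric"
    f_open <- f_open & !(m_age | m_age_lab)
    fate[f_open & m_dose] <- "unknown_cloz_dose"
    f_open <- f_open & !m_dose
    fate[f_open & lith_cat != "none" & m_lith] <- "unknown_lithium_dose"

    onset_fate <- rep(NA_character_, n)
    onset_fate[cloz & !y] <- "not_seizure"
    sz <- which(y)
    bad_dates <- m_start[sz] | p_start[sz] | m_onset[sz] | p_onset[sz]
    onset_fate[sz[bad_dates]] <- "missing_dates"
    onset_fate[sz[!bad_dates & onset_day[sz] > 1095]] <- "beyond_window"
    onset_fate[sz[!bad_dates & onset_day[sz] <= 1095]] <- "onset_ok"

    truth <- data.frame(
      case_id = id, clozapine = cloz, outcome = ifelse(cloz, y, NA),
      sex = ifelse(female, "female", "male"), age_cat = age_cat,
      cloz_dose_cat = dose_cat, cloz_dose_mg = dose_mg,
      polypharmacy = poly, lithium_cat = lith_cat, lithium_mg = lith_mg,
      fluvoxamine = fluvo, antiepileptic = antiep,
      convulsive_history = hx, onset_day = onset_day,
      fate = fate, onset_fate = onset_fate,
      stringsAsFactors = FALSE)

    mapping <- sim_table_mapping()

    structure(list(tables = list(demo = demo, drug = drug, reac = reac,
                                 hist = hist),
                   truth = truth, mapping = mapping, term_query = q,
                   config = config),
              class = "jader_sim")
  })
}

#' @export
print.jader_sim <- function(x, ...) {
  cat("<jader_sim> ", nrow(x$tables$demo), " cases (",
      sum(x$truth$clozapine), " study-drug, ",
      sum(x$truth$outcome, na.rm = TRUE), " seizure cases), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Column mapping of the simulator's table layout
#'
#' The simulator writes source-style column names (e.g. `age`, `drug`,
#' `dose`) rather than the package's normalized field names, so that the
#' mapping machinery of [read_jader_table()] is exercised on every
#' round-trip. This returns the mapping that reads them back.
#'
#' @return named list of per-table-kind column mappings.
#' @export
sim_table_mapping <- function() {
  list(
    DEMO = c(case_id = "case_id", sex = "sex", age_raw = "age"),
    DRUG = c(case_id = "case_id", drug_name = "drug",
             involvement = "involvement", dose_mg_per_day = "dose",
             start_date = "start_date"),
    REAC = c(case_id = "case_id", pt = "pt", onset_date = "onset_date"),
    HIST = c(case_id = "case_id", disease_pt = "disease_pt"))
}

#' Write simulated tables to delimited files
#'
#' Emits `demo`, `drug`, `reac`, `hist` files plus the ground truth and the
#' column mapping, in the directory given.
#'
#' @param sim a `jader_sim` object.
#' @param dir output directory (created if needed).
#' @param delim field delimiter.
#' @return named vector of the paths written, invisibly.
#' @export
write_jader_tables <- function(sim, dir, delim = ",") {
  stopifnot(inherits(sim, "jader_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(demo = file.path(dir, "demo.csv"),
             drug = file.path(dir, "drug.csv"),
             reac = file.path(dir, "reac.csv"),
             hist = file.path(dir, "hist.csv"),
             truth = file.path(dir, "truth.csv"))
  for (k in c("demo", "drug", "reac", "hist")) {
    utils::write.table(sim$tables[[k]], paths[[k]], sep = delim, na = "",
                       row.names = FALSE, qmethod = "double")
  }
  utils::write.table(sim$truth, paths[["truth"]], sep = delim, na = "",
                     row.names = FALSE, qmethod = "double")
  invisible(paths)
}

#' Read a simulated dump back into a case collection
#'
#' Convenience round-trip: reads the four files written by
#' [write_jader_tables()] with the simulator's column mapping and joins
#' them with [build_cases()].
#'
#' @param dir directory holding the four files.
#' @param delim field delimiter used when writing.
#' @return a `jader_cases` object.
#' @export
read_jader_dump <- function(dir, delim = ",") {
  mp <- sim_table_mapping()
  build_cases(
    read_jader_table(file.path(dir, "demo.csv"), "DEMO", mp$DEMO, delim = delim),
    read_jader_table(file.path(dir, "drug.csv"), "DRUG", mp$DRUG, delim = delim),
    read_jader_table(file.path(dir, "reac.csv"), "REAC", mp$REAC, delim = delim),
    read_jader_table(file.path(dir, "hist.csv"), "HIST", mp$HIST, delim = delim))
}

#' Build a case collection directly from a simulation (no files)
#'
#' Normalizes the in-memory simulated tables through the same mapping the
#' file reader uses, then joins them. Useful for large runs where writing a
#' dump to disk is unnecessary.
#'
#' @param sim a `jader_sim` object.
#' @return a `jader_cases` object.
#' @export
cases_from_sim <- function(sim) {
  stopifnot(inherits(sim, "jader_sim"))
  t <- sim$tables
  demo <- data.frame(case_id = t$demo$case_id,
                     sex = ifelse(t$demo$sex %in% c("male", "female"),
                                  t$demo$sex, "unknown"),
                     age_raw = t$demo$age, stringsAsFactors = FALSE)
  drug <- data.frame(case_id = t$drug$case_id,
                     drug_name = normalize_name(t$drug$drug),
                     involvement = t$drug$involvement,
                     dose_mg_per_day = t$drug$dose,
                     start_date = ifelse(t$drug$start_date == "",
                                         NA_character_, t$drug$start_date),
                     stringsAsFactors = FALSE)
  reac <- data.frame(case_id = t$reac$case_id, pt = t$reac$pt,
                     onset_date = ifelse(t$reac$onset_date == "",
                                         NA_character_, t$reac$onset_date),
                     stringsAsFactors = FALSE)
  hist <- data.frame(case_id = t$hist$case_id,
                     disease_pt = t$hist$disease_pt,
                     stringsAsFactors = FALSE)
  build_cases(demo, drug, reac, hist)
}
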