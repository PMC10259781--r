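# Shared fixtures: tiny hand-built tables and an independent brute-force
# Weibull oracle. All fixtures are built in code at test time.

demo_row <- function(case_id, sex = "male", age_raw = "20s") {
  data.frame(case_id = case_id, sex = sex, age_raw = age_raw,
             stringsAsFactors = FALSE)
}

drug_row <- function(case_id, drug_name = "clozapine",
                     involvement = "suspected", dose = NA_real_,
                     start_date = NA_character_) {
  data.frame(case_id = case_id, drug_name = normalize_name(drug_name),
             involvement = involvement, dose_mg_per_day = dose,
             start_date = start_date, stringsAsFactors = FALSE)
}

reac_row <- function(case_id, pt = "Seizure", onset_date = NA_character_) {
  data.frame(case_id = case_id, pt = pt, onset_date = onset_date,
             stringsAsFactors = FALSE)
}

hist_row <- function(case_id, disease_pt) {
  data.frame(case_id = case_id, disease_pt = disease_pt,
             stringsAsFactors = FALSE)
}

# one complete single-case collection, fully specified, seizure outcome
make_simple_case <- function(case_id = "A",
                             sex = "male", age_raw = "20s",
                             cloz_dose = 300, lithium_dose = NULL,
                             extra_drugs = NULL,
                             seizure = TRUE,
                             onset_date = "2020-03-01",
                             start_date = "2020-01-01",
                             hist_pt = NULL) {
  drugs <- drug_row(case_id, dose = cloz_dose, start_date = start_date)
  if (!is.null(lithium_dose)) {
    drugs <- rbind(drugs, drug_row(case_id, "lithium carbonate",
                                   "concomitant", lithium_dose, start_date))
  }
  if (!is.null(extra_drugs)) {
    for (d in extra_drugs) {
      drugs <- rbind(drugs, drug_row(case_id, d, "concomitant",
                                     NA_real_, start_date))
    }
  }
  reac <- if (seizure) reac_row(case_id, "Seizure", onset_date)
          else reac_row(case_id, "Nausea", onset_date)
  hist <- if (!is.null(hist_pt)) hist_row(case_id, hist_pt) else NULL
  build_cases(demo_row(case_id, sex, age_raw), drugs, reac, hist)
}

demo_query <- function() {
  read_term_list(jaderpv_example("smq_convulsions_demo.txt"))
}

# Brute-force 2-D grid search for the Weibull MLE over (log alpha,
# log beta): staged zoom, independent of the analytic fit path.
grid_weibull <- function(t, stages = 6L, pts = 41L) {
  ll <- function(la, lb) {
    sum(stats::dweibull(t, shape = exp(lb), scale = exp(la), log = TRUE))
  }
  la_rng <- c(log(min(t)) - 1, log(max(t)) + 1)
  lb_rng <- c(log(0.05), log(30))
  for (s in seq_len(stages)) {
    las <- seq(la_rng[1], la_rng[2], length.out = pts)
    lbs <- seq(lb_rng[1], lb_rng[2], length.out = pts)
    vals <- outer(las, lbs, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    la0 <- las[best[1]]; lb0 <- lbs[best[2]]
    da <- diff(la_rng) / (pts - 1); db <- diff(lb_rng) / (pts - 1)
    la_rng <- c(la0 - 2 * da, la0 + 2 * da)
    lb_rng <- c(lb0 - 2 * db, lb0 + 2 * db)
  }
  c(alpha = exp(la0), beta = exp(lb0))
}
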