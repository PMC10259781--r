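# Covariate construction and exclusion-ledger semantics.

test_that("age bands map to model categories with the under-30 reference", {
  expect_equal(as.character(categorize_age(c("0s", "10s", "20s"))),
               rep("le29", 3))
  expect_equal(as.character(categorize_age(c("30s", "40s", "50s"))),
               c("30s", "40s", "50s"))
  expect_equal(as.character(categorize_age(c("60s", "70s", "90s", "100s"))),
               rep("ge60", 4))
  expect_true(all(is.na(categorize_age(c("adult", "child", "elderly", "", NA)))))
})

test_that("dose bands use closed medium interval and cover (0, Inf) without gaps", {
  expect_equal(as.character(categorize_cloz_dose(c(199.9, 200, 400, 400.1, 600))),
               c("low", "medium", "medium", "high", "high"))
  expect_true(is.na(categorize_cloz_dose(NA_real_)))
  set.seed(20230612)
  d <- c(stats::runif(500, 0, 800), 0, 200, 400, 1e6)
  expect_false(anyNA(categorize_cloz_dose(d)))
})

test_that("multi-record dose resolution follows the configured rule", {
  cases <- build_cases(demo_row("A"),
                       rbind(drug_row("A", dose = 100),
                             drug_row("A", dose = 300),
                             drug_row("A", dose = NA)))
  expect_equal(unname(resolve_drug_dose(cases, "clozapine", "max")), 300)
  expect_equal(unname(resolve_drug_dose(cases, "clozapine", "first")), 100)
  expect_equal(unname(resolve_drug_dose(cases, "clozapine", "mean")), 200)
  all_missing <- build_cases(demo_row("B"), drug_row("B", dose = NA))
  expect_true(is.na(resolve_drug_dose(all_missing, "clozapine")))
})

test_that("lithium categorization distinguishes no use, banded use, and unknown dose", {
  no_li <- make_simple_case("A")
  expect_equal(as.character(categorize_lithium(no_li)), "none")
  low <- make_simple_case("B", lithium_dose = 600)
  expect_equal(as.character(categorize_lithium(low)), "low")
  high <- make_simple_case("C", lithium_dose = 900)
  expect_equal(as.character(categorize_lithium(high)), "high")
  unk <- make_simple_case("D", lithium_dose = NA_real_)
  expect_true(is.na(categorize_lithium(unk)))
})

test_that("polypharmacy flags other antipsychotics but never the study drug itself", {
  with_ap <- make_simple_case("A", extra_drugs = "risperidone")
  expect_true(flag_polypharmacy(with_ap))
  li_only <- make_simple_case("B", lithium_dose = 300)
  expect_false(flag_polypharmacy(li_only))
  dup_cloz <- build_cases(demo_row("C"),
                          rbind(drug_row("C", dose = 100), drug_row("C", dose = 200)))
  expect_false(flag_polypharmacy(dup_cloz))
})

test_that("antiepileptics started after seizure onset are nonconcomitant", {
  q <- demo_query()
  after <- build_cases(demo_row("A"),
                       rbind(drug_row("A", dose = 300, start_date = "2020-01-01"),
                             drug_row("A", "valproate sodium", "concomitant",
                                      NA, "2020-06-01")),
                       reac_row("A", "Seizure", "2020-03-01"))
  expect_false(flag_antiepileptic(after, flag_cases(after, q)))

  before <- build_cases(demo_row("B"),
                        rbind(drug_row("B", dose = 300, start_date = "2020-01-01"),
                              drug_row("B", "valproate sodium", "concomitant",
                                       NA, "2020-01-01")),
                        reac_row("B", "Seizure", "2020-03-01"))
  expect_true(flag_antiepileptic(before, flag_cases(before, q)))

  # missing start date on a non-seizure case: concomitant by default
  missing_start <- build_cases(demo_row("C"),
                               rbind(drug_row("C", dose = 300),
                                     drug_row("C", "diazepam", "concomitant")),
                               reac_row("C", "Nausea"))
  expect_true(flag_antiepileptic(missing_start, flag_cases(missing_start, q)))

  # partial start date gives no evidence of post-onset initiation
  partial <- build_cases(demo_row("D"),
                         rbind(drug_row("D", dose = 300, start_date = "2020-01-01"),
                               drug_row("D", "clonazepam", "concomitant",
                                        NA, "2020-06")),
                         reac_row("D", "Seizure", "2020-03-01"))
  expect_true(flag_antiepileptic(partial, flag_cases(partial, q)))
})

test_that("exclusions attribute to the first failing rule in the fixed order", {
  q <- demo_query()
  # unknown sex AND missing dose: counted as unknown_sex
  demo <- demo_row("A", sex = "unknown")
  cases <- build_cases(demo, drug_row("A", dose = NA), reac_row("A", "Nausea"))
  b <- build_cohort(cases, flag_cases(cases, q))
  expect_equal(b$ledger$n_retained, 0L)
  expect_equal(unname(b$ledger$exclusions["unknown_sex"]), 1L)
  expect_equal(sum(b$ledger$exclusions), 1L)
})

test_that("a fully specified case yields one complete cohort row", {
  q <- demo_query()
  cases <- make_simple_case("A", sex = "female", age_raw = "40s",
                            cloz_dose = 450, lithium_dose = 300,
                            extra_drugs = c("risperidone", "fluvoxamine"),
                            hist_pt = "Epilepsy")
  b <- build_cohort(cases, flag_cases(cases, q))
  expect_equal(nrow(b$cohort), 1L)
  row <- b$cohort
  expect_true(row$outcome_seizure)
  expect_equal(as.character(row$sex), "female")
  expect_equal(as.character(row$age_cat), "40s")
  expect_equal(as.character(row$cloz_dose_cat), "high")
  expect_true(row$polypharmacy)
  expect_equal(as.character(row$lithium_cat), "low")
  expect_true(row$fluvoxamine)
  expect_true(row$convulsive_history)
  expect_false(anyNA(row))
})

test_that("ledger conservation holds and counts match the generator's planted truth", {
  sim <- simulate_jader(sim_config(n_cases = 1500, seed = 20230612))
  cases <- cases_from_sim(sim)
  cz <- filter_drug_cases(cases, "clozapine")
  b <- build_cohort(cz, flag_cases(cz, demo_query()))
  led <- b$ledger
  expect_equal(led$n_input, led$n_retained + sum(led$exclusions))
  tr <- sim$truth[sim$truth$clozapine, ]
  expect_equal(led$n_retained, sum(tr$fate == "retained"))
  for (r in names(led$exclusions)) {
    expect_equal(unname(led$exclusions[r]), sum(tr$fate == r), label = r)
  }
  # retained covariates equal the latent truth case by case
  m <- merge(b$cohort, tr, by = "case_id", suffixes = c("", ".true"))
  expect_equal(nrow(m), led$n_retained)
  expect_equal(as.character(m$sex), m$sex.true)
  expect_equal(as.character(m$age_cat), m$age_cat.true)
  expect_equal(as.character(m$cloz_dose_cat), m$cloz_dose_cat.true)
  expect_equal(as.character(m$lithium_cat), m$lithium_cat.true)
  expect_equal(m$polypharmacy, m$polypharmacy.true)
  expect_equal(m$fluvoxamine, m$fluvoxamine.true)
  expect_equal(m$antiepileptic, m$antiepileptic.true)
  expect_equal(m$convulsive_history, m$convulsive_history.true)
  expect_equal(m$outcome_seizure, m$outcome)
})

test_that("exclusion is monotone: restoring a missing field never excludes a case", {
  q <- demo_query()
  broken <- build_cases(demo_row("A", sex = "unknown", age_raw = "adult"),
                        drug_row("A", dose = NA), reac_row("A", "Nausea"))
  fixed <- build_cases(demo_row("A", sex = "male", age_raw = "30s"),
                       drug_row("A", dose = 250), reac_row("A", "Nausea"))
  expect_equal(build_cohort(broken, flag_cases(broken, q))$ledger$n_retained, 0L)
  expect_equal(build_cohort(fixed, flag_cases(fixed, q))$ledger$n_retained, 1L)
})
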