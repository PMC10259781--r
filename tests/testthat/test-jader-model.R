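# Ingest, join and drug-filter semantics of the four-table model.

write_tmp <- function(df, delim = ",") {
  f <- tempfile(fileext = ".csv")
  utils::write.table(df, f, sep = delim, row.names = FALSE, na = "",
                     qmethod = "double")
  f
}

test_that("read_jader_table maps columns, preserves rows, and treats unmappable enums as unknown", {
  f <- write_tmp(data.frame(id = c("A", "B", "C"),
                            gender = c("male", "female", ""),
                            age_band = c("20s", "adult", "")))
  demo <- read_jader_table(f, "DEMO",
                           mapping = c(case_id = "id", sex = "gender",
                                       age_raw = "age_band"))
  expect_equal(nrow(demo), 3L)
  expect_equal(demo$sex, c("male", "female", "unknown"))
  # verbatim age strings, including the empty one
  expect_equal(demo$age_raw, c("20s", "adult", ""))
})

test_that("involvement labels map to the three categories via the value map", {
  f <- write_tmp(data.frame(case_id = c("A", "A", "B"),
                            drug_name = c("Clozapine ", "lithium carbonate", "x"),
                            involvement = c("suspected", "interaction", "oddball"),
                            dose_mg_per_day = c("300", "600 mg", ""),
                            start_date = c("2020-01-01", "2020-01", "")))
  drug <- read_jader_table(f, "DRUG")
  expect_equal(drug$involvement, c("suspected", "interaction", "unknown"))
  expect_equal(drug$drug_name[1], "clozapine")   # normalized
  expect_equal(drug$dose_mg_per_day, c(300, 600, NA))
  expect_equal(drug$start_date, c("2020-01-01", "2020-01", NA))
})

test_that("a mapping missing a required column raises a configuration error naming it", {
  f <- write_tmp(data.frame(id = "A", gender = "male", age_band = "20s"))
  expect_error(read_jader_table(f, "DEMO", mapping = c(case_id = "id", sex = "gender")),
               "age_raw")
  expect_error(read_jader_table(f, "DEMO",
                                mapping = c(case_id = "id", sex = "gender",
                                            age_raw = "nope")),
               "nope")
  expect_error(read_jader_table(tempfile(), "DEMO"), "cannot read")
})

test_that("build_cases joins one case per DEMO id and collects orphans", {
  demo <- rbind(demo_row("A"), demo_row("B"))
  drug <- rbind(drug_row("A"), drug_row("A", "risperidone"), drug_row("C"))
  cases <- build_cases(demo, drug, NULL, NULL)
  expect_equal(n_cases(cases), 2L)
  expect_equal(sum(cases$drug$case_id == "A"), 2L)
  expect_equal(sum(cases$drug$case_id == "B"), 0L)
  expect_equal(cases$orphans$drug$case_id, "C")
  # empty REAC input -> every case has zero event rows
  expect_equal(nrow(cases$reac), 0L)
})

test_that("duplicate DEMO ids are a validation error listing the ids", {
  demo <- rbind(demo_row("A"), demo_row("A"), demo_row("B"))
  expect_error(build_cases(demo, NULL, NULL, NULL), "duplicate.*A")
})

test_that("join conserves rows: every child row lands in a case or the orphan report", {
  sim <- simulate_jader(sim_config(n_cases = 300, seed = 11))
  cases <- cases_from_sim(sim)
  expect_equal(n_cases(cases), 300L)
  for (k in c("drug", "reac", "hist")) {
    expect_equal(nrow(cases[[k]]) + nrow(cases$orphans[[k]]),
                 nrow(sim$tables[[k]]))
  }
})

test_that("file round-trip reproduces the generator's in-memory truth losslessly", {
  sim <- simulate_jader(sim_config(n_cases = 500, seed = 42))
  dir <- tempfile()
  write_jader_tables(sim, dir)
  cases <- read_jader_dump(dir)
  direct <- cases_from_sim(sim)
  expect_equal(cases$demo, direct$demo)
  # byte-identical age and preferred-term strings
  expect_identical(cases$demo$age_raw, sim$tables$demo$age)
  expect_identical(cases$reac$pt, sim$tables$reac$pt)
  expect_equal(cases$drug$dose_mg_per_day, direct$drug$dose_mg_per_day)
  expect_equal(cases$drug$start_date, direct$drug$start_date)
})

test_that("tab-delimited files read back identically", {
  sim <- simulate_jader(sim_config(n_cases = 120, seed = 8))
  dir <- tempfile()
  write_jader_tables(sim, dir, delim = "\t")
  f <- file.path(dir, "demo.csv")
  demo <- read_jader_table(f, "DEMO",
                           mapping = c(case_id = "case_id", sex = "sex",
                                       age_raw = "age"),
                           delim = "\t")
  expect_identical(demo$age_raw, sim$tables$demo$age)
})

test_that("filter_drug_cases keeps any involvement category, matches the generator count, and is idempotent", {
  # concomitant-only mention is retained
  demo <- rbind(demo_row("A"), demo_row("B"))
  drug <- rbind(drug_row("A", "clozapine", involvement = "concomitant"),
                drug_row("B", "olanzapine"))
  cases <- build_cases(demo, drug, NULL, NULL)
  kept <- filter_drug_cases(cases, "clozapine")
  expect_equal(case_ids(kept), "A")
  expect_equal(n_cases(filter_drug_cases(cases, "quetiapine")), 0L)

  sim <- simulate_jader(sim_config(n_cases = 500, seed = 13))
  cases <- cases_from_sim(sim)
  cz <- filter_drug_cases(cases, "clozapine")
  expect_setequal(case_ids(cz), sim$truth$case_id[sim$truth$clozapine])
  twice <- filter_drug_cases(cz, "clozapine")
  expect_identical(case_ids(twice), case_ids(cz))
})

test_that("a synonym table folds brand names into the generic before matching", {
  demo <- demo_row("A")
  drug <- drug_row("A", "clozaril")
  cases <- build_cases(demo, drug, NULL, NULL)
  expect_equal(n_cases(filter_drug_cases(cases, "clozapine")), 0L)
  kept <- filter_drug_cases(cases, "clozapine",
                            synonyms = c(Clozaril = "clozapine"))
  expect_equal(case_ids(kept), "A")
})
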