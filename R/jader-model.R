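# Four-table spontaneous-report model: DEMO (demographics), DRUG (drug
# records), REAC (adverse events), HIST (medical history), all keyed by a
# case identification number. Ingest is lossless: age bands and preferred
# terms are kept verbatim; partial dates are kept partial.

.jader_fields <- list(
  DEMO = list(required = c("case_id", "sex", "age_raw"), optional = character()),
  DRUG = list(required = c("case_id", "drug_name", "involvement"),
              optional = c("dose_mg_per_day", "start_date")),
  REAC = list(required = c("case_id", "pt"), optional = "onset_date"),
  HIST = list(required = c("case_id", "disease_pt"), optional = character())
)

#' Default column and value mappings for the four report tables
#'
#' A mapping names, for each normalized field, the column holding it in the
#' source file. The real JADER dump uses Japanese headers, so the mapping is
#' configuration, not convention; the default simply assumes the normalized
#' names themselves (the layout the bundled simulator writes). Value maps
#' translate source labels for the `sex` and `involvement` enumerations;
#' unmapped labels become the unknown state rather than an error.
#'
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"HIST"`.
#' @return a named character vector (field -> source column).
#' @export
jader_default_mapping <- function(table_kind = c("DEMO", "DRUG", "REAC", "HIST")) {
  table_kind <- match.arg(table_kind)
  f <- .jader_fields[[table_kind]]
  stats::setNames(nm = c(f$required, f$optional))
}

#' @describeIn jader_default_mapping default source-label translations for
#'   enumerated fields.
#' @export
jader_default_values <- function() {
  list(
    sex = c(male = "male", female = "female",
            m = "male", f = "female"),
    involvement = c(suspected = "suspected", concomitant = "concomitant",
                    interaction = "interaction")
  )
}

#' Read one report table from a delimited file
#'
#' Reads a DEMO/DRUG/REAC/HIST table and normalizes it to the package's
#' column layout. One output row per input data row. Enumerated fields with
#' unrecognized labels become `"unknown"`; blank keys in non-key fields
#' become `NA`/empty as appropriate. Dates are kept as strings so that
#' partial dates (year or year-month) survive ingest; completeness is only
#' judged at analysis time.
#'
#' @param path path to a delimited text file with a header row.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"HIST"`.
#' @param mapping named character vector, normalized field -> source column
#'   name. Must cover the required fields of `table_kind`.
#' @param values value-label maps as from [jader_default_values()].
#' @param delim field delimiter (`","` or `"\t"`).
#' @param encoding file encoding (e.g. `"UTF-8"`, `"CP932"`).
#' @return a data.frame with the normalized columns for `table_kind`.
#' @export
read_jader_table <- function(path,
                             table_kind = c("DEMO", "DRUG", "REAC", "HIST"),
                             mapping = NULL,
                             values = jader_default_values(),
                             delim = ",",
                             encoding = "UTF-8") {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) stop("cannot read table file: ", path, call. = FALSE)
  if (is.null(mapping)) mapping <- jader_default_mapping(table_kind)
  f <- .jader_fields[[table_kind]]
  missing_req <- setdiff(f$required, names(mapping))
  if (length(missing_req)) {
    stop("mapping for ", table_kind, " lacks required field(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", fileEncoding = encoding,
                           check.names = FALSE, na.strings = NULL,
                           comment.char = "", stringsAsFactors = FALSE)
  # optional fields may be left out of the file only if left out of the mapping
  absent <- setdiff(unname(mapping), names(raw))
  if (length(absent)) {
    stop("column(s) named in mapping not found in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  get_col <- function(field, default = NA_character_) {
    if (field %in% names(mapping)) raw[[mapping[[field]]]]
    else rep(default, nrow(raw))
  }
  out <- data.frame(case_id = trimws(get_col("case_id")),
                    stringsAsFactors = FALSE)
  if (table_kind == "DEMO") {
    sex_raw <- normalize_name(get_col("sex"))
    sex <- unname(values$sex[sex_raw])
    sex[is.na(sex)] <- "unknown"
    out$sex <- sex
    out$age_raw <- get_col("age_raw")   # verbatim, no trimming even
  } else if (table_kind == "DRUG") {
    inv_raw <- normalize_name(get_col("involvement"))
    inv <- unname(values$involvement[inv_raw])
    inv[is.na(inv)] <- "unknown"
    out$drug_name <- normalize_name(get_col("drug_name"))
    out$involvement <- inv
    out$dose_mg_per_day <- parse_dose(get_col("dose_mg_per_day"))
    out$start_date <- trimws(get_col("start_date"))
    out$start_date[out$start_date == "" | is.na(out$start_date)] <- NA_character_
  } else if (table_kind == "REAC") {
    out$pt <- get_col("pt")
    out$onset_date <- trimws(get_col("onset_date"))
    out$onset_date[out$onset_date == "" | is.na(out$onset_date)] <- NA_character_
  } else {
    out$disease_pt <- get_col("disease_pt")
  }
  out
}

#' Join the four tables into a case collection
#'
#' Builds the relational case structure keyed by the case identification
#' number: exactly one case per distinct DEMO row. DRUG/REAC/HIST rows whose
#' case id does not appear in DEMO are collected into an orphan report —
#' they are never silently dropped.
#'
#' @param demo,drug,reac,hist normalized data.frames as returned by
#'   [read_jader_table()]. `drug`, `reac`, `hist` may be `NULL` or empty.
#' @return an object of class `jader_cases`: a list with the four tables
#'   (child tables restricted to known cases) and an `orphans` list.
#' @export
build_cases <- function(demo, drug = NULL, reac = NULL, hist = NULL) {
  stopifnot(is.data.frame(demo), "case_id" %in% names(demo))
  if (any(!nzchar(demo$case_id) | is.na(demo$case_id))) {
    stop("DEMO contains empty case ids", call. = FALSE)
  }
  dup <- unique(demo$case_id[duplicated(demo$case_id)])
  if (length(dup)) {
    stop("duplicate DEMO rows for case id(s): ",
         paste(utils::head(dup, 10L), collapse = ", "),
         if (length(dup) > 10L) " ..." else "", call. = FALSE)
  }
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
  if (is.null(drug)) drug <- empty(c("case_id", "drug_name", "involvement",
                                     "dose_mg_per_day", "start_date"))
  if (is.null(reac)) reac <- empty(c("case_id", "pt", "onset_date"))
  if (is.null(hist)) hist <- empty(c("case_id", "disease_pt"))
  split_known <- function(tab) {
    known <- tab$case_id %in% demo$case_id
    list(known = tab[known, , drop = FALSE],
         orphan = tab[!known, , drop = FALSE])
  }
  d <- split_known(drug); r <- split_known(reac); h <- split_known(hist)
  structure(list(demo = demo, drug = d$known, reac = r$known, hist = h$known,
                 orphans = list(drug = d$orphan, reac = r$orphan,
                                hist = h$orphan)),
            class = "jader_cases")
}

#' @export
print.jader_cases <- function(x, ...) {
  n_orph <- sum(vapply(x$orphans, nrow, integer(1)))
  cat("<jader_cases> ", nrow(x$demo), " cases; ",
      nrow(x$drug), " drug rows, ", nrow(x$reac), " event rows, ",
      nrow(x$hist), " history rows",
      if (n_orph) paste0("; ", n_orph, " orphan rows") else "", "\n", sep = "")
  invisible(x)
}

#' @describeIn build_cases case ids in DEMO order.
#' @param x a `jader_cases` object.
#' @export
case_ids <- function(x) {
  stopifnot(inherits(x, "jader_cases"))
  x$demo$case_id
}

#' @describeIn build_cases number of cases.
#' @export
n_cases <- function(x) nrow(x$demo)

# restrict a case collection to a subset of ids (DEMO order preserved)
subset_cases <- function(x, ids) {
  keep <- x$demo$case_id %in% ids
  structure(list(demo = x$demo[keep, , drop = FALSE],
                 drug = x$drug[x$drug$case_id %in% ids, , drop = FALSE],
                 reac = x$reac[x$reac$case_id %in% ids, , drop = FALSE],
                 hist = x$hist[x$hist$case_id %in% ids, , drop = FALSE],
                 orphans = x$orphans),
            class = "jader_cases")
}

#' Select the cases reporting a given drug
#'
#' Keeps every case with at least one drug record whose normalized name
#' matches `drug_name`, in any involvement category (suspected, concomitant
#' or interaction). Case order is preserved and the operation is idempotent.
#'
#' @param cases a `jader_cases` object.
#' @param drug_name generic drug name (normalized internally).
#' @param synonyms optional named character vector mapping alternative
#'   (e.g. brand) names to the generic name; applied to the drug table
#'   before matching.
#' @return a `jader_cases` object containing only the matching cases.
#' @export
filter_drug_cases <- function(cases, drug_name, synonyms = NULL) {
  stopifnot(inherits(cases, "jader_cases"), nzchar(drug_name))
  target <- normalize_name(drug_name)
  nm <- cases$drug$drug_name
  if (!is.null(synonyms)) {
    syn <- stats::setNames(normalize_name(synonyms), normalize_name(names(synonyms)))
    hit <- nm %in% names(syn)
    nm[hit] <- unname(syn[nm[hit]])
  }
  ids <- unique(cases$drug$case_id[nm == target])
  subset_cases(cases, ids)
}
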