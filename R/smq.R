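# Standardized MedDRA Query (SMQ) case definition: a named set of preferred
# terms used to flag adverse-event rows (outcome) and medical-history rows
# (a history covariate). The package bundles only a small demonstration term
# list; the licensed full SMQ term list is user-supplied.

#' Construct a term query (an SMQ-style preferred-term set)
#'
#' @param terms character vector of preferred terms. Duplicates (after
#'   normalization) are dropped with a warning; the set must be non-empty.
#' @param smq_code SMQ code string, e.g. `"20000079"`.
#' @param scope `"narrow"` or `"broad"`.
#' @param name optional human-readable name.
#' @return an object of class `term_query`.
#' @export
term_query <- function(terms, smq_code = "", scope = c("narrow", "broad"),
                       name = "") {
  scope <- match.arg(scope)
  terms <- terms[!is.na(terms) & nzchar(trimws(terms))]
  if (!length(terms)) stop("term list is empty", call. = FALSE)
  key <- normalize_name(terms)
  if (anyDuplicated(key)) {
    warning("dropping ", sum(duplicated(key)), " duplicated term(s)",
            call. = FALSE)
    terms <- terms[!duplicated(key)]
  }
  structure(list(smq_code = smq_code, scope = scope, name = name,
                 terms = trimws(terms)),
            class = "term_query")
}

#' @export
print.term_query <- function(x, ...) {
  cat("<term_query> ", if (nzchar(x$name)) paste0(x$name, " ") else "",
      if (nzchar(x$smq_code)) paste0("(SMQ", x$smq_code, ", ", x$scope, " scope) ")
      else "", length(x$terms), " preferred terms\n", sep = "")
  invisible(x)
}

#' @describeIn term_query number of terms in the set.
#' @param x a `term_query`.
#' @export
n_terms <- function(x) length(x$terms)

#' Read a term list file
#'
#' Plain-text format: one preferred term per line; `#` starts a comment;
#' optional header lines `code: <smq code>`, `scope: narrow|broad` and
#' `name: <label>`.
#'
#' @param path path to the term-list file.
#' @return a [term_query()].
#' @export
#' @examples
#' q <- read_term_list(jaderpv_example("smq_convulsions_demo.txt"))
#' n_terms(q)
read_term_list <- function(path) {
  if (!file.exists(path)) stop("cannot read term list: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- function(key) {
    m <- grepl(paste0("^", key, "\\s*:"), lines, ignore.case = TRUE)
    if (any(m)) trimws(sub("^[^:]*:", "", lines[which(m)[1L]])) else ""
  }
  code <- hdr("code"); scope <- hdr("scope"); name <- hdr("name")
  terms <- lines[!grepl("^(code|scope|name)\\s*:", lines, ignore.case = TRUE)]
  term_query(terms,
             smq_code = code,
             scope = if (nzchar(scope)) match.arg(tolower(scope),
                                                  c("narrow", "broad"))
                     else "narrow",
             name = name)
}

#' Flag cases against a term query
#'
#' For every case: is it a target-event case (any adverse-event preferred
#' term in the query), what is its event onset date (the earliest complete
#' onset date over matching events — missing if none is complete), and does
#' its medical history match the query (a history of the disorder).
#' Matching is exact on normalized strings. A partial onset date still makes
#' a case a target case; it only withholds the onset date, which matters
#' downstream in the time-to-onset analysis.
#'
#' @param cases a `jader_cases` object.
#' @param query a [term_query()].
#' @return a data.frame with one row per case (DEMO order): `case_id`,
#'   `is_seizure_case`, `seizure_onset_date` (`Date`, `NA` when unknown),
#'   `has_convulsive_history`.
#' @export
flag_cases <- function(cases, query) {
  stopifnot(inherits(cases, "jader_cases"), inherits(query, "term_query"))
  key <- normalize_name(query$terms)
  ids <- cases$demo$case_id

  reac_hit <- normalize_name(cases$reac$pt) %in% key
  hit_ids <- unique(cases$reac$case_id[reac_hit])

  onset <- rep(as.Date(NA), length(ids))
  names(onset) <- ids
  if (any(reac_hit)) {
    d <- parse_complete_date(cases$reac$onset_date[reac_hit])
    cid <- cases$reac$case_id[reac_hit]
    ok <- !is.na(d)
    if (any(ok)) {
      first <- tapply(d[ok], cid[ok], min)
      onset[names(first)] <- as.Date(first, origin = "1970-01-01")
    }
  }

  hist_hit <- normalize_name(cases$hist$disease_pt) %in% key
  hist_ids <- unique(cases$hist$case_id[hist_hit])

  data.frame(case_id = ids,
             is_seizure_case = ids %in% hit_ids,
             seizure_onset_date = unname(onset),
             has_convulsive_history = ids %in% hist_ids,
             stringsAsFactors = FALSE)
}
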