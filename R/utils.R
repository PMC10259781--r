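#' Normalize a drug or term name for matching
#'
#' Matching throughout the package is exact on a normalized string:
#' case-folded, leading/trailing whitespace trimmed, internal runs of
#' whitespace collapsed to a single space. Brand-to-generic translation is
#' the caller's responsibility (supply a synonym table before matching).
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_name(c("  Clozapine ", "LITHIUM   CARBONATE"))
normalize_name <- function(x) {
  x <- as.character(x)
  x <- trimws(x)
  x <- gsub("[[:space:]]+", " ", x)
  tolower(x)
}

#' Parse possibly partial calendar dates
#'
#' Spontaneous reports carry dates that may be complete (day precision),
#' partial (year or year-month only), or absent. `parse_complete_date()`
#' returns a `Date` for complete dates and `NA` otherwise; partial dates are
#' deliberately not imputed. Accepted complete forms: `YYYY-MM-DD`,
#' `YYYY/MM/DD`, `YYYYMMDD`.
#'
#' @param x character vector of raw date strings (may contain `NA` or "").
#' @return `Date` vector; `NA` where the date is missing or partial.
#' @export
#' @examples
#' parse_complete_date(c("2020-03-01", "2020-03", "2020", "", "20200301"))
parse_complete_date <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  iso <- grepl("^\\d{4}[-/]\\d{1,2}[-/]\\d{1,2}$", x)
  compact <- grepl("^\\d{8}$", x)
  out <- rep(as.Date(NA), length(x))
  if (any(iso, na.rm = TRUE)) {
    ok <- which(!is.na(x) & iso)
    out[ok] <- as.Date(gsub("/", "-", x[ok]), format = "%Y-%m-%d")
  }
  if (any(compact, na.rm = TRUE)) {
    ok <- which(!is.na(x) & compact)
    out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  }
  out
}

#' @describeIn parse_complete_date `TRUE` where the string holds a date at
#'   day precision.
#' @export
is_complete_date <- function(x) !is.na(parse_complete_date(x))

#' @describeIn parse_complete_date `TRUE` where the string holds a partial
#'   (year or year-month) date.
#' @export
is_partial_date <- function(x) {
  x <- trimws(as.character(x))
  grepl("^\\d{4}([-/]\\d{1,2})?$", x) | grepl("^\\d{6}$", x)
}

#' Parse a dose field to mg/day
#'
#' Accepts plain numbers and numbers with a trailing unit annotation
#' ("300", "300mg", "300 mg/day"). Anything else (including blanks) maps to
#' `NA`. Negative values are rejected as `NA`.
#'
#' @param x character or numeric vector.
#' @return numeric vector (mg/day).
#' @export
parse_dose <- function(x) {
  if (is.numeric(x)) {
    out <- as.numeric(x)
  } else {
    x <- trimws(as.character(x))
    x[x == ""] <- NA_character_
    has <- !is.na(x) & grepl("^[0-9]*\\.?[0-9]+(\\s*(mg|mg/day|mg/d))?$",
                             x, ignore.case = TRUE)
    out <- rep(NA_real_, length(x))
    out[has] <- as.numeric(sub("^([0-9]*\\.?[0-9]+).*$", "\\1", x[has]))
  }
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Path to a bundled example file
#'
#' @param file file name under the package's `extdata` directory; omit to
#'   list the available files.
#' @return a file path (or a vector of file names).
#' @export
jaderpv_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "jaderpv"))
  } else {
    path <- system.file("extdata", file, package = "jaderpv", mustWork = FALSE)
    if (!nzchar(path)) stop("no bundled file named '", file, "'", call. = FALSE)
    path
  }
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
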