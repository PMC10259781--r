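# Time-to-onset analysis. With no at-risk denominator in a spontaneous
# reporting system, onset hazard shape is summarized by fitting a Weibull
# distribution to per-report onset times: shape beta < 1 means a hazard
# decreasing over time (early failure), beta near 1 a constant hazard
# (random failure), beta > 1 an increasing hazard (wear-out failure), read
# off the 95% CI of beta.

#' Onset-day sample for target-event cases
#'
#' For each target-event case, the onset day is the difference between the
#' event onset date and the earliest complete start date of the study drug,
#' plus one under the default convention (so a same-day onset is day 1, a
#' positive time as Weibull support requires). Cases with a missing or
#' partial date on either side, or with onset before drug start, count as
#' missing-date exclusions; onset days beyond the analysis window (1,095
#' days by default) are window exclusions.
#'
#' @param cases a `jader_cases` object (study-drug cases).
#' @param flags output of [flag_cases()] for the same cases.
#' @param drug_name study drug whose start date anchors the clock.
#' @param window_days analysis window in days.
#' @param convention `"plus1"` (difference + 1) or `"halfday"` (raw
#'   difference with same-day onset scored as 0.5 days).
#' @return object of class `onset_sample`: `case_ids`, `days`,
#'   `n_excluded_missing_dates`, `n_excluded_beyond_window`, `window_days`.
#' @export
onset_days <- function(cases, flags, drug_name = "clozapine",
                       window_days = 1095,
                       convention = c("plus1", "halfday")) {
  convention <- match.arg(convention)
  stopifnot(inherits(cases, "jader_cases"), window_days > 0)
  fl <- flags[match(cases$demo$case_id, flags$case_id), , drop = FALSE]
  fl <- fl[fl$is_seizure_case, , drop = FALSE]

  target <- normalize_name(drug_name)
  rows <- cases$drug[cases$drug$drug_name %in% target, , drop = FALSE]
  start_all <- parse_complete_date(rows$start_date)
  ok <- !is.na(start_all)
  start <- rep(as.Date(NA), nrow(fl))
  if (any(ok)) {
    first <- tapply(start_all[ok], rows$case_id[ok], min)
    m <- match(fl$case_id, names(first))
    start[!is.na(m)] <- as.Date(unname(first[m[!is.na(m)]]),
                                origin = "1970-01-01")
  }

  diff_days <- as.numeric(fl$seizure_onset_date - start)
  day <- switch(convention,
                plus1 = diff_days + 1,
                halfday = ifelse(diff_days == 0, 0.5, diff_days))
  usable <- !is.na(day) & day > 0
  beyond <- usable & day > window_days
  keep <- usable & !beyond

  structure(list(case_ids = fl$case_id[keep],
                 days = day[keep],
                 n_excluded_missing_dates = sum(!usable),
                 n_excluded_beyond_window = sum(beyond),
                 window_days = window_days,
                 convention = convention),
            class = "onset_sample")
}

#' @describeIn onset_days assemble an `onset_sample` directly from onset
#'   days (e.g. simulated values); exclusions are zero.
#' @param days positive onset days.
#' @export
onset_sample <- function(days, window_days = 1095) {
  stopifnot(all(days > 0), all(days <= window_days))
  structure(list(case_ids = as.character(seq_along(days)), days = days,
                 n_excluded_missing_dates = 0L, n_excluded_beyond_window = 0L,
                 window_days = window_days, convention = "plus1"),
            class = "onset_sample")
}

#' @export
print.onset_sample <- function(x, ...) {
  cat("<onset_sample> n = ", length(x$days),
      " (", x$n_excluded_missing_dates, " excluded for missing dates, ",
      x$n_excluded_beyond_window, " beyond ", x$window_days, " days)\n",
      sep = "")
  invisible(x)
}

#' Median, quartiles and cumulative proportion of an onset sample
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the inclusive method), which makes the
#' median/IQR bit-reproducible across runs.
#'
#' @param sample an `onset_sample`.
#' @param quartile_type `stats::quantile` algorithm type.
#' @return list: `n`, `median`, `q1`, `q3`.
#' @export
onset_summary <- function(sample, quartile_type = 7) {
  stopifnot(inherits(sample, "onset_sample"), length(sample$days) > 0)
  q <- stats::quantile(sample$days, probs = c(0.25, 0.5, 0.75),
                       type = quartile_type, names = FALSE)
  list(n = length(sample$days), median = q[2], q1 = q[1], q3 = q[3])
}

#' @describeIn onset_summary proportion of onsets at or before day `t`.
#' @param t day threshold (e.g. 365 for one year).
#' @export
proportion_within <- function(sample, t) {
  stopifnot(inherits(sample, "onset_sample"), length(sample$days) > 0)
  sum(sample$days <= t) / length(sample$days)
}

# negative log-likelihood of Weibull(shape = exp(lb), scale = exp(la));
# returns a large finite value where the optimizer wanders into overflow
.weib_nll <- function(par, t) {
  ll <- suppressWarnings(
    sum(stats::dweibull(t, shape = exp(par[2]), scale = exp(par[1]),
                        log = TRUE)))
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Maximum-likelihood Weibull fit of onset times
#'
#' Fits the two-parameter Weibull density
#' f(t) = (beta/alpha) (t/alpha)^(beta-1) exp(-(t/alpha)^beta) to the onset
#' days by maximizing the log-likelihood over (log alpha, log beta) with
#' BFGS. 95% confidence intervals are Wald intervals on the log-parameter
#' scale from the observed information, back-transformed — so they respect
#' positivity. The failure type is read off the shape CI (see
#' [classify_failure()]).
#'
#' @param sample an `onset_sample` or a numeric vector of positive days.
#' @return object of class `weibull_fit`: `alpha` (scale, days), `beta`
#'   (shape), `alpha_ci`, `beta_ci`, `loglik`, `n`, `failure_type`.
#' @export
fit_weibull <- function(sample) {
  t <- if (inherits(sample, "onset_sample")) sample$days else as.numeric(sample)
  if (length(t) < 3L) stop("need at least 3 onset times", call. = FALSE)
  if (any(t <= 0)) stop("onset times must be positive", call. = FALSE)
  s <- stats::sd(log(t))
  if (!is.finite(s) || s == 0) {
    stop("degenerate sample (all onset times equal); shape is unbounded",
         call. = FALSE)
  }
  # moment start: sd(log T) = (pi/sqrt(6))/beta for Weibull
  b0 <- (pi / sqrt(6)) / s
  start <- c(log(mean(t)), log(b0))
  opt <- stats::optim(start, .weib_nll, t = t, method = "BFGS",
                      hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("Weibull fit did not converge (optim code ", opt$convergence, ")",
         call. = FALSE)
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) < 0)) {
    stop("observed information is singular at the optimum; ",
         "cannot form Wald intervals", call. = FALSE)
  }
  la <- opt$par[1]; lb <- opt$par[2]
  se <- sqrt(diag(vc))
  beta_ci <- exp(lb + c(-1, 1) * .z95 * se[2])
  structure(list(alpha = exp(la), beta = exp(lb),
                 alpha_ci = exp(la + c(-1, 1) * .z95 * se[1]),
                 beta_ci = beta_ci,
                 loglik = -opt$value, n = length(t),
                 failure_type = classify_failure(beta_ci[1], beta_ci[2])),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n = %d\n  scale alpha = %.2f days (95%% CI %.2f-%.2f)\n  shape beta  = %.3f (95%% CI %.3f-%.3f)\n  failure type: %s\n",
    x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
    x$beta, x$beta_ci[1], x$beta_ci[2], x$failure_type))
  invisible(x)
}

#' Classify the hazard by the Weibull shape confidence interval
#'
#' If the 95% CI of the shape includes 1 (boundaries inclusive), the hazard
#' is constant over time: random failure. If the lower limit exceeds 1, the
#' hazard increases: wear-out failure. If the upper limit is below 1, the
#' hazard decreases: early failure. The trichotomy is exhaustive and
#' mutually exclusive.
#'
#' @param ci_low,ci_high bounds of the shape 95% CI, `0 < ci_low <= ci_high`.
#' @return one of `"early"`, `"random"`, `"wearout"`.
#' @export
#' @examples
#' classify_failure(0.9, 1.1)
#' classify_failure(1.05, 1.4)
classify_failure <- function(ci_low, ci_high) {
  stopifnot(ci_low > 0, ci_low <= ci_high)
  if (ci_low > 1) "wearout"
  else if (ci_high < 1) "early"
  else "random"
}

#' Onset histogram over the analysis window
#'
#' Half-open bins `[0, w), [w, 2w), ...` covering the whole window (the
#' last bin may overrun it); empty tail bins are retained so histograms of
#' different samples align. Counts always sum to the sample size.
#'
#' @param sample an `onset_sample`.
#' @param bin_width_days bin width in days.
#' @return data.frame: `bin_start`, `bin_end`, `count`.
#' @export
onset_histogram <- function(sample, bin_width_days = 30) {
  stopifnot(inherits(sample, "onset_sample"), bin_width_days > 0)
  n_bins <- ceiling(sample$window_days / bin_width_days)
  starts <- (seq_len(n_bins) - 1L) * bin_width_days
  idx <- findInterval(sample$days, starts)   # days > 0 land in bins 1..n
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_start = starts, bin_end = starts + bin_width_days,
             count = counts)
}
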