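# Disproportionality estimation. In a spontaneous reporting system there is
# no exposure denominator, so the signal statistic is the reporting odds
# ratio: the odds of the target event among reports with a covariate level
# versus the reference level, crude (2x2 table) or adjusted (multivariate
# logistic regression, Wald intervals).

# two-sided 95% critical value, fixed for bit-stable output
.z95 <- 1.959964

#' Crude reporting odds ratio from a 2x2 table
#'
#' Cells: `a` target-event reports with the exposure, `b` other-event
#' reports with the exposure, `c` target-event reports without it, `d`
#' other-event reports without it. OR = ad/bc with the Wald interval
#' exp(log OR +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)). With a zero cell the
#' Haldane-Anscombe correction (add 0.5 to every cell) is applied when
#' `correction = TRUE`; otherwise the estimate is returned as undefined
#' (`NA` with `defined = FALSE`), never as an error.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param correction apply the 0.5 continuity correction when a cell is 0.
#' @param label label for the effect row.
#' @return one-row data.frame: `label`, `or`, `ci_low`, `ci_high`, `p`,
#'   `defined`, `corrected`.
#' @export
#' @examples
#' crude_ror(10, 90, 5, 95)
crude_ror <- function(a, b, c, d, correction = TRUE, label = "exposure") {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  zero <- any(cells == 0)
  corrected <- FALSE
  if (zero) {
    if (!correction) {
      return(data.frame(label = label, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, defined = FALSE,
                        corrected = FALSE, stringsAsFactors = FALSE))
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- log(or) / se
  data.frame(label = label,
             or = unname(or),
             ci_low = unname(exp(log(or) - .z95 * se)),
             ci_high = unname(exp(log(or) + .z95 * se)),
             p = unname(2 * stats::pnorm(-abs(z))),
             defined = TRUE, corrected = corrected,
             stringsAsFactors = FALSE)
}

#' Dummy-code a cohort for the reporting-odds model
#'
#' Treatment coding with the study's reference levels: male sex (by
#' default; configurable), age 29 and younger, low study-drug dose, no
#' lithium. Columns in fixed order: intercept; sex; four age dummies; two
#' dose dummies; polypharmacy; two lithium dummies; fluvoxamine;
#' antiepileptic; convulsive history — 13 dummies plus the intercept.
#'
#' @param cohort cohort data.frame from [build_cohort()].
#' @param sex_reference `"male"` or `"female"`.
#' @return list with `y` (0/1 outcome), `X` (design matrix), and `coding`
#'   (data.frame mapping columns to level-vs-reference labels).
#' @export
dummy_code <- function(cohort, sex_reference = c("male", "female")) {
  sex_reference <- match.arg(sex_reference)
  stopifnot(all(c("outcome_seizure", "sex", "age_cat", "cloz_dose_cat",
                  "polypharmacy", "lithium_cat", "fluvoxamine",
                  "antiepileptic", "convulsive_history") %in% names(cohort)))
  if (anyNA(cohort[, c("sex", "age_cat", "cloz_dose_cat", "lithium_cat")])) {
    stop("cohort rows must be complete; apply build_cohort() exclusions first",
         call. = FALSE)
  }
  n <- nrow(cohort)
  sex_other <- setdiff(c("male", "female"), sex_reference)
  dm <- function(f, lev) as.numeric(f == lev)
  X <- cbind(
    "(Intercept)" = rep(1, n),
    sex = dm(cohort$sex, sex_other),
    age_30s = dm(cohort$age_cat, "30s"),
    age_40s = dm(cohort$age_cat, "40s"),
    age_50s = dm(cohort$age_cat, "50s"),
    age_ge60 = dm(cohort$age_cat, "ge60"),
    dose_medium = dm(cohort$cloz_dose_cat, "medium"),
    dose_high = dm(cohort$cloz_dose_cat, "high"),
    polypharmacy = as.numeric(cohort$polypharmacy),
    lithium_low = dm(cohort$lithium_cat, "low"),
    lithium_high = dm(cohort$lithium_cat, "high"),
    fluvoxamine = as.numeric(cohort$fluvoxamine),
    antiepileptic = as.numeric(cohort$antiepileptic),
    convulsive_history = as.numeric(cohort$convulsive_history))
  coding <- data.frame(
    column = colnames(X)[-1L],
    label = c(paste0(sex_other, " vs ", sex_reference),
              "age 30-39 vs <=29", "age 40-49 vs <=29",
              "age 50-59 vs <=29", "age >=60 vs <=29",
              "medium dose vs low", "high dose vs low",
              "antipsychotic polypharmacy",
              "lithium low dose vs no use", "lithium high dose vs no use",
              "fluvoxamine", "antiepileptic agents",
              "history of convulsive disorder"),
    stringsAsFactors = FALSE)
  list(y = as.integer(cohort$outcome_seizure), X = X, coding = coding)
}

#' Fit the logistic reporting-odds model
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (delegated to `stats::glm.fit`), with rank screening of the
#' design, a separation check, and the covariance taken as the inverse of
#' the observed information at the optimum. Non-convergence and separation
#' are reported on the fit object with a warning — never silently.
#'
#' @param y 0/1 outcome vector.
#' @param X design matrix including the intercept column.
#' @param tol IRLS convergence tolerance (relative deviance change).
#' @param max_iter iteration cap.
#' @return an object of class `logistic_fit`: `coefficients`, `vcov`,
#'   `loglik`, `iter`, `converged`, `separation`, `gradient_max`, `n`.
#' @export
fit_logistic <- function(y, X, tol = 1e-10, max_iter = 100L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(x = X, y = y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  mu <- fit$fitted.values
  # glm.fit does not always flag separation on small samples; fitted
  # probabilities at the numerical boundary are just as diagnostic
  if (any(mu < 1e-10 | mu > 1 - 1e-10)) separation <- TRUE
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X), dimnames = dimnames(info))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  grad <- drop(crossprod(X, y - mu))
  converged <- isTRUE(fit$converged) && !separation && all(is.finite(vcov))
  if (!converged) {
    warning("logistic fit did not converge cleanly",
            if (separation) " (possible complete separation)" else "",
            "; estimates are unreliable", call. = FALSE)
  }
  ll <- sum(stats::dbinom(y, 1L, mu, log = TRUE))
  structure(list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
                 vcov = vcov, loglik = ll, iter = fit$iter,
                 converged = converged, separation = separation,
                 gradient_max = max(abs(grad)), n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n = ", x$n, ", ", length(x$coefficients),
      " coefficients, logLik = ", format(x$loglik, digits = 6),
      ", ", x$iter, " iterations",
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  invisible(x)
}

#' Effect estimates (adjusted RORs) from a logistic fit
#'
#' Exponentiates each non-intercept coefficient into an odds ratio with its
#' two-sided 95% Wald interval exp(b +- 1.96 SE) and Wald p-value.
#'
#' @param fit a converged [fit_logistic()] object.
#' @param coding optional coding table from [dummy_code()] supplying labels.
#' @return data.frame of class `effect_table`: `label`, `or`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
effects_from_fit <- function(fit, coding = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) {
    warning("effects from a non-converged fit; interpret with caution",
            call. = FALSE)
  }
  b <- fit$coefficients
  keep <- names(b) != "(Intercept)"
  b <- b[keep]
  se <- sqrt(diag(fit$vcov))[keep]
  lab <- names(b)
  if (!is.null(coding)) {
    m <- match(names(b), coding$column)
    lab[!is.na(m)] <- coding$label[m[!is.na(m)]]
  }
  z <- b / se
  out <- data.frame(label = lab,
                    or = exp(b),
                    ci_low = exp(b - .z95 * se),
                    ci_high = exp(b + .z95 * se),
                    p = 2 * stats::pnorm(-abs(z)),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Adjusted reporting odds ratios for a cohort
#'
#' Convenience wrapper: dummy-codes the cohort, fits the logistic model and
#' tabulates the adjusted RORs, adding per-level case counts
#' (`n_cases` target-event reports at the level, `n_noncases` other-event
#' reports at the level).
#'
#' @param cohort cohort data.frame from [build_cohort()].
#' @param sex_reference reference sex level.
#' @param tol,max_iter passed to [fit_logistic()].
#' @return list with `effects` (an `effect_table`) and `fit`.
#' @export
adjusted_ror <- function(cohort, sex_reference = "male",
                         tol = 1e-10, max_iter = 100L) {
  dc <- dummy_code(cohort, sex_reference = sex_reference)
  fit <- fit_logistic(dc$y, dc$X, tol = tol, max_iter = max_iter)
  eff <- effects_from_fit(fit, coding = dc$coding)
  eff$n_cases <- vapply(dc$coding$column, function(cl)
    sum(dc$X[, cl] == 1 & dc$y == 1L), numeric(1))
  eff$n_noncases <- vapply(dc$coding$column, function(cl)
    sum(dc$X[, cl] == 1 & dc$y == 0L), numeric(1))
  list(effects = eff, fit = fit)
}

#' @export
print.effect_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$or <- round(df$or, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  df$p <- signif(df$p, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
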