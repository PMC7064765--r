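# Model-versus-observation statistics: OLS regression of observed on
# predicted composition (both fourth-root transformed by the caller), a
# joint Wald F-test of slope = 1 and intercept = 0, and a Shapiro-Wilk
# normality check.

#' Regression of observed on predicted abundances
#'
#' Ordinary least squares `observed ~ predicted` (the axes convention of
#' model-validation scatter plots: model output on x, sample data on y; set
#' `direction = "predicted_on_observed"` to flip).  R-squared is the squared
#' Pearson correlation of the fit.
#'
#' @param observed,predicted equal-length numeric vectors (conventionally
#'   fourth-root transformed), `n >= 3`.
#' @param direction which variable is the response.
#' @return object of class `sml_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value` (slope t-test), `residuals`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_regression <- function(observed, predicted,
                           direction = c("observed_on_predicted",
                                         "predicted_on_observed")) {
  direction <- match.arg(direction)
  check_numeric_vec(observed, "observed")
  check_numeric_vec(predicted, "predicted")
  if (length(observed) != length(predicted))
    stop_("observed and predicted differ in length (%d vs %d)",
          length(observed), length(predicted))
  n <- length(observed)
  if (n < 3L) stop_("need n >= 3 points (got %d)", n)
  if (direction == "predicted_on_observed") {
    tmp <- observed; observed <- predicted; predicted <- tmp
  }
  if (stats::sd(predicted) == 0)
    stop_("predictor has zero variance; regression undefined")
  fit <- stats::lm(observed ~ predicted)
  # exact agreement (zero residual variance) is a legitimate input here
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2L, 4L]),
                 residuals = unname(stats::residuals(fit)),
                 n = n, lm = fit),
            class = "sml_fit")
}

#' @export
print.sml_fit <- function(x, ...) {
  cat(sprintf("<sml_fit> n = %d: slope %.3f, intercept %.3f, R^2 = %.3f, p = %.3g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Joint Wald test of slope and intercept
#'
#' F-test of the joint hypothesis `(slope, intercept) = (slope0,
#' intercept0)` — by default the line of perfect agreement, slope 1 and
#' intercept 0 — computed as the restricted-versus-full residual
#' sum-of-squares ratio on 2 and `n - 2` degrees of freedom.  A large p
#' means the regression is statistically indistinguishable from the
#' identity line.  Per-parameter t-tests are included for transparency.
#'
#' @param fit an [fit_regression()] result with `n >= 3`.
#' @param slope0,intercept0 hypothesized values.
#' @return list with `F`, `p_value`, `df` (c(2, n-2)), `ss` (extra sum of
#'   squares), and `t_tests` (per-parameter statistic and p).
#' @export
wald_slope_intercept_test <- function(fit, slope0 = 1, intercept0 = 0) {
  if (!inherits(fit, "sml_fit")) stop_("`fit` must come from fit_regression()")
  n <- fit$n
  if (n < 3L) stop_("Wald test needs n >= 3 (model is saturated at n = 2)")
  x <- fit$lm$model$predicted
  y <- fit$lm$model$observed
  rss_full <- sum(fit$residuals^2)
  rss_restr <- sum((y - intercept0 - slope0 * x)^2)
  ss <- max(rss_restr - rss_full, 0)     # restricted is a submodel
  if (rss_full <= .Machine$double.eps * max(1, rss_restr)) {
    # saturated fit: identical lines mean F = 0, otherwise infinite evidence
    Fstat <- if (ss == 0) 0 else Inf
  } else {
    Fstat <- (ss / 2) / (rss_full / (n - 2))
  }
  p <- stats::pf(Fstat, 2, n - 2, lower.tail = FALSE)
  sm <- suppressWarnings(summary(fit$lm))$coefficients
  se <- sm[, 2L]
  tstat <- c(intercept = (fit$intercept - intercept0) / se[1L],
             slope = (fit$slope - slope0) / se[2L])
  t_p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(F = Fstat, p_value = p, df = c(2L, n - 2L), ss = ss,
       t_tests = data.frame(parameter = c("intercept", "slope"),
                            statistic = unname(tstat), p_value = unname(t_p),
                            stringsAsFactors = FALSE))
}

#' Shapiro-Wilk normality check
#'
#' Thin contract over the standard Shapiro-Wilk routine; intended for
#' logging whether transformed abundances are consistent with normality,
#' never for gating an analysis.
#'
#' @param values numeric vector, `3 <= n <= 5000`, not constant.
#' @return list with `statistic` (W) and `p_value`.
#' @export
normality_check <- function(values) {
  check_numeric_vec(values, "values")
  if (length(unique(values)) == 1L)
    stop_("values are constant; normality test undefined")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Write a validation report as JSON
#'
#' @param fit an [fit_regression()] result.
#' @param wald a [wald_slope_intercept_test()] result (computed from `fit`
#'   if omitted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(fit, path, wald = NULL) {
  if (is.null(wald)) wald <- wald_slope_intercept_test(fit)
  jsonlite::write_json(
    list(slope = fit$slope, intercept = fit$intercept,
         r_squared = fit$r_squared, wald_F = wald$F,
         wald_p = wald$p_value, n = fit$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
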