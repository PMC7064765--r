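# Thermal response and seasonal temperature forcing.
#
# Each taxon's realized growth rate follows a Gaussian thermal-performance
# curve R(T) = r_max * dnorm(T, mu, sigma): r_max scales the curve, mu is the
# mean ideal growth temperature (degC) and sigma the ideal-temperature range
# (degC).  Note that under this (default, "density") form the peak rate is
# r_max / (sigma * sqrt(2*pi)), not r_max; `response = "peak"` drops the
# density normalization so that R(mu) = r_max exactly.

#' Per-taxon thermal growth parameters
#'
#' Builds and validates a growth-parameter table: one row per taxon with its
#' maximum growth-rate scale `r_max` (per day), mean ideal growth temperature
#' `mu` (degC) and ideal-temperature range `sigma` (degC).  This is the
#' in-memory form of the cultured-representative growth table read by
#' [read_growth_table()].
#'
#' @param taxon character vector of taxon labels (unique).
#' @param r_max numeric vector, > 0, per day.
#' @param mu numeric vector, degC.
#' @param sigma numeric vector, > 0, degC.
#' @return a `data.frame` of class `growth_params` with columns
#'   `taxon`, `r_max`, `mu`, `sigma`.
#' @seealso [growth_rate()], [read_growth_table()], [gen_growth_params()]
#' @export
#' @examples
#' growth_params(c("Alphaproteobacteria", "Bacilli"),
#'               r_max = c(1.2, 0.8), mu = c(26, 24), sigma = c(4, 5))
growth_params <- function(taxon, r_max, mu, sigma) {
  taxon <- as.character(taxon)
  n <- length(taxon)
  if (anyDuplicated(taxon))
    stop_("taxon labels must be unique (duplicated: %s)",
          taxon[anyDuplicated(taxon)])
  if (length(r_max) != n || length(mu) != n || length(sigma) != n)
    stop_("taxon, r_max, mu, sigma must have equal length")
  check_numeric_vec(r_max, "r_max"); check_numeric_vec(mu, "mu")
  check_numeric_vec(sigma, "sigma")
  if (any(r_max <= 0)) stop_("all r_max must be > 0")
  if (any(sigma <= 0)) stop_("all sigma must be > 0")
  structure(data.frame(taxon = taxon, r_max = r_max, mu = mu, sigma = sigma,
                       stringsAsFactors = FALSE),
            class = c("growth_params", "data.frame"))
}

as_growth_params <- function(x) {
  if (inherits(x, "growth_params")) return(x)
  if (is.data.frame(x)) {
    need <- c("taxon", "r_max", "mu", "sigma")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop_("growth table is missing column(s): %s",
            paste(miss, collapse = ", "))
    return(growth_params(x$taxon, x$r_max, x$mu, x$sigma))
  }
  stop_("cannot interpret object of class '%s' as growth parameters",
        class(x)[1L])
}

#' Temperature-dependent growth rate
#'
#' Evaluates the Gaussian thermal response
#' \deqn{R(T) = r_{max} \cdot \frac{1}{\sqrt{2\pi\sigma^2}}
#'       e^{-(T-\mu)^2 / 2\sigma^2}}
#' (the default `response = "density"`; the curve integrates to `r_max` over
#' all temperatures).  With `response = "peak"` the density normalization is
#' dropped and `r_max` is the literal peak rate attained at `T = mu`.
#'
#' @param params a [growth_params()] table (rows recycled against `temp` when
#'   a single row is given) or anything coercible to one.
#' @param temp temperature(s), degC; must be finite.
#' @param response `"density"` (default) or `"peak"`.
#' @return growth rate(s), per day; a matrix (taxon x temp) when `params` has
#'   more than one row and `temp` more than one value, otherwise a vector.
#' @export
#' @examples
#' p <- growth_params("x", r_max = 1, mu = 25, sigma = 1)
#' growth_rate(p, 25)   # 1/sqrt(2*pi)
growth_rate <- function(params, temp, response = c("density", "peak")) {
  response <- match.arg(response)
  params <- as_growth_params(params)
  if (!is.numeric(temp) || length(temp) == 0L || anyNA(temp) ||
      any(!is.finite(temp)))
    stop_("`temp` must be finite numeric temperature(s) in degC")
  rate1 <- function(r_max, mu, sigma) {
    z <- exp(-(temp - mu)^2 / (2 * sigma^2))
    if (response == "density") r_max * z / sqrt(2 * pi * sigma^2)
    else r_max * z
  }
  if (nrow(params) == 1L)
    return(rate1(params$r_max, params$mu, params$sigma))
  out <- matrix(NA_real_, nrow(params), length(temp),
                dimnames = list(params$taxon, NULL))
  for (i in seq_len(nrow(params)))
    out[i, ] <- rate1(params$r_max[i], params$mu[i], params$sigma[i])
  if (length(temp) == 1L) out[, 1L] else out
}

#' Seasonal temperature profile
#'
#' A sinusoidal seawater-temperature forcing
#' \eqn{T(t) = M + A \sin(\omega t + \theta)} with mean `M` (degC), amplitude
#' `A` (degC, >= 0), angular frequency `omega` (radians/day; the period is
#' `2*pi/omega`) and phase shift `theta` (radians).  With `A = 0` the profile
#' is constant at `M`.
#'
#' The phase may be given directly (`theta`) or as the calendar day on which
#' the annual minimum falls (`day_of_min`, default 45, mid-February); the two
#' are mutually exclusive.
#'
#' @param mean_temp M, degC.
#' @param amplitude A, degC, >= 0.
#' @param omega angular frequency, radians/day; default one cycle per 365 d.
#' @param theta phase shift in radians, or `NULL` to derive it from
#'   `day_of_min`.
#' @param day_of_min day of year of the annual temperature minimum (ignored
#'   when `theta` is given).
#' @return an object of class `temperature_profile`.
#' @seealso [temperature_at()]
#' @export
#' @examples
#' inner <- temperature_profile(24, 7)         # warm, fluctuating
#' temperature_at(inner, c(45, 45 + 365 / 2))  # annual min, annual max
temperature_profile <- function(mean_temp, amplitude, omega = 2 * pi / 365,
                                theta = NULL, day_of_min = 45) {
  check_number(mean_temp, "mean_temp")
  check_number(amplitude, "amplitude", nonneg = TRUE)
  check_number(omega, "omega", positive = TRUE)
  if (is.null(theta)) {
    check_number(day_of_min, "day_of_min")
    # sin(omega * day_of_min + theta) = -1  =>  minimum on day_of_min
    theta <- -pi / 2 - omega * day_of_min
  } else {
    check_number(theta, "theta")
  }
  structure(list(mean_temp = mean_temp, amplitude = amplitude,
                 omega = omega, theta = theta),
            class = "temperature_profile")
}

#' @export
print.temperature_profile <- function(x, ...) {
  cat(sprintf(
    "<temperature_profile> M = %g degC, A = %g degC, period = %g d, theta = %.4f rad\n",
    x$mean_temp, x$amplitude, 2 * pi / x$omega, x$theta))
  invisible(x)
}

#' Evaluate a temperature profile
#'
#' @param profile a [temperature_profile()].
#' @param t time(s), days.
#' @return temperature(s), degC.
#' @export
temperature_at <- function(profile, t) {
  if (!inherits(profile, "temperature_profile"))
    stop_("`profile` must be a temperature_profile")
  check_numeric_vec(t, "t")
  profile$mean_temp + profile$amplitude * sin(profile$omega * t + profile$theta)
}
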