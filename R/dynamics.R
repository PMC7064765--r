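# Community dynamics: coupled logistic growth under shared carrying capacity
# and network interactions,
#
#   dB_i/dt = R_i(T(t)) * B_i * (1 - sum_j B_j / k) * (1 + sum_j eta_ij B_j)
#
# integrated with an adaptive Dormand-Prince RK5(4) pair.  The competition
# bracket vanishes when total abundance reaches k; the interaction bracket
# raises or depresses each taxon's net growth according to its co-occurrence
# coefficients eta_ij.

#' Community ODE right-hand side
#'
#' Derivative of the network-coupled multi-taxon logistic system at time `t`.
#' The competition sum runs over all taxa (including `i`); the interaction
#' sum uses `eta` exactly as supplied, so zero the diagonal beforehand if
#' rank self-correlation should not feed back (the default in
#' [sml_integrate()] and [threshold_network()]).
#'
#' @param t time, days.
#' @param state numeric vector of abundances `B_i >= 0`.
#' @param growth a [growth_params()] table, one row per taxon, order aligned
#'   with `state`.
#' @param eta square interaction matrix (taxon x taxon), dimensionless.
#' @param profile a [temperature_profile()].
#' @param k shared carrying capacity, > 0, same units as `state`.
#' @param response thermal response form, see [growth_rate()].
#' @return derivative vector, abundance per day.
#' @export
sml_rhs <- function(t, state, growth, eta, profile, k,
                    response = c("density", "peak")) {
  response <- match.arg(response)
  growth <- as_growth_params(growth)
  n <- nrow(growth)
  check_numeric_vec(state, "state")
  if (length(state) != n)
    stop_("state has %d taxa but growth table has %d", length(state), n)
  if (!is.matrix(eta) || nrow(eta) != n || ncol(eta) != n)
    stop_("eta must be a %d x %d matrix (got %s)", n, n,
          paste(dim(eta), collapse = " x "))
  check_number(k, "k", positive = TRUE)
  temp <- temperature_at(profile, t)
  r <- growth_rate(growth, temp, response = response)
  unname(r * state * (1 - sum(state) / k) * (1 + drop(eta %*% state)))
}

# Dormand-Prince RK5(4) tableau (FSAL)
.dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)

# one adaptive leg from t0 to t1 (t1 > t0); returns state at t1 and the
# carried step size.  f(t, y) -> dy.
.rk45_leg <- function(f, t0, y, t1, h, rtol, atol) {
  n <- length(y)
  k <- matrix(0, n, 7)
  k[, 1] <- f(t0, y)
  t <- t0
  repeat {
    if (t >= t1) break
    h <- min(h, t1 - t)
    for (i in 2:7) {
      a <- .dp_a[[i - 1]]
      k[, i] <- f(t + .dp_c[i] * h,
                  y + h * drop(k[, seq_along(a), drop = FALSE] %*% a))
    }
    y5 <- y + h * drop(k %*% .dp_b5)
    y4 <- y + h * drop(k %*% .dp_b4)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1) {                       # accept
      t <- t + h
      y <- y5
      k[, 1] <- k[, 7]                    # FSAL
      if (any(y < -atol))
        stop_("integration produced negative abundance %.3e at t = %.6g d",
              min(y), t)
    }
    fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-1 / 5)))
    h <- h * fac
    if (h < 1e-12 * max(1, abs(t)))
      stop_("solver step size collapsed at t = %.6g d", t)
  }
  list(y = y, h = h)
}

#' Integrate the community dynamics
#'
#' Solves the coupled logistic system forward in time with an adaptive
#' Dormand-Prince RK5(4) integrator (default `rtol = 1e-8`,
#' `atol = 1e-10`).  Steps never cross a requested output time, so reported
#' states carry full solver accuracy (no dense-output interpolation).
#' Abundance excursions below `-atol` abort with the failing time; values in
#' `(-atol, 0]` are clipped to zero on output.
#'
#' @inheritParams sml_rhs
#' @param init initial abundance vector (one entry per taxon, all >= 0).
#' @param times strictly increasing output times in days; the first entry is
#'   the initial time.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param zero_self_interaction zero the diagonal of `eta` before use
#'   (default `TRUE`: a taxon's trivial rank self-correlation of 1 should
#'   not inflate its own growth).
#' @return an object of class `sml_trajectory`: list with `times` (days),
#'   `states` (time x taxon abundance matrix) and `taxa`.
#' @export
#' @examples
#' g <- growth_params("x", r_max = 5, mu = 24, sigma = 3)
#' p <- temperature_profile(24, 0)
#' tr <- sml_integrate(g, matrix(0, 1, 1), p, init = 10, k = 100,
#'                     times = seq(0, 30, by = 1))
#' tail(tr$states)  # saturates toward k = 100
sml_integrate <- function(growth, eta, profile, init, k = 100,
                          times = seq(0, 365, by = 1),
                          response = c("density", "peak"),
                          rtol = 1e-8, atol = 1e-10,
                          zero_self_interaction = TRUE) {
  response <- match.arg(response)
  growth <- as_growth_params(growth)
  n <- nrow(growth)
  check_numeric_vec(init, "init", nonneg = TRUE)
  if (length(init) != n)
    stop_("init has length %d but growth table has %d taxa", length(init), n)
  check_numeric_vec(times, "times")
  if (length(times) < 2L || any(diff(times) <= 0))
    stop_("`times` must be strictly increasing with at least two entries")
  if (!is.matrix(eta)) eta <- as.matrix(eta)
  if (zero_self_interaction) diag(eta) <- 0
  # validate dims once via sml_rhs, then close over constants
  invisible(sml_rhs(times[1L], init, growth, eta, profile, k, response))
  mu <- growth$mu; sigma <- growth$sigma; r_max <- growth$r_max
  dens <- response == "density"
  f <- function(t, y) {
    temp <- profile$mean_temp +
      profile$amplitude * sin(profile$omega * t + profile$theta)
    r <- r_max * exp(-(temp - mu)^2 / (2 * sigma^2))
    if (dens) r <- r / sqrt(2 * pi * sigma^2)
    r * y * (1 - sum(y) / k) * (1 + drop(eta %*% y))
  }
  states <- matrix(NA_real_, length(times), n,
                   dimnames = list(NULL, growth$taxon))
  y <- as.numeric(init)
  states[1L, ] <- y
  h <- min(0.1, diff(range(times)) / 100)
  for (i in seq_along(times)[-1L]) {
    leg <- .rk45_leg(f, times[i - 1L], y, times[i], h, rtol, atol)
    y <- leg$y
    h <- leg$h
    states[i, ] <- pmax(y, 0)           # clip (-atol, 0] excursions
  }
  structure(list(times = times, states = states, taxa = growth$taxon),
            class = "sml_trajectory")
}

#' @export
print.sml_trajectory <- function(x, ...) {
  cat(sprintf("<sml_trajectory> %d taxa, %d time points over [%g, %g] d\n",
              length(x$taxa), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Relative abundances at a sampling time
#'
#' Converts the community state at `t_sample` to percentages of total
#' abundance (summing to 100), the scale on which model output is compared
#' with metagenome-derived composition.  `t_sample` must fall inside the
#' trajectory's time range; states between stored output times are obtained
#' by linear interpolation.
#'
#' @param traj an [sml_integrate()] trajectory.
#' @param t_sample sampling time, days.
#' @return named vector of percentages summing to 100.
#' @export
relative_abundances <- function(traj, t_sample) {
  if (!inherits(traj, "sml_trajectory"))
    stop_("`traj` must be an sml_trajectory")
  check_number(t_sample, "t_sample")
  tt <- traj$times
  if (t_sample < tt[1L] || t_sample > tt[length(tt)])
    stop_("t_sample = %g outside trajectory range [%g, %g]",
          t_sample, tt[1L], tt[length(tt)])
  i <- findInterval(t_sample, tt)
  state <- if (tt[i] == t_sample || i == length(tt)) {
    traj$states[i, ]
  } else {
    w <- (t_sample - tt[i]) / (tt[i + 1L] - tt[i])
    (1 - w) * traj$states[i, ] + w * traj$states[i + 1L, ]
  }
  total <- sum(state)
  if (total <= 0)
    stop_("community is entirely extinct at t = %g; relative abundances undefined",
          t_sample)
  100 * state / total
}

#' Write a trajectory as tidy CSV
#'
#' Columns `time_days,taxon,abundance,relative_abundance_pct` (long format).
#'
#' @param traj an [sml_integrate()] trajectory.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "sml_trajectory"))
    stop_("`traj` must be an sml_trajectory")
  totals <- rowSums(traj$states)
  rel <- 100 * traj$states / ifelse(totals > 0, totals, NA_real_)
  out <- data.frame(
    time_days = rep(traj$times, times = length(traj$taxa)),
    taxon = rep(traj$taxa, each = length(traj$times)),
    abundance = as.vector(traj$states),
    relative_abundance_pct = as.vector(rel))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
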