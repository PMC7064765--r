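# The scenario grid: {specific, generalized} network x {specific
# fluctuating, generalized fluctuating, constant} temperature, run per reef
# zone, with model output validated against observed composition.

#' Enumerate the scenario grid
#'
#' The full Cartesian product of two network profiles (SN: zone-specific,
#' GN: generalized/pooled) and three temperature profiles (ST:
#' zone-specific fluctuating, GT: generalized fluctuating, CT: constant at
#' the zone mean): exactly six scenarios, stable order SN-ST, SN-GT, SN-CT,
#' GN-ST, GN-GT, GN-CT.  Crossing with the two reef zones yields 12 model
#' runs.
#'
#' @return data.frame with columns `label`, `network_profile`,
#'   `temperature_profile`.
#' @export
enumerate_scenarios <- function() {
  grid <- expand.grid(
    temperature_profile = c("specific_fluctuating", "generalized_fluctuating",
                            "constant"),
    network_profile = c("specific", "generalized"),
    stringsAsFactors = FALSE)[, 2:1]
  nl <- c(specific = "SN", generalized = "GN")
  tl <- c(specific_fluctuating = "ST", generalized_fluctuating = "GT",
          constant = "CT")
  grid$label <- paste(nl[grid$network_profile],
                      tl[grid$temperature_profile], sep = "-")
  grid[, c("label", "network_profile", "temperature_profile")]
}

#' Build the profile registry for both reef zones
#'
#' Assembles everything a scenario run needs: the three interaction
#' networks — one per zone from that zone's samples alone (SN) and one from
#' the pooled samples of both zones (GN) — and the five temperature
#' profiles (inner/outer specific fluctuating, generalized fluctuating,
#' inner/outer constant) with the configured parameters.
#'
#' @param inner_table,outer_table [abundance_table()]s sharing the same
#'   (already filtered) taxon set.
#' @param config a [default_config()]-shaped list.
#' @return object of class `profile_registry`: list with `networks`
#'   (`inner`, `outer`, `generalized` interaction matrices), `temperature`
#'   (`inner_st`, `outer_st`, `gt`, `inner_ct`, `outer_ct`) and `taxa`.
#' @export
build_registry <- function(inner_table, outer_table,
                           config = default_config()) {
  ti <- colnames(inner_table); to <- colnames(outer_table)
  if (!identical(ti, to)) {
    diff <- union(setdiff(ti, to), setdiff(to, ti))
    if (length(diff))
      stop_("zones disagree on taxa: %s", paste(diff, collapse = ", "))
    stop_("zones share taxa but in different order; align columns first")
  }
  pool <- rbind(unclass(inner_table), unclass(outer_table))
  rownames(pool) <- c(paste0("inner.", rownames(inner_table)),
                      paste0("outer.", rownames(outer_table)))
  pooled <- abundance_table(pool)
  thr <- function(tb) threshold_network(spearman_matrix(tb),
                                        rho_min = config$network$rho_min,
                                        p_max = config$network$p_max)
  tc <- config$temperature
  omega <- 2 * pi / tc$period_days
  prof <- function(mean, amplitude)
    temperature_profile(mean, amplitude, omega = omega, theta = tc$theta,
                        day_of_min = tc$day_of_min)
  structure(list(
    networks = list(inner = thr(inner_table), outer = thr(outer_table),
                    generalized = thr(pooled)),
    temperature = list(
      inner_st = prof(tc$inner$mean, tc$inner$amplitude),
      outer_st = prof(tc$outer$mean, tc$outer$amplitude),
      gt = prof(tc$generalized$mean, tc$generalized$amplitude),
      inner_ct = prof(tc$inner$mean, 0),
      outer_ct = prof(tc$outer$mean, 0)),
    taxa = ti), class = "profile_registry")
}

#' @export
print.profile_registry <- function(x, ...) {
  cat(sprintf("<profile_registry> %d taxa; networks: inner/outer/generalized; 5 temperature profiles\n",
              length(x$taxa)))
  invisible(x)
}

.registry_eta <- function(registry, network_profile, zone) {
  switch(network_profile,
         specific = registry$networks[[zone]],
         generalized = registry$networks$generalized,
         stop_("unknown network profile '%s'", network_profile))
}

.registry_profile <- function(registry, temperature_profile, zone) {
  switch(temperature_profile,
         specific_fluctuating = registry$temperature[[paste0(zone, "_st")]],
         generalized_fluctuating = registry$temperature$gt,
         constant = registry$temperature[[paste0(zone, "_ct")]],
         stop_("unknown temperature profile '%s'", temperature_profile))
}

.initial_state <- function(config, growth, observed = NULL) {
  k <- config$model$k
  n <- nrow(growth)
  init <- config$model$init
  if (is.numeric(init)) {
    if (length(init) != n) stop_("init vector has wrong length")
    return(init)
  }
  switch(init,
         equal = rep(k / 2 / n, n),
         observed = {
           if (is.null(observed))
             stop_("init = 'observed' needs an observed abundance table")
           p <- colMeans(as.matrix(observed))[growth$taxon]
           (k / 2) * p / sum(p)
         },
         stop_("unknown init mode '%s'", init))
}

#' Run one scenario
#'
#' Integrates the community model under the scenario's interaction network
#' and temperature profile for the configured number of years and reports
#' predicted relative abundances (percent, summing to 100) at the
#' configured sampling day of the final year.
#'
#' @param label scenario label (e.g., `"SN-ST"`) or a row of
#'   [enumerate_scenarios()].
#' @param zone `"inner"` or `"outer"`.
#' @param registry a [build_registry()] result.
#' @param growth a [growth_params()] table covering the registry taxa.
#' @param config configuration list.
#' @param observed optional observed table for `init = "observed"`.
#' @return named percentage vector with attributes `zone` and `scenario`.
#' @export
run_scenario <- function(label, zone = c("inner", "outer"), registry, growth,
                         config = default_config(), observed = NULL) {
  zone <- match.arg(zone)
  scen <- enumerate_scenarios()
  if (is.character(label)) {
    row <- scen[scen$label == label, ]
    if (nrow(row) != 1L)
      stop_("unknown scenario '%s' (choose from %s)", label,
            paste(scen$label, collapse = ", "))
  } else row <- as.data.frame(label)
  growth <- as_growth_params(growth)
  miss <- setdiff(registry$taxa, growth$taxon)
  if (length(miss))
    stop_("growth table lacks taxa: %s", paste(miss, collapse = ", "))
  growth <- growth[match(registry$taxa, growth$taxon), ]
  eta <- unclass(as.matrix(.registry_eta(registry, row$network_profile, zone)))
  profile <- .registry_profile(registry, row$temperature_profile, zone)
  mc <- config$model
  t_end <- mc$years * 365
  t_sample <- (mc$years - 1) * 365 + mc$sample_day
  init <- .initial_state(config, growth, observed)
  traj <- withCallingHandlers(
    sml_integrate(growth, eta, profile, init, k = mc$k,
                  times = c(0, t_sample, t_end),
                  response = mc$response, rtol = mc$rtol, atol = mc$atol,
                  zero_self_interaction = mc$zero_self_interaction),
    error = function(e)
      stop_("scenario %s/%s failed: %s", zone, row$label, conditionMessage(e)))
  out <- relative_abundances(traj, t_sample)
  attr(out, "zone") <- zone
  attr(out, "scenario") <- row$label
  out
}

#' Run the full scenario grid
#'
#' All six scenarios for both reef zones (12 runs) under one shared solver
#' configuration, so accuracy differences are attributable to the profiles.
#'
#' @inheritParams run_scenario
#' @param observed optional named list `list(inner = , outer = )` of
#'   observed tables (used only for `init = "observed"`).
#' @return named list of 12 prediction vectors, names `<zone>.<label>`.
#' @export
run_scenario_grid <- function(registry, growth, config = default_config(),
                              observed = NULL) {
  scen <- enumerate_scenarios()
  runs <- list()
  for (zone in c("inner", "outer")) for (i in seq_len(nrow(scen))) {
    key <- paste(zone, scen$label[i], sep = ".")
    runs[[key]] <- run_scenario(scen$label[i], zone, registry, growth, config,
                                observed = observed[[zone]])
  }
  runs
}

#' Regression report over scenario runs
#'
#' For every run, compares predicted with observed composition: observed
#' per-taxon means are renormalized over the modeled taxon set, both sides
#' are fourth-root transformed, and observed is regressed on predicted with
#' the joint Wald test of slope 1 / intercept 0.
#'
#' @param runs a [run_scenario_grid()] result.
#' @param observed named list `list(inner = , outer = )` of observed
#'   [abundance_table()]s over the modeled taxa.
#' @return data.frame with one row per run: `zone`, `scenario`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `wald_F`, `wald_p`, `n`.
#' @export
scenario_report <- function(runs, observed) {
  rows <- lapply(names(runs), function(key) {
    zone <- attr(runs[[key]], "zone")
    pred <- runs[[key]]
    obs_tab <- observed[[zone]]
    if (is.null(obs_tab)) stop_("no observed table for zone '%s'", zone)
    obs <- colMeans(as.matrix(obs_tab))[names(pred)]
    if (anyNA(obs))
      stop_("observed table for zone '%s' lacks modeled taxa", zone)
    obs <- 100 * obs / sum(obs)          # renormalize over modeled taxa
    fit <- fit_regression(fourth_root(obs), fourth_root(as.numeric(pred)))
    wald <- wald_slope_intercept_test(fit)
    data.frame(zone = zone, scenario = attr(runs[[key]], "scenario"),
               slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, p_value = fit$p_value,
               wald_F = wald$F, wald_p = wald$p_value, n = fit$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
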