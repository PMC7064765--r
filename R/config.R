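# One configuration schema shared by the scenario engine and the CLI.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the package defaults:
#'
#' * `temperature`: the five seasonal profiles — zone-specific fluctuating
#'   (inner M = 24, A = 7; outer M = 18, A = 5), generalized (M = 21, A = 6,
#'   the average of the two), and constant profiles at each zone mean
#'   (A = 0).  All fluctuating profiles share a 365-day period; the annual
#'   minimum falls on `day_of_min` (default 45, mid-February).
#' * `network`: edge-retention thresholds `rho_min = 0.7`, `p_max = 0.001`.
#' * `model`: carrying capacity `k = 100` (abundances read as percent of
#'   capacity), thermal `response = "density"`, initial condition mode
#'   (`"equal"`: equal abundances totaling `k/2`; `"observed"`: observed
#'   mean proportions scaled to `k/2`; or a user vector), integration over
#'   `years = 3` to wash out transients, sampling at day-of-year
#'   `sample_day = 150` (late May), solver tolerances `rtol = 1e-8`,
#'   `atol = 1e-10`.
#' * `filter`: mean-abundance cutoff (percent) for retaining taxa.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    temperature = list(
      inner = list(mean = 24, amplitude = 7),
      outer = list(mean = 18, amplitude = 5),
      generalized = list(mean = 21, amplitude = 6),
      period_days = 365,
      day_of_min = 45,
      theta = NULL),
    network = list(rho_min = 0.7, p_max = 0.001),
    model = list(k = 100, response = "density", init = "equal",
                 years = 3, sample_day = 150, rtol = 1e-8, atol = 1e-10,
                 zero_self_interaction = TRUE),
    filter = list(cutoff = 1))
}

# deep-merge user values over defaults
merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a YAML configuration
#'
#' Reads a YAML file with any subset of the [default_config()] keys and
#' merges it over the defaults (user values win).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return full configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_("config file '%s' not found", path)
  merge_config(cfg, yaml::read_yaml(path))
}
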