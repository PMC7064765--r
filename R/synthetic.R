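# Synthetic fixtures: growth-parameter tables, compositional abundance
# tables with planted rank-correlation blocks (Gaussian copula -> log-normal
# marginals -> closure to 100% per sample), and paired observed/predicted
# vectors for the validation statistics.  All generators require a seed and
# are bit-reproducible; caller RNG state is left untouched.

with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed))
    stop_("a seed is mandatory for reproducible generation")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification for a synthetic abundance table
#'
#' Describes the world a synthetic sample x taxon percentage table is drawn
#' from: sample/taxon counts, planted rank-correlation blocks (taxa within a
#' block share a target Spearman correlation of the given sign; taxa in
#' different blocks are independent), and per-taxon log-normal abundance
#' marginals.  Defaults emulate a reef-zone data set: 6 samples, 20
#' microbial classes, abundances spanning a few orders of magnitude.
#'
#' @param n_samples number of samples (metagenomes).
#' @param n_taxa number of taxa.
#' @param blocks list of planted blocks, each
#'   `list(members = <taxon indices>, rho = <target |rho| in (0, 1]>,
#'   sign = +1 or -1)`; members must be disjoint across blocks.  With
#'   `sign = -1`, block members alternate between positively correlated with
#'   each other and negatively with the rest of the block.
#' @param meanlog,sdlog log-normal marginal parameters, recycled per taxon.
#' @param seed mandatory integer seed.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 6, n_taxa = 20, blocks = list(),
                       meanlog = seq(2, -2, length.out = n_taxa), sdlog = 0.5,
                       seed) {
  check_number(n_samples, "n_samples", positive = TRUE)
  check_number(n_taxa, "n_taxa", positive = TRUE)
  meanlog <- rep_len(meanlog, n_taxa)
  sdlog <- rep_len(sdlog, n_taxa)
  seen <- integer(0)
  for (b in blocks) {
    if (!all(c("members", "rho") %in% names(b)))
      stop_("each block needs `members` and `rho`")
    if (any(b$members %in% seen)) stop_("block members must be disjoint")
    if (b$rho <= 0 || b$rho > 1) stop_("target |rho| must be in (0, 1]")
    seen <- c(seen, b$members)
    if (any(b$members > n_taxa)) stop_("block member index exceeds n_taxa")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_taxa = as.integer(n_taxa), blocks = blocks,
                 meanlog = meanlog, sdlog = sdlog, seed = as.integer(seed)),
            class = "synth_spec")
}

# latent correlation matrix with planted blocks
.block_correlation <- function(spec) {
  C <- diag(spec$n_taxa)
  for (b in spec$blocks) {
    sgn <- if (is.null(b$sign)) 1 else b$sign
    mem <- b$members
    s <- rep_len(c(1, sgn), length(mem))      # sign pattern within block
    for (i in seq_along(mem)) for (j in seq_along(mem)) {
      if (i != j) C[mem[i], mem[j]] <- b$rho * s[i] * s[j]
    }
  }
  C
}

#' Generate a synthetic abundance table
#'
#' Draws latent multivariate-normal scores with the planted block
#' correlation (Gaussian copula), pushes them through per-taxon log-normal
#' marginals, and closes each sample to 100%.  Closure rescales every taxon
#' in a sample by the same factor, so within-sample rank order is preserved
#' exactly (asserted); across samples the planted rank structure survives up
#' to the compositional perturbation, which is what makes the blocks
#' recoverable by [spearman_matrix()] + [threshold_network()] at adequate n.
#'
#' @param spec a [synth_spec()].
#' @return an [abundance_table()] (rows sum to 100).
#' @export
gen_abundance_table <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop_("`spec` must come from synth_spec()")
  C <- .block_correlation(spec)
  L <- tryCatch(chol(C), error = function(e)
    stop_("planted correlation matrix is not positive definite; reduce block rho or size"))
  with_seed(spec$seed, {
    Z <- matrix(stats::rnorm(spec$n_samples * spec$n_taxa),
                spec$n_samples, spec$n_taxa) %*% L
    U <- stats::pnorm(Z)
    X <- stats::qlnorm(U, meanlog = rep(spec$meanlog, each = spec$n_samples),
                       sdlog = rep(spec$sdlog, each = spec$n_samples))
    closed <- 100 * X / rowSums(X)
    for (i in seq_len(nrow(X)))           # closure must not disturb ranks
      stopifnot(identical(rank(X[i, ]), rank(closed[i, ])))
    abundance_table(closed,
                    sample_ids = sprintf("s%02d", seq_len(spec$n_samples)),
                    taxon_ids = sprintf("t%02d", seq_len(spec$n_taxa)))
  })
}

#' Generate a growth-parameter table
#'
#' Per-taxon `(r_max, mu, sigma)` sampled uniformly within the given ranges;
#' a synthetic stand-in for growth parameters compiled from cultured
#' representatives.
#'
#' @param n_taxa number of taxa.
#' @param mu_range mean ideal growth temperature range, degC.
#' @param sigma_range ideal-temperature range parameter bounds, degC.
#' @param rmax_range growth-rate scale bounds, per day.
#' @param seed mandatory integer seed.
#' @param taxa optional taxon labels (length `n_taxa`).
#' @return a [growth_params()] table.
#' @export
gen_growth_params <- function(n_taxa, mu_range = c(15, 35),
                              sigma_range = c(2, 8), rmax_range = c(0.1, 2),
                              seed, taxa = NULL) {
  check_number(n_taxa, "n_taxa", positive = TRUE)
  if (is.null(taxa)) taxa <- sprintf("t%02d", seq_len(n_taxa))
  if (length(taxa) != n_taxa) stop_("`taxa` must have length n_taxa")
  with_seed(seed, growth_params(
    taxa,
    r_max = stats::runif(n_taxa, rmax_range[1L], rmax_range[2L]),
    mu = stats::runif(n_taxa, mu_range[1L], mu_range[2L]),
    sigma = stats::runif(n_taxa, sigma_range[1L], sigma_range[2L])))
}

#' Generate a paired observed/predicted validation set
#'
#' `predicted` is sampled positive (log-normal); `observed = slope *
#' predicted + intercept + N(0, noise_sd)`.  With `noise_sd = 0` the
#' regression recovers `slope`/`intercept` exactly; under `slope = 1,
#' intercept = 0` with Gaussian noise the joint Wald p-value is uniform.
#'
#' @param n number of pairs.
#' @param slope,intercept true line.
#' @param noise_sd Gaussian noise standard deviation, >= 0.
#' @param seed mandatory integer seed.
#' @return list with numeric vectors `observed` and `predicted`.
#' @export
gen_paired_validation_set <- function(n, slope = 1, intercept = 0,
                                      noise_sd = 0.1, seed) {
  check_number(n, "n", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  with_seed(seed, {
    predicted <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
    observed <- slope * predicted + intercept +
      stats::rnorm(n, sd = noise_sd)
    list(observed = observed, predicted = predicted)
  })
}

#' Write a fixture with a sidecar JSON
#'
#' Writes a generated table to `path` and a `<path>.json` sidecar recording
#' the generating spec and seed, so every fixture is self-describing.
#'
#' @param spec the generating [synth_spec()] (or any list with a `seed`).
#' @param table the generated [abundance_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(spec, table, path) {
  write_abundance_table(table, path)
  side <- unclass(spec)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
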