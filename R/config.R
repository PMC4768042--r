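#' Default region labels: the 50 US states plus the District of Columbia
#'
#' @return Character vector of 51 two-letter region codes, sorted.
#' @export
default_regions <- function() {
  sort(c(datasets::state.abb, "DC"))
}

#' Default covariate moments and correlation structure
#'
#' Means and standard deviations of the five region-year predictors
#' (unemployment rate in percent, Gini coefficient, gross state product in
#' trillions of dollars, population growth rate in percent, past-orientation
#' index), and their 5x5 Pearson correlation matrix, as used by the synthetic
#' covariate generator.
#'
#' @return `default_covariate_means()` and `default_covariate_sds()` return
#'   named numeric vectors of length 5; `default_covariate_corr()` a named
#'   5x5 correlation matrix.
#' @export
default_covariate_means <- function() {
  c(unemployment = 6.309, gini = 0.607, gsp = 0.281,
    pop_growth = 0.899, past_orientation = 1.071)
}

#' @rdname default_covariate_means
#' @export
default_covariate_sds <- function() {
  c(unemployment = 2.285, gini = 0.035, gsp = 0.341,
    pop_growth = 0.887, past_orientation = 0.102)
}

#' @rdname default_covariate_means
#' @export
default_covariate_corr <- function() {
  nm <- predictor_names()
  r <- diag(5)
  dimnames(r) <- list(nm, nm)
  fill <- function(i, j, v) {
    r[i, j] <<- v
    r[j, i] <<- v
  }
  fill("unemployment", "gini", 0.082)
  fill("unemployment", "gsp", 0.134)
  fill("unemployment", "pop_growth", -0.128)
  fill("unemployment", "past_orientation", 0.012)
  fill("gini", "gsp", 0.296)
  fill("gini", "pop_growth", 0.087)
  fill("gini", "past_orientation", -0.154)
  fill("gsp", "pop_growth", -0.037)
  fill("gsp", "past_orientation", -0.238)
  fill("pop_growth", "past_orientation", 0.004)
  r
}

#' Default outcome-model coefficients
#'
#' Intercept and slopes of the linear suicide-rate model used as the
#' generating truth by [generate_outcomes()]: one coefficient per predictor,
#' on the scale suicides per 100,000 population per unit predictor.
#'
#' @return Named numeric vector of length 6 (intercept first).
#' @export
default_beta <- function() {
  c(intercept = -14.623, unemployment = 0.265, gini = 28.568,
    gsp = -4.122, pop_growth = 1.140, past_orientation = 8.501)
}

#' Default residual standard deviation of the outcome model
#'
#' Derived from the marginal outcome SD (3.779 per 100,000) and the explained
#' variance of the full five-predictor model (R-squared 0.324):
#' `3.779 * sqrt(1 - 0.324)`, about 3.107. With the default covariate moments
#' and correlations this makes the synthetic panel's total outcome variance
#' and model R-squared match the marginal figures the coefficients were
#' calibrated to.
#'
#' @return A positive scalar.
#' @export
default_resid_sd <- function() {
  3.779 * sqrt(1 - 0.324)
}

predictor_names <- function() {
  c("unemployment", "gini", "gsp", "pop_growth", "past_orientation")
}

# Deterministic 32-bit sub-seed per component, so regenerating one component
# never perturbs another drawn from the same master seed.
derive_seed <- function(seed, component) {
  offset <- c(latents = 101L, sizes = 211L, volumes = 307L,
              covariates = 401L, outcomes = 503L)[[component]]
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the synthetic data-generating process: the
#' region-by-year design, the monthly year-phrase query-count model, the
#' joint distribution of the socio-economic covariates, and the linear
#' outcome model. Defaults emulate a study of the 50 US states plus DC over
#' 2004-2012 (459 region-years).
#'
#' The monthly query model gives the past-year phrase a Poisson mean
#' `baseline_volume * region_size * phrase_share * latent * exp(-past_decay * (month - 1))`
#' and the future-year phrase the same with `exp(+future_rise * (month - 1))`
#' and no latent, so past-phrase interest is maximal in January and decays
#' through the year while future-phrase interest rises to a December peak.
#' The per-region latent is the generative counterpart of a persistent
#' regional past orientation: it scales the past phrase only.
#'
#' @param regions Character vector of unique region identifiers.
#' @param years Contiguous integer vector of base years.
#' @param baseline_volume Expected monthly total query count per average-size
#'   region; positive.
#' @param phrase_share Fraction of total volume attributable to one year
#'   phrase; in (0, 1).
#' @param past_decay,future_rise Per-month log-linear trend rates of the past
#'   and future phrase intensities; 0 means flat.
#' @param orientation_latents Named positive per-region multipliers on the
#'   past-phrase intensity. Default: log-normal around 1 (sdlog
#'   `latent_sdlog`), drawn from a sub-stream of `seed`.
#' @param latent_sdlog Log-scale SD of the default latent draw.
#' @param region_sizes Named positive per-region total-volume multipliers
#'   (a population proxy making share-mode normalization non-trivial).
#'   Default: log-normal (sdlog 0.5) from a sub-stream of `seed`.
#' @param covariate_means,covariate_sds Length-5 vectors of predictor means
#'   and SDs, in the order unemployment, gini, gsp, pop_growth,
#'   past_orientation.
#' @param covariate_corr 5x5 predictor correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite).
#' @param beta Length-6 outcome coefficients, intercept first.
#' @param resid_sd Residual SD of the outcome model; non-negative.
#' @param seed Master integer seed; component sub-streams are derived from it.
#' @param deterministic If `TRUE`, all sampling is replaced by its expectation
#'   (Poisson counts by their means, covariates by their mean vector,
#'   residuals by 0), making every output an exact function of the config.
#'
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config(regions = c("AA", "BB"), years = 2009:2010)
#' cfg$resid_sd
#' @export
generator_config <- function(regions = default_regions(),
                             years = 2004:2012,
                             baseline_volume = 50000,
                             phrase_share = 0.02,
                             past_decay = 0.08,
                             future_rise = 0.08,
                             orientation_latents = NULL,
                             latent_sdlog = 0.095,
                             region_sizes = NULL,
                             covariate_means = default_covariate_means(),
                             covariate_sds = default_covariate_sds(),
                             covariate_corr = default_covariate_corr(),
                             beta = default_beta(),
                             resid_sd = default_resid_sd(),
                             seed = 1L,
                             deterministic = FALSE) {
  regions <- as.character(regions)
  years <- as.integer(years)
  seed <- as.integer(seed)
  if (is.null(orientation_latents)) {
    orientation_latents <- with_seed(derive_seed(seed, "latents"), {
      stats::setNames(exp(stats::rnorm(length(regions), 0, latent_sdlog)),
                      regions)
    })
  }
  if (is.null(region_sizes)) {
    region_sizes <- with_seed(derive_seed(seed, "sizes"), {
      stats::setNames(exp(stats::rnorm(length(regions), 0, 0.5)), regions)
    })
  }
  cfg <- structure(
    list(regions = regions, years = years,
         baseline_volume = baseline_volume, phrase_share = phrase_share,
         past_decay = past_decay, future_rise = future_rise,
         orientation_latents = orientation_latents,
         region_sizes = region_sizes,
         covariate_means = covariate_means, covariate_sds = covariate_sds,
         covariate_corr = covariate_corr, beta = beta, resid_sd = resid_sd,
         seed = seed, deterministic = isTRUE(deterministic)),
    class = "generator_config")
  validate_config(cfg)
  cfg
}

# Run an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Validate a generator configuration
#'
#' Checks region uniqueness, year contiguity, positivity constraints, and
#' that the covariate correlation matrix is symmetric with unit diagonal and
#' positive semi-definite. Called by [generator_config()]; exported so
#' configurations edited by hand can be re-checked.
#'
#' @param cfg A `generator_config`.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (length(cfg$regions) == 0L) {
    stop("configuration error: region list is empty")
  }
  if (anyDuplicated(cfg$regions)) {
    stop("configuration error: region labels must be unique")
  }
  if (length(cfg$years) == 0L || !all(diff(cfg$years) == 1L)) {
    stop("configuration error: years must be a contiguous ascending range")
  }
  if (!is.numeric(cfg$baseline_volume) || cfg$baseline_volume <= 0) {
    stop("configuration error: baseline_volume must be positive")
  }
  if (cfg$phrase_share <= 0 || cfg$phrase_share >= 1) {
    stop("configuration error: phrase_share must be in (0, 1)")
  }
  for (fld in c("orientation_latents", "region_sizes")) {
    v <- cfg[[fld]]
    if (length(v) != length(cfg$regions) || any(v <= 0) ||
        !setequal(names(v), cfg$regions)) {
      stop("configuration error: ", fld,
           " must be positive and named by every region")
    }
  }
  if (length(cfg$covariate_means) != 5L || length(cfg$covariate_sds) != 5L) {
    stop("configuration error: covariate_means and covariate_sds must have length 5")
  }
  if (any(cfg$covariate_sds < 0)) {
    stop("configuration error: covariate_sds must be non-negative")
  }
  r <- cfg$covariate_corr
  if (!is.matrix(r) || !all(dim(r) == c(5L, 5L))) {
    stop("configuration error: covariate_corr must be a 5x5 matrix")
  }
  if (max(abs(r - t(r))) > 1e-10 || max(abs(diag(r) - 1)) > 1e-10) {
    stop("configuration error: covariate_corr must be symmetric with unit diagonal")
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "configuration error: covariate_corr is not positive semi-definite (eigenvalue %.6g)",
      min(ev)))
  }
  if (length(cfg$beta) != 6L) {
    stop("configuration error: beta must have length 6 (intercept + 5 slopes)")
  }
  if (!is.numeric(cfg$resid_sd) || cfg$resid_sd < 0) {
    stop("configuration error: resid_sd must be non-negative")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic study generator configuration\n")
  cat(sprintf("  %d regions x years %d-%d (%d region-years)\n",
              length(x$regions), min(x$years), max(x$years),
              length(x$regions) * length(x$years)))
  cat(sprintf("  monthly volumes: baseline %g, phrase share %g, past decay %g, future rise %g\n",
              x$baseline_volume, x$phrase_share, x$past_decay, x$future_rise))
  cat(sprintf("  outcome model: resid SD %.3f, beta = (%s)\n",
              x$resid_sd, paste(format(x$beta, digits = 4), collapse = ", ")))
  cat(sprintf("  seed %d%s\n", x$seed,
              if (x$deterministic) " (deterministic: sampling replaced by expectations)" else ""))
  invisible(x)
}
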