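#' Generate synthetic monthly year-phrase query volumes
#'
#' Emits one record per region x month x year-phrase term. For base year `t`
#' the two terms are the strings for `t - 1` (role `"past"`) and `t + 1`
#' (role `"future"`). Counts are Poisson with a log-linear monthly trend:
#' past-phrase means decay month over month within each calendar year while
#' future-phrase means rise to a December maximum; the region's orientation
#' latent multiplies the past-phrase mean only. A per-region-month total
#' query-volume proxy is emitted alongside for share-mode normalization.
#'
#' With `cfg$deterministic` the Poisson draw is replaced by its mean, so the
#' output is an exact function of the configuration.
#'
#' @param cfg A [generator_config()].
#' @return A data.frame with columns `region`, `year`, `month`, `term`,
#'   `role`, `count`, `total_volume`.
#' @examples
#' cfg <- generator_config(regions = c("AA", "BB"), years = 2009,
#'                         deterministic = TRUE)
#' head(generate_query_volumes(cfg))
#' @export
generate_query_volumes <- function(cfg) {
  validate_config(cfg)
  grid <- expand.grid(month = 1:12, year = cfg$years, region = cfg$regions,
                      role = c("past", "future"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  size <- cfg$region_sizes[grid$region]
  latent <- cfg$orientation_latents[grid$region]
  trend <- ifelse(grid$role == "past",
                  exp(-cfg$past_decay * (grid$month - 1)),
                  exp(cfg$future_rise * (grid$month - 1)))
  mu <- cfg$baseline_volume * size * cfg$phrase_share * trend *
    ifelse(grid$role == "past", latent, 1)
  count <- if (cfg$deterministic) {
    mu
  } else {
    with_seed(derive_seed(cfg$seed, "volumes"), stats::rpois(length(mu), mu))
  }
  out <- data.frame(
    region = grid$region,
    year = grid$year,
    month = grid$month,
    term = as.character(ifelse(grid$role == "past",
                               grid$year - 1L, grid$year + 1L)),
    role = grid$role,
    count = count,
    total_volume = cfg$baseline_volume * unname(size),
    stringsAsFactors = FALSE)
  out[order(out$region, out$year, out$month, out$role), , drop = FALSE]
}

#' Generate synthetic region-year covariates
#'
#' Draws the five predictors (unemployment rate, Gini coefficient, gross
#' product, population growth rate, and a past-orientation placeholder used
#' when running inference without the query-index pipeline) jointly
#' multivariate normal with the configured means, SDs and correlation
#' matrix, then truncates: Gini clipped into (0, 1); unemployment, gross
#' product and the orientation placeholder floored at a small positive value.
#'
#' @param cfg A [generator_config()].
#' @param n Optional row count overriding the region x year grid (rows are
#'   then labelled `R1...Rn` with year `NA`); used for moment checks.
#' @return A data.frame with columns `region`, `year`, `unemployment`,
#'   `gini`, `gsp`, `pop_growth`, `past_orientation`.
#' @export
generate_covariates <- function(cfg, n = NULL) {
  validate_config(cfg)
  if (is.null(n)) {
    grid <- expand.grid(year = cfg$years, region = cfg$regions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    region <- grid$region
    year <- grid$year
    n <- nrow(grid)
  } else {
    region <- paste0("R", seq_len(n))
    year <- rep(NA_integer_, n)
  }
  sigma <- diag(cfg$covariate_sds) %*% cfg$covariate_corr %*%
    diag(cfg$covariate_sds)
  draws <- if (cfg$deterministic || all(cfg$covariate_sds == 0)) {
    matrix(cfg$covariate_means, nrow = n, ncol = 5, byrow = TRUE)
  } else {
    with_seed(derive_seed(cfg$seed, "covariates"),
              MASS::mvrnorm(n, mu = cfg$covariate_means, Sigma = sigma))
  }
  colnames(draws) <- predictor_names()
  eps <- 1e-6
  draws[, "gini"] <- pmin(pmax(draws[, "gini"], eps), 1 - eps)
  for (v in c("unemployment", "gsp", "past_orientation")) {
    draws[, v] <- pmax(draws[, v], 0.01)
  }
  out <- data.frame(region = region, year = year, draws,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$region, out$year), , drop = FALSE]
}

#' Generate synthetic outcomes from a predictor table
#'
#' Applies the linear model
#' `suicide_rate = beta[1] + sum_j beta[j+1] * x_j + eps`,
#' with `eps ~ Normal(0, resid_sd^2)` i.i.d. per row. By default outcomes are
#' not clipped at zero, keeping the linear model exact; set `clip = TRUE` to
#' floor rates at 0.
#'
#' @param predictors Data.frame with columns `region`, `year` and the five
#'   predictor columns `unemployment`, `gini`, `gsp`, `pop_growth`,
#'   `past_orientation`.
#' @param beta Numeric length-6 coefficient vector, intercept first.
#' @param resid_sd Residual standard deviation; 0 gives noiseless outcomes.
#' @param seed Integer seed for the residual draw.
#' @param clip Floor outcomes at 0 when `TRUE`.
#' @return A data.frame `region`, `year`, `suicide_rate`.
#' @export
generate_outcomes <- function(predictors, beta, resid_sd, seed,
                              clip = FALSE) {
  nm <- predictor_names()
  missing_cols <- setdiff(nm, names(predictors))
  if (length(missing_cols)) {
    stop("predictor table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(beta) != length(nm) + 1L) {
    stop(sprintf("beta has length %d but %d predictors + intercept require %d",
                 length(beta), length(nm), length(nm) + 1L))
  }
  if (resid_sd < 0) stop("resid_sd must be non-negative")
  x <- as.matrix(predictors[, nm, drop = FALSE])
  mu <- beta[1] + drop(x %*% beta[-1])
  eps <- if (resid_sd == 0) {
    0
  } else {
    with_seed(as.integer(seed), stats::rnorm(nrow(x), 0, resid_sd))
  }
  rate <- mu + eps
  if (clip) rate <- pmax(rate, 0)
  data.frame(region = predictors$region, year = predictors$year,
             suicide_rate = rate, stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate an inference-only recovery panel
#'
#' The short route from configuration to analysis panel that bypasses the
#' query-index pipeline: covariates (including the multivariate-normal
#' past-orientation placeholder) are drawn with [generate_covariates()] and
#' outcomes with [generate_outcomes()] from the configured coefficients and
#' residual SD. Because the generating coefficients are known exactly, this
#' panel is the natural test bed for parameter-recovery checks of the OLS
#' machinery.
#'
#' @param cfg A [generator_config()].
#' @return A panel data.frame as from [build_panel()].
#' @export
simulate_recovery_panel <- function(cfg) {
  validate_config(cfg)
  covariates <- generate_covariates(cfg)
  outcomes <- generate_outcomes(
    covariates, cfg$beta,
    resid_sd = if (cfg$deterministic) 0 else cfg$resid_sd,
    seed = derive_seed(cfg$seed, "outcomes"))
  build_panel(NULL, covariates, outcomes)
}
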