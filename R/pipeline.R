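#' Predefined predictor sets for the four benchmark models
#'
#' Model 1: unemployment + Gini. Model 2: Model 1 plus past orientation.
#' Model 3: unemployment + Gini + gross product + population growth.
#' Model 4: Model 3 plus past orientation (the full specification).
#'
#' @return Named list of four character vectors.
#' @export
model_predictor_sets <- function() {
  list(model1 = c("unemployment", "gini"),
       model2 = c("unemployment", "gini", "past_orientation"),
       model3 = c("unemployment", "gini", "gsp", "pop_growth"),
       model4 = c("unemployment", "gini", "gsp", "pop_growth",
                  "past_orientation"))
}

#' Simulate a complete synthetic study
#'
#' Generates every table the analysis consumes, wired together coherently:
#' monthly query volumes (with per-region orientation latents), the
#' region-year orientation table computed from those volumes through the
#' index pipeline, region-year covariates, and outcomes generated from the
#' four socio-economic covariates plus the *computed* past orientation — so
#' the orientation signal in the panel genuinely drives the outcome, as the
#' analysis assumes. (The covariate table's own `past_orientation` column is
#' a multivariate-normal placeholder for inference runs that bypass the
#' query-index pipeline; it is not used for outcome generation here.)
#'
#' @param cfg A [generator_config()].
#' @param mode Index normalization mode for the orientation pipeline.
#' @return List with elements `volumes`, `orientation`, `covariates`,
#'   `outcomes`, `panel`, `config`.
#' @export
simulate_study <- function(cfg, mode = "share") {
  validate_config(cfg)
  volumes <- generate_query_volumes(cfg)
  orientation <- orientation_table(volumes, mode = mode)
  covariates <- generate_covariates(cfg)
  predictors <- merge(
    covariates[, c("region", "year", "unemployment", "gini", "gsp",
                   "pop_growth")],
    orientation[, c("region", "year", "past_orientation")],
    by = c("region", "year"))
  outcomes <- generate_outcomes(
    predictors, cfg$beta,
    resid_sd = if (cfg$deterministic) 0 else cfg$resid_sd,
    seed = derive_seed(cfg$seed, "outcomes"))
  panel <- build_panel(orientation, covariates, outcomes)
  list(volumes = volumes, orientation = orientation,
       covariates = covariates, outcomes = outcomes, panel = panel,
       config = cfg)
}

#' Per-region mean orientation and outcome
#'
#' Collapses the panel to one row per region: the across-years means of
#' past orientation and the suicide rate, the quantities behind a
#' region-level scatter of orientation against outcome.
#'
#' @param panel Panel from [build_panel()].
#' @return Data.frame `region`, `mean_past_orientation`,
#'   `mean_suicide_rate`, one row per region.
#' @export
export_scatter <- function(panel) {
  if (nrow(panel) == 0L) stop("empty panel")
  agg <- stats::aggregate(cbind(past_orientation, suicide_rate) ~ region,
                          data = panel, FUN = mean)
  out <- data.frame(region = agg$region,
                    mean_past_orientation = agg$past_orientation,
                    mean_suicide_rate = agg$suicide_rate,
                    stringsAsFactors = FALSE)
  out[order(out$region), , drop = FALSE]
}

write_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  path
}

#' Run the full pipeline and write publication-shaped outputs
#'
#' Executes simulate, index, panel, describe, the four benchmark fits, the
#' all-subsets ranking and the stepwise check, writing each stage's table as
#' CSV under `out_dir` together with a JSON run manifest recording the
#' configuration, seed and an MD5 digest of every file written. With a
#' deterministic configuration two runs produce byte-identical outputs (the
#' manifest then omits the wall-clock timestamp).
#'
#' Files written: `volumes.csv`, `covariates.csv`, `outcomes.csv`,
#' `orientation.csv`, `profile.csv`, `panel.csv`, `summary.csv`, `corr.csv`,
#' `fit_model1..4.csv`, `ranking.csv`, `stepwise.csv`, `scatter.csv`,
#' `manifest.json`.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param mode Index normalization mode.
#' @param alpha Stepwise significance level.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory `study`, `fits`, `ranking`,
#'   `stepwise` and the `manifest` path.
#' @export
run_pipeline <- function(cfg, out_dir, mode = "share", alpha = 0.01,
                         quiet = FALSE) {
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] ", stage), sprintf(fmt, ...))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(tab, name) {
    files[[name]] <<- write_table(tab, file.path(out_dir, name))
  }

  say("simulate", "seed %d, %d regions x %d years", cfg$seed,
      length(cfg$regions), length(cfg$years))
  study <- run_stage("simulate", simulate_study(cfg, mode = mode))
  emit(study$volumes, "volumes.csv")
  emit(study$covariates[, c("region", "year", "unemployment", "gini", "gsp",
                            "pop_growth")], "covariates.csv")
  emit(study$outcomes, "outcomes.csv")

  say("index", "%d region-year orientation values", nrow(study$orientation))
  emit(study$orientation, "orientation.csv")
  profile <- run_stage("profile", monthly_profile(
    trends_normalize(study$volumes, mode = mode)))
  emit(profile, "profile.csv")

  say("panel", "%d panel rows", nrow(study$panel))
  emit(study$panel, "panel.csv")

  summary_tab <- run_stage("describe", panel_summary(study$panel))
  emit(summary_tab, "summary.csv")
  ct <- run_stage("describe", correlation_matrix(study$panel))
  corr_tab <- data.frame(variable = rownames(ct$r),
                         as.data.frame(ct$r),
                         stringsAsFactors = FALSE, row.names = NULL)
  pcols <- as.data.frame(ct$p)
  names(pcols) <- paste0("p_", names(pcols))
  emit(cbind(corr_tab, pcols), "corr.csv")

  # a model a given panel cannot identify (toy sizes, degenerate inputs) is
  # reported in its table rather than aborting the remaining models
  fits <- lapply(model_predictor_sets(), function(s) {
    tryCatch(ols_fit(study$panel, s), error = function(e) e)
  })
  for (nm in names(fits)) {
    tab <- if (inherits(fits[[nm]], "error")) {
      data.frame(term = "(not fit)", coeff = "", se = "",
                 p = conditionMessage(fits[[nm]]), stringsAsFactors = FALSE)
    } else {
      fit_table(fits[[nm]])
    }
    emit(tab, paste0("fit_", nm, ".csv"))
  }
  say("fit", "models 1-4: AIC %s",
      paste(vapply(fits, function(f) {
        if (inherits(f, "error")) "NA" else sprintf("%.1f", f$aic)
      }, character(1)), collapse = ", "))

  ranking <- run_stage("select", all_subsets(study$panel,
                                             predictor_names()))
  emit(as.data.frame(ranking), "ranking.csv")
  sw <- run_stage("select", stepwise_select(study$panel, predictor_names(),
                                            alpha = alpha))
  emit(sw$trace, "stepwise.csv")
  say("select", "stepwise final: %s",
      if (length(sw$final)) paste(sw$final, collapse = "+") else "(empty)")

  emit(run_stage("scatter", export_scatter(study$panel)), "scatter.csv")

  manifest <- list(
    package = "orientia",
    seed = cfg$seed,
    deterministic = cfg$deterministic,
    regions = length(cfg$regions),
    years = range(cfg$years),
    mode = mode,
    alpha = alpha,
    config = cfg[c("baseline_volume", "phrase_share", "past_decay",
                   "future_rise", "resid_sd")],
    beta = as.list(cfg$beta),
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  if (!cfg$deterministic) {
    manifest$timestamp <- format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ")
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done", "%d files in %s", length(files) + 1L, out_dir)
  invisible(list(study = study, fits = fits, ranking = ranking,
                 stepwise = sw, manifest = manifest_path))
}
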