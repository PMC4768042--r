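#' Assemble the region-year analysis panel
#'
#' Inner-joins orientation values, covariates and outcomes on
#' `(region, year)`. In strict mode the joined panel must form a complete
#' regions-by-years grid; in permissive mode incomplete region-years are
#' dropped, one message per drop. Duplicate keys in any input, or an empty
#' join, are always errors.
#'
#' @param orientation Orientation table with `region`, `year`,
#'   `past_orientation` (e.g. from [orientation_table()]); `NULL` if
#'   `covariates` already carries a `past_orientation` column (the
#'   generator's placeholder route).
#' @param covariates Covariate table with `region`, `year`, `unemployment`,
#'   `gini`, `gsp`, `pop_growth`.
#' @param outcomes Outcome table with `region`, `year`, `suicide_rate`.
#' @param strict Require a complete grid (default).
#' @return A data.frame of panel rows sorted by `(region, year)`: `region`,
#'   `year`, `suicide_rate`, `unemployment`, `gini`, `gsp`, `pop_growth`,
#'   `past_orientation`.
#' @export
build_panel <- function(orientation, covariates, outcomes, strict = TRUE) {
  check_keys <- function(tab, what) {
    stopifnot(all(c("region", "year") %in% names(tab)))
    if (anyDuplicated(tab[, c("region", "year")])) {
      stop("duplicate (region, year) keys in ", what)
    }
  }
  check_keys(covariates, "covariates")
  check_keys(outcomes, "outcomes")
  cov_cols <- c("region", "year", "unemployment", "gini", "gsp", "pop_growth")
  stopifnot(all(cov_cols %in% names(covariates)))
  if (is.null(orientation)) {
    if (!"past_orientation" %in% names(covariates)) {
      stop("no orientation table given and covariates lack past_orientation")
    }
    joined <- covariates[, c(cov_cols, "past_orientation")]
  } else {
    check_keys(orientation, "orientation")
    joined <- merge(covariates[, cov_cols],
                    orientation[, c("region", "year", "past_orientation")],
                    by = c("region", "year"))
  }
  panel <- merge(joined, outcomes[, c("region", "year", "suicide_rate")],
                 by = c("region", "year"))
  if (nrow(panel) == 0L) stop("panel join is empty: no (region, year) keys align")
  complete <- stats::complete.cases(panel)
  if (!all(complete)) {
    labels <- paste0(panel$region[!complete], "/", panel$year[!complete])
    if (strict) {
      stop("incomplete panel rows in strict mode: ",
           paste(labels, collapse = ", "))
    }
    for (lab in labels) message("dropping incomplete panel row: ", lab)
    panel <- panel[complete, , drop = FALSE]
  }
  if (strict) {
    n_r <- length(unique(panel$region))
    n_y <- length(unique(panel$year))
    if (nrow(panel) != n_r * n_y) {
      stop(sprintf(
        "strict mode requires a complete grid: %d regions x %d years != %d rows",
        n_r, n_y, nrow(panel)))
    }
  }
  panel <- panel[order(panel$region, panel$year),
                 c("region", "year", "suicide_rate", "unemployment", "gini",
                   "gsp", "pop_growth", "past_orientation")]
  row.names(panel) <- NULL
  panel
}

#' Per-variable summary statistics of a panel
#'
#' For the outcome and each predictor: n, mean, sample SD (n-1 denominator),
#' min, max; for predictors additionally the variance inflation factor from
#' [vif()]. Variables with zero variance are flagged with a warning (they
#' break correlations and VIFs downstream) and reported with `NA` SD-derived
#' quantities where undefined.
#'
#' @param panel Panel from [build_panel()] (any data.frame with the standard
#'   panel columns present works; missing columns are skipped).
#' @return A data.frame, one row per variable: `variable`, `n`, `mean`, `sd`,
#'   `min`, `max`, `vif`.
#' @export
panel_summary <- function(panel) {
  if (nrow(panel) == 0L) stop("empty panel")
  vars <- intersect(c("suicide_rate", predictor_names()), names(panel))
  rows <- lapply(vars, function(v) {
    x <- panel[[v]]
    data.frame(variable = v, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  degenerate <- out$variable[is.na(out$sd) | out$sd == 0]
  if (length(degenerate)) {
    warning("zero or undefined variance for: ",
            paste(degenerate, collapse = ", "))
  }
  preds <- intersect(predictor_names(), names(panel))
  out$vif <- NA_real_
  if (length(preds) >= 2L && nrow(panel) > length(preds) + 1L &&
      !any(out$sd[out$variable %in% preds] %in% c(0, NA))) {
    v <- vif(panel, predictors = preds)
    out$vif[match(names(v), out$variable)] <- v
  }
  row.names(out) <- NULL
  out
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations among the panel variables, with two-sided
#' p-values from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Zero-variance columns make the affected pairs undefined; they are
#' reported as `NA` with a warning.
#'
#' @param panel Data.frame of observations.
#' @param vars Variables to correlate; default the outcome plus all
#'   predictors present.
#' @return An object of class `cor_table`: list with matrices `r` and `p`
#'   and the row count `n`. Printed in the journal style, p-values in
#'   parentheses.
#' @examples
#' d <- data.frame(suicide_rate = c(1, 2, 3, 5), unemployment = c(2, 4, 5, 9),
#'                 gini = c(0.4, 0.5, 0.45, 0.6))
#' correlation_matrix(d)
#' @export
correlation_matrix <- function(panel,
                               vars = intersect(c("suicide_rate",
                                                  predictor_names()),
                                                names(panel))) {
  x <- as.matrix(panel[, vars, drop = FALSE])
  n <- nrow(x)
  if (n < 3L) stop("correlation matrix requires at least 3 rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    warning("zero-variance column(s): ",
            paste(vars[sds == 0 | !is.finite(sds)], collapse = ", "),
            "; affected correlations are undefined")
  }
  p <- r <- matrix(NA_real_, length(vars), length(vars),
                   dimnames = list(vars, vars))
  for (i in seq_along(vars)) {
    for (j in seq_len(i)) {
      if (sds[i] == 0 || sds[j] == 0) next
      rij <- sum((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j]))) /
        ((n - 1) * sds[i] * sds[j])
      rij <- min(1, max(-1, rij)) # guard 1-ulp overshoot
      r[i, j] <- r[j, i] <- rij
      if (i == j) {
        p[i, j] <- NA_real_
      } else {
        tstat <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
      }
    }
  }
  structure(list(r = r, p = p, n = n), class = "cor_table")
}

#' @export
print.cor_table <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlation matrix (N = %d); p-values in parentheses\n",
              x$n))
  vars <- rownames(x$r)
  body <- matrix("", length(vars), length(vars),
                 dimnames = list(vars, vars))
  for (i in seq_along(vars)) {
    for (j in seq_len(i)) {
      body[i, j] <- if (i == j) {
        "1.000"
      } else if (is.na(x$r[i, j])) {
        "NA"
      } else {
        sprintf("%.*f (%.3f)", digits, x$r[i, j], x$p[i, j])
      }
    }
  }
  print(as.data.frame(body), right = TRUE)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor `j`
#' on the remaining predictors with an intercept. A VIF of 1 means the
#' predictor is orthogonal to the others; exact collinearity yields `Inf`
#' with a warning rather than failing silently.
#'
#' @param panel Data.frame containing the predictor columns.
#' @param predictors Predictor names; default all standard predictors
#'   present.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(panel, predictors = intersect(predictor_names(),
                                              names(panel))) {
  if (length(predictors) < 2L) stop("VIF requires at least 2 predictors")
  x <- as.matrix(panel[, predictors, drop = FALSE])
  if (nrow(x) <= length(predictors)) {
    stop("VIF requires more rows than predictors")
  }
  out <- vapply(seq_along(predictors), function(j) {
    fit <- suppressWarnings(stats::lsfit(x[, -j, drop = FALSE], x[, j]))
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- predictors
  if (any(!is.finite(out))) {
    warning("exact collinearity: infinite VIF for ",
            paste(predictors[!is.finite(out)], collapse = ", "))
  }
  out
}
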