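#' Ordinary least squares fit of the suicide-rate model
#'
#' Fits `response ~ intercept + predictors` by QR decomposition and returns
#' the full inferential summary: coefficients, standard errors from
#' `sigma2 * (X'X)^-1` with `sigma2 = RSS / (n - k)`, two-sided t tests on
#' `n - k` degrees of freedom, the Gaussian log-likelihood
#' `l = -(n/2) * (log(2*pi) + log(RSS/n) + 1)`, R-squared and adjusted
#' R-squared, the overall F test against the intercept-only model, and
#' AIC/BIC.
#'
#' The information-criterion parameter count `k` defaults to the number of
#' regression coefficients including the intercept (the convention under
#' which criteria of the form `-2l + 2k` are reported by most econometric
#' software); `k_convention = "coef_plus_sigma"` additionally counts the
#' error variance, matching [stats::AIC()] on `lm` fits.
#'
#' An optional set of year fixed effects (one dummy per year beyond the
#' first) replaces the single pooled intercept with year-specific ones.
#'
#' @param panel Data.frame holding `response` and `predictors` columns.
#' @param predictors Character vector of predictor column names; may be
#'   empty for the intercept-only model.
#' @param response Outcome column name; default `"suicide_rate"`.
#' @param k_convention `"coef"` (default) or `"coef_plus_sigma"`, see above.
#' @param year_fe Add year dummy variables (requires a `year` column).
#' @return An object of class `orientia_fit`: a list with elements
#'   `coefficients` (data.frame term/estimate/se/t/p), `n`, `k`, `rss`,
#'   `loglik`, `r_squared`, `adj_r_squared`, `f_statistic`, `f_p_value`,
#'   `aic`, `bic`, `sigma`, `residuals`, `fitted`, `predictors`, `response`,
#'   and `perfect_fit` (TRUE when RSS is numerically zero, in which case the
#'   criteria are `-Inf`).
#' @examples
#' d <- data.frame(suicide_rate = c(0, 1, 2), x = c(0, 1, 2))
#' fit <- ols_fit(d, "x")
#' fit$coefficients
#' @export
ols_fit <- function(panel, predictors, response = "suicide_rate",
                    k_convention = c("coef", "coef_plus_sigma"),
                    year_fe = FALSE) {
  k_convention <- match.arg(k_convention)
  stopifnot(response %in% names(panel))
  missing_cols <- setdiff(predictors, names(panel))
  if (length(missing_cols)) {
    stop("panel lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  y <- as.numeric(panel[[response]])
  n <- length(y)
  x <- cbind(`(Intercept)` = rep(1, n))
  if (length(predictors)) {
    x <- cbind(x, as.matrix(panel[, predictors, drop = FALSE]))
  }
  if (year_fe) {
    stopifnot("year" %in% names(panel))
    yrs <- sort(unique(panel$year))
    for (yr in yrs[-1]) {
      x <- cbind(x, as.numeric(panel$year == yr))
      colnames(x)[ncol(x)] <- paste0("year", yr)
    }
  }
  k <- ncol(x)
  if (n <= k) {
    stop(sprintf("n = %d observations cannot identify k = %d coefficients",
                 n, k))
  }
  qrx <- qr(x)
  if (qrx$rank < k) {
    dependent <- colnames(x)[qrx$pivot[(qrx$rank + 1):k]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dependent, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(x %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - k)
  xtx_inv <- if (identical(as.integer(qrx$pivot), seq_len(k))) {
    chol2inv(qr.R(qrx))
  } else {
    solve(crossprod(x))
  }
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(x)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  perfect <- rss <= max(1e-12 * tss, .Machine$double.eps * n)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  adj_r2 <- if (k > 1) 1 - (1 - r2) * (n - 1) / (n - k) else r2
  if (k > 1 && tss > rss && rss > 0) {
    f <- ((tss - rss) / (k - 1)) / (rss / (n - k))
    pf_val <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  } else if (k > 1 && perfect) {
    f <- Inf
    pf_val <- 0
  } else {
    f <- NA_real_
    pf_val <- NA_real_
  }
  loglik <- if (perfect) Inf else -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
  k_ic <- k + (k_convention == "coef_plus_sigma")
  structure(
    list(coefficients = data.frame(term = colnames(x),
                                   estimate = unname(beta),
                                   se = unname(se), t = unname(tval),
                                   p = unname(pval),
                                   stringsAsFactors = FALSE),
         n = n, k = k, k_ic = k_ic, rss = rss, sigma = sqrt(sigma2),
         loglik = loglik, r_squared = r2, adj_r_squared = adj_r2,
         f_statistic = f, f_p_value = pf_val,
         aic = -2 * loglik + 2 * k_ic,
         bic = -2 * loglik + k_ic * log(n),
         residuals = resid, fitted = fitted,
         predictors = predictors, response = response,
         k_convention = k_convention, perfect_fit = perfect),
    class = "orientia_fit")
}

#' Information criteria of a fitted model
#'
#' Recomputes `AIC = -2l + 2k` and `BIC = -2l + k*log(n)` from the fit's
#' Gaussian log-likelihood, with `k` under the fit's parameter-count
#' convention (see [ols_fit()]). A perfect fit (RSS numerically zero) has
#' infinite likelihood; both criteria are then `-Inf` and the result carries
#' a `perfect_fit` attribute.
#'
#' @param fit An `orientia_fit`.
#' @return Named numeric vector `c(AIC =, BIC =)`; attribute `perfect_fit`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "orientia_fit"))
  out <- c(AIC = -2 * fit$loglik + 2 * fit$k_ic,
           BIC = -2 * fit$loglik + fit$k_ic * log(fit$n))
  attr(out, "perfect_fit") <- fit$perfect_fit
  out
}

#' @export
print.orientia_fit <- function(x, digits = 3, ...) {
  cat(sprintf("OLS fit: %s ~ %s   (n = %d)\n", x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1", x$n))
  tab <- x$coefficients
  tab$estimate <- format(tab$estimate, digits = digits + 1)
  tab$se <- format(tab$se, digits = digits)
  tab$t <- format(tab$t, digits = digits)
  tab$p <- format.pval(tab$p, digits = digits, eps = 1e-3)
  print(tab, row.names = FALSE)
  cat(sprintf("R2 %.3f  adj R2 %.3f  F %.2f (p %s)\n", x$r_squared,
              x$adj_r_squared, x$f_statistic,
              format.pval(x$f_p_value, digits = 3, eps = 1e-3)))
  cat(sprintf("logLik %.2f  AIC %.1f  BIC %.1f  sigma %.3f\n",
              x$loglik, x$aic, x$bic, x$sigma))
  invisible(x)
}

#' Coefficient table in the publication layout
#'
#' One row per term with columns `Coeff.`, `SE`, `P>t`, followed by footer
#' rows carrying AIC, BIC, `P>F`, R-squared, adjusted R-squared and n, the
#' shape regression tables are printed in.
#'
#' @param fit An `orientia_fit`.
#' @return A data.frame with character columns `term`, `coeff`, `se`, `p`.
#' @export
fit_table <- function(fit) {
  stopifnot(inherits(fit, "orientia_fit"))
  num <- function(v) formatC(v, format = "g", digits = 6)
  body <- data.frame(term = fit$coefficients$term,
                     coeff = num(fit$coefficients$estimate),
                     se = num(fit$coefficients$se),
                     p = num(fit$coefficients$p),
                     stringsAsFactors = FALSE)
  footer <- data.frame(
    term = c("AIC", "BIC", "P>F", "R2", "adj R2", "n"),
    coeff = c(num(fit$aic), num(fit$bic), num(fit$f_p_value),
              num(fit$r_squared), num(fit$adj_r_squared), fit$n),
    se = "", p = "", stringsAsFactors = FALSE)
  rbind(body, footer)
}
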