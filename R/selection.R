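#' Exhaustive all-subsets model comparison
#'
#' Fits every non-empty subset of the candidate predictors (each with an
#' intercept) and ranks the `2^p - 1` models by AIC ascending, ties broken
#' by BIC, then by fewer predictors, then by subset name. This is the
#' goodness-of-fit table used to judge whether a candidate variable earns
#' its place: a variable that improves the fit appears in the top-ranked
#' subsets.
#'
#' A rank-deficient subset does not abort the enumeration; its row is kept
#' with `NA` statistics and the error message in the `note` column.
#'
#' @param panel Data.frame with the response and predictor columns.
#' @param predictors Candidate predictors (at most 20, guarding the `2^p`
#'   explosion).
#' @param response Outcome column; default `"suicide_rate"`.
#' @param k_convention Parameter-count convention, see [ols_fit()].
#' @return A data.frame of class `subset_ranking`: one 0/1 indicator column
#'   per predictor, then `subset`, `n_predictors`, `aic`, `bic`,
#'   `f_p_value`, `r_squared`, `adj_r_squared`, `note`.
#' @examples
#' set.seed(1)
#' d <- data.frame(suicide_rate = rnorm(30), a = rnorm(30), b = rnorm(30))
#' all_subsets(d, c("a", "b"))
#' @export
all_subsets <- function(panel, predictors, response = "suicide_rate",
                        k_convention = "coef") {
  p <- length(predictors)
  if (p < 1L) stop("at least one candidate predictor is required")
  if (p > 20L) stop("more than 20 predictors: 2^p enumeration refused")
  subsets <- unlist(lapply(seq_len(p), function(m) {
    utils::combn(predictors, m, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(s) {
    ind <- as.integer(predictors %in% s)
    names(ind) <- predictors
    base <- as.data.frame(as.list(ind))
    base$subset <- paste(s, collapse = "+")
    base$n_predictors <- length(s)
    fit <- tryCatch(ols_fit(panel, s, response = response,
                            k_convention = k_convention),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      base$aic <- base$bic <- base$f_p_value <- NA_real_
      base$r_squared <- base$adj_r_squared <- NA_real_
      base$note <- conditionMessage(fit)
    } else {
      base$aic <- fit$aic
      base$bic <- fit$bic
      base$f_p_value <- fit$f_p_value
      base$r_squared <- fit$r_squared
      base$adj_r_squared <- fit$adj_r_squared
      base$note <- ""
    }
    base
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$aic, tab$bic, tab$n_predictors, tab$subset,
               na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  row.names(tab) <- NULL
  class(tab) <- c("subset_ranking", "data.frame")
  tab
}

#' Stepwise predictor selection (forward with backward purge)
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' whose two-sided coefficient p-value in the augmented model is smallest,
#' provided it is at most `alpha`; after each addition, any included
#' predictor whose p-value has risen above `alpha` is removed (largest
#' first). The procedure stops at a fixed point; it is deterministic given
#' the panel. If no candidate ever clears `alpha` the final model is empty —
#' a valid result, not an error.
#'
#' @param panel Data.frame with the response and predictor columns.
#' @param predictors Candidate predictors.
#' @param response Outcome column; default `"suicide_rate"`.
#' @param alpha Significance level for entry and retention, in (0, 1);
#'   default 0.01.
#' @return An object of class `stepwise_trace`: list with `final` (retained
#'   predictor names), `trace` (data.frame step/action/predictor/p_value),
#'   `alpha`, and `variant = "forward_with_purge"`.
#' @export
stepwise_select <- function(panel, predictors, response = "suicide_rate",
                            alpha = 0.01) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  included <- character(0)
  trace <- list()
  step <- 0L
  seen <- character(0)
  repeat {
    state <- paste(sort(included), collapse = "+")
    if (state %in% seen) break # cycle guard
    seen <- c(seen, state)
    # a saturated (zero-residual) model leaves nothing for candidates to
    # explain; their p-values are undefined, so selection terminates
    if (length(included) &&
        ols_fit(panel, included, response = response)$perfect_fit) {
      break
    }
    candidates <- setdiff(predictors, included)
    changed <- FALSE
    if (length(candidates)) {
      entry_p <- vapply(candidates, function(cand) {
        fit <- tryCatch(ols_fit(panel, c(included, cand),
                                response = response),
                        error = function(e) NULL)
        if (is.null(fit)) return(Inf) # unfittable candidate never enters
        p <- fit$coefficients$p[match(cand, fit$coefficients$term)]
        if (is.finite(p)) p else Inf
      }, numeric(1))
      best <- which.min(entry_p)
      if (entry_p[best] <= alpha) {
        included <- c(included, candidates[best])
        step <- step + 1L
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = "add", predictor = candidates[best],
          p_value = unname(entry_p[best]), stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    # purge: drop the worst offender until all retained terms clear alpha
    repeat {
      if (length(included) == 0L) break
      fit <- ols_fit(panel, included, response = response)
      slope_rows <- fit$coefficients$term != "(Intercept)"
      pv <- fit$coefficients$p[slope_rows]
      names(pv) <- fit$coefficients$term[slope_rows]
      worst <- which.max(pv)
      if (pv[worst] <= alpha) break
      victim <- names(pv)[worst]
      included <- setdiff(included, victim)
      step <- step + 1L
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, action = "remove", predictor = victim,
        p_value = unname(pv[worst]), stringsAsFactors = FALSE)
      changed <- TRUE
    }
    if (!changed) break
  }
  trace_df <- if (length(trace)) {
    do.call(rbind, trace)
  } else {
    data.frame(step = integer(0), action = character(0),
               predictor = character(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(list(final = included, trace = trace_df, alpha = alpha,
                 variant = "forward_with_purge", response = response),
            class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat(sprintf("Stepwise selection (%s, alpha = %g) on %s\n", x$variant,
              x$alpha, x$response))
  if (nrow(x$trace)) print(x$trace, row.names = FALSE) else cat("  no moves\n")
  cat("final model:",
      if (length(x$final)) paste(x$final, collapse = " + ") else "(empty)",
      "\n")
  invisible(x)
}
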