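test_that("OLS reproduces exact and degenerate fits", {
  line <- data.frame(suicide_rate = c(0, 1, 2), x = c(0, 1, 2))
  fit <- ols_fit(line, "x")
  expect_equal(fit$coefficients$estimate, c(0, 1), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$perfect_fit)
  expect_identical(information_criteria(fit)[["AIC"]], -Inf)

  set.seed(2)
  const <- data.frame(suicide_rate = rep(4.2, 10), x = rnorm(10),
                      z = rnorm(10))
  cfit <- ols_fit(const, c("x", "z"))
  expect_equal(cfit$coefficients$estimate, c(4.2, 0, 0), tolerance = 1e-10)
  expect_equal(cfit$r_squared, 0)
})

test_that("OLS matches the independent reference implementation to 1e-8", {
  set.seed(20)
  for (rep in 1:5) {
    d <- data.frame(suicide_rate = rnorm(20), a = rnorm(20), b = rnorm(20),
                    c = rnorm(20))
    fit <- ols_fit(d, c("a", "b", "c"))
    ref <- lm(suicide_rate ~ a + b + c, data = d)
    s <- summary(ref)
    expect_equal(fit$coefficients$estimate, unname(coef(ref)),
                 tolerance = 1e-8)
    expect_equal(fit$coefficients$se, unname(s$coefficients[, "Std. Error"]),
                 tolerance = 1e-8)
    expect_equal(fit$coefficients$p, unname(s$coefficients[, "Pr(>|t|)"]),
                 tolerance = 1e-8)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
    expect_equal(fit$r_squared, s$r.squared, tolerance = 1e-8)
    expect_equal(fit$adj_r_squared, s$adj.r.squared, tolerance = 1e-8)
    expect_equal(fit$f_statistic, unname(s$fstatistic["value"]),
                 tolerance = 1e-8)
    # the sigma-counting convention reproduces R's AIC/BIC on lm objects
    fit_sigma <- ols_fit(d, c("a", "b", "c"),
                         k_convention = "coef_plus_sigma")
    expect_equal(fit_sigma$aic, AIC(ref), tolerance = 1e-8)
    expect_equal(fit_sigma$bic, BIC(ref), tolerance = 1e-8)
    # residual orthogonality to every design column
    x <- cbind(1, as.matrix(d[, c("a", "b", "c")]))
    expect_lt(max(abs(crossprod(x, fit$residuals))),
              1e-8 * sum(abs(d$suicide_rate)))
  }
})

test_that("OLS rejects rank-deficient and over-parameterized designs", {
  set.seed(3)
  d <- data.frame(suicide_rate = rnorm(10), a = rnorm(10))
  d$b <- 2 * d$a
  expect_error(ols_fit(d, c("a", "b")), "rank deficient.*b")
  expect_error(ols_fit(d[1:2, ], c("a", "b")), "cannot identify")
  expect_error(ols_fit(d, "nope"), "lacks predictor")
})

test_that("information criteria match the hand-evaluated closed form", {
  # Construct data with RSS exactly 10 on n = 10, k = 2: residuals are a
  # vector orthogonal to the design, scaled to squared norm 10.
  n <- 10
  x <- 1:10
  e_raw <- residuals(lm((1:10)^2 ~ x))
  e <- e_raw * sqrt(10 / sum(e_raw^2))
  d <- data.frame(suicide_rate = 3 + 2 * x + e, x = x)
  fit <- ols_fit(d, "x")
  expect_equal(fit$rss, 10, tolerance = 1e-10)
  loglik_hand <- -(10 / 2) * (log(2 * pi) + log(10 / 10) + 1)
  expect_equal(fit$loglik, loglik_hand, tolerance = 1e-10)
  ic <- information_criteria(fit)
  expect_equal(ic[["AIC"]], -2 * loglik_hand + 4, tolerance = 1e-10)
  expect_equal(ic[["BIC"]], -2 * loglik_hand + 2 * log(10),
               tolerance = 1e-10)

  # equal log-likelihoods, k differing by 1, n = e^2: both criteria move by 2
  delta_aic <- (-2 * loglik_hand + 2 * 3) - (-2 * loglik_hand + 2 * 2)
  delta_bic <- (-2 * loglik_hand + 3 * log(exp(2))) -
    (-2 * loglik_hand + 2 * log(exp(2)))
  expect_equal(delta_aic, 2)
  expect_equal(delta_bic, 2)

  # invariance under predictor permutation
  set.seed(5)
  d2 <- data.frame(suicide_rate = rnorm(15), a = rnorm(15), b = rnorm(15))
  expect_equal(information_criteria(ols_fit(d2, c("a", "b"))),
               information_criteria(ols_fit(d2, c("b", "a"))))
})

test_that("all-subsets enumeration is complete, ordered and monotone", {
  set.seed(6)
  d <- data.frame(suicide_rate = rnorm(40), v1 = rnorm(40), v2 = rnorm(40),
                  v3 = rnorm(40), v4 = rnorm(40), v5 = rnorm(40))
  preds <- paste0("v", 1:5)
  rank5 <- all_subsets(d, preds)
  expect_equal(nrow(rank5), 31L)
  expect_true(!is.unsorted(rank5$aic))
  expect_equal(nrow(all_subsets(d, "v1")), 1L)

  # nested subsets cannot lose R^2 (brute force over all nested pairs)
  subsets <- strsplit(rank5$subset, "+", fixed = TRUE)
  r2 <- rank5$r_squared
  for (i in seq_along(subsets)) {
    for (j in seq_along(subsets)) {
      if (i != j && all(subsets[[i]] %in% subsets[[j]])) {
        expect_gte(r2[j] + 1e-12, r2[i])
      }
    }
  }

  # the AIC winner agrees with an independent per-subset recomputation
  oracle_aic <- vapply(subsets, function(s) {
    ref <- lm(reformulate(s, "suicide_rate"), data = d)
    as.numeric(-2 * logLik(ref)) + 2 * (length(s) + 1)
  }, numeric(1))
  expect_equal(rank5$subset[which.min(rank5$aic)],
               rank5$subset[which.min(oracle_aic)])
  expect_equal(rank5$aic, oracle_aic, tolerance = 1e-8)

  # a rank-deficient subset is annotated, not fatal
  d$v6 <- d$v1
  rank6 <- all_subsets(d, c("v1", "v6"))
  expect_equal(nrow(rank6), 3L)
  bad <- rank6[rank6$subset == "v1+v6", ]
  expect_true(is.na(bad$aic) && grepl("rank deficient", bad$note))
  expect_error(all_subsets(d, character(0)), "at least one")
  expect_error(all_subsets(d, sprintf("x%d", 1:21)), "20")
})

test_that("stepwise selection adds the dominant predictor and stops", {
  set.seed(9)
  d <- data.frame(suicide_rate = rnorm(30), junk = rnorm(30))
  d$self <- d$suicide_rate
  sw <- stepwise_select(d, c("junk", "self"))
  expect_equal(sw$trace$predictor[1], "self")
  expect_equal(sw$trace$action[1], "add")
  expect_equal(sw$final, "self")
  expect_error(stepwise_select(d, "junk", alpha = 1.2), "alpha")
})

test_that("stepwise keeps the empty model on pure noise at the 1% level", {
  set.seed(1)
  n_rep <- 200
  empty <- 0L
  for (r in seq_len(n_rep)) {
    d <- as.data.frame(matrix(rnorm(200 * 6), 200, 6))
    names(d) <- c("suicide_rate", paste0("v", 1:5))
    sw <- stepwise_select(d, paste0("v", 1:5), alpha = 0.01)
    empty <- empty + (length(sw$final) == 0L)
  }
  expect_gte(empty / n_rep, 0.95)
})

test_that("coefficients are recovered without bias and with nominal coverage", {
  n_rep <- 200
  beta_true <- default_beta()
  est <- matrix(NA_real_, n_rep, 6)
  covered <- matrix(NA, n_rep, 6)
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(seed = 5000 + r)
    panel <- simulate_recovery_panel(cfg)
    fit <- ols_fit(panel, model_predictor_sets()$model4)
    est[r, ] <- fit$coefficients$estimate
    ci_half <- qt(0.975, fit$n - fit$k) * fit$coefficients$se
    covered[r, ] <- abs(fit$coefficients$estimate - beta_true) <= ci_half
  }
  bias <- colMeans(est) - beta_true
  mc_se <- apply(est, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(bias) <= 3 * mc_se))
  coverage <- colMeans(covered)
  expect_true(all(coverage >= 0.91 & coverage <= 0.99))
})

test_that("adding past orientation to the four-covariate model lowers AIC", {
  panel <- simulate_study(generator_config(seed = 2))$panel
  sets <- model_predictor_sets()
  fit3 <- ols_fit(panel, sets$model3)
  fit4 <- ols_fit(panel, sets$model4)
  expect_lt(fit4$aic, fit3$aic)
  expect_lt(fit4$bic, fit3$bic)
})
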