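## Shared fixture: 3 true signals among 20 features, moderate censoring.
cox_fixture <- function(n = 400, p = 20, seed = 5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    lp <- X[, 1] + X[, 2] - X[, 3]
    T <- rexp(n, exp(lp)); C <- rexp(n, 1)
    list(X = X, time = pmin(T, C) + 1e-6, event = as.integer(T <= C))
  })
}

test_that("the Cox fit maximizes the Breslow partial likelihood", {
  ## single binary covariate vs a fine grid-search oracle
  set.seed(1)
  x <- rep(c(0, 1), each = 15)
  T <- rexp(30, exp(0.8 * x)); C <- rexp(30, 0.5)
  time <- pmin(T, C) + 1e-6; event <- as.integer(T <= C)
  m <- fit_cox(matrix(x), time, event)
  b_grid <- oracle_cox_grid(x, time, event)
  expect_lt(abs(m$beta - b_grid), 1e-3)
  ## fitted logPL is at least the null logPL
  expect_gte(m$log_partial_likelihood, cox_logpl(0, matrix(x), time, event))
  ## information criteria identities
  expect_equal(m$aic, -2 * m$log_partial_likelihood + 2)
  expect_equal(m$bic, -2 * m$log_partial_likelihood + log(sum(event)))
})

test_that("duplicating every patient leaves the Breslow estimate unchanged", {
  fx <- cox_fixture(n = 80, p = 3, seed = 2)
  m1 <- fit_cox(fx$X, fx$time, fx$event)
  m2 <- fit_cox(fx$X[rep(1:80, 2), ], rep(fx$time, 2), rep(fx$event, 2))
  expect_equal(m1$beta, m2$beta, tolerance = 1e-6)
})

test_that("a covariate independent of survival gets a near-zero coefficient", {
  set.seed(3)
  n <- 2000
  x <- rnorm(n)
  T <- rexp(n); C <- rexp(n, 0.5)
  m <- fit_cox(matrix(x), pmin(T, C) + 1e-6, as.integer(T <= C))
  expect_lt(abs(m$beta), 0.1)
})

test_that("stepwise selection contracts and AIC is at least as large as BIC", {
  fx <- cox_fixture(seed = 5)
  ma <- stepwise_cox(fx$X, fx$time, fx$event, "AIC")
  mb <- stepwise_cox(fx$X, fx$time, fx$event, "BIC")
  ## criterion of the returned model beats both the null and full models
  full <- fit_cox(fx$X, fx$time, fx$event)
  null_ll <- cox_logpl(rep(0, 20), fx$X, fx$time, fx$event)
  expect_lte(ma$aic, full$aic)
  expect_lte(ma$aic, -2 * null_ll)
  expect_lte(mb$bic, full$bic)
  expect_lte(mb$bic, -2 * null_ll)
  ## AIC penalizes complexity less: it keeps at least as many features here
  expect_gte(length(ma$selected), length(mb$selected))
  ## both retain the true signal
  expect_true(all(1:3 %in% ma$selected))
  expect_true(all(1:3 %in% mb$selected))
})

test_that("BIC discards pure-noise features", {
  empties <- vapply(1:3, function(s) {
    withr::with_seed(s * 100, {
      n <- 300
      X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("n", 1:8)))
      T <- rexp(n); C <- rexp(n, 0.6)
      m <- stepwise_cox(X, pmin(T, C) + 1e-6, as.integer(T <= C), "BIC")
      length(m$selected)
    })
  }, 0)
  expect_lte(mean(empties), 1)
})

test_that("penalized fits honor the tuning-zero and path-entry identities", {
  fx <- cox_fixture(n = 200, p = 5, seed = 7)
  base <- fit_cox(fx$X, fx$time, fx$event)
  for (pen in c("lasso", "scad")) {
    m0 <- penalized_cox(fx$X, fx$time, fx$event, pen, lambda = 0)
    expect_equal(m0$beta, base$beta, tolerance = 1e-6)
  }
  ## the analytic maximal penalty matches glmnet's path entry, and just
  ## above it every coefficient is zero
  lam_max <- lasso_entry_lambda(fx$X, fx$time, fx$event)
  pf <- glmnet::glmnet(fx$X, survival::Surv(fx$time, fx$event),
                       family = "cox")
  expect_equal(lam_max, pf$lambda[1], tolerance = 1e-6)
  expect_warning(m_hi <- penalized_cox(fx$X, fx$time, fx$event, "lasso",
                                       lambda = lam_max * 1.01),
                 "degenerate")
  expect_true(all(m_hi$beta == 0))
})

test_that("the lasso active set grows monotonically down the path", {
  fx <- cox_fixture(seed = 5)
  pf <- glmnet::glmnet(fx$X, survival::Surv(fx$time, fx$event),
                       family = "cox")
  sizes <- colSums(abs(as.matrix(pf$beta)) > 1e-10)
  ## along increasing penalty (reverse path order) the set never grows
  expect_true(all(diff(rev(sizes)) <= 0))
})

test_that("lasso recovers the three true signals across seeds", {
  hits <- vapply(1:10, function(s) {
    fx <- cox_fixture(seed = s)
    m <- penalized_cox(fx$X, fx$time, fx$event, "lasso", seed = s)
    all(1:3 %in% m$selected)
  }, TRUE)
  expect_gte(sum(hits), 8)
})

test_that("SCAD approaches the lasso as its concavity parameter grows", {
  fx <- cox_fixture(n = 250, p = 8, seed = 9)
  lam <- 0.08
  ml <- penalized_cox(fx$X, fx$time, fx$event, "lasso", lambda = lam)
  d <- vapply(c(3.7, 10, 100, 1e4), function(a) {
    ms <- penalized_cox(fx$X, fx$time, fx$event, "scad", lambda = lam,
                        scad_a = a)
    max(abs(ms$beta - ml$beta))
  }, 0)
  expect_true(all(diff(d) <= 1e-8))
  expect_lt(d[4], d[1] / 100)
})

test_that("mean-risk-score thresholding follows the strict rule", {
  m <- structure(list(beta = 1, feature_names = "x"), class = "cox_model")
  cls <- risk_score_classify(m, matrix(c(1, 2, 3, 6)), matrix(c(6, 3)))
  expect_equal(cls$threshold, 3)
  expect_equal(cls$label, c(1L, 0L))     # 6 > 3 is high; 3 is not
  ## affine rescaling of a feature with matching beta rescale: same labels
  fx <- cox_fixture(n = 150, p = 3, seed = 11)
  m1 <- fit_cox(fx$X, fx$time, fx$event)
  X2 <- fx$X; X2[, 1] <- X2[, 1] * 10
  m2 <- m1; m2$beta[1] <- m2$beta[1] / 10
  c1 <- risk_score_classify(m1, fx$X, fx$X)
  c2 <- risk_score_classify(m2, X2, X2)
  expect_identical(c1$label, c2$label)
})
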