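test_that("Kaplan-Meier matches the hand product-limit oracle", {
  ## worked example: S(1) = 2/3, then the last subject fails at 3
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival, c(2 / 3, 0), tolerance = 1e-12)
  ## randomized fixtures against the oracle
  for (s in 1:5) {
    set.seed(s)
    n <- 25
    time <- round(rexp(n, 0.3) + 0.1, 2)
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) event[1] <- 1
    km <- kaplan_meier(time, event)
    ora <- oracle_km(time, event)
    expect_equal(km$times, ora$times, tolerance = 1e-12)
    expect_equal(km$survival, ora$survival, tolerance = 1e-9)
  }
  ## censored-only input: survival identically one
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_length(km0$times, 0)
  expect_equal(km_survival_at(km0, c(0.5, 2, 10)), c(1, 1, 1))
  ## doubling every record leaves the curve unchanged
  km2 <- kaplan_meier(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2))
  expect_equal(km2$survival, c(2 / 3, 0), tolerance = 1e-12)
})

test_that("Kaplan-Meier tracks the true exponential curve at large n", {
  set.seed(10)
  n <- 5000
  T <- rexp(n, 0.2); C <- rexp(n, 0.1)
  time <- pmin(T, C); event <- as.integer(T <= C)
  km <- kaplan_meier(time, event)
  keep <- km$times <= quantile(time, 0.95)
  expect_lt(max(abs(km$survival[keep] - exp(-0.2 * km$times[keep]))), 0.02)
})

test_that("log-rank matches an independent O/E/V tabulation", {
  ## 6-patient toy data
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  group <- c(0, 0, 0, 1, 1, 1)
  lr <- logrank_test(time, event, group)
  ora <- oracle_logrank(time, event, group)
  expect_equal(lr$chi2, ora$chi2, tolerance = 1e-9)
  expect_equal(lr$p, ora$p, tolerance = 1e-9)
  ## observed and expected totals balance
  expect_lt(abs(sum(lr$observed) - sum(lr$expected)), 1e-9)
  ## randomized fixtures with ties
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.5)
    group <- rbinom(n, 1, 0.5)
    if (length(unique(group)) < 2) next
    if (sum(event) == 0) event[1] <- 1
    lr <- logrank_test(time, event, group)
    ora <- oracle_logrank(time, event, group)
    expect_equal(lr$chi2, ora$chi2, tolerance = 1e-9)
  }
})

test_that("log-rank symmetry, conventions and monotone-time invariance", {
  ## mirror-image groups: no difference
  lr <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                     c(0, 0, 0, 1, 1, 1))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  ## zero events: p = 1 by convention
  expect_equal(logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), c(0, 0, 1, 1))$p, 1)
  ## single group errors
  expect_error(logrank_test(c(1, 2), c(1, 1), c(1, 1)), "two")
  ## invariant under common monotone time transform
  set.seed(7)
  time <- rexp(40) + 0.1; event <- rbinom(40, 1, 0.6); grp <- rbinom(40, 1, 0.5)
  lr1 <- logrank_test(time, event, grp)
  lr2 <- logrank_test(log(1 + time), event, grp)
  expect_equal(lr1$chi2, lr2$chi2, tolerance = 1e-12)
})

test_that("concordance matches exhaustive pair enumeration", {
  ## perfect ranking, no censoring
  expect_equal(concordance_index(4:1, 1:4, rep(1, 4))$c, 1)
  ## 8-patient toy set vs brute force
  set.seed(3)
  for (s in 1:5) {
    score <- rnorm(8)
    time <- sample(1:6, 8, replace = TRUE) + runif(8) * 0
    event <- rbinom(8, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    time <- time + seq(0, 0.007, by = 0.001)  # break time ties
    expect_equal(concordance_index(score, time, event)$c,
                 oracle_cindex(score, time, event), tolerance = 1e-9)
  }
  ## complement property without score ties
  score <- rnorm(30); time <- rexp(30) + 0.1; event <- rbinom(30, 1, 0.8)
  event[1] <- 1
  expect_equal(concordance_index(score, time, event)$c +
                 concordance_index(-score, time, event)$c, 1,
               tolerance = 1e-9)
  ## random scores hover at one half
  set.seed(4)
  n <- 1000
  expect_lt(abs(concordance_index(rnorm(n), rexp(n) + 0.01, rep(1, n))$c - 0.5),
            0.03)
})

test_that("Uno's AUC reduces to the empirical AUC without censoring", {
  set.seed(2)
  n <- 200
  tt <- rexp(n) + 0.1; sc <- rnorm(n)
  auc <- uno_auc(tt, rep(1, n), tt, rep(1, n), sc, tau = 0.7)
  cases <- tt <= 0.7; ctrl <- tt > 0.7
  emp <- mean(outer(sc[cases], sc[ctrl], ">") +
                0.5 * outer(sc[cases], sc[ctrl], "=="))
  expect_equal(auc, emp, tolerance = 1e-12)
  ## perfectly separating score
  sc2 <- -tt
  expect_equal(uno_auc(tt, rep(1, n), tt, rep(1, n), sc2, tau = 0.7), 1)
  ## random score with 50% censoring stays near 1/2
  set.seed(9)
  n2 <- 4000
  T <- rexp(n2); C <- rexp(n2); time <- pmin(T, C) + 0.01
  event <- as.integer(T <= C)
  auc3 <- uno_auc(time, event, time, event, rnorm(n2), tau = 0.7)
  expect_lt(abs(auc3 - 0.5), 0.05)
})

test_that("sensitivity counts the predicted fraction of true-high patients", {
  ds <- survival_dataset(matrix(rnorm(30), 15, 2),
                         time = c(rep(2, 11), rep(6, 4)),
                         event = c(rep(1, 11), rep(0, 4)))
  part <- partition_risk_groups(ds)
  expect_equal(length(part$high_idx), 11)
  pred <- c(rep(1, 8), rep(0, 7))
  expect_equal(sensitivity_at_horizon(pred, part), 8 / 11)
  expect_equal(sensitivity_at_horizon(rep(1, 15), part), 1)
  expect_equal(sensitivity_at_horizon(rep(0, 15), part), 0)
})
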