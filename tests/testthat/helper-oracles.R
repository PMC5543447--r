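## Independent brute-force oracles used to validate the package's survival
## statistics and Bayesian-network arithmetic.  These deliberately share no
## code with the implementation.

## Hand product-limit estimator: loop over distinct event times.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(times = ts, survival = surv)
}

## Two-sample log-rank by explicit O/E/V tabulation at each event time.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    n1 <- sum(time >= t & g == 1)
    n2 <- sum(time >= t & g == 2)
    d1 <- sum(time == t & event == 1 & g == 1)
    d2 <- sum(time == t & event == 1 & g == 2)
    n <- n1 + n2; d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       O = O, E = E)
}

## Harrell's C by exhaustive pair enumeration.
oracle_cindex <- function(score, time, event) {
  n <- length(time)
  conc <- 0; usable <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ## the pair is usable iff the smaller time is an event
    if (time[i] == time[j]) next
    first <- if (time[i] < time[j]) i else j
    second <- if (time[i] < time[j]) j else i
    if (event[first] != 1) next
    usable <- usable + 1
    if (score[first] > score[second]) conc <- conc + 1
    else if (score[first] == score[second]) conc <- conc + 0.5
  }
  conc / usable
}

## Full joint of a (small) discrete Bayesian network by state enumeration.
oracle_bn_joint <- function(bn) {
  p <- bn$dag$p
  states <- expand.grid(lapply(bn$dag$n_states, function(r) 0:(r - 1)))
  states <- as.matrix(states)
  pr <- apply(states, 1, function(x) {
    out <- 1
    for (j in seq_len(p)) {
      pa <- bn$dag$parents[[j]]
      cfg <- 1
      mult <- 1
      for (pp in pa) { cfg <- cfg + x[pp] * mult; mult <- mult * bn$dag$n_states[pp] }
      out <- out * bn$cpts[[j]][x[j] + 1, cfg]
    }
    out
  })
  list(states = states, prob = pr)
}

## Breslow partial likelihood on a fine beta grid (single covariate).
oracle_cox_grid <- function(x, time, event, grid = seq(-4, 4, by = 1e-3)) {
  ll <- vapply(grid, function(b) survfs::cox_logpl(b, matrix(x), time, event), 0)
  grid[which.max(ll)]
}

## Small reusable strong-signal cohort.
toy_cohort <- function(n = 300, seed = 42, beta = c(1.5, 1.5), censor = 0.5,
                       p_total = 6) {
  cfg <- survfs::synth_config(n = n, p_total = p_total, n_noise = 2,
                              n_factors = 2, informative_idx = 1:2,
                              beta = beta, censor_rate_target = censor,
                              seed = seed)
  survfs::generate_cohort(cfg)
}
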