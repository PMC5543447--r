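test_that("hill climbing keeps independent variables unconnected", {
  set.seed(3)
  codes <- cbind(sample(0:1, 500, TRUE), sample(0:1, 500, TRUE))
  dag <- learn_structure(codes)
  expect_equal(sum(lengths(dag$parents)), 0)
  ## and scoring agrees: the empty graph beats the single-edge graph
  s_empty <- survfs:::family_score(codes, 2, integer(0), c(2L, 2L))
  s_edge <- survfs:::family_score(codes, 2, 1L, c(2L, 2L))
  expect_gt(s_empty, s_edge)
})

test_that("a deterministic copy yields one edge with the lexicographic tie-break", {
  set.seed(5)
  a <- sample(0:1, 500, TRUE)
  dag <- learn_structure(cbind(a, a))
  expect_equal(dag$parents[[2]], 1L)     # A -> B (smaller parent preferred)
  expect_length(dag$parents[[1]], 0)
  ## both orientations score identically; the edge must beat no-edge
  s0 <- survfs:::family_score(cbind(a, a), 1, integer(0), c(2L, 2L)) +
    survfs:::family_score(cbind(a, a), 2, integer(0), c(2L, 2L))
  s1 <- survfs:::family_score(cbind(a, a), 1, integer(0), c(2L, 2L)) +
    survfs:::family_score(cbind(a, a), 2, 1L, c(2L, 2L))
  expect_gt(s1, s0)
  expect_equal(dag$score, s1, tolerance = 1e-9)
})

test_that("learned graphs are always acyclic", {
  for (s in 1:5) {
    set.seed(s)
    codes <- matrix(sample(0:2, 6 * 120, TRUE), 120, 6)
    ## correlate a few columns to invite edges
    codes[, 2] <- pmin(codes[, 1] + sample(0:1, 120, TRUE), 2L)
    codes[, 3] <- codes[, 2]
    dag <- learn_structure(codes)
    expect_length(survfs:::topo_order(dag), 6)   # errors on a cycle
  }
})

test_that("CPT estimation follows the (smoothed) ML formula", {
  codes <- matrix(c(0L, 0L, 0L, 1L), 4, 1)
  dag <- learn_structure(rbind(codes, codes)[1:5, , drop = FALSE],
                         n_states = 2L)
  dag$parents <- list(integer(0))
  bn0 <- fit_parameters(dag, codes, alpha = 0)
  expect_equal(as.numeric(bn0$cpts[[1]]), c(0.75, 0.25))
  bn1 <- fit_parameters(dag, codes, alpha = 1)
  expect_equal(as.numeric(bn1$cpts[[1]]), c(4 / 6, 2 / 6))
  ## rows always sum to one, including parent configurations
  set.seed(2)
  codes2 <- cbind(sample(0:2, 60, TRUE), sample(0:2, 60, TRUE))
  dag2 <- learn_structure(codes2, n_states = c(3L, 3L))
  dag2$parents <- list(integer(0), 1L)
  bn2 <- fit_parameters(dag2, codes2, alpha = 1)
  expect_equal(unname(colSums(bn2$cpts[[2]])), rep(1, 3), tolerance = 1e-9)
  ## unobserved parent configuration with alpha = 0: uniform row + warning
  codes3 <- cbind(rep(0L, 20), sample(0:1, 20, TRUE))
  dag3 <- learn_structure(codes3, n_states = c(2L, 2L))
  dag3$parents <- list(integer(0), 1L)
  expect_warning(bn3 <- fit_parameters(dag3, codes3, alpha = 0),
                 "unobserved")
  expect_equal(unname(bn3$cpts[[2]][, 2]), c(0.5, 0.5))
})

test_that("network log-likelihood equals the enumerated joint", {
  ## chain A -> B over 2 states: compare against full joint enumeration
  set.seed(8)
  a <- sample(0:1, 200, TRUE)
  b <- ifelse(runif(200) < 0.8, a, 1L - a)
  codes <- cbind(a, b)
  dag <- learn_structure(codes, n_states = c(2L, 2L))
  dag$parents <- list(integer(0), 1L)
  bn <- fit_parameters(dag, codes, alpha = 1)
  joint <- oracle_bn_joint(bn)
  ll <- log_likelihood(bn, joint$states)
  expect_equal(exp(ll), joint$prob, tolerance = 1e-12)
  expect_equal(sum(joint$prob), 1, tolerance = 1e-12)
  ## single-node case: one factor
  dag1 <- learn_structure(matrix(c(0L, 1L, 1L, 1L, 0L), 5, 1), n_states = 2L)
  bn1 <- fit_parameters(dag1, matrix(c(0L, 1L, 1L, 1L, 0L), 5, 1), alpha = 0)
  expect_equal(log_likelihood(bn1, 1L), log(0.6), tolerance = 1e-12)
  ## smoothing keeps every instance finite
  expect_true(all(is.finite(log_likelihood(bn, joint$states))))
})

test_that("two-network posterior follows the normalized form", {
  ## symmetric case: equal priors and equal likelihoods give one half
  set.seed(4)
  codes <- matrix(sample(0:2, 100, TRUE), 100, 1)
  dag <- learn_structure(codes, n_states = 3L)
  bn <- fit_parameters(dag, codes, class_prior = 0.5)
  expect_equal(posterior_high(matrix(1L, 1, 1), bn, bn), 0.5,
               tolerance = 1e-12)
  ## direct evaluation: priors 0.5/0.5, likelihoods 0.8/0.2 -> 0.8
  mk <- function(p1) {
    d <- list(parents = list(integer(0)), score = 0, n_states = 2L, p = 1L)
    class(d) <- "bn_dag"
    structure(list(dag = d, cpts = list(matrix(c(1 - p1, p1), 2, 1)),
                   class_prior = 0.5, smoothing_alpha = 1),
              class = "bn_model")
  }
  expect_equal(posterior_high(1L, mk(0.8), mk(0.2)), 0.8, tolerance = 1e-12)
  ## posteriors over both networks always sum to one
  set.seed(5)
  c_h <- matrix(sample(0:2, 300, TRUE), 100, 3)
  c_l <- matrix(sample(0:2, 300, TRUE, prob = c(0.5, 0.3, 0.2)), 100, 3)
  ns <- c(3L, 3L, 3L)
  bh <- fit_parameters(learn_structure(c_h, n_states = ns), c_h,
                       class_prior = 0.3)
  bl <- fit_parameters(learn_structure(c_l, n_states = ns), c_l,
                       class_prior = 0.7)
  inst <- matrix(sample(0:2, 3000, TRUE), 1000, 3)
  ph <- posterior_high(inst, bh, bl)
  pl <- posterior_high(inst, bl, bh)   # role swap = the low-group posterior
  expect_lt(max(abs(ph + pl - 1)), 1e-12)
  expect_true(all(ph >= 0 & ph <= 1))
})

test_that("posterior is invariant to common likelihood scaling", {
  ## scaling both networks' likelihood by the same constant is equivalent to
  ## adding a constant in log space; the normalized posterior must not move
  d <- list(parents = list(integer(0)), score = 0, n_states = 2L, p = 1L)
  class(d) <- "bn_dag"
  mk <- function(p1, prior) structure(
    list(dag = d, cpts = list(matrix(c(1 - p1, p1), 2, 1)),
         class_prior = prior, smoothing_alpha = 1), class = "bn_model")
  base <- posterior_high(1L, mk(0.6, 0.4), mk(0.3, 0.6))
  ## direct normalized form
  expect_equal(base, (0.4 * 0.6) / (0.4 * 0.6 + 0.6 * 0.3), tolerance = 1e-12)
  ## multiply both likelihoods by 1/4 (renormalizing over a bigger space is
  ## a common factor): posterior unchanged
  scaled <- (0.4 * 0.15) / (0.4 * 0.15 + 0.6 * 0.075)
  expect_equal(base, scaled, tolerance = 1e-12)
})

test_that("uncensoring is the identity without censored patients and monotone in the threshold", {
  cfg <- synth_config(n = 250, p_total = 6, n_noise = 2, n_factors = 2,
                      informative_idx = 1:2, beta = c(1.5, 1.5),
                      censor_rate_target = 0, seed = 13)
  ds0 <- generate_cohort(cfg)
  part0 <- partition_risk_groups(ds0)
  expect_length(part0$censored_idx, 0)
  lab0 <- uncensor(part0, ds0)
  expect_equal(which(lab0$label == 1), sort(part0$high_idx))
  expect_true(all(lab0$origin == "observed"))

  ## censored cohort: count labeled high is non-increasing in p_th
  ds <- toy_cohort(n = 400, seed = 19, censor = 0.6)
  part <- partition_risk_groups(ds)
  expect_gt(length(part$censored_idx), 10)
  fit <- survfs:::uncensor_fit(part, ds, uncensor_config())
  n_high <- vapply(seq(0.025, 0.975, length.out = 21), function(th)
    sum(fit$posteriors > th), 0L)
  expect_true(all(diff(n_high) <= 0))
  ## threshold limits
  expect_equal(sum(fit$posteriors > 0.0001) , length(part$censored_idx))
  expect_equal(sum(fit$posteriors > 0.9999), 0L)
})

test_that("identical networks with equal priors give posterior one half", {
  ds <- toy_cohort(n = 300, seed = 23, censor = 0.5)
  part <- partition_risk_groups(ds)
  fit <- survfs:::uncensor_fit(part, ds, uncensor_config())
  cens_codes <- survfs::apply_bins(fit$discretization,
                                   ds$features[part$censored_idx, , drop = FALSE])
  bn <- fit$bn_high
  bn$class_prior <- 0.5
  post <- posterior_high(cens_codes, bn, bn)
  expect_lt(max(abs(post - 0.5)), 1e-12)
  ## so every censored patient is labeled low for any threshold >= 0.5
  expect_equal(sum(post > 0.5), 0L)
})

test_that("imputed labels recover the generator's risk class on strong signal", {
  agree <- vapply(1:10, function(s) {
    cfg <- synth_config(n = 1000, p_total = 10, n_noise = 2, n_factors = 3,
                        censor_rate_target = 0.6, informative_idx = 1:3,
                        beta = c(3, 3, 3), seed = s)
    ds <- generate_cohort(cfg)
    part <- partition_risk_groups(ds)
    lab <- uncensor(part, ds)
    tr <- attr(ds, "truth")
    mean(lab$label[part$censored_idx] == tr$true_class[part$censored_idx])
  }, 0)
  expect_gte(mean(agree), 0.70)
})

test_that("networks serialize to JSON-ready structure and DOT", {
  set.seed(1)
  a <- sample(0:1, 200, TRUE)
  codes <- cbind(a, ifelse(runif(200) < 0.9, a, 1L - a))
  dag <- learn_structure(codes, n_states = c(2L, 2L))
  bn <- fit_parameters(dag, codes)
  ser <- bn_serialize(bn, c("alpha", "beta"))
  expect_equal(ser$nodes, c("alpha", "beta"))
  expect_match(attr(ser, "dot"), "digraph")
  expect_silent(jsonlite::toJSON(ser, auto_unbox = TRUE))
})
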