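#' Configuration for the synthetic two-center cohort generator
#'
#' The generator emulates the structure of multi-center post-operative
#' surveillance cohorts: ~45 continuous, correlated morphology-like features
#' with a low-rank latent-factor structure, a Weibull event-time model whose
#' log-hazard is linear in a few informative features, and independent
#' censoring calibrated to a target censored fraction (defaults emulate a
#' cohort of 457 patients with about 91 percent censoring).
#'
#' @param n number of patients (>= 20).
#' @param p_total total feature count.
#' @param n_factors latent factors generating the correlated features.
#' @param n_noise features loading on no factor (pure unique variance).
#' @param informative_idx indices of features that drive the hazard.
#' @param beta log-hazard coefficients for the informative features.
#' @param weibull_shape,weibull_scale event-time distribution (years).
#' @param censor_rate_target desired overall censored (event-free) fraction
#'   in [0, 1); 0 disables censoring.
#' @param horizon risk horizon in years.
#' @param center_shift mean offset added to every feature in the second
#'   center (scalar or length-p vector).
#' @param loading factor loading of each structured feature on its factor.
#' @param seed integer seed.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(n = 457, p_total = 45, n_factors = 6, n_noise = 20,
                         informative_idx = 1:3, beta = c(1, 1, 1),
                         weibull_shape = 1.2, weibull_scale = 60,
                         censor_rate_target = 0.91, horizon = 5,
                         center_shift = 0.15, loading = 0.8, seed = 1) {
  stopifnot(n >= 20, p_total >= 2, n_factors >= 1,
            n_noise >= 0, n_noise < p_total,
            censor_rate_target >= 0, censor_rate_target < 1,
            length(beta) == length(informative_idx),
            all(informative_idx >= 1), all(informative_idx <= p_total))
  structure(list(n = n, p_total = p_total, n_factors = n_factors,
                 n_noise = n_noise, informative_idx = informative_idx,
                 beta = beta, weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale,
                 censor_rate_target = censor_rate_target, horizon = horizon,
                 center_shift = center_shift, loading = loading, seed = seed),
            class = "synth_config")
}

## p x m loading matrix: structured features are dealt round-robin across
## factors with a common loading; the last n_noise features load on nothing.
synth_loadings <- function(cfg) {
  p <- cfg$p_total
  L <- matrix(0, p, cfg$n_factors)
  structured <- seq_len(p - cfg$n_noise)
  for (i in structured) L[i, (i - 1L) %% cfg$n_factors + 1L] <- cfg$loading
  L
}

## Follow-up (censoring) times are Uniform(0, c_max) -- staggered entry into
## a study of fixed length -- with c_max calibrated so the expected censored
## fraction E[P(C < T | T)] = E[min(T / c_max, 1)] matches the target.  The
## conditional probability is closed-form given the realised event times, so
## the search is a smooth deterministic 1-d root find.
calibrate_censor_scale <- function(t_latent, target) {
  f <- function(cmax) mean(pmin(t_latent / cmax, 1)) - target
  lo <- 1e-6; hi <- 1e6
  if (f(hi) > 0 || f(lo) < 0)
    stop(sprintf(paste0("censoring calibration failed: achievable censored ",
                        "fraction in (%.4f, %.4f) for this event-time ",
                        "distribution"), f(hi) + target, f(lo) + target))
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

generate_raw <- function(cfg, n, seed, shift = 0, censor_scale = NULL) {
  p <- cfg$p_total
  L <- synth_loadings(cfg)
  with_seed(seed, {
    Fm <- matrix(stats::rnorm(n * cfg$n_factors), n, cfg$n_factors)
    uniq_sd <- sqrt(pmax(1 - rowSums(L^2), 0.05))
    X <- Fm %*% t(L) + matrix(stats::rnorm(n * p), n, p) %*% diag(uniq_sd)
    X <- sweep(X, 2, rep_len(shift, p), "+")
    lp <- drop(X[, cfg$informative_idx, drop = FALSE] %*% cfg$beta)
    u <- stats::runif(n)
    t_latent <- cfg$weibull_scale * (-log(u))^(1 / cfg$weibull_shape) *
      exp(-lp / cfg$weibull_shape)
    t_latent <- pmax(t_latent, 1e-6)
    if (cfg$censor_rate_target > 0) {
      cmax <- censor_scale %||%
        calibrate_censor_scale(t_latent, cfg$censor_rate_target)
      cens <- stats::runif(n, 0, cmax)
    } else {
      cmax <- Inf
      cens <- rep(Inf, n)
    }
    time <- pmin(t_latent, cens)
    event <- as.integer(t_latent <= cens)
    list(X = X, time = pmax(time, 1e-6), event = event, lp = lp,
         t_latent = t_latent, censor_scale = cmax)
  })
}

## Ground-truth risk grouping is covariate-based: a median split on the
## informative linear predictor (unit weights if beta is all zero), so the
## grouping is outcome-independent under a null hazard.
truth_class <- function(cfg, X, lp) {
  if (any(cfg$beta != 0)) s <- lp
  else s <- drop(X[, cfg$informative_idx, drop = FALSE] %*%
                   rep(1, length(cfg$informative_idx)))
  as.integer(s > stats::median(s))
}

#' Generate a synthetic censored survival cohort
#'
#' Features follow a latent-factor model (so factor reduction has signal);
#' the event time is Weibull with log-hazard linear in the informative
#' features; independent exponential censoring is calibrated so the expected
#' event-free fraction matches \code{censor_rate_target}.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param seed optional seed overriding \code{cfg$seed}.
#' @return A \code{survival_dataset}; attribute \code{"truth"} carries the
#'   generator's ground truth (informative indices, coefficients, latent
#'   event times, linear predictor, covariate-based risk class).
#' @export
generate_cohort <- function(cfg, seed = cfg$seed) {
  raw <- generate_raw(cfg, cfg$n, child_seed(seed, 1L))
  ds <- survival_dataset(raw$X, raw$time, raw$event,
                         feature_names = paste0("f", seq_len(cfg$p_total)),
                         center = rep(1L, cfg$n))
  attr(ds, "truth") <- list(informative_idx = cfg$informative_idx,
                            beta = cfg$beta, lp = raw$lp,
                            t_latent = raw$t_latent,
                            censor_scale = raw$censor_scale,
                            true_class = truth_class(cfg, raw$X, raw$lp))
  ds
}

#' Generate a linked pair of centers with a distribution shift
#'
#' Center 1 has \code{cfg$n} patients; center 2 has \code{round(0.6 * n)}
#' patients with every feature mean offset by \code{center_shift} and the
#' same hazard law.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param seed optional seed overriding \code{cfg$seed}.
#' @return List with elements \code{center1} and \code{center2}.
#' @export
generate_two_centers <- function(cfg, seed = cfg$seed) {
  c1 <- generate_cohort(cfg, seed)
  n2 <- round(0.6 * cfg$n)
  ## both centers follow the same study design: the censoring (follow-up)
  ## distribution calibrated on center 1 is reused for center 2
  raw <- generate_raw(cfg, n2, child_seed(seed, 2L), shift = cfg$center_shift,
                      censor_scale = attr(c1, "truth")$censor_scale)
  c2 <- survival_dataset(raw$X, raw$time, raw$event,
                         feature_names = paste0("f", seq_len(cfg$p_total)),
                         center = rep(2L, n2))
  attr(c2, "truth") <- list(informative_idx = cfg$informative_idx,
                            beta = cfg$beta, lp = raw$lp,
                            t_latent = raw$t_latent,
                            true_class = truth_class(cfg, raw$X, raw$lp))
  list(center1 = c1, center2 = c2)
}
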