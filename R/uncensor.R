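#' Uncensoring configuration
#'
#' @param p_th censoring-correction threshold in (0, 1): a censored patient
#'   is labeled high risk when the high-risk posterior exceeds it.
#' @param n_bins equal-width discretization bins.
#' @param smoothing_alpha CPT pseudo-count (0 = pure maximum likelihood).
#' @param prior_rule \code{"group_proportion"} sets the class priors to the
#'   observed high/low proportions among uncensored patients;
#'   \code{"uniform"} uses 0.5/0.5.
#' @param max_parents hill-climbing parent cap per node.
#' @return An \code{uncensor_config} list.
#' @export
uncensor_config <- function(p_th = 0.5, n_bins = 5, smoothing_alpha = 1,
                            prior_rule = c("group_proportion", "uniform"),
                            max_parents = 3) {
  stopifnot(p_th > 0, p_th < 1, n_bins >= 2, smoothing_alpha >= 0)
  structure(list(p_th = p_th, n_bins = n_bins,
                 smoothing_alpha = smoothing_alpha,
                 prior_rule = match.arg(prior_rule),
                 max_parents = max_parents),
            class = "uncensor_config")
}

## Learn the two risk-group networks and return the censored patients'
## high-risk posteriors.  Discretization bins are learned on the combined
## high+low rows and reused to code the censored instances.
uncensor_fit <- function(partition, ds, cfg = uncensor_config(),
                         feature_cols = NULL) {
  if (length(partition$high_idx) < 5 || length(partition$low_idx) < 5)
    stop("high and low risk groups each need at least 5 patients")
  cols <- feature_cols %||% seq_len(ncol(ds$features))
  X <- ds$features[, cols, drop = FALSE]
  obs <- c(partition$high_idx, partition$low_idx)
  dd <- equal_width_discretize(X[obs, , drop = FALSE], cfg$n_bins)
  codes_high <- dd$codes[seq_along(partition$high_idx), , drop = FALSE]
  codes_low <- dd$codes[length(partition$high_idx) + seq_along(partition$low_idx),
                        , drop = FALSE]
  priors <- if (cfg$prior_rule == "uniform") c(0.5, 0.5) else
    c(length(partition$high_idx), length(partition$low_idx)) / length(obs)
  fit_one <- function(codes, prior) {
    ## state space must be shared across the two networks: use the bin count
    dag <- learn_structure(codes, max_parents = cfg$max_parents,
                           n_states = rep(dd$n_bins, ncol(codes)))
    fit_parameters(dag, codes, alpha = cfg$smoothing_alpha,
                   class_prior = prior)
  }
  bn_high <- fit_one(codes_high, priors[1])
  bn_low <- fit_one(codes_low, priors[2])
  post <- if (length(partition$censored_idx)) {
    cens_codes <- apply_bins(dd, X[partition$censored_idx, , drop = FALSE])
    posterior_high(cens_codes, bn_high, bn_low)
  } else numeric(0)
  list(bn_high = bn_high, bn_low = bn_low, posteriors = post,
       discretization = dd, partition = partition)
}

#' Impute high/low risk labels for censored patients
#'
#' Learns one Bayesian network per uncensored risk group (hill climbing +
#' maximum-likelihood CPTs on equal-width-discretized features) and labels
#' each censored patient high risk when its normalised two-network posterior
#' exceeds the censoring-correction threshold.  Observed patients keep their
#' partition labels.
#'
#' @param partition a \code{risk_partition} of \code{ds}.
#' @param ds the \code{survival_dataset}.
#' @param cfg an \code{\link{uncensor_config}}.
#' @param feature_cols optional feature subset (indices) to build the
#'   networks on.
#' @return Object of class \code{labeled_dataset}: \code{features}
#'   (continuous, original scale), \code{label} (1 = high risk),
#'   \code{origin} ("observed"/"imputed"), \code{posterior} (NA for observed
#'   patients), plus the fitted networks.
#' @export
uncensor <- function(partition, ds, cfg = uncensor_config(),
                     feature_cols = NULL) {
  fit <- uncensor_fit(partition, ds, cfg, feature_cols)
  n <- nrow(ds$features)
  label <- integer(n)
  label[partition$high_idx] <- 1L
  label[partition$low_idx] <- 0L
  origin <- rep("observed", n)
  posterior <- rep(NA_real_, n)
  if (length(partition$censored_idx)) {
    label[partition$censored_idx] <- as.integer(fit$posteriors > cfg$p_th)
    origin[partition$censored_idx] <- "imputed"
    posterior[partition$censored_idx] <- fit$posteriors
  }
  structure(list(features = ds$features, label = label, origin = origin,
                 posterior = posterior, bn_high = fit$bn_high,
                 bn_low = fit$bn_low, config = cfg),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled dataset: %d patients (%d imputed), %d high / %d low\n",
              length(x$label), sum(x$origin == "imputed"), sum(x$label == 1),
              sum(x$label == 0)))
  invisible(x)
}
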