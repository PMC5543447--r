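## Outer-loop model selection and the user-facing fitting front end.

## Train the full risk model (uncensor + ANN) on a dataset restricted to a
## feature subset; returns the ANN plus the labels used.
train_risk_model <- function(ds, subset, n_hidden, cfg, seed) {
  part <- partition_risk_groups(ds, cfg$horizon, cfg$late_events_low)
  lab <- uncensor(part, ds, uncfg_of(cfg), feature_cols = subset)
  ann <- train_ann(ds$features[, subset, drop = FALSE], lab$label, n_hidden,
                   seed = seed, lr = cfg$lr, momentum = cfg$momentum,
                   epochs = cfg$epochs)
  list(ann = ann, labels = lab)
}

#' Select the final reduced ANN risk model across outer folds
#'
#' Runs the outer cross-validation loop: the training cohort is split into
#' \code{outer_k} folds; on each outer training fold the stepwise wrapper
#' search is run once per hidden-neuron count in the grid, the fold's
#' candidate being the (subset, neurons) pair with the smallest nested-CV
#' averaged p.  Each fold candidate is then scored by the log-rank p of its
#' predicted risk groups on the fold's untouched outer test fold, and the
#' candidate with the smallest outer-test p wins.  The winner is refit
#' (uncensoring + ANN) on the whole training cohort.
#'
#' @param center1 training \code{survival_dataset}.
#' @param cfg an \code{\link{fs_control}}.
#' @return Object of class \code{final_model}: \code{feature_subset} (indices
#'   into \code{center1}'s columns), \code{feature_names}, \code{n_hidden},
#'   \code{ann}, \code{outer_test_p}, \code{candidates} (per-fold summary),
#'   \code{train_time}/\code{train_event} (kept for censoring-distribution
#'   weights), \code{cfg}.
#' @export
select_final_model <- function(center1, cfg = fs_control()) {
  folds <- kfold_split(center1, cfg$outer_k, child_seed(cfg$seed, 3L),
                       cfg$stratify)
  candidates <- vector("list", cfg$outer_k)
  for (f in seq_len(cfg$outer_k)) {
    otr <- subset_dataset(center1, which(folds$fold_of != f))
    ote <- subset_dataset(center1, which(folds$fold_of == f))
    best <- NULL
    for (h in cfg$neuron_grid) {
      st <- stepwise_select(otr, cfg, n_hidden = h, seed_tag = f)
      if (is.null(best) || st$minimum_avg_p < best$st$minimum_avg_p)
        best <- list(st = st, n_hidden = h)
    }
    ## outer-test evaluation of the fold's candidate
    subset <- best$st$minimum_subset
    outer_p <- tryCatch({
      fit <- train_risk_model(otr, subset, best$n_hidden, cfg,
                              seed = child_seed(cfg$seed, 19L, f))
      pred <- predict_risk(fit$ann, ote$features[, subset, drop = FALSE])
      if (length(unique(pred$label)) < 2) 1
      else logrank_test(ote$time, ote$event, pred$label)$p
    }, error = function(e) 1)
    candidates[[f]] <- list(fold = f, subset = subset,
                            n_hidden = best$n_hidden,
                            inner_avg_p = best$st$minimum_avg_p,
                            outer_test_p = outer_p,
                            trajectory = best$st$trajectory)
  }
  outer_ps <- vapply(candidates, `[[`, 0, "outer_test_p")
  if (all(outer_ps >= 1)) {
    warning("no candidate separated its outer test fold; returning the smallest subset")
    win <- which.min(vapply(candidates, function(cd) length(cd$subset), 0))
  } else win <- which.min(outer_ps)
  chosen <- candidates[[win]]
  refit <- train_risk_model(center1, chosen$subset, chosen$n_hidden, cfg,
                            seed = child_seed(cfg$seed, 23L))
  structure(list(feature_subset = chosen$subset,
                 feature_names = center1$feature_names[chosen$subset],
                 n_hidden = chosen$n_hidden, ann = refit$ann,
                 labels = refit$labels, outer_test_p = chosen$outer_test_p,
                 fold = win, candidates = candidates,
                 train_time = center1$time, train_event = center1$event,
                 cfg = cfg),
            class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  cat(sprintf("Final risk model: %d features, %d hidden neurons\n",
              length(x$feature_subset), x$n_hidden))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  cat(sprintf("  outer-test log-rank p: %.4g (fold %d)\n", x$outer_test_p,
              x$fold))
  invisible(x)
}

#' Evaluate a final model on an independent center
#'
#' Predicts each patient's risk group and reports the log-rank p between the
#' predicted groups, Harrell's concordance of the continuous score, Uno's
#' IPCW AUC at the horizon (censoring weights from the training cohort),
#' sensitivity against the center's uncensored high-risk group, predicted
#' group sizes, and per-group Kaplan-Meier curves.
#'
#' @param fm a \code{final_model} (or \code{survfs} fit).
#' @param center2 evaluation \code{survival_dataset}; must contain the
#'   model's features.
#' @return Object of class \code{evaluation_report}.
#' @export
evaluate_on_center <- function(fm, center2) {
  if (inherits(fm, "survfs")) return(evaluate_on_center(fm$final, center2))
  missing_feats <- setdiff(fm$feature_names, center2$feature_names)
  if (length(missing_feats))
    stop("evaluation center lacks model features: ",
         paste(missing_feats, collapse = ", "))
  cols <- match(fm$feature_names, center2$feature_names)
  pred <- predict_risk(fm$ann, center2$features[, cols, drop = FALSE])
  lr <- if (length(unique(pred$label)) < 2)
    list(chi2 = 0, p = 1) else
      logrank_test(center2$time, center2$event, pred$label)
  ci <- concordance_index(pred$score, center2$time, center2$event)
  auc <- tryCatch(uno_auc(fm$train_time, fm$train_event, center2$time,
                          center2$event, pred$score, fm$cfg$horizon),
                  error = function(e) NA_real_)
  part <- tryCatch(partition_risk_groups(center2, fm$cfg$horizon,
                                         fm$cfg$late_events_low),
                   error = function(e) NULL)
  sens <- if (is.null(part)) NA_real_ else
    sensitivity_at_horizon(pred$label, part)
  km_high <- if (any(pred$label == 1))
    kaplan_meier(center2$time[pred$label == 1], center2$event[pred$label == 1])
  km_low <- if (any(pred$label == 0))
    kaplan_meier(center2$time[pred$label == 0], center2$event[pred$label == 0])
  structure(list(logrank_p = lr$p, logrank_chi2 = lr$chi2, c_index = ci$c,
                 c_index_se = ci$se, uno_auc = auc, sensitivity = sens,
                 n_high = sum(pred$label == 1), n_low = sum(pred$label == 0),
                 km_high = km_high, km_low = km_low, score = pred$score,
                 label = pred$label),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Risk-group evaluation\n")
  cat(sprintf("  log-rank p: %.4g (chi2 = %.3f)\n", x$logrank_p, x$logrank_chi2))
  cat(sprintf("  concordance index: %.3f (SE %.4f)\n", x$c_index, x$c_index_se))
  cat(sprintf("  Uno's AUC: %s\n",
              if (is.na(x$uno_auc)) "not estimable" else sprintf("%.3f", x$uno_auc)))
  cat(sprintf("  sensitivity: %.3f\n", x$sensitivity))
  cat(sprintf("  predicted groups: %d high / %d low\n", x$n_high, x$n_low))
  invisible(x)
}

#' Plot Kaplan-Meier curves of the predicted risk groups
#'
#' @param x an \code{evaluation_report}.
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @export
plot.evaluation_report <- function(x, main = "Predicted risk groups", ...) {
  step_xy <- function(km, tmax) {
    if (is.null(km) || length(km$times) == 0)
      return(list(x = c(0, tmax), y = c(1, 1)))
    list(x = c(0, rep(km$times, each = 2), tmax),
         y = c(1, 1, rep(km$survival, each = 2)))
  }
  tmax <- max(c(x$km_high$times, x$km_low$times, 1))
  hi <- step_xy(x$km_high, tmax); lo <- step_xy(x$km_low, tmax)
  graphics::plot(hi$x, hi$y, type = "l", col = "firebrick", lwd = 2,
                 xlab = "Years", ylab = "Freedom from event", ylim = c(0, 1),
                 main = main, ...)
  graphics::lines(lo$x, lo$y, col = "navy", lwd = 2)
  graphics::legend("bottomleft",
                   legend = c(sprintf("high risk (n=%d)", x$n_high),
                              sprintf("low risk (n=%d)", x$n_low)),
                   col = c("firebrick", "navy"), lwd = 2, bty = "n")
  invisible(x)
}

#' Fit a reduced neural-network risk model to a censored survival cohort
#'
#' The package's main fitting function.  Runs the full selection pipeline on
#' the training cohort: (1) factor-analysis feature reduction (varimax
#' rotation, uniqueness-histogram threshold), (2) outer cross-validation
#' with permuted replicas, (3) stepwise wrapper feature selection scored by
#' nested-CV log-rank p-values, (4) Bayesian-network uncensoring inside
#' every inner split, (5) ANN risk classification, and (6) final model
#' selection on the outer test folds.
#'
#' @param formula a formula of the form
#'   \code{survival::Surv(time, event) ~ .} (or naming specific feature
#'   columns) describing the survival outcome and candidate features.
#' @param data a data frame, or a \code{survival_dataset} (in which case
#'   \code{formula} may be omitted).
#' @param cfg an \code{\link{fs_control}}.
#' @param reduce run the factor-analysis reduction first (default TRUE).
#' @param variance_fraction explained-variance target for the factor count.
#' @param bin_width uniqueness-histogram bin width.
#' @return Object of class \code{survfs}: the \code{final_model}, the factor
#'   model and retained features, and the adequacy report.
#' @examples
#' cfg <- synth_config(n = 120, p_total = 8, n_noise = 2, n_factors = 2,
#'                     censor_rate_target = 0.6, beta = c(1.5, 1.5),
#'                     informative_idx = 1:2, seed = 7)
#' ds <- generate_cohort(cfg)
#' fit <- survfs(data = ds,
#'               cfg = fs_control(outer_k = 2, inner_k = 2, replicas = 1,
#'                                neuron_grid = 3, epochs = 150, seed = 7),
#'               reduce = FALSE)
#' print(fit)
#' @export
survfs <- function(formula = NULL, data, cfg = fs_control(), reduce = TRUE,
                   variance_fraction = 0.80, bin_width = 0.05) {
  ds <- if (inherits(data, "survival_dataset")) data
        else dataset_from_formula(formula, data)
  adequacy <- NULL; fm <- NULL; retained <- seq_len(ncol(ds$features))
  threshold <- NA_real_
  if (reduce && ncol(ds$features) >= 5) {
    adequacy <- adequacy_tests(ds$features)
    m <- select_n_factors(ds$features, variance_fraction)
    m <- max(1L, min(m, ncol(ds$features) - 1L))
    fm <- fit_factor_model(ds$features, m)
    threshold <- uniqueness_threshold(fm, bin_width)
    retained <- tryCatch(reduce_features(fm, threshold),
                         error = function(e) integer(0))
    if (length(retained) < 2) {
      ## histogram cutoff too aggressive for this fit: fall back to the
      ## conventional 0.25 communality rule, then to no reduction
      threshold <- 0.25
      retained <- which(fm$uniquenesses <= threshold)
      if (length(retained) < 2) {
        warning("uniqueness filter would drop almost all features; skipping reduction")
        retained <- seq_len(ncol(ds$features))
        threshold <- NA_real_
      }
    }
  }
  reduced <- subset_features(ds, retained)
  final <- select_final_model(reduced, cfg)
  structure(list(final = final, factor_model = fm, adequacy = adequacy,
                 uniqueness_cutoff = threshold, retained = retained,
                 retained_names = ds$feature_names[retained],
                 feature_names = ds$feature_names, cfg = cfg,
                 n = nrow(ds$features), p = ncol(ds$features)),
            class = "survfs")
}

dataset_from_formula <- function(formula, data) {
  if (is.null(formula)) stop("supply a formula or a survival_dataset")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y))
    stop("the response must be a survival::Surv(time, event) object")
  X <- mf[, -1, drop = FALSE]
  if (!all(vapply(X, is.numeric, TRUE)))
    stop("all candidate features must be numeric")
  survival_dataset(as.matrix(X), y[, "time"], y[, "status"])
}

#' @export
print.survfs <- function(x, ...) {
  cat(sprintf("survfs fit: %d patients, %d candidate features\n", x$n, x$p))
  if (!is.null(x$factor_model))
    cat(sprintf("  factor reduction: %d -> %d features (uniqueness cutoff %.2f)\n",
                x$p, length(x$retained), x$uniqueness_cutoff))
  cat(sprintf("  wrapper selection: %d features, %d hidden neurons\n",
              length(x$final$feature_subset), x$final$n_hidden))
  cat("  selected:", paste(x$final$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.survfs <- function(object, ...) {
  x <- object
  cat("Reduced neural-network risk model for censored survival data\n\n")
  print(x)
  if (!is.null(x$adequacy)) { cat("\nAdequacy:\n"); print(x$adequacy) }
  cat("\nOuter-fold candidates:\n")
  for (cd in x$final$candidates)
    cat(sprintf("  fold %d: %d features, %d neurons, inner avg p %.4g, outer p %.4g\n",
                cd$fold, length(cd$subset), cd$n_hidden, cd$inner_avg_p,
                cd$outer_test_p))
  invisible(x)
}

#' Predict risk groups from a fitted model
#'
#' @param object a \code{survfs} fit (or \code{final_model}).
#' @param newdata a \code{survival_dataset} or data frame holding the
#'   model's feature columns.
#' @param ... unused.
#' @return Data frame with \code{score} and \code{label} (1 = high risk).
#' @export
predict.survfs <- function(object, newdata, ...) {
  fm <- object$final
  nm <- fm$feature_names
  X <- if (inherits(newdata, "survival_dataset")) {
    cols <- match(nm, newdata$feature_names)
    if (anyNA(cols)) stop("newdata lacks model features")
    newdata$features[, cols, drop = FALSE]
  } else {
    if (!all(nm %in% names(newdata))) stop("newdata lacks model features")
    as.matrix(newdata[, nm, drop = FALSE])
  }
  pred <- predict_risk(fm$ann, X)
  data.frame(score = pred$score, label = pred$label)
}

#' @export
plot.survfs <- function(x, newdata = NULL, ...) {
  if (is.null(newdata))
    stop("supply a survival_dataset via newdata to plot predicted KM curves")
  rep_ <- evaluate_on_center(x$final, newdata)
  plot(rep_, ...)
}
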