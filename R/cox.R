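## Cox proportional-hazards baselines: partial-likelihood fitting (Breslow
## ties), stepwise AIC/BIC selection, lasso/SCAD penalized selection, and
## mean-risk-score thresholding.

#' Breslow log partial likelihood at a fixed coefficient vector
#'
#' @param beta coefficient vector.
#' @param X feature matrix.
#' @param time,event survival data.
#' @return Log partial likelihood (Breslow tie handling).
#' @export
cox_logpl <- function(beta, X, time, event) {
  eta <- drop(as.matrix(X) %*% beta)
  ord <- order(time)
  eta <- eta[ord]; ev <- event[ord]; tt <- time[ord]
  ## risk-set sums from the back; ties share the same risk set (Breslow)
  w <- exp(eta)
  rs <- rev(cumsum(rev(w)))
  ll <- 0
  i <- 1; n <- length(tt)
  while (i <= n) {
    j <- i
    while (j < n && tt[j + 1] == tt[i]) j <- j + 1
    d <- which(ev[i:j] == 1) + i - 1
    if (length(d)) ll <- ll + sum(eta[d]) - length(d) * log(rs[i])
    i <- j + 1
  }
  ll
}

new_cox_model <- function(beta, feature_names, logpl, n_events, penalty,
                          tuning = NA_real_, threshold = NA_real_) {
  selected <- which(abs(beta) > 1e-10)
  k <- length(selected)
  structure(list(beta = beta, feature_names = feature_names,
                 log_partial_likelihood = logpl,
                 aic = -2 * logpl + 2 * k,
                 bic = -2 * logpl + log(max(n_events, 1)) * k,
                 penalty = penalty, tuning = tuning, selected = selected,
                 n_events = n_events, threshold = threshold),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("Cox model (%s): %d of %d features, logPL = %.3f, AIC = %.2f, BIC = %.2f\n",
              x$penalty, length(x$selected), length(x$beta),
              x$log_partial_likelihood, x$aic, x$bic))
  invisible(x)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial likelihood with Breslow tie handling (Newton-Raphson via
#' \code{survival::coxph}).  Monotone-likelihood (separation) fits are
#' flagged with a warning and the coefficients capped at |beta| = 20.
#'
#' @param X feature matrix (no constant columns).
#' @param time,event survival data (>= 2 events).
#' @return A \code{cox_model}.
#' @export
fit_cox <- function(X, time, event) {
  X <- as.matrix(X)
  if (sum(event) < 2) stop("need at least 2 events to fit a Cox model")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant feature column")
  df <- data.frame(X)
  df$.time <- time; df$.event <- event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", colnames(df)[seq_len(ncol(X))]),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  beta <- unname(stats::coef(fit))
  if (any(abs(beta) > 20)) {
    warning("possible monotone partial likelihood; coefficients capped at |beta| = 20")
    beta <- pmin(pmax(beta, -20), 20)
  }
  logpl <- cox_logpl(beta, X, time, event)
  new_cox_model(beta, colnames(X) %||% paste0("V", seq_len(ncol(X))), logpl,
                sum(event), penalty = "none")
}

#' Bidirectional stepwise Cox selection under AIC or BIC
#'
#' Starts from the null model and adds/drops one feature at a time until no
#' single move lowers the chosen criterion.
#'
#' @param X feature matrix.
#' @param time,event survival data.
#' @param criterion \code{"AIC"} or \code{"BIC"} (BIC uses log(number of
#'   events) as the sample-size term; set \code{bic_n = "n"} for log(n)).
#' @param bic_n sample-size convention for BIC.
#' @return A \code{cox_model} over the selected features (zero coefficients
#'   elsewhere).
#' @export
stepwise_cox <- function(X, time, event, criterion = c("AIC", "BIC"),
                         bic_n = c("events", "n")) {
  criterion <- match.arg(criterion)
  bic_n <- match.arg(bic_n)
  X <- as.matrix(X)
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- nm
  df <- data.frame(X, check.names = FALSE)
  df$.time <- time; df$.event <- event
  k_pen <- if (criterion == "AIC") 2 else
    log(if (bic_n == "events") sum(event) else length(time))
  null_fit <- survival::coxph(survival::Surv(.time, .event) ~ 1, data = df,
                              ties = "breslow")
  upper <- stats::as.formula(paste("~", paste(sprintf("`%s`", nm),
                                              collapse = " + ")))
  sel <- stats::step(null_fit, scope = list(lower = ~1, upper = upper),
                     direction = "both", k = k_pen, trace = 0)
  chosen <- names(stats::coef(sel))
  chosen <- gsub("`", "", chosen)
  beta <- stats::setNames(numeric(ncol(X)), nm)
  if (length(chosen)) beta[chosen] <- unname(stats::coef(sel))
  logpl <- cox_logpl(beta, X, time, event)
  m <- new_cox_model(unname(beta), nm, logpl, sum(event),
                     penalty = tolower(criterion))
  m
}

## SCAD penalty derivative (a = 3.7 is the standard choice)
scad_deriv <- function(b, lambda, a = 3.7) {
  b <- abs(b)
  ifelse(b <= lambda, lambda,
         ifelse(b < a * lambda, (a * lambda - b) / (a - 1), 0))
}

## glmnet rescales penalty factors to sum to nvars; compensate so the
## effective per-feature penalty is exactly lambda * w_j.
glmnet_weighted <- function(X, y, lambda, w) {
  p <- ncol(X)
  if (all(w < 1e-10)) return(NULL)
  lam_adj <- lambda * sum(w) / p
  fit <- glmnet::glmnet(X, y, family = "cox", alpha = 1,
                        penalty.factor = w, lambda = lam_adj,
                        standardize = TRUE, thresh = 1e-12)
  as.numeric(fit$beta)
}

#' Penalized Cox selection (lasso or SCAD)
#'
#' Lasso via \code{glmnet} over its log-spaced penalty path; SCAD by
#' local-linear-approximation reweighting (a = 3.7) around the same path.
#' The tuning parameter is chosen by k-fold cross-validated partial
#' likelihood (Verweij-van Houwelingen for SCAD).  Features are standardized
#' internally; coefficients are reported on the original scale.  A tuning
#' parameter of exactly 0 is the unpenalized Cox fit.
#'
#' @param X feature matrix.
#' @param time,event survival data.
#' @param penalty \code{"lasso"} or \code{"scad"}.
#' @param n_cv_folds cross-validation folds (default 10).
#' @param lambda optional fixed tuning parameter (skips cross-validation).
#' @param seed fold-assignment seed.
#' @param scad_a SCAD concavity parameter (default 3.7).
#' @return A \code{cox_model}; \code{tuning} records the chosen lambda.
#' @export
penalized_cox <- function(X, time, event, penalty = c("lasso", "scad"),
                          n_cv_folds = 10, lambda = NULL, seed = 1,
                          scad_a = 3.7) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  y <- survival::Surv(time, event)
  if (!is.null(lambda) && lambda == 0) {
    m <- fit_cox(X, time, event)
    m$penalty <- penalty; m$tuning <- 0
    return(m)
  }
  if (is.null(lambda) && sum(event) < n_cv_folds)
    stop("need at least n_cv_folds events for cross-validation")
  foldid <- with_seed(child_seed(seed, 31L),
                      sample(rep_len(seq_len(n_cv_folds), length(time))))
  path_fit <- glmnet::glmnet(X, y, family = "cox", alpha = 1,
                             standardize = TRUE, thresh = 1e-12)
  if (penalty == "lasso") {
    if (is.null(lambda)) {
      cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 1,
                              foldid = foldid, standardize = TRUE,
                              thresh = 1e-12)
      lambda <- cv$lambda.min
    }
    beta <- as.numeric(stats::coef(path_fit, s = lambda, exact = TRUE, x = X,
                                   y = y))
  } else {
    lla_fit <- function(Xm, ym, tt, ev, lam) {
      b <- as.numeric(stats::coef(path_fit, s = lam, exact = FALSE))
      for (it in 1:4) {
        w <- scad_deriv(b, lam, scad_a) / lam
        b_new <- glmnet_weighted(Xm, ym, lam, w)
        if (is.null(b_new)) {           # penalty vanished: unpenalized fit
          b_new <- fit_cox(Xm, tt, ev)$beta
        }
        if (max(abs(b_new - b)) < 1e-6) { b <- b_new; break }
        b <- b_new
      }
      b
    }
    if (is.null(lambda)) {
      lams <- path_fit$lambda[seq(1, length(path_fit$lambda), by = 4)]
      cvll <- vapply(lams, function(lam) {
        tot <- 0
        for (f in seq_len(n_cv_folds)) {
          tr <- foldid != f
          if (sum(event[tr]) < 2) next
          bf <- tryCatch(lla_fit(X[tr, , drop = FALSE], y[tr], time[tr],
                                 event[tr], lam),
                         error = function(e) rep(0, ncol(X)))
          tot <- tot + (cox_logpl(bf, X, time, event) -
                          cox_logpl(bf, X[tr, , drop = FALSE], time[tr],
                                    event[tr]))
        }
        tot
      }, 0)
      lambda <- lams[which.max(cvll)]
    }
    beta <- lla_fit(X, y, time, event, lambda)
  }
  if (all(abs(beta) < 1e-10))
    warning("degenerate penalized path: all coefficients zero at the chosen tuning")
  logpl <- cox_logpl(beta, X, time, event)
  new_cox_model(beta, nm, logpl, sum(event), penalty = penalty,
                tuning = lambda)
}

#' Analytic entry point of the lasso path for the Cox model
#'
#' The smallest penalty at which all coefficients are zero:
#' max_j |U_j| / n, with U the Breslow partial-likelihood score at beta = 0
#' computed on internally standardized features (glmnet's scale).
#'
#' @param X feature matrix.
#' @param time,event survival data.
#' @return The analytic maximal lambda.
#' @export
lasso_entry_lambda <- function(X, time, event) {
  X <- as.matrix(X)
  n <- nrow(X)
  sds <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  ord <- order(time)
  Xs <- Xs[ord, , drop = FALSE]
  ev <- event[ord]; tt <- time[ord]
  ## score at beta = 0: sum over events of (x_i - risk-set mean of x)
  csum <- apply(Xs[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  nrisk <- n:1
  U <- rep(0, ncol(Xs))
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && tt[j + 1] == tt[i]) j <- j + 1
    d <- which(ev[i:j] == 1) + i - 1
    if (length(d))
      U <- U + colSums(Xs[d, , drop = FALSE]) -
        length(d) * csum[i, ] / nrisk[i]
    i <- j + 1
  }
  max(abs(U)) / n
}

#' Classify patients by mean-risk-score thresholding
#'
#' The risk score is the Cox linear predictor beta . x; the threshold is the
#' mean score on the training cohort, and the same threshold is applied to
#' any test cohort.  A score strictly above the threshold is high risk.
#'
#' @param m a fitted \code{cox_model}.
#' @param X_train training feature matrix (defines the threshold).
#' @param X_test feature matrix to classify.
#' @return List with \code{label} (0/1 per test patient), \code{score},
#'   \code{threshold}.
#' @export
risk_score_classify <- function(m, X_train, X_test) {
  thr <- mean(drop(as.matrix(X_train) %*% m$beta))
  score <- drop(as.matrix(X_test) %*% m$beta)
  list(label = as.integer(score > thr), score = score, threshold = thr)
}
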