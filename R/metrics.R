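#' Kaplan-Meier product-limit curve
#'
#' @param time durations (> 0).
#' @param event 0/1 indicators.
#' @return Object of class \code{km_curve}: distinct event \code{times},
#'   \code{survival} S(t) at each, \code{at_risk} and \code{n_events} counts.
#'   With no events the curve is identically 1 (empty \code{times}).
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0) stop("empty input")
  stopifnot(length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], n_events = fit$n.event[keep],
                 n = length(time)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param km a \code{km_curve}.
#' @param t numeric times.
#' @return S(t); 1 before the first event.
#' @export
km_survival_at <- function(km, t) {
  if (length(km$times) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, km$times)
  c(1, km$survival)[idx + 1]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d event times\n",
              x$n, length(x$times)))
  invisible(x)
}

#' Export a Kaplan-Meier curve as a data frame / CSV
#' @param km a \code{km_curve}.
#' @param path optional CSV path; when given the table is also written there.
#' @export
km_as_table <- function(km, path = NULL) {
  df <- data.frame(time = km$times, survival = km$survival,
                   at_risk = km$at_risk, n_events = km$n_events)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Two-sample log-rank test
#'
#' Standard log-rank: at each event time expected events per group are
#' proportional to at-risk counts; the chi-square uses the hypergeometric
#' variance.  Zero total events gives p = 1 by convention.
#'
#' @param time durations.
#' @param event 0/1 indicators.
#' @param group binary group labels (two non-empty groups required).
#' @return Object of class \code{logrank_result}: \code{chi2}, \code{p},
#'   \code{observed}, \code{expected} per group.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(g) < 2) stop("log-rank test needs two non-empty groups")
  if (nlevels(g) > 2) stop("only the two-sample log-rank test is provided")
  if (sum(event) == 0)
    return(structure(list(chi2 = 0, p = 1, observed = c(0, 0),
                          expected = c(0, 0)), class = "logrank_result"))
  fit <- survival::survdiff(survival::Surv(time, event) ~ g)
  chi2 <- as.numeric(fit$chisq)
  structure(list(chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 observed = as.numeric(fit$obs),
                 expected = as.numeric(fit$exp)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chi2 = %.4f, p = %.4g (O = %s, E = %s)\n", x$chi2,
              x$p, paste(round(x$observed, 2), collapse = "/"),
              paste(round(x$expected, 2), collapse = "/")))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs (the smaller time has an observed event) where
#' the higher risk score accompanies the shorter survival; score ties count
#' one half.
#'
#' @param score continuous risk scores (higher = riskier).
#' @param time durations.
#' @param event 0/1 indicators.
#' @return List with \code{c} and \code{se}.
#' @export
concordance_index <- function(score, time, event) {
  stopifnot(length(score) >= 2)
  fit <- survival::concordance(survival::Surv(time, event) ~ score,
                               reverse = TRUE)
  counts <- fit$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no usable pairs for the concordance index")
  list(c = as.numeric(fit$concordance), se = sqrt(as.numeric(fit$var)))
}

#' Uno's IPCW time-dependent AUC at a horizon
#'
#' Inverse-probability-of-censoring-weighted estimate of
#' P(score_i > score_j | T_i <= tau < T_j): cases are patients with an
#' observed event by tau, controls are patients still under observation past
#' tau; case weights are 1 / G(T_i-)^2 with G the Kaplan-Meier curve of the
#' censoring distribution estimated from the training cohort.
#'
#' @param train_time,train_event training-cohort survival data (for G).
#' @param test_time,test_event,score evaluation data.
#' @param tau horizon in years.
#' @return AUC in [0, 1].
#' @export
uno_auc <- function(train_time, train_event, test_time, test_event, score,
                    tau) {
  stopifnot(tau > 0)
  Gkm <- kaplan_meier(train_time, 1 - train_event)
  cases <- which(test_time <= tau & test_event == 1)
  controls <- which(test_time > tau)
  if (length(cases) == 0 || length(controls) == 0)
    stop("need at least one case (event by tau) and one control (follow-up past tau)")
  Gt <- km_survival_at(Gkm, test_time[cases] - 1e-12)   # left limit G(T-)
  if (any(Gt <= 0))
    stop("censoring survival G reaches 0 before tau; use a smaller tau")
  w <- 1 / Gt^2
  sc <- score[cases]; sn <- score[controls]
  num <- 0
  for (i in seq_along(sc)) {
    cmp <- sum(sc[i] > sn) + 0.5 * sum(sc[i] == sn)
    num <- num + w[i] * cmp
  }
  num / (sum(w) * length(sn))
}

#' Sensitivity of a high-risk prediction at the horizon
#'
#' Fraction of the ground-truth (uncensored) high-risk group predicted high;
#' censored patients are excluded from the denominator.
#'
#' @param pred_high 0/1 predicted high-risk labels for all patients.
#' @param partition a \code{risk_partition}.
#' @return Sensitivity in [0, 1].
#' @export
sensitivity_at_horizon <- function(pred_high, partition) {
  if (length(partition$high_idx) == 0)
    stop("no true high-risk patients; sensitivity undefined")
  mean(pred_high[partition$high_idx] == 1)
}
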