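#' Construct a survival dataset
#'
#' The basic container used throughout the package: a numeric feature matrix
#' (one row per patient), a strictly positive follow-up time in years, and a
#' binary event indicator (1 = the event of interest, e.g. re-intervention,
#' was observed).
#'
#' @param features numeric matrix, n patients by p features; no missing values.
#' @param time numeric vector of follow-up times in years, strictly positive.
#' @param event integer/numeric vector in \{0, 1\}.
#' @param feature_names optional character vector of p unique names; defaults
#'   to the matrix column names or \code{V1..Vp}.
#' @param center optional per-patient cohort label.
#' @return An object of class \code{survival_dataset}.
#' @export
survival_dataset <- function(features, time, event, feature_names = NULL,
                             center = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (length(time) != n || length(event) != n)
    stop("time/event length must equal nrow(features)")
  if (anyNA(features) || anyNA(time) || anyNA(event))
    stop("survival_dataset does not allow missing values")
  if (any(time <= 0)) stop("follow-up times must be strictly positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (is.null(feature_names))
    feature_names <- colnames(features) %||% paste0("V", seq_len(ncol(features)))
  if (anyDuplicated(feature_names) || length(feature_names) != ncol(features))
    stop("feature_names must be unique and match the number of columns")
  colnames(features) <- feature_names
  if (!is.null(center) && length(center) != n)
    stop("center must have one label per patient")
  structure(list(features = features, feature_names = feature_names,
                 time = as.numeric(time), event = as.integer(event),
                 center = center),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset: %d patients, %d features\n",
              nrow(x$features), ncol(x$features)))
  cat(sprintf("  events: %d (%.1f%% censored)\n", sum(x$event),
              100 * mean(x$event == 0)))
  cat(sprintf("  follow-up: %.2f to %.2f years\n", min(x$time), max(x$time)))
  invisible(x)
}

#' @export
dim.survival_dataset <- function(x) dim(x$features)

## Row subset (used by all resampling code).
subset_dataset <- function(ds, idx) {
  survival_dataset(ds$features[idx, , drop = FALSE], ds$time[idx],
                   ds$event[idx], ds$feature_names,
                   if (!is.null(ds$center)) ds$center[idx])
}

## Column (feature) subset, keeping survival columns intact.
subset_features <- function(ds, cols) {
  survival_dataset(ds$features[, cols, drop = FALSE], ds$time, ds$event,
                   ds$feature_names[cols], ds$center)
}

#' Read a patient cohort from delimited text
#'
#' Reads a header-ed CSV/TSV, validates the survival columns, drops any row
#' with a missing value and reports how many were dropped (attribute
#' \code{"n_dropped"} and a message).
#'
#' @param path file path to a delimited text file (comma or tab separated,
#'   sniffed from the header line).
#' @param schema named list with \code{time_col}, \code{event_col}, optional
#'   \code{center_col} and \code{feature_cols} (defaults to every remaining
#'   numeric column).
#' @return A \code{survival_dataset}; attribute \code{n_dropped} holds the
#'   number of rows removed for missingness.
#' @export
read_cohort <- function(path, schema = list(time_col = "time", event_col = "event")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (key in c("time_col", "event_col"))
    if (is.null(schema[[key]]) || !schema[[key]] %in% names(df))
      stop(sprintf("schema error: required column '%s' (%s) not present",
                   schema[[key]] %||% "<unset>", key))
  feat_cols <- schema$feature_cols %||%
    setdiff(names(df), c(schema$time_col, schema$event_col, schema$center_col))
  missing_feats <- setdiff(feat_cols, names(df))
  if (length(missing_feats))
    stop("schema error: feature columns absent: ", paste(missing_feats, collapse = ", "))
  for (fc in feat_cols) {
    v <- df[[fc]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad))
        stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                     fc, bad[1]))
      df[[fc]] <- as.numeric(v)
    }
  }
  used <- df[, c(feat_cols, schema$time_col, schema$event_col, schema$center_col),
             drop = FALSE]
  keep <- stats::complete.cases(used)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("read_cohort: dropped %d row(s) with missing values", n_dropped))
  df <- df[keep, , drop = FALSE]
  ds <- survival_dataset(as.matrix(df[, feat_cols, drop = FALSE]),
                         df[[schema$time_col]], df[[schema$event_col]],
                         feature_names = feat_cols,
                         center = if (!is.null(schema$center_col)) df[[schema$center_col]])
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Write a cohort to CSV
#' @param ds a \code{survival_dataset}.
#' @param path output file path.
#' @export
write_cohort <- function(ds, path) {
  df <- as.data.frame(ds$features)
  df$time <- ds$time
  df$event <- ds$event
  if (!is.null(ds$center)) df$center <- ds$center
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Partition patients into high / low / censored five-year risk groups
#'
#' High risk: event observed at or before the horizon.  Low risk: followed
#' beyond the horizon (with or without a later event -- a patient who needed
#' no re-intervention within the horizon is low risk for the horizon).
#' Censored: event-free and lost to follow-up before the horizon.
#'
#' @param ds a \code{survival_dataset}.
#' @param horizon risk horizon in years (default 5).
#' @param late_events_low if \code{FALSE}, patients with an event after the
#'   horizon are excluded from the low group and treated as censored instead.
#' @return An object of class \code{risk_partition} with \code{high_idx},
#'   \code{low_idx}, \code{censored_idx} and \code{horizon}.
#' @export
partition_risk_groups <- function(ds, horizon = 5, late_events_low = TRUE) {
  stopifnot(horizon > 0)
  high <- which(ds$event == 1 & ds$time <= horizon)
  low <- if (late_events_low) which(ds$time > horizon)
         else which(ds$time > horizon & ds$event == 0)
  cens <- setdiff(seq_along(ds$time), c(high, low))
  if (length(high) == 0 || length(low) == 0)
    stop("degenerate partition: high and low risk groups must both be non-empty")
  structure(list(high_idx = high, low_idx = low, censored_idx = cens,
                 horizon = horizon),
            class = "risk_partition")
}

#' @export
print.risk_partition <- function(x, ...) {
  cat(sprintf("Risk partition at %g years: %d high, %d low, %d censored\n",
              x$horizon, length(x$high_idx), length(x$low_idx),
              length(x$censored_idx)))
  invisible(x)
}

#' Assign patients to cross-validation folds
#'
#' Reproducible k-fold assignment; by default events are stratified so each
#' fold receives its share of the (rare) events.
#'
#' @param ds a \code{survival_dataset}.
#' @param k number of folds (>= 2).
#' @param seed integer seed; the assignment is a pure function of it.
#' @param stratify_on_event spread event = 1 patients evenly across folds.
#' @return Object of class \code{fold_assignment}: \code{fold_of} (1..k per
#'   patient), \code{k}, \code{seed}.
#' @export
kfold_split <- function(ds, k, seed, stratify_on_event = TRUE) {
  n <- nrow(ds$features)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed the number of patients")
  fold_of <- integer(n)
  with_seed(seed, {
    if (stratify_on_event) {
      if (min(sum(ds$event == 1), sum(ds$event == 0)) < k && min(table(ds$event)) > 0)
        warning("a stratum has fewer members than folds; some folds lack it")
      ev <- which(ds$event == 1)
      nev <- which(ds$event == 0)
      ## shuffle within stratum, then deal the concatenation out cyclically:
      ## events land one-per-fold as far as they go, and overall fold sizes
      ## still differ by at most 1
      order_all <- c(ev[sample.int(length(ev))], nev[sample.int(length(nev))])
    } else {
      order_all <- sample.int(n)
    }
    fold_of[order_all] <- (seq_len(n) - 1L) %% k + 1L
  })
  structure(list(fold_of = fold_of, k = k, seed = seed),
            class = "fold_assignment")
}

#' Seeded row-permutation replicas of a cohort
#'
#' Produces \code{n_replicas} datasets, each a joint row reordering of the
#' input (features, time and event permuted together).  Replicas only vary
#' the downstream nested-fold assignments; the patient multiset is unchanged.
#'
#' @param ds a \code{survival_dataset}.
#' @param n_replicas number of replicas (>= 1).
#' @param seed integer seed.
#' @return List of \code{survival_dataset}s.
#' @export
permute_replicas <- function(ds, n_replicas, seed) {
  stopifnot(n_replicas >= 1)
  n <- nrow(ds$features)
  lapply(seq_len(n_replicas), function(r) {
    perm <- with_seed(child_seed(seed, 7L, r), sample.int(n))
    subset_dataset(ds, perm)
  })
}
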