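#' Control parameters for the wrapper feature-selection pipeline
#'
#' @param outer_k outer cross-validation folds (default 5).
#' @param inner_k nested (inner) folds per replica (default 5).
#' @param replicas seeded row-permutation replicas of each outer training
#'   fold (default 5).
#' @param neuron_grid hidden-layer sizes tried per outer fold (default 2:10).
#' @param horizon risk horizon in years (default 5).
#' @param p_th censoring-correction threshold (default 0.5).
#' @param n_bins equal-width discretization bins (default 5).
#' @param smoothing_alpha CPT pseudo-count (default 1, Laplace).
#' @param max_parents Bayesian-network parent cap (default 3).
#' @param lr,momentum,epochs ANN training hyper-parameters.
#' @param stratify stratify all splits on event status (default TRUE).
#' @param max_moves cap on committed stepwise moves (default 2p).
#' @param seed master seed; every randomised stage derives its own sub-seed
#'   from it.
#' @param late_events_low treat events after the horizon as low risk.
#' @return An \code{fs_control} list.
#' @export
fs_control <- function(outer_k = 5, inner_k = 5, replicas = 5,
                       neuron_grid = 2:10, horizon = 5, p_th = 0.5,
                       n_bins = 5, smoothing_alpha = 1, max_parents = 3,
                       lr = 0.1, momentum = 0.9, epochs = 500,
                       stratify = TRUE, max_moves = NULL, seed = 1,
                       late_events_low = TRUE) {
  structure(list(outer_k = outer_k, inner_k = inner_k, replicas = replicas,
                 neuron_grid = neuron_grid, horizon = horizon, p_th = p_th,
                 n_bins = n_bins, smoothing_alpha = smoothing_alpha,
                 max_parents = max_parents, lr = lr, momentum = momentum,
                 epochs = epochs, stratify = stratify, max_moves = max_moves,
                 seed = seed, late_events_low = late_events_low),
            class = "fs_control")
}

uncfg_of <- function(cfg) {
  uncensor_config(p_th = cfg$p_th, n_bins = cfg$n_bins,
                  smoothing_alpha = cfg$smoothing_alpha,
                  max_parents = cfg$max_parents)
}

## ---- nested-CV evaluation context -------------------------------------
## Precompute, once per outer training fold, everything that does not depend
## on the candidate feature subset: the permuted replicas, their inner fold
## assignments, the risk partition of each inner training portion, and the
## equal-width codes of all features (bins learned on the high+low rows,
## reused for the censored rows).  Candidate evaluation then only re-learns
## the Bayesian networks and the ANN on the subset's columns.
nested_context <- function(outer_train, cfg, seed_tag = 0L) {
  reps <- permute_replicas(outer_train, cfg$replicas,
                           child_seed(cfg$seed, 11L, seed_tag))
  splits <- list()
  for (r in seq_along(reps)) {
    ds_r <- reps[[r]]
    fa <- kfold_split(ds_r, cfg$inner_k,
                      child_seed(cfg$seed, 13L, seed_tag, r), cfg$stratify)
    for (f in seq_len(cfg$inner_k)) {
      tr_idx <- which(fa$fold_of != f)
      te_idx <- which(fa$fold_of == f)
      tr <- subset_dataset(ds_r, tr_idx)
      te <- subset_dataset(ds_r, te_idx)
      part <- tryCatch(partition_risk_groups(tr, cfg$horizon,
                                             cfg$late_events_low),
                       error = function(e) NULL)
      entry <- list(train = tr, test = te, partition = part, ok = !is.null(part))
      if (entry$ok &&
          (length(part$high_idx) < 5 || length(part$low_idx) < 5))
        entry$ok <- FALSE
      if (entry$ok) {
        obs <- c(part$high_idx, part$low_idx)
        dd <- equal_width_discretize(tr$features[obs, , drop = FALSE],
                                     cfg$n_bins)
        entry$codes_high <- dd$codes[seq_along(part$high_idx), , drop = FALSE]
        entry$codes_low <- dd$codes[length(part$high_idx) +
                                      seq_along(part$low_idx), , drop = FALSE]
        entry$codes_cens <- if (length(part$censored_idx))
          apply_bins(dd, tr$features[part$censored_idx, , drop = FALSE])
        else matrix(0L, 0, ncol(tr$features))
        entry$labels_obs <- c(rep(1L, length(part$high_idx)),
                              rep(0L, length(part$low_idx)))
        entry$prior_high <- length(part$high_idx) / length(obs)
        entry$ann_seed <- child_seed(cfg$seed, 17L, seed_tag, r, f)
      }
      splits[[length(splits) + 1L]] <- entry
    }
  }
  list(splits = splits, cfg = cfg)
}

## Averaged inner-test log-rank p of one candidate subset under a context.
eval_subset <- function(ctx, subset, n_hidden) {
  cfg <- ctx$cfg
  ps <- vapply(ctx$splits, function(sp) {
    if (!sp$ok) return(1)
    part <- sp$partition
    ## uncensor the inner training portion on the subset's columns
    ch <- sp$codes_high[, subset, drop = FALSE]
    cl <- sp$codes_low[, subset, drop = FALSE]
    ns <- rep(cfg$n_bins, length(subset))
    bh <- fit_parameters(learn_structure(ch, cfg$max_parents, n_states = ns),
                         ch, alpha = cfg$smoothing_alpha,
                         class_prior = sp$prior_high)
    bl <- fit_parameters(learn_structure(cl, cfg$max_parents, n_states = ns),
                         cl, alpha = cfg$smoothing_alpha,
                         class_prior = 1 - sp$prior_high)
    n_tr <- nrow(sp$train$features)
    label <- integer(n_tr)
    label[part$high_idx] <- 1L
    if (length(part$censored_idx)) {
      post <- posterior_high(sp$codes_cens[, subset, drop = FALSE], bh, bl)
      label[part$censored_idx] <- as.integer(post > cfg$p_th)
    }
    if (length(unique(label)) < 2) return(1)
    ann <- train_ann(sp$train$features[, subset, drop = FALSE], label,
                     n_hidden, seed = sp$ann_seed, lr = cfg$lr,
                     momentum = cfg$momentum, epochs = cfg$epochs)
    pred <- predict_risk(ann, sp$test$features[, subset, drop = FALSE])
    if (length(unique(pred$label)) < 2) return(1)
    logrank_test(sp$test$time, sp$test$event, pred$label)$p
  }, 0)
  mean(ps)
}

#' Nested-cross-validated log-rank p-value of a feature subset
#'
#' For each permuted replica of the outer training fold and each inner fold:
#' uncensor the inner training portion (Bayesian networks built on the
#' subset's features only), train the ANN on the imputed labels, predict the
#' inner test portion's risk groups, and take the log-rank p between them on
#' the inner test survival data.  Returns the average over all replica x
#' fold evaluations; degenerate splits (no usable partition, or a single
#' predicted group) contribute p = 1.
#'
#' @param outer_train a \code{survival_dataset}.
#' @param subset integer feature indices (non-empty).
#' @param n_hidden hidden-layer size of the ANN.
#' @param cfg an \code{\link{fs_control}}.
#' @return Averaged p-value in [0, 1].
#' @export
nested_cv_pvalue <- function(outer_train, subset, n_hidden,
                             cfg = fs_control()) {
  stopifnot(length(subset) >= 1)
  ctx <- nested_context(outer_train, cfg)
  eval_subset(ctx, sort(unique(subset)), n_hidden)
}

#' Stepwise elimination/re-entry wrapper feature search
#'
#' Starts from the full feature set.  Elimination stage: repeatedly evaluate
#' the removal of each remaining feature by its nested-CV averaged log-rank
#' p, commit the removal with the smallest average, and move the removed
#' feature to the visited pool; the best-so-far subset and p are tracked as
#' the minimum subset / minimum averaged p.  Addition stage: eliminated
#' features are offered re-entry one at a time; an addition is committed
#' only when it beats the minimum averaged p.  Never returns an empty
#' subset.
#'
#' @param outer_train a \code{survival_dataset} (an outer training fold).
#' @param cfg an \code{\link{fs_control}}.
#' @param n_hidden hidden-layer size used during the search (default: first
#'   element of \code{cfg$neuron_grid}).
#' @param seed_tag integer mixed into the fold/replica sub-seeds (used by the
#'   outer loop so different outer folds get different inner splits).
#' @return Object of class \code{search_state}: \code{current_subset},
#'   \code{visited_subset}, \code{minimum_subset}, \code{minimum_avg_p},
#'   \code{trajectory} (data frame of committed moves), \code{n_evals}.
#' @export
stepwise_select <- function(outer_train, cfg = fs_control(),
                            n_hidden = cfg$neuron_grid[1], seed_tag = 0L) {
  p <- ncol(outer_train$features)
  if (p < 2) stop("need at least 2 features to search over")
  ctx <- nested_context(outer_train, cfg, seed_tag)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  score <- function(subset) {
    key <- paste(subset, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_evals <<- n_evals + 1L
    val <- eval_subset(ctx, subset, n_hidden)
    cache[[key]] <- val
    val
  }
  max_moves <- cfg$max_moves %||% (2L * p)
  current <- seq_len(p)
  visited <- integer(0)
  min_p <- score(current)
  min_subset <- current
  traj <- list(list(stage = "init", feature = NA_integer_, avg_p = min_p,
                    size = p))
  moves <- 0L
  ## -- elimination stage --
  while (length(current) > 1 && moves < max_moves) {
    best_p <- Inf; best_f <- NA_integer_
    for (f in current) {
      pv <- score(setdiff(current, f))
      if (pv < best_p) { best_p <- pv; best_f <- f }
    }
    current <- setdiff(current, best_f)
    visited <- c(visited, best_f)
    moves <- moves + 1L
    if (best_p < min_p) { min_p <- best_p; min_subset <- current }
    traj[[length(traj) + 1L]] <- list(stage = "eliminate", feature = best_f,
                                      avg_p = best_p, size = length(current))
  }
  visited <- sort(unique(c(visited, setdiff(seq_len(p), current))))
  ## -- addition stage: eliminated features get another chance --
  repeat {
    cand <- setdiff(visited, current)
    if (length(cand) == 0 || moves >= max_moves) break
    best_p <- Inf; best_f <- NA_integer_
    for (f in cand) {
      pv <- score(sort(c(current, f)))
      if (pv < best_p) { best_p <- pv; best_f <- f }
    }
    if (best_p < min_p) {
      current <- sort(c(current, best_f))
      visited <- setdiff(visited, best_f)
      min_p <- best_p
      min_subset <- current
      moves <- moves + 1L
      traj[[length(traj) + 1L]] <- list(stage = "add", feature = best_f,
                                        avg_p = best_p, size = length(current))
    } else break
  }
  traj <- do.call(rbind, lapply(traj, as.data.frame))
  structure(list(current_subset = current, visited_subset = setdiff(visited, current),
                 minimum_subset = min_subset, minimum_avg_p = min_p,
                 n_hidden = n_hidden, trajectory = traj, n_evals = n_evals),
            class = "search_state")
}

#' @export
print.search_state <- function(x, ...) {
  cat(sprintf(paste0("Stepwise wrapper search: minimum subset of %d features",
                     " (avg log-rank p = %.4g, %d evaluations)\n"),
              length(x$minimum_subset), x$minimum_avg_p, x$n_evals))
  cat("  features:", paste(x$minimum_subset, collapse = ", "), "\n")
  invisible(x)
}
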