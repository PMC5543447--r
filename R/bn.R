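## Discrete Bayesian networks over equal-width-discretized features:
## hill-climbing structure search under an MDL score, maximum-likelihood
## (optionally Laplace-smoothed) CPTs, and log-space likelihood evaluation.
## These are the machinery behind the uncensoring step.

## ---- local family score ------------------------------------------------
## MDL local score of node j with parent set `parents`:
##   loglik(j | parents) - (log N / 2) * q * (r - 1)
## where r = states of j and q = product of parent state counts.
family_score <- function(codes, j, parents, n_states) {
  n <- nrow(codes)
  r <- n_states[j]
  x <- codes[, j] + 1L
  if (length(parents) == 0) {
    cnt <- tabulate(x, nbins = r)
    ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0] / n))
    pen <- (log(n) / 2) * (r - 1)
    return(ll - pen)
  }
  q <- prod(n_states[parents])
  cfg <- parent_config(codes, parents, n_states)
  idx <- (cfg - 1L) * r + x
  cnt <- tabulate(idx, nbins = r * q)
  dim(cnt) <- c(r, q)
  tot <- colSums(cnt)
  ll <- 0
  nzc <- which(tot > 0)
  for (cix in nzc) {
    col <- cnt[, cix]
    nz <- col > 0
    ll <- ll + sum(col[nz] * log(col[nz] / tot[cix]))
  }
  ll - (log(n) / 2) * q * (r - 1)
}

## mixed-radix index (1-based) of each row's parent configuration
parent_config <- function(codes, parents, n_states) {
  cfg <- rep(1L, nrow(codes))
  mult <- 1L
  for (pp in parents) {
    cfg <- cfg + codes[, pp] * mult
    mult <- mult * n_states[pp]
  }
  cfg
}

## ---- structure learning ------------------------------------------------

#' Learn a Bayesian-network DAG by hill climbing under an MDL score
#'
#' Steepest-ascent hill climbing from the empty graph over single-edge
#' additions, deletions and reversals, scored by a minimum-description-length
#' criterion (log-likelihood minus (log N / 2) free parameters).  Ties are
#' broken lexicographically over (parent, child, move type), so the result is
#' deterministic for a fixed column order.  Acyclicity is enforced at every
#' move and the parent count per node is capped.
#'
#' @param dd a \code{discretized_dataset} (or integer code matrix with
#'   attribute-free 0-based codes).
#' @param max_parents maximum parents per node (default 3).
#' @param max_iter maximum number of committed moves.
#' @param n_states optional per-node state counts (defaults to the maximum
#'   observed code + 1 per column).
#' @return A \code{bn_dag}: list with \code{parents} (list of integer parent
#'   indices per node), \code{score}, \code{n_states}.
#' @export
learn_structure <- function(dd, max_parents = 3, max_iter = NULL,
                            n_states = NULL) {
  codes <- if (inherits(dd, "discretized_dataset")) dd$codes else dd
  p <- ncol(codes)
  if (p < 1 || nrow(codes) < 5) stop("need >= 5 rows to learn a structure")
  if (is.null(n_states)) n_states <- pmax(apply(codes, 2, max) + 1L, 1L)
  n_states <- rep_len(as.integer(n_states), p)
  parents <- rep(list(integer(0)), p)
  fam <- vapply(seq_len(p), function(j) family_score(codes, j, integer(0),
                                                     n_states), 0)
  if (is.null(max_iter)) max_iter <- 3L * p
  adj <- matrix(FALSE, p, p)            # adj[a, b]: edge a -> b
  closure <- function(A) {              # desc[a, b]: b reachable from a
    D <- A
    repeat {
      D2 <- D | ((D %*% A) > 0)
      if (identical(D2, D)) return(D)
      D <- D2
    }
  }
  desc <- adj
  ## cached move deltas: delta[a, b] for adding (or deleting) edge a -> b
  ## given b's current parent set; columns are invalidated when a parent set
  ## changes.  Legality (cycles, parent caps) is checked at use time, so the
  ## cache only ever depends on the parent sets.
  add_delta <- matrix(NA_real_, p, p)
  del_delta <- matrix(NA_real_, p, p)
  stale <- rep(TRUE, p)
  for (iter in seq_len(max_iter)) {
    for (b in which(stale)) {
      for (a in seq_len(p)) {
        if (a == b) next
        if (adj[a, b]) {
          del_delta[a, b] <- family_score(codes, b,
                                          setdiff(parents[[b]], a),
                                          n_states) - fam[b]
          add_delta[a, b] <- NA_real_
        } else {
          add_delta[a, b] <- family_score(codes, b,
                                          sort(c(parents[[b]], a)),
                                          n_states) - fam[b]
          del_delta[a, b] <- NA_real_
        }
      }
      stale[b] <- FALSE
    }
    best <- list(delta = 1e-9, move = NULL)
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (a == b) next
      if (!adj[a, b]) {
        ## addition a -> b: illegal if a is reachable from b (cycle)
        if (length(parents[[b]]) >= max_parents || desc[b, a]) next
        if (add_delta[a, b] > best$delta + 1e-12)
          best <- list(delta = add_delta[a, b], move = c(1L, a, b))
      } else {
        ## deletion a -> b (always legal)
        d_del <- del_delta[a, b]
        if (d_del > best$delta + 1e-12)
          best <- list(delta = d_del, move = c(2L, a, b))
        ## reversal a -> b  =>  b -> a: legal iff no other a ~> b path
        if (length(parents[[a]]) < max_parents &&
            !is.na(add_delta[b, a])) {
          dd <- d_del + add_delta[b, a]
          if (dd > best$delta + 1e-12) {
            A2 <- adj; A2[a, b] <- FALSE
            if (!closure(A2)[a, b])
              best <- list(delta = dd, move = c(3L, a, b))
          }
        }
      }
    }
    if (is.null(best$move)) break
    mv <- best$move
    a <- mv[2]; b <- mv[3]
    if (mv[1] == 1L) {
      parents[[b]] <- sort(c(parents[[b]], a))
      adj[a, b] <- TRUE
      fam[b] <- family_score(codes, b, parents[[b]], n_states)
      stale[b] <- TRUE
    } else if (mv[1] == 2L) {
      parents[[b]] <- setdiff(parents[[b]], a)
      adj[a, b] <- FALSE
      fam[b] <- family_score(codes, b, parents[[b]], n_states)
      stale[b] <- TRUE
    } else {
      parents[[b]] <- setdiff(parents[[b]], a)
      parents[[a]] <- sort(c(parents[[a]], b))
      adj[a, b] <- FALSE
      adj[b, a] <- TRUE
      fam[b] <- family_score(codes, b, parents[[b]], n_states)
      fam[a] <- family_score(codes, a, parents[[a]], n_states)
      stale[c(a, b)] <- TRUE
    }
    desc <- closure(adj)
  }
  structure(list(parents = parents, score = sum(fam), n_states = n_states,
                 p = p),
            class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat(sprintf("Bayesian-network DAG: %d nodes, %d edges, MDL score %.2f\n",
              x$p, n_edges, x$score))
  invisible(x)
}

## topological order (exists because acyclicity is enforced)
topo_order <- function(dag) {
  p <- dag$p
  indeg <- lengths(dag$parents)
  order <- integer(0)
  avail <- which(indeg == 0)
  parents <- dag$parents
  while (length(avail)) {
    v <- min(avail)
    order <- c(order, v)
    avail <- setdiff(avail, v)
    for (b in seq_len(p)) {
      if (v %in% parents[[b]]) {
        parents[[b]] <- setdiff(parents[[b]], v)
        if (length(parents[[b]]) == 0 && !(b %in% order)) avail <- c(avail, b)
      }
    }
  }
  if (length(order) != p) stop("graph is not acyclic")
  order
}

#' Fit conditional probability tables by (smoothed) maximum likelihood
#'
#' CPT entries are (count + alpha) / (total + alpha * states); alpha = 0 is
#' pure maximum likelihood, in which case a never-observed parent
#' configuration yields a uniform row with a warning.
#'
#' @param dag a \code{bn_dag}.
#' @param dd the \code{discretized_dataset} the structure was learned on.
#' @param alpha pseudo-count (default 1, Laplace).
#' @param class_prior prior probability attached to this network's risk group.
#' @return Object of class \code{bn_model}: \code{dag}, \code{cpts} (list of
#'   r x q matrices), \code{class_prior}, \code{smoothing_alpha}.
#' @export
fit_parameters <- function(dag, dd, alpha = 1, class_prior = 0.5) {
  codes <- if (inherits(dd, "discretized_dataset")) dd$codes else dd
  stopifnot(ncol(codes) == dag$p)
  cpts <- vector("list", dag$p)
  for (j in seq_len(dag$p)) {
    r <- dag$n_states[j]
    pa <- dag$parents[[j]]
    q <- if (length(pa)) prod(dag$n_states[pa]) else 1L
    cfg <- if (length(pa)) parent_config(codes, pa, dag$n_states) else
      rep(1L, nrow(codes))
    cnt <- tabulate((cfg - 1L) * r + codes[, j] + 1L, nbins = r * q)
    dim(cnt) <- c(r, q)
    tot <- colSums(cnt)
    if (alpha == 0) {
      tab <- cnt
      empty <- tot == 0
      if (any(empty)) {
        warning("unobserved parent configuration with alpha = 0; uniform row used")
        tab[, empty] <- 1
        tot[empty] <- r
      }
      cpt <- sweep(tab, 2, pmax(tot, 1), "/")
    } else {
      cpt <- sweep(cnt + alpha, 2, tot + alpha * r, "/")
    }
    cpts[[j]] <- cpt
  }
  structure(list(dag = dag, cpts = cpts, class_prior = class_prior,
                 smoothing_alpha = alpha),
            class = "bn_model")
}

#' @export
print.bn_model <- function(x, ...) {
  print(x$dag)
  cat(sprintf("  class prior %.3f, smoothing alpha %g\n", x$class_prior,
              x$smoothing_alpha))
  invisible(x)
}

#' Log-likelihood of discretized instances under a Bayesian network
#'
#' Sum over nodes of log p(V_i = x_i | parents), i.e. the log of the product
#' form of the network factorisation.  A zero-probability factor (possible
#' only with alpha = 0) yields -Inf, not an error.
#'
#' @param bn a \code{bn_model}.
#' @param x integer code vector (0-based), or a matrix of instances (rows).
#' @return Numeric log-likelihood (vector for a matrix input).
#' @export
log_likelihood <- function(bn, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  stopifnot(ncol(X) == bn$dag$p)
  ll <- numeric(nrow(X))
  for (j in seq_len(bn$dag$p)) {
    r <- bn$dag$n_states[j]
    pa <- bn$dag$parents[[j]]
    cfg <- if (length(pa)) parent_config(X, pa, bn$dag$n_states) else
      rep(1L, nrow(X))
    pr <- bn$cpts[[j]][cbind(X[, j] + 1L, cfg)]
    ll <- ll + ifelse(pr > 0, log(pr), -Inf)
  }
  ll
}

#' Posterior probability that a censored instance is high risk
#'
#' Normalised two-network posterior: prior times network likelihood for the
#' high-risk network over the sum for both networks, computed in log space.
#' The instance's own marginal probability cancels in the normalisation.
#'
#' @param x discretized instance (0-based codes) or matrix of instances.
#' @param bn_high,bn_low fitted \code{bn_model}s over the same variables.
#' @return Posterior probability (vector for matrix input).
#' @export
posterior_high <- function(x, bn_high, bn_low) {
  stopifnot(bn_high$dag$p == bn_low$dag$p)
  lh <- log_likelihood(bn_high, x) + log(bn_high$class_prior)
  ll <- log_likelihood(bn_low, x) + log(bn_low$class_prior)
  if (any(!is.finite(lh) & !is.finite(ll)))
    stop("instance has zero likelihood under both networks")
  1 / (1 + exp(ll - lh))
}

#' Serialize a Bayesian network to a JSON-ready list / GraphViz DOT
#'
#' @param bn a \code{bn_model}.
#' @param feature_names optional node names.
#' @return List with nodes, parents and CPTs (suitable for
#'   \code{jsonlite::toJSON}); attribute \code{"dot"} carries a GraphViz DOT
#'   rendering of the structure.
#' @export
bn_serialize <- function(bn, feature_names = NULL) {
  p <- bn$dag$p
  nm <- feature_names %||% paste0("V", seq_len(p))
  out <- list(nodes = nm,
              parents = lapply(bn$dag$parents, function(pa) nm[pa]),
              n_states = as.integer(bn$dag$n_states),
              class_prior = bn$class_prior,
              smoothing_alpha = bn$smoothing_alpha,
              cpts = lapply(bn$cpts, function(m) unname(as.data.frame(m))))
  edges <- unlist(lapply(seq_len(p), function(b)
    vapply(bn$dag$parents[[b]], function(a)
      sprintf("  \"%s\" -> \"%s\";", nm[a], nm[b]), "")))
  attr(out, "dot") <- paste(c("digraph bn {", edges, "}"), collapse = "\n")
  out
}
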