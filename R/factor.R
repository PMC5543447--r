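#' Sampling-adequacy tests for factor analysis
#'
#' Kaiser-Meyer-Olkin measure (from the anti-image correlation matrix) and
#' Bartlett's test of sphericity, used to decide whether a common-factor
#' model is worth fitting at all.
#'
#' @param X numeric feature matrix (standardized internally).
#' @return List of class \code{adequacy_report}: \code{kmo_overall},
#'   \code{bartlett_stat}, \code{bartlett_df}, \code{bartlett_p}.
#' @export
adequacy_tests <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  R <- stats::cor(X)
  Ri <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix; prune collinear features before FA"))
  if (max(abs(Ri)) > 1e12)
    stop("singular correlation matrix; prune collinear features before FA")
  ## anti-image (partial) correlations
  D <- diag(1 / sqrt(diag(Ri)))
  Q <- -D %*% Ri %*% D
  off <- upper.tri(R)
  kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
  detR <- determinant(R, logarithm = TRUE)$modulus
  stat <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(detR)
  df <- p * (p - 1) / 2
  structure(list(kmo_overall = kmo, bartlett_stat = stat, bartlett_df = df,
                 bartlett_p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat(sprintf("KMO overall: %.3f\nBartlett chi-square: %.2f on %d df, p = %.3g\n",
              x$kmo_overall, x$bartlett_stat, x$bartlett_df, x$bartlett_p))
  invisible(x)
}

#' Choose the number of factors from the scree of eigenvalues
#'
#' Smallest m whose top-m correlation-matrix eigenvalues explain at least
#' \code{variance_fraction} of the total variance.
#'
#' @param X numeric feature matrix.
#' @param variance_fraction target explained-variance fraction (default 0.80).
#' @return Integer factor count.
#' @export
select_n_factors <- function(X, variance_fraction = 0.80) {
  stopifnot(variance_fraction > 0, variance_fraction <= 1)
  ev <- eigen(stats::cor(as.matrix(X)), symmetric = TRUE, only.values = TRUE)$values
  cum <- cumsum(ev) / sum(ev)
  which(cum >= variance_fraction - 1e-12)[1]
}

#' Fit a common-factor model with varimax rotation
#'
#' Principal-axis factoring on the correlation matrix (squared multiple
#' correlations as starting communalities, iterated to convergence) followed
#' by varimax rotation.  Variables are standardized internally, so
#' communality + uniqueness = 1 per variable.  Heywood cases are handled by
#' flooring the uniqueness at \code{uniq_floor} with a warning.
#'
#' @param X numeric feature matrix.
#' @param m number of factors (1 <= m < p).
#' @param max_iter,tol principal-axis iteration controls.
#' @param uniq_floor lower bound for uniquenesses (Heywood guard).
#' @return Object of class \code{factor_model}: \code{loadings} (p x m,
#'   varimax-rotated), \code{uniquenesses}, \code{communalities},
#'   \code{rotation} (m x m orthogonal), \code{explained_variance},
#'   \code{feature_names}.
#' @export
fit_factor_model <- function(X, m, max_iter = 100, tol = 1e-6,
                             uniq_floor = 1e-3) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(m >= 1, m < p)
  R <- stats::cor(X)
  ## starting communalities: squared multiple correlations
  Ri <- tryCatch(solve(R), error = function(e) NULL)
  h2 <- if (is.null(Ri)) rep(0.5, p) else pmin(pmax(1 - 1 / diag(Ri), 0.05), 1 - uniq_floor)
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    vals <- pmax(e$values[seq_len(m)], 0)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(vals), m)
    h2_new <- rowSums(L^2)
    if (any(h2_new > 1 - uniq_floor)) {
      h2_new <- pmin(h2_new, 1 - uniq_floor)
    }
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  if (any(rowSums(L^2) > 1 - uniq_floor + 1e-12))
    warning("Heywood case: uniqueness floored at ", uniq_floor)
  ## rescale loadings so communalities respect the floor exactly
  h2L <- rowSums(L^2)
  scale_fac <- sqrt(pmin(h2L, 1 - uniq_floor) / pmax(h2L, 1e-12))
  L <- L * scale_fac
  rot <- if (m > 1) stats::varimax(L, normalize = TRUE) else
    list(loadings = L, rotmat = diag(1))
  Lr <- matrix(as.numeric(rot$loadings), p, m)
  communality <- rowSums(Lr^2)
  uniqueness <- 1 - communality
  rownames(Lr) <- colnames(X) %||% paste0("V", seq_len(p))
  structure(list(loadings = Lr, uniquenesses = uniqueness,
                 communalities = communality, rotation = rot$rotmat,
                 explained_variance = colSums(Lr^2) / p,
                 feature_names = rownames(Lr), n_factors = m),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Common-factor model: %d variables, %d factors (varimax)\n",
              nrow(x$loadings), x$n_factors))
  cat(sprintf("  explained variance: %.1f%%\n", 100 * sum(x$explained_variance)))
  cat(sprintf("  uniqueness range: %.3f to %.3f\n", min(x$uniquenesses),
              max(x$uniquenesses)))
  invisible(x)
}

#' Uniqueness cut-off from the histogram's first sharp drop
#'
#' Builds a histogram of the uniquenesses (bins of \code{bin_width} on
#' [0, 1]) and returns the left edge of the first bin whose count falls to
#' at most half of the preceding non-empty bin's count, provided some mass
#' remains at or above that edge (otherwise there is nothing to drop).
#' Falls back to 0.25 when no such drop exists.
#'
#' @param fm a \code{factor_model} (or numeric vector of uniquenesses).
#' @param bin_width histogram bin width (default 0.05).
#' @return Numeric threshold in (0, 1].
#' @export
uniqueness_threshold <- function(fm, bin_width = 0.05) {
  u <- if (inherits(fm, "factor_model")) fm$uniquenesses else as.numeric(fm)
  stopifnot(length(u) >= 5)
  edges <- seq(0, 1 + bin_width, by = bin_width)
  counts <- tabulate(findInterval(u, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  nz <- which(counts > 0)
  if (length(nz) >= 2) {
    last <- max(nz)
    for (j in 2:last) {
      if (counts[j - 1] > 0 && counts[j] <= counts[j - 1] / 2 &&
          sum(counts[j:last]) > 0)
        return(edges[j])
    }
  }
  0.25
}

#' Drop features with high uniqueness
#'
#' Retains feature i iff its uniqueness is at most the threshold (high
#' uniqueness = low communality = not explained by any common factor).
#'
#' @param fm a \code{factor_model}.
#' @param threshold uniqueness cut-off in (0, 1).
#' @return Integer indices of retained features, in original order.
#' @export
reduce_features <- function(fm, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- which(fm$uniquenesses <= threshold)
  if (length(keep) == 0)
    stop("no features retained; increase the uniqueness threshold")
  keep
}
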