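#' Equal-width unsupervised discretization
#'
#' Splits each feature's observed range into \code{n_bins} equal-width
#' intervals.  The maximum lands in the top bin; the edges are kept so unseen
#' values can later be coded (clamped into the boundary bins).  A constant
#' feature collapses to a single code 0 with a warning.
#'
#' @param ds a \code{survival_dataset} or numeric matrix.
#' @param n_bins number of bins per feature (>= 2).
#' @return Object of class \code{discretized_dataset}: integer \code{codes}
#'   matrix (values in 0..n_bins-1), \code{bin_edges} list, \code{n_bins}.
#' @export
equal_width_discretize <- function(ds, n_bins = 5) {
  stopifnot(n_bins >= 2)
  n_bins <- as.integer(n_bins)
  X <- if (inherits(ds, "survival_dataset")) ds$features else as.matrix(ds)
  p <- ncol(X)
  edges <- vector("list", p)
  codes <- matrix(0L, nrow(X), p, dimnames = dimnames(X))
  for (j in seq_len(p)) {
    lo <- min(X[, j]); hi <- max(X[, j])
    if (hi == lo) {
      warning(sprintf("feature %s is constant; coded as a single bin",
                      colnames(X)[j] %||% j))
      edges[[j]] <- c(lo, lo)           # degenerate marker
      codes[, j] <- 0L
    } else {
      edges[[j]] <- seq(lo, hi, length.out = n_bins + 1)
      codes[, j] <- code_with_edges(X[, j], edges[[j]], n_bins)
    }
  }
  structure(list(codes = codes, bin_edges = edges, n_bins = as.integer(n_bins)),
            class = "discretized_dataset")
}

code_with_edges <- function(x, edges, n_bins) {
  if (length(edges) == 2 && edges[1] == edges[2]) return(rep(0L, length(x)))
  k <- findInterval(x, edges, rightmost.closed = TRUE) - 1L
  as.integer(pmin(pmax(k, 0L), n_bins - 1L))  # clamp unseen values into boundary bins
}

#' Code new data with previously learned bin edges
#'
#' @param dd a \code{discretized_dataset} (source of the edges).
#' @param X numeric matrix with the same columns the edges were learned on.
#' @return Integer code matrix; out-of-range values are clamped.
#' @export
apply_bins <- function(dd, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(dd$bin_edges))
  out <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X)))
    out[, j] <- code_with_edges(X[, j], dd$bin_edges[[j]], dd$n_bins)
  out
}
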