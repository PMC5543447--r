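#' Train a three-layer sigmoid perceptron by gradient descent with momentum
#'
#' One hidden layer, sigmoid activations throughout, full-batch
#' backpropagation on the cross-entropy loss with a momentum term.  Inputs
#' are standardized with training-set means/SDs (stored in the model and
#' applied exactly once at prediction).  Deterministic given the seed.
#'
#' @param X numeric feature matrix.
#' @param y binary 0/1 labels (both classes must be present).
#' @param n_hidden hidden-layer size.
#' @param seed integer seed for the weight initialisation.
#' @param lr learning rate (default 0.1).
#' @param momentum momentum coefficient (default 0.9).
#' @param epochs full-batch epochs (default 500).
#' @return Object of class \code{ann_model}.
#' @export
train_ann <- function(X, y, n_hidden, seed = 1, lr = 0.1, momentum = 0.9,
                      epochs = 500) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("need at least 10 training rows")
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training labels are single-class")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  with_seed(seed, {
    W1 <- matrix(stats::runif(p * n_hidden, -0.5, 0.5), p, n_hidden)
    b1 <- stats::runif(n_hidden, -0.5, 0.5)
    W2 <- matrix(stats::runif(n_hidden, -0.5, 0.5), n_hidden, 1)
    b2 <- stats::runif(1, -0.5, 0.5)
  })
  ## biases folded in as an extra input/hidden unit fixed at 1
  Xb <- cbind(Xs, 1)
  A1 <- rbind(W1, b1)                   # (p+1) x h
  A2 <- rbind(W2, b2)                   # (h+1) x 1
  v1 <- A1 * 0; v2 <- A2 * 0
  for (ep in seq_len(epochs)) {
    H <- 1 / (1 + exp(-(Xb %*% A1)))
    Hb <- cbind(H, 1)
    o <- drop(1 / (1 + exp(-(Hb %*% A2))))
    ## cross-entropy gradient: d loss / d z_out = (o - y) / n
    dout <- (o - y) / n
    g2 <- crossprod(Hb, dout)
    dh <- (dout %*% t(A2[seq_len(n_hidden), , drop = FALSE])) * H * (1 - H)
    g1 <- crossprod(Xb, dh)
    v1 <- momentum * v1 - lr * g1
    v2 <- momentum * v2 - lr * g2
    A1 <- A1 + v1; A2 <- A2 + v2
  }
  W1 <- A1[seq_len(p), , drop = FALSE]; b1 <- A1[p + 1, ]
  W2 <- A2[seq_len(n_hidden), , drop = FALSE]; b2 <- A2[n_hidden + 1, 1]
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, mu = mu, sd = sd_,
                 n_hidden = n_hidden,
                 hyperparams = list(lr = lr, momentum = momentum,
                                    epochs = epochs, seed = seed)),
            class = "ann_model")
}

#' Risk scores and labels from a trained network
#'
#' @param m an \code{ann_model}.
#' @param X feature matrix with the same columns the model was trained on.
#' @return List with \code{score} (sigmoid output in (0, 1)) and
#'   \code{label} (1 iff score > 0.5; ties go low).
#' @export
predict_risk <- function(m, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(m$W1))
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 nrow(m$W1), ncol(X)))
  Xs <- sweep(sweep(X, 2, m$mu), 2, m$sd, "/")
  sig <- function(z) 1 / (1 + exp(-z))
  H <- sig(sweep(Xs %*% m$W1, 2, m$b1, "+"))
  score <- drop(sig(H %*% m$W2 + m$b2))
  list(score = score, label = as.integer(score > 0.5))
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("Sigmoid MLP: %d-%d-1, lr %g, momentum %g, %d epochs\n",
              nrow(x$W1), x$n_hidden, x$hyperparams$lr, x$hyperparams$momentum,
              x$hyperparams$epochs))
  invisible(x)
}
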