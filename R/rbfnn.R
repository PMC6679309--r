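# Radial basis function network classifier, written from scratch:
# Gaussian hidden layer h_i(x) = exp(-||x - c_i||^2 / sigma_i^2), linear
# output layer y_j = sum_i w_ij h_i(x), full-batch gradient descent on the
# mean squared error coefficient Ec, with an Ec threshold as stopping rule.
# Widths are optimized in log-space so they stay positive.

#' Training configuration for the RBF network
#'
#' @param n_hidden Number of Gaussian hidden units.
#' @param learning_rate Gradient-descent step size.
#' @param max_epochs Maximum number of full-batch epochs.
#' @param ec_threshold Stop as soon as the error coefficient Ec falls below
#'   this value.
#' @param n_outputs Number of output units (one per health class).
#' @param seed Seed for parameter initialization.
#' @return An object of class `rbf_config`.
#' @export
rbf_config <- function(n_hidden = 20, learning_rate = 0.05, max_epochs = 500,
                       ec_threshold = 0.02, n_outputs = 4, seed = 1) {
  stopifnot(n_hidden >= 1, learning_rate > 0, max_epochs >= 1,
            ec_threshold > 0, n_outputs >= 1)
  structure(list(n_hidden = as.integer(n_hidden), learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), ec_threshold = ec_threshold,
                 n_outputs = as.integer(n_outputs), seed = as.integer(seed)),
            class = "rbf_config")
}

#' Initialize an RBF network from training data
#'
#' Centres are drawn uniformly from the training rows (without replacement
#' when possible), widths start at the median pairwise distance between the
#' chosen centres (a data-scale value), and output weights are small random
#' normals. Reproducible from the config seed.
#'
#' @param config An [rbf_config()].
#' @param x Training feature matrix (rows are samples; typically scaled to
#'   \[0,1\] with the 0/1 mask column appended, giving 8 inputs).
#' @return An object of class `rbf_network` with fields `centers`
#'   (n_hidden x input_dim), `widths` (positive, length n_hidden) and
#'   `weights` (n_hidden x n_outputs).
#' @export
rbf_init <- function(config, x) {
  stopifnot(inherits(config, "rbf_config"))
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need training rows to initialize")
  h <- config$n_hidden
  withr::with_seed(config$seed, {
    idx <- if (h <= nrow(x)) sample.int(nrow(x), h) else
      sample.int(nrow(x), h, replace = TRUE)
    centers <- x[idx, , drop = FALSE]
    dists <- stats::dist(centers)
    width0 <- if (length(dists) && stats::median(dists) > 0)
      stats::median(dists) else {
        sdx <- stats::sd(as.vector(x))
        if (is.finite(sdx) && sdx > 0) sdx else 1
      }
    weights <- matrix(stats::rnorm(h * config$n_outputs, sd = 0.1),
                      h, config$n_outputs)
    structure(list(centers = centers, widths = rep(width0, h),
                   weights = weights, input_dim = ncol(x),
                   n_outputs = config$n_outputs),
              class = "rbf_network")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# K x H matrix of squared distances ||x_k - c_i||^2
rbf_sqdist <- function(net, x) {
  xc <- tcrossprod(x, net$centers)                       # K x H
  sweep(sweep(-2 * xc, 1, rowSums(x^2), "+"), 2, rowSums(net$centers^2), "+")
}

#' Hidden-layer activations
#'
#' @param net An [rbf_network][rbf_init()].
#' @param x Feature matrix (K x input_dim) or a single row.
#' @return K x n_hidden matrix of Gaussian activations.
#' @export
rbf_hidden <- function(net, x) {
  x <- to_row_matrix(x, net$input_dim)
  r2 <- pmax(rbf_sqdist(net, x), 0)
  exp(-sweep(r2, 2, net$widths^2, "/"))
}

to_row_matrix <- function(x, dim) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != dim) stop("dimension mismatch: expected ", dim, " inputs, got ", ncol(x))
  x
}

#' Forward pass: per-class scores
#'
#' Computes `y_j = sum_i w_ij exp(-||x - c_i||^2 / sigma_i^2)` for every row.
#'
#' @inheritParams rbf_hidden
#' @return K x n_outputs score matrix.
#' @export
rbf_forward <- function(net, x) {
  rbf_hidden(net, x) %*% net$weights
}

#' Per-output error distances
#'
#' The elementwise absolute difference between predicted and target scores.
#'
#' @param y_pred,y_true Equal-shape numeric matrices or vectors.
#' @return `abs(y_pred - y_true)`, same shape.
#' @export
error_distance <- function(y_pred, y_true) {
  if (length(y_pred) != length(y_true)) stop("length mismatch")
  abs(y_pred - y_true)
}

#' Error coefficient Ec
#'
#' The mean of squared error distances over all samples and output units:
#' `Ec = sum_k sum_i Ed_ki^2 / (k * i)`. Used as the training stopping
#' criterion.
#'
#' @param distances Matrix (samples x outputs) or vector of error distances.
#' @return A single non-negative number.
#' @export
error_coefficient <- function(distances) {
  if (!length(distances)) stop("empty input")
  mean(distances^2)
}

#' One-hot encode integer class labels
#'
#' @param labels Integer vector with values in `0:(n_classes - 1)`.
#' @param n_classes Number of classes.
#' @return Matrix (length(labels) x n_classes) of 0/1 targets.
#' @export
one_hot <- function(labels, n_classes = 4) {
  labels <- as.integer(labels)
  stopifnot(all(labels >= 0 & labels < n_classes))
  diag(n_classes)[labels + 1L, , drop = FALSE]
}

#' Analytic gradients of Ec
#'
#' Full-batch gradients of the error coefficient with respect to the output
#' weights, the centres, and the log-widths (widths are trained in log-space
#' to preserve positivity).
#'
#' @param net An `rbf_network`.
#' @param x Feature matrix (K x input_dim).
#' @param y One-hot target matrix (K x n_outputs).
#' @return List with `ec`, `d_weights`, `d_centers`, `d_log_widths`.
#' @export
rbf_gradients <- function(net, x, y) {
  x <- to_row_matrix(x, net$input_dim)
  k <- nrow(x)
  j <- net$n_outputs
  r2 <- pmax(rbf_sqdist(net, x), 0)
  h <- exp(-sweep(r2, 2, net$widths^2, "/"))
  e <- h %*% net$weights - y                         # K x J, pred - true
  ec <- mean(e^2)
  scale <- 2 / (k * j)
  d_weights <- scale * crossprod(h, e)
  b <- (e %*% t(net$weights)) * h                    # K x H
  colsum_b <- colSums(b)
  inv_s2 <- 1 / net$widths^2
  d_centers <- 2 * scale * (crossprod(b, x) - colsum_b * net$centers) * inv_s2
  d_log_widths <- 2 * scale * colSums(b * r2) * inv_s2
  list(ec = ec, d_weights = d_weights, d_centers = d_centers,
       d_log_widths = d_log_widths)
}

#' Train an RBF network by full-batch gradient descent
#'
#' Descends the error coefficient Ec with respect to all three parameter
#' groups (centres, widths, output weights) using a fixed learning rate, and
#' stops when Ec drops below `config$ec_threshold` or after
#' `config$max_epochs` epochs.
#'
#' @param net An initialized `rbf_network` (see [rbf_init()]).
#' @param x Training feature matrix.
#' @param y One-hot target matrix (see [one_hot()]).
#' @param config An [rbf_config()].
#' @return List with `net` (trained network) and `trace`, a list holding the
#'   per-epoch `ec` values, `final_epoch` and `stop_reason`
#'   (`"threshold"` or `"max_epochs"`).
#' @export
rbf_train <- function(net, x, y, config) {
  stopifnot(inherits(net, "rbf_network"), inherits(config, "rbf_config"))
  x <- to_row_matrix(x, net$input_dim)
  y <- as.matrix(y)
  if (nrow(y) != nrow(x) || ncol(y) != net$n_outputs)
    stop("target matrix must be ", nrow(x), " x ", net$n_outputs)
  lr <- config$learning_rate
  ec_trace <- numeric(config$max_epochs)
  stop_reason <- "max_epochs"
  final <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    g <- rbf_gradients(net, x, y)
    if (!is.finite(g$ec))
      stop("training diverged: non-finite Ec at epoch ", epoch)
    ec_trace[epoch] <- g$ec
    if (g$ec < config$ec_threshold) {
      stop_reason <- "threshold"
      final <- epoch
      break
    }
    net$weights <- net$weights - lr * g$d_weights
    net$centers <- net$centers - lr * g$d_centers
    net$widths <- exp(log(net$widths) - lr * g$d_log_widths)
  }
  list(net = net,
       trace = list(ec = ec_trace[seq_len(final)], final_epoch = final,
                    stop_reason = stop_reason))
}

#' Predict health classes
#'
#' Decodes the four output scores by argmax; exact ties resolve to the
#' lowest class index.
#'
#' @param net A trained `rbf_network`.
#' @param x Feature matrix or single row.
#' @return Integer vector of class labels `0:(n_outputs - 1)`.
#' @export
rbf_predict <- function(net, x) {
  scores <- rbf_forward(net, x)
  max.col(scores, ties.method = "first") - 1L
}

#' Save / load an RBF model as JSON
#'
#' Serializes the network together with optional normalization parameters
#' and the training configuration, so a trained model can be reapplied to
#' new measurements.
#'
#' @param net An `rbf_network`.
#' @param path JSON file path.
#' @param params Optional [fit_minmax()] parameters used before training.
#' @param config Optional [rbf_config()].
#' @export
rbf_save <- function(net, path, params = NULL, config = NULL) {
  obj <- list(centers = net$centers, widths = net$widths, weights = net$weights,
              input_dim = net$input_dim, n_outputs = net$n_outputs)
  if (!is.null(params))
    obj$normalization <- list(min = params$min, max = params$max,
                              degenerate = params$degenerate)
  if (!is.null(config)) obj$config <- unclass(config)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname rbf_save
#' @return `rbf_load()` returns a list with `net`, `params` (or `NULL`) and
#'   `config` (or `NULL`).
#' @export
rbf_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- structure(list(centers = as.matrix(obj$centers),
                        widths = as.numeric(obj$widths),
                        weights = as.matrix(obj$weights),
                        input_dim = obj$input_dim, n_outputs = obj$n_outputs),
                   class = "rbf_network")
  params <- if (!is.null(obj$normalization))
    structure(list(min = unlist(obj$normalization$min),
                   max = unlist(obj$normalization$max),
                   degenerate = unlist(obj$normalization$degenerate)),
              class = "minmax_params")
  config <- if (!is.null(obj$config)) do.call(rbf_config, obj$config)
  list(net = net, params = params, config = config)
}

#' @export
print.rbf_network <- function(x, ...) {
  cat(sprintf("<rbf_network> %d Gaussian units, %d inputs -> %d outputs\n",
              nrow(x$centers), x$input_dim, x$n_outputs))
  invisible(x)
}
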