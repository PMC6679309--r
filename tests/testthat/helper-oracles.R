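# Independent reference implementations used as oracles. These deliberately
# recompute everything from scratch (batch statistics, nested loops) rather
# than reusing any streaming machinery from the package.

# Brute-force screening reference: at every judged row the mean and sd of
# the accepted differences are recomputed from the full list.
adi_reference <- function(x, Z, chain = c("adjacent", "eliminate")) {
  chain <- match.arg(chain)
  x <- as.matrix(x)
  n <- nrow(x)
  acc <- diff(x[1:Z, , drop = FALSE])     # accepted differences so far
  flags <- logical(n)
  last <- Z
  for (t in (Z + 1):n) {
    d <- x[t, ] - x[last, ]
    mu <- colMeans(acc)
    sdv <- sqrt(colMeans(sweep(acc, 2, mu)^2))
    bad <- logical(length(d))
    for (j in seq_along(d)) {
      bad[j] <- if (sdv[j] == 0) abs(d[j] - mu[j]) > 1e-9 else
        d[j] < mu[j] - 3 * sdv[j] || d[j] > mu[j] + 3 * sdv[j]
    }
    if (any(bad)) {
      flags[t] <- TRUE
      if (chain == "adjacent") last <- t
    } else {
      acc <- rbind(acc, d)
      last <- t
    }
  }
  flags
}

# Central finite-difference gradient of the error coefficient for one
# parameter block of an RBF network.
numeric_gradient <- function(net, x, y, block, eps = 1e-6) {
  get <- switch(block,
                weights = function(n) n$weights,
                centers = function(n) n$centers,
                log_widths = function(n) log(n$widths))
  set <- switch(block,
                weights = function(n, v) { n$weights[] <- v; n },
                centers = function(n, v) { n$centers[] <- v; n },
                log_widths = function(n, v) { n$widths <- exp(as.vector(v)); n })
  th <- get(net)
  out <- array(0, dim = dim(as.matrix(th)))
  for (i in seq_along(th)) {
    up <- th; up[i] <- th[i] + eps
    dn <- th; dn[i] <- th[i] - eps
    out[i] <- (rbf_gradients(set(net, up), x, y)$ec -
                 rbf_gradients(set(net, dn), x, y)$ec) / (2 * eps)
  }
  out
}

# Plain nested-loop k-nearest-neighbour classifier with the package's tie
# rules (majority vote; ties to smallest mean neighbour distance, then
# lowest class).
knn_reference <- function(train_x, train_y, query_x, k) {
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  out <- integer(nrow(query_x))
  for (q in seq_len(nrow(query_x))) {
    dd <- numeric(nrow(train_x))
    for (i in seq_len(nrow(train_x)))
      dd[i] <- sqrt(sum((query_x[q, ] - train_x[i, ])^2))
    nb <- order(dd)[seq_len(k)]
    cls <- sort(unique(train_y[nb]))
    votes <- vapply(cls, function(cl) sum(train_y[nb] == cl), integer(1))
    best <- cls[votes == max(votes)]
    if (length(best) > 1) {
      md <- vapply(best, function(cl) mean(dd[nb][train_y[nb] == cl]), numeric(1))
      best <- best[order(md, best)]
    }
    out[q] <- best[1]
  }
  out
}

# Small clean series helper used across ADI tests.
flat_series <- function(n, m = 3, sd = 0.1, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(n * m, sd = sd), n, m))
}
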