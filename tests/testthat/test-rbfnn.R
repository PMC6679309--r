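tiny_net <- function(centers, widths, weights) {
  structure(list(centers = as.matrix(centers), widths = widths,
                 weights = as.matrix(weights), input_dim = ncol(as.matrix(centers)),
                 n_outputs = ncol(as.matrix(weights))),
            class = "rbf_network")
}

test_that("forward pass at a centre returns that unit's weights exactly", {
  net <- tiny_net(matrix(c(0.2, 0.8), 1), widths = 0.5,
                  weights = matrix(c(5, -1, 0, 2), 1))
  expect_equal(as.vector(rbf_forward(net, c(0.2, 0.8))), c(5, -1, 0, 2))
  net$weights[] <- 0
  expect_equal(as.vector(rbf_forward(net, c(0.9, 0.1))), rep(0, 4))
})

test_that("forward pass matches a hand-evaluated two-unit network", {
  c1 <- c(0, 0); c2 <- c(1, 1)
  net <- tiny_net(rbind(c1, c2), widths = c(0.7, 1.3),
                  weights = rbind(c(1, -2), c(0.5, 3)))
  x <- c(0.3, -0.4)
  h1 <- exp(-sum((x - c1)^2) / 0.7^2)
  h2 <- exp(-sum((x - c2)^2) / 1.3^2)
  expect_equal(as.vector(rbf_forward(net, x)),
               c(1 * h1 + 0.5 * h2, -2 * h1 + 3 * h2), tolerance = 1e-12)
})

test_that("error distance and error coefficient follow their definitions", {
  expect_equal(error_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), c(1, 1, 0, 0))
  expect_equal(error_distance(c(0.25, 0.5), c(0.25, 0.5)), c(0, 0))
  expect_equal(error_coefficient(matrix(c(1, 1, 0, 0), 1)), 0.5)
  d <- withr::with_seed(2, matrix(runif(20), 5, 4))
  expect_equal(error_coefficient(d), error_coefficient(d[sample(5), ]))
  expect_error(error_coefficient(numeric(0)), "empty")
})

test_that("initialization is reproducible and respects its contracts", {
  x <- withr::with_seed(6, matrix(runif(80), 20, 4))
  cfg <- rbf_config(n_hidden = 6, seed = 9)
  n1 <- rbf_init(cfg, x)
  n2 <- rbf_init(cfg, x)
  expect_identical(n1, n2)
  expect_true(all(n1$widths > 0))
  # every centre is a training row
  expect_true(all(apply(n1$centers, 1, function(cc)
    any(apply(x, 1, function(r) all(r == cc))))))
  expect_error(rbf_config(n_hidden = 0), "n_hidden")
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(21, {
    for (i in 1:5) {
      k <- sample(5:12, 1); d <- sample(2:5, 1); h <- sample(2:6, 1)
      x <- matrix(runif(k * d), k, d)
      y <- one_hot(sample(0:3, k, replace = TRUE))
      net <- rbf_init(rbf_config(n_hidden = h, seed = i), x)
      g <- rbf_gradients(net, x, y)
      for (block in c("weights", "centers", "log_widths")) {
        num <- numeric_gradient(net, x, y, block)
        ana <- switch(block, weights = g$d_weights, centers = g$d_centers,
                      log_widths = g$d_log_widths)
        expect_equal(as.vector(ana), as.vector(num), tolerance = 1e-6)
      }
    }
  })
})

test_that("training stops immediately when the threshold already holds", {
  x <- withr::with_seed(3, matrix(runif(20), 10, 2))
  y <- one_hot(rep(0:1, 5))
  cfg <- rbf_config(n_hidden = 3, ec_threshold = 100, seed = 4)
  fit <- rbf_train(rbf_init(cfg, x), x, y, cfg)
  expect_identical(fit$trace$stop_reason, "threshold")
  expect_identical(fit$trace$final_epoch, 1L)
})

test_that("gradient descent solves an XOR-style four-point problem", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  lab <- c(0L, 1L, 1L, 0L)
  cfg <- rbf_config(n_hidden = 4, learning_rate = 2, max_epochs = 3000,
                    ec_threshold = 1e-3, seed = 2)
  fit <- rbf_train(rbf_init(cfg, x), x, one_hot(lab), cfg)
  expect_lt(tail(fit$trace$ec, 1), 0.05)
  expect_identical(rbf_predict(fit$net, x), lab)
})

test_that("with a small learning rate the error coefficient does not increase", {
  x <- withr::with_seed(10, matrix(runif(30), 15, 2))
  y <- one_hot(withr::with_seed(11, sample(0:3, 15, replace = TRUE)))
  cfg <- rbf_config(n_hidden = 5, learning_rate = 0.01, max_epochs = 200,
                    ec_threshold = 1e-9, seed = 7)
  fit <- rbf_train(rbf_init(cfg, x), x, y, cfg)
  expect_lt(tail(fit$trace$ec, 1), fit$trace$ec[1])
})

test_that("a unit-per-sample network interpolates a tiny training set", {
  x <- withr::with_seed(14, matrix(runif(16), 8, 2))
  lab <- rep(0:3, 2)
  cfg <- rbf_config(n_hidden = 8, learning_rate = 1, max_epochs = 3000,
                    ec_threshold = 5e-3, seed = 3)
  net <- rbf_init(cfg, x)
  net$widths[] <- 0.2      # narrow bumps: activations near the identity
  fit <- rbf_train(net, x, one_hot(lab), cfg)
  expect_lt(tail(fit$trace$ec, 1), 0.01)
  expect_identical(rbf_predict(fit$net, x), lab)
})

test_that("hidden units are exchangeable: permuting them preserves outputs", {
  x <- withr::with_seed(5, matrix(runif(40), 10, 4))
  net <- rbf_init(rbf_config(n_hidden = 6, seed = 8), x)
  perm <- c(4, 1, 6, 2, 5, 3)
  pnet <- net
  pnet$centers <- net$centers[perm, ]
  pnet$widths <- net$widths[perm]
  pnet$weights <- net$weights[perm, ]
  expect_equal(rbf_forward(pnet, x), rbf_forward(net, x), tolerance = 1e-14)
})

test_that("prediction decodes by argmax with ties to the lowest class", {
  net <- tiny_net(matrix(0, 1, 1), widths = 1, weights = matrix(c(0.9, 0.1, 0, 0), 1))
  expect_identical(rbf_predict(net, matrix(0)), 0L)
  net$weights <- matrix(c(0.5, 0.5, 0, 0), 1)
  expect_identical(rbf_predict(net, matrix(0)), 0L)
  net$weights <- matrix(c(0, 0.5, 0.5, 0.2), 1)
  expect_identical(rbf_predict(net, matrix(0)), 1L)
})

test_that("models survive a JSON save/load round trip", {
  x <- withr::with_seed(9, matrix(runif(40, 10, 20), 10, 4))
  cfg <- rbf_config(n_hidden = 4, seed = 5)
  net <- rbf_init(cfg, x)
  params <- fit_minmax(x)
  path <- withr::local_tempfile(fileext = ".json")
  rbf_save(net, path, params = params, config = cfg)
  back <- rbf_load(path)
  expect_equal(back$net$centers, net$centers, ignore_attr = TRUE)
  expect_equal(back$net$widths, net$widths)
  expect_equal(back$net$weights, net$weights, ignore_attr = TRUE)
  expect_equal(unname(back$params$min), unname(params$min))
  expect_equal(back$config$n_hidden, cfg$n_hidden)
  expect_equal(rbf_forward(back$net, x[1, ]), rbf_forward(net, x[1, ]),
               ignore_attr = TRUE)
})
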