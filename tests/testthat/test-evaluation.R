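balanced_labels <- function(n_per_class = 30)
  rep(0:3, each = n_per_class)

test_that("fold plans are balanced stratified partitions, reproducible by seed", {
  labels <- withr::with_seed(1, sample(balanced_labels(26)))   # n = 104
  plan <- make_folds(labels, seed = 9)
  expect_length(plan, 10)
  val_sizes <- lengths(lapply(plan, `[[`, "validation"))
  expect_true(all(val_sizes %in% c(10, 11)))
  all_val <- sort(unlist(lapply(plan, `[[`, "validation")))
  expect_identical(all_val, seq_along(labels))                 # true partition
  for (f in plan)
    expect_identical(sort(c(f$train, f$validation)), seq_along(labels))
  # stratification: every validation split sees every class
  for (f in plan)
    expect_setequal(unique(labels[f$validation]), 0:3)
  expect_identical(make_folds(labels, seed = 9), plan)
  expect_false(identical(make_folds(labels, seed = 10), plan))
  expect_error(make_folds(rep(0, 5)), "at least 10")
})

test_that("confusion matrix is column-normalized with predicted rows", {
  truth <- balanced_labels(5)
  cm <- confusion_matrix(truth, truth)
  expect_equal(unname(diag(cm)), rep(100, 4))
  expect_equal(sum(cm), 400)

  cm3 <- confusion_matrix(truth, rep(3L, 20))
  expect_equal(unname(cm3["P3", ]), rep(100, 4))
  expect_equal(unname(colSums(cm3)), rep(100, 4))

  mixed <- c(0L, 0L, 1L, 2L)
  cm_m <- confusion_matrix(c(0L, 1L, 1L, 2L), mixed)
  expect_equal(unname(cm_m["P0", "T1"]), 50)
  expect_error(confusion_matrix(0:1, 0L), "length mismatch")
})

test_that("an oracle predictor scores 100% and a constant one scores chance", {
  x <- withr::with_seed(2, matrix(runif(120 * 3), 120, 3))
  labels <- balanced_labels(30)
  folds <- make_folds(labels, seed = 4)
  # plant the true label as a feature so the predictor can read it back
  # (stratified folds put all four classes in every training split, so the
  # per-fold scaling maps the label column to exactly {0, 1/3, 2/3, 1})
  x_or <- cbind(x, lab = labels)
  oracle <- cross_validate(x_or, labels, seed = 4, folds = folds,
                           predictor = function(tx, ty, vx)
                             as.integer(round(vx[, "lab"] * 3)))
  expect_equal(oracle$mean_accuracy, 100)
  constant <- cross_validate(x, labels, seed = 4, folds = folds,
                             predictor = function(tx, ty, vx)
                               rep(2L, nrow(vx)))
  expect_equal(constant$mean_accuracy, 25, tolerance = 0.1)
  expect_equal(unname(constant$confusion["P2", ]), rep(100, 4))
})

test_that("per-fold normalization is fitted on the training split only", {
  x <- matrix(c(seq(0, 119)), 120, 1)
  colnames(x) <- "v"
  labels <- balanced_labels(30)
  seen <- new.env(); seen$ranges <- list()
  cross_validate(x, labels, seed = 1,
                 predictor = function(tx, ty, vx) {
                   seen$ranges <- c(seen$ranges, list(range(vx)))
                   rep(0L, nrow(vx))
                 })
  # scaled validation rows must sometimes escape [0,1]: the fold max/min
  # of the full column cannot all live in every training split
  expect_true(any(vapply(seen$ranges, function(r) r[1] < 0 | r[2] > 1, TRUE)))
})

test_that("excluded rows neither train nor score, with folds intact", {
  x <- withr::with_seed(6, matrix(runif(200 * 2), 200, 2))
  labels <- balanced_labels(50)
  excl <- withr::with_seed(7, runif(200) < 0.25)
  folds <- make_folds(labels, seed = 2)
  cv <- cross_validate(x, labels, seed = 2, folds = folds, exclude = excl,
                       predictor = function(tx, ty, vx) rep(0L, nrow(vx)))
  expect_identical(cv$n_scored, sum(!excl))
  expect_length(cv$folds, 10)
})

test_that("knn prediction matches a nested-loop reference with tie rules", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(10:25, 1); d <- sample(1:3, 1)
      tx <- matrix(round(runif(n * d), 2), n, d)   # rounding forces distance ties
      ty <- sample(0:3, n, replace = TRUE)
      qx <- matrix(round(runif(6 * d), 2), 6, d)
      k <- sample(1:5, 1)
      expect_identical(knn_predict(tx, ty, qx, k = k),
                       knn_reference(tx, ty, qx, k = k))
    }
  })
  # self-exclusion: nearest distinct neighbour decides
  tx <- matrix(c(0, 0.1, 5), 3)
  ty <- c(2L, 1L, 0L)
  expect_identical(knn_predict(tx, ty, tx, k = 1, exclude_self = TRUE),
                   c(1L, 2L, 1L))
  expect_identical(knn_predict(tx, ty, tx, k = 1, exclude_self = FALSE), ty)
  expect_identical(knn_predict(matrix(1), 3L, matrix(c(0, 9), 2), k = 1),
                   c(3L, 3L))
  expect_error(knn_predict(tx, ty, tx, k = 5), "exceeds")
})

test_that("the knn baseline separates an easy synthetic dataset", {
  cfg <- synthetic_preset("separable", sample_interval = 120,
                          n_trees_per_class = 1, seed = 15)
  st <- stack_dataset(generate_dataset(cfg)$data)
  cv <- knn_baseline(st$x, st$label, k = 7, seed = 5)
  expect_gt(cv$mean_accuracy, 90)
})

test_that("feature ablation runs one exclusion per feature and finds the signal", {
  # one informative feature: class mean moves only on air temperature
  p <- default_class_profiles()
  base <- p$mean[1, ]
  p$mean <- matrix(rep(base, each = 4), 4, dimnames = dimnames(p$mean))
  p$mean[, "at_c"] <- 20 + 3 * (0:3)
  p$amplitude[] <- 0
  cfg <- synthetic_config(class_profiles = p, sample_interval = 120,
                          n_trees_per_class = 1, seed = 21)
  st <- stack_dataset(generate_dataset(cfg)$data)
  knn7 <- function(tx, ty, vx) knn_predict(tx, ty, vx, k = 7)
  folds <- make_folds(st$label, seed = 6)
  full <- cross_validate(st$x, st$label, seed = 6, folds = folds, predictor = knn7)
  drop_sig <- cross_validate(st$x[, setdiff(PEF_FEATURES, "at_c")], st$label,
                             seed = 6, folds = folds, predictor = knn7)
  drop_noise <- cross_validate(st$x[, setdiff(PEF_FEATURES, "sh_pct")], st$label,
                               seed = 6, folds = folds, predictor = knn7)
  expect_gt(full$mean_accuracy, 90)
  expect_lt(drop_sig$mean_accuracy, 40)          # near the 25% chance level
  expect_gt(drop_noise$mean_accuracy, 90)        # pure-noise feature is inert

  tab <- ablate_pefs(st$x, st$label,
                     rbf_config(n_hidden = 8, max_epochs = 60, seed = 2),
                     seed = 6)
  expect_identical(nrow(tab), 7L)
  expect_identical(tab$removed, PEF_FEATURES)
  expect_true(all(tab$full_accuracy == tab$full_accuracy[1]))
})

test_that("arms of the screening comparison share folds and stay close on clean data", {
  cfg <- synthetic_preset("separable", sample_interval = 120,
                          n_trees_per_class = 1, seed = 33)
  gen <- generate_dataset(cfg)
  cmp <- compare_adi(gen$data, Z = 20, config = rbf_config(seed = 3), seed = 8)
  # disturbance-free: screen keeps nearly everything, arms agree within noise
  expect_gt(cmp$retained, 0.95)
  expect_gt(cmp$with_adi$mean_accuracy, 90)
  expect_gt(cmp$without_adi$mean_accuracy, 90)
  expect_lt(abs(cmp$gain), 5)
  # determinism of the full comparison
  cmp2 <- compare_adi(gen$data, Z = 20, config = rbf_config(seed = 3), seed = 8)
  expect_identical(cmp$with_adi$fold_accuracy, cmp2$with_adi$fold_accuracy)
  expect_identical(cmp$gain, cmp2$gain)
})
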