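# Evaluation harness: stratified 10-fold cross-validation, accuracy and
# confusion matrix, with/without-anomaly-screening comparison, per-feature
# ablation, and a k-nearest-neighbour baseline.

#' Build a stratified k-fold plan
#'
#' Randomly partitions the samples into `n_folds` validation groups of equal
#' size (within one), stratified by class so every fold sees every class.
#' Each group serves as the validation set exactly once.
#'
#' @param labels Integer class label per sample.
#' @param n_folds Number of folds (default 10).
#' @param seed Random seed; the plan is reproducible.
#' @return An object of class `fold_plan`: a list of `n_folds` elements,
#'   each with integer vectors `train` and `validation`.
#' @export
make_folds <- function(labels, n_folds = 10, seed = 1) {
  n <- length(labels)
  if (n < n_folds) stop("need at least ", n_folds, " samples")
  fold_of <- integer(n)
  withr::with_seed(seed, {
    ordered <- unlist(lapply(split(seq_len(n), labels), sample))
  })
  fold_of[ordered] <- rep_len(seq_len(n_folds), n)
  plan <- lapply(seq_len(n_folds), function(f)
    list(train = which(fold_of != f), validation = which(fold_of == f)))
  structure(plan, class = "fold_plan", seed = seed)
}

#' Confusion matrix in column percentages
#'
#' Entry `(p, t)` is `100 * count(pred = p & true = t) / count(true = t)`:
#' rows index the predicted class, columns the true class, and every
#' non-empty column sums to 100.
#'
#' @param true,pred Integer label vectors of equal length.
#' @param n_classes Number of classes.
#' @return `n_classes` x `n_classes` numeric matrix of percentages (columns
#'   with no true samples are `NaN`).
#' @export
confusion_matrix <- function(true, pred, n_classes = 4) {
  if (length(true) != length(pred)) stop("length mismatch")
  lv <- 0:(n_classes - 1)
  counts <- table(factor(pred, levels = lv), factor(true, levels = lv))
  out <- sweep(counts, 2, colSums(counts), "/") * 100
  dimnames(out) <- list(predicted = paste0("P", lv), true = paste0("T", lv))
  as.matrix(out)
}

#' Cross-validate a classifier over a fold plan
#'
#' For each fold, min-max normalization is fitted on the training rows only
#' (the 0/1 mask column, if present, is passed through unscaled), a
#' classifier is trained, and the validation rows are predicted. The default
#' classifier is the RBF network; `predictor` can substitute any
#' `function(train_x, train_y, valid_x) -> labels`, e.g. for the KNN
#' baseline or a control.
#'
#' @param x Feature matrix (raw scale; one row per sample).
#' @param labels Integer class labels per row.
#' @param config An [rbf_config()] (ignored when `predictor` is given).
#' @param seed Seed controlling the fold plan and per-fold training.
#' @param folds Optional [make_folds()] plan; built from `labels` and `seed`
#'   when omitted.
#' @param predictor Optional custom classifier function.
#' @param exclude Optional logical vector over rows: rows marked `TRUE` are
#'   treated as eliminated from the dataset (e.g. anomaly-flagged rows) —
#'   they join no training split and are not predicted or scored — while the
#'   fold plan itself is still defined over all rows, so a screened and an
#'   unscreened run can share identical folds.
#' @return An object of class `cv_result`: `fold_accuracy` (percent, one per
#'   fold), `mean_accuracy`, `confusion` (pooled 4 x 4 column-percentage
#'   matrix), `n_scored` (rows scored across validation splits), `warnings`
#'   (folds missing a class), `folds`.
#' @export
cross_validate <- function(x, labels, config = rbf_config(), seed = 1,
                           folds = NULL, predictor = NULL, exclude = NULL) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels))
  if (is.null(exclude)) exclude <- logical(nrow(x))
  stopifnot(length(exclude) == nrow(x))
  if (is.null(folds)) folds <- make_folds(labels, seed = seed)
  n_classes <- max(4L, max(labels) + 1L)
  mask_col <- which(colnames(x) == MASK_COLUMN)
  warn <- character(0)
  pooled_true <- integer(0); pooled_pred <- integer(0)
  acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; va <- folds[[f]]$validation
    tr <- tr[!exclude[tr]]
    va <- va[!exclude[va]]
    if (!length(va)) {
      warn <- c(warn, sprintf("fold %d: no rows left to score", f))
      acc[f] <- NA_real_
      next
    }
    missing_cls <- setdiff(unique(labels), labels[tr])
    if (length(missing_cls))
      warn <- c(warn, sprintf("fold %d: class %s absent from training split",
                              f, paste(missing_cls, collapse = ",")))
    scale_cols <- setdiff(seq_len(ncol(x)), mask_col)
    params <- fit_minmax(x[tr, scale_cols, drop = FALSE])
    xt <- x[tr, , drop = FALSE]; xv <- x[va, , drop = FALSE]
    xt[, scale_cols] <- apply_minmax(params, xt[, scale_cols, drop = FALSE])
    xv[, scale_cols] <- apply_minmax(params, xv[, scale_cols, drop = FALSE])
    pred <- if (is.null(predictor)) {
      cfg <- config
      cfg$seed <- config$seed + f
      net <- rbf_init(cfg, xt)
      fit <- rbf_train(net, xt, one_hot(labels[tr], n_classes), cfg)
      rbf_predict(fit$net, xv)
    } else {
      predictor(xt, labels[tr], xv)
    }
    acc[f] <- 100 * mean(pred == labels[va])
    pooled_true <- c(pooled_true, labels[va])
    pooled_pred <- c(pooled_pred, as.integer(pred))
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc, na.rm = TRUE),
                 confusion = confusion_matrix(pooled_true, pooled_pred, n_classes),
                 n_scored = length(pooled_true), warnings = warn, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, mean accuracy %.1f%% (fold range %.1f-%.1f%%)\n",
              length(x$fold_accuracy), x$mean_accuracy,
              min(x$fold_accuracy), max(x$fold_accuracy)))
  cat("confusion (column %):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

fold_hash <- function(folds) {
  paste(vapply(folds, function(f) sum(f$validation * seq_along(f$validation)),
               numeric(1)), collapse = "/")
}

#' Compare classification with and without anomaly screening
#'
#' Runs the anomaly screen over every series, then cross-validates two arms
#' with an identical fold plan and identical seeds. The unscreened arm uses
#' the raw 7 features of every row. The screened arm is the dataset the
#' screen builds: rows flagged abnormal are eliminated — they join no
#' training split and are not scored — and the surviving rows carry the
#' 8-column masked representation (7 features plus the 0/1 mask, the form
#' the classifier consumes downstream). The screen uses the eliminate
#' differencing chain, under which a sustained disturbance flags its whole
#' block. The fold plan is built once over all rows and shared, so the
#' arms are paired; the accuracy difference measures what screening the
#' dataset buys.
#'
#' @param data List of [pef_series] (raw, possibly disturbed).
#' @param Z Burn-in rows for [run_adi()].
#' @param config An [rbf_config()].
#' @param seed Seed shared by both arms.
#' @return List with `with_adi` and `without_adi` ([cross_validate()]
#'   results), `gain` (accuracy difference in percentage points),
#'   `retained` (fraction of rows surviving the screen) and `adi_results`.
#' @export
compare_adi <- function(data, Z = 360, config = rbf_config(), seed = 1) {
  screened <- adi_dataset(data, Z = Z, mode = "mask", chain = "eliminate")
  masked <- stack_dataset(screened$data)
  raw <- masked$x[, PEF_FEATURES, drop = FALSE]
  flagged <- masked$x[, MASK_COLUMN] == 1
  folds <- make_folds(masked$label, seed = seed)
  with_adi <- cross_validate(masked$x, masked$label, config, seed,
                             folds = folds, exclude = flagged)
  without_adi <- cross_validate(raw, masked$label, config, seed, folds = folds)
  stopifnot(fold_hash(with_adi$folds) == fold_hash(without_adi$folds))
  list(with_adi = with_adi, without_adi = without_adi,
       gain = with_adi$mean_accuracy - without_adi$mean_accuracy,
       retained = 1 - mean(flagged), adi_results = screened$results)
}

#' Leave-one-feature-out ablation
#'
#' Re-runs cross-validation seven times, each time removing one of the seven
#' features (the mask column, when present, is always retained), and reports
#' the accuracy next to the full-model accuracy. Larger drops mark more
#' important features.
#'
#' @param x Feature matrix including all seven features (and optionally the
#'   mask column).
#' @param labels Integer class labels.
#' @param config An [rbf_config()].
#' @param seed Seed shared across runs (identical folds).
#' @return Data frame with columns `removed`, `mean_accuracy` and
#'   `full_accuracy`.
#' @export
ablate_pefs <- function(x, labels, config = rbf_config(), seed = 1) {
  x <- as.matrix(x)
  stopifnot(all(PEF_FEATURES %in% colnames(x)))
  folds <- make_folds(labels, seed = seed)
  full <- cross_validate(x, labels, config, seed, folds = folds)
  acc <- vapply(PEF_FEATURES, function(f) {
    keep <- setdiff(colnames(x), f)
    cross_validate(x[, keep, drop = FALSE], labels, config, seed,
                   folds = folds)$mean_accuracy
  }, numeric(1))
  data.frame(removed = PEF_FEATURES, mean_accuracy = unname(acc),
             full_accuracy = full$mean_accuracy, stringsAsFactors = FALSE)
}

#' K-nearest-neighbour prediction
#'
#' Majority vote among the `k` nearest training rows by Euclidean distance.
#' Vote ties break to the class with the smallest mean neighbour distance,
#' then to the lowest class index. With `exclude_self = TRUE` a query that
#' coincides with a training row ignores one zero-distance copy of itself.
#'
#' @param train_x,train_y Training rows and labels.
#' @param query_x Rows to classify.
#' @param k Neighbour count (`k <=` usable training rows).
#' @param exclude_self Drop one exact-match neighbour per query?
#' @return Integer predicted labels.
#' @export
knn_predict <- function(train_x, train_y, query_x, k = 7, exclude_self = FALSE) {
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  train_y <- as.integer(train_y)
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(train_x) - exclude_self) stop("k exceeds available training rows")
  d2 <- pmax(sweep(sweep(-2 * tcrossprod(query_x, train_x), 1,
                         rowSums(query_x^2), "+"), 2, rowSums(train_x^2), "+"), 0)
  apply_one <- function(dq) {
    ord <- order(dq)
    if (exclude_self && dq[ord[1]] < 1e-24) ord <- ord[-1]
    nb <- ord[seq_len(k)]
    votes <- table(train_y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      mean_d <- vapply(top, function(cl)
        mean(sqrt(dq[nb][train_y[nb] == as.integer(cl)])), numeric(1))
      top <- top[order(mean_d, as.integer(top))]
    }
    as.integer(top[1])
  }
  vapply(seq_len(nrow(query_x)), function(i) apply_one(d2[i, ]), integer(1))
}

#' KNN baseline under cross-validation
#'
#' Evaluates the k-nearest-neighbour classifier (`k = 7` by default, the
#' conventional reference setting) over the same fold machinery as the RBF
#' network, for a like-for-like baseline comparison.
#'
#' @param x Feature matrix.
#' @param labels Integer class labels.
#' @param k Neighbour count.
#' @param seed Fold seed.
#' @param folds Optional [make_folds()] plan.
#' @return A [cross_validate()] result.
#' @export
knn_baseline <- function(x, labels, k = 7, seed = 1, folds = NULL) {
  cross_validate(x, labels, seed = seed, folds = folds,
                 predictor = function(tx, ty, vx) knn_predict(tx, ty, vx, k = k))
}
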