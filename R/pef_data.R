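# Proximity environmental feature (PEF) containers, CSV I/O and [0,1] scaling.

#' Proximity environmental feature names
#'
#' Column names of the seven ambient features measured around each tree:
#' air temperature (degC), air humidity (%RH), oxygen concentration (%),
#' carbon dioxide concentration (ppm), illumination intensity (lux),
#' soil humidity (%) and soil acidity (pH).
#'
#' @format Character vector of length 7.
#' @export
PEF_FEATURES <- c("at_c", "ah_pct", "oc_pct", "cdc_ppm", "ii_lux", "sh_pct", "sa_ph")

# Name of the appended abnormality mask column.
MASK_COLUMN <- "d"

#' Construct a PEF series for one tree
#'
#' A PEF series holds the chronological measurements of the seven proximity
#' environmental features for a single tree, together with the tree's health
#' class. Health classes follow the four-level visual-assessment scale:
#' 0 (great), 1 (good), 2 (general), 3 (poor).
#'
#' @param values Numeric matrix with one row per time point and one column per
#'   feature (columns named as in [PEF_FEATURES]; an optional extra `d` mask
#'   column is allowed). All entries must be finite.
#' @param timestamp Numeric vector of seconds since the start of the series,
#'   strictly increasing, non-negative, one per row.
#' @param tree_id Identifier of the tree the series belongs to.
#' @param label Integer health class in `0:3`.
#' @param sample_interval Nominal sampling interval in seconds.
#' @return An object of class `pef_series`.
#' @examples
#' x <- matrix(rnorm(21), ncol = 7, dimnames = list(NULL, PEF_FEATURES))
#' s <- pef_series(x, timestamp = c(0, 10, 20), tree_id = "t1", label = 2)
#' nrow(s$values)
#' @export
pef_series <- function(values, timestamp, tree_id, label, sample_interval = 10) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!ncol(values) %in% c(7L, 8L))
    stop("'values' must have 7 feature columns (plus optional mask column)")
  if (is.null(colnames(values)))
    colnames(values) <- if (ncol(values) == 7L) PEF_FEATURES else c(PEF_FEATURES, MASK_COLUMN)
  if (!all(PEF_FEATURES %in% colnames(values)))
    stop("'values' columns must be named ", paste(PEF_FEATURES, collapse = ", "))
  if (!all(is.finite(values)))
    stop("all feature values must be finite")
  timestamp <- as.numeric(timestamp)
  if (length(timestamp) != nrow(values))
    stop("'timestamp' length must equal the number of rows")
  if (any(timestamp < 0))
    stop("timestamps must be non-negative")
  if (nrow(values) > 1 && any(diff(timestamp) <= 0))
    stop("timestamps must be strictly increasing")
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || !label %in% 0:3)
    stop("'label' must be a single integer in 0:3")
  structure(
    list(values = values, timestamp = timestamp, tree_id = as.character(tree_id),
         label = label, sample_interval = as.numeric(sample_interval)),
    class = "pef_series")
}

#' @export
print.pef_series <- function(x, ...) {
  cat(sprintf("<pef_series> tree %s: %d rows x %d features, label %d, interval %gs\n",
              x$tree_id, nrow(x$values), ncol(x$values), x$label, x$sample_interval))
  invisible(x)
}

csv_columns <- function(masked = FALSE) {
  c("tree_id", "timestamp_s", PEF_FEATURES, if (masked) MASK_COLUMN, "label")
}

#' Read a PEF dataset from CSV
#'
#' Reads a CSV file in the package schema (`tree_id, timestamp_s, at_c,
#' ah_pct, oc_pct, cdc_ppm, ii_lux, sh_pct, sa_ph[, d], label`) and returns
#' one [pef_series] per tree, rows sorted by timestamp. The optional `d`
#' column carries the abnormality mask written after anomaly screening.
#'
#' @param path Path to a readable CSV file.
#' @return A list of `pef_series`, one per `tree_id`, in order of first
#'   appearance.
#' @seealso [write_pef_csv()]
#' @export
read_pef_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  masked <- MASK_COLUMN %in% names(df)
  need <- csv_columns(masked)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  feat_cols <- c(PEF_FEATURES, if (masked) MASK_COLUMN)
  for (cl in c("timestamp_s", feat_cols, "label")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d", cl, bad[1]))
    df[[cl]] <- as.numeric(df[[cl]])
  }
  ids <- unique(df$tree_id)
  if (nrow(df) == 0L) return(list())
  out <- lapply(ids, function(id) {
    sub <- df[df$tree_id == id, , drop = FALSE]
    labels <- unique(sub$label)
    if (length(labels) != 1L)
      stop(sprintf("inconsistent label within series '%s' (first conflict at data row %d)",
                   id, which(df$tree_id == id & df$label != labels[1])[1]))
    ord <- order(sub$timestamp_s)
    sub <- sub[ord, , drop = FALSE]
    interval <- if (nrow(sub) > 1) stats::median(diff(sub$timestamp_s)) else 10
    pef_series(as.matrix(sub[, feat_cols, drop = FALSE]), sub$timestamp_s,
               tree_id = id, label = labels[1], sample_interval = interval)
  })
  out
}

#' Write a PEF dataset to CSV
#'
#' Inverse of [read_pef_csv()]: values round-trip at full double precision
#' (17 significant digits).
#'
#' @param data List of [pef_series] (may be empty: a header-only file is
#'   written).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pef_csv <- function(data, path) {
  stopifnot(is.list(data))
  masked <- length(data) > 0 && MASK_COLUMN %in% colnames(data[[1]]$values)
  rows <- lapply(data, function(s) {
    stopifnot(inherits(s, "pef_series"))
    cbind(data.frame(tree_id = s$tree_id, timestamp_s = s$timestamp,
                     stringsAsFactors = FALSE),
          as.data.frame(s$values),
          data.frame(label = s$label))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(csv_columns(FALSE)))),
                    csv_columns(FALSE))
  df <- df[, csv_columns(masked), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  # 17 digits preserves doubles exactly across the round trip
  old <- options(digits = 17)
  on.exit(options(old), add = TRUE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit per-feature min-max normalization parameters
#'
#' Computes the per-column minimum and maximum over the supplied (training)
#' rows. Features whose maximum equals their minimum are marked degenerate
#' and later map to the neutral value 0.5.
#'
#' @param x Numeric matrix of feature rows (at least one row).
#' @return An object of class `minmax_params` with fields `min`, `max` and
#'   `degenerate` (logical per feature).
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one row to fit normalization")
  mn <- apply(x, 2, min)
  mx <- apply(x, 2, max)
  structure(list(min = mn, max = mx, degenerate = mx == mn),
            class = "minmax_params")
}

#' Apply (or invert) min-max scaling
#'
#' Maps each feature affinely to `(x - min) / (max - min)` using parameters
#' fitted on training data, so training columns span exactly \[0,1\].
#' Values outside the training range are by default left outside \[0,1\]
#' (the map stays affine); set `clip = TRUE` to clamp. Degenerate (constant)
#' features map to 0.5.
#'
#' @param params A `minmax_params` object from [fit_minmax()].
#' @param x Numeric matrix with the same number of columns as the fit.
#' @param clip Clamp the output into \[0,1\]?
#' @return Scaled matrix of the same shape.
#' @export
apply_minmax <- function(params, x, clip = FALSE) {
  stopifnot(inherits(params, "minmax_params"))
  x <- as.matrix(x)
  if (ncol(x) != length(params$min))
    stop("dimension mismatch: params fitted for ", length(params$min),
         " features, got ", ncol(x))
  rng <- params$max - params$min
  rng[params$degenerate] <- 1  # avoid 0/0; overwritten below
  out <- sweep(sweep(x, 2, params$min, "-"), 2, rng, "/")
  if (any(params$degenerate)) out[, params$degenerate] <- 0.5
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' @rdname apply_minmax
#' @details `invert_minmax()` undoes the scaling for non-degenerate features
#'   (degenerate features are restored to their constant training value).
#' @export
invert_minmax <- function(params, x) {
  stopifnot(inherits(params, "minmax_params"))
  x <- as.matrix(x)
  if (ncol(x) != length(params$min)) stop("dimension mismatch")
  rng <- params$max - params$min
  out <- sweep(sweep(x, 2, rng, "*"), 2, params$min, "+")
  if (any(params$degenerate))
    out[, params$degenerate] <- rep(params$min[params$degenerate],
                                    each = nrow(x))
  out
}

#' Stack a dataset into a design matrix
#'
#' Concatenates the rows of every series into one matrix, with the per-series
#' health class repeated for each of its rows; this is the sample unit used
#' throughout evaluation (each sensor snapshot is one sample).
#'
#' @param data List of [pef_series].
#' @return List with `x` (row-bound feature matrix), `label` (integer vector)
#'   and `tree_id` (character vector), all aligned by row.
#' @export
stack_dataset <- function(data) {
  stopifnot(length(data) > 0)
  x <- do.call(rbind, lapply(data, `[[`, "values"))
  label <- unlist(lapply(data, function(s) rep(s$label, nrow(s$values))))
  tree <- unlist(lapply(data, function(s) rep(s$tree_id, nrow(s$values))))
  list(x = x, label = as.integer(label), tree_id = tree)
}
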