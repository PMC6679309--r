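# Adaptive data identifying (ADI): sequential first-difference 3-sigma
# screening of sensor series, with mask-column augmentation.
#
# The detector treats the first Z rows of a series as standard data, seeds
# per-feature running statistics from their consecutive differences, and then
# judges every incoming row's difference against the running mean +/- 3 sd
# band. Flagged differences never enter the statistics. Differences are taken
# between adjacent rows of the current dataset, so the two output modes
# differ in the differencing chain: in drop mode flagged rows leave the
# dataset and the next difference is taken against the last accepted row
# (a single spike flags exactly one row); in mask mode flagged rows are
# retained (masked 1) and differencing stays strictly adjacent (a single
# spike flags the spike row and the return step after it).

SIGMA_TOL <- 1e-9  # equality tolerance for the degenerate sigma = 0 band

#' Column-wise first differences of a series
#'
#' @param x A [pef_series] or a numeric matrix with at least two rows.
#' @return Matrix of `nrow(x) - 1` difference rows (`x[t+1, ] - x[t, ]`).
#' @export
diff_rows <- function(x) {
  x <- adi_input_matrix(x)
  if (nrow(x) < 2L) stop("need at least two rows to difference")
  diff(x)
}

adi_input_matrix <- function(x) {
  if (inherits(x, "pef_series")) x <- x$values
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Initialize running difference statistics
#'
#' Holds, per feature column, the running mean and standard deviation of the
#' differences accepted so far (population-style divisor: the count of
#' differences), maintained by Welford updates.
#'
#' @param n_features Number of feature columns tracked.
#' @return An object of class `adi_state` with fields `n` (accepted
#'   difference count), `mean`, `m2` (sum of squared deviations) and `sd`.
#' @export
adi_state <- function(n_features) {
  structure(list(n = 0L, mean = numeric(n_features), m2 = numeric(n_features),
                 sd = numeric(n_features)),
            class = "adi_state")
}

#' Incorporate one accepted difference row into the running statistics
#'
#' After `k` updates the state equals the batch mean and the batch
#' root-mean-square deviation (divisor `k`) over the same `k` difference
#' rows.
#'
#' @param state An `adi_state`.
#' @param diff_row Numeric vector, one difference per feature column.
#' @return The updated `adi_state`.
#' @export
adi_update_stats <- function(state, diff_row) {
  stopifnot(inherits(state, "adi_state"),
            length(diff_row) == length(state$mean))
  n <- state$n + 1L
  delta <- diff_row - state$mean
  mean <- state$mean + delta / n
  m2 <- state$m2 + delta * (diff_row - mean)
  state$n <- n
  state$mean <- mean
  state$m2 <- m2
  state$sd <- sqrt(pmax(m2, 0) / n)
  state
}

#' Judge a difference row against the 3-sigma band
#'
#' A difference is abnormal when it falls outside
#' `[mean - 3 sd, mean + 3 sd]` of the accepted differences for its column
#' (for a Gaussian difference stream this band contains 99.7% of values).
#' When the running sd is zero the band degenerates to the mean, with an
#' absolute tolerance of `1e-9` so constant channels do not flag float noise.
#'
#' @param state An `adi_state` with at least one accepted difference.
#' @param diff_row Numeric vector of differences, one per feature column.
#' @return Logical vector: `TRUE` where the column judges abnormal.
#' @export
adi_judge <- function(state, diff_row) {
  stopifnot(inherits(state, "adi_state"))
  if (state$n < 1L) stop("cannot judge before any standard differences are recorded")
  if (length(diff_row) != length(state$mean)) stop("dimension mismatch")
  lo <- state$mean - 3 * state$sd
  hi <- state$mean + 3 * state$sd
  zero <- state$sd == 0
  out <- diff_row < lo | diff_row > hi
  if (any(zero))
    out[zero] <- abs(diff_row[zero] - state$mean[zero]) > SIGMA_TOL
  out
}

#' Run the adaptive data identifying algorithm on one series
#'
#' Screens a chronological sensor series for abnormal rows. The first `Z`
#' rows are standard data: they are never flagged and their consecutive
#' differences seed the per-column statistics. Each later row's difference is
#' judged per column with [adi_judge()]; if any column is abnormal the whole
#' row is flagged and its difference is excluded from the statistics.
#' Accepted differences update the running statistics.
#'
#' Differences run between adjacent rows of the current dataset, and the two
#' output modes imply different chains. Under the `"eliminate"` chain a
#' flagged row leaves the dataset, so the next row is differenced against
#' the last accepted row; an isolated spike then flags exactly its own row
#' (the return to baseline is judged against the pre-spike row and is
#' normal), and a sustained level shift flags its whole block. Under the
#' `"adjacent"` chain flagged rows remain in the differencing sequence, so a
#' spike flags the spike row and the return step after it, while only the
#' boundaries of a level shift flag. By default drop mode uses the
#' eliminate chain and mask mode the adjacent chain; `chain` overrides this,
#' e.g. the classification pipeline screens with the eliminate chain and
#' then retains every row masked (see [compare_adi()]).
#'
#' @param x A [pef_series] or numeric matrix (rows chronological).
#' @param Z Burn-in row count (>= 2); default 360 rows, one hour at the
#'   10-second sampling interval.
#' @param mode `"mask"` appends a 0/1 abnormality column `d` to the output
#'   matrix; `"drop"` removes flagged rows instead.
#' @param chain Differencing chain, `"adjacent"` or `"eliminate"`; defaults
#'   to `"adjacent"` for mask mode and `"eliminate"` for drop mode.
#' @return An object of class `adi_result`: `flags` (logical per input row),
#'   `flagged_rows` (indices), `x_new` (augmented or reduced matrix),
#'   `record` (data frame of every triggering column with the difference,
#'   mean and sd at the moment of judgement), `n_judged`, `Z`, `mode`,
#'   `chain`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), ncol = 1)
#' x[200, 1] <- x[200, 1] + 25          # inject a spike
#' run_adi(x, Z = 100, mode = "drop")$flagged_rows
#' @export
run_adi <- function(x, Z = 360, mode = c("mask", "drop"), chain = NULL) {
  mode <- match.arg(mode)
  if (is.null(chain)) chain <- if (mode == "mask") "adjacent" else "eliminate"
  chain <- match.arg(chain, c("adjacent", "eliminate"))
  series <- if (inherits(x, "pef_series")) x else NULL
  x <- adi_input_matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  Z <- as.integer(Z)
  if (Z < 2L) stop("Z must be at least 2 (sd undefined below that)")
  if (n <= Z + 1L) stop("series too short: need more than Z + 1 = ", Z + 1L, " rows")

  # Inlined Welford state (same updates as adi_update_stats, kept flat for
  # speed on 1e5-row series).
  burn <- diff(x[1:Z, , drop = FALSE])
  cnt <- nrow(burn)
  mu <- colMeans(burn)
  m2 <- colSums(sweep(burn, 2, mu)^2)
  sdv <- sqrt(m2 / cnt)

  flags <- logical(n)
  rec_row <- vector("list", 64L); rec_i <- 0L
  last <- Z
  for (t in (Z + 1L):n) {
    d <- x[t, ] - x[last, ]
    lo <- mu - 3 * sdv
    hi <- mu + 3 * sdv
    bad <- d < lo | d > hi
    zero <- sdv == 0
    if (any(zero)) bad[zero] <- abs(d[zero] - mu[zero]) > SIGMA_TOL
    if (any(bad)) {
      flags[t] <- TRUE
      rec_i <- rec_i + 1L
      rec_row[[rec_i]] <- list(t, which(bad), d[bad], mu[bad], sdv[bad])
      if (rec_i == length(rec_row)) rec_row <- c(rec_row, vector("list", length(rec_row)))
      # eliminate chain keeps differencing from the last accepted row;
      # adjacent chain moves on with the flagged row still in the sequence
      if (chain == "adjacent") last <- t
    } else {
      cnt <- cnt + 1L
      delta <- d - mu
      mu <- mu + delta / cnt
      m2 <- m2 + delta * (d - mu)
      sdv <- sqrt(pmax(m2, 0) / cnt)
      last <- t
    }
  }

  feature_names <- colnames(x)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(m))
  rec_row <- rec_row[seq_len(rec_i)]
  record <- data.frame(
    row = unlist(lapply(rec_row, function(r) rep.int(r[[1]], length(r[[2]])))),
    feature = feature_names[unlist(lapply(rec_row, `[[`, 2))],
    diff = unlist(lapply(rec_row, `[[`, 3)),
    mean = unlist(lapply(rec_row, `[[`, 4)),
    sigma = unlist(lapply(rec_row, `[[`, 5)),
    stringsAsFactors = FALSE)
  if (!rec_i)
    record <- data.frame(row = integer(), feature = character(), diff = numeric(),
                         mean = numeric(), sigma = numeric(), stringsAsFactors = FALSE)
  x_new <- if (mode == "mask") {
    cbind(x, d = as.numeric(flags))
  } else {
    x[!flags, , drop = FALSE]
  }
  state <- adi_state(m)
  state$n <- cnt; state$mean <- mu; state$m2 <- m2; state$sd <- sdv
  structure(
    list(flags = flags, flagged_rows = which(flags), x_new = x_new,
         record = record, n_judged = n - Z, Z = Z, mode = mode, chain = chain,
         tree_id = if (!is.null(series)) series$tree_id else NA_character_,
         state = state),
    class = "adi_result")
}

#' @export
print.adi_result <- function(x, ...) {
  cat(sprintf("<adi_result> %d rows judged (Z = %d burn-in), %d flagged (%.2f%%), mode = %s\n",
              x$n_judged, x$Z, length(x$flagged_rows),
              100 * length(x$flagged_rows) / x$n_judged, x$mode))
  invisible(x)
}

#' Attach abnormality masks to a dataset
#'
#' Appends each series' 0/1 flag column `d` as the eighth feature, the form
#' in which screened data feed the classifier.
#'
#' @param results List of [run_adi()] results (mask mode), one per series.
#' @param data List of [pef_series] in the same order.
#' @return The dataset with `d` appended to every series' value matrix.
#' @export
mask_dataset <- function(results, data) {
  if (length(results) != length(data))
    stop("length mismatch: ", length(results), " results for ", length(data), " series")
  Map(function(r, s) {
    stopifnot(inherits(r, "adi_result"), inherits(s, "pef_series"))
    if (length(r$flags) != nrow(s$values))
      stop("result/series row count mismatch for tree ", s$tree_id)
    s$values <- cbind(s$values[, PEF_FEATURES, drop = FALSE],
                      d = as.numeric(r$flags))
    s
  }, results, data)
}

#' Run ADI over every series of a dataset
#'
#' @inheritParams run_adi
#' @param data List of [pef_series].
#' @return List with `results` (per-series [run_adi()] output) and `data`
#'   (the mask-augmented dataset, mask mode only).
#' @export
adi_dataset <- function(data, Z = 360, mode = "mask", chain = NULL) {
  results <- lapply(data, run_adi, Z = Z, mode = mode, chain = chain)
  list(results = results,
       data = if (mode == "mask") mask_dataset(results, data) else NULL)
}
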