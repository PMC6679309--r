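# Synthetic PEF generator: diurnal trends per feature, class-dependent mean
# levels, Gaussian sensor noise, and two injected disturbance families
# (weather-like level shifts; logger faults: spikes and zero dropouts) with a
# ground-truth log for scoring the anomaly screen.

#' Default class profiles for the synthetic generator
#'
#' Each of the four health classes places every feature's daily mean at an
#' increasing distance from a "suitable range" centre; for some features the
#' side of the centre alternates with class, so class regions are not
#' linearly ordered along any single axis. The diurnal amplitude (shared
#' across classes) follows a half-sine day shape: temperature and
#' illumination peak mid-window, humidity and CO2 dip while photosynthesis
#' is most active.
#'
#' @return List of three 4 x 7 matrices (`mean`, `amplitude`, `noise_sd`),
#'   rows = classes 0-3, columns = [PEF_FEATURES].
#' @export
default_class_profiles <- function() {
  centre <- c(at_c = 24, ah_pct = 65, oc_pct = 20.9, cdc_ppm = 410,
              ii_lux = 20000, sh_pct = 32, sa_ph = 6.6)
  step <- c(at_c = 1.5, ah_pct = -4, oc_pct = -0.15, cdc_ppm = 25,
            ii_lux = -3000, sh_pct = -3, sa_ph = 0.25)
  # per-class multiplier of the step; alternating sign for at_c, cdc_ppm and
  # sa_ph makes those class sequences fold back across the centre
  side <- rbind(at_c = c(0, 1, -2, 3), ah_pct = 0:3, oc_pct = 0:3,
                cdc_ppm = c(0, -1, 2, -3), ii_lux = 0:3, sh_pct = 0:3,
                sa_ph = c(0, 1, -2, 3))
  mean <- t(centre + step * side)
  amplitude <- matrix(rep(c(at_c = 6, ah_pct = -12, oc_pct = 0.3,
                            cdc_ppm = -60, ii_lux = 60000, sh_pct = -4,
                            sa_ph = 0.15), each = 4), nrow = 4,
                      dimnames = list(NULL, PEF_FEATURES))
  noise_sd <- matrix(rep(c(at_c = 0.4, ah_pct = 1.0, oc_pct = 0.05,
                           cdc_ppm = 8, ii_lux = 2000, sh_pct = 0.8,
                           sa_ph = 0.05), each = 4), nrow = 4,
                     dimnames = list(NULL, PEF_FEATURES))
  dimnames(mean) <- list(NULL, PEF_FEATURES)
  list(mean = mean, amplitude = amplitude, noise_sd = noise_sd)
}

#' Configuration of the synthetic PEF generator
#'
#' @param n_trees_per_class Trees per health class; either one count or a
#'   vector of four.
#' @param days_per_tree Measurement days per tree.
#' @param sample_interval Sampling interval in seconds (default 10).
#' @param window Daily measurement window in seconds since midnight; default
#'   `c(36000, 57600)`, i.e. 10:00-16:00.
#' @param class_profiles List of 4 x 7 `mean`, `amplitude`, `noise_sd`
#'   matrices; see [default_class_profiles()].
#' @param disturbance_rate Expected weather-like level shifts per series
#'   (Poisson).
#' @param fault_rate Expected logger faults per series (Poisson; each fault
#'   is a spike or a zero dropout with equal probability).
#' @param shift_range Weather-shift magnitude range, in multiples of the
#'   feature's noise sd.
#' @param spike_range Spike magnitude range, in multiples of the feature's
#'   noise sd.
#' @param shift_span Weather-shift duration range as a fraction of the
#'   series length.
#' @param seed Root random seed; all generation is reproducible from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_trees_per_class = 2, days_per_tree = 1,
                             sample_interval = 10, window = c(36000, 57600),
                             class_profiles = default_class_profiles(),
                             disturbance_rate = 0, fault_rate = 0,
                             shift_range = c(5, 20), spike_range = c(10, 20),
                             shift_span = c(0.05, 0.15), seed = 1) {
  if (length(n_trees_per_class) == 1L) n_trees_per_class <- rep(n_trees_per_class, 4L)
  stopifnot(length(n_trees_per_class) == 4L, all(n_trees_per_class >= 0),
            days_per_tree >= 1, sample_interval > 0,
            length(window) == 2L, window[2] > window[1],
            disturbance_rate >= 0, fault_rate >= 0,
            all(dim(class_profiles$mean) == c(4L, 7L)),
            all(dim(class_profiles$amplitude) == c(4L, 7L)),
            all(dim(class_profiles$noise_sd) == c(4L, 7L)),
            all(class_profiles$noise_sd >= 0))
  structure(list(n_trees_per_class = as.integer(n_trees_per_class),
                 days_per_tree = as.integer(days_per_tree),
                 sample_interval = sample_interval, window = window,
                 class_profiles = class_profiles,
                 disturbance_rate = disturbance_rate, fault_rate = fault_rate,
                 shift_range = shift_range, spike_range = spike_range,
                 shift_span = shift_span, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Named generator presets
#'
#' `"separable"`: default profiles, no disturbances — classes are cleanly
#' recoverable. `"noisy"`: noise sd multiplied by 4. `"high-disturbance"`:
#' several weather shifts and logger faults per series.
#' `"table2-proportions"`: tree counts per class in the ratio
#' 11306:10421:10244:9302 (scaled to about 1/1000).
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("separable", "noisy", "high-disturbance",
                                      "table2-proportions"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    "separable" = list(),
    "noisy" = {
      p <- default_class_profiles(); p$noise_sd <- p$noise_sd * 4
      list(class_profiles = p)
    },
    "high-disturbance" = list(disturbance_rate = 4, fault_rate = 8),
    "table2-proportions" = list(n_trees_per_class = c(11L, 10L, 10L, 9L)))
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

# Daily half-sine shape: 0 at window start, 1 mid-window, back to 0.
day_shape <- function(t_in_window, window) {
  sin(pi * (t_in_window - window[1]) / (window[2] - window[1]))
}

#' Generate one clean synthetic series
#'
#' Each feature follows `mean + amplitude * s(t) + noise`, where `s(t)` is a
#' half-sine over the daily measurement window (each feature rises from its
#' minimum to a single daily extreme and back) and the noise is i.i.d.
#' Gaussian with the class profile's sd.
#'
#' @param class_label Health class 0-3.
#' @param config A [synthetic_config()].
#' @param seed Seed for this series (defaults to the config seed).
#' @param tree_id Identifier for the generated tree.
#' @return A [pef_series].
#' @export
generate_series <- function(class_label, config, seed = config$seed,
                            tree_id = paste0("tree_c", class_label, "_s", seed)) {
  stopifnot(inherits(config, "synthetic_config"), class_label %in% 0:3)
  win <- config$window
  per_day <- floor((win[2] - win[1]) / config$sample_interval)
  t_day <- win[1] + (seq_len(per_day) - 1) * config$sample_interval
  timestamp <- as.vector(outer(t_day, (seq_len(config$days_per_tree) - 1) * 86400, "+"))
  s <- rep(day_shape(t_day, win), config$days_per_tree)
  n <- length(timestamp)
  p <- config$class_profiles
  k <- class_label + 1L
  values <- withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(n * 7L), n, 7L) *
      rep(p$noise_sd[k, ], each = n)
    base <- rep(p$mean[k, ], each = n) + outer(s, p$amplitude[k, ])
    base + noise
  })
  colnames(values) <- PEF_FEATURES
  pef_series(values, timestamp - timestamp[1], tree_id = tree_id,
             label = class_label, sample_interval = config$sample_interval)
}

#' Inject disturbances into a series, keeping ground truth
#'
#' Three event kinds are injected at Poisson counts: `weather_shift` adds a
#' step of 5-20 noise sd (random sign) to a contiguous block of rows on a
#' random non-empty feature subset; `spike_fault` perturbs a single reading
#' by 10-20 noise sd; `dropout_fault` zeroes a single reading. Every altered
#' row is recorded in the returned log.
#'
#' @param series A [pef_series].
#' @param config A [synthetic_config()] (rates and magnitude ranges).
#' @param seed Seed for the injection stream.
#' @param min_row Earliest row an event may touch (default 1). Setting this
#'   past the screening burn-in models a deployment whose standard data are
#'   known good; with the default, events may contaminate the burn-in and
#'   widen the screen's bands, as they would on an unattended logger.
#' @return List with `series` (disturbed copy) and `log`, a data frame with
#'   columns `tree_id, row_start, row_end, feature, kind, magnitude`.
#' @export
inject_disturbances <- function(series, config, seed = config$seed, min_row = 1) {
  stopifnot(inherits(series, "pef_series"), inherits(config, "synthetic_config"))
  x <- series$values
  n <- nrow(x)
  k <- series$label + 1L
  sds <- config$class_profiles$noise_sd[k, ]
  log <- list()
  withr::with_seed(seed, {
    n_shift <- stats::rpois(1, config$disturbance_rate)
    n_fault <- stats::rpois(1, config$fault_rate)
    min_row <- max(1L, as.integer(min_row))
    for (i in seq_len(n_shift)) {
      len <- max(1L, round(stats::runif(1, config$shift_span[1], config$shift_span[2]) * n))
      start <- min_row - 1L + sample.int(n - len - min_row + 2L, 1)
      feats <- which(stats::runif(7) < 0.5)
      if (!length(feats)) feats <- sample.int(7, 1)
      for (f in feats) {
        mag <- sign(stats::runif(1) - 0.5) *
          stats::runif(1, config$shift_range[1], config$shift_range[2]) * sds[f]
        x[start:(start + len - 1L), f] <- x[start:(start + len - 1L), f] + mag
        log[[length(log) + 1L]] <- data.frame(
          tree_id = series$tree_id, row_start = start, row_end = start + len - 1L,
          feature = PEF_FEATURES[f], kind = "weather_shift", magnitude = mag,
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(n_fault)) {
      row <- min_row - 1L + sample.int(n - min_row + 1L, 1)
      f <- sample.int(7, 1)
      if (stats::runif(1) < 0.5) {
        mag <- sign(stats::runif(1) - 0.5) *
          stats::runif(1, config$spike_range[1], config$spike_range[2]) * sds[f]
        x[row, f] <- x[row, f] + mag
        kind <- "spike_fault"
      } else {
        mag <- -x[row, f]
        x[row, f] <- 0
        kind <- "dropout_fault"
      }
      log[[length(log) + 1L]] <- data.frame(
        tree_id = series$tree_id, row_start = row, row_end = row,
        feature = PEF_FEATURES[f], kind = kind, magnitude = mag,
        stringsAsFactors = FALSE)
    }
  })
  series$values <- x
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(tree_id = character(), row_start = integer(), row_end = integer(),
               feature = character(), kind = character(), magnitude = numeric(),
               stringsAsFactors = FALSE)
  list(series = series, log = log)
}

#' Generate a full labelled synthetic dataset
#'
#' Produces `n_trees_per_class` series per health class, injects disturbances
#' at the configured rates, and returns the ground-truth disturbance log.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `data` (list of [pef_series]) and `log` (row-bound
#'   disturbance log; see [inject_disturbances()]).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  data <- list(); logs <- list()
  idx <- 0L
  for (cls in 0:3) {
    for (i in seq_len(config$n_trees_per_class[cls + 1L])) {
      idx <- idx + 1L
      seed_i <- (config$seed * 1009L + idx * 7919L) %% .Machine$integer.max
      s <- generate_series(cls, config, seed = seed_i,
                           tree_id = sprintf("tree_c%d_%02d", cls, i))
      inj <- inject_disturbances(s, config, seed = seed_i + 1L)
      data[[idx]] <- inj$series
      logs[[idx]] <- inj$log
    }
  }
  list(data = data, log = do.call(rbind, logs))
}

#' Score anomaly detection against the ground-truth log
#'
#' Computes, per event kind, the fraction of injected events whose rows were
#' flagged. Only rows after the burn-in (`row > Z`) can be flagged, so events
#' falling entirely inside the burn-in are excluded from the denominator.
#' Point events (faults) count as recovered when their row is flagged; for
#' weather shifts the per-row flag fraction over the shifted block is
#' averaged.
#'
#' @param results List of [run_adi()] results, one per series.
#' @param data List of [pef_series] matching `results`.
#' @param log Ground-truth disturbance log from [generate_dataset()].
#' @return Data frame with columns `kind`, `n_events`, `recall`.
#' @export
detection_recall <- function(results, data, log) {
  ids <- vapply(data, `[[`, "", "tree_id")
  per_event <- vapply(seq_len(nrow(log)), function(i) {
    j <- match(log$tree_id[i], ids)
    if (is.na(j)) return(NA_real_)
    r <- results[[j]]
    rows <- log$row_start[i]:log$row_end[i]
    rows <- rows[rows > r$Z]
    if (!length(rows)) return(NA_real_)
    mean(r$flags[rows])
  }, numeric(1))
  keep <- !is.na(per_event)
  stats::aggregate(recovered ~ kind,
                   data = data.frame(kind = log$kind[keep], recovered = per_event[keep]),
                   FUN = function(v) c(n = length(v), recall = mean(v))) -> agg
  data.frame(kind = agg$kind, n_events = agg$recovered[, "n"],
             recall = agg$recovered[, "recall"], stringsAsFactors = FALSE)
}

#' Write a disturbance log to CSV
#'
#' @param log Disturbance log data frame.
#' @param path Output path.
#' @export
write_disturbance_csv <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
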