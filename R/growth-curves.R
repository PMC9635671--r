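#' Remove isolated spikes with a rolling median filter
#'
#' Replaces each point by the median of a centred window. At the series
#' boundaries the window shrinks symmetrically (half-width limited by the
#' distance to the nearer end), so the output has the same length as the
#' input and endpoints are their own medians.
#'
#' @param x Numeric series.
#' @param window Odd window width >= 3 and <= `length(x)`.
#' @return Numeric series of the same length.
#' @examples
#' x <- rep(1000, 20); x[7] <- 5000
#' despike_median(x, 5)
#' @export
despike_median <- function(x, window = 5) {
  n <- length(x)
  if (window %% 2 != 1 || window < 3) {
    ea_abort("`window` must be an odd integer >= 3.", "parameter_error")
  }
  if (window > n) ea_abort("`window` exceeds the series length.", "parameter_error")
  half <- (window - 1L) %/% 2L
  # C-speed interior; endrule = "keep" leaves the first/last `half` points raw
  y <- as.numeric(runmed(x, window, endrule = "keep"))
  for (i in seq_len(half)) {
    h <- i - 1L
    y[i] <- median(x[(i - h):(i + h)])
    j <- n - i + 1L
    y[j] <- median(x[(j - h):(j + h)])
  }
  y
}

#' Excise local spikes detected against a rolling median
#'
#' Median-filter-based spike removal that alters only the spiked points:
#' each point is compared with the median of a `window`-wide neighbourhood
#' (shifted to full width at the series boundaries, so endpoint spikes are
#' still seen against real neighbours); points deviating by more than
#' `threshold_log2` doublings are replaced by log-linear interpolation
#' between the surrounding unspiked points (nearest unspiked value at the
#' ends). Unlike a plain rolling median ([despike_median()]), this leaves
#' clean stretches of an exponential ramp bit-identical, so downstream
#' slope estimation is not perturbed by filter artefacts.
#'
#' @param x Positive numeric series (cell counts).
#' @param window Odd detection window width (default 5).
#' @param threshold_log2 Deviation (doublings) above which a point counts as
#'   a spike (default 0.5).
#' @return A list: `series` (despiked values) and `spike_mask` (logical).
#' @examples
#' x <- 5e4 * 2^(seq(0, 6, length.out = 30)); x[10] <- x[10] * 6
#' remove_spikes(x)$spike_mask[10]
#' @export
remove_spikes <- function(x, window = 5, threshold_log2 = 0.5) {
  n <- length(x)
  if (window %% 2 != 1 || window < 3 || window > n) {
    ea_abort("`window` must be odd, >= 3 and <= the series length.", "parameter_error")
  }
  if (any(x <= 0)) ea_abort("`x` must be positive.", "parameter_error")
  half <- (window - 1L) %/% 2L
  ref <- as.numeric(runmed(x, window, endrule = "keep"))
  for (i in seq_len(half)) {  # full-width shifted windows at the boundaries
    ref[i] <- median(x[1:window])
    ref[n - i + 1L] <- median(x[(n - window + 1L):n])
  }
  mask <- abs(log2(x / ref)) > threshold_log2
  y <- x
  if (any(mask) && !all(mask)) {
    idx <- which(!mask)
    y[mask] <- 2^stats::approx(idx, log2(x[idx]), xout = which(mask),
                               rule = 2)$y
  }
  list(series = y, spike_mask = mask)
}

#' Smooth a series with a truncated Gaussian kernel
#'
#' Discrete Gaussian convolution with the kernel truncated at +/- 4 sigma and
#' renormalized where it overhangs the series boundaries. The operation is a
#' pure vector filter; the curve-processing pipeline applies it to
#' log2-transformed cell counts so that exponential growth stays linear.
#'
#' @param x Numeric series.
#' @param sigma Kernel standard deviation in sample points (> 0).
#' @return Numeric series of the same length.
#' @examples
#' smooth_gaussian(c(1, 1, 10, 1, 1), sigma = 1)
#' @export
smooth_gaussian <- function(x, sigma = 1.5) {
  if (!is.numeric(sigma) || sigma <= 0) {
    ea_abort("`sigma` must be positive.", "parameter_error")
  }
  n <- length(x)
  L <- ceiling(4 * sigma)
  k <- exp(-((-L:L)^2) / (2 * sigma^2))
  k <- k / sum(k)
  xpad <- c(rep(0, L), x, rep(0, L))
  wpad <- c(rep(0, L), rep(1, n), rep(0, L))
  num <- stats::filter(xpad, k, sides = 2)
  den <- stats::filter(wpad, k, sides = 2)
  as.numeric(num[(L + 1):(L + n)] / den[(L + 1):(L + n)])
}

#' Estimate the maximum specific growth rate from a growth curve
#'
#' Slides a window of `window` consecutive time points along the (smoothed)
#' curve and fits ordinary least squares of log2(cells) on time in each
#' window; the maximum slope is the maximum specific growth rate mu_max in
#' doublings per hour, converted to a doubling time D = 1/mu_max. Ties are
#' broken by the earliest window.
#'
#' @param time_h Strictly increasing time points (hours).
#' @param cells Positive cell counts (same length), typically despiked and
#'   Gaussian-smoothed beforehand.
#' @param window Number of consecutive points per regression window
#'   (default 5).
#' @return A one-row tibble: `mu_max` (doublings/h), `D_h` (hours, `NA` when
#'   no window has positive slope), `window_start` (1-based index of the
#'   steepest window), `qc_status` (`"ok"` or `"no_growth"`).
#' @examples
#' t <- seq(0, 24, by = 1 / 3)
#' estimate_mu_max(t, 5e4 * 2^(t / 2))  # D = 2 h
#' @export
estimate_mu_max <- function(time_h, cells, window = 5) {
  n <- length(time_h)
  stopifnot(length(cells) == n)
  if (window < 2 || window > n) {
    ea_abort("`window` must be between 2 and the number of points.", "parameter_error")
  }
  if (any(diff(time_h) <= 0)) {
    ea_abort("`time_h` must be strictly increasing.", "parameter_error")
  }
  if (any(cells <= 0)) ea_abort("`cells` must be positive.", "parameter_error")
  y <- log2(cells)
  # vectorised per-window OLS slopes: embed() reverses within rows, which is
  # irrelevant for slope computation
  Tm <- stats::embed(time_h, window)
  Ym <- stats::embed(y, window)
  tc <- Tm - rowMeans(Tm)
  yc <- Ym - rowMeans(Ym)
  slopes <- rowSums(tc * yc) / rowSums(tc * tc)
  mx <- max(slopes)
  # earliest window wins ties (within floating-point jitter)
  best <- which(slopes >= mx - 1e-9 * max(abs(mx), 1))[1]
  mu <- slopes[best]
  if (!is.finite(mu) || mu <= 0) {
    return(tibble(mu_max = mu, D_h = NA_real_, window_start = NA_integer_,
                  qc_status = "no_growth"))
  }
  tibble(mu_max = mu, D_h = 1 / mu, window_start = as.integer(best),
         qc_status = "ok")
}

#' Count population doublings in a cycle
#'
#' Generations G = log2(last / first) over the despiked series endpoints.
#' The despiked (but not Gaussian-smoothed) series is used so that an
#' endpoint spike cannot inflate G.
#'
#' @param cells Positive cell counts, already despiked.
#' @return G in doublings; `NA` with a warning condition if either endpoint
#'   is non-positive.
#' @examples
#' count_generations(c(5e4, 1e5, 3.2e6))  # 6 doublings
#' @export
count_generations <- function(cells) {
  first <- cells[1]
  last <- cells[length(cells)]
  if (!is.finite(first) || !is.finite(last) || first <= 0 || last <= 0) {
    warn("non-positive curve endpoints; generations undefined",
         class = "evoadapt_qc_flag")
    return(NA_real_)
  }
  log2(last / first)
}

#' Quality-control a growth curve
#'
#' Deterministic screening of a raw curve before parameter extraction:
#' * fewer than `min_points` points, or any non-positive count -> `"excluded"`;
#' * dynamic range below `min_doublings` population doublings (after
#'   despiking) -> `"no_growth"`;
#' * despiked endpoints decreasing by more than `endpoint_tol` doublings, or
#'   more than `max_spike_fraction` of points displaced by the median filter
#'   by over `spike_log2_threshold` doublings -> `"flagged"`;
#' * otherwise `"ok"`.
#'
#' The thresholds are package choices (exposed here) — screening criteria of
#' this kind are platform-internal in colony phenomics pipelines.
#'
#' @param time_h,cells The raw curve.
#' @param min_points Minimum usable length (default 10).
#' @param min_doublings Minimum dynamic range in doublings (default 1).
#' @param max_spike_fraction Maximum tolerated fraction of spiked points
#'   (default 0.2).
#' @param spike_log2_threshold Displacement (doublings) above which a point
#'   counts as spiked (default 0.5).
#' @param endpoint_tol Tolerated endpoint decrease in doublings (default 0.2).
#' @param median_window Despiking window used for the checks.
#' @return One of `"ok"`, `"flagged"`, `"excluded"`, `"no_growth"`.
#' @examples
#' t <- seq(0, 72, by = 1 / 3)
#' qc_curve(t, rep(5e4, length(t)))  # flat: no growth
#' @export
qc_curve <- function(time_h, cells, min_points = 10, min_doublings = 1,
                     max_spike_fraction = 0.2, spike_log2_threshold = 0.5,
                     endpoint_tol = 0.2, median_window = 5) {
  n <- length(cells)
  if (n < min_points || any(!is.finite(cells)) || any(cells <= 0)) {
    return("excluded")
  }
  w <- min(median_window, n - (1 - n %% 2))
  sp <- remove_spikes(cells, w, spike_log2_threshold)
  ds <- sp$series
  if (log2(max(ds) / min(ds)) < min_doublings) return("no_growth")
  if (mean(sp$spike_mask) > max_spike_fraction) return("flagged")
  if (log2(ds[n] / ds[1]) < -endpoint_tol) return("flagged")
  "ok"
}

#' Extract per-cycle growth parameters from a long curve table
#'
#' The full curve-processing chain for every colony x cycle: QC screening,
#' median-filter spike excision ([remove_spikes()]), Gaussian smoothing of
#' log2 counts, sliding-window mu_max estimation, and generation counting on
#' the despiked (but not Gaussian-smoothed) series.
#'
#' @param curves Long tibble with columns `plate_id`, `row`, `col`, `cycle`,
#'   `time_h`, `cells` (as written by [write_experiment()] or read by
#'   [read_curve_table()]).
#' @param median_window Despiking window (odd, default 5 points).
#' @param gaussian_sd Gaussian kernel sd in points (default 1.5).
#' @param fit_window Regression window for mu_max (default 5 points).
#' @return A tibble with one row per colony x cycle: position/cycle keys,
#'   `mu_max`, `D_h`, `generations`, `window_start`, `qc_status`.
#' @examples
#' cfg <- sim_config(n_strains = 2, replicates_per_strain = 1, n_cycles = 1,
#'                   plate_dim = c(4, 4), seed = 9)
#' ex <- simulate_experiment(cfg)
#' analyze_growth_curves(ex$curves)
#' @export
analyze_growth_curves <- function(curves, median_window = 5, gaussian_sd = 1.5,
                                  fit_window = 5) {
  required <- c("plate_id", "row", "col", "cycle", "time_h", "cells")
  if (!all(required %in% names(curves))) {
    ea_abort(paste("curve table must have columns:", paste(required, collapse = ", ")),
             "schema_error")
  }
  curves |>
    group_by(.data$plate_id, .data$row, .data$col, .data$cycle) |>
    arrange(.data$time_h, .by_group = TRUE) |>
    group_modify(function(df, key) {
      analyze_one_curve(df$time_h, df$cells, median_window, gaussian_sd, fit_window)
    }) |>
    ungroup()
}

analyze_one_curve <- function(time_h, cells, median_window, gaussian_sd,
                              fit_window) {
  status <- qc_curve(time_h, cells, median_window = median_window)
  if (status %in% c("excluded", "no_growth")) {
    return(tibble(mu_max = NA_real_, D_h = NA_real_, generations = NA_real_,
                  window_start = NA_integer_, qc_status = status))
  }
  ds <- remove_spikes(cells, median_window)$series
  sm <- 2^smooth_gaussian(log2(ds), gaussian_sd)
  est <- estimate_mu_max(time_h, sm, fit_window)
  g <- count_generations(ds)
  tibble(mu_max = est$mu_max, D_h = est$D_h, generations = g,
         window_start = est$window_start,
         qc_status = if (est$qc_status == "no_growth") "no_growth" else status)
}
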