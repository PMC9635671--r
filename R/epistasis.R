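#' Stress-specific resistance deficit of a strain
#'
#' The stress-specific component of a strain's growth defect: the doubling
#' time under stress minus the doubling time in basal medium, in hours.
#' Larger values mean more sensitivity to the stressor. Comparing the two
#' media as a difference isolates the stress response from the strain's
#' general growth rate.
#'
#' @param d_basal_h,d_stress_h Positive doubling times (hours); vectorized.
#' @param mode `"difference"` (default, hours) or `"ratio"`
#'   (dimensionless `d_stress / d_basal`), exposed for sensitivity checks.
#' @return Numeric vector of resistance deficits.
#' @examples
#' stress_specific_resistance(2.27, 3.61)  # 1.34 h
#' @export
stress_specific_resistance <- function(d_basal_h, d_stress_h,
                                       mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  bad <- !is.finite(d_basal_h) | !is.finite(d_stress_h) |
    d_basal_h <= 0 | d_stress_h <= 0
  if (any(bad)) {
    ea_abort("doubling times must be positive and finite; exclude incomplete records upstream.",
             "input_error")
  }
  if (mode == "ratio") d_stress_h / d_basal_h else d_stress_h - d_basal_h
}

#' Stress-specific effect of a reconstructed mutation
#'
#' For matched background / reconstructed-strain pairs, the mutation's
#' stress-specific benefit is the reduction it causes in the resistance
#' deficit:
#' `delta = (D_stress_bg - D_basal_bg) - (D_stress_mut - D_basal_mut)`
#' in hours. Any basal-growth cost of the mutation enters both stress and
#' basal measurements of the reconstructed strain and cancels exactly, so
#' delta isolates the stress-specific benefit. Pairs whose mutation class
#' is structurally inaccessible in the background (e.g. deleting a gene the
#' background already lacks) are marked inapplicable and get `NA` effects.
#'
#' @param pairs Tibble with one row per background x mutation class:
#'   `background_id`, `class`, `D_basal_bg`, `D_stress_bg`, `D_basal_mut`,
#'   `D_stress_mut`, and optionally `applicable` (logical, default `TRUE`).
#' @param mode Passed to [stress_specific_resistance()].
#' @return The input with added columns `resistance_bg`, `resistance_mut`,
#'   `delta_h` (`NA` where inapplicable).
#' @examples
#' pairs <- tibble::tibble(background_id = "bg1", class = "fps1_loss",
#'                         D_basal_bg = 2.27, D_stress_bg = 5.27,
#'                         D_basal_mut = 2.47, D_stress_mut = 2.77)
#' mutation_effects(pairs)$delta_h  # 2.7 h
#' @export
mutation_effects <- function(pairs, mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  required <- c("background_id", "class", "D_basal_bg", "D_stress_bg",
                "D_basal_mut", "D_stress_mut")
  if (!all(required %in% names(pairs))) {
    ea_abort(paste("pairs need columns:", paste(required, collapse = ", ")),
             "schema_error")
  }
  if (!"applicable" %in% names(pairs)) pairs$applicable <- TRUE
  complete <- complete.cases(pairs[, required[3:6]])
  if (any(!complete)) {
    inform(sprintf("%d pair(s) with missing measurements excluded.", sum(!complete)))
  }
  pairs |>
    filter(complete) |>
    mutate(
      resistance_bg = stress_specific_resistance(.data$D_basal_bg,
                                                 .data$D_stress_bg, mode),
      resistance_mut = stress_specific_resistance(.data$D_basal_mut,
                                                  .data$D_stress_mut, mode),
      delta_h = ifelse(.data$applicable,
                       .data$resistance_bg - .data$resistance_mut, NA_real_)
    )
}

#' Fit the diminishing-return relationship for one mutation class
#'
#' OLS of the mutation's stress-specific benefit on the background strain's
#' doubling time under stress. Under diminishing-return (global) epistasis
#' the slope is positive — the mutation helps sensitive backgrounds more —
#' and, when benefits are generated as a fixed fraction phi of each
#' background's stress deficit, the slope estimates phi. The regression on
#' the background *deficit* (stress minus basal doubling time) is reported
#' alongside; the two predictors differ by the basal doubling-time offset.
#'
#' @param effects Output of [mutation_effects()] for a single class, or a
#'   multi-class table (then `class` must name one).
#' @param class Mutation class to fit when `effects` holds several.
#' @param predictor `"stress_D"` (default) regresses on `D_stress_bg`;
#'   `"deficit"` regresses on `resistance_bg`.
#' @return An object of class `"epistasis_fit"` with `slope`, `intercept`,
#'   `r_squared`, `n`, the underlying `lm`, and [tidy()]/[glance()] methods.
#' @examples
#' eff <- tibble::tibble(background_id = letters[1:5], class = "arr3_dup",
#'                       D_basal_bg = 2.27, D_stress_bg = 2.27 + 1:5,
#'                       D_basal_mut = 2.27,
#'                       D_stress_mut = 2.27 + 0.4 * (1:5)) |>
#'   mutation_effects()
#' glance(fit_diminishing_return(eff))  # slope 0.6, R^2 = 1
#' @export
fit_diminishing_return <- function(effects, class = NULL,
                                   predictor = c("stress_D", "deficit")) {
  predictor <- match.arg(predictor)
  if (!is.null(class)) effects <- effects |> filter(.data$class == !!class)
  cls <- unique(effects$class)
  if (length(cls) != 1) {
    ea_abort("`effects` must contain exactly one mutation class (use `class = `).",
             "parameter_error")
  }
  df <- effects |> filter(is.finite(.data$delta_h))
  if (nrow(df) < 3) {
    ea_abort("at least 3 applicable records are required.", "parameter_error")
  }
  x <- if (predictor == "stress_D") df$D_stress_bg else df$resistance_bg
  if (sd(x) == 0) {
    ea_abort("all backgrounds have identical predictor values; fit undefined.",
             "parameter_error")
  }
  fit <- lm(df$delta_h ~ x)
  structure(
    list(lm = fit, class = cls, predictor = predictor,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = quiet_summary(fit)$r.squared, n = nrow(df), data = df),
    class = "epistasis_fit"
  )
}

#' @export
print.epistasis_fit <- function(x, ...) {
  cat(sprintf("<epistasis_fit> %s: benefit ~ background %s, slope %.3f, R^2 %.3f (n = %d)\n",
              x$class, x$predictor, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_diminishing_return
#' @param x An `"epistasis_fit"`.
#' @param ... Unused.
#' @method tidy epistasis_fit
#' @export
tidy.epistasis_fit <- function(x, ...) {
  s <- quiet_summary(x$lm)$coefficients
  tibble(term = c("(Intercept)", x$predictor), estimate = s[, 1],
         std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_diminishing_return
#' @method glance epistasis_fit
#' @export
glance.epistasis_fit <- function(x, ...) {
  tibble(class = x$class, slope = x$slope, intercept = x$intercept,
         r.squared = x$r_squared, n = x$n, predictor = x$predictor)
}

#' Simulate a reconstructed-mutation panel
#'
#' Generates matched background / reconstruction doubling-time measurements
#' for a panel of backgrounds into which one mutation class is introduced:
#' backgrounds carry uniformly drawn stress deficits, the reconstruction
#' removes fraction `phi` of each background's deficit, adds a random basal
#' growth cost, and every measured doubling time gets additive measurement
#' noise.
#'
#' @param n_backgrounds Number of backgrounds.
#' @param phi Rescue fraction of the reconstructed class.
#' @param class Class label carried through to the output.
#' @param basal_D_h Basal doubling time of all backgrounds (hours).
#' @param deficit_range_h Uniform range of background stress deficits.
#' @param basal_cost_range_h Uniform range of the mutation's basal growth
#'   cost (hours).
#' @param noise_sd_h Additive measurement noise sd on each doubling time.
#' @param seed Integer seed.
#' @return A tibble in [mutation_effects()] input format with extra
#'   ground-truth columns `true_deficit_h` and `true_delta_h`.
#' @examples
#' panel <- simulate_reconstruction_panel(10, phi = 0.9, seed = 1)
#' fit_diminishing_return(mutation_effects(panel))
#' @export
simulate_reconstruction_panel <- function(n_backgrounds = 140, phi = 0.6,
                                          class = "arr3_dup",
                                          basal_D_h = 2.27,
                                          deficit_range_h = c(0.5, 4),
                                          basal_cost_range_h = c(0, 0.3),
                                          noise_sd_h = 0.15, seed = 1) {
  set.seed(seed)
  deficit <- runif(n_backgrounds, deficit_range_h[1], deficit_range_h[2])
  cost <- runif(n_backgrounds, basal_cost_range_h[1], basal_cost_range_h[2])
  noise <- function() rnorm(n_backgrounds, 0, noise_sd_h)
  tibble(
    background_id = sprintf("bg_%03d", seq_len(n_backgrounds)),
    class = class,
    true_deficit_h = deficit,
    true_delta_h = phi * deficit,
    D_basal_bg = basal_D_h + noise(),
    D_stress_bg = basal_D_h + deficit + noise(),
    D_basal_mut = basal_D_h + cost + noise(),
    D_stress_mut = basal_D_h + cost + (1 - phi) * deficit + noise()
  )
}
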