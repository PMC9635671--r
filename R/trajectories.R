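#' Assemble per-population adaptation trajectories
#'
#' Converts per-cycle records into (cumulative generations, doubling time)
#' points per population. Cumulative generations are the running sum of
#' every cycle's doublings — including qc-failed cycles, whose generations
#' still elapse even though they contribute no measured point — so a
#' population's cycle-k measurement sits at the total doublings accumulated
#' through cycle k. Generation 0 (the preadaptation state) precedes the
#' first measured point and is reached by the LOESS fit's evaluation.
#'
#' Populations with fewer than `min_points` qc-ok cycles are dropped and
#' reported via the `"dropped"` attribute.
#'
#' @param records Tibble with columns `strain_id`, `replicate`, `cycle`,
#'   `D_h` (use normalized doubling times where available), `generations`,
#'   `qc_status`.
#' @param min_points Minimum usable cycles per population (default 4).
#' @return Tibble (`strain_id`, `replicate`, `cycle`, `cum_generations`,
#'   `D_h`), qc-ok points only, with attribute `dropped` (tibble of excluded
#'   populations and their usable-point counts).
#' @examples
#' rec <- tibble::tibble(strain_id = "s", replicate = 1, cycle = 1:6,
#'                       D_h = 4 - 0.2 * (1:6), generations = 5.5,
#'                       qc_status = "ok")
#' assemble_trajectories(rec)
#' @export
assemble_trajectories <- function(records, min_points = 4) {
  required <- c("strain_id", "replicate", "cycle", "D_h", "generations", "qc_status")
  if (!all(required %in% names(records))) {
    ea_abort(paste("records need columns:", paste(required, collapse = ", ")),
             "schema_error")
  }
  d_col <- if ("D_norm_h" %in% names(records)) "D_norm_h" else "D_h"
  pts <- records |>
    arrange(.data$strain_id, .data$replicate, .data$cycle) |>
    group_by(.data$strain_id, .data$replicate) |>
    mutate(
      g_filled = ifelse(is.finite(.data$generations), .data$generations, 0),
      cum_generations = cumsum(.data$g_filled)
    ) |>
    ungroup() |>
    filter(.data$qc_status == "ok", is.finite(.data[[d_col]])) |>
    transmute(.data$strain_id, .data$replicate, .data$cycle,
              .data$cum_generations, D_h = .data[[d_col]])
  counts <- pts |> count(.data$strain_id, .data$replicate, name = "n_points")
  dropped <- counts |> filter(.data$n_points < min_points)
  all_pops <- records |> distinct(.data$strain_id, .data$replicate)
  never <- all_pops |>
    anti_join(counts, by = c("strain_id", "replicate")) |>
    mutate(n_points = 0L)
  dropped <- bind_rows(dropped, never)
  if (nrow(dropped) > 0) {
    inform(sprintf("%d population(s) excluded with fewer than %d usable cycles.",
                   nrow(dropped), min_points))
  }
  keep <- counts |> filter(.data$n_points >= min_points)
  out <- pts |> semi_join(keep, by = c("strain_id", "replicate"))
  attr(out, "dropped") <- dropped
  out
}

#' Fit a LOESS adaptation curve to one trajectory
#'
#' Tricube-weighted local polynomial regression of doubling time on
#' cumulative generations, evaluated with the exact ("direct") surface so
#' fits are deterministic and evaluable anywhere on the trajectory's
#' support. The symmetric (redescending biweight) family with 2 robustness
#' iterations damps residual outlier cycles.
#'
#' @param cum_generations,D_h Trajectory points.
#' @param span LOESS span as a fraction of points (default 0.4).
#' @param degree Local polynomial degree (default 2; degree 1 underfits the
#'   sharp early phase of saturating adaptation curves).
#' @param iterations Robustness iterations (default 2).
#' @return A `loess` fit object carrying `support` (range of generations).
#' @examples
#' g <- seq(0, 100, length.out = 19)
#' fit <- fit_adaptation_loess(g, 2.3 + 1.3 * exp(-g / 20))
#' predict(fit, data.frame(cum_generations = 50))
#' @export
fit_adaptation_loess <- function(cum_generations, D_h, span = 0.4, degree = 2,
                                 iterations = 2) {
  n <- length(cum_generations)
  if (n < 4) ea_abort("LOESS fitting needs at least 4 points.", "parameter_error")
  if (span <= 0 || round(span * n) < 2) {
    ea_abort("`span` too small for the number of points and degree.", "parameter_error")
  }
  # short trajectories: widen the neighbourhood so each local fit keeps more
  # points than parameters, and drop to local-linear below 7 points
  if (n < 7) degree <- min(degree, 1)
  span <- max(span, min(1, (degree + 3) / n))
  df <- data.frame(cum_generations = cum_generations, D_h = D_h)
  # loess emits conditioning chatter on degenerate (e.g. constant) inputs
  # that it handles correctly via the pseudoinverse; silence only that
  fit <- withCallingHandlers(
    loess(D_h ~ cum_generations, data = df, span = span, degree = degree,
          family = "symmetric",
          control = loess.control(surface = "direct",
                                  iterations = iterations)),
    warning = function(w) {
      if (grepl("pseudoinverse|reciprocal condition|neighborhood radius|singularities",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  attr(fit, "support") <- range(cum_generations)
  fit
}

#' Extract preadaptation fitness and adaptation milestones from a fit
#'
#' Preadaptation doubling time is the LOESS fit evaluated at generation 0,
#' clamped to the fit's support: when the first measured point sits after
#' generation 0 (as in real trajectories, where the first measurement closes
#' cycle 1) the fit is read at its first point rather than extrapolated —
#' local-polynomial extrapolation beyond the support inflates boundary bias.
#' The adaptation milestone A_g is the doubling-time *reduction* achieved by
#' generation g, `fit(0) - fit(g)` in hours (positive = faster growth).
#' Milestones beyond the trajectory's support are `NA` (undefined, not
#' zero).
#'
#' @param fit A fit from [fit_adaptation_loess()].
#' @param milestones Generations at which to read adaptation
#'   (default 25, 50, 75).
#' @return One-row tibble: `preadaptation_D_h`, one `A<g>` column per
#'   milestone, `max_generations`.
#' @examples
#' g <- seq(0, 100, length.out = 19)
#' fit <- fit_adaptation_loess(g, rep(3, 19))
#' extract_milestones(fit)  # all zero
#' @export
extract_milestones <- function(fit, milestones = c(25, 50, 75)) {
  if (any(milestones <= 0) || is.unsorted(milestones, strictly = TRUE)) {
    ea_abort("`milestones` must be positive and strictly increasing.", "parameter_error")
  }
  support <- attr(fit, "support")
  quiet_predict <- function(g) {
    withCallingHandlers(
      as.numeric(predict(fit, data.frame(cum_generations = g))),
      warning = function(w) {
        if (grepl("pseudoinverse|reciprocal condition|neighborhood radius|singularities",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  g0 <- max(0, support[1])
  d0 <- quiet_predict(g0)
  vals <- vapply(milestones, function(g) {
    if (g > support[2]) return(NA_real_)
    d0 - quiet_predict(g)
  }, numeric(1))
  out <- tibble(preadaptation_D_h = d0)
  for (i in seq_along(milestones)) out[[paste0("A", milestones[i])]] <- vals[i]
  out$max_generations <- support[2]
  out
}

#' Fit trajectories and extract milestones for every population
#'
#' Maps [fit_adaptation_loess()] + [extract_milestones()] over all
#' populations of an assembled trajectory table.
#'
#' @param trajectories Output of [assemble_trajectories()].
#' @param milestones Generations at which to read adaptation.
#' @param span,degree,iterations LOESS parameters, see
#'   [fit_adaptation_loess()].
#' @param preadaptation `"fit0"` (default) evaluates the LOESS fit at
#'   generation 0; `"first_cycle"` uses the first measured cycle's doubling
#'   time instead.
#' @return Tibble with one row per population: `strain_id`, `replicate`,
#'   `preadaptation_D_h`, milestone columns (`A25`, ...), `max_generations`,
#'   `n_points`.
#' @examples
#' rec <- tibble::tibble(strain_id = "s", replicate = 1, cycle = 1:10,
#'                       D_h = 3 + 2 * exp(-(1:10) / 3), generations = 5.5,
#'                       qc_status = "ok")
#' milestone_table(assemble_trajectories(rec))
#' @export
milestone_table <- function(trajectories, milestones = c(25, 50, 75),
                            span = 0.4, degree = 2, iterations = 2,
                            preadaptation = c("fit0", "first_cycle")) {
  preadaptation <- match.arg(preadaptation)
  trajectories |>
    group_by(.data$strain_id, .data$replicate) |>
    group_modify(function(df, key) {
      fit <- fit_adaptation_loess(df$cum_generations, df$D_h, span = span,
                                  degree = degree, iterations = iterations)
      ms <- extract_milestones(fit, milestones)
      if (preadaptation == "first_cycle") {
        first_d <- df$D_h[which.min(df$cum_generations)]
        shift <- first_d - ms$preadaptation_D_h
        ms$preadaptation_D_h <- first_d
        for (nm in paste0("A", milestones)) ms[[nm]] <- ms[[nm]] + shift
      }
      ms$n_points <- nrow(df)
      ms
    }) |>
    ungroup()
}
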