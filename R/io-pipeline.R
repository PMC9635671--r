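#' Read and validate a long-format growth-curve table
#'
#' The canonical curve table is a CSV with columns `plate_id`, `row`, `col`
#' (0-based), `cycle` (1-based; 0 reserved for the stress-free preculture
#' measurement), `time_h`, `cells`. Validation rejects missing columns,
#' reports malformed rows with their line numbers, rejects duplicated
#' (plate, row, col, cycle, time) keys, and requires strictly increasing
#' times within each colony x cycle.
#'
#' @param path CSV file path.
#' @return A tibble of curves, sorted by position, cycle and time.
#' @export
read_curve_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("plate_id", "row", "col", "cycle", "time_h", "cells")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ea_abort(paste("curve table missing column(s):", paste(missing, collapse = ", ")),
             "schema_error")
  }
  bad <- which(!is.finite(df$time_h) | !is.finite(df$cells) | df$cells <= 0 |
                 is.na(df$plate_id))
  if (length(bad) > 0) {
    ea_abort(sprintf("malformed curve rows (non-finite or non-positive values) at data line(s): %s",
                     paste(head(bad, 10), collapse = ", ")),
             "record_error")
  }
  key <- paste(df$plate_id, df$row, df$col, df$cycle, df$time_h, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    ea_abort(sprintf("duplicated (plate, row, col, cycle, time) row(s) at data line(s): %s",
                     paste(head(dup, 10), collapse = ", ")),
             "record_error")
  }
  df <- df |> arrange(.data$plate_id, .data$row, .data$col, .data$cycle, .data$time_h)
  nondec <- df |>
    group_by(.data$plate_id, .data$row, .data$col, .data$cycle) |>
    summarise(ok = all(diff(.data$time_h) > 0), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(nondec) > 0) {
    ea_abort(paste("non-increasing times within colony:",
                   paste(sprintf("%s(%d,%d) cycle %d", nondec$plate_id,
                                 nondec$row, nondec$col, nondec$cycle),
                         collapse = "; ")),
             "record_error")
  }
  df
}

#' Read and validate a plate-layout table
#'
#' CSV with columns `plate_id`, `row`, `col` (0-based), `role`
#' (strain/reference/empty), `strain_id`, `replicate`.
#'
#' @param path CSV file path.
#' @return A layout tibble.
#' @export
read_layout_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("plate_id", "row", "col", "role", "strain_id", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ea_abort(paste("layout table missing column(s):", paste(missing, collapse = ", ")),
             "schema_error")
  }
  if (!all(df$role %in% c("strain", "reference", "empty"))) {
    ea_abort("layout `role` must be one of strain, reference, empty.", "record_error")
  }
  df
}

#' Run the full adaptation-analysis pipeline
#'
#' Orchestrates every stage on a curve table and layout: growth-parameter
#' extraction per colony x cycle, per-(plate, cycle) spatial normalization
#' against reference colonies, trajectory assembly, LOESS milestone
#' extraction, strain summaries, fitness-adaptation regression per
#' milestone, FDR outlier screening, and replicate repeatability. A
#' structured log records the record counts surviving every filtering step.
#'
#' @param curves Curve tibble (or path to a curve CSV).
#' @param layout Layout tibble (or path to a layout CSV).
#' @param milestones Adaptation milestones in generations
#'   (default 25, 50, 75).
#' @param q_threshold FDR level for outlier calling (default 0.05).
#' @param median_window,gaussian_sd,fit_window Curve-processing parameters,
#'   see [analyze_growth_curves()].
#' @param span,degree LOESS parameters, see [fit_adaptation_loess()].
#' @param normalize Set `FALSE` to skip spatial normalization (e.g. layouts
#'   without references).
#' @param seed Seed for the repeatability half-split.
#' @return A list of class `"ale_results"`: `cycle_records`, `milestones`,
#'   `strain_summaries`, `regressions` (list per milestone), `outliers`
#'   (list per milestone), `repeatability`, `log` (tibble of stage counts).
#' @export
run_pipeline <- function(curves, layout, milestones = c(25, 50, 75),
                         q_threshold = 0.05, median_window = 5,
                         gaussian_sd = 1.5, fit_window = 5, span = 0.4,
                         degree = 2, normalize = TRUE, seed = 1) {
  if (is.character(curves)) curves <- read_curve_table(curves)
  if (is.character(layout)) layout <- read_layout_table(layout)
  log <- list()
  note <- function(stage, n) log[[length(log) + 1]] <<- tibble(stage = stage, n = n)
  note("curves_read", nrow(distinct(curves, .data$plate_id, .data$row,
                                    .data$col, .data$cycle)))

  records <- analyze_growth_curves(curves, median_window = median_window,
                                   gaussian_sd = gaussian_sd,
                                   fit_window = fit_window)
  note("curves_qc_ok", sum(records$qc_status == "ok"))
  note("curves_qc_excluded", sum(records$qc_status != "ok"))

  if (normalize) {
    surface <- fit_reference_surface(records, layout)
    records <- normalize_plate(records, surface)
  }

  strain_records <- records |>
    inner_join(layout |> filter(.data$role == "strain") |>
                 select("plate_id", "row", "col", "strain_id", "replicate"),
               by = c("plate_id", "row", "col")) |>
    filter(.data$cycle >= 1)
  note("strain_cycle_records", nrow(strain_records))

  traj <- assemble_trajectories(strain_records)
  note("populations_with_trajectory",
       nrow(distinct(traj, .data$strain_id, .data$replicate)))
  note("populations_excluded", nrow(attr(traj, "dropped")))

  ms <- milestone_table(traj, milestones = milestones, span = span,
                        degree = degree)
  summaries <- summarize_strains(ms)
  note("strains_summarized", nrow(summaries))

  ms_cols <- paste0("A", milestones)
  regressions <- list()
  outliers <- list()
  for (mc in ms_cols) {
    ok <- sum(is.finite(summaries[[mc]]))
    if (ok >= 3 && sd(summaries$preadaptation_D_h[is.finite(summaries[[mc]])]) > 0) {
      regressions[[mc]] <- regress_adaptation(summaries, mc)
      outliers[[mc]] <- call_outliers(ms, regressions[[mc]], q_threshold)
    }
  }
  note("strains_tested_for_outliers",
       if (length(outliers) > 0) nrow(outliers[[length(outliers)]]$strains) else 0L)
  repeatability <- purrr::map(
    setNames(names(regressions), names(regressions)),
    ~ replicate_repeatability(ms, .x, seed = seed)
  )

  structure(
    list(cycle_records = records, milestones = ms,
         strain_summaries = summaries, regressions = regressions,
         outliers = outliers, repeatability = repeatability,
         log = bind_rows(log)),
    class = "ale_results"
  )
}

#' @export
print.ale_results <- function(x, ...) {
  cat("<ale_results>\n")
  for (mc in names(x$regressions)) {
    r <- x$regressions[[mc]]
    cat(sprintf("  %s ~ preadaptation D: R^2 %.3f, slope %.3f (n = %d)\n",
                mc, r$r_squared, r$slope, r$n))
  }
  cat("  log:\n")
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("    %-28s %d\n", x$log$stage[i], x$log$n[i]))
  }
  invisible(x)
}

#' Write pipeline results as versioned CSV tables
#'
#' Writes `cycle_records.csv`, `milestones.csv`, `strain_summaries.csv`,
#' `regressions.csv`, `outliers.csv` and `log.csv` into a directory. Each
#' file begins with a `# evoadapt schema 1` comment line; read them back
#' with `readr::read_csv(..., comment = "#")`.
#'
#' @param results An `"ale_results"` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "ale_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_versioned <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines("# evoadapt schema 1", con)
    close(con)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
    path
  }
  reg <- purrr::imap(results$regressions, ~ glance(.x)) |> bind_rows()
  out <- purrr::imap(results$outliers,
                     ~ mutate(.x$strains, milestone = .y)) |> bind_rows()
  paths <- c(
    write_versioned(results$cycle_records, "cycle_records"),
    write_versioned(results$milestones, "milestones"),
    write_versioned(results$strain_summaries, "strain_summaries"),
    write_versioned(reg, "regressions"),
    write_versioned(out, "outliers"),
    write_versioned(results$log, "log")
  )
  invisible(paths)
}
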