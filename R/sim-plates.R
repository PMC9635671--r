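#' Build a plate layout with interleaved reference positions
#'
#' Reserves the (even row, even col) member of every 2x2 position quartet for
#' non-evolving reference colonies (one reference per quartet, i.e. every
#' fourth position), then assigns strain x replicate populations to the
#' remaining positions, spilling onto additional plates as needed. Rows and
#' columns are 0-based.
#'
#' @param strains Character vector of strain ids.
#' @param replicates Replicates per strain.
#' @param plate_dim Length-2 integer, rows x columns per plate (must be even).
#' @return A tibble (`plate_id`, `row`, `col`, `role`, `strain_id`,
#'   `replicate`) with `role` in `"strain"`, `"reference"`, `"empty"`.
#' @examples
#' layout <- make_plate_layout(c("a", "b"), replicates = 3, plate_dim = c(4, 4))
#' table(layout$role)
#' @export
make_plate_layout <- function(strains, replicates, plate_dim = c(16L, 24L)) {
  nr <- plate_dim[1]; nc <- plate_dim[2]
  if (nr %% 2 != 0 || nc %% 2 != 0) {
    ea_abort("plate dimensions must be even to host 2x2 reference quartets.",
             "layout_error")
  }
  pops <- tidyr::expand_grid(strain_id = strains, replicate = seq_len(replicates))
  slots_per_plate <- nr * nc * 3L / 4L
  n_plates <- max(1, ceiling(nrow(pops) / slots_per_plate))
  grid <- tidyr::expand_grid(plate_id = sprintf("plate_%02d", seq_len(n_plates)),
                             row = 0:(nr - 1), col = 0:(nc - 1))
  grid$role <- ifelse(grid$row %% 2 == 0 & grid$col %% 2 == 0, "reference", "empty")
  open <- which(grid$role == "empty")
  if (nrow(pops) > length(open)) {
    ea_abort(sprintf("layout capacity exceeded: %d populations, %d non-reference positions.",
                     nrow(pops), length(open)), "layout_error")
  }
  grid$strain_id <- NA_character_
  grid$replicate <- NA_integer_
  take <- open[seq_len(nrow(pops))]
  grid$role[take] <- "strain"
  grid$strain_id[take] <- pops$strain_id
  grid$replicate[take] <- pops$replicate
  as_tibble(grid)
}

#' Simulate a spatial plate gradient field
#'
#' Environmental variation across a plate is modelled as a smooth additive
#' field on log2 doubling time: a random tilted plane plus a low-frequency
#' sinusoid, scaled so the largest multiplicative distortion equals
#' `amplitude` (0.1 = +/-10% on doubling time).
#'
#' @param plate_dim Length-2 integer, rows x columns.
#' @param amplitude Maximum multiplicative deviation; 0 gives a flat field.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A tibble (`row`, `col`, `offset_log2`).
#' @examples
#' g <- simulate_gradient_field(c(8, 12), amplitude = 0.1, seed = 1)
#' range(2^g$offset_log2)
#' @export
simulate_gradient_field <- function(plate_dim, amplitude = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- plate_dim[1]; nc <- plate_dim[2]
  grid <- tidyr::expand_grid(row = 0:(nr - 1), col = 0:(nc - 1))
  if (amplitude <= 0) {
    grid$offset_log2 <- 0
    return(as_tibble(grid))
  }
  u <- rnorm(2); u <- u / sqrt(sum(u^2))
  phase <- runif(2, 0, 2 * pi)
  wsin <- runif(1, 0.2, 0.5)  # sinusoid share of the field
  x <- grid$row / max(nr - 1, 1) - 0.5
  y <- grid$col / max(nc - 1, 1) - 0.5
  plane <- u[1] * x + u[2] * y
  sine <- sin(2 * pi * x + phase[1]) * sin(2 * pi * y + phase[2])
  field <- (1 - wsin) * plane + wsin * sine
  grid$offset_log2 <- field / max(abs(field)) * log2(1 + amplitude)
  as_tibble(grid)
}

#' Simulate a full serial-transfer experiment on plates
#'
#' Combines the lineage simulator, the plate layout, spatial gradients and
#' the curve-rendering forward model into a complete synthetic experiment:
#' per-position growth curves for every cycle (evolving strain populations
#' and non-evolving reference colonies alike), the plate layout, per-cycle
#' gradient fields, and a ground-truth table of undistorted per-cycle
#' doubling times and adaptations.
#'
#' A fresh gradient field is drawn for every (plate, cycle), reflecting that
#' each cycle is cultivated on a freshly poured plate; reference colonies
#' share the configured doubling time distorted only by the gradient (and
#' curve noise), which is what plate normalization exploits.
#'
#' @param config A [sim_config()].
#' @param render_curves If `FALSE`, skip rendering and return per-position
#'   observed doubling times directly (gradient-distorted, with measurement
#'   noise) in place of curves — useful when the curve-processing stage is
#'   not under study.
#' @return A list of class `"ale_experiment"`: `curves` (long tibble
#'   `plate_id`, `row`, `col`, `cycle`, `time_h`, `cells`; absent when
#'   `render_curves = FALSE`), `measurements` (present when
#'   `render_curves = FALSE`), `layout`, `gradients` (per plate x cycle),
#'   `truth` (per population x cycle true effective D and adaptation),
#'   `strains`, `config`.
#' @examples
#' cfg <- sim_config(n_strains = 3, replicates_per_strain = 2, n_cycles = 2,
#'                   plate_dim = c(4, 6), seed = 5)
#' ex <- simulate_experiment(cfg)
#' dplyr::count(ex$layout, role)
#' @export
simulate_experiment <- function(config, render_curves = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  strains <- build_strain_collection(config)  # seeds the RNG stream
  layout <- make_plate_layout(strains$strain_id, config$replicates_per_strain,
                              config$plate_dim)
  plates <- unique(layout$plate_id)

  gradients <- tidyr::expand_grid(plate_id = plates, cycle = seq_len(config$n_cycles)) |>
    rowwise() |>
    reframe(simulate_gradient_field(config$plate_dim, config$gradient_amplitude),
            plate_id = .data$plate_id, cycle = .data$cycle) |>
    select("plate_id", "cycle", "row", "col", "offset_log2")

  # lineage dynamics per population
  pops <- layout |> filter(.data$role == "strain")
  traj <- vector("list", nrow(pops))
  truth <- vector("list", nrow(pops))
  for (i in seq_len(nrow(pops))) {
    st <- strains[strains$strain_id == pops$strain_id[i], ]
    if (!is.finite(st$stress_deficit_h)) {
      traj[[i]] <- NULL
      truth[[i]] <- tibble(strain_id = st$strain_id, replicate = pops$replicate[i],
                           plate_id = pops$plate_id[i], row = pops$row[i],
                           col = pops$col[i], cycle = seq_len(config$n_cycles),
                           true_D_h = Inf, true_adaptation_h = NA_real_)
      next
    }
    tr <- simulate_serial_transfer(st, config)
    traj[[i]] <- tr
    truth[[i]] <- tibble(
      strain_id = st$strain_id, replicate = pops$replicate[i],
      plate_id = pops$plate_id[i], row = pops$row[i], col = pops$col[i],
      cycle = tr$cycles$cycle, true_D_h = tr$cycles$effective_D_h,
      true_adaptation_h = st$stress_D_h - tr$cycles$effective_D_h
    )
  }
  truth <- bind_rows(truth)

  grad_key <- paste(gradients$plate_id, gradients$cycle, gradients$row,
                    gradients$col, sep = "|")
  grad_lookup <- setNames(gradients$offset_log2, grad_key)
  grad_at <- function(plate, cy, r, c) {
    unname(grad_lookup[paste(plate, cy, r, c, sep = "|")])
  }

  if (!render_curves) {
    meas <- truth |>
      left_join(gradients, by = c("plate_id", "cycle", "row", "col")) |>
      mutate(
        D_obs_h = ifelse(is.finite(.data$true_D_h),
                         pmax(.data$true_D_h * 2^.data$offset_log2 +
                                rnorm(n(), 0, config$d_noise_sd_h), 0.05),
                         NA_real_),
        qc_status = ifelse(is.finite(.data$true_D_h), "ok", "no_growth")
      ) |>
      select("plate_id", "row", "col", "strain_id", "replicate", "cycle",
             "D_obs_h", "qc_status")
    return(structure(list(measurements = meas, layout = layout,
                          gradients = gradients, truth = truth,
                          strains = strains, config = config),
                     class = "ale_experiment"))
  }

  noise <- config$curve_noise
  curves <- vector("list", nrow(layout) * config$n_cycles)
  k <- 0
  for (cy in seq_len(config$n_cycles)) {
    for (j in seq_len(nrow(layout))) {
      pos <- layout[j, ]
      if (pos$role == "empty") next
      off <- grad_at(pos$plate_id, cy, pos$row, pos$col)
      if (pos$role == "reference") {
        state <- tibble(count = config$bottleneck_size,
                        D_h = config$reference_D_h * 2^off)
        cap <- runif(1, config$final_size_range[1], config$final_size_range[2])
      } else {
        idx <- which(pops$plate_id == pos$plate_id & pops$row == pos$row &
                       pops$col == pos$col)
        tr <- traj[[idx]]
        if (is.null(tr)) {  # non-grower: flat noisy curve at bottleneck size
          state <- tibble(count = config$bottleneck_size, D_h = Inf)
          cap <- config$bottleneck_size
        } else {
          bt <- tr$bottlenecks |> filter(.data$cycle == cy)
          state <- tibble(count = bt$count, D_h = bt$D_h * 2^off)
          cap <- tr$cycles$final_size[tr$cycles$cycle == cy]
        }
      }
      cv <- render_growth_curve(state, noise, carrying_capacity = cap)
      k <- k + 1
      curves[[k]] <- tibble(plate_id = pos$plate_id, row = pos$row,
                            col = pos$col, cycle = cy,
                            time_h = cv$time_h, cells = cv$cells,
                            spiked = cv$spiked)
    }
  }
  structure(
    list(curves = bind_rows(curves[seq_len(k)]), layout = layout,
         gradients = gradients, truth = truth, strains = strains,
         config = config),
    class = "ale_experiment"
  )
}

#' @export
print.ale_experiment <- function(x, ...) {
  cat(sprintf("<ale_experiment> %d strains x %d replicates, %d cycles, %d plates\n",
              x$config$n_strains, x$config$replicates_per_strain,
              x$config$n_cycles, length(unique(x$layout$plate_id))))
  invisible(x)
}

#' Write a simulated experiment to CSV files
#'
#' Writes the canonical long-format curve table (`curves.csv`), the plate
#' layout (`layout.csv`) and the ground-truth table (`truth.csv`) into a
#' directory, in the formats [read_curve_table()] and [read_layout_table()]
#' accept.
#'
#' @param experiment An `"ale_experiment"` from [simulate_experiment()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "ale_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(curves = file.path(dir, "curves.csv"),
             layout = file.path(dir, "layout.csv"),
             truth = file.path(dir, "truth.csv"))
  if (!is.null(experiment$curves)) {
    readr::write_csv(experiment$curves |>
                       select("plate_id", "row", "col", "cycle", "time_h", "cells"),
                     paths["curves"])
  }
  readr::write_csv(experiment$layout, paths["layout"])
  readr::write_csv(experiment$truth, paths["truth"])
  invisible(paths)
}
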