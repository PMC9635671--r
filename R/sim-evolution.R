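#' Draw a synthetic strain collection
#'
#' Assigns each strain a basal doubling time, a stress-specific doubling-time
#' deficit drawn uniformly from `config$deficit_range_h`, and the set of
#' mutation classes accessible in its background. A configurable fraction of
#' strains is injected as non-growers (infinite stress deficit) to exercise
#' downstream QC. Strains whose (synthetic) deleted gene matches a class's
#' `blocked_in` label cannot acquire that class.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per strain: `strain_id`, `deleted_gene`,
#'   `basal_D_h`, `stress_deficit_h`, `stress_D_h`, and a list-column
#'   `accessible_classes` of class names.
#' @examples
#' build_strain_collection(sim_config(n_strains = 4, seed = 7))
#' @export
build_strain_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_strains
  deficits <- runif(n, config$deficit_range_h[1], config$deficit_range_h[2])
  # Deleted-gene labels: mostly generic, but sprinkle in genes matching the
  # mutation-class targets so structural inaccessibility is represented.
  genes <- sprintf("YGD%04d", seq_len(n))
  blocked <- config$mutation_classes$blocked_in
  blocked <- blocked[!is.na(blocked)]
  if (length(blocked) > 0 && n >= 20) {
    idx <- seq_len(length(blocked))
    genes[idx] <- blocked  # first few strains carry the blocked deletions
  }
  if (config$nongrower_fraction > 0) {
    n_bad <- round(config$nongrower_fraction * n)
    if (n_bad > 0) {
      bad <- sample.int(n, n_bad)
      deficits[bad] <- Inf
    }
  }
  cls <- config$mutation_classes
  accessible <- lapply(genes, function(g) {
    cls$name[is.na(cls$blocked_in) | cls$blocked_in != g]
  })
  tibble(
    strain_id = sprintf("strain_%04d", seq_len(n)),
    deleted_gene = genes,
    basal_D_h = config$basal_doubling_time_h,
    stress_deficit_h = deficits,
    stress_D_h = config$basal_doubling_time_h + deficits,
    accessible_classes = accessible
  )
}

#' Doubling time of a genotype from its acquired mutation classes
#'
#' Each acquired class removes its rescue fraction phi of the deficit that
#' remains when it is acquired, so the composed doubling time is
#' `basal + deficit * prod(1 - phi)` over the acquired classes — independent
#' of acquisition order and never below the basal floor.
#'
#' @param basal_D_h Basal doubling time (hours).
#' @param deficit_h Ancestral stress-specific deficit (hours).
#' @param phi Numeric vector of rescue fractions of the acquired classes
#'   (possibly empty).
#' @return Doubling time in hours.
#' @examples
#' compose_doubling_time(2.27, 3, 0.9)        # 2.27 + 0.3
#' compose_doubling_time(2.27, 3, c(0.9, 0.6)) # order-invariant
#' @export
compose_doubling_time <- function(basal_D_h, deficit_h, phi = numeric()) {
  basal_D_h + deficit_h * prod(1 - phi)
}

#' Simulate one population through serial-transfer evolution
#'
#' Runs a single evolving colony population through `config$n_cycles` batch
#' cycles. Within a cycle each lineage grows deterministically and
#' exponentially at its own rate (1/D doublings per hour) until the colony
#' total reaches a size drawn uniformly from `config$final_size_range`; new
#' mutant lineages are seeded stochastically in proportion to the divisions
#' each lineage performed (Poisson supply, uniformly placed along the
#' division count); the transfer bottleneck is a multinomial sample of
#' `config$bottleneck_size` cells. Drift therefore acts only at the
#' bottleneck, which is where it matters at these colony sizes.
#'
#' @param strain One row of [build_strain_collection()] output (or a list
#'   with `basal_D_h`, `stress_deficit_h`, `accessible_classes`).
#' @param config A [sim_config()].
#' @param seed Optional integer seed; if `NULL` the current RNG state is used
#'   (so callers can orchestrate a single stream).
#' @return An object of class `"lineage_trajectory"`: a list with
#'   * `cycles` — tibble (`cycle`, `generations`, `effective_D_h`,
#'     `final_size`, `growth_time_h`),
#'   * `lineages` — tibble of per-cycle end-of-growth lineage states
#'     (`cycle`, `genotype`, `frequency`, `D_h`),
#'   * `bottlenecks` — tibble of post-transfer lineage states
#'     (`cycle`, `genotype`, `count`, `D_h`), where `cycle` is the cycle the
#'     sample seeds.
#' @examples
#' cfg <- sim_config(n_strains = 1, seed = 3)
#' st <- build_strain_collection(cfg)
#' traj <- simulate_serial_transfer(st[1, ], cfg, seed = 3)
#' traj$cycles
#' @export
simulate_serial_transfer <- function(strain, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(strain)) strain <- as.list(strain[1, ])
  if (is.list(strain$accessible_classes) && !is.character(strain$accessible_classes)) {
    strain$accessible_classes <- strain$accessible_classes[[1]]
  }
  if (!is.finite(strain$stress_deficit_h)) {
    ea_abort("strain is not viable under stress (infinite deficit); simulate_serial_transfer requires finite D.",
             "sim_error")
  }
  basal <- strain$basal_D_h
  deficit <- strain$stress_deficit_h
  cls <- config$mutation_classes
  cls <- cls[cls$name %in% strain$accessible_classes, , drop = FALSE]

  # lineage state as parallel vectors (hot loop: no data-frame churn);
  # genotype key = sorted acquired class names ("" = ancestor)
  lin_geno <- ""
  lin_count <- config$bottleneck_size
  lin_D <- basal + deficit
  cls_name <- cls$name
  cls_rate <- cls$rate_per_division
  cls_phi <- cls$rescue_fraction

  nc <- config$n_cycles
  cyc_gen <- cyc_deff <- cyc_final <- cyc_t <- numeric(nc)
  lineages <- vector("list", nc)
  bottlenecks <- vector("list", nc)

  for (cy in seq_len(nc)) {
    bottlenecks[[cy]] <- list(cycle = cy, genotype = lin_geno,
                              count = lin_count, D_h = lin_D)
    final_size <- runif(1, config$final_size_range[1], config$final_size_range[2])
    t_end <- solve_growth_time(lin_count, lin_D, final_size)
    grown <- lin_count * 2^(t_end / lin_D)
    divisions <- grown - lin_count

    # mutation supply, proportional to divisions per lineage and class
    mut_geno <- character(); mut_count <- numeric(); mut_D <- numeric()
    if (length(cls_name) > 0) {
      for (i in seq_along(lin_geno)) {
        acquired <- genotype_classes(lin_geno[i])
        open <- which(!(cls_name %in% acquired))
        if (length(open) == 0) next
        n_events <- rpois(length(open), cls_rate[open] * divisions[i])
        for (jj in which(n_events > 0)) {
          j <- open[jj]
          k <- min(n_events[jj], 1000L)  # cap per-lineage events, ample here
          u <- runif(k)
          t_m <- lin_D[i] * log2((lin_count[i] + u * divisions[i]) / lin_count[i])
          new_classes <- sort(c(acquired, cls_name[j]))
          phi <- cls_phi[match(new_classes, cls_name)]
          d_new <- compose_doubling_time(basal, deficit, phi)
          mut_geno <- c(mut_geno, paste(new_classes, collapse = "+"))
          mut_count <- c(mut_count, sum(2^((t_end - t_m) / d_new)))
          mut_D <- c(mut_D, d_new)
        }
      }
    }
    st_geno <- c(lin_geno, mut_geno)
    st_count <- c(grown, mut_count)
    st_D <- c(lin_D, mut_D)
    if (anyDuplicated(st_geno)) {
      agg <- rowsum(st_count, st_geno, reorder = FALSE)
      keep1 <- !duplicated(st_geno)
      st_geno <- st_geno[keep1]
      st_D <- st_D[keep1]
      st_count <- agg[match(st_geno, rownames(agg)), 1]
    }
    # mutant cells are descendants of counted divisions: rescale so the
    # colony total equals the drawn final size exactly
    st_count <- st_count * final_size / sum(st_count)

    generations <- log2(final_size / config$bottleneck_size)
    cyc_gen[cy] <- generations
    cyc_deff[cy] <- t_end / generations
    cyc_final[cy] <- final_size
    cyc_t[cy] <- t_end
    lineages[[cy]] <- list(cycle = cy, genotype = st_geno,
                           frequency = st_count / sum(st_count), D_h = st_D)

    counts <- as.vector(rmultinom(1, size = config$bottleneck_size,
                                  prob = st_count))
    keep <- counts > 0
    lin_geno <- st_geno[keep]
    lin_count <- counts[keep]
    lin_D <- st_D[keep]
  }

  lineage_tbl <- tibble(
    cycle = rep.int(seq_len(nc), vapply(lineages, function(x) length(x$genotype), 0L)),
    genotype = unlist(lapply(lineages, `[[`, "genotype")),
    frequency = unlist(lapply(lineages, `[[`, "frequency")),
    D_h = unlist(lapply(lineages, `[[`, "D_h"))
  )
  bottleneck_tbl <- tibble(
    cycle = rep.int(seq_len(nc), vapply(bottlenecks, function(x) length(x$genotype), 0L)),
    genotype = unlist(lapply(bottlenecks, `[[`, "genotype")),
    count = unlist(lapply(bottlenecks, `[[`, "count")),
    D_h = unlist(lapply(bottlenecks, `[[`, "D_h"))
  )
  structure(
    list(cycles = tibble(cycle = seq_len(nc), generations = cyc_gen,
                         effective_D_h = cyc_deff, final_size = cyc_final,
                         growth_time_h = cyc_t),
         lineages = lineage_tbl, bottlenecks = bottleneck_tbl),
    class = "lineage_trajectory"
  )
}

genotype_classes <- function(genotype) {
  if (identical(genotype, "")) character() else strsplit(genotype, "+", fixed = TRUE)[[1]]
}

# Time at which a mixture of exponentially growing lineages reaches `target`
# total cells. Closed form for one lineage, monotone root otherwise.
solve_growth_time <- function(counts, D, target) {
  if (length(counts) == 1) return(D * log2(target / counts))
  f <- function(t) sum(counts * 2^(t / D)) - target
  upper <- max(D) * log2(target / min(counts))
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' @export
print.lineage_trajectory <- function(x, ...) {
  cat(sprintf("<lineage_trajectory> %d cycles, final D %.3f h\n",
              nrow(x$cycles), tail(x$cycles$effective_D_h, 1)))
  invisible(x)
}

#' @method tidy lineage_trajectory
#' @export
tidy.lineage_trajectory <- function(x, ...) x$cycles

#' Render a noisy population-size growth curve from a lineage state
#'
#' Forward model for the measured colony curves: each lineage expands
#' exponentially from its bottleneck share after a lag, the colony total
#' saturates at a carrying capacity, multiplicative log-normal noise is
#' applied, and isolated spikes are injected with a per-point probability.
#'
#' @param lineage_state Tibble with columns `count` (cells at the bottleneck)
#'   and `D_h` (hours); one row per lineage.
#' @param noise A [curve_noise_config()].
#' @param carrying_capacity Cells at saturation.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A tibble (`time_h`, `cells`, `spiked`), one row per time point.
#' @examples
#' st <- tibble::tibble(count = 5e4, D_h = 2)
#' render_growth_curve(st, curve_noise_config(spike_probability = 0,
#'                                            multiplicative_noise_sd = 0),
#'                     carrying_capacity = 3e6)
#' @export
render_growth_curve <- function(lineage_state, noise = curve_noise_config(),
                                carrying_capacity = 3e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("count", "D_h") %in% names(lineage_state)))
  times <- seq(0, noise$duration_h, by = noise$sampling_interval_h)
  tg <- pmax(0, times - noise$lag_h)
  total <- rowSums(outer(tg, seq_len(nrow(lineage_state)),
                         function(t, i) lineage_state$count[i] * 2^(t / lineage_state$D_h[i])))
  total <- pmin(total, carrying_capacity)
  if (noise$multiplicative_noise_sd > 0) {
    total <- total * exp(rnorm(length(total), 0, noise$multiplicative_noise_sd))
  }
  spiked <- rep(FALSE, length(total))
  if (noise$spike_probability > 0) {
    spiked <- runif(length(total)) < noise$spike_probability
    if (any(spiked)) {
      total[spiked] <- total[spiked] *
        runif(sum(spiked), noise$spike_magnitude_range[1], noise$spike_magnitude_range[2])
    }
  }
  tibble(time_h = times, cells = total, spiked = spiked)
}

#' Simulate a cohort at the doubling-time level
#'
#' Runs the full lineage simulator for every strain x replicate population
#' and reports the per-cycle effective doubling time with additive
#' measurement noise, skipping curve rendering and plate effects. This is
#' the economical generator for statistical studies of the analysis chain
#' (trajectory fitting, fitness-adaptation regression, outlier screening)
#' where the curve-processing stage is validated separately.
#'
#' @param config A [sim_config()].
#' @return A list of class `"ale_cohort"`:
#'   * `measurements` — tibble (`strain_id`, `replicate`, `cycle`,
#'     `D_obs_h`, `generations`, `qc_status`),
#'   * `truth` — the strain collection with per-strain true preadaptation
#'     stress doubling time,
#'   * `population_truth` — tibble of true per-cycle effective doubling
#'     times per population,
#'   * `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_strains = 3, replicates_per_strain = 2,
#'                                   n_cycles = 5, seed = 2))
#' head(coh$measurements)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  strains <- build_strain_collection(config)  # seeds the stream
  meas <- vector("list", nrow(strains) * config$replicates_per_strain)
  truth <- vector("list", length(meas))
  k <- 0
  for (i in seq_len(nrow(strains))) {
    st <- strains[i, ]
    for (r in seq_len(config$replicates_per_strain)) {
      k <- k + 1
      if (!is.finite(st$stress_deficit_h)) {
        meas[[k]] <- tibble(
          strain_id = st$strain_id, replicate = r,
          cycle = seq_len(config$n_cycles),
          D_obs_h = NA_real_, generations = 0,
          qc_status = "no_growth"
        )
        truth[[k]] <- tibble(strain_id = st$strain_id, replicate = r,
                             cycle = seq_len(config$n_cycles),
                             true_D_h = Inf)
        next
      }
      traj <- simulate_serial_transfer(st, config)
      d_obs <- traj$cycles$effective_D_h +
        rnorm(config$n_cycles, 0, config$d_noise_sd_h)
      d_obs <- pmax(d_obs, 0.05)
      meas[[k]] <- tibble(
        strain_id = st$strain_id, replicate = r,
        cycle = traj$cycles$cycle, D_obs_h = d_obs,
        generations = traj$cycles$generations,
        qc_status = "ok"
      )
      truth[[k]] <- tibble(strain_id = st$strain_id, replicate = r,
                           cycle = traj$cycles$cycle,
                           true_D_h = traj$cycles$effective_D_h)
    }
  }
  structure(
    list(measurements = bind_rows(meas), truth = strains,
         population_truth = bind_rows(truth), config = config),
    class = "ale_cohort"
  )
}
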