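#' Simulation configuration for a serial-transfer evolution experiment
#'
#' Bundles every parameter of the synthetic adaptive-laboratory-evolution
#' generator: the strain collection (stress-specific doubling-time deficits),
#' the batch-cycle structure (bottleneck and saturation sizes, number of
#' cycles), the mutation supply (classes with per-division rates and rescue
#' fractions), and the measurement layer (curve rendering noise, plate
#' gradients, doubling-time measurement error).
#'
#' Defaults emulate a yeast deletion-collection arsenite evolution: a basal
#' (unstressed) wild-type doubling time of 2.27 h, stress-specific deficits
#' drawn uniformly from 0.5–4 h, 19 batch cycles each expanding a colony from
#' a ~50,000-cell bottleneck to 2–4 million cells (~5.3–6.3 doublings per
#' cycle), and three beneficial mutation classes whose benefit is a fixed
#' fraction of the *remaining* stress deficit (diminishing-return epistasis
#' by construction).
#'
#' @param n_strains Number of distinct strains (gene deletions) in the
#'   collection.
#' @param replicates_per_strain Number of independently evolving replicate
#'   populations per strain.
#' @param basal_doubling_time_h Wild-type doubling time in hours without
#'   stress; the floor below which no genotype can grow faster.
#' @param deficit_range_h Length-2 numeric: lower/upper bound of the uniform
#'   distribution of stress-specific doubling-time deficits (hours) across
#'   strains. Lower bound must be >= 0.
#' @param n_cycles Number of serial-transfer batch cycles.
#' @param bottleneck_size Cells transferred to seed each cycle.
#' @param final_size_range Length-2 numeric: colony size at the end of a
#'   growth cycle is drawn uniformly from this interval (cells).
#' @param mutation_classes Tibble describing the beneficial mutation classes;
#'   see [mutation_classes()].
#' @param curve_noise Curve rendering noise model; see [curve_noise_config()].
#' @param d_noise_sd_h Additive measurement noise (hours, sd) applied to
#'   per-cycle doubling-time estimates in doubling-time-level simulation
#'   ([simulate_cohort()]).
#' @param gradient_amplitude Maximum multiplicative deviation of the spatial
#'   plate gradient (0.1 = +/-10% on doubling time). 0 disables gradients.
#' @param nongrower_fraction Fraction of strains injected with an infinite
#'   stress deficit (no growth under stress) to exercise QC paths.
#' @param plate_dim Length-2 integer: plate rows and columns for rendered
#'   experiments (e.g. c(16, 24) for 384, c(32, 48) for 1536 positions).
#' @param reference_D_h Doubling time (hours) of the non-evolving reference
#'   colonies under stress, before gradient distortion.
#' @param seed Integer seed controlling all randomness in the generator.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [build_strain_collection()], [simulate_cohort()],
#'   [simulate_experiment()]
#' @examples
#' cfg <- sim_config(n_strains = 10, replicates_per_strain = 3, seed = 1)
#' cfg$n_cycles
#' @export
sim_config <- function(n_strains = 300,
                       replicates_per_strain = 12,
                       basal_doubling_time_h = 2.27,
                       deficit_range_h = c(0.5, 4),
                       n_cycles = 19,
                       bottleneck_size = 5e4,
                       final_size_range = c(2e6, 4e6),
                       mutation_classes = default_mutation_classes(),
                       curve_noise = curve_noise_config(),
                       d_noise_sd_h = 0.15,
                       gradient_amplitude = 0.1,
                       nongrower_fraction = 0,
                       plate_dim = c(16L, 24L),
                       reference_D_h = 3.61,
                       seed = 1L) {
  if (length(deficit_range_h) != 2 || deficit_range_h[1] < 0 ||
      deficit_range_h[2] < deficit_range_h[1]) {
    ea_abort("`deficit_range_h` must be an increasing interval with lower bound >= 0.",
             "config_error")
  }
  if (length(final_size_range) != 2 || final_size_range[2] < final_size_range[1]) {
    ea_abort("`final_size_range` must be an increasing interval.", "config_error")
  }
  if (bottleneck_size >= final_size_range[1]) {
    ea_abort("`bottleneck_size` must be below the minimum final colony size.",
             "config_error")
  }
  if (n_cycles < 1) ea_abort("`n_cycles` must be >= 1.", "config_error")
  if (basal_doubling_time_h <= 0) {
    ea_abort("`basal_doubling_time_h` must be positive.", "config_error")
  }
  if (nongrower_fraction < 0 || nongrower_fraction >= 1) {
    ea_abort("`nongrower_fraction` must be in [0, 1).", "config_error")
  }
  validate_mutation_classes(mutation_classes)
  structure(
    list(
      n_strains = as.integer(n_strains),
      replicates_per_strain = as.integer(replicates_per_strain),
      basal_doubling_time_h = basal_doubling_time_h,
      deficit_range_h = deficit_range_h,
      n_cycles = as.integer(n_cycles),
      bottleneck_size = bottleneck_size,
      final_size_range = final_size_range,
      mutation_classes = mutation_classes,
      curve_noise = curve_noise,
      d_noise_sd_h = d_noise_sd_h,
      gradient_amplitude = gradient_amplitude,
      nongrower_fraction = nongrower_fraction,
      plate_dim = as.integer(plate_dim),
      reference_D_h = reference_D_h,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Beneficial mutation classes
#'
#' A mutation class is an abstract adaptive solution (no sequence-level
#' representation): acquiring it removes a fixed fraction `rescue_fraction`
#' (phi) of the strain's *remaining* stress-specific doubling-time deficit.
#' Because the benefit scales with the remaining deficit, fitter backgrounds
#' gain less in absolute hours — diminishing-return (global) epistasis is
#' built into the generative model, and the empirical benefit-vs-background
#' regression slope estimates phi.
#'
#' `blocked_in` names a deleted gene that makes the class inaccessible in
#' matching backgrounds (a strain already lacking the gene cannot lose it
#' again), modelling structural inaccessibility.
#'
#' @param name Character label per class.
#' @param rate_per_division Probability of the mutation per cell division.
#' @param rescue_fraction Fraction phi in [0, 1] of the remaining deficit
#'   removed on acquisition.
#' @param blocked_in Deleted-gene label blocking the class, or `NA`.
#' @return A tibble with one row per class.
#' @examples
#' mutation_classes("arr3_dup", 5e-7, 0.6)
#' default_mutation_classes()
#' @export
mutation_classes <- function(name, rate_per_division, rescue_fraction,
                             blocked_in = NA_character_) {
  cls <- tibble(
    name = as.character(name),
    rate_per_division = rate_per_division,
    rescue_fraction = rescue_fraction,
    blocked_in = as.character(blocked_in)
  )
  validate_mutation_classes(cls)
  cls
}

#' @rdname mutation_classes
#' @details `default_mutation_classes()` returns three classes patterned on
#' the known routes to arsenite resistance in yeast: loss of the importing
#' aquaglyceroporin (fps1-like, phi = 0.9), loss of its regulator (ask10-like,
#' phi = 0.3), and duplication of the exporter (arr3-like, phi = 0.6). The
#' phi values put the simulated mean benefits of the strongest and weakest
#' classes in roughly a 3:1 ratio.
#' @export
default_mutation_classes <- function() {
  mutation_classes(
    name = c("fps1_loss", "ask10_loss", "arr3_dup"),
    rate_per_division = c(1e-6, 1e-6, 5e-7),
    rescue_fraction = c(0.9, 0.3, 0.6),
    blocked_in = c("FPS1", "ASK10", NA)
  )
}

validate_mutation_classes <- function(cls) {
  stopifnot(is.data.frame(cls))
  required <- c("name", "rate_per_division", "rescue_fraction", "blocked_in")
  if (!all(required %in% names(cls))) {
    ea_abort("mutation classes need columns name, rate_per_division, rescue_fraction, blocked_in.",
             "config_error")
  }
  if (any(cls$rate_per_division < 0 | cls$rate_per_division > 1)) {
    ea_abort("`rate_per_division` must lie in [0, 1].", "config_error")
  }
  if (any(cls$rescue_fraction < 0 | cls$rescue_fraction > 1)) {
    ea_abort("`rescue_fraction` must lie in [0, 1].", "config_error")
  }
  if (anyDuplicated(cls$name)) ea_abort("mutation class names must be unique.", "config_error")
  invisible(cls)
}

#' Growth-curve rendering noise model
#'
#' Parameters of the forward model that turns a lineage state into a noisy
#' population-size time series: sampling cadence and duration, a lag before
#' exponential growth, multiplicative log-normal noise, and isolated
#' measurement spikes.
#'
#' @param sampling_interval_h Hours between measurements (default 1/3, i.e.
#'   20 min).
#' @param duration_h Total cultivation time covered by the curve (hours).
#' @param lag_h Lag before exponential growth starts (hours).
#' @param spike_probability Per-point probability of an isolated spike.
#' @param spike_magnitude_range Length-2 numeric: multiplicative spike factor
#'   is drawn uniformly from this interval.
#' @param multiplicative_noise_sd Standard deviation of log-normal
#'   multiplicative noise (natural-log scale).
#' @return A list of class `"curve_noise_config"`.
#' @examples
#' curve_noise_config(spike_probability = 0)
#' @export
curve_noise_config <- function(sampling_interval_h = 1 / 3,
                               duration_h = 72,
                               lag_h = 2,
                               spike_probability = 0.01,
                               spike_magnitude_range = c(3, 8),
                               multiplicative_noise_sd = 0.02) {
  if (sampling_interval_h <= 0) {
    ea_abort("`sampling_interval_h` must be positive.", "config_error")
  }
  if (duration_h < 10 * sampling_interval_h) {
    ea_abort("`duration_h` must cover at least 10 sampling intervals.", "config_error")
  }
  structure(
    list(
      sampling_interval_h = sampling_interval_h,
      duration_h = duration_h,
      lag_h = lag_h,
      spike_probability = spike_probability,
      spike_magnitude_range = spike_magnitude_range,
      multiplicative_noise_sd = multiplicative_noise_sd
    ),
    class = "curve_noise_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  strains: %d x %d replicates, %d cycles\n",
              x$n_strains, x$replicates_per_strain, x$n_cycles))
  cat(sprintf("  basal D: %.2f h; deficits U[%.2f, %.2f] h\n",
              x$basal_doubling_time_h, x$deficit_range_h[1], x$deficit_range_h[2]))
  cat(sprintf("  bottleneck %g -> final %g-%g cells\n",
              x$bottleneck_size, x$final_size_range[1], x$final_size_range[2]))
  cat(sprintf("  mutation classes: %s\n",
              paste(x$mutation_classes$name, collapse = ", ")))
  invisible(x)
}
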