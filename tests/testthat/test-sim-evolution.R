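cfg_small <- function(...) {
  sim_config(n_strains = 3, replicates_per_strain = 2, n_cycles = 5,
             plate_dim = c(4, 6), seed = 101, ...)
}

test_that("strain collection respects the deficit range and the seed", {
  cfg0 <- sim_config(n_strains = 3, deficit_range_h = c(0, 0), seed = 1)
  st0 <- build_strain_collection(cfg0)
  expect_equal(st0$stress_D_h, st0$basal_D_h)

  cfg <- sim_config(n_strains = 200, deficit_range_h = c(0.5, 4), seed = 5)
  expect_identical(build_strain_collection(cfg), build_strain_collection(cfg))

  cfg2 <- sim_config(n_strains = 1000, deficit_range_h = c(0.5, 4), seed = 9)
  st <- build_strain_collection(cfg2)
  # uniform moments: mean 2.25, se = (range width / sqrt(12)) / sqrt(n)
  se <- (4 - 0.5) / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(st$stress_deficit_h) - 2.25), 3 * se)
  expect_error(sim_config(deficit_range_h = c(-1, 2)), class = "evoadapt_config_error")
})

test_that("without mutations doubling time is constant and adaptation zero", {
  cls <- mutation_classes("null", 0, 0.5)
  cfg <- sim_config(n_strains = 1, n_cycles = 19, mutation_classes = cls, seed = 3)
  st <- build_strain_collection(cfg)
  tr <- simulate_serial_transfer(st[1, ], cfg, seed = 3)
  expect_equal(tr$cycles$effective_D_h, rep(st$stress_D_h[1], 19))
})

test_that("a fully rescuing mutation drives D to the basal floor after fixation", {
  cls <- mutation_classes("sweep", 5e-5, 1)  # very high supply: fixation by cycle 2
  cfg <- sim_config(n_strains = 1, n_cycles = 6, mutation_classes = cls,
                    deficit_range_h = c(3, 3), seed = 11)
  st <- build_strain_collection(cfg)
  tr <- simulate_serial_transfer(st[1, ], cfg, seed = 11)
  expect_equal(tail(tr$cycles$effective_D_h, 1), st$basal_D_h[1], tolerance = 1e-3)
})

test_that("partial rescue follows the closed form D = basal + (1 - phi) * deficit", {
  cls <- mutation_classes("phi09", 5e-5, 0.9)
  cfg <- sim_config(n_strains = 1, n_cycles = 8, mutation_classes = cls,
                    deficit_range_h = c(3, 3), seed = 13)
  st <- build_strain_collection(cfg)
  tr <- simulate_serial_transfer(st[1, ], cfg, seed = 13)
  expect_equal(tail(tr$cycles$effective_D_h, 1),
               st$basal_D_h[1] + (1 - 0.9) * 3, tolerance = 1e-3)
})

test_that("lineage frequencies sum to one and composition is order-invariant", {
  cfg <- sim_config(n_strains = 1, n_cycles = 10, seed = 17,
                    deficit_range_h = c(2, 2))
  st <- build_strain_collection(cfg)
  tr <- simulate_serial_transfer(st[1, ], cfg, seed = 17)
  sums <- tapply(tr$lineages$frequency, tr$lineages$cycle, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(tr$lineages$D_h >= st$basal_D_h[1] - 1e-12))

  # composed D does not depend on acquisition order
  phis <- c(0.9, 0.3, 0.6)
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1), c(2, 1, 3))
  ds <- vapply(perms, function(p) compose_doubling_time(2.27, 3, phis[p]),
               numeric(1))
  expect_equal(max(ds) - min(ds), 0)
})

test_that("generations per cycle stay inside the log2 bounds of the size range", {
  cfg <- sim_config(n_strains = 2, n_cycles = 19, seed = 19)
  st <- build_strain_collection(cfg)
  for (i in 1:2) {
    tr <- simulate_serial_transfer(st[i, ], cfg)
    expect_true(all(tr$cycles$generations >= log2(2e6 / 5e4) - 1e-9))
    expect_true(all(tr$cycles$generations <= log2(4e6 / 5e4) + 1e-9))
    # oracle: direct log2 of the drawn final sizes
    expect_equal(tr$cycles$generations, log2(tr$cycles$final_size / 5e4))
  }
})

test_that("noiseless rendering is log-linear at the lineage doubling time", {
  noise0 <- curve_noise_config(spike_probability = 0, multiplicative_noise_sd = 0,
                               lag_h = 0)
  cv <- render_growth_curve(tibble::tibble(count = 5e4, D_h = 2), noise0,
                            carrying_capacity = Inf)
  slopes <- diff(log2(cv$cells)) / diff(cv$time_h)
  expect_equal(slopes, rep(0.5, length(slopes)), tolerance = 1e-9)
})

test_that("spike injection bookkeeping matches the seeded generator", {
  noise <- curve_noise_config(spike_probability = 0.02)
  n_spiked <- integer(50)
  for (i in 1:50) {
    cv <- render_growth_curve(tibble::tibble(count = 5e4, D_h = 2), noise,
                              carrying_capacity = 3e6, seed = i)
    n_spiked[i] <- sum(cv$spiked)
  }
  # 217 points x 0.02 = 4.34 expected spikes per curve
  expect_equal(mean(n_spiked), 217 * 0.02, tolerance = 0.25)
})

test_that("a 50/50 mixture of fast and slow lineages grows between their rates", {
  noise0 <- curve_noise_config(spike_probability = 0, multiplicative_noise_sd = 0,
                               lag_h = 0)
  st <- tibble::tibble(count = c(2.5e4, 2.5e4), D_h = c(2, 4))
  cv <- render_growth_curve(st, noise0, carrying_capacity = Inf)
  early <- cv$time_h < 10
  slopes <- diff(log2(cv$cells[early])) / diff(cv$time_h[early])
  expect_true(all(slopes > 0.25 & slopes < 0.5))
  # numeric-differentiation oracle on the analytic sum
  f <- function(t) 2.5e4 * 2^(t / 2) + 2.5e4 * 2^(t / 4)
  t_mid <- cv$time_h[early][-1] - diff(cv$time_h[early]) / 2
  orc <- (log2(f(t_mid + 1e-4)) - log2(f(t_mid - 1e-4))) / 2e-4
  expect_equal(slopes, orc, tolerance = 1e-3)
})

test_that("plate layouts reserve one reference per 2x2 quartet and host all populations", {
  layout <- make_plate_layout(character(0), 1, plate_dim = c(32, 48))
  expect_equal(sum(layout$role == "reference"), 384)

  # 12 strains x 3 replicates on a 48-position subgrid: bijection onto
  # non-reference positions (exhaustive audit)
  layout2 <- make_plate_layout(sprintf("s%02d", 1:12), 3, plate_dim = c(6, 8))
  strains <- layout2[layout2$role == "strain", ]
  expect_equal(nrow(strains), 36)
  expect_equal(sum(layout2$role == "reference"), 12)
  expect_false(any(strains$row %% 2 == 0 & strains$col %% 2 == 0))
  expect_equal(anyDuplicated(paste(strains$strain_id, strains$replicate)), 0L)
  expect_equal(anyDuplicated(paste(strains$row, strains$col)), 0L)
  expect_setequal(paste(strains$strain_id, strains$replicate),
                  paste(rep(sprintf("s%02d", 1:12), each = 3), 1:3))

  expect_error(make_plate_layout(sprintf("s%d", 1:40), 1, plate_dim = c(5, 8)),
               class = "evoadapt_layout_error")
})

test_that("zero-amplitude gradients leave reference doubling times identical", {
  g <- simulate_gradient_field(c(8, 12), amplitude = 0, seed = 2)
  expect_true(all(g$offset_log2 == 0))
  g2 <- simulate_gradient_field(c(8, 12), amplitude = 0.1, seed = 2)
  expect_equal(max(abs(g2$offset_log2)), log2(1.1), tolerance = 1e-9)
})

test_that("a fixed seed reproduces the experiment bundle bit for bit", {
  ex1 <- simulate_experiment(cfg_small())
  ex2 <- simulate_experiment(cfg_small())
  expect_identical(ex1$curves, ex2$curves)
  expect_identical(ex1$truth, ex2$truth)
  expect_identical(ex1$gradients, ex2$gradients)
})

test_that("cohort simulation flags injected non-growers and keeps ground truth", {
  cfg <- sim_config(n_strains = 20, replicates_per_strain = 2, n_cycles = 5,
                    nongrower_fraction = 0.1, seed = 23)
  coh <- simulate_cohort(cfg)
  n_bad <- sum(!is.finite(coh$truth$stress_deficit_h))
  expect_equal(n_bad, 2)
  bad_meas <- coh$measurements[coh$measurements$qc_status == "no_growth", ]
  expect_equal(length(unique(bad_meas$strain_id)), 2)
  expect_true(all(is.na(bad_meas$D_obs_h)))
})
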