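# replicate-level milestone table with a known generative structure
synth_milestones <- function(n_strains = 300, n_rep = 12, resid_sd = 0.2,
                             n_outliers = 0, shift = 0.5, seed = 1,
                             slope = 0.9, basal = 2.3) {
  set.seed(seed)
  pre <- runif(n_strains, basal + 0.5, basal + 4)
  true_a <- slope * (pre - basal)
  outlier <- rep(FALSE, n_strains)
  if (n_outliers > 0) {
    outlier[sample.int(n_strains, n_outliers)] <- TRUE
    true_a[outlier] <- true_a[outlier] + shift
  }
  tbl <- tidyr::expand_grid(strain = seq_len(n_strains), replicate = seq_len(n_rep))
  tbl$strain_id <- sprintf("s%04d", tbl$strain)
  tbl$preadaptation_D_h <- pre[tbl$strain]
  tbl$A75 <- true_a[tbl$strain] + rnorm(nrow(tbl), 0, resid_sd)
  attr(tbl, "outliers") <- sprintf("s%04d", which(outlier))
  tbl
}

test_that("collinear strain summaries give an exact regression fit", {
  s <- tibble::tibble(strain_id = letters[1:6], preadaptation_D_h = 3:8,
                      A75 = 0.7 * (3:8) - 1.2)
  fit <- regress_adaptation(s, "A75")
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.7)
  expect_equal(fit$intercept, -1.2)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, 6)

  expect_error(regress_adaptation(s[1:2, ], "A75"), class = "evoadapt_parameter_error")
  s_flat <- dplyr::mutate(s, preadaptation_D_h = 5)
  expect_error(regress_adaptation(s_flat, "A75"), class = "evoadapt_parameter_error")
})

test_that("shuffling adaptation across strains destroys the association", {
  ms <- synth_milestones(n_strains = 300, n_rep = 4, resid_sd = 0.1, seed = 3)
  sm <- summarize_strains(ms)
  fit <- regress_adaptation(sm, "A75")
  expect_gt(fit$r_squared, 0.9)
  set.seed(4)
  sm_perm <- dplyr::mutate(sm, A75 = sample(A75))
  fit_perm <- regress_adaptation(sm_perm, "A75")
  expect_lt(fit_perm$r_squared, 0.05)
})

test_that("BH correction matches the hand-applied step-up rule", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.3)
  q <- oracle_bh(p)
  expect_equal(p.adjust(p, method = "BH"), q)
  # largest k with p(k) <= k q / m is 2 (p3 = 0.039 > 3 * 0.05 / 7)
  expect_equal(sum(q <= 0.05), 2)

  set.seed(5)
  for (rep in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p))
  }
})

test_that("outlier calling recovers planted strains and stays silent on nulls", {
  ms0 <- synth_milestones(n_strains = 200, n_rep = 12, resid_sd = 0.2, seed = 6)
  ms0$A75 <- 0.9 * (ms0$preadaptation_D_h - 2.3)  # residuals identically zero
  sm0 <- summarize_strains(ms0)
  fit0 <- regress_adaptation(sm0, "A75")
  calls0 <- call_outliers(ms0, fit0)
  expect_equal(sum(calls0$strains$significant), 0)

  ms <- synth_milestones(n_strains = 300, n_rep = 12, resid_sd = 0.2,
                         n_outliers = 20, shift = 0.5, seed = 7)
  sm <- summarize_strains(ms)
  fit <- regress_adaptation(sm, "A75")
  calls <- call_outliers(ms, fit, q_threshold = 0.05)
  planted <- attr(ms, "outliers")
  called <- calls$strains$strain_id[calls$strains$significant]
  expect_gte(length(intersect(called, planted)), 18)
  false_calls <- setdiff(called, planted)
  expect_lte(length(false_calls), 0.05 * 280 + 3)
  expect_true(all(calls$strains$direction[calls$strains$strain_id %in% planted &
                                            calls$strains$significant] == "better"))
})

test_that("single-replicate strains are skipped with a notice", {
  ms <- synth_milestones(n_strains = 20, n_rep = 3, seed = 8)
  ms <- ms[!(ms$strain_id == "s0001" & ms$replicate > 1), ]
  sm <- summarize_strains(ms)
  fit <- regress_adaptation(sm, "A75")
  expect_message(calls <- call_outliers(ms, fit), "skipped")
  expect_false("s0001" %in% calls$strains$strain_id)
})

test_that("repeatability is 1 for duplicated replicates and ~0 for pure noise", {
  ms <- synth_milestones(n_strains = 100, n_rep = 1, resid_sd = 0, seed = 9)
  ms2 <- dplyr::bind_rows(ms, dplyr::mutate(ms, replicate = 2L))
  expect_equal(replicate_repeatability(ms2, "A75", seed = 1)$r_squared, 1)

  noise <- synth_milestones(n_strains = 300, n_rep = 6, resid_sd = 1,
                            slope = 0, seed = 10)
  noise$A75 <- rnorm(nrow(noise))
  expect_lt(replicate_repeatability(noise, "A75", seed = 2)$r_squared, 0.05)
})

test_that("repeatability follows the attenuation closed form", {
  # replicate = truth + noise; half-means correlate as
  # Var(truth) / (Var(truth) + 2 Var(noise) / n)
  set.seed(11)
  n_strains <- 500; n_rep <- 6
  truth <- rnorm(n_strains, 0, 1)
  ms <- tidyr::expand_grid(strain = seq_len(n_strains), replicate = seq_len(n_rep))
  ms$strain_id <- sprintf("s%04d", ms$strain)
  ms$preadaptation_D_h <- 3
  ms$A75 <- truth[ms$strain] + rnorm(nrow(ms), 0, 0.8)
  obs <- replicate_repeatability(ms, "A75", seed = 3)$r_squared
  expected <- 1 / (1 + 2 * 0.8^2 / 3)
  expect_equal(obs, expected, tolerance = 0.05)
})

test_that("Fisher overlap test matches exhaustive enumeration", {
  # N = 20, |A| = 5, |B| = 4, overlap = 4
  res <- overlap_test(letters[1:5], letters[2:5], letters[1:20])
  expect_equal(res$observed, 4)
  expect_equal(res$expected, 1)
  expect_equal(res$p_value, oracle_fisher_two_sided(4, 5, 4, 20), tolerance = 1e-9)

  set.seed(12)
  for (rep in 1:30) {
    n_u <- sample(8:25, 1)
    n_a <- sample(1:n_u, 1)
    n_b <- sample(1:n_u, 1)
    u <- sprintf("g%02d", seq_len(n_u))
    a <- sample(u, n_a); b <- sample(u, n_b)
    res <- overlap_test(a, b, u)
    expect_equal(res$p_value,
                 oracle_fisher_two_sided(res$observed, n_a, n_b, n_u),
                 tolerance = 1e-9)
  }
})

test_that("degenerate and disjoint overlaps behave as expected", {
  u <- sprintf("g%02d", 1:30)
  res_full <- overlap_test(u, u, u)
  expect_equal(res_full$observed, 30)
  expect_equal(res_full$expected, 30)
  expect_equal(res_full$p_value, 1)

  res_disj <- overlap_test(u[1:3], u[4:6], u)
  expect_equal(res_disj$observed, 0)
  expect_gt(res_disj$p_value, 0.5)

  expect_error(overlap_test(c("x"), c("y"), u), class = "evoadapt_input_error")
})

test_that("type-I error of outlier calling is controlled without planted effects", {
  rates <- vapply(1:5, function(s) {
    ms <- synth_milestones(n_strains = 200, n_rep = 8, resid_sd = 0.2,
                           seed = 100 + s)
    sm <- summarize_strains(ms)
    fit <- regress_adaptation(sm, "A75")
    calls <- call_outliers(ms, fit)
    mean(calls$strains$significant)
  }, numeric(1))
  expect_lt(mean(rates), 0.05)
})
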