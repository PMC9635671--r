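# one plate's worth of doubling times on a known layout
plate_d <- function(layout, strain_D = 3.2, ref_D = 3.0, field = NULL,
                    noise_sd = 0) {
  d <- layout
  d$D_h <- ifelse(d$role == "reference", ref_D,
                  ifelse(d$role == "strain", strain_D, NA_real_))
  if (!is.null(field)) d$D_h <- d$D_h * 2^field(d$row, d$col)
  if (noise_sd > 0) d$D_h <- d$D_h * 2^rnorm(nrow(d), 0, noise_sd)
  d$qc_status <- ifelse(is.na(d$D_h), "excluded", "ok")
  d
}

test_that("flat reference plates give zero offsets and identity normalization", {
  layout <- make_plate_layout(sprintf("s%d", 1:24), 1, plate_dim = c(8, 8))
  d <- plate_d(layout, ref_D = 3.0)
  surf <- fit_reference_surface(d, layout, ref_median_h = 3.0)
  expect_equal(max(abs(surf$offset_log2)), 0)
  norm <- normalize_plate(d, surf)
  expect_equal(norm$D_norm_h, norm$D_h)
})

test_that("an exact planar gradient is reproduced at all interior positions", {
  layout <- make_plate_layout(sprintf("s%d", 1:40), 1, plate_dim = c(10, 12))
  plane <- function(r, c) 0.015 * r - 0.01 * c + 0.02
  d <- plate_d(layout, field = plane)
  surf <- fit_reference_surface(d, layout, ref_median_h = 3.0)
  interior <- surf$row < 9 & surf$col < 11  # inside the reference hull
  ref_part <- log2(3.0 / 3.0)
  expected <- plane(surf$row, surf$col) + log2(3.0) - log2(3.0)
  expect_equal(surf$offset_log2[interior], expected[interior], tolerance = 1e-9)
  # outside the hull the nearest-reference rule clamps the coordinate
  edge <- surf[surf$row == 9 & surf$col == 11, ]
  expect_equal(edge$offset_log2, plane(8, 10), tolerance = 1e-9)
})

test_that("failed references are imputed from neighbours and the surface stays finite", {
  layout <- make_plate_layout(sprintf("s%d", 1:20), 1, plate_dim = c(8, 8))
  d <- plate_d(layout, ref_D = 3.0)
  corner <- d$role == "reference" & d$row == 0 & d$col == 0
  d$qc_status[corner] <- "excluded"
  d$D_h[corner] <- NA_real_
  surf <- fit_reference_surface(d, layout, ref_median_h = 3.0)
  expect_true(all(is.finite(surf$offset_log2)))
  expect_equal(max(abs(surf$offset_log2)), 0)  # neighbours all at the median

  # fewer than 4 usable references is unrecoverable
  d2 <- plate_d(layout, ref_D = 3.0)
  refs <- which(d2$role == "reference")
  d2$qc_status[refs[-(1:3)]] <- "excluded"
  expect_error(fit_reference_surface(d2, layout),
               class = "evoadapt_normalization_error")
})

test_that("normalization is idempotent", {
  set.seed(55)
  layout <- make_plate_layout(sprintf("s%d", 1:40), 1, plate_dim = c(10, 12))
  plane <- function(r, c) 0.02 * r - 0.012 * c
  d <- plate_d(layout, field = plane, noise_sd = 0.01)
  surf <- fit_reference_surface(d, layout)
  norm <- normalize_plate(d, surf)
  renorm_input <- dplyr::mutate(norm, D_h = D_norm_h)
  surf2 <- fit_reference_surface(renorm_input, layout,
                                 ref_median_h = attr(surf, "ref_median_h"))
  expect_lt(max(abs(surf2$offset_log2[surf2$row %% 2 == 0 & surf2$col %% 2 == 0])),
            1e-6)
})

test_that("gradient removal restores reference homogeneity and strain accuracy", {
  set.seed(77)
  layout <- make_plate_layout(sprintf("s%02d", 1:40), 3, plate_dim = c(10, 16))
  n_better <- 0
  for (p in 1:20) {
    plane <- function(r, c) {
      a <- runif(2, -1, 1)
      force(a)
      function(r, c) (a[1] * (r / 9 - 0.5) + a[2] * (c / 15 - 0.5)) * log2(1.1)
    }
    f <- plane()
    d <- plate_d(layout[layout$plate_id == "plate_01", ], strain_D = 3.4,
                 ref_D = 3.0, field = f)
    surf <- fit_reference_surface(d, layout, ref_median_h = 3.0)
    norm <- normalize_plate(d, surf)
    refs <- norm[norm$role == "reference", ]
    expect_lt(sd(refs$D_norm_h) / mean(refs$D_norm_h), 0.01)
    strains <- norm[norm$role == "strain", ]
    rmse_norm <- sqrt(mean((strains$D_norm_h - 3.4)^2))
    rmse_raw <- sqrt(mean((strains$D_h - 3.4)^2))
    if (rmse_norm < rmse_raw) n_better <- n_better + 1
  }
  expect_gte(n_better, 19)
})

test_that("between-plate level differences are harmonized to the plate-set median", {
  layout <- make_plate_layout(sprintf("s%02d", 1:40), 6, plate_dim = c(10, 16))
  expect_equal(length(unique(layout$plate_id)), 2)
  d1 <- plate_d(layout[layout$plate_id == "plate_01", ], strain_D = 3.3, ref_D = 3.0)
  d2 <- plate_d(layout[layout$plate_id == "plate_02", ], strain_D = 3.3 * 1.2,
                ref_D = 3.6)
  d <- dplyr::bind_rows(d1, d2)
  surf <- fit_reference_surface(d, layout)
  norm <- normalize_plate(d, surf)
  s1 <- norm$D_norm_h[norm$role == "strain" & norm$plate_id == "plate_01"]
  s2 <- norm$D_norm_h[norm$role == "strain" & norm$plate_id == "plate_02"]
  # identical strains on both plates: normalized estimates must agree
  expect_equal(mean(s1), mean(s2), tolerance = 1e-9)
})

test_that("gradient-free normalization barely perturbs strain estimates", {
  set.seed(88)
  layout <- make_plate_layout(sprintf("s%02d", 1:40), 3, plate_dim = c(10, 16))
  one <- layout[layout$plate_id == "plate_01", ]
  d <- plate_d(one, strain_D = 3.4, ref_D = 3.0)
  strain_pos <- d$role == "strain"
  d$D_h[strain_pos] <- d$D_h[strain_pos] * 2^rnorm(sum(strain_pos), 0, 0.01)
  surf <- fit_reference_surface(d, layout)
  norm <- normalize_plate(d, surf)
  strains <- norm[norm$role == "strain", ]
  expect_lt(max(abs(strains$D_norm_h / strains$D_h - 1)), 0.005)
})
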