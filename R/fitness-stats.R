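#' Aggregate replicate milestones into per-strain summaries
#'
#' Strain-level adaptation is the mean over replicate populations of each
#' milestone and of the preadaptation doubling time.
#'
#' @param milestones Per-population milestone table from [milestone_table()].
#' @return Tibble with one row per strain: `strain_id`, `n_replicates`,
#'   `preadaptation_D_h`, and mean milestone columns.
#' @export
summarize_strains <- function(milestones) {
  ms_cols <- grep("^A[0-9]+$", names(milestones), value = TRUE)
  milestones |>
    group_by(.data$strain_id) |>
    summarise(
      n_replicates = n(),
      preadaptation_D_h = mean(.data$preadaptation_D_h),
      across(all_of(ms_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Regress adaptation on preadaptation fitness
#'
#' Ordinary least squares of strain-mean adaptation (doubling-time reduction
#' in hours at one milestone) on strain-mean preadaptation doubling time.
#' Under diminishing-return epistasis the slope is positive — less fit
#' strains (longer preadaptation doubling times) adapt more — and the R^2
#' measures how completely preadaptation fitness predicts adaptation.
#'
#' @param strain_summaries Output of [summarize_strains()] (or any tibble
#'   with `preadaptation_D_h` and the milestone column).
#' @param milestone Name of the adaptation column to model (default
#'   `"A75"`).
#' @return An object of class `"adaptation_fit"` wrapping the `lm` fit, with
#'   [tidy()] and [glance()] methods and an [ggplot2::autoplot()] method.
#' @examples
#' s <- tibble::tibble(strain_id = letters[1:5],
#'                     preadaptation_D_h = 3:7,
#'                     A75 = 0.9 * (3:7 - 2.3))
#' glance(regress_adaptation(s))
#' @export
regress_adaptation <- function(strain_summaries, milestone = "A75") {
  if (!milestone %in% names(strain_summaries)) {
    ea_abort(sprintf("milestone column `%s` not found.", milestone), "parameter_error")
  }
  df <- strain_summaries |>
    filter(is.finite(.data$preadaptation_D_h), is.finite(.data[[milestone]]))
  if (nrow(df) < 3) {
    ea_abort("at least 3 strains with a defined milestone are required.",
             "parameter_error")
  }
  if (sd(df$preadaptation_D_h) == 0) {
    ea_abort("zero variance in preadaptation doubling time; regression undefined.",
             "parameter_error")
  }
  fml <- stats::reformulate("preadaptation_D_h", response = milestone)
  fit <- lm(fml, data = df)
  structure(
    list(lm = fit, milestone = milestone, data = df,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = quiet_summary(fit)$r.squared, n = nrow(df)),
    class = "adaptation_fit"
  )
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat(sprintf("<adaptation_fit> %s ~ preadaptation D: slope %.3f h/h, R^2 %.3f (n = %d)\n",
              x$milestone, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @rdname regress_adaptation
#' @param x An `"adaptation_fit"`.
#' @param ... Unused.
#' @method tidy adaptation_fit
#' @export
tidy.adaptation_fit <- function(x, ...) {
  s <- quiet_summary(x$lm)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname regress_adaptation
#' @method glance adaptation_fit
#' @export
glance.adaptation_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         n = x$n, milestone = x$milestone)
}

#' Call strains adapting faster or slower than their fitness predicts
#'
#' For each strain, replicate-level residuals (replicate adaptation minus
#' the regression prediction at the strain's mean preadaptation doubling
#' time) are tested against zero with a two-sided one-sample t-test;
#' Benjamini-Hochberg correction across strains controls the FDR at
#' `q_threshold`. Significant strains are labelled `"better"` (positive
#' residual: more adaptation than predicted) or `"worse"`.
#'
#' @param milestones Per-population milestone table ([milestone_table()]).
#' @param fit An [regress_adaptation()] fit for the same milestone.
#' @param q_threshold FDR level (default 0.05).
#' @return A list of class `"outlier_calls"`: `strains` (per-strain tibble
#'   with mean residual, t statistic, `p_value`, `q_value`, `significant`,
#'   `direction`), `summary` (counts and median absolute deviations per
#'   direction), `q_threshold`.
#' @export
call_outliers <- function(milestones, fit, q_threshold = 0.05) {
  stopifnot(inherits(fit, "adaptation_fit"))
  if (q_threshold <= 0 || q_threshold >= 1) {
    ea_abort("`q_threshold` must be in (0, 1).", "parameter_error")
  }
  ms <- fit$milestone
  strain_pre <- milestones |>
    group_by(.data$strain_id) |>
    summarise(preadaptation_D_h = mean(.data$preadaptation_D_h), .groups = "drop")
  resid_tbl <- milestones |>
    filter(is.finite(.data[[ms]])) |>
    select("strain_id", "replicate", adaptation = all_of(ms)) |>
    left_join(strain_pre, by = "strain_id") |>
    mutate(predicted = fit$intercept + fit$slope * .data$preadaptation_D_h,
           residual = .data$adaptation - .data$predicted)
  per_strain <- resid_tbl |>
    group_by(.data$strain_id) |>
    summarise(n = n(), mean_residual = mean(.data$residual),
              sd_residual = sd(.data$residual), .groups = "drop")
  skipped <- per_strain |> filter(.data$n < 2)
  if (nrow(skipped) > 0) {
    inform(sprintf("%d strain(s) with a single replicate skipped in outlier testing.",
                   nrow(skipped)))
  }
  tested <- per_strain |>
    filter(.data$n >= 2, .data$sd_residual > 0) |>
    mutate(
      t_statistic = .data$mean_residual / (.data$sd_residual / sqrt(.data$n)),
      p_value = 2 * pt(abs(.data$t_statistic), df = .data$n - 1, lower.tail = FALSE),
      q_value = p.adjust(.data$p_value, method = "BH"),
      significant = .data$q_value <= q_threshold,
      direction = case_when(
        !.data$significant ~ "none",
        .data$mean_residual > 0 ~ "better",
        TRUE ~ "worse"
      )
    )
  summary_tbl <- tested |>
    filter(.data$significant) |>
    group_by(.data$direction) |>
    summarise(n = n(),
              median_deviation_h = median(abs(.data$mean_residual)),
              .groups = "drop")
  structure(
    list(strains = tested, skipped = skipped, summary = summary_tbl,
         q_threshold = q_threshold, milestone = ms),
    class = "outlier_calls"
  )
}

#' @export
print.outlier_calls <- function(x, ...) {
  n_sig <- sum(x$strains$significant)
  cat(sprintf("<outlier_calls> %s: %d/%d strains significant at q = %g\n",
              x$milestone, n_sig, nrow(x$strains), x$q_threshold))
  if (nrow(x$summary) > 0) print(x$summary)
  invisible(x)
}

#' Replicate repeatability of adaptation measurements
#'
#' Splits each strain's replicates into two disjoint random halves, averages
#' the milestone within each half, and reports the squared Pearson
#' correlation (OLS R^2) between half-means across strains. This is the
#' ceiling that measurement error and mutational randomness impose on any
#' strain-level predictor.
#'
#' @param milestones Per-population milestone table.
#' @param milestone Milestone column (default `"A75"`).
#' @param seed Seed for the random half-split.
#' @param method `"half_split"` (default) splits replicates into two random
#'   halves per strain and correlates the half-means; `"pairwise"` averages
#'   the squared correlation over all replicate-index pairings (no
#'   randomness).
#' @return A one-row tibble: `r_squared`, `n_strains`, `method`.
#' @export
replicate_repeatability <- function(milestones, milestone = "A75", seed = 1,
                                    method = c("half_split", "pairwise")) {
  method <- match.arg(method)
  usable <- milestones |>
    filter(is.finite(.data[[milestone]])) |>
    group_by(.data$strain_id) |>
    filter(n() >= 2) |>
    mutate(rep_index = row_number()) |>
    ungroup()
  if (method == "pairwise") {
    wide <- usable |>
      select("strain_id", "rep_index", value = all_of(milestone)) |>
      tidyr::pivot_wider(names_from = "rep_index", values_from = "value")
    mat <- as.matrix(wide[, -1])
    k <- ncol(mat)
    r2s <- c()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      both <- complete.cases(mat[, c(i, j)])
      if (sum(both) >= 3) r2s <- c(r2s, stats::cor(mat[both, i], mat[both, j])^2)
    }
    return(tibble(r_squared = mean(r2s), n_strains = nrow(wide),
                  method = method))
  }
  set.seed(seed)
  halves <- usable |>
    group_by(.data$strain_id) |>
    group_modify(function(df, key) {
      idx <- sample.int(nrow(df))
      h1 <- idx[seq_len(floor(nrow(df) / 2))]
      h2 <- idx[(floor(nrow(df) / 2) + 1):nrow(df)]
      tibble(half1 = mean(df[[milestone]][h1]), half2 = mean(df[[milestone]][h2]))
    }) |>
    ungroup()
  r2 <- stats::cor(halves$half1, halves$half2)^2
  tibble(r_squared = r2, n_strains = nrow(halves), method = method)
}

#' Fisher overlap test between two gene sets
#'
#' Observed vs expected overlap of two sets drawn from a common universe,
#' with a two-sided Fisher's exact test on the 2x2 membership table
#' (exact hypergeometric tail summation).
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Character vector of all testable elements, or a single
#'   integer giving the universe size (then `set_a`/`set_b` sizes and
#'   `overlap` must be consistent with it).
#' @return One-row tibble: `observed`, `expected`, `p_value`, `n_a`, `n_b`,
#'   `n_universe`.
#' @examples
#' overlap_test(letters[1:5], letters[4:8], letters)
#' @export
overlap_test <- function(set_a, set_b, universe) {
  if (is.numeric(universe) && length(universe) == 1) {
    n_u <- as.integer(universe)
    n_a <- length(unique(set_a)); n_b <- length(unique(set_b))
    ov <- length(intersect(unique(set_a), unique(set_b)))
  } else {
    universe <- unique(universe)
    set_a <- unique(set_a); set_b <- unique(set_b)
    if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
      ea_abort("both sets must be subsets of the universe.", "input_error")
    }
    n_u <- length(universe); n_a <- length(set_a); n_b <- length(set_b)
    ov <- length(intersect(set_a, set_b))
  }
  if (ov > min(n_a, n_b)) {
    ea_abort("overlap exceeds the smaller set size.", "input_error")
  }
  tab <- matrix(c(ov, n_a - ov, n_b - ov, n_u - n_a - n_b + ov), nrow = 2)
  if (any(tab < 0)) ea_abort("set sizes inconsistent with the universe.", "input_error")
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  tibble(observed = ov, expected = n_a * n_b / n_u, p_value = p,
         n_a = n_a, n_b = n_b, n_universe = n_u)
}
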