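#' Fit a spatial reference surface for one or more plates
#'
#' Non-evolving reference colonies occupy one member of every 2x2 position
#' quartet; their doubling times sample the environmental field of the
#' plate. For each plate (and cycle, when a `cycle` column is present) the
#' log2 reference doubling times are bilinearly interpolated over the
#' reference grid to every position, with nearest-reference extrapolation
#' beyond the outermost reference rows/columns and imputation of failed
#' references from their four nearest usable neighbours. Offsets are
#' expressed relative to the plate-set reference median, so subtracting them
#' removes both within-plate gradients and between-plate level shifts.
#'
#' @param d_table Tibble of doubling-time estimates with columns `plate_id`,
#'   `row`, `col`, `D_h`, `qc_status` (and optionally `cycle`).
#' @param layout Plate layout tibble ([make_plate_layout()] format); `role`
#'   identifies reference positions.
#' @param ref_median_h Plate-set reference median (hours). Computed from the
#'   qc-ok references in `d_table` when `NULL`.
#' @param min_references Minimum usable references per plate (default 4).
#' @return A tibble of class `"reference_surface"` with columns `plate_id`
#'   (`cycle` if present), `row`, `col`, `offset_log2`, and attribute
#'   `ref_median_h`.
#' @seealso [normalize_plate()]
#' @export
fit_reference_surface <- function(d_table, layout, ref_median_h = NULL,
                                  min_references = 4) {
  stopifnot(all(c("plate_id", "row", "col", "D_h") %in% names(d_table)))
  if (!"qc_status" %in% names(d_table)) d_table$qc_status <- "ok"
  has_cycle <- "cycle" %in% names(d_table)
  refs <- layout |>
    filter(.data$role == "reference") |>
    select("plate_id", "row", "col")
  ref_d <- d_table |>
    inner_join(refs, by = c("plate_id", "row", "col"))
  usable <- ref_d |> filter(.data$qc_status == "ok", is.finite(.data$D_h))
  if (is.null(ref_median_h)) {
    if (nrow(usable) == 0) {
      ea_abort("no usable reference colonies in the plate set.", "normalization_error")
    }
    ref_median_h <- median(usable$D_h)
  }
  keys <- if (has_cycle) c("plate_id", "cycle") else "plate_id"
  groups <- d_table |> distinct(across(all_of(keys)))
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sel <- ref_d$plate_id == g$plate_id
    if (has_cycle) sel <- sel & ref_d$cycle == g$cycle
    plate_refs <- ref_d[sel, ]
    psel <- d_table$plate_id == g$plate_id
    if (has_cycle) psel <- psel & d_table$cycle == g$cycle
    positions <- d_table[psel, c("row", "col")]
    surf <- interpolate_reference_grid(plate_refs, positions, ref_median_h,
                                       min_references)
    out[[i]] <- bind_cols(g[rep(1, nrow(surf)), , drop = FALSE], surf)
  }
  res <- bind_rows(out)
  attr(res, "ref_median_h") <- ref_median_h
  class(res) <- c("reference_surface", class(res))
  res
}

# Bilinear interpolation of log2 reference D over the regular reference grid
# (rows/cols 0, 2, 4, ...), clamped to the grid hull (nearest-reference
# extrapolation at edges). Failed references are imputed from the 4 nearest
# usable references.
interpolate_reference_grid <- function(plate_refs, positions, ref_median_h,
                                       min_references) {
  ok <- plate_refs$qc_status == "ok" & is.finite(plate_refs$D_h)
  if (sum(ok) < min_references) {
    ea_abort(sprintf("plate has %d usable references; >= %d required — plate unnormalizable.",
                     sum(ok), min_references), "normalization_error")
  }
  ref_rows <- sort(unique(plate_refs$row))
  ref_cols <- sort(unique(plate_refs$col))
  Z <- matrix(NA_real_, nrow = length(ref_rows), ncol = length(ref_cols),
              dimnames = list(ref_rows, ref_cols))
  Z[cbind(match(plate_refs$row[ok], ref_rows), match(plate_refs$col[ok], ref_cols))] <-
    log2(plate_refs$D_h[ok])
  if (anyNA(Z)) {
    miss <- which(is.na(Z), arr.ind = TRUE)
    good <- which(!is.na(Z), arr.ind = TRUE)
    gr <- ref_rows[good[, 1]]; gc <- ref_cols[good[, 2]]
    for (m in seq_len(nrow(miss))) {
      mr <- ref_rows[miss[m, 1]]; mc <- ref_cols[miss[m, 2]]
      d2 <- (gr - mr)^2 + (gc - mc)^2
      nn <- order(d2)[seq_len(min(4, length(d2)))]
      Z[miss[m, 1], miss[m, 2]] <- mean(Z[good[nn, , drop = FALSE]])
    }
  }
  # clamp query coordinates into the reference hull -> nearest-edge behaviour
  qr <- pmin(pmax(positions$row, min(ref_rows)), max(ref_rows))
  qc <- pmin(pmax(positions$col, min(ref_cols)), max(ref_cols))
  interp <- pracma::interp2(x = ref_cols, y = ref_rows, Z = Z,
                            xp = qc, yp = qr, method = "linear")
  tibble(row = positions$row, col = positions$col,
         offset_log2 = interp - log2(ref_median_h))
}

#' Normalize doubling times against a fitted reference surface
#'
#' Subtracts the per-position log2 offset of the reference surface from the
#' log2 doubling time, i.e. divides D by the local multiplicative
#' environmental distortion and re-centres all plates on the plate-set
#' reference median.
#'
#' @param d_table Tibble with `plate_id`, `row`, `col`, `D_h` (and `cycle`
#'   if the surface was fitted per cycle).
#' @param surface A `"reference_surface"` from [fit_reference_surface()].
#' @return `d_table` with an added `D_norm_h` column.
#' @examples
#' layout <- make_plate_layout("s1", 1, plate_dim = c(4, 4))
#' d <- dplyr::mutate(layout, D_h = 3, qc_status = "ok")
#' surf <- fit_reference_surface(d, layout)
#' normalize_plate(d, surf)$D_norm_h
#' @export
normalize_plate <- function(d_table, surface) {
  keys <- intersect(c("plate_id", "cycle", "row", "col"), names(surface))
  out <- d_table |>
    left_join(surface |> select(all_of(c(keys, "offset_log2"))), by = keys) |>
    mutate(D_norm_h = 2^(log2(.data$D_h) - .data$offset_log2)) |>
    select(-"offset_log2")
  out
}
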