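#' Relative defect size
#'
#' Expresses each animal's resection defect length as a percentage of its
#' hemimandible perimeter and of its full mandible perimeter.
#'
#' @param records Tibble with columns `defect_length`, `hemi_perimeter`,
#'   `full_perimeter` (mm); other columns pass through.
#' @return The input with `pct_of_hemi` and `pct_of_full` columns added.
#' @export
relative_defect_size <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("defect_length", "hemi_perimeter", "full_perimeter")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("missing field(s): ", paste(missing, collapse = ", "))
  }
  if (any(is.na(records[needed]))) stop("missing length value(s)")
  if (any(records$hemi_perimeter <= 0) || any(records$full_perimeter <= 0)) {
    stop("perimeters must be positive")
  }
  dplyr::mutate(records,
                pct_of_hemi = 100 * .data$defect_length / .data$hemi_perimeter,
                pct_of_full = 100 * .data$defect_length / .data$full_perimeter)
}

#' Polygon area by the shoelace formula
#'
#' @param vertices Two-column matrix or data frame of (x, y) vertices (mm),
#'   in order around the polygon.
#' @return Area in mm^2 (absolute value; collinear vertices give 0).
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3) stop("a polygon needs at least 3 vertices")
  x <- v[, 1]
  y <- v[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Interior angle at a vertex between two landmarks
#'
#' The angle (degrees, in [0, 180]) at `vertex` subtended by the segments to
#' `p1` and `p2`; used for the stump-displacement angle between the proximal
#' mandible endpoints and the medial resection margin.
#'
#' @param p1,vertex,p2 Numeric (x, y) points.
#' @return Angle in degrees.
#' @export
displacement_angle <- function(p1, vertex, p2) {
  u <- as.numeric(p1) - as.numeric(vertex)
  w <- as.numeric(p2) - as.numeric(vertex)
  nu <- sqrt(sum(u^2))
  nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) stop("vertex coincides with an endpoint")
  cosang <- sum(u * w) / (nu * nw)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Percent perimeter reduction relative to intact
#'
#' @param resected Resected-mandible perimeter (mm); vectorised.
#' @param intact Intact-control perimeter (mm), positive.
#' @return `100 * (intact - resected) / intact`; negative values indicate
#'   growth beyond the control.
#' @export
perimeter_change <- function(resected, intact) {
  if (any(intact <= 0)) stop("intact perimeter must be positive")
  100 * (intact - resected) / intact
}

#' Per-time-point cohort summary of morphometry records
#'
#' @param records Tibble with a `time_dpi` column and numeric measurement
#'   columns (e.g. `defect_area_mm2`, `angle_deg`).
#' @return Tibble of per-time-point means and animal counts.
#' @export
summarize_morphometry <- function(records) {
  records |>
    dplyr::group_by(.data$time_dpi) |>
    dplyr::summarize(
      dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE),
                    .names = "mean_{.col}"),
      n = dplyr::n(),
      .groups = "drop"
    )
}
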