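# Vessel-to-tumor distance histograms and directional (polar) statistics.

#' Angle of a vessel as seen from the tumor mass centre
#'
#' Image-coordinate convention: 0 degrees points right (+col), angles grow
#' counter-clockwise on the displayed image (row 0 at the top), so a vessel
#' directly above the tumor on screen is at 90 degrees. Computed as
#' `atan2(-(row - row_t), col - col_t)` mapped to [0, 360).
#'
#' @param centroid_rc Numeric (row, col), or an n x 2 matrix of centroids,
#'   0-based pixel coordinates.
#' @param tumor_centroid_rc Numeric (row, col) of the tumor mass centre.
#' @return Angle(s) in degrees, in [0, 360).
#' @export
vessel_angle <- function(centroid_rc, tumor_centroid_rc) {
  m <- if (is.matrix(centroid_rc)) centroid_rc else
    matrix(centroid_rc, ncol = 2)
  dr <- m[, 1] - tumor_centroid_rc[1]
  dc <- m[, 2] - tumor_centroid_rc[2]
  if (any(dr == 0 & dc == 0))
    stop("undefined-angle error: centroid coincides with the tumor centre",
         call. = FALSE)
  (atan2(-dr, dc) * 180 / pi) %% 360
}

#' Histogram of vessel-to-tumor distances
#'
#' Bins vessel distances into half-open intervals `[e_i, e_{i+1})` of width
#' `bin_width_mm`. Unless given, the upper limit is the smallest multiple of
#' the bin width strictly covering the largest distance. On slides where
#' vessels cluster near the tumor and again towards the tissue border the
#' histogram is bimodal with an empty gap.
#'
#' @param records Tibble with a `distance_to_tumor_mm` column
#'   (from [vessel_records()]), or a numeric vector of distances in mm.
#' @param bin_width_mm Bin width in millimetres (default 0.1).
#' @param max_mm Optional upper limit in millimetres.
#' @return A tibble of class `distance_profile` with columns `bin_lo_mm`,
#'   `bin_hi_mm`, `count`, `frequency` (normalized counts; all zero when no
#'   vessel exists).
#' @export
distance_histogram <- function(records, bin_width_mm = 0.1, max_mm = NULL) {
  stopifnot(bin_width_mm > 0)
  d <- if (is.data.frame(records)) records$distance_to_tumor_mm else
    as.numeric(records)
  d <- d[is.finite(d)]
  if (is.null(max_mm)) {
    nbins <- if (length(d) == 0L) 1L else
      as.integer(floor(max(d) / bin_width_mm)) + 1L
  } else {
    stopifnot(max_mm > 0)
    nbins <- as.integer(ceiling(max_mm / bin_width_mm))
    d <- d[d < nbins * bin_width_mm]
  }
  counts <- tabulate(floor(d / bin_width_mm) + 1L, nbins = nbins)
  total <- sum(counts)
  out <- tibble::tibble(
    bin_lo_mm = (seq_len(nbins) - 1) * bin_width_mm,
    bin_hi_mm = seq_len(nbins) * bin_width_mm,
    count = counts,
    frequency = if (total > 0) counts / total else rep(0, nbins))
  class(out) <- c("distance_profile", class(out))
  attr(out, "bin_width_mm") <- bin_width_mm
  out
}

SECTOR_CENTERS_DEG <- seq(0, 315, by = 45)

#' Directional vessel distribution around the tumor
#'
#' Vessels whose tumor distance lies in `(low, high]` are assigned to eight
#' 45-degree sectors centred at 0, 45, ..., 315 degrees counter-clockwise
#' (sector s covers `[s - 22.5, s + 22.5)`, wrapping at 360). The linear
#' vessel density of a sector is its count divided by the radial window
#' length, in vessels per millimetre — the quantity drawn on the polar
#' graph.
#'
#' @param records Tibble with `distance_to_tumor_mm` and `angle_deg` columns.
#' @param window_mm Radial window `(low, high)` in millimetres, default
#'   `c(0, 2)` — the peritumoral region of interest.
#' @return A tibble of class `directional_profile` with columns
#'   `sector_center_deg`, `count`, `density_per_mm`; the window is kept in
#'   `attr(, "window_mm")`.
#' @export
directional_profile <- function(records, window_mm = c(0, 2)) {
  stopifnot(length(window_mm) == 2, window_mm[1] < window_mm[2])
  d <- records$distance_to_tumor_mm
  a <- records$angle_deg
  sel <- is.finite(d) & is.finite(a) & d > window_mm[1] & d <= window_mm[2]
  sector_idx <- (floor((a[sel] + 22.5) / 45) %% 8) + 1L
  counts <- tabulate(sector_idx, nbins = 8L)
  out <- tibble::tibble(
    sector_center_deg = SECTOR_CENTERS_DEG,
    count = counts,
    density_per_mm = counts / (window_mm[2] - window_mm[1]))
  class(out) <- c("directional_profile", class(out))
  attr(out, "window_mm") <- window_mm
  out
}

#' Plot a distance profile
#'
#' @param object A `distance_profile`.
#' @param ... Unused.
#' @return A ggplot bar chart of vessel counts per distance bin.
#' @export
autoplot.distance_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = (.data$bin_lo_mm + .data$bin_hi_mm) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width_mm") %||% 0.1,
                      fill = "steelblue", colour = NA) +
    ggplot2::labs(x = "distance to tumor (mm)", y = "vessel count") +
    ggplot2::theme_minimal()
}

#' Plot a directional profile as a polar graph
#'
#' One radial spoke per 45-degree sector; spoke length is the linear vessel
#' density (vessels/mm) of the sector.
#'
#' @param object A `directional_profile`.
#' @param ... Unused.
#' @return A ggplot with polar coordinates.
#' @export
autoplot.directional_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sector_center_deg,
                                   y = .data$density_per_mm)) +
    ggplot2::geom_col(width = 45, fill = "firebrick", alpha = 0.7) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-22.5, 337.5),
                                breaks = SECTOR_CENTERS_DEG) +
    ggplot2::labs(x = "direction from tumor mass centre (deg)",
                  y = "vessel density (1/mm)") +
    ggplot2::theme_minimal()
}

#' Export a directional profile as CSV plus a polar plot
#'
#' @param profile A `directional_profile`.
#' @param path Output path stem; writes `<path>.csv` and `<path>.png`.
#' @return Invisibly, the two file paths.
#' @export
polar_export <- function(profile, path) {
  stopifnot(inherits(profile, "directional_profile"))
  csv <- paste0(path, ".csv")
  pngf <- paste0(path, ".png")
  utils::write.csv(as.data.frame(profile), csv, row.names = FALSE)
  p <- autoplot.directional_profile(profile)
  grDevices::png(pngf, width = 700, height = 700)
  print(p)
  grDevices::dev.off()
  invisible(c(csv = csv, png = pngf))
}
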