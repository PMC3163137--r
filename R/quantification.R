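# Distance maps, peritumoral band, per-vessel records, LVD reports.

#' Euclidean distance map to the tumor
#'
#' Exact Euclidean distance transform of the complement of the tumor mask:
#' each pixel holds the centre-to-centre distance, in micrometres, to the
#' nearest tumor pixel; tumor pixels hold 0.
#'
#' @param tumor_mask A [binary_mask] with at least one true pixel.
#' @return An object of class `distance_map` with fields `values`
#'   (micrometre matrix) and `pixel_size_um`.
#' @export
distance_map <- function(tumor_mask) {
  stopifnot(inherits(tumor_mask, "binary_mask"))
  if (!any(tumor_mask$values))
    stop("no-tumor error: tumor mask is empty", call. = FALSE)
  comp <- 1 - (tumor_mask$values + 0)   # tumor pixels become background 0
  d <- EBImage::distmap(comp, metric = "euclidean")
  structure(list(values = as.matrix(d) * tumor_mask$pixel_size_um,
                 pixel_size_um = tumor_mask$pixel_size_um),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %d x %d px, %.4g um/px, max %.3g mm\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              max(x$values) / 1000))
  invisible(x)
}

#' Write a distance map as 32-bit float TIFF
#'
#' @param dmap A [distance_map].
#' @param path Output TIFF path. Values are stored in micrometres.
#' @return `path`, invisibly.
#' @export
write_distance_map <- function(dmap, path) {
  stopifnot(inherits(dmap, "distance_map"))
  tiff::writeTIFF(dmap$values / max(1, max(dmap$values)), path,
                  bits.per.sample = 32L, reduce = FALSE)
  # raw micrometre scale stored alongside, TIFF payload is normalized float
  jsonlite::write_json(list(max_um = max(dmap$values),
                            pixel_size_um = dmap$pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Peritumoral band mask
#'
#' Stromal tissue within `band_mm` of the tumor invasion edge: pixels whose
#' tumor distance d satisfies 0 < d <= band_mm, intersected with the tissue
#' mask. Tumor pixels (d = 0) are excluded, so the band is stroma only.
#'
#' @param tumor_mask Full-resolution tumor [binary_mask].
#' @param tissue_mask Tissue [binary_mask]; decimated masks are upsampled by
#'   nearest neighbour.
#' @param band_mm Band width in millimetres (default 2).
#' @return A [binary_mask] named `"peritumoral"`.
#' @export
peritumoral_mask <- function(tumor_mask, tissue_mask, band_mm = 2.0) {
  stopifnot(inherits(tumor_mask, "binary_mask"), band_mm >= 0)
  dmap <- distance_map(tumor_mask)
  tissue <- conform_mask(tissue_mask, dim(tumor_mask$values),
                         tumor_mask$pixel_size_um)$values
  band <- dmap$values > 0 & dmap$values <= band_mm * 1000 & tissue
  binary_mask(band, tumor_mask$pixel_size_um, "peritumoral")
}

#' Per-vessel geometry records
#'
#' For every labeled vessel object: its unweighted centroid (0-based
#' row/col), pixel and physical area, the tumor distance read from the
#' distance map at the pixel nearest the centroid, and the angle of the
#' centroid as seen from the tumor mass centre (see [vessel_angle()]).
#'
#' @param labels Integer label matrix (0 = background), or a
#'   `vessel_segmentation`.
#' @param dmap A [distance_map] co-registered with `labels`.
#' @param tumor_centroid_rc Optional 0-based (row, col) of the tumor mass
#'   centre; when absent, angles are `NA`.
#' @return A tibble with one row per vessel: `label`, `centroid_row`,
#'   `centroid_col`, `area_px`, `area_um2`, `distance_to_tumor_mm`,
#'   `angle_deg`. Carries the pixel size in `attr(, "pixel_size_um")`.
#' @export
vessel_records <- function(labels, dmap, tumor_centroid_rc = NULL) {
  if (inherits(labels, "vessel_segmentation")) labels <- labels$labels
  stopifnot(is.matrix(labels), inherits(dmap, "distance_map"))
  if (!identical(dim(labels), dim(dmap$values)))
    stop("registration error: label map and distance map differ in shape",
         call. = FALSE)
  rec <- label_stats(labels, dmap$pixel_size_um)
  if (nrow(rec) == 0L) {
    rec$distance_to_tumor_mm <- numeric(0)
    rec$angle_deg <- numeric(0)
    attr(rec, "pixel_size_um") <- dmap$pixel_size_um
    return(rec)
  }
  ri <- floor(rec$centroid_row + 0.5) + 1L
  ci <- floor(rec$centroid_col + 0.5) + 1L
  d_um <- dmap$values[cbind(ri, ci)]
  if (any(d_um == 0))
    warning(sum(d_um == 0), " vessel centroid(s) fall on tumor pixels ",
            "(distance 0)")
  rec$distance_to_tumor_mm <- d_um / 1000
  if (is.null(tumor_centroid_rc)) {
    rec$angle_deg <- NA_real_
  } else {
    coincident <- rec$centroid_row == tumor_centroid_rc[1] &
                  rec$centroid_col == tumor_centroid_rc[2]
    ang <- rep(NA_real_, nrow(rec))
    if (any(coincident))
      warning(sum(coincident), " vessel centroid(s) coincide with the tumor ",
              "mass centre; angle set to NA")
    if (any(!coincident))
      ang[!coincident] <- vessel_angle(
        cbind(rec$centroid_row[!coincident], rec$centroid_col[!coincident]),
        tumor_centroid_rc)
    rec$angle_deg <- ang
  }
  attr(rec, "pixel_size_um") <- dmap$pixel_size_um
  rec
}

#' Mass centre of a mask
#'
#' Unweighted centroid of all true pixels, 0-based (row, col). Used for the
#' tumor mass centre even when tumor bundles are disconnected.
#'
#' @param mask A [binary_mask].
#' @return Numeric (row, col).
#' @export
mask_centroid <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$values)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  nr <- nrow(mask$values)
  c(mean((idx - 1L) %% nr), mean((idx - 1L) %/% nr))
}

#' Lymphatic vessel density report
#'
#' LVD is the number of lymphatic vessel sections per square millimetre of
#' stromal tissue. Either supply `records` plus a `region_mask` (a vessel
#' belongs to the region iff the pixel nearest its centroid is in the mask),
#' or supply `vessel_count` and `surface_mm2` directly to reproduce the
#' arithmetic from published counts and surfaces.
#'
#' @param records Tibble from [vessel_records()], or `NULL`.
#' @param region_mask A [binary_mask] delimiting the region, or `NULL`.
#' @param region Region name (`"whole_tissue"`, `"peritumoral"`, or custom).
#' @param vessel_count,surface_mm2 Direct inputs bypassing the rasters.
#' @return A one-row tibble: `region`, `surface_mm2`, `vessel_count`,
#'   `lvd_per_mm2`.
#' @export
compute_lvd <- function(records = NULL, region_mask = NULL,
                        region = "custom", vessel_count = NULL,
                        surface_mm2 = NULL) {
  if (is.null(vessel_count) || is.null(surface_mm2)) {
    if (is.null(records) || is.null(region_mask))
      stop("supply either records + region_mask or vessel_count + surface_mm2",
           call. = FALSE)
    stopifnot(inherits(region_mask, "binary_mask"))
    if (!any(region_mask$values))
      stop("zero-area error: region mask is empty", call. = FALSE)
    surface_mm2 <- mask_area_mm2(region_mask)
    if (nrow(records) == 0L) {
      vessel_count <- 0L
    } else {
      rec_px <- attr(records, "pixel_size_um")
      f <- if (is.null(rec_px)) 1 else region_mask$pixel_size_um / rec_px
      ri <- pmin(pmax(floor(floor(records$centroid_row + 0.5) / f), 0),
                 nrow(region_mask$values) - 1L) + 1L
      ci <- pmin(pmax(floor(floor(records$centroid_col + 0.5) / f), 0),
                 ncol(region_mask$values) - 1L) + 1L
      vessel_count <- sum(region_mask$values[cbind(ri, ci)])
    }
  }
  if (surface_mm2 <= 0)
    stop("zero-area error: surface must be positive", call. = FALSE)
  tibble::tibble(region = region,
                 surface_mm2 = as.numeric(surface_mm2),
                 vessel_count = as.integer(vessel_count),
                 lvd_per_mm2 = vessel_count / surface_mm2)
}

#' Whole-slide example measurements
#'
#' Region surfaces and vessel section counts measured on a whole-slide
#' section of an early invasive cervical carcinoma stained for podoplanin
#' (D2-40), as used in the worked example: the whole tissue section, the
#' 2 mm peritumoral band, and a conventional Weidner-style hot-spot field
#' for comparison.
#'
#' @return A tibble with columns `region`, `surface_mm2`, `vessel_count`.
#' @export
cervical_example_measurements <- function() {
  tibble::tibble(
    region = c("whole_tissue", "peritumoral", "hot_spot"),
    surface_mm2 = c(294.91, 38.21, 0.6),
    vessel_count = c(2084L, 463L, 43L))
}

#' Whole-slide vs hot-spot comparison ratios
#'
#' How much more of the microenvironment the whole-slide measurement covers
#' than a single hot-spot field: the ratio of surfaces and the ratio of
#' vessel counts between a reference region (usually the peritumoral band)
#' and the hot spot.
#'
#' @param measurements Tibble with `region`, `surface_mm2`, `vessel_count`
#'   (default [cervical_example_measurements()]).
#' @param region Reference region name (default `"peritumoral"`).
#' @param hotspot Hot-spot region name (default `"hot_spot"`).
#' @return A one-row tibble: `surface_ratio`, `count_ratio`.
#' @export
hotspot_comparison <- function(measurements = cervical_example_measurements(),
                               region = "peritumoral", hotspot = "hot_spot") {
  a <- measurements[measurements$region == region, ]
  h <- measurements[measurements$region == hotspot, ]
  if (nrow(a) != 1L || nrow(h) != 1L)
    stop("regions not found in measurements", call. = FALSE)
  tibble::tibble(surface_ratio = a$surface_mm2 / h$surface_mm2,
                 count_ratio = a$vessel_count / h$vessel_count)
}
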