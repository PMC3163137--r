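# Image and mask containers, file I/O, decimation.
#
# Coordinate convention used throughout the package: rasters are stored as R
# matrices indexed [row, col] with row 1 at the top of the displayed image.
# All user-facing pixel coordinates (centroids, polygon vertices, tumor mass
# centres) are 0-based, so the centre of the top-left pixel is (0, 0).

DEFAULT_PIXEL_SIZE_UM <- 0.65

#' Construct a slide image
#'
#' A `slide_image` is an 8-bit RGB raster together with the physical size of
#' one pixel edge in micrometres. The pixel size is the unit-bearing root of
#' every physical measurement (areas in mm^2, distances in mm) downstream.
#'
#' @param pixels Integer array of dimension rows x cols x 3 (R, G, B), values
#'   in 0..255.
#' @param pixel_size_um Positive number, micrometres per pixel edge.
#' @return An object of class `slide_image` with elements `pixels` and
#'   `pixel_size_um`.
#' @export
slide_image <- function(pixels, pixel_size_um = DEFAULT_PIXEL_SIZE_UM) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a rows x cols x 3 array", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  px <- array(as.integer(pixels), dim = dim(pixels))
  if (anyNA(px) || min(px) < 0L || max(px) > 255L)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  structure(list(pixels = px, pixel_size_um = as.numeric(pixel_size_um)),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %d x %d px, %.4g um/px (%.3g x %.3g mm)\n",
              d[1], d[2], x$pixel_size_um,
              d[1] * x$pixel_size_um / 1000, d[2] * x$pixel_size_um / 1000))
  invisible(x)
}

#' Construct a binary mask
#'
#' Boolean raster carrying its own physical pixel size and a free-text role
#' tag (`"wall"`, `"lumen"`, `"vessel"`, `"tissue"`, `"tumor"`,
#' `"exclusion"`, ...). A mask decimated by a factor k has pixel size k times
#' that of its source.
#'
#' @param values Logical matrix (rows x cols).
#' @param pixel_size_um Positive number, micrometres per pixel edge.
#' @param name Role tag, free text.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, pixel_size_um = DEFAULT_PIXEL_SIZE_UM,
                        name = "mask") {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask values must not contain NA", call. = FALSE)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be positive", call. = FALSE)
  structure(list(values = values, pixel_size_um = as.numeric(pixel_size_um),
                 name = as.character(name)[1]),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask \"%s\"> %d x %d px, %.4g um/px, %d true (%.3g mm^2)\n",
              x$name, nrow(x$values), ncol(x$values), x$pixel_size_um,
              sum(x$values), mask_area_mm2(x)))
  invisible(x)
}

#' Physical area of the true region of a mask
#'
#' @param mask A [binary_mask].
#' @return Area in mm^2.
#' @export
mask_area_mm2 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * (mask$pixel_size_um / 1000)^2
}

tiff_pixel_size_um <- function(info) {
  xres <- attr(info, "x.resolution")
  unit <- attr(info, "resolution.unit")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  per_um <- switch(if (is.null(unit)) "inch" else unit,
                   inch = xres / 25400, cm = xres / 10000, NULL)
  if (is.null(per_um) || per_um <= 0) return(NULL)
  1 / per_um
}

to_uint8 <- function(arr) {
  a <- floor(arr * 255 + 0.5)
  array(as.integer(a), dim = dim(arr))
}

#' Read an RGB slide image from PNG or TIFF
#'
#' Reads an 8-bit RGB raster. The physical pixel size is resolved in order of
#' precedence: the `pixel_size_um` argument, then TIFF resolution metadata
#' (XResolution/ResolutionUnit) when present, then the default 0.65 um/px of
#' a 100x whole-slide scan, with a warning.
#'
#' @param path Path to a PNG or baseline TIFF file.
#' @param pixel_size_um Optional explicit pixel size (overrides metadata).
#' @return A [slide_image].
#' @export
read_slide <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  meta_px <- NULL
  if (length(magic) >= 4 &&
      identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    arr <- png::readPNG(path)
  } else if (length(magic) >= 2 &&
             (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
              identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (!is.null(bits) && bits > 8)
      stop("format error: bits.per.sample is ", bits,
           ", only 8-bit images are supported", call. = FALSE)
    meta_px <- tiff_pixel_size_um(arr)
  } else {
    stop("cannot decode ", path, ": not a PNG or TIFF file", call. = FALSE)
  }
  if (length(dim(arr)) != 3L)
    stop("format error: image is single-channel, 3-channel RGB required",
         call. = FALSE)
  nch <- dim(arr)[3]
  if (nch == 4L) {
    warning("dropping alpha channel of ", path)
    arr <- arr[, , 1:3, drop = FALSE]
  } else if (nch != 3L) {
    stop("format error: image has ", nch,
         " channels, 3-channel RGB required", call. = FALSE)
  }
  px <- if (!is.null(pixel_size_um)) pixel_size_um else meta_px
  if (is.null(px)) {
    warning("no pixel size given or found in metadata; assuming ",
            DEFAULT_PIXEL_SIZE_UM, " um/px")
    px <- DEFAULT_PIXEL_SIZE_UM
  }
  slide_image(to_uint8(arr), px)
}

#' Write a slide image as PNG
#'
#' @param image A [slide_image].
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_slide <- function(image, path) {
  stopifnot(inherits(image, "slide_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Write a binary mask as PNG with a JSON sidecar
#'
#' The raster goes to a single-channel PNG (0 = false, 255 = true); pixel
#' size and role tag go to `<path>.json`.
#'
#' @param mask A [binary_mask].
#' @param path Output path (PNG); the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$values * 1.0, path)
  jsonlite::write_json(
    list(pixel_size_um = mask$pixel_size_um, name = mask$name),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path PNG path; `<path>.json` is consulted when present.
#' @param pixel_size_um,name Fallbacks when no sidecar exists.
#' @return A [binary_mask].
#' @export
read_mask <- function(path, pixel_size_um = DEFAULT_PIXEL_SIZE_UM,
                      name = "mask") {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$name)) name <- meta$name
  }
  binary_mask(arr > 0.5, pixel_size_um, name)
}

block_pool_sum <- function(mat, factor) {
  ri <- (seq_len(nrow(mat)) - 1L) %/% factor
  ci <- (seq_len(ncol(mat)) - 1L) %/% factor
  m <- rowsum(mat + 0, group = ri, reorder = TRUE)
  out <- t(rowsum(t(m), group = ci, reorder = TRUE))
  dimnames(out) <- NULL
  out
}

check_factor <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != floor(factor))
    stop("`factor` must be a single integer >= 1", call. = FALSE)
  as.integer(factor)
}

#' Decimate a binary mask by block-OR pooling
#'
#' Resolution reduction used before quantification so that gigapixel binary
#' rasters stay tractable. An output pixel is true iff any pixel of its
#' factor x factor source block is true, so no object — however small — is
#' lost. Edge blocks may be smaller than factor x factor. The output pixel
#' size is `factor` times the input pixel size.
#'
#' @param mask A [binary_mask].
#' @param factor Integer >= 1.
#' @return A [binary_mask] of shape `ceiling(dim / factor)`.
#' @export
decimate_binary <- function(mask, factor) {
  stopifnot(inherits(mask, "binary_mask"))
  factor <- check_factor(factor)
  if (factor == 1L) return(mask)
  pooled <- block_pool_sum(mask$values, factor) > 0
  binary_mask(pooled, mask$pixel_size_um * factor, mask$name)
}

#' Decimate a grey-level channel by block-mean pooling
#'
#' Block means are rounded half-up to the nearest integer; edge blocks
#' smaller than factor x factor are averaged over the available pixels.
#'
#' @param channel Numeric matrix of grey levels.
#' @param factor Integer >= 1.
#' @return Integer matrix of shape `ceiling(dim / factor)`.
#' @export
decimate_channel <- function(channel, factor) {
  stopifnot(is.matrix(channel))
  factor <- check_factor(factor)
  if (factor == 1L) {
    out <- floor(channel + 0.5)
    storage.mode(out) <- "integer"
    return(out)
  }
  sums <- block_pool_sum(channel, factor)
  cnts <- block_pool_sum(matrix(1L, nrow(channel), ncol(channel)), factor)
  out <- floor(sums / cnts + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' Upsample a decimated mask back to a reference shape
#'
#' Nearest-neighbour expansion: source pixel at 0-based decimated index i
#' covers full-resolution rows/cols `i * factor .. (i + 1) * factor - 1`.
#'
#' @param mask A [binary_mask] at decimated resolution.
#' @param shape Integer pair, the full-resolution (rows, cols).
#' @param pixel_size_um Pixel size of the full-resolution raster.
#' @return A [binary_mask] of dimension `shape`.
#' @export
upsample_mask <- function(mask, shape, pixel_size_um) {
  stopifnot(inherits(mask, "binary_mask"))
  f <- mask$pixel_size_um / pixel_size_um
  if (abs(f - round(f)) > 1e-6)
    stop("mask pixel size is not an integer multiple of the target",
         call. = FALSE)
  f <- as.integer(round(f))
  ri <- pmin((seq_len(shape[1]) - 1L) %/% f + 1L, nrow(mask$values))
  ci <- pmin((seq_len(shape[2]) - 1L) %/% f + 1L, ncol(mask$values))
  binary_mask(mask$values[ri, ci, drop = FALSE], pixel_size_um, mask$name)
}

# Bring a mask to the shape/pixel size of a full-resolution reference,
# upsampling when needed; error on non-conforming shapes.
conform_mask <- function(mask, shape, pixel_size_um) {
  if (identical(dim(mask$values), as.integer(shape))) return(mask)
  upsample_mask(mask, shape, pixel_size_um)
}

#' Rasterize GeoJSON polygons to a binary mask
#'
#' Accepts a GeoJSON FeatureCollection (path or already-parsed list) of
#' Polygon / MultiPolygon features with vertices in 0-based pixel
#' coordinates, GeoJSON axis order `[x, y] = [col, row]`. Filling uses the
#' even-odd rule at pixel centres, so interior rings become holes.
#'
#' @param geojson Path to a GeoJSON file, or a parsed list.
#' @param shape Integer pair (rows, cols) of the target raster.
#' @param pixel_size_um Pixel size of the target raster.
#' @param name Role tag for the resulting mask.
#' @return A [binary_mask].
#' @export
rasterize_polygons <- function(geojson, shape,
                               pixel_size_um = DEFAULT_PIXEL_SIZE_UM,
                               name = "exclusion") {
  if (is.character(geojson))
    geojson <- jsonlite::read_json(geojson, simplifyVector = FALSE)
  feats <- if (identical(geojson$type, "FeatureCollection")) geojson$features
           else list(geojson)
  out <- matrix(FALSE, shape[1], shape[2])
  for (ft in feats) {
    geom <- if (!is.null(ft$geometry)) ft$geometry else ft
    rings <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    for (ring in rings) {
      xy <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
      out <- xor(out, fill_ring(xy, shape))
    }
  }
  binary_mask(out, pixel_size_um, name)
}

# Even-odd scanline fill of one closed ring; xy is an n x 2 matrix of
# (x = col, y = row) vertices in 0-based pixel-centre coordinates.
fill_ring <- function(xy, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (nrow(xy) < 3) return(m)
  if (!all(xy[1, ] == xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
  x <- xy[, 1]; y <- xy[, 2]
  r_lo <- max(0L, ceiling(min(y))); r_hi <- min(shape[1] - 1L, floor(max(y)))
  if (r_lo > r_hi) return(m)
  n <- nrow(xy) - 1L
  for (r in r_lo:r_hi) {
    crossings <- numeric(0)
    for (i in seq_len(n)) {
      y1 <- y[i]; y2 <- y[i + 1]
      if ((y1 <= r) != (y2 <= r)) {
        crossings <- c(crossings, x[i] + (r - y1) * (x[i + 1] - x[i]) / (y2 - y1))
      }
    }
    crossings <- sort(crossings)
    for (k in seq_len(length(crossings) %/% 2)) {
      a <- crossings[2 * k - 1]; b <- crossings[2 * k]
      c_lo <- max(0L, ceiling(a)); c_hi <- min(shape[2] - 1L, ceiling(b) - 1L)
      if (c_lo <= c_hi) m[r + 1L, (c_lo:c_hi) + 1L] <- TRUE
    }
  }
  m
}
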