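# Ground-truthed synthetic stained-slide generator.
#
# Emulates the appearance of a podoplanin/permanent-red stained section with
# hematoxylin counterstain: near-white glass, a pink-blue tissue blob, red
# annular vessel walls with bright lumens, distinctly recolored tumor blobs,
# and optional podoplanin-positive tumor-cell clumps (confounders) rendered
# in wall colour inside the tumor. A single RNG stream seeded from `seed`
# governs all placements and noise.

SYNTH_COLORS <- list(
  glass  = c(245, 245, 248),
  tissue = c(195, 180, 160),
  wall   = c(200, 40, 60),
  lumen  = c(242, 242, 242),
  tumor  = c(120, 190, 140))

#' Synthetic slide configuration
#'
#' Defaults describe the standard validation condition used throughout the
#' package: a 2000 x 2000 px tile at 0.65 um/px (1.3 x 1.3 mm), 50 vessel
#' sections of 15-45 um outer radius with 5 um walls, one tumor blob of
#' 150-250 um radius, and Gaussian pixel noise of sigma 5.
#'
#' @param image_size_px Integer pair (rows, cols).
#' @param pixel_size_um Micrometres per pixel edge.
#' @param n_vessels Number of vessel sections to place.
#' @param vessel_radius_um (min, max) outer radius of a vessel section, um.
#' @param wall_thickness_um Stained wall thickness, um.
#' @param n_tumor_blobs Number of tumor blobs.
#' @param tumor_radius_um (min, max) tumor blob radius, um.
#' @param anisotropy Optional (low, high) angular interval in degrees
#'   (counter-clockwise, 0 = right) confining vessel placement as seen from
#'   the tumor mass centre.
#' @param clustering_band_mm Optional (low, high) radial band (distance from
#'   the tumor edge, mm) for a `clustering_fraction` of vessels.
#' @param clustering_fraction Fraction of vessels placed in the band.
#' @param n_confounders Podoplanin-positive tumor clumps rendered in wall
#'   colour inside the tumor.
#' @param noise_sigma Gaussian pixel noise standard deviation (grey levels).
#' @param seed RNG seed; the only entropy source.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(image_size_px = c(2000, 2000),
                         pixel_size_um = 0.65,
                         n_vessels = 50,
                         vessel_radius_um = c(15, 45),
                         wall_thickness_um = 5,
                         n_tumor_blobs = 1,
                         tumor_radius_um = c(150, 250),
                         anisotropy = NULL,
                         clustering_band_mm = NULL,
                         clustering_fraction = 1,
                         n_confounders = 0,
                         noise_sigma = 5,
                         seed = 0) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid `", field, "`: ", msg, call. = FALSE)
  chk(length(image_size_px) == 2 && all(image_size_px >= 64),
      "image_size_px", "need two dimensions >= 64")
  chk(pixel_size_um > 0, "pixel_size_um", "must be positive")
  chk(n_vessels >= 0, "n_vessels", "must be >= 0")
  chk(all(vessel_radius_um > 0) && vessel_radius_um[1] <= vessel_radius_um[2],
      "vessel_radius_um", "need 0 < min <= max")
  chk(wall_thickness_um > 0 && wall_thickness_um < vessel_radius_um[1],
      "wall_thickness_um", "must be positive and below the smallest radius")
  chk(n_tumor_blobs >= 0, "n_tumor_blobs", "must be >= 0")
  chk(all(tumor_radius_um > 0) && tumor_radius_um[1] <= tumor_radius_um[2],
      "tumor_radius_um", "need 0 < min <= max")
  chk(is.null(anisotropy) ||
        (length(anisotropy) == 2 && anisotropy[1] < anisotropy[2]),
      "anisotropy", "need (low, high) degrees with low < high")
  chk(is.null(clustering_band_mm) ||
        (length(clustering_band_mm) == 2 &&
         clustering_band_mm[1] < clustering_band_mm[2]),
      "clustering_band_mm", "need (low, high) mm with low < high")
  chk(clustering_fraction >= 0 && clustering_fraction <= 1,
      "clustering_fraction", "must be in [0, 1]")
  chk(n_confounders >= 0, "n_confounders", "must be >= 0")
  chk(noise_sigma >= 0, "noise_sigma", "must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be one number")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_um = vessel_radius_um,
                 wall_thickness_um = wall_thickness_um,
                 n_tumor_blobs = as.integer(n_tumor_blobs),
                 tumor_radius_um = tumor_radius_um,
                 anisotropy = anisotropy,
                 clustering_band_mm = clustering_band_mm,
                 clustering_fraction = clustering_fraction,
                 n_confounders = as.integer(n_confounders),
                 noise_sigma = noise_sigma,
                 seed = seed),
            class = "synth_config")
}

#' Read a synthetic slide configuration from YAML
#'
#' @param path YAML file with any subset of [synth_config()] fields.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(synth_config, vals)
}

#' Write a synthetic slide configuration to YAML
#'
#' @param config A `synth_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_synth_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Paint colour `col` at positions `sel` (logical matrix) of pixel array.
paint <- function(px, sel, col) {
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[sel] <- col[ch]
    px[, , ch] <- plane
  }
  px
}

# Wobbled disc: radius modulated by low-order harmonics so blobs are not
# perfect circles. Returns a logical matrix over the given 0-based grids.
wobbled_disc <- function(rr, cc, center, radius, amp = c(0.08, 0.05),
                         phase = c(0, 0)) {
  dr <- rr - center[1]; dc <- cc - center[2]
  theta <- atan2(dr, dc)
  rad <- radius * (1 + amp[1] * sin(3 * theta + phase[1]) +
                       amp[2] * sin(5 * theta + phase[2]))
  dr * dr + dc * dc <= rad * rad
}

#' Generate a synthetic stained slide with ground truth
#'
#' Renders glass background, a wobbled tissue blob, tumor blobs, annular
#' vessel walls with bright lumens, optional confounder clumps, then adds
#' clipped Gaussian noise. Placement is by rejection sampling; an error
#' names the violated constraint after 10^4 failed draws.
#'
#' @param config A [synth_config()].
#' @return A list with elements `image` (a [slide_image]) and `truth`, a
#'   list holding `vessel_labels` (integer matrix), `tumor_mask`,
#'   `tissue_mask`, `confounder_mask` ([binary_mask]s), `tumor_centroid_rc`
#'   (0-based, or NULL), and `vessels` — a tibble with the true label,
#'   centroid, outer radius, tumor distance and angle of every vessel.
#' @export
generate_slide <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  upp <- config$pixel_size_um
  rr <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)

  # tissue blob centred in the frame
  center <- c((nr - 1) / 2, (nc - 1) / 2)
  tissue <- wobbled_disc(rr, cc, center, 0.46 * min(nr, nc),
                         amp = c(0.06, 0.04),
                         phase = stats::runif(2, 0, 2 * pi))
  px <- array(0L, dim = c(nr, nc, 3))
  for (ch in 1:3) px[, , ch] <- SYNTH_COLORS$glass[ch]
  px <- paint(px, tissue, SYNTH_COLORS$tissue)
  dt_tissue <- as.matrix(EBImage::distmap(tissue + 0))   # px to tissue edge

  fail <- function(what) stop("placement error: cannot satisfy `", what,
                              "` after 10000 draws", call. = FALSE)

  # tumor blobs, fully inside tissue
  tumor <- matrix(FALSE, nr, nc)
  for (b in seq_len(config$n_tumor_blobs)) {
    r_um <- stats::runif(1, config$tumor_radius_um[1], config$tumor_radius_um[2])
    rpx <- r_um / upp
    elig <- which(dt_tissue >= rpx * 1.15 + 2)
    if (length(elig) == 0) fail("tumor_radius_um")
    idx <- elig[sample.int(length(elig), 1)]
    ctr <- c((idx - 1) %% nr, (idx - 1) %/% nr)
    blob <- wobbled_disc(rr, cc, ctr, rpx,
                         phase = stats::runif(2, 0, 2 * pi))
    tumor <- tumor | blob
  }
  has_tumor <- any(tumor)
  d_tumor_px <- if (has_tumor)
    as.matrix(EBImage::distmap(1 - (tumor + 0))) else NULL
  tumor_ctr <- if (has_tumor) {
    idx <- which(tumor)
    c(mean((idx - 1) %% nr), mean((idx - 1) %/% nr))
  } else NULL
  px <- paint(px, tumor, SYNTH_COLORS$tumor)

  # vessels: annular walls + bright lumens, in stroma, non-overlapping
  labels <- matrix(0L, nr, nc)
  wall_px <- config$wall_thickness_um / upp
  max_out <- config$vessel_radius_um[2] / upp
  margin <- max_out + 3
  elig_base <- dt_tissue >= margin
  if (has_tumor) elig_base <- elig_base & d_tumor_px > margin
  elig_idx <- which(elig_base)
  placed <- matrix(numeric(0), ncol = 3)   # row, col, outer radius (px)
  vs <- vector("list", config$n_vessels)
  for (i in seq_len(config$n_vessels)) {
    r_out_um <- stats::runif(1, config$vessel_radius_um[1],
                             config$vessel_radius_um[2])
    r_out <- r_out_um / upp
    use_band <- !is.null(config$clustering_band_mm) &&
      (config$clustering_fraction >= 1 ||
       stats::runif(1) < config$clustering_fraction)
    ok <- FALSE
    for (try in seq_len(10000L)) {
      if (use_band || !is.null(config$anisotropy)) {
        if (!has_tumor) fail("clustering_band_mm (no tumor present)")
        theta <- if (!is.null(config$anisotropy))
          stats::runif(1, config$anisotropy[1], config$anisotropy[2]) else
          stats::runif(1, 0, 360)
        band <- if (use_band) config$clustering_band_mm * 1000 else
          c(0, max(d_tumor_px) * upp)
        d_target <- stats::runif(1, max(band[1], (r_out + 3) * upp), band[2])
        dirv <- c(-sin(theta * pi / 180), cos(theta * pi / 180))
        # walk outward from the tumor mass centre to the target edge distance
        tmax <- max(nr, nc)
        pos <- NULL
        for (step in seq(5, tmax, by = 5)) {
          p <- round(tumor_ctr + step * dirv)
          if (any(p < 0) || p[1] >= nr || p[2] >= nc) break
          if (d_tumor_px[p[1] + 1, p[2] + 1] * upp >= d_target) {
            pos <- p; break
          }
        }
        if (is.null(pos)) next
        r0 <- pos[1]; c0 <- pos[2]
      } else {
        if (length(elig_idx) == 0) fail("vessel_radius_um (no eligible area)")
        idx <- elig_idx[sample.int(length(elig_idx), 1)]
        r0 <- (idx - 1) %% nr; c0 <- (idx - 1) %/% nr
      }
      if (dt_tissue[r0 + 1, c0 + 1] < r_out + 2) next
      if (has_tumor && d_tumor_px[r0 + 1, c0 + 1] <= r_out + 2) next
      if (use_band &&
          d_tumor_px[r0 + 1, c0 + 1] * upp > config$clustering_band_mm[2] * 1000)
        next
      if (nrow(placed) > 0) {
        dd <- sqrt((placed[, 1] - r0)^2 + (placed[, 2] - c0)^2)
        if (any(dd < placed[, 3] + r_out + 3)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) fail("n_vessels (overlap-free placement)")
    placed <- rbind(placed, c(r0, c0, r_out))
    # render locally
    w <- ceiling(r_out + 2)
    rs <- max(1, r0 + 1 - w):min(nr, r0 + 1 + w)
    cs <- max(1, c0 + 1 - w):min(nc, c0 + 1 + w)
    ld <- sqrt(outer((rs - 1 - r0)^2, (cs - 1 - c0)^2, "+"))
    r_in <- r_out - wall_px
    for (ch in 1:3) {
      plane <- px[rs, cs, ch]
      plane[ld <= r_in] <- SYNTH_COLORS$lumen[ch]
      plane[ld > r_in & ld <= r_out] <- SYNTH_COLORS$wall[ch]
      px[rs, cs, ch] <- plane
    }
    lab_w <- labels[rs, cs]
    lab_w[ld <= r_out] <- i
    labels[rs, cs] <- lab_w
    vs[[i]] <- tibble::tibble(label = i, centroid_row = r0, centroid_col = c0,
                              radius_um = r_out_um)
  }
  vessels <- if (config$n_vessels > 0) dplyr::bind_rows(vs) else
    tibble::tibble(label = integer(0), centroid_row = numeric(0),
                   centroid_col = numeric(0), radius_um = numeric(0))

  # confounders: podoplanin-positive tumor clumps in wall colour
  confounder <- matrix(FALSE, nr, nc)
  if (config$n_confounders > 0) {
    if (!has_tumor) fail("n_confounders (no tumor to host them)")
    dt_in_tumor <- as.matrix(EBImage::distmap(tumor + 0))
    for (k in seq_len(config$n_confounders)) {
      r_um <- stats::runif(1, 10, 25)
      rpx <- r_um / upp
      elig <- which(dt_in_tumor >= rpx + 2 & !confounder)
      if (length(elig) == 0) fail("n_confounders")
      idx <- elig[sample.int(length(elig), 1)]
      ctr <- c((idx - 1) %% nr, (idx - 1) %/% nr)
      blob <- wobbled_disc(rr, cc, ctr, rpx,
                           phase = stats::runif(2, 0, 2 * pi))
      confounder <- confounder | blob
    }
    px <- paint(px, confounder, SYNTH_COLORS$wall)
  }

  # pixel noise
  if (config$noise_sigma > 0) {
    px <- px + stats::rnorm(length(px), 0, config$noise_sigma)
    px <- pmin(pmax(floor(px + 0.5), 0), 255)
    px <- array(as.integer(px), dim = c(nr, nc, 3))
  }

  # true distances/angles from the rendered tumor
  if (has_tumor && nrow(vessels) > 0) {
    d_um <- d_tumor_px[cbind(vessels$centroid_row + 1,
                             vessels$centroid_col + 1)] * upp
    vessels$distance_to_tumor_mm <- d_um / 1000
    vessels$angle_deg <- vessel_angle(
      cbind(vessels$centroid_row, vessels$centroid_col), tumor_ctr)
  } else {
    vessels$distance_to_tumor_mm <- rep(NA_real_, nrow(vessels))
    vessels$angle_deg <- rep(NA_real_, nrow(vessels))
  }

  list(
    image = slide_image(px, upp),
    truth = list(
      vessel_labels = labels,
      tumor_mask = binary_mask(tumor, upp, "tumor"),
      tissue_mask = binary_mask(tissue, upp, "tissue"),
      confounder_mask = binary_mask(confounder, upp, "exclusion"),
      tumor_centroid_rc = tumor_ctr,
      vessels = vessels))
}

#' Generate the anisotropic validation scenario
#'
#' Vessels are confined to the angular half (90, 270) degrees as seen from
#' the tumor mass centre and to the (0, 2] mm radial band around the tumor
#' edge — the configuration whose directional profile must be empty in the
#' sectors centred at 315, 0 and 45 degrees. Rendered at 2 um/px on a
#' 2000 x 2000 frame (4 x 4 mm) so the 2 mm band fits around a centred
#' tumor.
#'
#' @param seed RNG seed.
#' @return As [generate_slide()].
#' @export
generate_anisotropic_case <- function(seed = 0) {
  generate_slide(synth_config(
    image_size_px = c(2000, 2000), pixel_size_um = 2.0,
    n_vessels = 50, vessel_radius_um = c(20, 45), wall_thickness_um = 6,
    n_tumor_blobs = 1, tumor_radius_um = c(250, 350),
    anisotropy = c(91, 269), clustering_band_mm = c(0, 2),
    noise_sigma = 5, seed = seed))
}

#' Match detected vessel objects to ground truth
#'
#' A detected object matches a true vessel when their intersection over
#' union reaches `iou`. Recall is the fraction of true vessels with a
#' matching detection; precision the fraction of detections matching a true
#' vessel.
#'
#' @param truth_labels Ground-truth label matrix (from `generate_slide()`).
#' @param detected_labels Detected label matrix (e.g.
#'   `segment_slide(...)$labels`), same shape.
#' @param iou Intersection-over-union threshold (default 0.3).
#' @return A one-row tibble: `n_true`, `n_detected`, `n_matched_true`,
#'   `n_matched_detected`, `recall`, `precision`.
#' @export
evaluate_detection <- function(truth_labels, detected_labels, iou = 0.3) {
  if (inherits(detected_labels, "vessel_segmentation"))
    detected_labels <- detected_labels$labels
  stopifnot(identical(dim(truth_labels), dim(detected_labels)))
  n_true <- max(truth_labels); n_det <- max(detected_labels)
  a_true <- tabulate(truth_labels[truth_labels > 0L], nbins = max(n_true, 1))
  a_det <- tabulate(detected_labels[detected_labels > 0L],
                    nbins = max(n_det, 1))
  n_true_obj <- sum(a_true > 0); n_det_obj <- sum(a_det > 0)
  both <- truth_labels > 0L & detected_labels > 0L
  matched_t <- logical(n_true); matched_d <- logical(n_det)
  if (any(both)) {
    key <- (as.numeric(detected_labels[both]) - 1) * n_true +
      truth_labels[both]
    inter <- tabulate(key, nbins = n_true * n_det)
    pair <- which(inter > 0)
    pt <- (pair - 1L) %% n_true + 1L
    pd <- (pair - 1L) %/% n_true + 1L
    iou_val <- inter[pair] / (a_true[pt] + a_det[pd] - inter[pair])
    matched_t[unique(pt[iou_val >= iou])] <- TRUE
    matched_d[unique(pd[iou_val >= iou])] <- TRUE
  }
  tibble::tibble(
    n_true = n_true_obj, n_detected = n_det_obj,
    n_matched_true = sum(matched_t), n_matched_detected = sum(matched_d),
    recall = if (n_true_obj > 0) sum(matched_t) / n_true_obj else NA_real_,
    precision = if (n_det_obj > 0) sum(matched_d) / n_det_obj else NA_real_)
}
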