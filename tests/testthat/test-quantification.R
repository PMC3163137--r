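test_that("distance map is the exact Euclidean transform in micrometres", {
  full <- binary_mask(matrix(TRUE, 8, 8), 1, "tumor")
  expect_true(all(distance_map(full)$values == 0))

  one <- binary_mask(matrix(FALSE, 10, 10), 1, "tumor")
  one$values[1, 1] <- TRUE
  d <- distance_map(one)
  expect_equal(d$values[4, 5], 5.0)   # 3-4-5 triangle from (0,0)
  expect_equal(d$values[1, 1], 0.0)

  expect_error(distance_map(binary_mask(matrix(FALSE, 5, 5), 1)), "no-tumor")

  set.seed(3)
  tum <- matrix(runif(32 * 32) < 0.05, 32, 32)
  if (!any(tum)) tum[7, 21] <- TRUE
  m <- binary_mask(tum, 2.5, "tumor")
  expect_lt(max(abs(distance_map(m)$values - oracle_distance(tum, 2.5))),
            1e-6)
})

test_that("distance map scales linearly with pixel size", {
  set.seed(31)
  tum <- matrix(runif(400) < 0.1, 20, 20)
  d1 <- distance_map(binary_mask(tum, 1, "tumor"))
  d2 <- distance_map(binary_mask(tum, 2, "tumor"))
  expect_equal(d2$values, 2 * d1$values)
})

test_that("peritumoral band matches the analytic annulus", {
  # 100 um tumor disc, 10 um pixels, all-tissue frame, 2 mm band
  nr <- 460
  tumor <- disc_mask(nr, nr, c(229.5, 229.5), 10, pixel_size_um = 10)
  tissue <- binary_mask(matrix(TRUE, nr, nr), 10, "tissue")
  band <- peritumoral_mask(tumor, tissue, band_mm = 2)
  area_um2 <- sum(band$values) * 100
  analytic <- pi * (2100^2 - 100^2)
  expect_lt(abs(area_um2 - analytic) / analytic, 0.02)

  empty_tissue <- binary_mask(matrix(FALSE, nr, nr), 10, "tissue")
  expect_equal(sum(peritumoral_mask(tumor, empty_tissue, 2)$values), 0)
  expect_equal(sum(peritumoral_mask(tumor, tissue, 0)$values), 0)
  expect_false(any(band$values & tumor$values))
})

test_that("vessel records hold centroids, areas, distances and angles", {
  labels <- matrix(0L, 12, 12)
  labels[1:3, 1:3] <- 1L
  tumor <- binary_mask(matrix(FALSE, 12, 12), 1, "tumor")
  tumor$values[12, 12] <- TRUE
  rec <- vessel_records(labels, distance_map(tumor), c(11, 11))
  expect_equal(rec$centroid_row, 1.0)
  expect_equal(rec$centroid_col, 1.0)
  expect_equal(rec$area_px, 9L)
  expect_equal(rec$area_um2, 9)
  expect_equal(rec$distance_to_tumor_mm, sqrt(200) / 1000)

  # centroid on a tumor pixel: distance 0 with a warning
  labels2 <- matrix(0L, 12, 12); labels2[11:12, 11:12] <- 1L
  tumor2 <- binary_mask(matrix(FALSE, 12, 12), 1, "tumor")
  tumor2$values[11:12, 11:12] <- TRUE
  expect_warning(rec2 <- vessel_records(labels2, distance_map(tumor2)),
                 "tumor")
  expect_equal(rec2$distance_to_tumor_mm, 0)

  # empty label map: empty tibble, not an error
  rec3 <- vessel_records(matrix(0L, 5, 5),
                         distance_map(disc_mask(5, 5, c(2, 2), 1)))
  expect_equal(nrow(rec3), 0)
})

test_that("centroids equal brute-force per-label coordinate means", {
  set.seed(4)
  labels <- matrix(0L, 80, 80)
  for (i in 1:20) {
    r <- sample(5:75, 1); c <- sample(5:75, 1); rad <- sample(2:4, 1)
    rr <- matrix(seq_len(80) - 1, 80, 80)
    cc <- matrix(seq_len(80) - 1, 80, 80, byrow = TRUE)
    sel <- (rr - r)^2 + (cc - c)^2 <= rad^2 & labels == 0L
    labels[sel] <- i
  }
  tumor <- disc_mask(80, 80, c(1, 1), 1)
  rec <- vessel_records(labels, distance_map(tumor), c(1, 1))
  for (i in rec$label) {
    idx <- which(labels == i, arr.ind = TRUE)
    expect_equal(rec$centroid_row[rec$label == i], mean(idx[, 1] - 1))
    expect_equal(rec$centroid_col[rec$label == i], mean(idx[, 2] - 1))
  }
})

test_that("LVD reports divide count by surface and stay consistent", {
  r <- compute_lvd(vessel_count = 0, surface_mm2 = 12.5, region = "empty")
  expect_equal(r$lvd_per_mm2, 0)

  set.seed(41)
  for (k in 1:10) {
    n <- sample(0:3000, 1); s <- runif(1, 1, 400)
    rep <- compute_lvd(vessel_count = n, surface_mm2 = s)
    expect_lt(abs(rep$lvd_per_mm2 * rep$surface_mm2 - rep$vessel_count), 0.5)
  }
  expect_error(compute_lvd(vessel_count = 5, surface_mm2 = 0), "zero-area")
})

test_that("region membership by centroid is additive over disjoint regions", {
  set.seed(42)
  labels <- matrix(0L, 60, 60)
  for (i in 1:15) labels[sample(3:58, 1) + 0:1, sample(3:58, 1) + 0:1] <- i
  tumor <- disc_mask(60, 60, c(0, 0), 1)
  rec <- vessel_records(labels, distance_map(tumor), c(0, 0))
  left <- binary_mask(cbind(matrix(TRUE, 60, 30), matrix(FALSE, 60, 30)), 1)
  right <- binary_mask(cbind(matrix(FALSE, 60, 30), matrix(TRUE, 60, 30)), 1)
  whole <- binary_mask(matrix(TRUE, 60, 60), 1)
  nA <- compute_lvd(rec, left, "A")$vessel_count
  nB <- compute_lvd(rec, right, "B")$vessel_count
  nAB <- compute_lvd(rec, whole, "AB")$vessel_count
  expect_equal(nA + nB, nAB)
  expect_equal(nAB, length(unique(labels[labels > 0])))
  expect_error(compute_lvd(rec, binary_mask(matrix(FALSE, 60, 60), 1)),
               "zero-area")
})

test_that("membership maps full-resolution centroids into decimated masks", {
  labels <- matrix(0L, 64, 64)
  labels[10:12, 10:12] <- 1L   # centroid (10, 10) 0-based
  labels[50:52, 50:52] <- 2L
  tumor <- disc_mask(64, 64, c(0, 0), 1)
  rec <- vessel_records(labels, distance_map(tumor), c(0, 0))
  # decimated region covering only the top-left quadrant
  region <- binary_mask(rbind(c(TRUE, FALSE), c(FALSE, FALSE)), 32, "custom")
  r <- compute_lvd(rec, region, "custom")
  expect_equal(r$vessel_count, 1L)
  expect_equal(r$surface_mm2, (32 / 1000)^2)
})

test_that("doubling pixel size doubles distances and quadruples surfaces", {
  out <- small_synth(seed = 6)
  seg <- segment_slide(out$image)
  tum <- out$truth$tumor_mask
  tum2 <- binary_mask(tum$values, tum$pixel_size_um * 2, "tumor")
  rec1 <- vessel_records(seg$labels, distance_map(tum))
  rec2 <- vessel_records(seg$labels, distance_map(tum2))
  expect_equal(rec2$distance_to_tumor_mm, 2 * rec1$distance_to_tumor_mm)
  expect_equal(rec2$area_um2, 4 * rec1$area_um2)
  m <- binary_mask(out$truth$tissue_mask$values, 1.3, "tissue")
  expect_equal(mask_area_mm2(m), 4 * mask_area_mm2(out$truth$tissue_mask))
})

test_that("hot-spot comparison ratios come from the measurement table", {
  hc <- hotspot_comparison()
  tab <- cervical_example_measurements()
  expect_equal(hc$surface_ratio,
               tab$surface_mm2[tab$region == "peritumoral"] / 0.6)
  expect_equal(hc$count_ratio,
               tab$vessel_count[tab$region == "peritumoral"] / 43)
})
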