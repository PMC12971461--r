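test_that("segmentation recovers ideal disks to pixel precision", {
  blank <- matrix(0.1, 200, 200)
  expect_equal(nrow(segment_particles(blank, 0.1)$particles), 0)
  noisy_blank <- gen_puncta_image(
    image_spec(puncta_per_layer = c(I = 0, II = 0, III = 0)))
  expect_equal(nrow(segment_particles(noisy_blank$image, 0.1)$particles),
               0)

  # one disk of radius 5 px at pixel 0.1 um: area within 10% of pi r^2
  img <- matrix(0.1, 100, 100)
  for (i in 1:100) for (j in 1:100)
    if ((i - 50)^2 + (j - 50)^2 <= 25) img[i, j] <- 0.9
  seg <- segment_particles(img, 0.1)
  expect_equal(nrow(seg$particles), 1)
  expect_lt(abs(seg$particles$area_um2 - pi * 0.5^2) / (pi * 0.5^2), 0.10)

  # 50 generated non-overlapping disks: every component matches its
  # ground-truth pixel count exactly
  sp <- image_spec(field_size = c(60, 60), pixel_size = 0.1,
                   layer_bands = list(A = c(0, 60)),
                   puncta_per_layer = c(A = 50), area_mean = 0.8,
                   area_sd = 0.3, area_range = c(0.3, 2),
                   circularity_range = c(1, 1), seed = 8)
  out <- gen_puncta_image(sp)
  seg <- segment_particles(out$image, out$pixel_size)
  expect_equal(nrow(seg$particles), 50)
  for (i in seq_len(50)) {
    d <- sqrt((seg$particles$cx_um - out$ground_truth$cx_um[i])^2 +
                (seg$particles$cy_um - out$ground_truth$cy_um[i])^2)
    j <- which.min(d)
    expect_lte(abs(seg$particles$area_px[j] - out$ground_truth$area_px[i]),
               1)
  }
  expect_error(segment_particles(out$image, NULL), "calibration")
})

test_that("particle filters retain exactly the published windows, inclusively", {
  tab <- data.frame(area_um2 = c(0.04, 0.05, 3.0, 3.05),
                    circularity = 0.9)
  kept <- apply_filter(tab, glast_filter())
  expect_equal(kept$area_um2, c(0.05, 3.0))

  circ <- data.frame(area_um2 = 1, circularity = c(0.2, 0.3, 1.0))
  expect_equal(apply_filter(circ, glast_filter())$circularity, c(0.3, 1.0))

  gfap <- data.frame(area_um2 = c(0.9, 1.0, 50), circularity = 0.5)
  expect_equal(apply_filter(gfap, gfap_filter())$area_um2, c(1, 50))

  empty <- tab[0, ]
  expect_equal(nrow(apply_filter(empty)), 0)
})

test_that("apply_filter is idempotent and row-order independent", {
  set.seed(9)
  tab <- data.frame(area_um2 = runif(200, 0, 4),
                    circularity = runif(200))
  once <- apply_filter(tab)
  expect_identical(apply_filter(once), once)
  shuffled <- tab[sample(nrow(tab)), ]
  resh <- apply_filter(shuffled)
  expect_setequal(rownames(resh), rownames(once))
})

test_that("layer metrics compute the documented arithmetic and recover generator totals", {
  one <- data.frame(area_um2 = 2, cy_um = 5)
  roi <- layer_roi(width_um = 10, depth_range = c(0, 10), label = "II")
  m <- layer_metrics(one, roi)
  expect_equal(m$coverage_pct, 2)
  expect_equal(m$density_per_1000um2, 10)
  expect_equal(m$mean_area_um2, 2)

  none <- layer_metrics(one[0, ], roi)
  expect_true(is.na(none$mean_area_um2))
  expect_equal(none$coverage_pct, 0)
  expect_equal(none$density_per_1000um2, 0)

  sp <- image_spec(seed = 10)
  out <- gen_puncta_image(sp)
  seg <- segment_particles(out$image, out$pixel_size)
  for (layer in c("I", "II", "III")) {
    band <- sp$layer_bands[[layer]]
    roi <- layer_roi(100, band, layer)
    m <- layer_metrics(seg$particles, roi)
    gt <- out$ground_truth[out$ground_truth$layer == layer, ]
    expect_equal(m$n, nrow(gt))
    gt_cov <- 100 * sum(gt$area_px * out$pixel_size^2) / roi$area_um2
    expect_lt(abs(m$coverage_pct - gt_cov) / gt_cov, 0.05)
    expect_lt(abs(m$mean_area_um2 -
                    mean(gt$area_px * out$pixel_size^2)) /
                m$mean_area_um2, 0.05)
  }
})

test_that("coverage of an ideal mask equals total true area over ROI area", {
  sp <- image_spec(field_size = c(50, 30), pixel_size = 0.1,
                   layer_bands = list(A = c(0, 30)),
                   puncta_per_layer = c(A = 20), seed = 12)
  out <- gen_puncta_image(sp)
  seg <- segment_particles(out$image, out$pixel_size)
  roi <- layer_roi(50, c(0, 30), "A")
  m <- layer_metrics(seg$particles, roi)
  expect_equal(m$coverage_pct,
               100 * sum(out$ground_truth$area_px * 0.1^2) / roi$area_um2,
               tolerance = 1e-6)
})

test_that("layer I subdivides into equal thirds that partition the ROI", {
  roi <- layer_roi(width_um = 80, depth_range = c(0, 30), label = "I")
  subs <- subdivide_layer1(roi)
  expect_equal(vapply(subs, function(s) s$label, ""),
               c("I-1", "I-2", "I-3"))
  expect_equal(vapply(subs, function(s) diff(s$depth_range), 1),
               rep(10, 3))
  expect_equal(sum(vapply(subs, function(s) s$area_um2, 1)),
               roi$area_um2)
  # bands partition: half-open metrics assign each punctum exactly once
  pts <- data.frame(area_um2 = 1, cy_um = seq(0.5, 29.5, by = 1))
  counts <- vapply(subs, function(s) layer_metrics(pts, s)$n, 1)
  expect_equal(sum(counts), nrow(pts))
  expect_error(layer_roi(10, c(5, 5)), "degenerate")
})
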