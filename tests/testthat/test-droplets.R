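test_that("a blank noise field yields no condensates and an empty summary", {
  fs <- field_spec(seed = 201)
  sf <- render_droplet_field(fs, random_droplets(fs, 0, seed = 201))
  q <- quant_droplets(sf$image)
  expect_equal(nrow(q$records), 0)
  expect_equal(q$density, 0)
  expect_equal(nrow(q$summary), 0)
})

test_that("a 1.0 um disk at 10x background is found with its diameter", {
  fs <- field_spec(bg_sd = 2, seed = 202)
  dr <- random_droplets(fs, 1, diameter_um = 1.0, partition_ratio = 10, seed = 202)
  sf <- render_droplet_field(fs, dr)
  rec <- detect_condensates(sf$image)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$equivalent_diameter_um, 1.0, tolerance = 0.15)
})

test_that("the 0.5 um diameter filter is definitional", {
  fs <- field_spec(seed = 203)
  small <- random_droplets(fs, 10, diameter_um = 0.3, partition_ratio = 8,
                           seed = 203)
  sf <- render_droplet_field(fs, small)
  expect_equal(nrow(detect_condensates(sf$image)), 0)
  # lowering the diameter threshold shows they were intensity-detected
  cfg <- detection_config(min_diameter_um = 0.1)
  expect_gt(nrow(detect_condensates(sf$image, config = cfg)), 0)
})

test_that("partition ratios are simple intensity ratios with guarded input", {
  expect_equal(partition_ratio(890, 100), 8.9)
  bg <- estimate_background(field_image(matrix(100, 32, 32), 0.1))
  expect_equal(partition_ratio(100, bg), 1.0)
  expect_error(partition_ratio(890, 0), "positive")
})

test_that("true partition ratios are recovered by the full recipe", {
  sf <- demo_droplet_field(seed = 204, n = 40, partition_ratio = 7.7,
                           width_px = 512, height_px = 512)
  q <- quant_droplets(sf$image)
  expect_gte(nrow(q$records), 35)
  expect_equal(median(q$records$partition_ratio), 7.7, tolerance = 0.10)
})

test_that("density normalizes counts to the imaging-view area", {
  recs <- tibble::tibble(label = 1:15)
  img1 <- field_image(matrix(100, 10, 443), 1)   # exactly 4430 um^2
  img2 <- field_image(matrix(100, 20, 443), 1)   # exactly 8860 um^2
  expect_equal(droplet_density(recs, img1), 15)
  expect_equal(droplet_density(recs, img2), 7.5)
})

test_that("summaries are order-invariant and match single records", {
  sf <- demo_droplet_field(seed = 205, n = 20)
  rec <- quant_droplets(sf$image)$records
  s1 <- summarize_droplets(rec)
  s2 <- summarize_droplets(rec[sample(nrow(rec)), ])
  expect_equal(s1, s2)
  one <- summarize_droplets(rec[3, ])
  expect_equal(one$median[one$metric == "partition_ratio"],
               rec$partition_ratio[3])
  # pooled diameters drawn from 1.4-1.8 um land inside that interval
  med <- s1$median[s1$metric == "equivalent_diameter_um"]
  expect_gte(med, 1.4); expect_lte(med, 1.8)
})

test_that("detection is scale invariant and monotone in the threshold multiplier", {
  sf <- demo_droplet_field(seed = 206, n = 12)
  q1 <- quant_droplets(sf$image)
  scaled <- field_image(sf$image$data * 3.7, sf$image$pixel_size_um)
  q2 <- quant_droplets(scaled)
  expect_equal(nrow(q1$records), nrow(q2$records))
  expect_equal(q2$records$partition_ratio, q1$records$partition_ratio,
               tolerance = 1e-12)
  expect_equal(q2$records$area_um2, q1$records$area_um2)

  counts <- vapply(c(2, 3, 4, 6), function(k) {
    nrow(detect_condensates(sf$image,
                            config = detection_config(sd_multiplier = k)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("with nominal background on a clean field, masks equal ground truth exactly", {
  fs <- field_spec(bg_sd = 0, psf_sigma_um = 0, seed = 207)
  dr <- random_droplets(fs, 8, seed = 207)
  sf <- render_droplet_field(fs, dr)
  bg <- condensatr:::new_background(100, 10, length(sf$image$data), "masked", 0L)
  rec <- detect_condensates(sf$image, bg)
  labels <- attr(rec, "labels")
  expect_equal(nrow(rec), 8)
  for (id in dr$droplet_id) {
    truth_mask <- sf$truth_labels == id
    det_label <- unique(labels[truth_mask])
    expect_length(det_label, 1)
    expect_identical(labels == det_label, truth_mask)
  }
})

test_that("border-touching objects are excluded by default but recoverable", {
  fs <- field_spec(bg_sd = 1, psf_sigma_um = 0, seed = 208)
  edge <- tibble::tibble(droplet_id = 1L, x_um = 0.5, y_um = 8,
                         diameter_um = 1.2, partition_ratio = 6,
                         shape = "filled", ring_core_fraction = NA_real_)
  # rendered flush against the left border by bypassing the margin check
  fs_img <- matrix(100, 256, 256)
  co <- pixel_coords(field_image(fs_img, 0.065))
  inside <- (co$x - 0)^2 + (co$y - 8)^2 <= 0.6^2
  fs_img[inside] <- 600
  img <- field_image(fs_img, 0.065)
  bg <- condensatr:::new_background(100, 10, length(fs_img), "masked", 0L)
  expect_equal(nrow(detect_condensates(img, bg)), 0)
  cfg <- detection_config(exclude_border = FALSE)
  expect_equal(nrow(detect_condensates(img, bg, cfg)), 1)
})
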