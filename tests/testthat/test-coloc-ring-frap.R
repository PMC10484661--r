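test_that("PCC is affine-invariant and guarded against degenerate input", {
  withr::with_seed(42, {
    a <- field_image(matrix(rnorm(64 * 64, 100, 15), 64), 0.065)
  })
  b <- field_image(2 * a$data + 5, 0.065)
  expect_equal(pearson_colocalization(a, b), 1.0)
  neg <- field_image(-a$data + 300, 0.065)
  expect_equal(pearson_colocalization(a, neg), -1.0)

  withr::with_seed(43, {
    c2 <- field_image(a$data + rnorm(64 * 64, 0, 20), 0.065)
  })
  raw <- pearson_colocalization(a, c2)
  resc <- pearson_colocalization(
    field_image(3 * a$data - 40, 0.065),
    field_image(0.5 * c2$data + 11, 0.065))
  expect_equal(resc, raw, tolerance = 1e-12)

  const <- field_image(matrix(5, 64, 64), 0.065)
  expect_error(pearson_colocalization(a, const), "variance")
  expect_error(pearson_colocalization(a, b, matrix(FALSE, 64, 64)), "empty")
  expect_error(pearson_colocalization(a, field_image(matrix(1, 32, 32), 0.065)),
               "dimensions")
})

test_that("ring and filled condensates are classified from radial profiles", {
  fs <- field_spec(seed = 401)
  dr <- random_droplets(fs, 16, diameter_um = 1.2, partition_ratio = 6,
                        shape = rep(c("ring", "filled"), 8),
                        ring_core_fraction = 0.2, seed = 401)
  sf <- render_droplet_field(fs, dr)
  q <- quant_droplets(sf$image)
  calls <- classify_rings(sf$image, q$records)
  m <- match_by_centroid(calls$centroid_x_um, calls$centroid_y_um,
                         dr$x_um, dr$y_um)
  expect_true(all(!is.na(m)))
  expect_equal(calls$call, dr$shape[m])

  # scale invariance of the call
  calls2 <- classify_rings(field_image(sf$image$data * 5, 0.065), q$records)
  expect_equal(calls2$call, calls$call)

  # tiny objects are indeterminate
  tiny <- tibble::tibble(label = 1L, equivalent_diameter_um = 0.15,
                         centroid_x_um = 5, centroid_y_um = 5)
  tc <- classify_rings(sf$image, tiny)
  expect_false(tc$determinate)
  expect_true(is.na(tc$call))
})

test_that("ring percentages are simple determinate fractions", {
  expect_equal(ring_percentage(rep("ring", 5)), 100)
  expect_equal(ring_percentage(rep("filled", 5)), 0)
  expect_equal(ring_percentage(c("ring", "filled", "filled", NA)), 100 / 3)
  expect_error(ring_percentage(c(NA_character_)), "determinate")
})

test_that("FRAP normalization fixes the pre-bleach mean at 1 and is scale-free", {
  tr <- render_frap_series(pre_bleach = 380, post_bleach = 40,
                           mobile_fraction = 0.8, noise_sd = 2, seed = 402)
  nm <- frap_normalize(tr)
  expect_equal(mean(nm$intensity[nm$phase == "pre"]), 1.0)
  nm10 <- frap_normalize(dplyr::mutate(tr, intensity = intensity * 10))
  expect_equal(nm10$intensity, nm$intensity, tolerance = 1e-12)

  flat <- tibble::tibble(time_s = 0:9, intensity = 1,
                         phase = c("pre", rep("post", 9)))
  expect_error(frap_normalize(flat), "no bleach")
})

test_that("the noise-free exponential fit matches the closed form", {
  tr <- render_frap_series(mobile_fraction = 8 / 9, tau_s = 20, noise_sd = 0)
  fit <- frap_fit(tr)
  expect_equal(fit$mobile_fraction, 8 / 9, tolerance = 1e-6)
  expect_equal(round(fit$mobile_fraction, 3), 0.889)
  expect_equal(fit$t_half_s, 20 * log(2), tolerance = 1e-6)
  expect_equal(round(fit$t_half_s, 2), 13.86)
  expect_equal(fit$plateau, 0.9, tolerance = 1e-6)
  expect_equal(fit$post_bleach, 0.1, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-8)

  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "mobile_fraction"], fit$mobile_fraction)
  gl <- glance(fit)
  expect_equal(gl$tau_s, 20, tolerance = 1e-6)
})

test_that("a flat post-bleach trace has a near-zero mobile fraction", {
  flat <- render_frap_series(mobile_fraction = 0, noise_sd = 0.005, seed = 403)
  fit <- frap_fit(flat)
  expect_lt(fit$mobile_fraction, 0.05)
})

test_that("noisy traces recover mobile fraction and tau without bias", {
  tau <- 30 / log(10)
  fits <- purrr::map_dfr(1:30, function(s) {
    glance(frap_fit(render_frap_series(noise_sd = 0.02, tau_s = tau,
                                       mobile_fraction = 0.9, seed = s)))
  })
  expect_equal(mean(fits$mobile_fraction), 0.9, tolerance = 0.05 / 0.9)
  expect_equal(mean(fits$tau_s), tau, tolerance = 0.10)
})
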