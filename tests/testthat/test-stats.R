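test_that("the pooled t-test reproduces the hand-computed example", {
  res <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.2879, tolerance = 1e-3)
})

test_that("t-test handles identity, symmetry and degenerate variance", {
  x <- c(1.5, 2.5, 9)
  same <- two_sample_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  ab <- two_sample_ttest(c(1, 2, 3), c(5, 6, 9))
  ba <- two_sample_ttest(c(5, 6, 9), c(1, 2, 3))
  expect_equal(ab$p, ba$p)
  expect_equal(ab$t, -ba$t)

  expect_equal(two_sample_ttest(c(2, 2), c(2, 2))$p, 1)
  expect_error(two_sample_ttest(c(2, 2), c(3, 3)), "undefined")
  expect_error(two_sample_ttest(1, c(1, 2)), "n >= 2")
})

test_that("t and p match the reference implementation to 1e-9 on random cases", {
  withr::with_seed(77, {
    for (i in 1:100) {
      a <- rnorm(sample(3:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
      b <- rnorm(sample(3:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
      ref <- stats::t.test(a, b, var.equal = TRUE)
      mine <- two_sample_ttest(a, b)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
      refw <- stats::t.test(a, b)
      minew <- two_sample_ttest(a, b, welch = TRUE)
      expect_equal(minew$p, refw$p.value, tolerance = 1e-9)
    }
  })
})

test_that("kinetics t90 follows the exponential algebra", {
  tau <- 120
  t <- seq(0, 1500, by = 10)
  pf <- tibble::tibble(time_s = t, count = 100 * (1 - exp(-t / tau)))
  ks <- kinetics_summary(pf, series = "count")
  expect_true(ks$reached)
  # plateau is the tail mean, slightly under the asymptote; t90 stays within
  # one frame interval of tau * ln(10)
  expect_equal(ks$t90_s, tau * log(10), tolerance = 10 / (tau * log(10)))

  const <- tibble::tibble(time_s = t, count = 42)
  kc <- kinetics_summary(const, series = "count")
  expect_equal(kc$t90_s, 0)

  # t90 is invariant under positive rescaling of the series
  ks2 <- kinetics_summary(dplyr::mutate(pf, count = count * 3.3), series = "count")
  expect_equal(ks2$t90_s, ks$t90_s)
})

test_that("kinetics t90 recovers the generator's growth time constant", {
  fs <- field_spec(seed = 405)
  t90 <- purrr::map_dbl(1:8, function(s) {
    k <- render_kinetics_series(field_spec(seed = 404 + s),
                                nucleation_rate = 2, growth_tau_s = 300 / log(10),
                                nucleation_sat_tau_s = 10,
                                n_frames = 90, frame_interval_s = 10)
    ks <- kinetics_summary(k$per_frame, series = "mean_diameter_um")
    ks$t90_s
  })
  expect_equal(mean(t90), 300, tolerance = 0.10)
})

test_that("aggregation by repeat-content ratio is order-invariant", {
  meta <- construct_metadata(c("20R", "31R", "47R"), c(20, 31, 47),
                             c(580, 613, 661))
  expect_equal(meta$ratio_pct, 100 * 3 * c(20, 31, 47) / c(580, 613, 661))
  withr::with_seed(88, {
    rec <- tibble::tibble(
      construct = rep(c("20R", "31R", "47R"), each = 50),
      equivalent_diameter_um = rnorm(150, 1.6, 0.1),
      partition_ratio = rnorm(150, 7.5, 0.5))
  })
  t1 <- aggregate_by_ratio(rec, meta)
  t2 <- aggregate_by_ratio(rec[sample(nrow(rec)), ], meta)
  expect_equal(t1, t2)
  expect_equal(t1$construct, c("20R", "31R", "47R"))  # ordered by ratio
  # identically distributed groups agree within 3 SEM
  expect_true(all(abs(diff(t1$mean_partition_ratio)) <=
                    3 * sqrt(sum(t1$sem_partition_ratio^2))))

  one <- aggregate_by_ratio(rec[rec$construct == "47R", ], meta)
  expect_equal(nrow(one), 1)
  expect_equal(one$n, 50)
})

test_that("field-level aggregation pools replicate fields before the SEM", {
  withr::with_seed(89, {
    rec <- tibble::tibble(
      construct = "47R", field = rep(1:3, each = 30),
      equivalent_diameter_um = rnorm(90, 1.6, 0.1),
      partition_ratio = rnorm(90, 7.5, 0.5))
  })
  meta <- construct_metadata("47R", 47, 661)
  byf <- aggregate_by_ratio(rec, meta, by_field = TRUE)
  expect_equal(byf$n, 3)
})

test_that("concentration calibration is linear with clipping at zero", {
  expect_equal(fluorescence_to_concentration(200, slope = 100), 2.0)
  expect_equal(fluorescence_to_concentration(150, slope = 100, intercept = 150), 0)
  expect_warning(out <- fluorescence_to_concentration(50, 100, intercept = 100),
                 "clipped")
  expect_equal(out, 0)
  expect_error(fluorescence_to_concentration(100, slope = 0), "positive")
  # round trip through the generator's intensity scale: a condensate at
  # partition ratio r over bg b has mean r*b, so slope b ADU per ratio unit
  sf <- demo_droplet_field(seed = 406, n = 10, partition_ratio = 7.4)
  q <- quant_droplets(sf$image)
  conc <- fluorescence_to_concentration(q$records$mean_intensity,
                                        slope = q$background$mean)
  expect_equal(median(conc), 7.4, tolerance = 0.1)
})
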