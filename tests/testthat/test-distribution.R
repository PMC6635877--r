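test_that("KDE peak and HWHM match the Gaussian closed form", {
  set.seed(41)
  draws <- lapply(1:50, function(i) kde_estimate(rnorm(1e4, 100, 20)))
  # the mode of one draw fluctuates; its expectation is the true mode
  expect_lt(abs(mean(vapply(draws, `[[`, numeric(1), "peak")) - 100), 1)
  d <- draws[[1]]
  # HWHM of a Gaussian is sqrt(2 log 2) sigma, inflated by the kernel
  hwhm_oracle <- sqrt(2 * log(2)) * sqrt(20^2 + d$kernel_width^2)
  expect_lt(abs(d$hwhm - hwhm_oracle) / hwhm_oracle, 0.05)
})

test_that("identical values give a kernel-limited distribution", {
  d <- kde_estimate(rep(12, 50), kernel_width = 0.5)
  expect_equal(d$peak, 12, tolerance = 0.01)
  expect_equal(d$hwhm, sqrt(2 * log(2)) * 0.5, tolerance = 0.02)
  expect_error(kde_estimate(1:5), "at least 10")
})

test_that("pentamer-multiple data shows maxima at multiples of five", {
  set.seed(42)
  mult <- sample(1:7, 400, replace = TRUE,
                 prob = c(4, 6, 5, 3, 2, 1, 1))
  x <- 5 * mult + rnorm(400, 0, 0.4)
  d <- kde_estimate(x, kernel_width = 0.5)
  peaks <- d$grid[which(diff(sign(diff(d$density))) == -2) + 1]
  peaks <- peaks[d$density[match(peaks, d$grid)] > 0.02 * max(d$density)]
  expect_gte(length(peaks), 4)
  off <- abs(peaks / 5 - round(peaks / 5)) * 5
  expect_true(all(off < 1))
})

test_that("subtracting a distribution from itself leaves nothing", {
  set.seed(43)
  d <- kde_estimate(rnorm(500, 30, 5))
  corr <- subtract_background_distribution(d, d, background_rate = 1)
  expect_true(all(corr$density < 1e-12))
  expect_true(is.na(corr$peak))
})

test_that("a known 70/30 mixture is corrected back to the signal peak", {
  set.seed(44)
  sig <- rnorm(1400, 37, 8)
  bg <- rnorm(600, 12, 6)
  sample_d <- kde_estimate(c(sig, bg))
  bg_d <- kde_estimate(rnorm(2000, 12, 6))
  corr <- subtract_background_distribution(sample_d, bg_d,
                                           background_rate = 0.3)
  expect_lt(abs(corr$peak - 37), 2)
})

test_that("background far from the signal leaves the peak untouched", {
  set.seed(45)
  sig_d <- kde_estimate(rnorm(2000, 300, 30))
  bg_d <- kde_estimate(rnorm(2000, 12, 6))
  corr <- subtract_background_distribution(sig_d, bg_d,
                                           background_rate = 0.1)
  expect_lt(abs(corr$peak - sig_d$peak) / sig_d$peak, 0.01)
  expect_error(subtract_background_distribution(sig_d, bg_d,
                                                background_rate = 1.5),
               "0, 1")
})

test_that("functional-unit arithmetic is exact and linear", {
  expect_equal(functional_units(37, 5), 7.4)
  expect_equal(functional_units(6822, 8), 852.75)
  expect_equal(round(functional_units(6822, 8)), 853)
  expect_equal(round(functional_units(12057, 8)), 1507)
  expect_equal(functional_units(0, 5), 0)
  x <- c(10, 37, 300)
  expect_equal(functional_units(3 * x, 5), 3 * functional_units(x, 5))
  expect_error(functional_units(10, 0), "oligomer_size")
})

test_that("whole-percent proportions round as reported", {
  expect_equal(percent_proportion(16, 27), 59)
  expect_equal(percent_proportion(3, 33), 9)
  expect_equal(percent_proportion(4, 51), 8)
  expect_error(percent_proportion(5, 0), "k <= n")
})

test_that("triple-Gaussian decomposition recovers a known mixture", {
  set.seed(46)
  vals <- c(rnorm(1200, 35, 8), rnorm(400, 60, 6), rnorm(400, 95, 10))
  fit <- fit_triple_gaussian(kde_estimate(vals))
  expect_equal(fit$means, c(35, 60, 95), tolerance = 0.05)
  expect_true(all(abs(fit$fractions - c(0.6, 0.2, 0.2)) < 0.05))
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.99)
})

test_that("a pure Gaussian is explained by one dominant component", {
  set.seed(47)
  fit <- fit_triple_gaussian(kde_estimate(rnorm(2000, 50, 7)))
  expect_gte(max(fit$fractions), 0.95)
  expect_true(any(fit$degenerate) || max(fit$fractions) >= 0.95)
})

test_that("a single focus can never overlap", {
  m <- overlap_fraction(1, quiet_cell(), 250)
  expect_equal(m$fraction, 0)
})

test_that("analytic and Monte-Carlo overlap fractions agree", {
  geom <- quiet_cell()
  for (n in c(2, 5, 10, 20)) {
    a <- overlap_fraction(n, geom, 250, mode = "analytic")
    set.seed(100 + n)
    mc <- overlap_fraction(n, geom, 250, mode = "montecarlo")
    expect_lt(abs(a$fraction - mc$fraction), 3 * mc$mc_se)
  }
})

test_that("overlap probability grows with focus crowding", {
  geom <- quiet_cell()
  fr <- vapply(c(2, 5, 10, 20), function(n)
    overlap_fraction(n, geom, 250, mode = "analytic")$fraction,
    numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("overlapping pairs peak at twice the singles peak", {
  set.seed(48)
  singles <- kde_estimate(rnorm(2000, 35, 5))
  m <- overlap_fraction(5, quiet_cell(), 250, mode = "analytic",
                        singles = singles)
  pair_peak <- m$mixture$grid[which.max(m$mixture$pairs)]
  expect_lt(abs(pair_peak - 70), 2)
})

test_that("confocal maxima detection honours prominence and saturation", {
  expect_equal(nrow(confocal_foci_intensities(matrix(5, 20, 20), 3)), 0)
  img <- matrix(10, 45, 45)
  amps <- c(100, 80, 60, 40, 25)
  xs <- c(8, 22, 36, 10, 30); ys <- c(8, 10, 12, 30, 32)
  for (i in 1:5) img <- paint_spot(img, xs[i], ys[i], amps[i])
  foci <- confocal_foci_intensities(img, noise_tolerance = 10)
  expect_equal(nrow(foci), 5)
  expect_equal(order(-foci$peak_intensity), 1:5)  # rank order preserved
  got <- foci[order(foci$x), ]
  # saturated focus excluded
  foci_sat <- confocal_foci_intensities(img, noise_tolerance = 10,
                                        saturation = 105)
  expect_equal(nrow(foci_sat), 4)
  expect_equal(attr(foci_sat, "n_saturated"), 1L)
})

test_that("twin peaks inside one tolerance basin merge", {
  img <- matrix(0, 30, 30)
  img <- paint_spot(img, 14, 15, 100)
  img <- paint_spot(img, 17, 15, 90)
  expect_equal(nrow(confocal_foci_intensities(img, noise_tolerance = 30)), 1)
  # far enough apart they separate again
  img2 <- matrix(0, 30, 30)
  img2 <- paint_spot(img2, 7, 15, 100)
  img2 <- paint_spot(img2, 22, 15, 90)
  expect_equal(nrow(confocal_foci_intensities(img2, noise_tolerance = 30)), 2)
})

test_that("cytosolic background correction is exact for a flat cytosol", {
  peaks <- c(500, 300, 200)
  profile0 <- rep(0, 60)
  r0 <- cytosolic_background_correct(peaks, profile0)
  expect_equal(r0$intensities, peaks)
  profile_c <- rep(40, 60)
  rc <- cytosolic_background_correct(peaks + 40, profile_c,
                                     focus_positions = c(10, 30, 50))
  expect_equal(rc$intensities, peaks)
  expect_equal(rc$background, 40)
})

test_that("foci dimmer than the cytosol clip to zero with a flag", {
  r <- cytosolic_background_correct(c(30, 500), rep(40, 50))
  expect_equal(r$intensities[1], 0)
  expect_true(r$clipped[1])
  expect_false(r$clipped[2])
  expect_warning(
    cytosolic_background_correct(10, rep(5, 9), focus_positions = 5,
                                 exclusion_radius = 10),
    "skipped")
})

test_that("calibration arithmetic and round trip are exact", {
  cal <- calibrate(500, 37)
  expect_equal(cal$factor, 0.074)
  expect_equal(apply_calibration(cal, 1000), 74)
  expect_equal(apply_calibration(cal, cal$confocal_peak), 37)
  expect_error(calibrate(500, 37, strain_confocal = "ccmL",
                         strain_slimfield = "rbcS"), "mismatch")
  expect_error(calibrate(0, 37), "positive")
})

test_that("calibrated peaks track a twofold change in true copies", {
  set.seed(49)
  ref <- rnorm(1500, 200, 30)      # confocal intensities, reference
  doubled <- rnorm(1500, 400, 60)  # same optics, twice the copies
  ref_peak <- kde_estimate(ref)$peak
  cal <- calibrate(ref_peak, 37)
  ratio <- kde_estimate(apply_calibration(cal, doubled))$peak /
    kde_estimate(apply_calibration(cal, ref))$peak
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("identical conditions are not significant", {
  set.seed(50)
  a <- rnorm(300, 50, 10)
  cmp <- compare_conditions(a, a)
  expect_gt(cmp$p_value, 0.05)
  expect_equal(cmp$fold_change, 1.0)
  expect_equal(cmp$significance, "ns")
})

test_that("a 30% shift at n = 500 is highly significant", {
  set.seed(51)
  a <- rnorm(500, 65, 15)
  b <- rnorm(500, 50, 15)
  cmp <- compare_conditions(a, b, oligomer_size = 5)
  expect_lt(cmp$p_value, 0.005)
  expect_equal(cmp$significance, "***")
  expect_equal(cmp$fold_change, median(a) / median(b), tolerance = 1e-10)
})

test_that("significance stars follow the reporting thresholds", {
  expect_equal(significance_stars(0.04), "*")
  expect_equal(significance_stars(0.004), "***")
  expect_equal(significance_stars(0.2), "ns")
  expect_error(significance_stars(-0.1), "0, 1")
})

test_that("tied-only samples warn and return P = 1", {
  expect_warning(cmp <- compare_conditions(rep(5, 10), rep(5, 10)),
                 "tied")
  expect_equal(cmp$p_value, 1)
})

test_that("constant data has zero grouped sampling error", {
  r <- grouped_sampling_error(rep(50, 300), group_size = 75,
                              kernel_width = 0.5, n_resamples = 3)
  expect_equal(r$relative_error, 0)
  expect_false(r$flagged)
})

test_that("grouped peak error scales with the sampling noise floor", {
  set.seed(52)
  x <- rnorm(1000, 100, 20)
  r <- grouped_sampling_error(x, n_resamples = 10)
  sem <- 20 / (100 * sqrt(r$group_size))  # analytic lower bound (mean)
  expect_gt(r$relative_error, sem)        # a mode is noisier than a mean
  expect_lt(r$relative_error, 6 * sem)
  expect_error(grouped_sampling_error(rnorm(100), group_size = 80),
               "at least")
})
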