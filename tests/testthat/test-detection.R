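test_that("featureless images yield no candidates", {
  expect_equal(nrow(find_candidates(matrix(7, 40, 40))), 0)
  expect_equal(nrow(find_candidates(matrix(0, 5, 5))), 0)
})

test_that("well-separated organelles are each found within one pixel", {
  opt <- slim_optics()
  geom <- bg_cell()
  mk <- function(p) organelle_spec(p, 200, 50, 100)
  orgs <- list(mk(c(-0.8, 0, 0)), mk(c(0, 0.2, 0)), mk(c(0.9, -0.1, 0)))
  set.seed(5)
  img <- render_frame(geom, orgs, opt)
  cand <- find_candidates(img)
  expect_equal(nrow(cand), 3)
  nx <- ncol(img); ny <- nrow(img)
  to_px <- function(u, n) u * 1000 / opt$pixel_size + (n - 1) / 2
  for (o in orgs) {
    d <- sqrt((cand$x - to_px(o$position[1], nx))^2 +
                (cand$y - to_px(o$position[2], ny))^2)
    expect_lt(min(d), 1.01)
  }
})

test_that("Gaussian masking is exact for a symmetric noiseless focus", {
  opt <- slim_optics()
  o <- organelle_spec(c(0, 0, 0), copy_number = 10,
                      photons_per_fluorophore = 1000)
  img <- render_frame(quiet_cell(), list(o), opt, dim = c(29, 29),
                      noise = FALSE)
  loc <- iterative_gaussian_mask(img, c(14, 14), mask_sigma = 2)
  expect_true(loc$converged)
  expect_equal(loc$centroid, c(14, 14), tolerance = 1e-3)
})

test_that("sub-pixel offsets are recovered to 0.05 px at high photon count", {
  opt <- slim_optics()
  # emitter displaced +0.30 px in x from the image centre pixel
  off_um <- 0.30 * opt$pixel_size / 1000
  o <- organelle_spec(c(off_um, 0, 0), copy_number = 100,
                      photons_per_fluorophore = 1000)
  set.seed(8)
  img <- render_frame(quiet_cell(), list(o), opt, dim = c(29, 29))
  loc <- iterative_gaussian_mask(img, c(14, 14), mask_sigma = 2)
  expect_true(loc$converged)
  expect_lt(abs(loc$centroid[1] - 14.30), 0.05)
  expect_lt(abs(loc$centroid[2] - 14), 0.05)
})

test_that("nearby starting points converge to the same fixed point", {
  opt <- slim_optics()
  o <- organelle_spec(c(0.01, -0.01, 0), copy_number = 50,
                      photons_per_fluorophore = 500)
  set.seed(9)
  img <- render_frame(quiet_cell(), list(o), opt, dim = c(29, 29))
  l1 <- iterative_gaussian_mask(img, c(13, 14), mask_sigma = 2)
  l2 <- iterative_gaussian_mask(img, c(15, 15), mask_sigma = 2)
  expect_true(l1$converged && l2$converged)
  expect_equal(l1$centroid, l2$centroid, tolerance = 5e-3)
})

test_that("ROI photometry handles null and flat fields", {
  m0 <- measure_intensity(matrix(0, 31, 31), c(15, 15))
  expect_equal(m0$summed_intensity, 0)
  expect_equal(m0$bg_mean, 0)
  mb <- measure_intensity(matrix(123.4, 31, 31), c(15, 15))
  expect_equal(mb$summed_intensity, 0)   # perfect cancellation
  expect_equal(mb$bg_mean, 123.4)
})

test_that("measured ROI intensity matches the photometric expectation", {
  opt <- slim_optics()
  photons <- 5000
  o <- organelle_spec(c(0, 0, 0), copy_number = 1,
                      photons_per_fluorophore = photons)
  set.seed(21)
  reps <- vapply(1:8, function(i) {
    img <- render_frame(quiet_cell(), list(o), opt, dim = c(29, 29))
    measure_intensity(img, c(14, 14))$summed_intensity
  }, numeric(1))
  oracle <- opt$counts_per_photon * photons *
    roi_estimator_expectation(14, 14, 160 / 80)
  # Poisson error of one 81-pixel ROI sum, scaled by the gain
  poisson_sd <- opt$counts_per_photon * sqrt(photons)
  expect_lt(abs(mean(reps) - oracle), 3 * poisson_sd / sqrt(length(reps)))
})

test_that("adding a constant offset leaves summed intensity unchanged", {
  opt <- slim_optics()
  o <- organelle_spec(c(0, 0, 0), copy_number = 10,
                      photons_per_fluorophore = 1000)
  set.seed(10)
  img <- render_frame(quiet_cell(), list(o), opt, dim = c(29, 29))
  m1 <- measure_intensity(img, c(14, 14))
  m2 <- measure_intensity(img + 500, c(14, 14))
  expect_lt(abs(m2$summed_intensity - m1$summed_intensity),
            0.005 * abs(m1$summed_intensity))
})

test_that("measured intensity is proportional to fluorophore count", {
  opt <- slim_optics()
  counts <- c(1, 10, 100, 1000)
  vals <- vapply(counts, function(n) {
    o <- organelle_spec(c(0, 0, 0), copy_number = n,
                        photons_per_fluorophore = 100)
    img <- render_frame(quiet_cell(), list(o), opt, dim = c(29, 29),
                        noise = FALSE)
    measure_intensity(img, c(14, 14))$summed_intensity
  }, numeric(1))
  ratios <- vals / counts
  expect_lt((max(ratios) - min(ratios)) / mean(ratios), 0.05)
})

test_that("localization precision improves with photon count", {
  opt <- slim_optics()
  prec <- vapply(c(100, 1000, 10000), function(photons) {
    errs <- vapply(1:12, function(i) {
      set.seed(1000 * photons + i)
      o <- organelle_spec(c(0, 0, 0), copy_number = 1,
                          photons_per_fluorophore = photons)
      img <- render_frame(bg_cell(), list(o), opt, dim = c(29, 29))
      loc <- iterative_gaussian_mask(img, c(14, 14), mask_sigma = 2)
      sqrt(sum((loc$centroid - c(14, 14))^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(prec) < 0))  # monotone improvement
})

test_that("the SNR gate is strict at the threshold", {
  m <- function(snr) list(snr = snr)
  expect_true(accept_focus(m(0.41)))
  expect_false(accept_focus(m(0.4)))   # boundary: strict inequality
  expect_false(accept_focus(m(0.0)))
  expect_true(accept_focus(m(Inf)))    # bg_sd = 0, positive signal
})

test_that("zero-variance background follows the documented convention", {
  img <- matrix(5, 31, 31)
  img[16, 16] <- 50                     # bright single pixel, flat bg
  m <- measure_intensity(img, c(15, 15))
  expect_true(is.infinite(m$snr))
  expect_true(accept_focus(m))
  m0 <- measure_intensity(matrix(5, 31, 31), c(15, 15))
  expect_equal(m0$snr, 0)
  expect_false(accept_focus(m0))
})

test_that("a stationary focus links into a single full-length track", {
  meas <- meas_table(1:50, rep(10, 50) + rnorm(50, 0, 0.05),
                     rep(12, 50) + rnorm(50, 0, 0.05))
  tracks <- link_foci(meas, max_displacement = 2)
  expect_length(tracks, 1)
  expect_equal(nrow(tracks[[1]]$measurements), 50)
})

test_that("two slowly moving foci keep their identities", {
  set.seed(13)
  n <- 40
  xa <- cumsum(c(5, runif(n - 1, -0.5, 0.5)))
  xb <- cumsum(c(15, runif(n - 1, -0.5, 0.5)))
  meas <- rbind(meas_table(1:n, xa, rep(5, n)),
                meas_table(1:n, xb, rep(5, n)))
  tracks <- link_foci(meas, max_displacement = 2)
  expect_length(tracks, 2)
  got_a <- tracks[[1]]$measurements$x
  expect_equal(got_a, xa)               # no identity swaps
  expect_equal(tracks[[2]]$measurements$x, xb)
})

test_that("equidistant assignments resolve to the lowest track id", {
  meas <- rbind(meas_table(1, c(0, 10), c(0, 0)),
                meas_table(2, 5, 0))    # exactly between both heads
  tracks <- link_foci(meas, max_displacement = 6)
  expect_equal(nrow(tracks[[1]]$measurements), 2)
  expect_equal(nrow(tracks[[2]]$measurements), 1)
})

test_that("overtracking continues photometry after the bleach endpoint", {
  opt <- slim_optics()
  o <- organelle_spec(c(0, 0, 0), copy_number = 30,
                      photons_per_fluorophore = 100, bleach_rate = 0.15)
  sim <- simulate_photobleach_stack(bg_cell(), list(o), opt, 120, seed = 6)
  tracks <- track_stack(sim$stack, max_gap = 3, overtrack_frames = 20)
  main <- tracks[[which.max(vapply(tracks, function(t)
    nrow(t$measurements), numeric(1)))]]
  expect_gt(nrow(main$overtracked_tail), 0)
  expect_lte(nrow(main$overtracked_tail), 20)
  # tail samples sit at background level: well below one fluorophore
  expect_lt(mean(main$overtracked_tail$summed_intensity), 500)
})
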