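#' Kernel density estimate of a copy-number distribution
#'
#' Gaussian-kernel density on a grid extending three bandwidths past the
#' data range, with the modal peak and half width at half maximum read
#' off the curve. `kernel_width = "standard"` uses Silverman's
#' rule-of-thumb bandwidth; an explicit numeric width (e.g. 0.5
#' molecules, the uncertainty of the characteristic intensity) is used
#' for periodicity analysis.
#'
#' @param values Per-organelle copy estimates (n >= 10).
#' @param kernel_width `"standard"` or a positive number (molecules).
#' @param n_grid Grid resolution.
#' @return A `copy_number_distribution`: `values`, `kernel_width`,
#'   `grid`, `density`, `peak`, `hwhm`, `n`.
#' @export
kde_estimate <- function(values, kernel_width = "standard",
                         n_grid = 2048) {
  values <- values[is.finite(values)]
  if (length(values) < 10)
    stop("need at least 10 values for a density estimate", call. = FALSE)
  if (identical(kernel_width, "standard")) {
    bw <- if (stats::sd(values) > 0) stats::bw.nrd0(values) else
      max(abs(values[1]) * 1e-3, 1e-3)
  } else {
    if (!is.numeric(kernel_width) || kernel_width <= 0)
      stop("kernel_width must be positive or \"standard\"", call. = FALSE)
    bw <- kernel_width
  }
  d <- stats::density(values, bw = bw, from = min(values) - 3 * bw,
                      to = max(values) + 3 * bw, n = n_grid)
  ph <- .density_peak_hwhm(d$x, d$y)
  structure(list(values = values, kernel_width = bw, grid = d$x,
                 density = d$y, peak = ph$peak, hwhm = ph$hwhm,
                 n = length(values)),
            class = "copy_number_distribution")
}

#' @export
print.copy_number_distribution <- function(x, ...) {
  cat(sprintf(
    "<copy_number_distribution> peak %.3g +/- %.3g (HWHM), n = %d\n",
    x$peak, x$hwhm, x$n))
  invisible(x)
}

#' @export
plot.copy_number_distribution <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l",
                 xlab = "copies per organelle", ylab = "density", ...)
  graphics::abline(v = x$peak, lty = 2)
  invisible(x)
}

# trapezoid integral
.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                          utils::tail(y, -1)) / 2)

#' Subtract a background copy-number distribution
#'
#' Corrects a sample density for foci that are background (e.g.
#' chlorophyll-derived spots detected in unlabelled cells):
#' `corrected = max(sample - rate * background, 0)`, with the background
#' density resampled onto the sample grid, the result renormalized and
#' the peak/HWHM recomputed. The rate is the expected fraction of sample
#' foci that are background; it can be given directly or derived from
#' foci-per-cell counts of the labelled strain and the unlabelled
#' control.
#'
#' @param sample,background `copy_number_distribution` objects.
#' @param background_rate Fraction in `[0, 1]`, or `NULL` to derive it.
#' @param sample_foci_per_cell,background_foci_per_cell Mean foci counts
#'   used to derive the rate when `background_rate` is `NULL`.
#' @return A corrected `copy_number_distribution` (with `values = NA`;
#'   the correction acts on the density, not on individual organelles).
#' @export
subtract_background_distribution <- function(sample, background,
                                             background_rate = NULL,
                                             sample_foci_per_cell = NULL,
                                             background_foci_per_cell = NULL) {
  if (is.null(background_rate)) {
    if (is.null(sample_foci_per_cell) || is.null(background_foci_per_cell))
      stop("give background_rate or both foci-per-cell counts",
           call. = FALSE)
    background_rate <- background_foci_per_cell / sample_foci_per_cell
  }
  if (background_rate < 0 || background_rate > 1)
    stop("background_rate must lie in [0, 1]", call. = FALSE)
  bg <- stats::approx(background$grid, background$density,
                      xout = sample$grid, yleft = 0, yright = 0)$y
  corrected <- pmax(sample$density - background_rate * bg, 0)
  total <- .trapz(sample$grid, corrected)
  norm <- if (total > 0) corrected / total else corrected
  ph <- if (total > 0) .density_peak_hwhm(sample$grid, norm) else
    list(peak = NA_real_, hwhm = NA_real_)
  structure(list(values = NA, kernel_width = sample$kernel_width,
                 grid = sample$grid, density = norm, peak = ph$peak,
                 hwhm = ph$hwhm, n = sample$n,
                 background_rate = background_rate),
            class = "copy_number_distribution")
}

#' Convert subunit copies to functional oligomeric units
#'
#' A carboxysome protein assembled as an m-mer contributes one
#' functional unit per m subunit copies: 37 pentamer subunits are 7.4
#' pentamers, 6822 small Rubisco subunits are 852.75 (about 853) L8S8
#' holoenzymes. Returned unrounded; rounding is presentation.
#'
#' @param copies Subunit copy numbers (any numeric vector).
#' @param oligomer_size Subunits per functional unit (>= 1).
#' @return `copies / oligomer_size`.
#' @export
functional_units <- function(copies, oligomer_size) {
  if (!is.numeric(oligomer_size) || length(oligomer_size) != 1 ||
      oligomer_size < 1)
    stop("oligomer_size must be a single number >= 1", call. = FALSE)
  copies / oligomer_size
}

#' Proportion as a whole percentage
#'
#' @param k Count of interest.
#' @param n Total count.
#' @return `round(100 * k / n)`.
#' @export
percent_proportion <- function(k, n) {
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  round(100 * k / n)
}

#' Decompose a copy-number density into three Gaussian populations
#'
#' Least-squares fit of a sum of three Gaussians to the kernel density
#' curve (not the raw values), weighted by the density so the populated
#' regions dominate. Components are reported in ascending order of mean
#' with their area fractions (normalized to sum to one); components
#' holding under 1% of the area are flagged degenerate.
#'
#' When a single Gaussian already explains the density curve (R^2 above
#' `single_r2`), the three-component least-squares problem is degenerate
#' (overlapping components share the mass arbitrarily); in that case the
#' single-component solution is reported, with the two spare components
#' flagged degenerate at zero area.
#'
#' @param distribution A `copy_number_distribution`.
#' @param init_means Optional length-3 starting means; auto-seeded at
#'   the three strongest local maxima (padded with quantiles) otherwise.
#' @param single_r2 Curve R^2 above which one component suffices.
#' @return A `mixture_fit`: `means`, `sds`, `fractions`, `r_squared`,
#'   `degenerate`, `fitted` (curve).
#' @export
fit_triple_gaussian <- function(distribution, init_means = NULL,
                                single_r2 = 0.995) {
  x <- distribution$grid
  y <- distribution$density
  single <- tryCatch(
    minpack.lm::nlsLM(y ~ a * stats::dnorm(x, m, s),
                      data = data.frame(x = x, y = y),
                      start = list(a = .trapz(x, y), m = x[which.max(y)],
                                   s = max(distribution$hwhm / 1.177,
                                           diff(range(x)) / 50)),
                      lower = c(0, min(x), 1e-6),
                      weights = pmax(y, 0)),
    error = function(e) NULL)
  if (!is.null(single)) {
    r2_single <- 1 - sum((y - stats::predict(single))^2) /
      sum((y - mean(y))^2)
    if (r2_single >= single_r2) {
      p <- stats::coef(single)
      return(structure(list(means = c(p[["m"]], NA, NA),
                            sds = c(p[["s"]], NA, NA),
                            fractions = c(1, 0, 0),
                            r_squared = r2_single,
                            degenerate = c(FALSE, TRUE, TRUE),
                            grid = x, fitted = stats::predict(single)),
                       class = "mixture_fit"))
    }
  }
  if (is.null(init_means)) {
    lm_idx <- which(diff(sign(diff(y))) == -2) + 1
    lm_idx <- lm_idx[order(-y[lm_idx])]
    means <- x[lm_idx]
    if (length(means) < 3) {
      pad <- stats::quantile(rep(x, pmax(round(y / max(y) * 100), 0)),
                             c(0.25, 0.5, 0.75))
      means <- c(means, pad)[1:3]
    } else means <- means[1:3]
    init_means <- sort(as.numeric(means))
  }
  if (length(init_means) != 3)
    stop("init_means must have length 3", call. = FALSE)
  s0 <- max(distribution$hwhm / 1.177, diff(range(x)) / 50)
  a0 <- .trapz(x, y) / 3
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * stats::dnorm(x, m1, s1) + a2 * stats::dnorm(x, m2, s2) +
        a3 * stats::dnorm(x, m3, s3),
      data = df,
      start = list(a1 = a0, a2 = a0, a3 = a0,
                   m1 = init_means[1], m2 = init_means[2],
                   m3 = init_means[3], s1 = s0, s2 = s0, s3 = s0),
      lower = c(0, 0, 0, rep(min(x), 3), rep(s0 / 50, 3)),
      upper = c(rep(Inf, 3), rep(max(x), 3), rep(diff(range(x)), 3)),
      weights = pmax(y, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    stop("triple-Gaussian fit did not converge; supply init_means",
         call. = FALSE)
  p <- stats::coef(fit)
  areas <- p[c("a1", "a2", "a3")]
  means <- p[c("m1", "m2", "m3")]
  sds <- p[c("s1", "s2", "s3")]
  ord <- order(means)
  fractions <- as.numeric(areas[ord] / sum(areas))
  fitted <- stats::predict(fit)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(means = as.numeric(means[ord]),
                 sds = as.numeric(sds[ord]),
                 fractions = fractions,
                 r_squared = 1 - ss_res / ss_tot,
                 degenerate = fractions < 0.01,
                 grid = x, fitted = fitted),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> 3 Gaussian components (ascending means):\n")
  for (i in 1:3)
    cat(sprintf("  mean %.3g, sd %.3g, area %.1f%%%s\n", x$means[i],
                x$sds[i], 100 * x$fractions[i],
                if (x$degenerate[i]) " [degenerate]" else ""))
  cat(sprintf("  R^2 on density curve: %.4f\n", x$r_squared))
  invisible(x)
}

# uniform random points in the 2D projection of a spherocylinder
.runif_capsule <- function(n, geometry) {
  L <- geometry$length; R <- geometry$radius
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) * 4 / pi + 10)
    x <- stats::runif(m, -L / 2, L / 2)
    y <- stats::runif(m, -R, R)
    ok <- .capsule_radial_dist(x, y, geometry) <= R
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

.capsule_area <- function(geometry)
  (geometry$length - 2 * geometry$radius) * 2 * geometry$radius +
  pi * geometry$radius^2

#' Probability that diffraction-limited foci overlap in a cell
#'
#' For `n_foci` organelles placed uniformly at random in the 2D
#' projection of the cell, computes the probability that a focus has at
#' least one neighbour closer than `resolution_radius`, i.e. that two or
#' more organelles merge into one diffraction-limited spot.
#'
#' The analytic mode evaluates, on a fine pixelization of the projected
#' cell, the exact conditional probability
#' `1 - (1 - a(x)/A)^(n-1)` (with `a(x)` the neighbourhood area clipped
#' to the cell) averaged over positions; the Monte-Carlo mode places at
#' least `n_placements` points and counts foci with a near neighbour.
#' When a singles copy-number distribution is supplied, the predicted
#' distribution of overlapping spots (the self-convolution of the
#' singles density) is attached, mixed in with weight equal to the
#' overlap fraction.
#'
#' @param n_foci Number of foci per cell (>= 1).
#' @param geometry A [cell_geometry()] (its 2D projection is used).
#' @param resolution_radius Merging radius in nm (default 250, the
#'   measured focus sigma width).
#' @param mode `"analytic"` or `"montecarlo"`.
#' @param n_placements Minimum total points placed in Monte-Carlo mode.
#' @param singles Optional `copy_number_distribution` of single
#'   organelles.
#' @return An `overlap_model`: `n_foci`, `area`, `resolution_radius`,
#'   `fraction`, `mc_se` (Monte-Carlo only), and optionally `mixture`
#'   (`grid`, `singles`, `pairs`, `density`).
#' @export
overlap_fraction <- function(n_foci, geometry, resolution_radius = 250,
                             mode = c("analytic", "montecarlo"),
                             n_placements = 1e5, singles = NULL) {
  mode <- match.arg(mode)
  if (n_foci < 1) stop("n_foci must be >= 1", call. = FALSE)
  if (resolution_radius <= 0)
    stop("resolution_radius must be > 0", call. = FALSE)
  rho <- resolution_radius / 1000  # nm -> um
  if (rho > 2 * geometry$radius)
    warning("resolution radius exceeds the cell width; ",
            "overlap fraction saturates near 1")
  A <- .capsule_area(geometry)
  mc_se <- NA_real_
  if (n_foci == 1) {
    fraction <- 0
  } else if (mode == "analytic") {
    h <- min(rho / 40, geometry$radius / 40)
    L <- geometry$length; R <- geometry$radius
    xs <- seq(-L / 2 + h / 2, L / 2, by = h)
    ys <- seq(-R + h / 2, R, by = h)
    inside <- outer(ys, xs, function(yy, xx)
      .capsule_radial_dist(xx, yy, geometry) <= R)
    r_px <- ceiling(rho / h)
    ker_off <- seq(-r_px, r_px)
    ker <- outer(ker_off, ker_off, function(i, j)
      (i^2 + j^2) * h^2 <= rho^2) * h^2
    cov <- EBImage::filter2(matrix(as.numeric(inside), nrow(inside)),
                            ker, boundary = 0)
    p_inside <- 1 - (1 - pmin(cov[inside] / A, 1))^(n_foci - 1)
    fraction <- mean(p_inside)
  } else {
    trials <- ceiling(n_placements / n_foci)
    pts <- .runif_capsule(trials * n_foci, geometry)
    xs <- matrix(pts[, 1], nrow = trials)
    ys <- matrix(pts[, 2], nrow = trials)
    has_nb <- matrix(FALSE, trials, n_foci)
    for (k in seq_len(n_foci - 1)) for (l in (k + 1):n_foci) {
      close <- (xs[, k] - xs[, l])^2 + (ys[, k] - ys[, l])^2 <= rho^2
      has_nb[, k] <- has_nb[, k] | close
      has_nb[, l] <- has_nb[, l] | close
    }
    per_trial <- rowMeans(has_nb)
    fraction <- mean(per_trial)
    mc_se <- stats::sd(per_trial) / sqrt(trials)
  }
  mixture <- NULL
  if (!is.null(singles)) {
    g <- singles$grid
    dx <- g[2] - g[1]
    dens <- singles$density
    conv <- stats::convolve(dens, rev(dens), type = "open") * dx
    grid2 <- seq(2 * g[1], by = dx, length.out = length(conv))
    pair_on_g2 <- conv / max(.trapz(grid2, conv), .Machine$double.eps)
    singles_on_g2 <- stats::approx(g, dens, xout = grid2,
                                   yleft = 0, yright = 0)$y
    mixture <- list(grid = grid2, singles = singles_on_g2,
                    pairs = pair_on_g2,
                    density = (1 - fraction) * singles_on_g2 +
                      fraction * pair_on_g2)
  }
  structure(list(n_foci = n_foci, area = A,
                 resolution_radius = resolution_radius,
                 fraction = fraction, mc_se = mc_se, mode = mode,
                 mixture = mixture),
            class = "overlap_model")
}

#' @export
print.overlap_model <- function(x, ...) {
  cat(sprintf(paste0("<overlap_model> %d foci in %.3g um^2: overlap ",
                     "fraction %.3f (%s)\n"),
              x$n_foci, x$area, x$fraction, x$mode))
  invisible(x)
}

#' Peak intensities of foci in a confocal image
#'
#' Finds local intensity maxima whose prominence exceeds
#' `noise_tolerance` (determined from background fluctuations in empty
#' regions): a maximum is accepted only if the connected region of
#' pixels within `noise_tolerance` below it contains no brighter pixel,
#' so twin peaks closer than the resolution merge into the brighter one.
#' Saturated peaks (at or above `saturation`) are excluded and counted
#' in the `n_saturated` attribute.
#'
#' @param image Numeric matrix.
#' @param noise_tolerance Required prominence in counts (>= 0).
#' @param saturation Optional saturation level of the detector.
#' @return `data.frame` with `x`, `y` (0-based) and `peak_intensity`,
#'   ordered by decreasing intensity; attribute `n_saturated`.
#' @export
confocal_foci_intensities <- function(image, noise_tolerance,
                                      saturation = NULL) {
  if (noise_tolerance < 0)
    stop("noise_tolerance must be >= 0", call. = FALSE)
  lm_mask <- .local_maxima(image)
  gmin <- min(image)
  cand <- which(lm_mask & image > gmin + noise_tolerance, arr.ind = TRUE)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      peak_intensity = numeric(0))
  attr(empty, "n_saturated") <- 0L
  if (nrow(cand) == 0) return(empty)
  vals <- image[cand]
  ord <- order(-vals)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  accepted <- matrix(NA_real_, 0, 2)
  acc_vals <- numeric(0)
  n_sat <- 0L
  for (i in seq_len(nrow(cand))) {
    v <- vals[i]
    mask <- image >= v - noise_tolerance
    lab <- EBImage::bwlabel(mask)
    comp <- lab[cand[i, 1], cand[i, 2]]
    comp_mask <- lab == comp
    if (max(image[comp_mask]) > v) next             # merged into a brighter peak
    if (nrow(accepted) > 0) {
      inside <- comp_mask[cbind(accepted[, 1], accepted[, 2])]
      if (any(inside)) next                          # plateau duplicate
    }
    if (!is.null(saturation) && v >= saturation) { n_sat <- n_sat + 1L; next }
    accepted <- rbind(accepted, cand[i, ])
    acc_vals <- c(acc_vals, v)
  }
  out <- data.frame(x = accepted[, 2] - 1, y = accepted[, 1] - 1,
                    peak_intensity = acc_vals)
  attr(out, "n_saturated") <- n_sat
  out
}

#' Subtract cytosolic background from confocal focus intensities
#'
#' The cytosolic level is the mean of the intensity profile along the
#' cell's central line outside focus regions (points within
#' `exclusion_radius` of a focus position are excluded). Corrected
#' intensities below zero are clipped to 0 and flagged.
#'
#' @param peak_intensities Numeric focus peak intensities.
#' @param axis_profile Intensity profile sampled along the central line.
#' @param focus_positions Indices along the profile occupied by foci
#'   (optional; `NULL` excludes nothing).
#' @param exclusion_radius Half-width, in profile samples, excluded
#'   around each focus.
#' @return List with `intensities`, `background`, `clipped` (logical).
#' @export
cytosolic_background_correct <- function(peak_intensities, axis_profile,
                                         focus_positions = NULL,
                                         exclusion_radius = 3) {
  keep <- rep(TRUE, length(axis_profile))
  for (p in focus_positions) {
    idx <- seq(max(1, round(p) - exclusion_radius),
               min(length(axis_profile), round(p) + exclusion_radius))
    keep[idx] <- FALSE
  }
  if (!any(keep)) {
    warning("no non-focus region on the central line; correction skipped")
    return(list(intensities = peak_intensities, background = 0,
                clipped = rep(FALSE, length(peak_intensities))))
  }
  bg <- mean(axis_profile[keep])
  corrected <- peak_intensities - bg
  clipped <- corrected < 0
  corrected[clipped] <- 0
  list(intensities = corrected, background = bg, clipped = clipped)
}

#' Calibration factor from confocal intensity to absolute copies
#'
#' Anchors the confocal intensity scale of a strain to the absolute
#' molecule scale measured by Slimfield under the reference condition:
#' `factor = slimfield_peak / confocal_peak` (molecules per intensity
#' unit). Applying the factor to any confocal intensity of the same
#' strain yields molecules.
#'
#' @param confocal_peak Modal focus intensity of the reference confocal
#'   distribution (intensity units).
#' @param slimfield_peak Modal copy number of the matching Slimfield
#'   distribution (molecules).
#' @param strain_confocal,strain_slimfield Optional strain labels; a
#'   mismatch is refused.
#' @return A `calibration_factor`.
#' @export
calibrate <- function(confocal_peak, slimfield_peak,
                      strain_confocal = NULL, strain_slimfield = NULL) {
  if (!is.null(strain_confocal) && !is.null(strain_slimfield) &&
      !identical(strain_confocal, strain_slimfield))
    stop(sprintf("strain mismatch: confocal '%s' vs Slimfield '%s'",
                 strain_confocal, strain_slimfield), call. = FALSE)
  if (confocal_peak <= 0 || slimfield_peak <= 0)
    stop("both peaks must be positive", call. = FALSE)
  structure(list(slimfield_peak = slimfield_peak,
                 confocal_peak = confocal_peak,
                 factor = slimfield_peak / confocal_peak,
                 strain = strain_confocal),
            class = "calibration_factor")
}

#' Apply a calibration factor to confocal intensities
#'
#' @param calibration A `calibration_factor`.
#' @param intensities Confocal intensities.
#' @return Molecule copy numbers.
#' @export
apply_calibration <- function(calibration, intensities) {
  if (!inherits(calibration, "calibration_factor"))
    stop("calibration must come from calibrate()", call. = FALSE)
  intensities * calibration$factor
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf(
    "<calibration_factor> %.4g molecules per intensity unit%s\n",
    x$factor, if (is.null(x$strain)) "" else paste0(" (", x$strain, ")")))
  invisible(x)
}

#' Compare copy numbers between two growth conditions
#'
#' Two-sided Mann-Whitney U test on the per-organelle values, with the
#' fold change of functional-unit medians and the significance stars
#' used throughout the analysis: `***` for P < 0.005, `*` for P < 0.05,
#' `ns` otherwise.
#'
#' @param a,b Per-organelle copies under the two conditions (n >= 8
#'   each).
#' @param oligomer_size Subunits per functional unit (cancels in the
#'   fold change; kept for unit bookkeeping).
#' @return A `condition_comparison`: `statistic`, `p_value`,
#'   `fold_change` (median(a)/median(b) in functional units),
#'   `significance`, `n`.
#' @export
compare_conditions <- function(a, b, oligomer_size = 1) {
  if (length(a) < 8 || length(b) < 8)
    stop("need at least 8 observations per condition", call. = FALSE)
  fa <- functional_units(a, oligomer_size)
  fb <- functional_units(b, oligomer_size)
  if (length(unique(c(a, b))) == 1) {
    warning("all observations tied; P set to 1")
    w <- list(statistic = c(W = length(a) * length(b) / 2), p.value = 1)
  } else {
    w <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
  }
  p <- w$p.value
  stars <- significance_stars(p)
  structure(list(statistic = unname(w$statistic), p_value = p,
                 fold_change = stats::median(fa) / stats::median(fb),
                 significance = stars,
                 n = c(length(a), length(b))),
            class = "condition_comparison")
}

#' Significance stars for condition comparisons
#'
#' `***` for P < 0.005, `*` for P < 0.05, `ns` otherwise.
#'
#' @param p P-value in `[0, 1]`.
#' @return Character string.
#' @export
significance_stars <- function(p) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  if (p < 0.005) "***" else if (p < 0.05) "*" else "ns"
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(paste0("<condition_comparison> U = %.4g, P = %.3g (%s), ",
                     "fold change %.3g (n = %d, %d)\n"),
              x$statistic, x$p_value, x$significance, x$fold_change,
              x$n[1], x$n[2]))
  invisible(x)
}

#' Sampling error of a distribution peak by randomized grouping
#'
#' Randomly partitions the values into groups of `group_size` entries,
#' estimates the kernel-density peak of every group, and reports the
#' relative spread (sd/mean) of the group peaks, averaged over
#' `n_resamples` random partitions. A relative error above
#' `error_threshold` (default 5%) raises the quality flag used to gate
#' distribution summaries.
#'
#' @param values Per-focus intensities or copies.
#' @param group_size Entries per group; the default picks a size in the
#'   70-100 range that tiles the data.
#' @param n_resamples Number of random partitions.
#' @param kernel_width Passed to [kde_estimate()].
#' @param error_threshold Quality-flag threshold on the relative error.
#' @return List with `relative_error`, `group_size`, `n_groups`,
#'   `flagged`.
#' @export
grouped_sampling_error <- function(values, group_size = NULL,
                                   n_resamples = 20,
                                   kernel_width = "standard",
                                   error_threshold = 0.05) {
  n <- length(values)
  if (is.null(group_size)) {
    k <- max(2, floor(n / 85))
    group_size <- floor(n / k)
    group_size <- min(max(group_size, 70), 100)
  }
  if (n < 2 * group_size)
    stop(sprintf("need at least %d values (2 groups of %d)",
                 2 * group_size, group_size), call. = FALSE)
  n_groups <- floor(n / group_size)
  rel <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    idx <- sample.int(n)
    peaks <- vapply(seq_len(n_groups), function(g) {
      rows <- idx[((g - 1) * group_size + 1):(g * group_size)]
      kde_estimate(values[rows], kernel_width = kernel_width,
                   n_grid = 512)$peak
    }, numeric(1))
    m <- mean(peaks)
    rel[r] <- if (m == 0) 0 else stats::sd(peaks) / abs(m)
  }
  err <- mean(rel)
  list(relative_error = err, group_size = group_size,
       n_groups = n_groups, flagged = err > error_threshold)
}
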