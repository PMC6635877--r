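# Shared fixture builders: all synthetic, generated in code.

slim_optics <- function(...)
  optical_model(psf_sigma_lateral = 160, psf_sigma_axial = 400,
                pixel_size = 80, counts_per_photon = 10, baseline = 100,
                exposure = 5, ...)

confocal_optics <- function()
  optical_model(psf_sigma_lateral = 160, psf_sigma_axial = 400,
                pixel_size = 41.5, counts_per_photon = 1, baseline = 10,
                exposure = 5)

quiet_cell <- function(...)
  cell_geometry(length = 3, radius = 0.5, thylakoid_thickness = 0.1,
                thylakoid_photon_density = 0, cytosol_photon_density = 0,
                ...)

bg_cell <- function(thy = 5, cyt = 2)
  cell_geometry(length = 3, radius = 0.5, thylakoid_thickness = 0.1,
                thylakoid_photon_density = thy,
                cytosol_photon_density = cyt)

# Independent numeric oracle: photon mass of a 2D Gaussian PSF inside a
# pixel disk of given radius centred at (x0, y0), by per-pixel erf
# integration over a wide lattice. 0-based pixel coordinates.
psf_mass_in_disk <- function(x0, y0, sigma_px, radius, half_width = 30) {
  xs <- round(x0) + (-half_width:half_width)
  ys <- round(y0) + (-half_width:half_width)
  mx <- pnorm(xs + 0.5, x0, sigma_px) - pnorm(xs - 0.5, x0, sigma_px)
  my <- pnorm(ys + 0.5, y0, sigma_px) - pnorm(ys - 0.5, y0, sigma_px)
  d2 <- outer((ys - y0)^2, (xs - x0)^2, `+`)
  sum((my %o% mx)[d2 <= radius^2])
}

# Expectation oracle for the background-corrected ROI estimator: PSF mass
# in the inner disk minus n_inner times the mean PSF mass per background
# pixel of the 17x17 window (the estimator's exact expectation for a
# point source on a flat field).
roi_estimator_expectation <- function(x0, y0, sigma_px, inner_radius = 5,
                                      bg_size = 17) {
  half <- (bg_size - 1) / 2
  xs <- round(x0) + (-half:half)
  ys <- round(y0) + (-half:half)
  mx <- pnorm(xs + 0.5, x0, sigma_px) - pnorm(xs - 0.5, x0, sigma_px)
  my <- pnorm(ys + 0.5, y0, sigma_px) - pnorm(ys - 0.5, y0, sigma_px)
  mass <- my %o% mx
  d2 <- outer((ys - y0)^2, (xs - x0)^2, `+`)
  inner <- d2 <= inner_radius^2
  sum(mass[inner]) - sum(inner) * mean(mass[!inner])
}

# analytic Gaussian spot painted onto a matrix (no PSF model involvement)
paint_spot <- function(img, x, y, amp, sigma = 1.5) {
  nr <- nrow(img); nc <- ncol(img)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    img[r, c] <- img[r, c] +
      amp * exp(-(((c - 1) - x)^2 + ((r - 1) - y)^2) / (2 * sigma^2))
  img
}

# synthetic measurement table for linker tests
meas_table <- function(frames, xs, ys) {
  data.frame(frame = frames, x = xs, y = ys, summed_intensity = 1000,
             bg_mean = 0, bg_sd = 1, snr = 10, n_inner = 81,
             edge_truncated = FALSE)
}
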