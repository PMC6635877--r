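# Continuous pixel coordinate of a physical position (µm, cell frame).
# Convention: 0-based pixel indices, origin of a pixel at its centre, so
# pixel j covers [j - 0.5, j + 0.5]; the cell centre maps to the image
# centre.
.um_to_px <- function(u, n, pixel_size) u * 1000 / pixel_size + (n - 1) / 2
.px_to_um <- function(p, n, pixel_size) (p - (n - 1) / 2) * pixel_size / 1000

# Default field of view: cell plus a margin, in pixels (ncol = x, nrow = y)
.default_dim <- function(geometry, optics, margin_px = 8) {
  nx <- ceiling(geometry$length * 1000 / optics$pixel_size) + 2 * margin_px
  ny <- ceiling(2 * geometry$radius * 1000 / optics$pixel_size) +
    2 * margin_px
  c(ny, nx)
}

# PSF photon mass per pixel for an emitter at continuous pixel position
# (x0, y0): separable product of Gaussian integrals over pixel edges.
.psf_mass <- function(x0, y0, sigma_px, nrow, ncol) {
  mx <- diff(stats::pnorm(seq(-0.5, ncol - 0.5), mean = x0, sd = sigma_px))
  my <- diff(stats::pnorm(seq(-0.5, nrow - 0.5), mean = y0, sd = sigma_px))
  outer(my, mx)
}

# Expected background photons per pixel: volumetric emission integrated
# along z through the spherocylinder (cytosol core + thylakoid shell).
.background_photons <- function(geometry, optics, dim) {
  nrow <- dim[1]; ncol <- dim[2]
  px_um <- optics$pixel_size / 1000
  x_um <- .px_to_um(seq_len(ncol) - 1, ncol, optics$pixel_size)
  y_um <- .px_to_um(seq_len(nrow) - 1, nrow, optics$pixel_size)
  g <- expand.grid(y = y_um, x = x_um)
  d <- .capsule_radial_dist(g$x, g$y, geometry)
  chord <- function(r) ifelse(d < r, 2 * sqrt(pmax(r^2 - d^2, 0)), 0)
  outer_chord <- chord(geometry$radius)
  inner_chord <- chord(geometry$radius - geometry$thylakoid_thickness)
  photons <- geometry$cytosol_photon_density * inner_chord +
    geometry$thylakoid_photon_density * (outer_chord - inner_chord)
  matrix(photons * px_um^2, nrow = nrow, ncol = ncol)
}

#' Render one camera frame of a model cell
#'
#' Forms the expected photon image as the sum of every organelle's PSF
#' contribution plus the volumetric background of the cell, then applies
#' Poisson noise on the photon scale and converts to camera counts:
#' `counts = baseline + gain * Poisson(photons)`.
#'
#' Organelles are rendered as point emitters convolved with the Gaussian
#' PSF; with `render_mode = "sphere"` the emitter is a uniform sphere of
#' the organelle's diameter, approximated by widening the lateral sigma by
#' the projected sphere variance. Axial displacement attenuates the
#' collected photons by the axial Gaussian factor.
#'
#' @param geometry A [cell_geometry()].
#' @param organelles List of [organelle_spec()].
#' @param optics An [optical_model()].
#' @param dim Image dimensions `c(nrow, ncol)`; default covers the cell
#'   with an 8-pixel margin.
#' @param surviving Optional integer vector of currently emitting
#'   fluorophores per organelle (defaults to each `copy_number`).
#' @param noise Logical; `FALSE` returns the noiseless expectation.
#' @param render_mode `"point"` or `"sphere"`.
#' @param read_noise_sd Optional additive Gaussian read noise (counts).
#' @return Numeric matrix of camera counts.
#' @export
render_frame <- function(geometry, organelles, optics, dim = NULL,
                         surviving = NULL, noise = TRUE,
                         render_mode = c("point", "sphere"),
                         read_noise_sd = 0) {
  render_mode <- match.arg(render_mode)
  if (!inherits(optics, "optical_model"))
    stop("optics must be an optical_model", call. = FALSE)
  if (is.null(dim)) dim <- .default_dim(geometry, optics)
  if (is.null(surviving))
    surviving <- vapply(organelles, function(o) o$copy_number, integer(1))
  stopifnot(length(surviving) == length(organelles))
  photons <- .background_photons(geometry, optics, dim)
  for (i in seq_along(organelles)) {
    o <- organelles[[i]]
    if (surviving[i] > o$copy_number)
      stop("surviving count exceeds copy_number", call. = FALSE)
    if (surviving[i] <= 0) next
    sigma_nm <- optics$psf_sigma_lateral
    if (render_mode == "sphere" && o$diameter > 0)
      sigma_nm <- sqrt(sigma_nm^2 + (o$diameter / 2)^2 / 5)
    sigma_px <- sigma_nm / optics$pixel_size
    x0 <- .um_to_px(o$position[1], dim[2], optics$pixel_size)
    y0 <- .um_to_px(o$position[2], dim[1], optics$pixel_size)
    z_nm <- o$position[3] * 1000
    atten <- exp(-z_nm^2 / (2 * optics$psf_sigma_axial^2))
    total <- surviving[i] * o$photons_per_fluorophore * atten
    photons <- photons + total * .psf_mass(x0, y0, sigma_px, dim[1], dim[2])
  }
  if (noise) {
    counts <- optics$baseline +
      optics$counts_per_photon *
        matrix(stats::rpois(length(photons), photons), nrow = dim[1])
    if (read_noise_sd > 0)
      counts <- counts + matrix(stats::rnorm(length(counts),
                                             sd = read_noise_sd),
                                nrow = dim[1])
  } else {
    counts <- optics$baseline + optics$counts_per_photon * photons
  }
  counts
}

.new_image_stack <- function(frames, optics, frame_interval = NA_real_) {
  structure(list(frames = frames,
                 pixel_size = optics$pixel_size,
                 exposure = optics$exposure,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px, %.1f nm/px\n",
              length(x$frames), d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Simulate a Slimfield photobleaching stack with ground truth
#'
#' Each fluorophore of each organelle photobleaches independently at an
#' exponentially distributed frame (geometric per-frame approximation with
#' survival probability `exp(-bleach_rate)` per frame); emission stops
#' after bleaching. Frames are rendered with [render_frame()].
#'
#' @inheritParams render_frame
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; identical seed and configuration reproduce a
#'   bit-identical stack.
#' @return A list with components `stack` (an `image_stack`) and `truth`
#'   (per-organelle bleach frames, per-frame surviving counts, centroids,
#'   and the seed).
#' @export
simulate_photobleach_stack <- function(geometry, organelles, optics,
                                       n_frames, seed = 1, dim = NULL,
                                       noise = TRUE) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  set.seed(seed)
  n_org <- length(organelles)
  surviving <- matrix(0L, nrow = n_frames, ncol = n_org)
  bleach_frames <- vector("list", n_org)
  for (i in seq_len(n_org)) {
    o <- organelles[[i]]
    if (o$bleach_rate > 0) {
      p <- 1 - exp(-o$bleach_rate)
      # frame index of the last frame during which each fluorophore emits
      life <- stats::rgeom(o$copy_number, p) + 1L
    } else {
      life <- rep(Inf, o$copy_number)
    }
    bleach_frames[[i]] <- life
    surviving[, i] <- vapply(seq_len(n_frames),
                             function(f) sum(life >= f), numeric(1))
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames))
    frames[[f]] <- render_frame(geometry, organelles, optics, dim = dim,
                                surviving = surviving[f, ], noise = noise)
  centroids <- t(vapply(organelles, function(o) o$position, numeric(3)))
  list(stack = .new_image_stack(frames, optics),
       truth = list(bleach_frames = bleach_frames, surviving = surviving,
                    centroids = centroids, seed = seed))
}

# Reflect a proposed position at the spherocylinder surface (radial mirror
# about the capsule surface; adequate for steps small relative to the cell
# radius). Points that remain outside after one reflection are clamped
# just inside.
.reflect_into_cell <- function(p, geometry) {
  half_axis <- geometry$length / 2 - geometry$radius
  cx <- min(max(p[1], -half_axis), half_axis)
  u <- p - c(cx, 0, 0)
  d <- sqrt(sum(u^2))
  R <- geometry$radius
  if (d <= R) return(p)
  d_new <- 2 * R - d
  if (d_new < 0) d_new <- 0.99 * R
  c(cx, 0, 0) + u / d * d_new
}

#' Simulate a confocal-style time-lapse stack of diffusing organelles
#'
#' Organelle centroids perform a Brownian random walk: per-frame
#' displacements are independent Gaussian with variance `2 * D * dt` per
#' axis, reflected at the spherocylinder surface so that the stationary
#' density stays uniform. Every frame is rendered with [render_frame()].
#'
#' @inheritParams simulate_photobleach_stack
#' @param frame_interval Time between frames in s.
#' @return List with `stack` (an `image_stack` carrying `frame_interval`)
#'   and `truth` (per-organelle track arrays in µm, the seed).
#' @export
simulate_diffusion_stack <- function(geometry, organelles, optics,
                                     n_frames, frame_interval = 60,
                                     seed = 1, dim = NULL, noise = TRUE) {
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  for (o in organelles)
    if (!inside_cell(o$position, geometry))
      stop("organelle initial position outside the cell", call. = FALSE)
  set.seed(seed)
  n_org <- length(organelles)
  tracks <- vector("list", n_org)
  for (i in seq_len(n_org)) {
    o <- organelles[[i]]
    sd_step <- sqrt(2 * o$diffusion_coefficient * frame_interval)
    pos <- matrix(NA_real_, nrow = n_frames, ncol = 3)
    p <- o$position
    pos[1, ] <- p
    if (n_frames > 1) for (f in 2:n_frames) {
      p <- .reflect_into_cell(p + stats::rnorm(3, sd = sd_step), geometry)
      pos[f, ] <- p
    }
    tracks[[i]] <- pos
  }
  if (is.null(dim)) dim <- .default_dim(geometry, optics)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    orgs_f <- organelles
    for (i in seq_len(n_org)) orgs_f[[i]]$position <- tracks[[i]][f, ]
    frames[[f]] <- render_frame(geometry, orgs_f, optics, dim = dim,
                                noise = noise)
  }
  list(stack = .new_image_stack(frames, optics, frame_interval),
       truth = list(tracks = tracks, seed = seed,
                    frame_interval = frame_interval))
}

#' Fast trace-level photobleaching simulator
#'
#' Generates background-corrected summed-intensity traces directly from
#' the photophysical model, bypassing image rendering and photometry:
#' the trace at frame f is `gain * Poisson(photons * survivors_f)` plus
#' Gaussian residual-background noise. Used for population-scale
#' stoichiometry studies where rendering every organelle's image stack is
#' unnecessary; the image-level and trace-level paths share the same
#' bleaching model.
#'
#' @param n_traces Number of organelles.
#' @param copies True fluorophore copies per organelle (scalar or vector).
#' @param photons_per_fluorophore Photons per fluorophore per frame.
#' @param gain Counts per photon.
#' @param bleach_rate Per-frame bleach rate.
#' @param n_frames Trace length.
#' @param bg_noise_sd Gaussian noise sd (counts) emulating residual
#'   background fluctuation after ROI correction.
#' @param seed Integer seed.
#' @return List with `traces` (list of numeric vectors), `survivors`
#'   (list of integer vectors) and `copies`.
#' @export
simulate_bleach_traces <- function(n_traces, copies,
                                   photons_per_fluorophore = 100,
                                   gain = 10, bleach_rate = 0.015,
                                   n_frames = 600, bg_noise_sd = 30,
                                   seed = 1) {
  set.seed(seed)
  copies <- rep_len(copies, n_traces)
  p <- 1 - exp(-bleach_rate)
  traces <- survivors <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    life <- stats::rgeom(copies[i], p) + 1L
    surv <- vapply(seq_len(n_frames), function(f) sum(life >= f), numeric(1))
    lam <- surv * photons_per_fluorophore
    tr <- gain * stats::rpois(n_frames, lam) +
      stats::rnorm(n_frames, sd = bg_noise_sd)
    traces[[i]] <- tr
    survivors[[i]] <- as.integer(surv)
  }
  list(traces = traces, survivors = survivors, copies = copies)
}
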