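# 2D cross-correlation shift between two frames (b relative to a) with
# parabolic sub-pixel refinement of the correlation peak
.xcorr_shift <- function(a, b) {
  fa <- stats::fft(a - mean(a))
  fb <- stats::fft(b - mean(b))
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  refine <- function(im1, i0, ip) {
    denom <- im1 - 2 * i0 + ip
    if (denom == 0) 0 else 0.5 * (im1 - ip) / denom
  }
  nr <- nrow(a); nc <- ncol(a)
  wrap_r <- function(i) ((i - 1) %% nr) + 1
  wrap_c <- function(j) ((j - 1) %% nc) + 1
  dy <- pk[1] - 1; dx <- pk[2] - 1
  dy <- dy + refine(cc[wrap_r(pk[1] - 1), pk[2]], cc[pk[1], pk[2]],
                    cc[wrap_r(pk[1] + 1), pk[2]])
  dx <- dx + refine(cc[pk[1], wrap_c(pk[2] - 1)], cc[pk[1], pk[2]],
                    cc[pk[1], wrap_c(pk[2] + 1)])
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  c(dx = unname(dx), dy = unname(dy))
}

# translate an image by (dx, dy) pixels with bilinear interpolation,
# filling uncovered pixels with the image median
.translate_bilinear <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  fill <- stats::median(img)
  xs <- seq_len(nc) + dx
  ys <- seq_len(nr) + dy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  at <- function(r, c) {
    ok <- r >= 1 & r <= nr
    okc <- c >= 1 & c <= nc
    m <- matrix(fill, length(r), length(c))
    m[ok, okc] <- img[r[ok], c[okc]]
    m
  }
  (1 - fy) %o% (1 - fx) * at(y0, x0) + (1 - fy) %o% fx * at(y0, x0 + 1) +
    fy %o% (1 - fx) * at(y0 + 1, x0) + fy %o% fx * at(y0 + 1, x0 + 1)
}

#' Correct a time-lapse stack for lateral stage drift
#'
#' Estimates a per-frame translation against the first frame by
#' Fourier cross-correlation with parabolic sub-pixel refinement, and
#' resamples every frame onto the first frame's grid by bilinear
#' interpolation. Frames without structure produce a zero shift with a
#' warning.
#'
#' @param stack An `image_stack` (>= 2 frames).
#' @return List with `stack` (registered) and `shifts` (frames x 2
#'   matrix of estimated drifts `dx`, `dy` in pixels).
#' @export
register_drift <- function(stack) {
  n <- length(stack$frames)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  ref <- stack$frames[[1]]
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dx", "dy")))
  out <- stack
  for (f in 2:n) {
    fr <- stack$frames[[f]]
    if (stats::sd(fr) == 0 || stats::sd(ref) == 0) {
      warning(sprintf("frame %d featureless; zero shift assumed", f))
      next
    }
    s <- .xcorr_shift(fr, ref)
    shifts[f, ] <- s
    out$frames[[f]] <- .translate_bilinear(fr, s["dx"], s["dy"])
  }
  list(stack = out, shifts = shifts)
}

#' Time-averaged mean squared displacement of a track
#'
#' `MSD(tau = k dt)` is the mean over all start frames of the squared
#' 2D displacement after `k` frames, for lags up to half the track
#' length.
#'
#' @param track Matrix or data.frame of positions in µm (columns x, y;
#'   one row per frame, constant frame interval).
#' @param frame_interval Frame interval in s (default 60).
#' @return An `msd_profile`: `tau` (s), `msd` (µm^2), `n_pairs`,
#'   `frame_interval`.
#' @export
msd <- function(track, frame_interval = 60) {
  pos <- as.matrix(track)[, 1:2, drop = FALSE]
  n <- nrow(pos)
  if (n < 8) stop("track too short (need >= 8 frames)", call. = FALSE)
  kmax <- floor(n / 2)
  m <- n_pairs <- numeric(kmax)
  for (k in seq_len(kmax)) {
    d <- pos[(k + 1):n, , drop = FALSE] - pos[1:(n - k), , drop = FALSE]
    m[k] <- mean(rowSums(d^2))
    n_pairs[k] <- n - k
  }
  structure(list(tau = seq_len(kmax) * frame_interval, msd = m,
                 n_pairs = n_pairs, frame_interval = frame_interval),
            class = "msd_profile")
}

#' @export
print.msd_profile <- function(x, ...) {
  cat(sprintf("<msd_profile> %d lags, tau %.3g..%.3g s\n",
              length(x$tau), min(x$tau), max(x$tau)))
  if (!is.null(x$apparent_D))
    cat(sprintf("  apparent D = %.4g um^2/s (intercept %.3g um^2)\n",
                x$apparent_D, x$intercept))
  invisible(x)
}

#' @export
plot.msd_profile <- function(x, ...) {
  graphics::plot(x$tau, x$msd, xlab = "tau (s)", ylab = "MSD (um^2)", ...)
  if (!is.null(x$apparent_D))
    graphics::abline(x$intercept, 4 * x$apparent_D, lty = 2)
  invisible(x)
}

#' Apparent diffusion coefficient from the first MSD points
#'
#' Ordinary least squares of MSD on tau over the first `n_points` lags,
#' with a free intercept absorbing the localization-noise offset;
#' `D = slope / 4` (2D convention). The coefficient is "apparent"
#' because no claim of pure Brownian motion is made beyond the fitted
#' range. A negative slope is reported as `D = 0` with `d_flagged`.
#'
#' @param profile An `msd_profile` with at least `n_points` lags.
#' @param n_points Lags used in the fit (default 6).
#' @return The profile with `apparent_D` (µm^2/s), `intercept` (µm^2)
#'   and `d_flagged` added.
#' @export
fit_apparent_D <- function(profile, n_points = 6) {
  if (length(profile$tau) < n_points)
    stop(sprintf("profile has %d lags; need >= %d", length(profile$tau),
                 n_points), call. = FALSE)
  sel <- seq_len(n_points)
  fit <- stats::lm(profile$msd[sel] ~ profile$tau[sel])
  slope <- unname(stats::coef(fit)[2])
  profile$intercept <- unname(stats::coef(fit)[1])
  profile$d_flagged <- slope < 0
  profile$apparent_D <- max(slope, 0) / 4
  profile
}

#' Anomalous diffusion exponent of an MSD profile
#'
#' Slope of `log(MSD)` versus `log(tau)` over all positive-MSD lags:
#' 1 for Brownian motion, 2 for ballistic motion, below 1 for
#' subdiffusive (confined) motion at the probed timescales.
#'
#' @param profile An `msd_profile`.
#' @return The exponent alpha (numeric).
#' @export
anomalous_exponent <- function(profile) {
  sel <- profile$msd > 0
  if (sum(sel) < 2)
    stop("not enough positive MSD lags for a log-log fit", call. = FALSE)
  fit <- stats::lm(log(profile$msd[sel]) ~ log(profile$tau[sel]))
  unname(stats::coef(fit)[2])
}

#' Track diffusing organelles through a time-lapse stack
#'
#' Convenience wrapper: optional drift registration, detection and
#' linking with [track_stack()] (maximum displacement scaled to the
#' expected Brownian step plus a 3-pixel margin), and conversion of the
#' tracked centroids to µm.
#'
#' @param stack An `image_stack` with `frame_interval` set.
#' @param expected_D Prior diffusion coefficient (µm^2/s) used only to
#'   scale the linking gate.
#' @param register Run drift registration first?
#' @param max_gap Missed detections bridged inside a track (time-lapse
#'   foci are sparse, so small gaps are safe to close).
#' @param ... Passed to [track_stack()].
#' @return List of data.frames with columns `t` (s), `x`, `y` (µm).
#' @export
track_timelapse <- function(stack, expected_D = 2e-5, register = FALSE,
                            max_gap = 2, ...) {
  if (register) stack <- register_drift(stack)$stack
  dt <- stack$frame_interval
  px_um <- stack$pixel_size / 1000
  gate <- sqrt(4 * expected_D * dt) / px_um + 3
  tracks <- track_stack(stack, max_displacement = gate, max_gap = max_gap,
                        ...)
  lapply(tracks, function(tr) {
    m <- tr$measurements
    if (nrow(m) < 2)
      return(data.frame(t = (m$frame - 1) * dt, x = m$x * px_um,
                        y = m$y * px_um))
    frames <- seq(min(m$frame), max(m$frame))
    # bridged gaps are filled by linear interpolation to keep the
    # frame interval constant for the MSD estimator
    x <- stats::approx(m$frame, m$x, xout = frames)$y
    y <- stats::approx(m$frame, m$y, xout = frames)$y
    data.frame(t = (frames - 1) * dt, x = x * px_um, y = y * px_um)
  })
}
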