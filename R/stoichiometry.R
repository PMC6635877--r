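# Background noise estimate for a bleaching trace. Photon noise scales
# with the signal, so the estimate comes from the trace end (where
# bleaching is complete or nearly so): robust sd of first differences
# over the final fifth of the trace.
.trace_noise_sd <- function(trace) {
  tail_len <- max(20, ceiling(length(trace) / 5))
  s <- stats::mad(diff(utils::tail(trace, tail_len))) / sqrt(2)
  if (!is.finite(s) || s == 0)
    s <- max(stats::sd(trace) * 1e-6, .Machine$double.eps)
  s
}

# photometric background noise of a tracked focus: the sd of an
# n_inner-pixel background sum
.focus_noise_sd <- function(tr) {
  m <- rbind(tr$measurements, tr$overtracked_tail)
  stats::median(sqrt(m$n_inner) * m$bg_sd)
}

.as_trace <- function(x) {
  if (!inherits(x, "tracked_focus")) return(as.numeric(x))
  m <- x$measurements
  if (nrow(m) < 2) return(m$summed_intensity)
  frames <- seq(min(m$frame), max(m$frame))
  if (length(frames) == nrow(m)) return(m$summed_intensity)
  # bridge linking gaps so frame index doubles as the time axis
  stats::approx(m$frame, m$summed_intensity, xout = frames)$y
}

#' Chung-Kennedy edge-preserving filter
#'
#' Non-linear two-window filter that suppresses noise on intensity
#' plateaus while preserving abrupt photobleaching steps. Each output
#' point is a weighted mean of the forward-window mean (the `window`
#' samples starting at the point) and the backward-window mean (the
#' `window` samples before it); the weights are the window variances
#' raised to `-exponent`, so the window that straddles a step gets
#' negligible weight. A zero-variance window receives all the weight;
#' when both windows are exactly flat the forward window (which contains
#' the current sample) wins, so noiseless steps pass through unchanged.
#'
#' @param trace Numeric intensity trace (counts per frame) or a
#'   `tracked_focus`.
#' @param window Window length in frames (>= 2, < trace length).
#' @param exponent Positive edge-weighting exponent (larger = harder
#'   switching between windows).
#' @return Numeric filtered trace, same length as the input.
#' @export
chung_kennedy_filter <- function(trace, window = 10, exponent = 4) {
  trace <- .as_trace(trace)
  n <- length(trace)
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  if (window >= n) stop("window must be shorter than the trace",
                        call. = FALSE)
  out <- numeric(n)
  eps <- (max(abs(trace)) + 1) * 1e-12
  for (i in seq_len(n)) {
    fwd <- trace[i:min(n, i + window - 1)]
    bwd <- if (i > 1) trace[max(1, i - window):(i - 1)] else numeric(0)
    mf <- mean(fwd)
    vf <- if (length(fwd) > 1) stats::var(fwd) else Inf
    mb <- if (length(bwd) > 0) mean(bwd) else NA_real_
    vb <- if (length(bwd) > 1) stats::var(bwd) else Inf
    if (is.na(mb)) { out[i] <- mf; next }
    zf <- vf <= eps; zb <- vb <= eps
    if (zf) { out[i] <- mf; next }          # flat forward window wins
    if (zb) { out[i] <- mb; next }
    wf <- vf^(-exponent); wb <- vb^(-exponent)
    out[i] <- (wf * mf + wb * mb) / (wf + wb)
  }
  out
}

.new_unit_intensity <- function(value, method, uncertainty) {
  if (value <= 0) stop("unit intensity must be positive", call. = FALSE)
  structure(list(value = value, method = method,
                 uncertainty = max(uncertainty, 0)),
            class = "unit_intensity")
}

#' @export
print.unit_intensity <- function(x, ...) {
  cat(sprintf("<unit_intensity> %.4g counts (+/- %.2g), method: %s\n",
              x$value, x$uncertainty, x$method))
  invisible(x)
}

# peak and half width at half maximum of a density curve around its argmax
.density_peak_hwhm <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  left <- which(y[seq_len(i)] < half)
  right <- which(y[i:length(y)] < half)
  wl <- if (length(left)) x[i] - x[max(left)] else NA_real_
  wr <- if (length(right)) x[i + min(right) - 1] - x[i] else NA_real_
  hw <- mean(c(wl, wr), na.rm = TRUE)
  if (!is.finite(hw)) hw <- 0
  list(peak = x[i], hwhm = hw)
}

#' Characteristic single-fluorophore intensity from end-of-bleach samples
#'
#' Pools focus intensities from the final `tail_fraction` of every
#' track's visible bleaching course (the stretch before the trace falls
#' permanently below the noise floor), together with any overtracked-tail
#' samples above background, and returns the modal peak of their kernel
#' density as the characteristic intensity of one fluorophore. The
#' uncertainty is the half width at half maximum of that modal peak.
#'
#' @param tracks List of numeric traces and/or `tracked_focus` objects.
#' @param tail_fraction Fraction of each track's visible length pooled
#'   from the end.
#' @param noise_sd Background noise sd in counts; estimated per trace
#'   from first differences when `NULL`. Samples must exceed
#'   `3 * noise_sd` to enter the distribution.
#' @param bw Kernel bandwidth for the sample density (Silverman when
#'   `NULL`).
#' @param min_samples Minimum pooled sample count (default 20).
#' @return A `unit_intensity` object.
#' @export
unit_intensity_endpoint <- function(tracks, tail_fraction = 0.25,
                                    noise_sd = NULL, bw = NULL,
                                    min_samples = 20) {
  samples <- numeric(0)
  for (tr in tracks) {
    trace <- .as_trace(tr)
    ns <- if (!is.null(noise_sd)) noise_sd
      else if (inherits(tr, "tracked_focus")) .focus_noise_sd(tr)
      else .trace_noise_sd(trace)
    floor_ <- 3 * ns
    # end of the visible bleach course, judged on a 5-frame running
    # mean so an isolated noise spike cannot stretch the window into
    # pure background
    smooth <- stats::filter(trace, rep(1 / 5, 5), sides = 2)
    smooth[is.na(smooth)] <- trace[is.na(smooth)]
    above <- which(smooth > floor_)
    if (length(above) == 0) next
    end <- max(above)
    start <- max(1, ceiling(end * (1 - tail_fraction)))
    seg <- trace[start:end]
    samples <- c(samples, seg[seg > floor_])
    if (inherits(tr, "tracked_focus") && nrow(tr$overtracked_tail) > 0) {
      ov <- tr$overtracked_tail$summed_intensity
      samples <- c(samples, ov[ov > floor_])
    }
  }
  if (length(samples) < min_samples)
    stop(sprintf(paste0("only %d end-of-bleach samples (need >= %d); ",
                        "provide more tracks"),
                 length(samples), min_samples), call. = FALSE)
  d <- if (is.null(bw)) stats::density(samples) else
    stats::density(samples, bw = bw)
  # the unit is the lowest quantized intensity level: take the
  # lowest-intensity substantial local maximum (higher maxima are the
  # two-, three-fluorophore dwells)
  lm_idx <- which(diff(sign(diff(d$y))) == -2) + 1
  lm_idx <- lm_idx[d$y[lm_idx] >= 0.1 * max(d$y)]
  i <- if (length(lm_idx)) lm_idx[1] else which.max(d$y)
  half <- d$y[i] / 2
  left <- which(d$y[seq_len(i)] < half)
  right <- which(d$y[i:length(d$y)] < half)
  wl <- if (length(left)) d$x[i] - d$x[max(left)] else NA_real_
  wr <- if (length(right)) d$x[i + min(right) - 1] - d$x[i] else NA_real_
  hw <- mean(c(wl, wr), na.rm = TRUE)
  .new_unit_intensity(d$x[i], "endpoint", if (is.finite(hw)) hw else 0)
}

#' Characteristic intensity from the Fourier spectrum of intensity values
#'
#' Estimates the single-fluorophore intensity as the fundamental period
#' of the intensity distribution: a narrow-kernel density of the values
#' is detrended by a wide-kernel density (removing the distribution
#' envelope) and Fourier transformed over the intensity axis; the
#' reciprocal of the dominant frequency is returned. Values clustered at
#' integer multiples of the unit produce a comb whose fundamental is the
#' unit itself. Significance of the dominant peak is calibrated against
#' a Monte-Carlo null: the same spectral statistic computed on
#' envelope-preserving resamples of the values (bootstrap plus a
#' wide-kernel jitter, which destroys periodicity but keeps the overall
#' distribution shape). If the observed peak does not exceed the null
#' the estimator signals failure so the caller can fall back to
#' [unit_intensity_endpoint()].
#'
#' @param values Numeric intensity samples (>= 50, spanning several
#'   multiples of the unit).
#' @param bw Narrow kernel bandwidth (default: 1/100 of the value range).
#' @param n_null Number of null resamples for the significance test.
#' @param alpha Significance level on the null peak-power distribution.
#' @return A `unit_intensity`, or `NULL` when no significant periodicity
#'   is found.
#' @export
unit_intensity_fourier <- function(values, bw = NULL, n_null = 60,
                                   alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 50)
    stop("need >= 50 intensity values", call. = FALSE)
  rng <- diff(range(values))
  if (is.null(bw)) bw <- max(rng / 100, .Machine$double.eps)
  vmax <- max(values)
  if (rng < 2 * bw)  # degenerate: a single intensity level
    return(.new_unit_intensity(mean(values), "fourier", stats::sd(values)))
  n_grid <- 4096
  L <- vmax + 4 * bw
  dx <- L / (n_grid - 1)
  band_power <- function(v) {
    dens <- function(b) stats::density(v, bw = b, from = 0, to = L,
                                       n = n_grid)$y
    signal <- dens(bw) - dens(rng / 4)   # comb minus envelope
    Mod(stats::fft(signal - mean(signal)))^2
  }
  freq <- (seq_len(n_grid) - 1) / (n_grid * dx)
  band <- which(freq > 2 / vmax & freq < 1 / (4 * bw) &
                  seq_len(n_grid) <= n_grid / 2)
  if (length(band) < 3) return(NULL)
  p <- band_power(values)
  pk <- band[which.max(p[band])]
  # Monte-Carlo null with an internally fixed, caller-restored RNG state
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(871221L)
  null_max <- vapply(seq_len(n_null), function(i) {
    v0 <- sample(values, replace = TRUE) +
      stats::rnorm(length(values), sd = rng / 4)
    max(band_power(v0)[band])
  }, numeric(1))
  p_val <- (1 + sum(null_max >= p[pk])) / (n_null + 1)
  if (p_val > alpha) return(NULL)
  # parabolic interpolation of the spectral peak for sub-bin frequency
  f0 <- freq[pk]
  if (pk > 1 && pk < n_grid / 2) {
    a <- p[pk - 1]; b <- p[pk]; c <- p[pk + 1]
    denom <- a - 2 * b + c
    if (denom != 0)
      f0 <- freq[pk] + 0.5 * (a - c) / denom * (freq[2] - freq[1])
  }
  # half-power width of the peak -> uncertainty on the period
  halfp <- p[pk] / 2
  lo <- pk; while (lo > band[1] && p[lo] > halfp) lo <- lo - 1
  hi <- pk; while (hi < band[length(band)] && p[hi] > halfp) hi <- hi + 1
  df <- (freq[hi] - freq[lo]) / 2
  unit <- 1 / f0
  .new_unit_intensity(unit, "fourier", unit * df / f0)
}

#' Initial (unbleached) intensity of a photobleaching trace
#'
#' Fits a single exponential decay to the Chung-Kennedy-filtered trace
#' and back-extrapolates it to frame 0, correcting for the bleaching
#' that occurs during the first illuminated frames. Falls back to the
#' mean of the first `n_initial` frames when the fit cannot be obtained.
#'
#' @param trace Numeric trace (frame 1 is the first exposure) or a
#'   `tracked_focus`.
#' @param n_initial Frames averaged by the fallback estimator.
#' @param ck_window,ck_exponent Chung-Kennedy filter parameters.
#' @return Intensity in counts at frame 0 (0 for an all-zero trace).
#' @export
initial_intensity <- function(trace, n_initial = 10, ck_window = 10,
                              ck_exponent = 4) {
  trace <- .as_trace(trace)
  if (all(trace == 0)) return(0)
  if (stats::sd(trace) == 0) return(trace[1])
  filt <- chung_kennedy_filter(trace, window = ck_window,
                               exponent = ck_exponent)
  floor_ <- 3 * .trace_noise_sd(trace)
  sel <- which(filt > floor_)
  fallback <- mean(trace[seq_len(min(n_initial, length(trace)))])
  if (length(sel) < 5) return(fallback)
  t <- sel
  y <- filt[sel]
  # log-linear start values, then least squares on the linear scale
  lf <- stats::lm(log(y) ~ t)
  a0 <- exp(stats::coef(lf)[1])
  k0 <- max(-stats::coef(lf)[2], 1e-8)
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-k * t), start = list(A = a0, k = k0),
               algorithm = "port", lower = c(A = 0, k = 0),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  unname(stats::coef(fit)[["A"]])
}

#' Fluorophore copies in one focus
#'
#' Converts a track's back-extrapolated initial intensity to absolute
#' fluorophore copies by dividing by the characteristic
#' single-fluorophore intensity. For acquisitions made through a neutral
#' density filter, `attenuation_factor` rescales the measured intensity
#' to the unattenuated scale first.
#'
#' @param track Numeric trace or `tracked_focus`.
#' @param unit A `unit_intensity`.
#' @param attenuation_factor Multiplier applied to the measured
#'   intensity before division (default 1).
#' @param ... Passed to [initial_intensity()].
#' @return One-row `data.frame` with `id`, `initial_intensity`, `copies`.
#' @export
copies_per_focus <- function(track, unit, attenuation_factor = 1, ...) {
  if (!inherits(unit, "unit_intensity") || unit$value <= 0)
    stop("unit must be a positive unit_intensity", call. = FALSE)
  id <- if (inherits(track, "tracked_focus")) track$id else NA_integer_
  init <- initial_intensity(track, ...) * attenuation_factor
  data.frame(id = id, initial_intensity = init,
             copies = max(init, 0) / unit$value)
}
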