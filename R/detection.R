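# Coordinate convention used throughout: 0-based pixel indices with the
# origin of each pixel at its centre, x along columns, y along rows.
# Matrices are indexed [row, col] = [y + 1, x + 1].

# TRUE where a pixel is a strict-or-plateau local maximum in its 3x3
# neighbourhood
.local_maxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- img[rs[ok_r], cs[ok_c]]
    out
  }
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (img >= shift(dr, dc))
  }
  res
}

#' Find candidate fluorescent foci in one image
#'
#' Applies a morphological top-hat transform (image minus its grayscale
#' opening with a disc structuring element) to suppress slowly varying
#' background, then thresholds and keeps local maxima separated by at
#' least `min_separation` pixels (brighter candidate wins a merge).
#'
#' @param image Numeric matrix (one frame).
#' @param threshold Absolute threshold on the top-hat image; default
#'   `median + threshold_sd * mad` of the top-hat image.
#' @param threshold_sd Robust z-score used for the default threshold.
#' @param tophat_radius Disc radius (pixels) of the structuring element.
#' @param min_separation Minimum distance between candidates in pixels.
#' @return `data.frame` with columns `x`, `y` (0-based pixel positions)
#'   and `value` (top-hat intensity), ordered by decreasing value. Empty
#'   for featureless images.
#' @export
find_candidates <- function(image, threshold = NULL, threshold_sd = 5,
                            tophat_radius = 5, min_separation = 2) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("image must be a finite numeric matrix", call. = FALSE)
  if (stats::sd(image) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  brush <- EBImage::makeBrush(2 * tophat_radius + 1, shape = "disc")
  tophat <- image - EBImage::opening(image, brush)
  if (is.null(threshold)) {
    m <- stats::median(tophat)
    s <- stats::mad(tophat)
    if (s == 0) s <- stats::sd(tophat)
    threshold <- m + threshold_sd * s
  }
  cand <- which(.local_maxima(tophat) & tophat > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  vals <- tophat[cand]
  ord <- order(-vals)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    d2 <- (kept[, 1] - cand[i, 1])^2 + (kept[, 2] - cand[i, 2])^2
    keep[i] <- all(d2 >= min_separation^2)
  }
  data.frame(x = cand[keep, 2] - 1, y = cand[keep, 1] - 1,
             value = vals[keep])
}

#' Sub-pixel localization by iterative Gaussian masking
#'
#' Repeatedly multiplies a local background-subtracted window by a
#' Gaussian mask centred on the current estimate and moves the estimate to
#' the intensity-weighted centroid, until the displacement per iteration
#' falls below `tol`.
#'
#' @param image Numeric matrix.
#' @param initial Numeric `(x, y)` starting position, 0-based pixels.
#' @param mask_sigma Gaussian mask sigma in pixels (default: the PSF
#'   sigma is the natural choice).
#' @param tol Convergence tolerance in pixels.
#' @param max_iter Iteration cap; non-convergence is flagged, not an
#'   error, so callers can exclude the measurement.
#' @param window_radius Half-width of the local analysis window.
#' @return List with `centroid` (x, y), `converged`, `iterations`.
#' @export
iterative_gaussian_mask <- function(image, initial, mask_sigma = 2,
                                    tol = 1e-3, max_iter = 100,
                                    window_radius = NULL) {
  if (mask_sigma <= 0) stop("mask_sigma must be > 0", call. = FALSE)
  if (initial[1] < 0 || initial[1] > ncol(image) - 1 ||
      initial[2] < 0 || initial[2] > nrow(image) - 1)
    stop("initial position outside image", call. = FALSE)
  if (is.null(window_radius))
    window_radius <- max(7, ceiling(3 * mask_sigma))
  centre <- as.numeric(initial)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    cx <- round(centre[1]); cy <- round(centre[2])
    xs <- max(0, cx - window_radius):min(ncol(image) - 1, cx + window_radius)
    ys <- max(0, cy - window_radius):min(nrow(image) - 1, cy + window_radius)
    win <- image[ys + 1, xs + 1, drop = FALSE]
    # local background: mean over the window border
    border <- rbind(win[1, , drop = FALSE], win[nrow(win), , drop = FALSE])
    border <- c(border, win[, 1], win[, ncol(win)])
    w <- pmax(win - mean(border), 0)
    gx <- exp(-(xs - centre[1])^2 / (2 * mask_sigma^2))
    gy <- exp(-(ys - centre[2])^2 / (2 * mask_sigma^2))
    w <- w * outer(gy, gx)
    tot <- sum(w)
    if (tot <= 0) break
    new_centre <- c(sum(w %*% xs) / tot, sum(ys %*% w) / tot)
    shift <- sqrt(sum((new_centre - centre)^2))
    centre <- new_centre
    if (shift < tol) { converged <- TRUE; break }
  }
  list(centroid = centre, converged = converged, iterations = iter)
}

#' Background-corrected ROI photometry of one focus
#'
#' Sums the intensity inside a circular region of interest of
#' `inner_radius` pixels around the centroid (pixel membership by
#' centre-in-circle) and corrects it with the mean background estimated
#' over a surrounding `bg_size` x `bg_size` pixel window excluding the
#' inner disk. The signal-to-noise ratio is the background-corrected mean
#' inner intensity divided by the standard deviation of the outer region.
#'
#' @param image Numeric matrix.
#' @param centroid `(x, y)` sub-pixel position, 0-based pixels.
#' @param inner_radius Circular ROI radius in pixels (default 5).
#' @param bg_size Side of the square background window in pixels
#'   (default 17).
#' @param frame Optional frame index stored in the measurement.
#' @return A one-row `data.frame` (class `focus_measurement`) with
#'   columns `frame`, `x`, `y`, `summed_intensity`, `bg_mean`, `bg_sd`,
#'   `snr`, `n_inner`, `edge_truncated`.
#' @export
measure_intensity <- function(image, centroid, inner_radius = 5,
                              bg_size = 17, frame = NA_integer_) {
  cx <- round(centroid[1]); cy <- round(centroid[2])
  half <- (bg_size - 1) / 2
  xs <- (cx - half):(cx + half)
  ys <- (cy - half):(cy + half)
  edge <- any(xs < 0) || any(xs > ncol(image) - 1) ||
    any(ys < 0) || any(ys > nrow(image) - 1)
  xs <- xs[xs >= 0 & xs <= ncol(image) - 1]
  ys <- ys[ys >= 0 & ys <= nrow(image) - 1]
  win <- image[ys + 1, xs + 1, drop = FALSE]
  d2 <- outer((ys - centroid[2])^2, (xs - centroid[1])^2, `+`)
  inner <- d2 <= inner_radius^2
  n_inner <- sum(inner)
  bg_vals <- win[!inner]
  bg_mean <- if (length(bg_vals)) mean(bg_vals) else 0
  bg_sd <- if (length(bg_vals) > 1) stats::sd(bg_vals) else 0
  summed <- sum(win[inner]) - n_inner * bg_mean
  inner_mean <- if (n_inner > 0) summed / n_inner else 0
  snr <- if (bg_sd > 0) inner_mean / bg_sd else
    if (inner_mean > 0) Inf else 0
  out <- data.frame(frame = frame, x = centroid[1], y = centroid[2],
                    summed_intensity = summed, bg_mean = bg_mean,
                    bg_sd = bg_sd, snr = snr, n_inner = n_inner,
                    edge_truncated = edge)
  class(out) <- c("focus_measurement", "data.frame")
  out
}

#' Accept or reject a focus by its signal-to-noise ratio
#'
#' A focus is kept only if its SNR strictly exceeds the threshold
#' (default 0.4, the gate used for Slimfield foci).
#'
#' @param measurement A `focus_measurement` row (or anything with an
#'   `snr` element).
#' @param snr_threshold Strict lower bound on the SNR.
#' @return Logical.
#' @export
accept_focus <- function(measurement, snr_threshold = 0.4) {
  if (snr_threshold <= 0) stop("snr_threshold must be > 0", call. = FALSE)
  isTRUE(measurement$snr > snr_threshold)
}

#' Link per-frame focus measurements into tracks
#'
#' Greedy nearest-neighbour assignment between consecutive frames: pairs
#' are linked in order of increasing distance, each focus used at most
#' once, links longer than `max_displacement` forbidden. Equidistant
#' candidates are resolved in favour of the lowest track id. Tracks may
#' bridge up to `max_gap` missing frames (default 0: no gap closing).
#'
#' @param measurements `data.frame` of accepted measurements with at
#'   least columns `frame`, `x`, `y`.
#' @param max_displacement Maximum link length in pixels.
#' @param max_gap Maximum number of skipped frames inside a track.
#' @return List of `tracked_focus` objects: each has `id`,
#'   `measurements` (a `data.frame`) and an empty `overtracked_tail`
#'   (filled by [track_stack()]).
#' @export
link_foci <- function(measurements, max_displacement = 5, max_gap = 0) {
  if (nrow(measurements) == 0) return(list())
  measurements <- measurements[order(measurements$frame), , drop = FALSE]
  frames <- sort(unique(measurements$frame))
  track_id_of <- integer(0)        # per measurement row
  rows_of_track <- list()
  head_pos <- list()               # track id -> c(x, y, last_frame)
  next_id <- 1L
  assign_rows <- function(rows) {
    for (r in rows) {
      rows_of_track[[next_id]] <<- r
      head_pos[[next_id]] <<- c(measurements$x[r], measurements$y[r],
                                measurements$frame[r])
      next_id <<- next_id + 1L
    }
  }
  for (f in frames) {
    rows <- which(measurements$frame == f)
    if (length(head_pos) == 0) { assign_rows(rows); next }
    active <- which(vapply(head_pos, function(h)
      f - h[3] >= 1 && f - h[3] <= max_gap + 1, logical(1)))
    if (length(active) == 0) { assign_rows(rows); next }
    # candidate links sorted by (distance, track id) for determinism
    cand <- expand.grid(t = active, r = rows)
    cand$d <- sqrt((vapply(head_pos[cand$t], `[`, numeric(1), 1) -
                      measurements$x[cand$r])^2 +
                   (vapply(head_pos[cand$t], `[`, numeric(1), 2) -
                      measurements$y[cand$r])^2)
    cand <- cand[cand$d <= max_displacement, , drop = FALSE]
    cand <- cand[order(cand$d, cand$t), , drop = FALSE]
    used_t <- integer(0); used_r <- integer(0)
    for (k in seq_len(nrow(cand))) {
      t <- cand$t[k]; r <- cand$r[k]
      if (t %in% used_t || r %in% used_r) next
      rows_of_track[[t]] <- c(rows_of_track[[t]], r)
      head_pos[[t]] <- c(measurements$x[r], measurements$y[r], f)
      used_t <- c(used_t, t); used_r <- c(used_r, r)
    }
    assign_rows(setdiff(rows, used_r))
  }
  lapply(seq_along(rows_of_track), function(id) {
    m <- measurements[rows_of_track[[id]], , drop = FALSE]
    rownames(m) <- NULL
    structure(list(id = id, measurements = m,
                   overtracked_tail = m[0, , drop = FALSE]),
              class = "tracked_focus")
  })
}

#' @export
print.tracked_focus <- function(x, ...) {
  cat(sprintf("<tracked_focus> id %d, %d frames (+%d overtracked)\n",
              x$id, nrow(x$measurements), nrow(x$overtracked_tail)))
  invisible(x)
}

#' Detect, measure and track foci through an image stack
#'
#' Runs the full per-frame detection chain (candidate finding, iterative
#' Gaussian-mask localization, ROI photometry, SNR gating), links the
#' accepted measurements into tracks, and finally "overtracks" each
#' ended track: photometry continues at the last known centroid for
#' `overtrack_frames` further frames, sampling intensities at and below
#' the single-fluorophore level for the unit-intensity estimators.
#'
#' Measurements whose background window leaves the image are flagged
#' `edge_truncated` and excluded from tracking.
#'
#' @param stack An `image_stack`.
#' @param mask_sigma,snr_threshold,max_displacement,max_gap,inner_radius,bg_size,threshold_sd
#'   Stage parameters, see the stage functions.
#' @param overtrack_frames Number of frames measured past each track end.
#' @return List of `tracked_focus`.
#' @export
track_stack <- function(stack, mask_sigma = 2, snr_threshold = 0.4,
                        max_displacement = 5, max_gap = 0,
                        inner_radius = 5, bg_size = 17,
                        threshold_sd = 5, overtrack_frames = 0) {
  all_meas <- list()
  for (f in seq_along(stack$frames)) {
    img <- stack$frames[[f]]
    cand <- find_candidates(img, threshold_sd = threshold_sd)
    frame_meas <- list()
    for (i in seq_len(nrow(cand))) {
      loc <- iterative_gaussian_mask(img, c(cand$x[i], cand$y[i]),
                                     mask_sigma = mask_sigma)
      if (!loc$converged) next
      m <- measure_intensity(img, loc$centroid, inner_radius = inner_radius,
                             bg_size = bg_size, frame = f)
      if (m$edge_truncated) next
      if (accept_focus(m, snr_threshold))
        frame_meas[[length(frame_meas) + 1]] <- m
    }
    if (length(frame_meas) == 0) next
    fm <- do.call(rbind, frame_meas)
    # distinct candidates frequently converge onto the same focus;
    # keep the brightest measurement per converged position
    fm <- fm[order(-fm$summed_intensity), , drop = FALSE]
    keep <- rep(TRUE, nrow(fm))
    for (i in seq_len(nrow(fm))) {
      if (!keep[i]) next
      if (i < nrow(fm)) {
        later <- (i + 1):nrow(fm)
        d2 <- (fm$x[later] - fm$x[i])^2 + (fm$y[later] - fm$y[i])^2
        keep[later][d2 < 2^2] <- FALSE
      }
    }
    all_meas[[length(all_meas) + 1]] <- fm[keep, , drop = FALSE]
  }
  if (length(all_meas) == 0) return(list())
  meas <- do.call(rbind, all_meas)
  tracks <- link_foci(meas, max_displacement = max_displacement,
                      max_gap = max_gap)
  n_frames <- length(stack$frames)
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    last <- tr$measurements[nrow(tr$measurements), ]
    tail_frames <- seq(last$frame + 1,
                       min(n_frames, last$frame + overtrack_frames))
    if (overtrack_frames > 0 && last$frame < n_frames) {
      tail <- do.call(rbind, lapply(tail_frames, function(f)
        measure_intensity(stack$frames[[f]], c(last$x, last$y),
                          inner_radius = inner_radius, bg_size = bg_size,
                          frame = f)))
      tracks[[i]]$overtracked_tail <- tail
    }
  }
  tracks
}
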