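#' Fluorescence image time series
#'
#' @param frames list of numeric matrices of constant shape, non-negative
#'   intensities (counts)
#' @param timestamps_s strictly increasing acquisition times, seconds from
#'   series start; default follows the acquisition cadence
#'   `(exposure + pause) * frame index`
#' @param exposure_ms,pause_ms acquisition metadata (defaults: 200-ms
#'   exposure, 600-ms pause)
#' @return An object of class `image_series`.
#' @export
image_series <- function(frames, timestamps_s = NULL,
                         exposure_ms = 200, pause_ms = 600) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), dims) &&
                 all(f >= 0), logical(1))
  if (!all(ok)) stop("frames must be non-negative matrices of constant shape")
  if (is.null(timestamps_s))
    timestamps_s <- (seq_along(frames) - 1) * (exposure_ms + pause_ms) / 1000
  stopifnot(length(timestamps_s) == length(frames),
            all(diff(timestamps_s) > 0) || length(frames) == 1)
  structure(list(frames = frames, timestamps_s = timestamps_s,
                 exposure_ms = exposure_ms, pause_ms = pause_ms),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_series> %d frames of %d x %d, %.3g s span\n",
              length(x$frames), d[1], d[2],
              diff(range(x$timestamps_s))))
  invisible(x)
}

#' Region-of-interest specification
#'
#' Rectangle (row/column extents) or explicit pixel mask, plus the number of
#' brightest pixels averaged by [roi_intensity()] (default 21).
#'
#' @param row0,col0 top-left corner (1-based)
#' @param height,width rectangle size in pixels
#' @param mask optional logical matrix (frame-shaped); overrides the
#'   rectangle
#' @param k number of brightest pixels to average (default 21); clipped to
#'   the region size with a warning when the region is smaller
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(row0 = 1, col0 = 1, height = NULL, width = NULL,
                     mask = NULL, k = 21) {
  stopifnot(k >= 1, k == round(k))
  structure(list(row0 = row0, col0 = col0, height = height, width = width,
                 mask = mask, k = as.integer(k)), class = "roi_spec")
}

roi_pixels <- function(frame, roi) {
  if (!is.null(roi$mask)) {
    stopifnot(identical(dim(roi$mask), dim(frame)))
    px <- frame[roi$mask]
  } else {
    stopifnot(roi$row0 >= 1, roi$col0 >= 1, !is.null(roi$height),
              !is.null(roi$width),
              roi$row0 + roi$height - 1 <= nrow(frame),
              roi$col0 + roi$width - 1 <= ncol(frame))
    px <- frame[seq.int(roi$row0, length.out = roi$height),
                seq.int(roi$col0, length.out = roi$width)]
  }
  as.numeric(px) # row-major flattening is irrelevant: order statistics only
}

#' ROI intensity as the mean of the k brightest pixels
#'
#' The detection statistic of the fluorescence-imager protocol: the mean of
#' the `k` (default 21) largest pixel values inside the region. Ties at the
#' k-th value are broken by pixel order, which is immaterial for the mean.
#'
#' @param frame numeric matrix
#' @param roi a [roi_spec()]
#' @return Scalar intensity.
#' @export
roi_intensity <- function(frame, roi = roi_spec(1, 1, nrow(frame), ncol(frame))) {
  px <- roi_pixels(frame, roi)
  if (length(px) == 0) stop("empty ROI")
  k <- roi$k
  if (k > length(px)) {
    warning("k larger than ROI (", length(px), " pixels); clipped")
    k <- length(px)
  }
  mean(sort(px, decreasing = TRUE)[seq_len(k)])
}

#' ROI intensity trace of an image series
#'
#' @param series an [image_series()]
#' @param roi a [roi_spec()]
#' @param refind if `TRUE` the k brightest pixels are re-detected per frame
#'   (the default); the ROI region itself stays fixed
#' @return Numeric vector, one intensity per frame.
#' @export
series_intensity <- function(series, roi, refind = TRUE) {
  stopifnot(inherits(series, "image_series"))
  if (refind)
    return(vapply(series$frames, roi_intensity, numeric(1), roi = roi))
  # fixed-pixel mode: brightest pixels located on the first frame
  px1 <- roi_pixels(series$frames[[1]], roi)
  k <- min(roi$k, length(px1))
  sel <- order(px1, decreasing = TRUE)[seq_len(k)]
  vapply(series$frames, function(f) mean(roi_pixels(f, roi)[sel]), numeric(1))
}

#' Normalize an intensity series to its first value
#'
#' @param intensities numeric vector with positive first element
#' @return `intensities / intensities[1]` (first element exactly 1).
#' @export
normalize_series <- function(intensities) {
  stopifnot(length(intensities) >= 1)
  if (!is.finite(intensities[1]) || intensities[1] <= 0)
    stop("first value must be positive for first-frame normalization")
  intensities / intensities[1]
}

#' Stability metrics of a normalized intensity series
#'
#' @param normalized series normalized to its first value
#'   (see [normalize_series()])
#' @param band_halfwidth relative half-width of the compliance band around 1
#'   (default 0.02, the +/- 2 percent interval)
#' @param timestamps_s optional timestamps for drift in percent per minute
#' @return An object of class `stability_report`: `std_percent` (sample,
#'   n-1, of the normalized series, in percent), `drift_percent_per_frame`
#'   and `drift_percent_per_min` (ordinary least squares), `in_band_fraction`,
#'   `n`, and `available = FALSE` when fewer than 3 points were supplied.
#' @export
stability_metrics <- function(normalized, band_halfwidth = 0.02,
                              timestamps_s = NULL) {
  n <- length(normalized)
  inband <- mean(abs(normalized - 1) <= band_halfwidth)
  if (n < 3) {
    return(structure(list(available = FALSE, n = n,
                          std_percent = NA_real_,
                          drift_percent_per_frame = NA_real_,
                          drift_percent_per_min = NA_real_,
                          in_band_fraction = inband,
                          band_halfwidth = band_halfwidth),
                     class = "stability_report"))
  }
  fr <- seq_len(n) - 1
  slope <- coef(lm(normalized ~ fr))[[2]]
  per_min <- if (!is.null(timestamps_s)) {
    tmin <- timestamps_s / 60
    coef(lm(normalized ~ tmin))[[2]] * 100
  } else NA_real_
  structure(list(available = TRUE, n = n,
                 std_percent = 100 * sd(normalized),
                 drift_percent_per_frame = 100 * slope,
                 drift_percent_per_min = per_min,
                 in_band_fraction = inband,
                 band_halfwidth = band_halfwidth),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  if (!x$available) {
    cat("<stability_report> fewer than 3 points; metrics unavailable\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<stability_report> n = %d, std = %.3g%%, drift = %.3g%%/frame, %.3g%% of points within +/-%g%%\n",
    x$n, x$std_percent, x$drift_percent_per_frame,
    100 * x$in_band_fraction, 100 * x$band_halfwidth))
  invisible(x)
}

#' Fit an exponential photobleaching model to an intensity series
#'
#' Least-squares fit of `I(t) = A * exp(-k t) + B`. The total relative drop
#' is evaluated on the fitted curve between the first and last timestamps.
#' When the nonlinear fit cannot converge the raw first-versus-last drop is
#' reported with `converged = FALSE`.
#'
#' @param intensities raw (unnormalized) intensity series, >= 5 points
#' @param timestamps time of each point (frames, seconds, or days — the rate
#'   is reported in the reciprocal unit)
#' @return List `total_drop_percent`, `rate`, `amplitude`, `offset`,
#'   `converged`.
#' @export
fit_bleaching <- function(intensities, timestamps = seq_along(intensities) - 1) {
  stopifnot(length(intensities) >= 5,
            length(timestamps) == length(intensities))
  y <- as.numeric(intensities)
  t <- as.numeric(timestamps)
  span <- diff(range(t))
  if (sd(y) < 1e-12 * max(abs(y))) {
    return(list(total_drop_percent = 0, rate = 0, amplitude = 0,
                offset = y[1], converged = TRUE))
  }
  nh <- max(2, length(y) %/% 5)
  k0 <- (log(max(mean(head(y, nh)), 1e-12)) -
         log(max(mean(tail(y, nh)), 1e-12))) / max(span, 1e-12)
  k0 <- max(k0, 1e-6 / max(span, 1))
  resid_fn <- function(p) y - (p[1] * exp(-p[3] * t) + p[2])
  starts <- list(c(max(y[1] - min(y) / 2, 0.1 * y[1]), min(y) / 2, k0),
                 c(y[1], 0, 2 * k0),
                 c(diff(range(y)) + 0.1 * y[1], 0.9 * min(y), k0 / 2))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = c(0, -Inf, 0), upper = c(Inf, Inf, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4 &&
        (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) {
    return(list(total_drop_percent = 100 * (y[1] - y[length(y)]) / y[1],
                rate = NA_real_, amplitude = NA_real_, offset = NA_real_,
                converged = FALSE))
  }
  p <- list(A = best$par[1], B = best$par[2], k = best$par[3])
  f <- function(tt) p$A * exp(-p$k * tt) + p$B
  i0 <- f(t[1]); i1 <- f(t[length(t)])
  list(total_drop_percent = 100 * (i0 - i1) / i0,
       rate = p$k, amplitude = p$A, offset = p$B, converged = TRUE)
}
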