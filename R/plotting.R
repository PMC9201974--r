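#' Plot a DTOF on a log count scale
#'
#' @param x a [dtof()]
#' @param log plot log10 of the values (default TRUE)
#' @param ... passed to [graphics::plot()]
#' @return Invisibly `x`.
#' @export
plot.dtof <- function(x, log = TRUE, ...) {
  tt <- dtof_times(x)
  v <- x$values
  if (log) {
    keep <- v > 0
    graphics::plot(tt[keep], log10(v[keep]), type = "l",
                   xlab = "time (ps)", ylab = "log10 weight", ...)
  } else {
    graphics::plot(tt, v, type = "l", xlab = "time (ps)",
                   ylab = "weight", ...)
  }
  invisible(x)
}

#' Heatmap of a property map
#'
#' Renders the lattice as an image; masked cells are blank. The phantom
#' outline is overlaid as a circle.
#'
#' @param x a [property_map_frame()]
#' @param ... passed to [graphics::image()]
#' @return Invisibly `x`.
#' @export
plot.property_map <- function(x, ...) {
  xs <- sort(unique(x$x))
  ys <- sort(unique(x$y))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(x$x, xs), match(x$y, ys))] <-
    ifelse(x$valid, x$value, NA_real_)
  graphics::image(xs, ys, z, xlab = "x (mm)", ylab = "y (mm)",
                  main = attr(x, "what"), asp = 1, ...)
  out <- attr(x, "outline")
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(out$cx + out$radius_mm * cos(th),
                  out$cy + out$radius_mm * sin(th))
  invisible(x)
}

#' Write / read an image series as a 16-bit grayscale TIFF stack
#'
#' Intensities are scaled by `1 / full_scale` into `[0, 1]` for storage and
#' rescaled on reading. Requires the `tiff` package. Timestamps and
#' acquisition metadata travel in a YAML sidecar.
#'
#' @param series an [image_series()]
#' @param path TIFF file path
#' @param full_scale intensity mapped to the 16-bit maximum
#' @return `write_image_series` returns `path` invisibly; `read_image_series`
#'   the [image_series()].
#' @export
write_image_series <- function(series, path, full_scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  stopifnot(inherits(series, "image_series"))
  imgs <- lapply(series$frames, function(f) pmin(pmax(f / full_scale, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  meta <- list(timestamps_s = series$timestamps_s,
               exposure_ms = series$exposure_ms,
               pause_ms = series$pause_ms, full_scale = full_scale)
  writeLines(yaml::as.yaml(meta), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF import")
  imgs <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  fs <- meta$full_scale %||% 65535
  frames <- lapply(imgs, function(m) m * fs)
  image_series(frames, as.numeric(meta$timestamps_s),
               meta$exposure_ms %||% 200, meta$pause_ms %||% 600)
}
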