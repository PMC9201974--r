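#' Spectrum container
#'
#' @param wavelength_nm strictly increasing wavelengths, nm
#' @param value extinction / absorbance / fluorescence intensity (a.u.)
#' @param kind one of `"extinction"`, `"absorbance"`, `"fluorescence"`
#' @param excitation_nm excitation wavelength for fluorescence spectra
#'   (e.g. 740)
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("fluorescence", "extinction", "absorbance"),
                     excitation_nm = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(wavelength_nm) == length(value),
            all(diff(wavelength_nm) > 0), all(is.finite(value)))
  if (kind == "fluorescence" && is.null(excitation_nm))
    stop("fluorescence spectra must carry their excitation wavelength")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 value = as.numeric(value), kind = kind,
                 excitation_nm = excitation_nm), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d points, %g..%g nm%s\n", x$kind,
              length(x$value), min(x$wavelength_nm), max(x$wavelength_nm),
              if (!is.null(x$excitation_nm))
                sprintf(", ex %g nm", x$excitation_nm) else ""))
  invisible(x)
}

#' Dye concentration series
#'
#' @param concentration strictly increasing concentrations
#' @param intensity band intensity per concentration, or `NULL` when the
#'   series carries full spectra
#' @param unit concentration unit, recorded verbatim (e.g. `"ug/g"`,
#'   `"ug/mL"`, `"nmol/L"`)
#' @param spectra optional list of [spectrum()] objects, one per
#'   concentration
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(concentration, intensity = NULL,
                                 unit = "ug/g", spectra = NULL) {
  stopifnot(all(diff(concentration) > 0))
  if (is.null(intensity) && is.null(spectra))
    stop("either intensities or spectra must be supplied")
  if (!is.null(intensity))
    stopifnot(length(intensity) == length(concentration))
  if (!is.null(spectra))
    stopifnot(length(spectra) == length(concentration))
  structure(list(concentration = as.numeric(concentration),
                 intensity = intensity, unit = unit, spectra = spectra),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> %d concentrations, %g..%g %s%s\n",
              length(x$concentration), min(x$concentration),
              max(x$concentration), x$unit,
              if (is.null(x$spectra)) "" else ", with spectra"))
  invisible(x)
}

#' Straight-line background subtraction for extinction spectra
#'
#' Fits a least-squares line through the samples inside the anchor windows
#' (wavelength intervals assumed free of the dye band) and subtracts it.
#' When the mean residual inside any anchor window exceeds 3 residual
#' standard deviations the linear-background assumption is flagged with a
#' warning (anchors probably overlap the band).
#'
#' @param spec a [spectrum()]
#' @param anchor_windows list of `c(lo_nm, hi_nm)` intervals, at least 2,
#'   non-overlapping, each containing at least 2 samples; defaults to
#'   550-620 nm and 870-900 nm, outside the dye band
#' @param clip if `TRUE`, negative corrected values are clipped at 0
#'   (default `FALSE`)
#' @return List `slope`, `intercept`, `corrected` (a [spectrum()]),
#'   `anchor_ok` (per-window flag).
#' @export
fit_linear_background <- function(spec,
                                  anchor_windows = list(c(550, 620),
                                                        c(870, 900)),
                                  clip = FALSE) {
  stopifnot(inherits(spec, "spectrum"), length(anchor_windows) >= 2)
  wl <- spec$wavelength_nm
  iv <- t(vapply(anchor_windows, function(w) sort(w), numeric(2)))
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
    stop("anchor windows must not overlap")
  win_of <- rep(NA_integer_, length(wl))
  for (i in seq_len(nrow(iv)))
    win_of[wl >= iv[i, 1] & wl <= iv[i, 2]] <- i
  counts <- tabulate(win_of, nbins = nrow(iv))
  if (any(counts < 2))
    stop("every anchor window needs at least 2 samples")
  sel <- !is.na(win_of)
  fit <- lm(spec$value[sel] ~ wl[sel])
  line <- coef(fit)[[1]] + coef(fit)[[2]] * wl
  res <- spec$value[sel] - line[sel]
  # anchor validity: with >= 3 windows, refit the line leaving each window
  # out; a window whose mean residual against that line exceeds 3 residual
  # standard deviations of the fitting points likely overlaps the dye band
  anchor_ok <- vapply(seq_len(nrow(iv)), function(i) {
    if (nrow(iv) >= 3) {
      keep <- sel & win_of != i
      f2 <- lm(spec$value[keep] ~ wl[keep])
      l2 <- coef(f2)[[1]] + coef(f2)[[2]] * wl
      s2 <- max(sd(spec$value[keep] - l2[keep]), 1e-12 * max(abs(spec$value)))
      here <- sel & win_of == i
      abs(mean(spec$value[here] - l2[here])) <= 3 * s2
    } else {
      s <- max(sd(res), 1e-12 * max(abs(spec$value)))
      abs(mean(res[win_of[sel] == i])) <= 3 * s
    }
  }, logical(1))
  if (!all(anchor_ok))
    warning("anchor-window mean deviates > 3 sigma from the fitted line; ",
            "anchors may overlap the dye band")
  corr <- spec$value - line
  if (clip) corr[corr < 0] <- 0
  corrected <- spec
  corrected$value <- corr
  list(slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
       corrected = corrected, anchor_ok = anchor_ok)
}

#' Sub-sample peak wavelength by parabolic interpolation
#'
#' Locates the global maximum (ties broken to the shortest wavelength) and
#' refines it with the parabola through the maximum and its two neighbours.
#' A maximum on the boundary is returned as-is with attribute
#' `boundary = TRUE`.
#'
#' @param spec a [spectrum()]
#' @return Peak wavelength, nm (with attribute `boundary`).
#' @export
peak_wavelength <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  wl <- spec$wavelength_nm
  v <- spec$value
  i <- which.max(v)
  if (i == 1L || i == length(v)) {
    out <- wl[i]
    attr(out, "boundary") <- TRUE
    return(out)
  }
  # parabola through three points, general (possibly non-uniform) spacing
  x <- wl[(i - 1):(i + 1)] - wl[i]
  y <- v[(i - 1):(i + 1)]
  d21 <- (y[2] - y[1]) / (x[2] - x[1])
  d32 <- (y[3] - y[2]) / (x[3] - x[2])
  a <- (d32 - d21) / (x[3] - x[1])
  out <- if (a < 0) {
    b <- d21 + a * (0 - x[1] - x[2])
    wl[i] - b / (2 * a)
  } else wl[i]
  attr(out, "boundary") <- FALSE
  out
}

#' Long-pass band intensity of a spectrum
#'
#' Trapezoidal integral of the spectrum over wavelengths above the cut-on,
#' with the curve linearly interpolated at the cut-on itself (emulating an
#' ideal long-pass filter).
#'
#' @param spec a [spectrum()]
#' @param cut_on_nm cut-on wavelength, nm, inside the sampled range
#' @return Scalar band intensity (nm times value units).
#' @export
band_intensity <- function(spec, cut_on_nm = 800) {
  stopifnot(inherits(spec, "spectrum"))
  wl <- spec$wavelength_nm
  if (cut_on_nm < min(wl) || cut_on_nm > max(wl))
    stop("cut_on_nm outside the sampled wavelength range")
  if (cut_on_nm == max(wl)) return(0)
  v0 <- approx(wl, spec$value, xout = cut_on_nm)$y
  keep <- wl > cut_on_nm
  x <- c(cut_on_nm, wl[keep])
  y <- c(v0, spec$value[keep])
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Detect the concentration-linearity onset of a dye series
#'
#' Fits the reference slope through the origin on the lowest
#' `n_ref_points` concentrations (zero dye gives zero fluorescence) and
#' reports the smallest concentration whose intensity deviates from
#' `slope * c` by more than `rel_threshold` relative — the onset of the
#' inner-filter (reabsorption) saturation.
#'
#' @param series a [concentration_series()] with intensities
#' @param n_ref_points number of low concentrations defining the reference
#'   slope (>= 2, default 2)
#' @param rel_threshold relative deviation threshold (default 0.05)
#' @return List of class `linearity_result`: `slope`, `onset` (`NA` when no
#'   point deviates beyond the threshold), `deviation` (per-point relative
#'   deviation), `rel_threshold`, `unit`, `monotone` (FALSE flags
#'   non-monotone intensities).
#' @export
linearity_onset <- function(series, n_ref_points = 2, rel_threshold = 0.05) {
  stopifnot(inherits(series, "concentration_series"),
            !is.null(series$intensity),
            n_ref_points >= 2,
            length(series$concentration) >= n_ref_points + 1)
  cc <- series$concentration
  ii <- series$intensity
  monotone <- all(diff(ii) >= 0)
  ref <- seq_len(n_ref_points)
  slope <- sum(cc[ref] * ii[ref]) / sum(cc[ref]^2) # LS through the origin
  expect <- slope * cc
  dev <- abs(ii - expect) / expect
  over <- which(dev > rel_threshold)
  onset <- if (length(over)) cc[min(over)] else NA_real_
  structure(list(slope = slope, onset = onset, deviation = dev,
                 rel_threshold = rel_threshold, unit = series$unit,
                 monotone = monotone),
            class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf("<linearity_result> slope %.4g per %s, onset %s (threshold %g%%)%s\n",
              x$slope, x$unit,
              if (is.na(x$onset)) "none" else paste(x$onset, x$unit),
              100 * x$rel_threshold,
              if (x$monotone) "" else " [non-monotone intensities]"))
  invisible(x)
}

#' Equivalent concentration by calibration-curve inversion
#'
#' Monotone piecewise-linear inversion of a calibration series (e.g. to
#' express a phantom's fluorescence as the equivalent concentration of a
#' reference dye). Extrapolation outside the calibrated intensity range is
#' refused.
#'
#' @param query_intensity intensity to invert
#' @param calibration a [concentration_series()] with strictly increasing
#'   intensities
#' @return Concentration in the calibration's unit.
#' @export
equivalent_concentration <- function(query_intensity, calibration) {
  stopifnot(inherits(calibration, "concentration_series"),
            !is.null(calibration$intensity))
  ii <- calibration$intensity
  if (any(diff(ii) <= 0))
    stop("calibration intensities must be strictly increasing")
  if (query_intensity < min(ii) || query_intensity > max(ii))
    stop("query intensity outside the calibration range; extrapolation refused")
  approx(ii, calibration$concentration, xout = query_intensity)$y
}
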