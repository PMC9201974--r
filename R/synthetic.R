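#' Parametric dye model for the synthetic generator
#'
#' Gaussian absorption and emission lineshapes anchored at the measured
#' peak positions, with an effective reabsorption (inner-filter) strength,
#' a per-frame photobleaching rate and storage-decay rates.
#'
#' @param name label
#' @param absorption_peak_nm,absorption_fwhm_nm Gaussian absorption band
#' @param emission_peak_nm,emission_fwhm_nm Gaussian emission band
#' @param brightness relative brightness (arbitrary units per concentration
#'   unit)
#' @param reabsorption_strength effective optical depth of self-absorption
#'   per concentration unit (decadic exponent per ug/g); controls the
#'   saturation onset and red shift of the observed emission
#' @param bleach_rate_per_frame fractional fluorescence loss rate per
#'   exposure frame (exponential)
#' @param decay_dark_per_month,decay_daylight_per_month storage decay rates,
#'   exponential per month, for dark and daylight storage
#' @return An object of class `dye_model`.
#' @export
dye_model <- function(name, absorption_peak_nm, absorption_fwhm_nm,
                      emission_peak_nm, emission_fwhm_nm,
                      brightness = 1, reabsorption_strength = 0,
                      bleach_rate_per_frame = 0,
                      decay_dark_per_month = 0,
                      decay_daylight_per_month = 0) {
  stopifnot(absorption_fwhm_nm > 0, emission_fwhm_nm > 0, brightness > 0,
            reabsorption_strength >= 0, bleach_rate_per_frame >= 0,
            decay_dark_per_month >= 0, decay_daylight_per_month >= 0)
  structure(list(name = name,
                 absorption_peak_nm = absorption_peak_nm,
                 absorption_fwhm_nm = absorption_fwhm_nm,
                 emission_peak_nm = emission_peak_nm,
                 emission_fwhm_nm = emission_fwhm_nm,
                 brightness = brightness,
                 reabsorption_strength = reabsorption_strength,
                 bleach_rate_per_frame = bleach_rate_per_frame,
                 decay_dark_per_month = decay_dark_per_month,
                 decay_daylight_per_month = decay_daylight_per_month),
            class = "dye_model")
}

#' Lumogen-like stable NIR dye preset
#'
#' Cured-material absorption peak at 762 nm, emission at 790 nm with 60-nm
#' half-width, no photobleaching and no storage decay; the reabsorption
#' strength is calibrated so that the concentration-linearity onset of the
#' default series sits at 1.5 ug/g.
#' @return A [dye_model()].
#' @export
lumogen_dye <- function() {
  dye_model("lumogen-like",
            absorption_peak_nm = 762, absorption_fwhm_nm = 60,
            emission_peak_nm = 790, emission_fwhm_nm = 60,
            brightness = 1,
            reabsorption_strength = 0.18,
            bleach_rate_per_frame = 0,
            decay_dark_per_month = 0,
            decay_daylight_per_month = 0)
}

#' ICG-like unstable NIR dye preset
#'
#' Absorption at 784 nm, emission near 810 nm; the photobleaching rate is
#' set so the fluorescence drops by 4.5 percent over a 100-frame sequence,
#' and the storage decay reproduces a 10 percent loss per month in the dark
#' and 30 percent under daylight.
#' @return A [dye_model()].
#' @export
icg_dye <- function() {
  dye_model("icg-like",
            absorption_peak_nm = 784, absorption_fwhm_nm = 55,
            emission_peak_nm = 810, emission_fwhm_nm = 60,
            brightness = 1,
            reabsorption_strength = 0.18,
            bleach_rate_per_frame = -log(1 - 0.045) / 99,
            decay_dark_per_month = -log(1 - 0.10),
            decay_daylight_per_month = -log(1 - 0.30))
}

#' Fluorescence hand-imager model for the synthetic generator
#'
#' Emulates a camera-based imager: two Gaussian LED illumination fields
#' (740-nm excitation), long-pass detection, a per-frame multiplicative
#' intensity noise, an exponential warm-up drift of the LED output, and a
#' small per-pixel camera noise.
#'
#' @param n_rows,n_cols frame size, pixels
#' @param led_centers list of two `c(row, col)` LED field centres (defaults
#'   to the two lateral thirds of the frame)
#' @param led_sigma_px Gaussian width of each LED field, pixels
#' @param cut_on_nm detection long-pass cut-on (must exceed the 740-nm
#'   excitation)
#' @param frame_noise_rel per-frame multiplicative noise, relative standard
#'   deviation (default 0.0035)
#' @param warmup_amplitude_rel total relative LED output loss due to
#'   warm-up (default 0.005)
#' @param warmup_tau_frames warm-up time constant, frames
#' @param pixel_noise_rel per-pixel relative camera noise
#' @param exposure_ms,pause_ms acquisition cadence
#' @return An object of class `imager_model`.
#' @export
imager_model <- function(n_rows = 64, n_cols = 96,
                         led_centers = NULL, led_sigma_px = 24,
                         cut_on_nm = 800,
                         frame_noise_rel = 0.0035,
                         warmup_amplitude_rel = 0.005,
                         warmup_tau_frames = 40,
                         pixel_noise_rel = 0.002,
                         exposure_ms = 200, pause_ms = 600) {
  stopifnot(frame_noise_rel >= 0, warmup_amplitude_rel >= 0,
            pixel_noise_rel >= 0, cut_on_nm > 740)
  if (is.null(led_centers))
    led_centers <- list(c(n_rows / 2, n_cols / 3),
                        c(n_rows / 2, 2 * n_cols / 3))
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 led_centers = led_centers, led_sigma_px = led_sigma_px,
                 cut_on_nm = cut_on_nm,
                 frame_noise_rel = frame_noise_rel,
                 warmup_amplitude_rel = warmup_amplitude_rel,
                 warmup_tau_frames = warmup_tau_frames,
                 pixel_noise_rel = pixel_noise_rel,
                 exposure_ms = exposure_ms, pause_ms = pause_ms),
            class = "imager_model")
}

illumination_field <- function(imager) {
  r <- matrix(seq_len(imager$n_rows), imager$n_rows, imager$n_cols)
  cl <- matrix(seq_len(imager$n_cols), imager$n_rows, imager$n_cols,
               byrow = TRUE)
  f <- 0
  for (cen in imager$led_centers)
    f <- f + exp(-((r - cen[1])^2 + (cl - cen[2])^2) /
                   (2 * imager$led_sigma_px^2))
  f / max(f)
}

#' Ground-truth description of a synthetic phantom
#'
#' @param props [optical_properties()] at the working wavelength (per
#'   wavelength when a named list keyed by wavelength is given)
#' @param dye a [dye_model()]
#' @param concentration dye concentration (generator units, ug/g)
#' @param geom a [slab_geometry()]
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(props = optical_properties(0.08, 9.5),
                          dye = lumogen_dye(), concentration = 1.5,
                          geom = slab_geometry()) {
  stopifnot(inherits(dye, "dye_model"), concentration > 0)
  structure(list(props = props, dye = dye, concentration = concentration,
                 geom = geom), class = "phantom_truth")
}

props_at <- function(truth, wavelength_nm) {
  p <- truth$props
  if (inherits(p, "optical_properties")) return(p)
  key <- as.character(wavelength_nm)
  if (!key %in% names(p)) stop("no optical properties stored for ",
                               wavelength_nm, " nm")
  p[[key]]
}

#' Generate a noisy synthetic DTOF from a phantom truth
#'
#' Diffusion forward model, IRF convolution, scaling to the expected total
#' counts, and a per-bin Poisson draw — the statistical structure of a
#' photon-counting transmittance measurement. Setting
#' `poisson = FALSE` returns the deterministic expectation curve.
#'
#' @param truth a [phantom_truth()]
#' @param wavelength_nm working wavelength (710, 750, 800, 850 or 900 in
#'   the measurement protocol; any value accepted)
#' @param response an [irf()]
#' @param total_counts expected total detected counts (>= 1)
#' @param stream an [rng_stream()]
#' @param poisson draw Poisson counts (default) or return the noise-free
#'   curve
#' @param bin_width_ps,t_max_ps time axis
#' @param model forward model, `"diffusion"` (default, fast and noise-free)
#'   or `"mc"` (photon-packet Monte Carlo with `mc_photons` packets, for
#'   cross-validation)
#' @param mc_photons packets for the MC-backed mode
#' @return List `dtof` (synthetic-kind [dtof()]) and `truth` (the inputs,
#'   recorded verbatim for truth-recovery tests).
#' @export
gen_dtof <- function(truth, wavelength_nm = 800, response = irf(35),
                     total_counts = 1e6, stream = rng_stream(1),
                     poisson = TRUE, bin_width_ps = 10, t_max_ps = 6000,
                     model = c("diffusion", "mc"), mc_photons = 1e6) {
  model <- match.arg(model)
  stopifnot(inherits(truth, "phantom_truth"), total_counts >= 1)
  pr <- props_at(truth, wavelength_nm)
  centres <- seq(bin_width_ps / 2, t_max_ps - bin_width_ps / 2,
                 by = bin_width_ps)
  base <- if (model == "diffusion") {
    diffusion_slab_dtof(pr, truth$geom, centres)
  } else {
    white <- suppressWarnings(simulate_white_dtof(
      optical_properties(0, pr$mu_sp, pr$g, pr$n_in, pr$n_out),
      truth$geom, mc_photons, bin_width_ps, t_max_ps, stream))
    apply_absorption(white, pr$mu_a)
  }
  curve <- convolve_irf(base, response)
  expected <- curve$values / sum(curve$values) * total_counts
  vals <- if (poisson) {
    with_stream(stream, rpois(length(expected), expected))
  } else expected
  meta <- list(wavelength_nm = wavelength_nm, mu_sp = pr$mu_sp,
               mu_a = pr$mu_a, n_in = pr$n_in, n_out = pr$n_out,
               thickness_cm = truth$geom$thickness_cm,
               total_counts = total_counts, model = model,
               seed = stream$seed, substream = stream$substream,
               poisson = poisson)
  list(dtof = dtof(c(centres - bin_width_ps / 2,
                     t_max_ps), vals, kind = "synthetic", meta = meta),
       truth = list(mu_sp = pr$mu_sp, mu_a = pr$mu_a,
                    wavelength_nm = wavelength_nm))
}

#' Generate a synthetic scan-grid dataset with controlled inhomogeneity
#'
#' Builds a regular lattice covering the disc outline, computes one
#' diffusion-forward DTOF per band and modulates its intensity per position
#' by (i) localized anomalies, (ii) a smooth edge roll-off inside the margin
#' (emulating side losses of the finite disc), and (iii) multiplicative
#' position noise, then draws Poisson counts.
#'
#' @param truth a [phantom_truth()]
#' @param step_mm lattice step (default 5)
#' @param outline_radius_mm disc radius (default 40, the 8-cm disc)
#' @param anomalies list of `list(x =, y =, amplitude =)` entries; the cell
#'   containing `(x, y)` (and any cell within `anomaly_radius_mm`) is scaled
#'   by `1 + amplitude` (e.g. `amplitude = 0.07` for a 7 percent hot spot)
#' @param anomaly_radius_mm anomaly footprint radius (default half a step:
#'   a single cell)
#' @param edge_rolloff_mm width of the edge intensity roll-off band
#' @param edge_min relative intensity at the outline itself
#' @param noise_rel per-position multiplicative noise (default 0.01, the
#'   single-measurement reproducibility)
#' @param total_counts expected DTOF counts per position
#' @param bands band labels (both bands share the truth properties; the
#'   fluorescence band is scaled by the dye brightness)
#' @param stream an [rng_stream()]
#' @param poisson draw Poisson counts per bin (default TRUE)
#' @param bin_width_ps,t_max_ps time axis
#' @return List `scan` (a [scan_grid()]) and `truth_map` (data frame `x`,
#'   `y`, `multiplier` of the programmed intensity field, noise excluded).
#' @export
gen_scan <- function(truth, step_mm = 5, outline_radius_mm = 40,
                     anomalies = list(), anomaly_radius_mm = NULL,
                     edge_rolloff_mm = 10, edge_min = 0.7,
                     noise_rel = 0.01, total_counts = 1e6,
                     bands = c("excitation", "fluorescence"),
                     stream = rng_stream(1), poisson = TRUE,
                     bin_width_ps = 10, t_max_ps = 6000) {
  stopifnot(inherits(truth, "phantom_truth"), step_mm > 0,
            outline_radius_mm > step_mm)
  if (is.null(anomaly_radius_mm)) anomaly_radius_mm <- step_mm / 2
  g <- seq(-floor(outline_radius_mm / step_mm) * step_mm,
           floor(outline_radius_mm / step_mm) * step_mm, by = step_mm)
  pos <- expand.grid(x = g, y = g)
  pos <- pos[sqrt(pos$x^2 + pos$y^2) <= outline_radius_mm, , drop = FALSE]
  rownames(pos) <- NULL
  for (a in anomalies) {
    if (sqrt(a$x^2 + a$y^2) > outline_radius_mm)
      stop("anomaly outside the phantom outline")
  }
  mult <- rep(1, nrow(pos))
  for (a in anomalies) {
    hit <- sqrt((pos$x - a$x)^2 + (pos$y - a$y)^2) <= anomaly_radius_mm
    mult[hit] <- mult[hit] * (1 + a$amplitude)
  }
  edge_d <- outline_radius_mm - sqrt(pos$x^2 + pos$y^2)
  roll <- ifelse(edge_d < edge_rolloff_mm,
                 edge_min + (1 - edge_min) * edge_d / edge_rolloff_mm, 1)
  field <- mult * roll

  pr <- props_at(truth, 800)
  centres <- seq(bin_width_ps / 2, t_max_ps - bin_width_ps / 2,
                 by = bin_width_ps)
  base <- diffusion_slab_dtof(pr, truth$geom, centres)
  shape <- base$values / sum(base$values)
  band_scale <- setNames(rep(1, length(bands)), bands)
  if ("fluorescence" %in% bands)
    band_scale["fluorescence"] <- truth$dye$brightness

  dtofs <- with_stream(stream, {
    lapply(seq_len(nrow(pos)), function(i) {
      noise <- if (noise_rel > 0) 1 + rnorm(length(bands)) * noise_rel else
        rep(1, length(bands))
      noise <- pmax(noise, 0.01)
      out <- lapply(seq_along(bands), function(b) {
        expected <- shape * total_counts * field[i] * band_scale[b] * noise[b]
        vals <- if (poisson) rpois(length(expected), expected) else expected
        dtof(c(centres - bin_width_ps / 2, t_max_ps), vals,
             kind = "synthetic",
             meta = list(x_mm = pos$x[i], y_mm = pos$y[i],
                         band = bands[b], mu_sp = pr$mu_sp, mu_a = pr$mu_a,
                         n_in = pr$n_in, total_counts = total_counts))
      })
      names(out) <- bands
      out
    })
  })
  list(scan = scan_grid(pos, step_mm, dtofs,
                        outline = list(cx = 0, cy = 0,
                                       radius_mm = outline_radius_mm)),
       truth_map = data.frame(x = pos$x, y = pos$y, multiplier = field))
}

#' Generate a synthetic fluorescence-imager time series
#'
#' Per frame and phantom, the rendered intensity is base brightness times
#' the LED illumination field, an exponential photobleaching factor, a
#' storage-decay factor, the LED warm-up drift and a per-frame
#' multiplicative noise; frames add a per-pixel camera noise on a dark
#' background.
#'
#' @param phantoms list of `list(truth =, region =)` entries, `region` a
#'   [roi_spec()] rectangle; regions must be disjoint and inside the frame
#' @param imager an [imager_model()]
#' @param n_frames number of frames (default 100)
#' @param timestamps_s acquisition times; defaults to the imager cadence
#' @param storage `"dark"` or `"daylight"` — selects the storage-decay rate
#'   applied over the timestamps
#' @param base_counts full-scale intensity of a unit-brightness phantom
#'   (counts)
#' @param stream an [rng_stream()]
#' @return List `series` (an [image_series()]) and `truth` (per-phantom
#'   programmed bleach rate, decay rate and base intensity).
#' @export
gen_image_series <- function(phantoms, imager = imager_model(),
                             n_frames = 100, timestamps_s = NULL,
                             storage = c("dark", "daylight"),
                             base_counts = 30000, stream = rng_stream(1)) {
  storage <- match.arg(storage)
  stopifnot(length(phantoms) >= 1)
  if (is.null(timestamps_s))
    timestamps_s <- (seq_len(n_frames) - 1) *
      (imager$exposure_ms + imager$pause_ms) / 1000
  n_frames <- length(timestamps_s)
  occ <- matrix(FALSE, imager$n_rows, imager$n_cols)
  for (ph in phantoms) {
    r <- ph$region
    rows <- seq.int(r$row0, length.out = r$height)
    cols <- seq.int(r$col0, length.out = r$width)
    if (max(rows) > imager$n_rows || max(cols) > imager$n_cols)
      stop("phantom region outside the frame")
    if (any(occ[rows, cols])) stop("phantom regions overlap")
    occ[rows, cols] <- TRUE
  }
  illum <- illumination_field(imager)
  months <- timestamps_s / (86400 * 30.44)
  warm <- 1 - imager$warmup_amplitude_rel *
    (1 - exp(-(seq_len(n_frames) - 1) / imager$warmup_tau_frames))
  truth <- lapply(phantoms, function(ph) {
    dye <- ph$truth$dye
    rate <- if (storage == "dark") dye$decay_dark_per_month else
      dye$decay_daylight_per_month
    list(name = dye$name,
         bleach_rate_per_frame = dye$bleach_rate_per_frame,
         storage_decay_per_month = rate,
         base_intensity = base_counts * dye$brightness *
           ph$truth$concentration)
  })
  frames <- with_stream(stream, {
    lapply(seq_len(n_frames), function(fi) {
      fr <- matrix(0, imager$n_rows, imager$n_cols)
      eps_frame <- if (imager$frame_noise_rel > 0)
        1 + rnorm(1) * imager$frame_noise_rel else 1
      for (pi in seq_along(phantoms)) {
        ph <- phantoms[[pi]]
        tr <- truth[[pi]]
        r <- ph$region
        rows <- seq.int(r$row0, length.out = r$height)
        cols <- seq.int(r$col0, length.out = r$width)
        inten <- tr$base_intensity * illum[rows, cols] *
          exp(-tr$bleach_rate_per_frame * (fi - 1)) *
          exp(-tr$storage_decay_per_month * months[fi]) *
          warm[fi] * eps_frame
        fr[rows, cols] <- inten
      }
      if (imager$pixel_noise_rel > 0) {
        fr <- fr * (1 + matrix(rnorm(length(fr)), nrow(fr)) *
                      imager$pixel_noise_rel)
      }
      pmax(fr, 0)
    })
  })
  list(series = image_series(frames, timestamps_s,
                             imager$exposure_ms, imager$pause_ms),
       truth = truth)
}

gaussian_profile <- function(wl, peak, fwhm) {
  exp(-4 * log(2) * (wl - peak)^2 / fwhm^2)
}

#' Generate concentration-dependent dye emission spectra with reabsorption
#'
#' The observed emission is
#' `c * emission0(lambda) * 10^(-eps(lambda) * c * reabsorption_strength)`
#' with `eps` the (unit-peak) Gaussian absorption profile — the inner-filter
#' model. It produces a sublinear long-pass band intensity and a red shift
#' of the observed emission peak as the concentration grows.
#'
#' @param dye a [dye_model()]
#' @param concentrations strictly increasing, > 0 (default 0.25..5 ug/g)
#' @param wavelength_nm emission sampling grid (default 750..900 nm in
#'   1-nm steps, the fluorometer range)
#' @param noise_rel relative multiplicative noise per sample (default 0,
#'   deterministic)
#' @param stream an [rng_stream()] (used only when `noise_rel > 0`)
#' @param unit concentration unit label
#' @return A [concentration_series()] carrying full spectra and the
#'   long-pass (> 800 nm) band intensities.
#' @export
gen_dye_spectra <- function(dye = lumogen_dye(),
                            concentrations = c(0.25, 0.5, 0.75, 1, 1.25,
                                               1.5, 2, 2.5, 3, 4, 5),
                            wavelength_nm = seq(750, 900, by = 1),
                            noise_rel = 0, stream = rng_stream(1),
                            unit = "ug/g") {
  stopifnot(inherits(dye, "dye_model"), all(concentrations > 0),
            all(diff(concentrations) > 0))
  em0 <- gaussian_profile(wavelength_nm, dye$emission_peak_nm,
                          dye$emission_fwhm_nm)
  eps <- gaussian_profile(wavelength_nm, dye$absorption_peak_nm,
                          dye$absorption_fwhm_nm)
  make <- function(cc, noise) {
    v <- dye$brightness * cc * em0 *
      10^(-eps * cc * dye$reabsorption_strength)
    spectrum(wavelength_nm, v * noise, kind = "fluorescence",
             excitation_nm = 740)
  }
  noises <- if (noise_rel > 0) {
    with_stream(stream, lapply(concentrations, function(cc)
      pmax(1 + rnorm(length(wavelength_nm)) * noise_rel, 0)))
  } else {
    rep(list(rep(1, length(wavelength_nm))), length(concentrations))
  }
  spectra <- Map(make, concentrations, noises)
  band <- vapply(spectra, band_intensity, numeric(1), cut_on_nm = 800)
  concentration_series(concentrations, intensity = band, unit = unit,
                       spectra = spectra)
}
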