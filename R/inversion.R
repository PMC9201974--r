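#' Instrument response function
#'
#' Either a parametric Gaussian of given FWHM (sampled on the DTOF time axis
#' at convolution time) or an explicit sampled curve; in both cases the
#' kernel is normalized to unit area before use.
#'
#' @param fwhm_ps full width at half maximum of a Gaussian IRF, ps
#' @param times_ps,values optional sampled IRF (times relative to the nominal
#'   laser pulse, ps); overrides `fwhm_ps` when given
#' @return An object of class `irf`.
#' @export
irf <- function(fwhm_ps = 35, times_ps = NULL, values = NULL) {
  if (!is.null(values)) {
    stopifnot(!is.null(times_ps), length(times_ps) == length(values),
              all(values >= 0), any(values > 0))
    structure(list(type = "sampled", times_ps = times_ps,
                   values = values / sum(values)), class = "irf")
  } else {
    stopifnot(fwhm_ps >= 0)
    structure(list(type = "gaussian", fwhm_ps = fwhm_ps), class = "irf")
  }
}

#' @export
print.irf <- function(x, ...) {
  if (x$type == "gaussian")
    cat(sprintf("<irf> Gaussian, FWHM %.3g ps\n", x$fwhm_ps))
  else
    cat(sprintf("<irf> sampled, %d points\n", length(x$values)))
  invisible(x)
}

# discrete unit-area kernel of the IRF on a uniform grid of width bw
irf_kernel <- function(x, bw) {
  if (x$type == "gaussian") {
    if (x$fwhm_ps <= bw / 20) return(list(values = 1, center = 1L))
    sigma <- x$fwhm_ps / (2 * sqrt(2 * log(2)))
    half <- ceiling(5 * sigma / bw)
    tt <- seq(-half, half) * bw
    k <- exp(-tt^2 / (2 * sigma^2))
    list(values = k / sum(k), center = half + 1L)
  } else {
    tt <- seq(floor(min(x$times_ps) / bw), ceiling(max(x$times_ps) / bw)) * bw
    k <- approx(x$times_ps, x$values, xout = tt, yleft = 0, yright = 0)$y
    if (sum(k) <= 0) stop("sampled IRF has no support on this time grid")
    list(values = k / sum(k), center = which.min(abs(tt)))
  }
}

#' Apply absorption to a white DTOF (microscopic Beer-Lambert scaling)
#'
#' Multiplies each bin of a zero-absorption DTOF by
#' `exp(-mu_a * c_M * t_centre)` with `c_M = c0 / n_in`. Exact because every
#' photon arriving at time t has travelled the path length `c_M * t`. The
#' result is flagged absorbing so the scaling cannot be applied twice.
#'
#' @param x a white-kind [dtof()]
#' @param mu_a absorption coefficient, 1/cm (>= 0)
#' @param n_in refractive index of the medium; defaults to the value stored
#'   in the DTOF metadata
#' @return An absorbing-kind [dtof()] (white when `mu_a = 0` would still be
#'   marked absorbing to keep the contract simple; values are unchanged).
#' @export
apply_absorption <- function(x, mu_a, n_in = x$meta$n_in) {
  stopifnot(inherits(x, "dtof"), mu_a >= 0)
  if (x$kind != "white")
    stop("apply_absorption() requires a white-kind DTOF ",
         "(double-attenuation hazard)")
  if (is.null(n_in)) stop("n_in not given and absent from DTOF metadata")
  v <- c0_cm_per_ps() / n_in
  vals <- x$values * exp(-mu_a * v * dtof_times(x))
  meta <- x$meta
  meta$mu_a <- mu_a
  dtof(x$bin_edges_ps, vals, kind = "absorbing", meta = meta)
}

#' Convolve a DTOF with an instrument response function
#'
#' Discrete convolution on the DTOF's own time axis; total weight is
#' preserved (the kernel has unit area and out-of-range spill is negligible
#' when the DTOF support is interior to the axis).
#'
#' @param x a [dtof()]
#' @param response an [irf()]
#' @return A [dtof()] of the same kind and axis. `meta$irf_wide = TRUE` flags
#'   a kernel wider than the DTOF support.
#' @export
convolve_irf <- function(x, response) {
  stopifnot(inherits(x, "dtof"), inherits(response, "irf"))
  bw <- dtof_bin_width(x)
  k <- irf_kernel(response, bw)
  kv <- k$values
  if (length(kv) == 1L && kv == 1) return(x)
  n <- length(x$values)
  full <- convolve_full(x$values, kv)
  out <- full[seq.int(k$center, k$center + n - 1L)]
  out[out < 0] <- 0
  meta <- x$meta
  supp <- range(which(x$values > 0))
  if (length(kv) > diff(supp) + 1) meta$irf_wide <- TRUE
  dtof(x$bin_edges_ps, out, kind = x$kind, meta = meta)
}

# linear full convolution, length n + m - 1
convolve_full <- function(a, b) {
  stats::convolve(a, rev(b), type = "open")
}

#' White Monte Carlo lookup table
#'
#' One white DTOF per reduced-scattering grid value on a common time axis.
#' The default grid spans 0.1 to 20 1/cm in steps of 0.1 (200 entries).
#'
#' @param grid_min,grid_max,grid_step reduced scattering grid, 1/cm
#' @param geom [slab_geometry()]
#' @param n_photons launched packets per entry
#' @param bin_width_ps,t_max_ps common time axis
#' @param stream [rng_stream()]; entry i uses substream `stream$substream + i`
#'   so the table is reproducible and entries are independent
#' @param n_in,n_out refractive indices for all entries
#' @param model `"mc"` (photon-packet Monte Carlo, default) or `"diffusion"`
#'   (noise-free closed form, useful for fast self-consistency studies)
#' @return An object of class `white_lut` with fields `mu_sp_grid`,
#'   `dtofs` (list of white DTOFs), `bin_edges_ps` and `provenance`.
#' @export
build_lut <- function(grid_min = 0.1, grid_max = 20, grid_step = 0.1,
                      geom = slab_geometry(), n_photons = 1e5,
                      bin_width_ps = 10, t_max_ps = 6000,
                      stream = rng_stream(1), n_in = 1.54, n_out = 1.0,
                      model = c("mc", "diffusion")) {
  model <- match.arg(model)
  stopifnot(grid_min > 0, grid_step > 0, grid_max >= grid_min)
  grid <- seq(grid_min, grid_max, by = grid_step)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  dtofs <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    props <- optical_properties(0, grid[i], 0, n_in = n_in, n_out = n_out)
    if (model == "mc") {
      dtofs[[i]] <- suppressWarnings(simulate_white_dtof(
        props, geom, n_photons, bin_width_ps, t_max_ps,
        rng_stream(stream$seed, stream$substream + i)))
    } else {
      centres <- seq(bin_width_ps / 2, t_max_ps - bin_width_ps / 2,
                     by = bin_width_ps)
      d <- suppressWarnings(diffusion_slab_dtof(props, geom, centres))
      d$kind <- "white"
      dtofs[[i]] <- d
    }
  }
  structure(list(mu_sp_grid = grid, dtofs = dtofs,
                 bin_edges_ps = dtofs[[1]]$bin_edges_ps,
                 provenance = list(geom = geom, n_in = n_in, n_out = n_out,
                                   n_photons = n_photons, model = model,
                                   seed = stream$seed,
                                   substream = stream$substream)),
            class = "white_lut")
}

#' @export
print.white_lut <- function(x, ...) {
  g <- x$mu_sp_grid
  cat(sprintf(
    "<white_lut> %d entries, mu_sp %.3g..%.3g 1/cm, %d bins x %.3g ps (%s)\n",
    length(g), min(g), max(g), length(x$dtofs[[1]]$values),
    mean(diff(x$bin_edges_ps)), x$provenance$model))
  invisible(x)
}

#' Fit-window configuration for DTOF analysis
#'
#' The fit window opens on the leading edge at the last bin at or below
#' `rise_fraction` of the peak and closes on the trailing edge at the first
#' bin at or below `tail_fraction` of the peak — the usual TCSPC windowing.
#'
#' @param rise_fraction leading-edge threshold, fraction of peak (default 0.80)
#' @param tail_fraction trailing-edge threshold, fraction of peak
#'   (default 0.01)
#' @param mu_a_bounds absorption search interval, 1/cm
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(rise_fraction = 0.80, tail_fraction = 0.01,
                       mu_a_bounds = c(0, 1)) {
  stopifnot(tail_fraction > 0, tail_fraction < rise_fraction,
            rise_fraction <= 1, length(mu_a_bounds) == 2,
            mu_a_bounds[1] >= 0, diff(mu_a_bounds) > 0)
  structure(list(rise_fraction = rise_fraction,
                 tail_fraction = tail_fraction,
                 mu_a_bounds = mu_a_bounds), class = "fit_config")
}

#' Select the fit window of a DTOF
#'
#' @param x a [dtof()] with a unique global peak (ties broken to the
#'   earliest bin)
#' @param cfg a [fit_config()]
#' @return Integer vector `c(first, last)` of bin indices (inclusive).
#' @export
select_fit_range <- function(x, cfg = fit_config()) {
  stopifnot(inherits(x, "dtof"), inherits(cfg, "fit_config"))
  v <- x$values
  if (all(v <= 0)) stop("cannot select a fit range on an all-zero DTOF")
  ipk <- which.max(v)
  pk <- v[ipk]
  lead <- which(v[seq_len(ipk)] <= cfg$rise_fraction * pk)
  first <- if (length(lead)) max(lead) else 1L
  trail <- which(v <= cfg$tail_fraction * pk)
  trail <- trail[trail > ipk]
  last <- if (length(trail)) min(trail) else length(v)
  if (last <= first) stop("empty fit window")
  c(first, last)
}

# Poisson-weighted chi^2 with closed-form amplitude for one model curve
chi2_amplitude <- function(y, m, w) {
  den <- sum(w * m * m)
  if (den <= 0) return(list(chi2 = Inf, amplitude = NA_real_))
  A <- sum(w * m * y) / den
  if (!is.finite(A) || A <= 0) return(list(chi2 = Inf, amplitude = NA_real_))
  list(chi2 = sum(w * (y - A * m)^2), amplitude = A)
}

#' Invert a measured DTOF to optical properties via the white lookup table
#'
#' For each lookup-table entry the forward model is
#' `amplitude * convolve_irf(apply_absorption(entry, mu_a), irf)`; `mu_a` is
#' optimized by golden-section search with the amplitude solved in closed
#' form, both under Poisson weights `1 / max(counts, 1)` on the fit window of
#' the measured curve. The reported `mu_sp` is refined off-grid by parabolic
#' interpolation of the chi-square profile through the three best adjacent
#' grid nodes.
#'
#' @param measured a [dtof()] on the lookup-table time axis (counts)
#' @param lut a [build_lut()] table
#' @param response an [irf()] (default 35-ps Gaussian)
#' @param cfg a [fit_config()]
#' @return An object of class `fit_result`: `mu_sp`, `mu_a`, `amplitude`,
#'   `chi2_reduced`, `window`, `converged` (FALSE when the optimum sits on the
#'   grid or `mu_a` boundary), `low_counts` (fewer than 1000 counts in the
#'   window), and the per-node `chi2_profile`.
#' @export
fit_dtof <- function(measured, lut, response = irf(35), cfg = fit_config()) {
  stopifnot(inherits(measured, "dtof"), inherits(lut, "white_lut"),
            inherits(response, "irf"), inherits(cfg, "fit_config"))
  if (length(measured$values) != length(lut$dtofs[[1]]$values) ||
      abs(dtof_bin_width(measured) - mean(diff(lut$bin_edges_ps))) >
        1e-9 * mean(diff(lut$bin_edges_ps)))
    stop("measured DTOF and LUT must share the time axis; ",
         "resample with rebin_dtof()/resample_dtof() first")
  win <- select_fit_range(measured, cfg)
  idx <- seq.int(win[1], win[2])
  y <- measured$values[idx]
  w <- 1 / pmax(y, 1)
  low_counts <- sum(y) < 1000

  grid <- lut$mu_sp_grid
  ng <- length(grid)
  chi2 <- numeric(ng)
  mua <- numeric(ng)
  amp <- numeric(ng)
  for (i in seq_len(ng)) {
    entry <- lut$dtofs[[i]]
    obj <- function(a) {
      m <- convolve_irf(apply_absorption(entry, a), response)$values[idx]
      chi2_amplitude(y, m, w)$chi2
    }
    o <- optimize(obj, interval = cfg$mu_a_bounds, tol = 1e-5)
    mua[i] <- o$minimum
    m <- convolve_irf(apply_absorption(entry, mua[i]), response)$values[idx]
    ca <- chi2_amplitude(y, m, w)
    chi2[i] <- ca$chi2
    amp[i] <- ca$amplitude
  }
  best <- which.min(chi2)
  converged <- TRUE
  mu_sp <- grid[best]
  mu_a <- mua[best]
  if (ng >= 3 && best > 1 && best < ng) {
    cm <- chi2[best - 1]; c0 <- chi2[best]; cp <- chi2[best + 1]
    den <- cm - 2 * c0 + cp
    if (is.finite(den) && den > 0) {
      delta <- 0.5 * (cm - cp) / den
      delta <- max(-0.5, min(0.5, delta))
      step <- grid[best + 1] - grid[best]
      mu_sp <- grid[best] + delta * step
      # interpolate mu_a linearly toward the neighbouring node
      nb <- if (delta >= 0) best + 1 else best - 1
      mu_a <- mua[best] + abs(delta) * (mua[nb] - mua[best])
    }
  } else {
    converged <- FALSE
  }
  tol_b <- 1e-4 * diff(cfg$mu_a_bounds)
  if (min(abs(mu_a - cfg$mu_a_bounds)) < tol_b && mu_a > tol_b)
    converged <- FALSE
  structure(list(mu_sp = mu_sp, mu_a = mu_a, amplitude = amp[best],
                 chi2_reduced = chi2[best] / max(1, length(idx) - 3),
                 window = win, converged = converged,
                 low_counts = low_counts,
                 chi2_profile = data.frame(mu_sp = grid, chi2 = chi2,
                                           mu_a = mua)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> mu_sp = %.3f 1/cm, mu_a = %.4f 1/cm, amplitude = %.4g, chi2_red = %.3g%s%s\n",
    x$mu_sp, x$mu_a, x$amplitude, x$chi2_reduced,
    if (x$converged) "" else " [not converged]",
    if (x$low_counts) " [low counts]" else ""))
  invisible(x)
}
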