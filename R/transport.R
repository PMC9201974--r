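#' Unpolarized Fresnel reflectance at a planar interface
#'
#' @param n_from refractive index of the incidence medium
#' @param n_to refractive index of the far medium
#' @param angle_deg incidence angle from the surface normal, degrees, `[0, 90]`
#' @return Reflection probability in `[0, 1]`; 1 beyond the critical angle
#'   (total internal reflection).
#' @export
fresnel_reflectance <- function(n_from, n_to, angle_deg) {
  stopifnot(all(angle_deg >= 0), all(angle_deg <= 90), n_from > 0, n_to > 0)
  vapply(angle_deg, function(a) .fresnel_cpp(n_from, n_to, a), numeric(1))
}

mc_meta <- function(props, geom, n_photons, bin_width_ps, t_max_ps, stream,
                    kind, raw) {
  list(mu_sp = props$mu_sp, mu_a = props$mu_a, g = props$g,
       n_in = props$n_in, n_out = props$n_out,
       thickness_cm = geom$thickness_cm,
       detector_radius_cm = geom$detector_radius_cm,
       acceptance_deg = geom$acceptance_deg,
       lateral_radius_cm = geom$lateral_radius_cm,
       n_photons = n_photons, bin_width_ps = bin_width_ps,
       t_max_ps = t_max_ps,
       seed = stream$seed, substream = stream$substream,
       kind = kind,
       detected = raw$detected,
       transmitted_other = raw$transmitted_other,
       reflected = raw$reflected,
       side_loss = raw$side_loss,
       residual = raw$residual)
}

run_mc <- function(props, geom, n_photons, bin_width_ps, t_max_ps, stream) {
  lat <- if (is.finite(geom$lateral_radius_cm)) geom$lateral_radius_cm else -1
  det <- if (is.finite(geom$detector_radius_cm)) geom$detector_radius_cm else -1
  .mc_slab_cpp(props$mu_s, props$g, geom$thickness_cm,
               props$n_in, props$n_out,
               det, geom$acceptance_deg, lat,
               n_photons, bin_width_ps, t_max_ps,
               props$mu_a, stream$seed, stream$substream)
}

# t_max too short: the histogram is still near its maximum in the last bins
tail_warning <- function(values) {
  n <- length(values)
  m <- max(values)
  n >= 3 && m > 0 && mean(values[(n - 2):n]) > 0.5 * m
}

#' Simulate a white (zero-absorption) photon time-of-flight distribution
#'
#' Photon-packet Monte Carlo through a homogeneous slab with `mu_a = 0`.
#' Boundary crossings use unpolarized Fresnel probabilities for the
#' `n_in`/`n_out` mismatch (including the specular entry reflection);
#' detection requires exit through the coaxial detector disc within the
#' acceptance cone. Arrival time is path length divided by the in-medium
#' speed `c_M = c0 / n_in`. Because trajectories are absorption-free, the
#' same white DTOF serves every absorption value via [apply_absorption()].
#'
#' @param props [optical_properties()] with `mu_a = 0`
#' @param geom [slab_geometry()]
#' @param n_photons number of launched photon packets (>= 1)
#' @param bin_width_ps histogram bin width, ps
#' @param t_max_ps histogram end time, ps; packets whose path exceeds
#'   `c_M * t_max_ps` are terminated and counted as residual weight
#' @param stream [rng_stream()]; identical streams reproduce identical
#'   trajectories bit-for-bit
#' @return A white-kind [dtof()]; `meta` carries the full provenance, the
#'   energy-bookkeeping counters (detected / transmitted_other / reflected /
#'   side_loss / residual) and a `tail_truncated` flag when the histogram
#'   peak falls in the last 3 bins (t_max too short).
#' @export
simulate_white_dtof <- function(props, geom = slab_geometry(),
                                n_photons = 1e6, bin_width_ps = 10,
                                t_max_ps = 6000, stream = rng_stream(1)) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "slab_geometry"),
            inherits(stream, "rng_stream"),
            n_photons >= 1, bin_width_ps > 0, t_max_ps > bin_width_ps)
  if (props$mu_a != 0)
    stop("white Monte Carlo requires mu_a = 0; use simulate_absorbing_dtof()")
  raw <- run_mc(props, geom, n_photons, bin_width_ps, t_max_ps, stream)
  meta <- mc_meta(props, geom, n_photons, bin_width_ps, t_max_ps, stream,
                  "white", raw)
  meta$tail_truncated <- tail_warning(raw$values)
  if (meta$tail_truncated)
    warning("DTOF peak falls in the last 3 bins; t_max_ps is likely too short")
  n_bins <- length(raw$values)
  dtof(seq(0, by = bin_width_ps, length.out = n_bins + 1), raw$values,
       kind = "white", meta = meta)
}

#' Simulate an absorbing photon time-of-flight distribution
#'
#' Runs the identical trajectory ensemble as [simulate_white_dtof()] for the
#' same stream (absorption does not alter scattering paths) and attenuates
#' the detected weight in each arrival-time bin by `exp(-mu_a * c_M * t)`,
#' the microscopic Beer-Lambert factor, with the path length quantized to the
#' bin centre. Consequently it equals `apply_absorption()` of the white DTOF
#' exactly, which is the validation identity for the absorption-scaling step.
#'
#' @inheritParams simulate_white_dtof
#' @param props [optical_properties()] with `mu_a > 0`
#' @return An absorbing-kind [dtof()].
#' @export
simulate_absorbing_dtof <- function(props, geom = slab_geometry(),
                                    n_photons = 1e6, bin_width_ps = 10,
                                    t_max_ps = 6000, stream = rng_stream(1)) {
  stopifnot(inherits(props, "optical_properties"), props$mu_a > 0,
            n_photons >= 1, bin_width_ps > 0)
  raw <- run_mc(props, geom, n_photons, bin_width_ps, t_max_ps, stream)
  meta <- mc_meta(props, geom, n_photons, bin_width_ps, t_max_ps, stream,
                  "absorbing", raw)
  meta$tail_truncated <- tail_warning(raw$counts)
  n_bins <- length(raw$values)
  dtof(seq(0, by = bin_width_ps, length.out = n_bins + 1), raw$values,
       kind = "absorbing", meta = meta)
}

# Extrapolation coefficient A of the diffusion boundary condition from the
# exact effective reflectance (angular Fresnel integrals over the internal
# hemisphere), A = (1 + R_eff) / (1 - R_eff).
boundary_A <- function(n_in, n_out) {
  if (abs(n_in - n_out) < 1e-12) return(1)
  RF <- function(th) fresnel_reflectance(n_in, n_out, th * 180 / pi)
  Rphi <- stats::integrate(function(th) 2 * sin(th) * cos(th) * RF(th),
                           0, pi / 2, rel.tol = 1e-10)$value
  Rj <- stats::integrate(function(th) 3 * sin(th) * cos(th)^2 * RF(th),
                         0, pi / 2, rel.tol = 1e-10)$value
  Reff <- (Rphi + Rj) / (2 - Rphi + Rj)
  (1 + Reff) / (1 - Reff)
}

#' Closed-form time-domain diffusion transmittance of a slab
#'
#' Image-source solution of the time-dependent diffusion equation for an
#' infinite slab with extrapolated boundaries, used as the noise-free oracle
#' for the Monte Carlo model and as the fast forward model of the synthetic
#' generator. The diffusion coefficient is `D = 1/(3 mu_sp)` (absorption
#' excluded), so absorption enters only through the factor
#' `exp(-mu_a * c_M * t)` — the same factorization the scaling step uses.
#'
#' @param props [optical_properties()]
#' @param geom [slab_geometry()]; a finite `detector_radius_cm` applies the
#'   radial disc-collection factor `1 - exp(-r^2 / (4 D c_M t))`; the
#'   acceptance cone is not modelled (diffuse exit assumed)
#' @param time_ps vector of bin-centre times, ps, or a [dtof()] whose axis to
#'   reuse
#' @param n_images image-source series truncation order (terms `-m..m`);
#'   the default 10 bounds the truncation error far below 1e-9 relative for
#'   diffusive slabs on a few-ns axis
#' @return A synthetic-kind [dtof()] with per-bin weight per launched photon
#'   (`T(t) * bin_width`); `meta$diffusive = FALSE` flags `mu_sp * thickness
#'   < 5`, where the diffusion approximation is unreliable.
#' @export
diffusion_slab_dtof <- function(props, geom = slab_geometry(),
                                time_ps = seq(5, 5995, by = 10),
                                n_images = 10) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "slab_geometry"))
  if (inherits(time_ps, "dtof")) time_ps <- dtof_times(time_ps)
  stopifnot(all(diff(time_ps) > 0))
  d <- geom$thickness_cm
  v <- c0_cm_per_ps() / props$n_in
  D <- 1 / (3 * props$mu_sp)
  z0 <- 1 / props$mu_sp
  ze <- 2 * boundary_A(props$n_in, props$n_out) * D
  diffusive <- props$mu_sp * d >= 5
  if (!diffusive)
    warning("mu_sp * thickness < 5: outside the diffusive regime, ",
            "diffusion solution unreliable")
  t <- time_ps
  denom <- 4 * D * v * t
  s <- 0
  for (m in seq(-n_images, n_images)) {
    z1 <- d * (1 - 2 * m) - 4 * m * ze - z0
    z2 <- d * (1 - 2 * m) - (4 * m - 2) * ze + z0
    s <- s + z1 * exp(-z1^2 / denom) - z2 * exp(-z2^2 / denom)
  }
  Tt <- exp(-props$mu_a * v * t) / (2 * sqrt(4 * pi * D * v) * t^1.5) * s
  Tt[Tt < 0] <- 0
  if (is.finite(geom$detector_radius_cm))
    Tt <- Tt * (1 - exp(-geom$detector_radius_cm^2 / denom))
  bw <- mean(diff(t))
  if (length(t) > 1 && diff(range(diff(t))) > 1e-9 * bw)
    stop("time_ps must be uniformly spaced bin centres")
  edges <- c(t - bw / 2, t[length(t)] + bw / 2)
  dtof(edges, Tt * bw, kind = "synthetic",
       meta = list(model = "diffusion", mu_sp = props$mu_sp,
                   mu_a = props$mu_a, n_in = props$n_in,
                   n_out = props$n_out, thickness_cm = d,
                   detector_radius_cm = geom$detector_radius_cm,
                   diffusive = diffusive, n_images = n_images))
}

#' Steady-state diffusion transmittance of a non-absorbing slab
#'
#' Fraction of injected photons transmitted through the slab in the
#' extrapolated-boundary diffusion model with `mu_a = 0`; closed form
#' `(z0 + ze) / (d + 2 ze)`. Serves as an integral check on
#' [diffusion_slab_dtof()].
#'
#' @param props [optical_properties()] (`mu_a` ignored; must be 0 for the
#'   closed form to apply)
#' @param geom [slab_geometry()]
#' @return Transmitted fraction in `(0, 1)`.
#' @export
cw_slab_transmittance <- function(props, geom = slab_geometry()) {
  D <- 1 / (3 * props$mu_sp)
  z0 <- 1 / props$mu_sp
  ze <- 2 * boundary_A(props$n_in, props$n_out) * D
  (z0 + ze) / (geom$thickness_cm + 2 * ze)
}
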