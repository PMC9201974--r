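#' @useDynLib nirphantom, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx coef lm nls optimize rnorm rpois sd setNames
#' @importFrom utils head read.csv tail write.csv
NULL

#' Speed of light in vacuum, cm/ps
#'
#' Used throughout to convert photon path length inside the medium to arrival
#' time via the in-medium speed `c_M = c0_cm_per_ps() / n_in`.
#' @return Scalar, cm/ps.
#' @export
c0_cm_per_ps <- function() 0.0299792458

#' Bulk optical properties of a homogeneous turbid medium
#'
#' @param mu_a absorption coefficient, 1/cm (>= 0)
#' @param mu_sp reduced scattering coefficient `mu_s * (1 - g)`, 1/cm (> 0)
#' @param g scattering anisotropy factor in `[0, 1)`; the similarity relation
#'   lets the simulation run at `g = 0` with `mu_s = mu_sp`
#' @param n_in refractive index of the medium (>= 1)
#' @param n_out refractive index of the surroundings (>= 1)
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a = 0, mu_sp = 10, g = 0,
                               n_in = 1.54, n_out = 1.0) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1, mu_a >= 0,
            is.numeric(mu_sp), length(mu_sp) == 1, mu_sp > 0,
            is.numeric(g), length(g) == 1, g >= 0, g < 1,
            n_in >= 1, n_out >= 1)
  structure(list(mu_a = mu_a, mu_sp = mu_sp, g = g,
                 n_in = n_in, n_out = n_out,
                 mu_s = mu_sp / (1 - g)),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties> mu_a = %.4g 1/cm, mu_sp = %.4g 1/cm, g = %.3g, n_in = %.3g, n_out = %.3g\n",
    x$mu_a, x$mu_sp, x$g, x$n_in, x$n_out))
  invisible(x)
}

#' Slab geometry for transmittance simulation
#'
#' Pencil beam at normal incidence on the entry face; detection through a
#' coaxial disc on the exit face within an acceptance cone measured outside
#' the medium.
#'
#' @param thickness_cm slab thickness, cm (> 0)
#' @param detector_radius_cm radius of the coaxial detection disc, cm;
#'   `Inf` collects the whole exit face
#' @param acceptance_deg acceptance half-angle in degrees, `(0, 90]`
#' @param lateral_radius_cm lateral extent of the slab, cm; `Inf` (default)
#'   models the laterally unbounded slab used in the analysis; a finite value
#'   turns on side losses (e.g. 4 cm for an 8-cm disc phantom)
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(thickness_cm = 2, detector_radius_cm = Inf,
                          acceptance_deg = 90, lateral_radius_cm = Inf) {
  stopifnot(thickness_cm > 0,
            detector_radius_cm > 0,
            acceptance_deg > 0, acceptance_deg <= 90,
            lateral_radius_cm > 0)
  structure(list(thickness_cm = thickness_cm,
                 detector_radius_cm = detector_radius_cm,
                 acceptance_deg = acceptance_deg,
                 lateral_radius_cm = lateral_radius_cm),
            class = "slab_geometry")
}

#' @export
print.slab_geometry <- function(x, ...) {
  cat(sprintf(
    "<slab_geometry> thickness %.3g cm, detector r = %.3g cm / %.3g deg, lateral r = %.3g cm\n",
    x$thickness_cm, x$detector_radius_cm, x$acceptance_deg,
    x$lateral_radius_cm))
  invisible(x)
}

#' Distribution of times of flight of photons (DTOF)
#'
#' A time-binned histogram of detected photon weight (or counts), the central
#' data object of the time-resolved transmittance chain.
#'
#' @param bin_edges_ps strictly increasing, uniformly spaced bin edges, ps
#' @param values per-bin photon weight or counts, `length(bin_edges_ps) - 1`,
#'   all non-negative
#' @param kind one of `"white"` (zero-absorption trajectories), `"absorbing"`,
#'   `"measured"`, `"synthetic"`
#' @param meta named list of metadata (wavelength_nm, scan position,
#'   geometry, n_in, launched photons, seed, warning flags, ...)
#' @return An object of class `dtof`.
#' @export
dtof <- function(bin_edges_ps, values,
                 kind = c("white", "absorbing", "measured", "synthetic"),
                 meta = list()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(bin_edges_ps), length(bin_edges_ps) >= 2,
            all(diff(bin_edges_ps) > 0),
            length(values) == length(bin_edges_ps) - 1,
            all(values >= 0), all(is.finite(values)))
  w <- diff(bin_edges_ps)
  if (diff(range(w)) > 1e-9 * mean(w))
    stop("bin_edges_ps must be uniformly spaced")
  structure(list(bin_edges_ps = as.numeric(bin_edges_ps),
                 values = as.numeric(values),
                 kind = kind, meta = meta),
            class = "dtof")
}

#' Bin centres of a DTOF, ps
#' @param x a [dtof()] object
#' @return Numeric vector of bin-centre times, ps.
#' @export
dtof_times <- function(x) {
  e <- x$bin_edges_ps
  (e[-1] + e[-length(e)]) / 2
}

#' Uniform bin width of a DTOF, ps
#' @param x a [dtof()] object
#' @return Scalar bin width, ps.
#' @export
dtof_bin_width <- function(x) mean(diff(x$bin_edges_ps))

#' Time integral of a DTOF
#'
#' @param x a [dtof()] object
#' @param per_time if `TRUE` the values are treated as a rate (per ps) and the
#'   integral is `sum(values) * bin_width`; if `FALSE` (default) values are
#'   per-bin weights and the integral is their plain sum
#' @return Scalar total weight.
#' @export
dtof_integral <- function(x, per_time = FALSE) {
  if (per_time) sum(x$values) * dtof_bin_width(x) else sum(x$values)
}

#' @export
print.dtof <- function(x, ...) {
  tt <- dtof_times(x)
  pk <- if (any(x$values > 0)) tt[which.max(x$values)] else NA_real_
  cat(sprintf(
    "<dtof> %s, %d bins x %.3g ps, total weight %.6g, peak at %.5g ps\n",
    x$kind, length(x$values), dtof_bin_width(x), sum(x$values), pk))
  invisible(x)
}

#' Rebin a DTOF by an integer aggregation factor
#'
#' Adjacent bins are summed; trailing bins that do not fill a complete group
#' are dropped. Useful for shape comparisons at coarser time resolution.
#'
#' @param x a [dtof()] object
#' @param factor integer >= 1, number of adjacent bins to merge
#' @return A [dtof()] with `floor(n / factor)` bins.
#' @export
rebin_dtof <- function(x, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(x)
  n <- length(x$values) %/% factor
  idx <- seq_len(n * factor)
  vals <- as.numeric(tapply(x$values[idx], rep(seq_len(n), each = factor), sum))
  edges <- x$bin_edges_ps[seq(1, n * factor + 1, by = factor)]
  dtof(edges, vals, kind = x$kind, meta = x$meta)
}

#' Reproducible random stream identifier
#'
#' A (seed, substream) pair. The Monte Carlo core derives one counter-based
#' generator per photon from it, so identical pairs reproduce identical
#' trajectories bit-for-bit; R-level generators derive a 31-bit seed from it.
#'
#' @param seed non-negative integer master seed
#' @param substream non-negative integer substream index
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed, substream = 0) {
  stopifnot(seed >= 0, seed == round(seed),
            substream >= 0, substream == round(substream))
  structure(list(seed = as.numeric(seed), substream = as.numeric(substream)),
            class = "rng_stream")
}

# 31-bit seed for R's RNG derived deterministically from (seed, substream)
derive_r_seed <- function(stream) {
  s <- (stream$seed * 2654435761 + stream$substream * 40503 + 97) %% 2147483647
  as.integer(s)
}

# evaluate expr with R's RNG seeded from the stream, restoring global state
with_stream <- function(stream, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(derive_r_seed(stream))
  expr
}
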