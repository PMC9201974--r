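#' Scan-grid DTOF dataset
#'
#' DTOFs recorded on a regular lattice across a disc phantom, one per
#' spectral band per position. Bands follow the measurement protocol:
#' `"excitation"` (short-pass filtered) and `"fluorescence"` (long-pass
#' filtered), but any label set is accepted.
#'
#' @param positions data frame with columns `x`, `y` (mm) on a regular
#'   lattice
#' @param step_mm lattice step, mm
#' @param dtofs list (length `nrow(positions)`) of named lists of [dtof()]
#'   objects, one element per band
#' @param outline list with `cx`, `cy`, `radius_mm` describing the phantom
#'   disc
#' @return An object of class `scan_grid`.
#' @export
scan_grid <- function(positions, step_mm, dtofs,
                      outline = list(cx = 0, cy = 0, radius_mm = 40)) {
  stopifnot(is.data.frame(positions), all(c("x", "y") %in% names(positions)),
            length(dtofs) == nrow(positions), step_mm > 0,
            outline$radius_mm > 0)
  bands <- sort(names(dtofs[[1]]))
  ok <- vapply(dtofs, function(d) identical(sort(names(d)), bands), logical(1))
  if (!all(ok)) stop("every position must carry the same band set")
  offgrid <- c((positions$x - outline$cx) %% step_mm,
               (positions$y - outline$cy) %% step_mm)
  if (any(pmin(offgrid, step_mm - offgrid) > 1e-6 * step_mm))
    stop("positions must lie on a regular lattice of the given step")
  structure(list(positions = positions, step_mm = step_mm, dtofs = dtofs,
                 bands = bands, outline = outline), class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("<scan_grid> %d positions, step %g mm, bands: %s, disc r = %g mm\n",
              nrow(x$positions), x$step_mm, paste(x$bands, collapse = ", "),
              x$outline$radius_mm))
  invisible(x)
}

# distance of each lattice position from the disc edge, mm
edge_distance <- function(scan) {
  with(scan$positions,
       scan$outline$radius_mm - sqrt((x - scan$outline$cx)^2 +
                                     (y - scan$outline$cy)^2))
}

#' Lattice map of per-position scalar values
#'
#' @param scan the originating [scan_grid()]
#' @param values numeric vector aligned with `scan$positions`
#' @param valid logical mask of usable cells
#' @param edge_margin_mm margin from the disc outline inside which cells are
#'   edge-masked for central statistics
#' @param reference normalization reference value, recorded for auditability
#'   (`NA` when the map is not normalized)
#' @param what label of the mapped quantity
#' @return An object of class `property_map` (a data frame `x`, `y`,
#'   `value`, `valid`, `edge` with attributes).
#' @export
property_map_frame <- function(scan, values, valid = rep(TRUE, length(values)),
                               edge_margin_mm = 10, reference = NA_real_,
                               what = "value") {
  ed <- edge_distance(scan)
  df <- data.frame(x = scan$positions$x, y = scan$positions$y,
                   value = ifelse(valid, values, NA_real_),
                   valid = valid & ed >= 0,
                   edge = ed < edge_margin_mm)
  structure(df, class = c("property_map", "data.frame"),
            step_mm = scan$step_mm, outline = scan$outline,
            edge_margin_mm = edge_margin_mm, reference = reference,
            what = what)
}

#' @export
print.property_map <- function(x, ...) {
  cen <- x$valid & !x$edge
  cat(sprintf("<property_map> %s: %d cells (%d central), reference %s\n",
              attr(x, "what"), sum(x$valid), sum(cen),
              format(attr(x, "reference"))))
  invisible(x)
}

#' Normalized DTOF-integral homogeneity map
#'
#' Per-position time integral of the DTOF in one band, divided by the
#' maximum over the unmasked central region (cells at least
#' `edge_margin_mm` from the disc outline). The normalization reference is
#' recorded in the map attributes.
#'
#' @param scan a [scan_grid()]
#' @param band band label present in the scan
#' @param edge_margin_mm edge-mask margin, mm (default 10)
#' @return A [property_map_frame()] of normalized integrals.
#' @export
integral_map <- function(scan, band = "fluorescence", edge_margin_mm = 10) {
  stopifnot(inherits(scan, "scan_grid"))
  if (!band %in% scan$bands)
    stop("band '", band, "' not present; available: ",
         paste(scan$bands, collapse = ", "))
  ints <- vapply(scan$dtofs, function(d) dtof_integral(d[[band]]), numeric(1))
  ed <- edge_distance(scan)
  central <- ed >= edge_margin_mm
  if (!any(central)) stop("empty central region: edge margin too large")
  ref <- max(ints[central])
  if (ref <= 0) stop("central region carries no signal")
  property_map_frame(scan, ints / ref, edge_margin_mm = edge_margin_mm,
                     reference = ref, what = paste0("integral_", band))
}

#' Per-position optical-property maps by lookup-table inversion
#'
#' Applies [fit_dtof()] at every scan position of one band; positions whose
#' fit does not converge are masked.
#'
#' @param scan a [scan_grid()]
#' @param lut a [build_lut()] table consistent with the scan geometry
#' @param response an [irf()]
#' @param cfg a [fit_config()]
#' @param band band label
#' @param edge_margin_mm edge-mask margin, mm
#' @return List with elements `mu_a` and `mu_sp` ([property_map_frame()]s)
#'   and `report`, a data frame of per-position convergence and low-count
#'   flags.
#' @export
property_map <- function(scan, lut, response = irf(35), cfg = fit_config(),
                         band = "excitation", edge_margin_mm = 10) {
  stopifnot(inherits(scan, "scan_grid"), inherits(lut, "white_lut"))
  if (!band %in% scan$bands) stop("band '", band, "' not present")
  n <- nrow(scan$positions)
  mu_a <- mu_sp <- rep(NA_real_, n)
  conv <- low <- logical(n)
  for (i in seq_len(n)) {
    fr <- fit_dtof(scan$dtofs[[i]][[band]], lut, response, cfg)
    mu_a[i] <- fr$mu_a
    mu_sp[i] <- fr$mu_sp
    conv[i] <- fr$converged
    low[i] <- fr$low_counts
  }
  list(mu_a = property_map_frame(scan, mu_a, valid = conv,
                                 edge_margin_mm = edge_margin_mm,
                                 what = "mu_a"),
       mu_sp = property_map_frame(scan, mu_sp, valid = conv,
                                  edge_margin_mm = edge_margin_mm,
                                  what = "mu_sp"),
       report = data.frame(x = scan$positions$x, y = scan$positions$y,
                           converged = conv, low_counts = low))
}

#' Central-region homogeneity statistics of a property map
#'
#' On valid cells at least `edge_margin_mm` away from the disc outline,
#' reports the maximum absolute relative deviation from the central mean,
#' the relative standard deviation, and the location of the extreme cell.
#'
#' @param map a [property_map_frame()]
#' @param edge_margin_mm margin, mm; defaults to the margin stored in the map
#' @return List `max_rel_dev`, `rel_sd`, `mean`, `n_cells`, `extreme_cell`
#'   (list `x`, `y`, `value`).
#' @export
central_stats <- function(map, edge_margin_mm = attr(map, "edge_margin_mm")) {
  stopifnot(inherits(map, "property_map"))
  out <- attr(map, "outline")
  ed <- out$radius_mm - sqrt((map$x - out$cx)^2 + (map$y - out$cy)^2)
  if (edge_margin_mm >= out$radius_mm)
    stop("edge margin must be smaller than the outline radius")
  sel <- map$valid & !is.na(map$value) & ed >= edge_margin_mm
  if (!any(sel)) stop("edge margin excludes all cells")
  v <- map$value[sel]
  mu <- mean(v)
  rel <- v / mu - 1
  i <- which.max(abs(rel))
  list(max_rel_dev = abs(rel[i]),
       rel_sd = if (length(v) > 1) sd(v) / mu else 0,
       mean = mu,
       n_cells = length(v),
       extreme_cell = list(x = map$x[sel][i], y = map$y[sel][i],
                           value = v[i]))
}
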