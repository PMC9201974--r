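#' Resample a DTOF onto a new uniform time axis
#'
#' Mass-preserving resampling via linear interpolation of the cumulative
#' distribution, so total weight is conserved for axes covering the support.
#'
#' @param x a [dtof()]
#' @param new_edges_ps strictly increasing uniform bin edges, ps
#' @return A [dtof()] on the new axis, same kind and metadata.
#' @export
resample_dtof <- function(x, new_edges_ps) {
  stopifnot(inherits(x, "dtof"), all(diff(new_edges_ps) > 0))
  cum <- c(0, cumsum(x$values))
  ci <- approx(x$bin_edges_ps, cum, xout = new_edges_ps, rule = 2)$y
  dtof(new_edges_ps, pmax(0, diff(ci)), kind = x$kind, meta = x$meta)
}

#' Write / read a DTOF as CSV with a YAML metadata sidecar
#'
#' The CSV has the header `time_ps,value`, one row per bin left edge; the
#' sidecar `<path>.yaml` carries kind, bin width and all metadata.
#'
#' @param x a [dtof()]
#' @param path CSV file path; the sidecar is written to `paste0(path, ".yaml")`
#' @return `write_dtof` returns `path` invisibly; `read_dtof` the [dtof()].
#' @export
write_dtof <- function(x, path) {
  stopifnot(inherits(x, "dtof"))
  df <- data.frame(time_ps = head(x$bin_edges_ps, -1), value = x$values)
  write.csv(df, path, row.names = FALSE)
  meta <- x$meta
  meta$kind <- x$kind
  meta$bin_width_ps <- dtof_bin_width(x)
  meta <- lapply(meta, function(v) if (is.list(v)) unclass(v) else v)
  writeLines(yaml::as.yaml(meta), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_dtof
#' @export
read_dtof <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_ps", "value") %in% names(df)))
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  kind <- meta$kind %||% "measured"
  bw <- meta$bin_width_ps %||% mean(diff(df$time_ps))
  meta$kind <- NULL
  edges <- c(df$time_ps, df$time_ps[length(df$time_ps)] + bw)
  dtof(edges, df$value, kind = kind, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist / load a white lookup table
#'
#' Plain-text representation: `<path>` is a CSV matrix (first column
#' `time_ps` bin left edges, one further column per grid entry named
#' `mu_sp_<value>`) and `<path>.yaml` carries the provenance (geometry,
#' refractive indices, photons per entry, seed, model).
#'
#' @param lut a [build_lut()] table
#' @param path CSV file path
#' @return `write_lut` returns `path` invisibly; `read_lut` the `white_lut`.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "white_lut"))
  mat <- sapply(lut$dtofs, function(d) d$values)
  df <- data.frame(time_ps = head(lut$bin_edges_ps, -1), mat)
  names(df) <- c("time_ps", sprintf("mu_sp_%g", lut$mu_sp_grid))
  write.csv(df, path, row.names = FALSE)
  prov <- lut$provenance
  meta <- list(mu_sp_grid = lut$mu_sp_grid,
               thickness_cm = prov$geom$thickness_cm,
               detector_radius_cm = prov$geom$detector_radius_cm,
               acceptance_deg = prov$geom$acceptance_deg,
               lateral_radius_cm = prov$geom$lateral_radius_cm,
               n_in = prov$n_in, n_out = prov$n_out,
               n_photons = prov$n_photons, model = prov$model,
               seed = prov$seed, substream = prov$substream)
  writeLines(yaml::as.yaml(meta), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  df <- read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  grid <- as.numeric(meta$mu_sp_grid)
  bw <- mean(diff(df$time_ps))
  edges <- c(df$time_ps, df$time_ps[nrow(df)] + bw)
  geom <- slab_geometry(meta$thickness_cm, meta$detector_radius_cm,
                        meta$acceptance_deg, meta$lateral_radius_cm)
  dtofs <- lapply(seq_along(grid), function(i) {
    dtof(edges, df[[i + 1]], kind = "white",
         meta = list(mu_sp = grid[i], mu_a = 0, n_in = meta$n_in,
                     n_out = meta$n_out, thickness_cm = meta$thickness_cm))
  })
  structure(list(mu_sp_grid = grid, dtofs = dtofs, bin_edges_ps = edges,
                 provenance = list(geom = geom, n_in = meta$n_in,
                                   n_out = meta$n_out,
                                   n_photons = meta$n_photons,
                                   model = meta$model, seed = meta$seed,
                                   substream = meta$substream)),
            class = "white_lut")
}
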