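test_that("default lookup-table grid spans 0.1..20 in 200 steps", {
  lut <- build_lut(model = "diffusion")
  expect_length(lut$mu_sp_grid, 200)
  expect_equal(lut$mu_sp_grid[1], 0.1)
  expect_equal(lut$mu_sp_grid[200], 20)
  expect_true(all(vapply(lut$dtofs, function(d) d$kind == "white",
                         logical(1))))
})

test_that("degenerate single-entry table still drives a fit", {
  lut <- build_lut(9.5, 9.5, 0.1, model = "diffusion")
  expect_length(lut$mu_sp_grid, 1)
  meas <- convolve_irf(apply_absorption(lut$dtofs[[1]], 0.08), irf(35))
  meas$kind <- "measured"
  fr <- fit_dtof(meas, lut)
  expect_equal(fr$mu_a, 0.08, tolerance = 1e-3)
  expect_false(fr$converged) # off-grid refinement impossible on one node
})

test_that("rebuilding a Monte Carlo table with the same seed is bitwise stable", {
  a <- build_lut(9.5, 9.6, 0.1, n_photons = 1e4, stream = rng_stream(5))
  b <- build_lut(9.5, 9.6, 0.1, n_photons = 1e4, stream = rng_stream(5))
  expect_identical(lapply(a$dtofs, `[[`, "values"),
                   lapply(b$dtofs, `[[`, "values"))
})

test_that("absorption scaling has the exact Beer-Lambert factor", {
  # one bin centred at 1000 ps
  x <- dtof(c(995, 1005), 1, kind = "white", meta = list(n_in = 1.54))
  y <- apply_absorption(x, 0.1)
  expect_equal(y$values, exp(-0.1 * (c0_cm_per_ps() / 1.54) * 1000),
               tolerance = 1e-12)
  # identity at zero absorption
  w <- small_diffusion_lut()$dtofs[[6]]
  expect_equal(apply_absorption(w, 0)$values, w$values)
  # exponential semigroup: 0.1 twice = 0.2 once
  once <- apply_absorption(w, 0.2)
  half <- apply_absorption(w, 0.1)
  half$kind <- "white" # re-mark to apply the second half
  twice <- apply_absorption(half, 0.1)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  # double attenuation is refused
  expect_error(apply_absorption(once, 0.1), "white")
})

test_that("IRF convolution preserves weight and reproduces known kernels", {
  w <- small_diffusion_lut()$dtofs[[11]]
  # delta IRF is the identity
  expect_equal(convolve_irf(w, irf(0))$values, w$values)
  # total weight is conserved (support interior to the axis)
  interior <- dtof(w$bin_edges_ps,
                   ifelse(dtof_times(w) < 4000, w$values, 0),
                   kind = "white", meta = w$meta)
  cv <- convolve_irf(interior, irf(35))
  expect_equal(sum(cv$values), sum(interior$values), tolerance = 1e-9)
  # a single-bin pulse maps onto the Gaussian kernel with FWHM 35 ps
  pulse <- dtof(seq(0, 2000, by = 10), c(rep(0, 99), 1, rep(0, 100)),
                kind = "measured")
  g <- convolve_irf(pulse, irf(35))
  tt <- dtof_times(g)
  above <- tt[g$values >= max(g$values) / 2]
  expect_lt(abs(diff(range(above)) + 10 - 35), 11) # 35-ps FWHM on a 10-ps grid
  expect_equal(tt[which.max(g$values)], 995)
})

test_that("fit-window selection matches an exhaustive threshold scan", {
  x <- triangle_dtof()
  cfg <- fit_config(rise_fraction = 0.8, tail_fraction = 0.01)
  win <- select_fit_range(x, cfg)
  # brute force: scan every bin against the thresholds
  v <- x$values
  pk <- which.max(v)
  first_bf <- max(which(v[1:pk] <= 0.8 * max(v)))
  cand <- which(v <= 0.01 * max(v))
  last_bf <- min(cand[cand > pk])
  expect_equal(win, c(first_bf, last_bf))
  expect_true(win[1] < pk && win[2] > pk)
  # rise 1.0, tail -> 0: window from the peak to the last non-zero bin
  win2 <- select_fit_range(x, fit_config(1.0, 1e-9))
  expect_equal(win2[1], pk)
  expect_equal(win2[2], max(which(v > 0)) + 1)
  # degenerate input
  z <- dtof(seq(0, 100, by = 10), rep(0, 10), kind = "measured")
  expect_error(select_fit_range(z), "all-zero")
})

test_that("noise-free self-consistency inversion recovers the forward truth", {
  lut <- small_diffusion_lut()
  meas <- convolve_irf(apply_absorption(lut$dtofs[[11]], 0.08), irf(35))
  meas <- dtof(meas$bin_edges_ps, meas$values * 1e6 / sum(meas$values),
               kind = "measured", meta = meas$meta)
  fr <- fit_dtof(meas, lut)
  expect_equal(fr$mu_sp, 9.5, tolerance = 0.05 / 9.5)
  expect_equal(fr$mu_a, 0.08, tolerance = 0.001 / 0.08)
  expect_true(fr$converged)
})

test_that("white table entry with a delta IRF inverts to zero absorption", {
  lut <- small_diffusion_lut()
  meas <- lut$dtofs[[11]]
  meas <- dtof(meas$bin_edges_ps, meas$values * 1e6 / sum(meas$values),
               kind = "measured", meta = meas$meta)
  fr <- fit_dtof(meas, lut, response = irf(0))
  expect_lt(fr$mu_a, 0.001)
})

test_that("fit is scale-equivariant in the measured amplitude", {
  lut <- small_diffusion_lut()
  meas <- convolve_irf(apply_absorption(lut$dtofs[[8]], 0.07), irf(35))
  m1 <- dtof(meas$bin_edges_ps, meas$values * 1e6 / sum(meas$values),
             kind = "measured", meta = meas$meta)
  m2 <- dtof(m1$bin_edges_ps, m1$values * 3.7, kind = "measured",
             meta = m1$meta)
  f1 <- fit_dtof(m1, lut)
  f2 <- fit_dtof(m2, lut)
  expect_equal(f2$mu_sp, f1$mu_sp, tolerance = 1e-6)
  expect_equal(f2$mu_a, f1$mu_a, tolerance = 1e-4)
  expect_equal(f2$amplitude / f1$amplitude, 3.7, tolerance = 1e-6)
})

test_that("chi-square profile is locally convex at the reported optimum", {
  lut <- small_diffusion_lut()
  meas <- convolve_irf(apply_absorption(lut$dtofs[[11]], 0.08), irf(35))
  meas <- dtof(meas$bin_edges_ps, meas$values * 1e6 / sum(meas$values),
               kind = "measured", meta = meas$meta)
  fr <- fit_dtof(meas, lut)
  prof <- fr$chi2_profile
  i <- which.min(prof$chi2)
  expect_true(i > 1 && i < nrow(prof))
  expect_gt(prof$chi2[i - 1] - 2 * prof$chi2[i] + prof$chi2[i + 1], 0)
})

test_that("log-integral of an attenuated DTOF is affine in mu_a", {
  # slope of ln(integral) vs mu_a equals -c_M * <t> of the white curve
  w <- small_diffusion_lut()$dtofs[[11]]
  v <- c0_cm_per_ps() / 1.54
  tt <- dtof_times(w)
  h <- 1e-5
  f <- function(mua) log(sum(apply_absorption(w, mua)$values))
  slope_fd <- (f(0.08 + h) - f(0.08 - h)) / (2 * h)
  wa <- apply_absorption(w, 0.08)
  mean_t <- sum(tt * wa$values) / sum(wa$values)
  expect_equal(slope_fd, -v * mean_t, tolerance = 1e-6)
})

test_that("a 2x coarser analysis axis moves the fit by less than its precision", {
  lut <- small_diffusion_lut()
  meas <- convolve_irf(apply_absorption(lut$dtofs[[11]], 0.08), irf(35))
  meas <- dtof(meas$bin_edges_ps, meas$values * 1e6 / sum(meas$values),
               kind = "measured", meta = meas$meta)
  f1 <- fit_dtof(meas, lut)
  lut2 <- build_lut(8.5, 10.5, 0.1, slab_geometry(2), bin_width_ps = 20,
                    model = "diffusion")
  f2 <- fit_dtof(rebin_dtof(meas, 2), lut2)
  expect_lt(abs(f2$mu_sp - f1$mu_sp), 0.05) # half the grid-step resolution
  expect_lt(abs(f2$mu_a - f1$mu_a), 0.0025)
})

test_that("low-count windows are flagged", {
  lut <- small_diffusion_lut()
  meas <- convolve_irf(apply_absorption(lut$dtofs[[11]], 0.08), irf(35))
  meas <- dtof(meas$bin_edges_ps, meas$values * 500 / sum(meas$values),
               kind = "measured", meta = meas$meta)
  fr <- fit_dtof(meas, lut)
  expect_true(fr$low_counts)
})
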