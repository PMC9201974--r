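test_that("infinite-count mode returns the deterministic forward curve", {
  tr <- study_truth()
  g <- gen_dtof(tr, total_counts = 1e6, poisson = FALSE)
  base <- convolve_irf(diffusion_slab_dtof(tr$props, tr$geom,
                                           seq(5, 5995, by = 10)), irf(35))
  expect_equal(g$dtof$values, base$values / sum(base$values) * 1e6,
               tolerance = 1e-12)
  expect_equal(g$truth$mu_sp, 9.5)
  expect_equal(g$truth$mu_a, 0.08)
})

test_that("different seeds give different counts but identical truth", {
  tr <- study_truth()
  a <- gen_dtof(tr, total_counts = 1e5, stream = rng_stream(1))
  b <- gen_dtof(tr, total_counts = 1e5, stream = rng_stream(2))
  a2 <- gen_dtof(tr, total_counts = 1e5, stream = rng_stream(1))
  expect_false(identical(a$dtof$values, b$dtof$values))
  expect_identical(a$dtof$values, a2$dtof$values)
  expect_identical(a$truth, b$truth)
})

test_that("generated DTOFs obey the absorption factorization before noise", {
  # with a delta IRF the mu_a curve is the mu_a = 0 curve rescaled by
  # exp(-mu_a c_M t) (up to the common count normalization)
  geom <- slab_geometry(2)
  t0 <- phantom_truth(optical_properties(0, 9.5), geom = geom)
  ta <- phantom_truth(optical_properties(0.08, 9.5), geom = geom)
  g0 <- gen_dtof(t0, response = irf(0), total_counts = 1, poisson = FALSE)
  ga <- gen_dtof(ta, response = irf(0), total_counts = 1, poisson = FALSE)
  v <- c0_cm_per_ps() / 1.54
  scaled <- g0$dtof$values * exp(-0.08 * v * dtof_times(g0$dtof))
  scaled <- scaled / sum(scaled)
  expect_equal(ga$dtof$values, scaled, tolerance = 1e-9)
})

test_that("round trip: inversion recovers the generator truth", {
  tr <- study_truth()
  lut <- small_diffusion_lut()
  fits <- vapply(1:5, function(s) {
    g <- gen_dtof(tr, total_counts = 1e6, stream = rng_stream(100 + s))
    fr <- fit_dtof(g$dtof, lut)
    c(fr$mu_sp, fr$mu_a)
  }, numeric(2))
  expect_lt(abs(mean(fits[1, ]) - 9.5), 0.2)
  expect_lt(abs(mean(fits[2, ]) - 0.08), 0.005)
})

test_that("noise-free homogeneous scans map to exactly ones", {
  gs <- gen_scan(study_truth(), noise_rel = 0, poisson = FALSE,
                 total_counts = 1e6)
  m <- integral_map(gs$scan, "fluorescence")
  cen <- m$valid & !m$edge
  expect_true(all(abs(m$value[cen] - 1) < 1e-12))
  # the edge roll-off only affects cells inside the margin band
  expect_true(all(m$value[m$edge] <= 1 + 1e-12))
})

test_that("a programmed +7% anomaly appears at its position and amplitude", {
  gs <- gen_scan(study_truth(),
                 anomalies = list(list(x = -15, y = -15, amplitude = 0.07)),
                 noise_rel = 0, poisson = FALSE, total_counts = 1e6)
  cs <- central_stats(integral_map(gs$scan, "fluorescence"))
  expect_equal(cs$extreme_cell$x, -15)
  expect_equal(cs$extreme_cell$y, -15)
  n <- cs$n_cells
  expect_equal(cs$max_rel_dev, 0.07 * (1 - 1 / n) / (1 + 0.07 / n),
               tolerance = 1e-9)
  # anomalies outside the disc are refused
  expect_error(gen_scan(study_truth(),
                        anomalies = list(list(x = 50, y = 0,
                                              amplitude = 0.07))),
               "outline")
})

test_that("scan generation is reproducible per stream", {
  a <- gen_scan(study_truth(), total_counts = 1e4, stream = rng_stream(9))
  b <- gen_scan(study_truth(), total_counts = 1e4, stream = rng_stream(9))
  expect_identical(a$scan$dtofs[[5]]$fluorescence$values,
                   b$scan$dtofs[[5]]$fluorescence$values)
})

test_that("zero-noise zero-drift series is exactly constant", {
  im <- imager_model(frame_noise_rel = 0, warmup_amplitude_rel = 0,
                     pixel_noise_rel = 0)
  reg <- roi_spec(20, 20, 16, 16, k = 21)
  g <- gen_image_series(list(list(truth = phantom_truth(dye = lumogen_dye()),
                                  region = reg)), im, n_frames = 10,
                        stream = rng_stream(1))
  inten <- series_intensity(g$series, reg)
  expect_equal(max(inten) - min(inten), 0, tolerance = 1e-12)
  # overlapping phantom regions are refused
  expect_error(gen_image_series(list(
    list(truth = phantom_truth(), region = roi_spec(20, 20, 16, 16)),
    list(truth = phantom_truth(), region = roi_spec(25, 25, 16, 16))),
    im, n_frames = 3), "overlap")
})

test_that("storage decay reduces day-scale series as programmed", {
  im <- imager_model(frame_noise_rel = 0, warmup_amplitude_rel = 0,
                     pixel_noise_rel = 0)
  reg <- roi_spec(20, 20, 16, 16, k = 21)
  days <- seq(0, 30.44, length.out = 6) * 86400
  for (storage in c("dark", "daylight")) {
    g <- gen_image_series(list(list(truth = phantom_truth(dye = icg_dye()),
                                    region = reg)), im,
                          timestamps_s = days, storage = storage,
                          stream = rng_stream(1))
    # remove the per-frame bleaching contribution (6 exposures)
    inten <- series_intensity(g$series, reg) /
      exp(-icg_dye()$bleach_rate_per_frame * (seq_along(days) - 1))
    drop <- 1 - inten[6] / inten[1]
    expect_equal(drop, if (storage == "dark") 0.10 else 0.30,
                 tolerance = 1e-6)
  }
})

test_that("dye spectra show linear low-concentration response and red shift", {
  d <- lumogen_dye()
  # c -> 0: the band intensity per unit concentration converges
  lo <- gen_dye_spectra(d, concentrations = c(0.001, 0.01))
  per_c <- lo$intensity / lo$concentration
  expect_lt(abs(per_c[2] / per_c[1] - 1), 0.01)
  # red shift: observed emission peak is non-decreasing in concentration
  s <- gen_dye_spectra(d)
  peaks <- vapply(s$spectra, function(sp) as.numeric(peak_wavelength(sp)),
                  numeric(1))
  expect_true(all(diff(peaks) >= 0))
  expect_gt(peaks[length(peaks)], peaks[1])
})

test_that("default dye calibration places the linearity onset at 1.5 ug/g", {
  s <- gen_dye_spectra(lumogen_dye())
  r <- linearity_onset(s)
  grid_tol <- c(1.25, 1.5, 2.0) # onset within one grid point of the target
  expect_true(r$onset %in% grid_tol)
  expect_equal(r$onset, 1.5)
})
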