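test_that("Fresnel reflectance reproduces closed-form boundary physics", {
  # matched media reflect nothing at any angle
  expect_equal(fresnel_reflectance(1.54, 1.54, c(0, 30, 89)), rep(0, 3))
  # normal incidence: ((n1 - n2) / (n1 + n2))^2
  expect_equal(fresnel_reflectance(1.54, 1.0, 0), (0.54 / 2.54)^2,
               tolerance = 1e-12)
  # beyond the critical angle asin(1/1.54) ~ 40.5 deg: total internal reflection
  expect_equal(fresnel_reflectance(1.54, 1.0, 50), 1.0)
  expect_lt(fresnel_reflectance(1.54, 1.0, 40), 1.0)
  # reflectance is a probability everywhere
  r <- fresnel_reflectance(1.0, 1.54, seq(0, 90, by = 5))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("white Monte Carlo is reproducible and stream-separated", {
  props <- optical_properties(0, 10, 0, 1.54)
  geom <- slab_geometry(2)
  a <- simulate_white_dtof(props, geom, 2e4, 10, 6000, rng_stream(11, 3))
  b <- simulate_white_dtof(props, geom, 2e4, 10, 6000, rng_stream(11, 3))
  expect_identical(a$values, b$values)
  d <- simulate_white_dtof(props, geom, 2e4, 10, 6000, rng_stream(11, 4))
  expect_false(identical(a$values, d$values))
})

test_that("detected weight scales linearly with launched photons", {
  props <- optical_properties(0, 10, 0, 1.54)
  geom <- slab_geometry(2)
  a <- simulate_white_dtof(props, geom, 1e5, 10, 6000, rng_stream(21, 0))
  b <- simulate_white_dtof(props, geom, 2e5, 10, 6000, rng_stream(21, 1))
  na <- a$meta$detected
  nb <- b$meta$detected
  ratio <- nb / na
  se <- ratio * sqrt(1 / na + 1 / nb)
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("energy bookkeeping closes exactly, including side losses", {
  props <- optical_properties(0, 10, 0, 1.54)
  for (lat in c(Inf, 4)) {
    geom <- slab_geometry(2, lateral_radius_cm = lat)
    w <- simulate_white_dtof(props, geom, 5e4, 10, 6000, rng_stream(31))
    m <- w$meta
    total <- m$detected + m$transmitted_other + m$reflected +
      m$side_loss + m$residual
    expect_equal(total, 5e4)
    if (is.finite(lat)) expect_gt(m$side_loss, 0) else
      expect_equal(m$side_loss, 0)
  }
})

test_that("no detected weight arrives before the ballistic flight time", {
  props <- optical_properties(0, 10, 0, 1.54)
  w <- simulate_white_dtof(props, slab_geometry(2), 1e5, 10, 6000,
                           rng_stream(41))
  t_ballistic <- 2 * 1.54 / c0_cm_per_ps() # 102.7 ps
  early <- dtof_times(w) < t_ballistic - 5
  expect_true(all(w$values[early] == 0))
})

test_that("absorbing simulation equals analytic scaling of the white run", {
  props0 <- optical_properties(0, 10, 0, 1.54)
  geom <- slab_geometry(2)
  s <- rng_stream(51)
  w <- simulate_white_dtof(props0, geom, 5e4, 10, 6000, s)
  for (mua in c(0.08, 0.5)) {
    a <- simulate_absorbing_dtof(optical_properties(mua, 10, 0, 1.54),
                                 geom, 5e4, 10, 6000, s)
    ref <- apply_absorption(w, mua)
    nz <- ref$values > 0
    expect_lt(max(abs(a$values[nz] / ref$values[nz] - 1)), 1e-12)
    expect_true(all(a$values[!nz] == 0))
  }
  # monotone attenuation: stronger absorption never increases a bin
  a1 <- simulate_absorbing_dtof(optical_properties(0.1, 10, 0, 1.54),
                                geom, 5e4, 10, 6000, s)
  a5 <- simulate_absorbing_dtof(optical_properties(0.5, 10, 0, 1.54),
                                geom, 5e4, 10, 6000, s)
  expect_true(all(a5$values <= a1$values))
  # continuity at zero absorption
  a0 <- simulate_absorbing_dtof(optical_properties(1e-9, 10, 0, 1.54),
                                geom, 5e4, 10, 6000, s)
  expect_equal(a0$values, w$values, tolerance = 1e-6)
  # white contract rejects non-zero absorption
  expect_error(simulate_white_dtof(optical_properties(0.1, 10), geom,
                                   1e3, 10, 6000, s), "mu_a = 0")
})

test_that("diffusion solution factorizes absorption exactly", {
  props0 <- optical_properties(0, 10, 0, 1.54)
  props <- optical_properties(0.05, 10, 0, 1.54)
  tt <- seq(55, 5995, by = 10)
  d0 <- diffusion_slab_dtof(props0, slab_geometry(2), tt)
  da <- diffusion_slab_dtof(props, slab_geometry(2), tt)
  v <- c0_cm_per_ps() / 1.54
  expect_equal(da$values, d0$values * exp(-0.05 * v * tt), tolerance = 1e-12)
})

test_that("time-integrated diffusion transmittance matches the CW closed form", {
  props <- optical_properties(0, 10, 0, 1.54)
  geom <- slab_geometry(2)
  # fine axis, long tail, so quadrature truncation stays below 0.1%
  d <- diffusion_slab_dtof(props, geom, seq(1, 29999, by = 2))
  expect_equal(dtof_integral(d), cw_slab_transmittance(props, geom),
               tolerance = 1e-3)
})

test_that("mean time of flight grows with reduced scattering", {
  geom <- slab_geometry(2)
  tt <- seq(5, 5995, by = 10)
  mt <- function(musp) {
    d <- diffusion_slab_dtof(optical_properties(0, musp, 0, 1.54), geom, tt)
    sum(tt * d$values) / sum(d$values)
  }
  expect_gt(mt(10), mt(9))
})

test_that("non-diffusive inputs warn but still evaluate", {
  expect_warning(
    d <- diffusion_slab_dtof(optical_properties(0, 1, 0, 1.54),
                             slab_geometry(2), seq(5, 5995, by = 10)),
    "diffusive")
  expect_false(d$meta$diffusive)
})

test_that("similarity relation: anisotropic and isotropic runs agree on mu_sp", {
  # g = 0.9 with mu_s = mu_sp / (1 - g) vs g = 0 with mu_s = mu_sp
  geom <- slab_geometry(2)
  iso <- simulate_white_dtof(optical_properties(0, 10, 0, 1.54), geom,
                             4e5, 10, 6000, rng_stream(61, 0))
  ani <- simulate_white_dtof(optical_properties(0, 10, 0.9, 1.54), geom,
                             4e5, 10, 6000, rng_stream(61, 1))
  ri <- rebin_dtof(iso, 40)
  ra <- rebin_dtof(ani, 40)
  sel <- ri$values >= 4000 & ra$values >= 4000
  expect_gte(sum(sel), 4)
  a <- ri$values / sum(ri$values)
  b <- ra$values / sum(ra$values)
  expect_lt(max(abs(a[sel] / b[sel] - 1)), 0.05)
})

test_that("warning flags a histogram whose peak spills into the last bins", {
  props <- optical_properties(0, 10, 0, 1.54)
  # peak of the full distribution sits near 900 ps; a 600-ps axis truncates it
  expect_warning(
    w <- simulate_white_dtof(props, slab_geometry(2), 1e5, 10, 600,
                             rng_stream(71)),
    "t_max")
  expect_true(w$meta$tail_truncated)
  full <- simulate_white_dtof(props, slab_geometry(2), 2e4, 10, 6000,
                              rng_stream(71))
  expect_false(full$meta$tail_truncated)
})
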