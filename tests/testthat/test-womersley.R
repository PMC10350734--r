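test_that("complex Bessel evaluation matches base besselJ on the real axis", {
  z <- c(0.1, 1.7, 4.14, 9.3, 18)
  expect_lt(max(Mod(besselJ_complex(0L, z) - besselJ(z, 0))), 1e-13)
  expect_lt(max(Mod(besselJ_complex(1L, z) - besselJ(z, 1))), 1e-13)
})

test_that("Womersley number follows its defining scaling", {
  expect_equal(womersley_number(3e-3, 0, 3.3e-6), 0)
  a <- womersley_number(3e-3, 2 * pi, 3.3e-6)
  expect_equal(a, sqrt((3e-3)^2 * 2 * pi / 3.3e-6), tolerance = 1e-12)
  expect_equal(a, 4.14, tolerance = 1e-2)
  expect_equal(womersley_number(6e-3, 2 * pi, 3.3e-6), 2 * a, tolerance = 1e-12)
  expect_error(womersley_number(-1e-3, 1, 3.3e-6), class = "graftflow_domain_error")
  expect_error(womersley_number(3e-3, 1, 0), class = "graftflow_domain_error")
})

test_that("tube flow ratio matches quadrature of the closed-form profile", {
  R <- 3e-3
  # steady limit: exact Poiseuille ratio
  expect_identical(womersley_tube_ratio(R, 0), complex(real = pi * R^2 / 2))
  for (alpha in c(0.1, 1, 4.14, 10)) {
    ratio <- womersley_tube_ratio(R, alpha)
    oracle <- tube_flow_by_quadrature(alpha, R)
    expect_lt(Mod(ratio - oracle) / Mod(oracle), 1e-6)
  }
})

test_that("channel flow ratio matches quadrature of the cosh profile", {
  a <- 3e-3
  expect_identical(womersley_channel_ratio(a, 0), complex(real = 4 * a / 3))
  for (alpha in c(0.1, 1, 4.14, 10)) {
    ratio <- womersley_channel_ratio(a, alpha)
    oracle <- channel_flow_by_quadrature(alpha, a)
    expect_lt(Mod(ratio - oracle) / Mod(oracle), 1e-6)
  }
})

test_that("flow conversion reduces to Poiseuille in the steady limit and is linear", {
  R <- 3e-3
  tt <- seq(0, 1, length.out = 65)[1:64]
  const <- velocity_waveform(tt, rep(0.5, 64), 1)
  Q <- flow_from_centerline(const, R, blood())
  expect_equal(Q$Q, rep(pi * R^2 * 0.5 / 2, 64), tolerance = 1e-12)
  zero <- velocity_waveform(tt, rep(0, 64), 1)
  expect_true(all(flow_from_centerline(zero, R, blood())$Q == 0))
})

test_that("inlet profile satisfies no-slip and reproduces the flow by quadrature", {
  R <- 3e-3
  fl <- blood()
  tt <- seq(0, 1, length.out = 129)[1:128]
  u <- synth_duplex_waveform(0.8, 0.3, T = 1, n = 128)
  Q <- flow_from_centerline(u, R, fl)
  rr <- seq(-R, R, length.out = 801)
  teval <- c(0.1, 0.3, 0.62)
  prof <- inlet_profile(Q, R, fl, teval, rr)
  expect_true(all(prof[c(1, 801), ] == 0))
  # quadrature of the profile recovers the band-limited flow
  Qbl <- harmonic_eval(fourier_decompose(Q, 10), teval)
  for (k in seq_along(teval)) {
    up <- prof[, k] * abs(rr)
    Qq <- pi * sum(diff(rr) * (up[-1] + up[-length(rr)]) / 2)
    expect_lt(abs(Qq - Qbl[k]) / max(abs(Qbl)), 1e-4)  # test-quadrature limited
  }
  expect_error(inlet_profile(Q, R, fl, 0, 1.1 * R), class = "graftflow_range_error")
})

test_that("band-limited centerline round trip through flow conversion", {
  R <- 3e-3
  fl <- blood()
  u <- synth_duplex_waveform(0.9, 0.3, T = 0.9, n = 256)
  Q <- flow_from_centerline(u, R, fl, N = 10)
  ubl <- harmonic_eval(fourier_decompose(u, 10), u$t)
  back <- inlet_profile(Q, R, fl, u$t, 0, N = 10)
  expect_lt(max(abs(as.numeric(back) - ubl)) / max(abs(ubl)), 1e-6)
})

test_that("channel inlet profile integrates back to the per-depth flow", {
  a <- 3e-3
  fl <- blood()
  tt <- seq(0, 1, length.out = 129)[1:128]
  q <- flow_waveform(tt, 1e-3 * (1 + 0.8 * cos(2 * pi * tt) + 0.3 * sin(4 * pi * tt)), 1)
  yy <- seq(-a, a, length.out = 1201)
  teval <- c(0.05, 0.4, 0.77)
  prof <- inlet_profile_channel(q, a, fl, teval, yy)
  expect_true(all(prof[c(1, 1201), ] == 0))
  qev <- harmonic_eval(fourier_decompose(q, 10), teval)
  for (k in seq_along(teval)) {
    qq <- sum(diff(yy) * (prof[-1, k] + prof[-1201, k]) / 2)
    expect_lt(abs(qq - qev[k]) / max(abs(qev)), 1e-5)  # test-quadrature limited
  }
})

test_that("oscillatory profiles show annular overshoot and plug-like core at high alpha", {
  a <- 3e-3
  om <- 2 * pi
  alpha <- 10
  nu <- a^2 * om / alpha^2
  fl <- fluid_properties(rho = 1060, mu = 1060 * nu)
  tt <- seq(0, 1, length.out = 65)[1:64]
  q <- flow_waveform(tt, 1e-3 * cos(om * tt), 1)
  yy <- seq(-a, a, length.out = 801)
  prof <- inlet_profile_channel(q, a, fl, seq(0, 0.95, by = 0.05), yy)
  # at alpha = 10 the peak envelope sits off-center (annular overshoot)
  env <- apply(abs(prof), 1, max)
  expect_gt(max(env[abs(yy) > 0.5 * a]), max(env[abs(yy) < 0.1 * a]))
})

test_that("hematocrit-viscosity relation is monotone with a plasma limit", {
  expect_gt(viscosity_from_hematocrit(0.43), viscosity_from_hematocrit(0.30))
  expect_gt(viscosity_from_hematocrit(0.36), viscosity_from_hematocrit(0.35))
  expect_equal(viscosity_from_hematocrit(1e-9), 1.2e-3, tolerance = 1e-6)
  expect_error(viscosity_from_hematocrit(1.2), class = "graftflow_domain_error")
  expect_error(viscosity_from_hematocrit(0), class = "graftflow_domain_error")
  # default bypass without hematocrit
  expect_equal(fluid_properties()$mu, 3.5e-3)
  expect_equal(fluid_properties(hematocrit = 0.43)$mu,
               viscosity_from_hematocrit(0.43))
})
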