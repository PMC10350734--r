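test_that("steady and zero-flow limits of the RCR response are exact", {
  tt <- seq(0, 1, length.out = 201)[1:200]
  p <- rcr_parameters(Rp = 0.09 * 1.6e9, C = 1 / (3 * 0.91 * 1.6e9), Rd = 0.91 * 1.6e9)
  Q <- flow_waveform(tt, rep(5e-6, 200), 1)
  r <- rcr_pressure(Q, p)
  expect_equal(r$P, rep(8000, 200), tolerance = 1e-9)
  p2 <- rcr_parameters(1e8, 1e-9, 1e9, P_ref = 1200)
  Q0 <- flow_waveform(tt, rep(0, 200), 1)
  expect_equal(rcr_pressure(Q0, p2)$P, rep(1200, 200), tolerance = 1e-9)
})

test_that("sinusoidal RCR response matches the closed-form phasor solution", {
  n <- 2048L
  tt <- seq(0, 1, length.out = n + 1L)[1:n]
  om <- 2 * pi
  p <- rcr_parameters(1.2e8, 2e-9, 1.2e9, P_ref = 500)
  amp <- 2e-6
  Q <- flow_waveform(tt, 5e-6 + amp * sin(om * tt), 1)
  r <- rcr_pressure(Q, p, tol = 1e-12)
  Z <- rcr_impedance(om, p)
  Pex <- p$P_ref + mean(Q$Q) * (p$Rp + p$Rd) + Re(Z * (-1i * amp) * exp(1i * om * tt))
  expect_lt(rel_l2 <- sqrt(sum((r$P - Pex)^2) / sum(Pex^2)), 1e-6)
  expect_equal(mean(r$P) - p$P_ref, mean(Q$Q) * (p$Rp + p$Rd), tolerance = 1e-8)
})

test_that("impedance has the DC, characteristic-frequency and high-frequency limits", {
  p <- rcr_parameters(2e8, 1.5e-9, 1.8e9)
  expect_identical(Re(rcr_impedance(0, p)), p$Rp + p$Rd)
  expect_identical(Im(rcr_impedance(0, p)), 0)
  wc <- 1 / (p$Rd * p$C)
  expect_equal(rcr_impedance(wc, p), complex(real = p$Rp + p$Rd / 2, imaginary = -p$Rd / 2),
               tolerance = 1e-12)
  expect_equal(Mod(rcr_impedance(1e6 * wc, p)), p$Rp, tolerance = 1e-6)
  om <- 10^seq(-2, 4, by = 0.25)
  expect_true(all(diff(Mod(rcr_impedance(om, p))) <= 1e-12))
})

test_that("RCR response is linear in the flow", {
  tt <- seq(0, 0.8, length.out = 257)[1:256]
  p <- rcr_parameters(1.5e8, 1.2e-9, 1.4e9, P_ref = 0)
  Q1 <- flow_waveform(tt, 4e-6 + 2e-6 * sin(2 * pi * tt / 0.8) + 1e-6 * cos(4 * pi * tt / 0.8), 0.8)
  Q2 <- flow_waveform(tt, 2 * Q1$Q, 0.8)
  r1 <- rcr_pressure(Q1, p, tol = 1e-11)
  r2 <- rcr_pressure(Q2, p, tol = 1e-11)
  expect_equal(r2$P - p$P_ref, 2 * (r1$P - p$P_ref), tolerance = 1e-7)
})

test_that("delivered power respects the proximal-resistance floor", {
  tt <- seq(0, 1, length.out = 257)[1:256]
  p <- rcr_parameters(1.5e8, 1.2e-9, 1.4e9, P_ref = 0)
  for (seed in 1:4) {
    w <- synth_duplex_waveform(0.8, 0.3, noise_sd = 0.02, seed = seed, n = 256)
    Q <- flow_from_centerline(w, 3e-3, blood())
    r <- rcr_pressure(Q, p)
    expect_gte(mean(Q$Q * (r$P - p$P_ref)), mean(Q$Q)^2 * p$Rp)
  }
})

test_that("tuning recovers generating RCR parameters from synthetic outlet flows", {
  geom <- default_geometry()
  fl <- fluid_properties(hematocrit = 0.43)
  u <- synth_duplex_waveform(0.9, 0.3, T = 1, n = 200)
  Qin <- flow_from_centerline(u, 4e-3, fl)
  true <- list(SFA = rcr_parameters(1.4e8, 1.9e-9, 1.5e9),
               DFA = rcr_parameters(2.2e8, 1.3e-9, 2.3e9))
  depth <- pi * 4e-3 / 2
  bR <- c(SFA = graftflow:::lubrication_resistance(geom, "SFA", fl$mu, depth),
          DFA = graftflow:::lubrication_resistance(geom, "DFA", fl$mu, depth))
  sim <- surrogate_split(Qin, true, bR)
  targets <- lapply(c("SFA", "DFA"), function(v)
    tuning_target(v, sim$flows[[v]],
                  mean_pressure_target = mean(sim$flows[[v]]$Q) * (true[[v]]$Rp + true[[v]]$Rd)))
  tuned <- tune_rcr(targets, Qin, geom, fl, depth)
  for (v in c("SFA", "DFA")) {
    rt_true <- true[[v]]$Rp + true[[v]]$Rd
    expect_lt(abs((tuned[[v]]$Rp + tuned[[v]]$Rd) - rt_true) / rt_true, 0.05)
  }
  sim2 <- surrogate_split(Qin, tuned, bR)
  split_true <- mean(sim$flows$SFA$Q) / mean(Qin$Q)
  split_tuned <- mean(sim2$flows$SFA$Q) / mean(Qin$Q)
  expect_lt(abs(split_tuned - split_true), 0.01)
})

test_that("symmetric targets on a symmetric bifurcation tune to symmetric parameters", {
  geom <- symmetric_geometry()
  fl <- blood()
  u <- synth_duplex_waveform(0.8, 0.3, T = 1, n = 128)
  Qin <- flow_from_centerline(u, 4e-3, fl)
  half <- flow_waveform(Qin$t, Qin$Q / 2, 1)
  targets <- list(tuning_target("A", half), tuning_target("B", half))
  tuned <- tune_rcr(targets, Qin, geom, fl, depth = pi * 4e-3 / 2, maxit = 200L)
  expect_equal(tuned$A$Rp + tuned$A$Rd, tuned$B$Rp + tuned$B$Rd, tolerance = 0.02)
})

test_that("targets exceeding the inlet mean flow are rejected", {
  geom <- default_geometry()
  fl <- blood()
  u <- synth_duplex_waveform(0.5, 0.3, T = 1, n = 128)
  Qin <- flow_from_centerline(u, 4e-3, fl)
  big <- flow_waveform(Qin$t, 2 * abs(Qin$Q) + 1e-6, 1)
  targets <- list(tuning_target("SFA", big), tuning_target("DFA", big))
  expect_error(tune_rcr(targets, Qin, geom, fl, depth = pi * 4e-3 / 2),
               class = "graftflow_validation_error")
})
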