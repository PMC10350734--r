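test_that("steady channel flow reproduces Poiseuille profile and pressure drop", {
  fl <- blood()
  a <- 3e-3; L <- 0.03
  m <- mesh_channel(L, a, a / 8)
  depth <- 1e-2
  cfg <- solver_config(dt = 1e-3, fluid = fl, depth = depth, convection = FALSE)
  qpd <- 2e-3 * 2 * a
  st <- solve_steady(m, qpd * depth, list(outlet = list(type = "pressure", P = 0)), cfg)
  mid <- which(abs(m$nodes[, 1] - L / 2) < 1e-9)
  yy <- m$nodes[mid, 2]
  uex <- 3 * (qpd / (2 * a)) / 2 * (1 - (yy / a)^2)
  expect_lt(rel_l2 <- sqrt(sum((st$ux[mid] - uex)^2) / sum(uex^2)), 0.02)
  expect_lt(max(abs(st$uy[mid])) / max(uex), 0.01)
  dp_ex <- 3 * fl$mu * qpd * L / (2 * a^3)
  expect_equal(st$inlet_pressure - st$outlet_pressures$outlet, dp_ex, tolerance = 0.02)
  # discrete mass conservation is exact
  expect_equal(st$outlet_flows$outlet, qpd * depth * (1 - 1 / (2 * 8)^2 / 3),
               tolerance = 2e-3)
})

test_that("zero inflow from rest stays identically zero with outlet pressures at P_ref", {
  fl <- blood()
  m <- mesh_channel(0.02, 3e-3, 3e-3 / 4)
  tt <- seq(0, 1, length.out = 41)[1:40]
  Q0 <- flow_waveform(tt, rep(0, 40), 1)
  cfg <- solver_config(dt = 5e-3, fluid = fl, depth = 1e-2, convection = FALSE,
                       cycles_max = 2, periodicity_tol = 0.5, ramp = FALSE)
  h <- solve_pulsatile(m, Q0, list(outlet = rcr_parameters(1e8, 1e-9, 1e9, P_ref = 700)), cfg)
  # zero up to direct-solver roundoff at the P_ref pressure scale
  expect_lt(max(abs(h$ux)), 1e-9)
  expect_lt(max(abs(h$uy)), 1e-9)
  expect_equal(as.numeric(h$pressure[, 10]), rep(700, nrow(m$nodes)), tolerance = 1e-6)
})

test_that("check_periodicity returns the first cycle below tolerance", {
  base <- sin(2 * pi * seq(0, 1, length.out = 65)[1:64])
  mk <- function(devs) do.call(rbind, lapply(devs, function(d) base * (1 + d)))
  # identical consecutive cycles converge at the second
  expect_identical(check_periodicity(list(o = mk(c(0, 0))), 0.01), 2L)
  # 10% then 0.1% change with tol 1%: converged at the third
  expect_identical(check_periodicity(list(o = mk(c(0, 0.10, 0.101 - 0.001))), 0.01), 3L)
  # geometric decay: oracle computes the first compliant cycle independently
  devs <- cumsum(c(0, 0.08 * 0.5^(0:4)))
  M <- mk(devs)
  changes <- vapply(2:nrow(M), function(k) {
    sqrt(sum((M[k, ] - M[k - 1, ])^2)) / sqrt(sum(M[k - 1, ]^2))
  }, 0)
  expected <- which(changes < 0.01)[1] + 1L
  expect_identical(check_periodicity(list(o = M), 0.01), expected)
  # both outlets must comply
  expect_identical(check_periodicity(list(a = mk(c(0, 0, 0)), b = mk(c(0, 0.5, 0.5))), 0.01), 3L)
  expect_true(is.na(check_periodicity(list(o = mk(c(0, 0.5, 1.0))), 0.01)))
})

test_that("Stokes-regime response is linear in the inflow", {
  fl <- blood()
  g <- symmetric_geometry()
  m <- mesh_bifurcation(g, 0.75e-3)
  cfg <- solver_config(dt = 1e-3, fluid = fl, depth = 1e-2, convection = FALSE)
  Q1 <- 1e-9  # Reynolds << 1
  s1 <- solve_steady(m, Q1, list(A = list(type = "pressure", P = 0),
                                 B = list(type = "pressure", P = 0)), cfg)
  s3 <- solve_steady(m, 3 * Q1, list(A = list(type = "pressure", P = 0),
                                     B = list(type = "pressure", P = 0)), cfg)
  expect_equal(s3$ux, 3 * s1$ux, tolerance = 1e-9)
  expect_equal(s3$pressure, 3 * s1$pressure, tolerance = 1e-9)
})

test_that("symmetric geometry and outlets give a mirror-symmetric field", {
  fl <- blood()
  g <- symmetric_geometry()
  m <- mesh_bifurcation(g, 0.75e-3)
  cfg <- solver_config(dt = 1e-3, fluid = fl, depth = 1e-2, convection = FALSE)
  st <- solve_steady(m, 2e-8, list(A = list(type = "pressure", P = 0),
                                   B = list(type = "pressure", P = 0)), cfg)
  expect_equal(st$outlet_flows$outlet_A, st$outlet_flows$outlet_B, tolerance = 0.01)
  # match nodes to their mirror images and compare (ux even, uy odd);
  # residual asymmetry is discretization-level (the quad-split diagonals
  # are not mirror images), so the tolerance is a few percent
  key <- paste(round(m$nodes[, 1], 9), round(m$nodes[, 2], 9))
  mirror <- match(paste(round(m$nodes[, 1], 9), round(-m$nodes[, 2], 9)), key)
  expect_true(all(!is.na(mirror)))
  scale <- max(abs(st$ux))
  expect_lt(max(abs(st$ux - st$ux[mirror])) / scale, 0.03)
  expect_lt(max(abs(st$uy + st$uy[mirror])) / scale, 0.03)
})

test_that("pulsatile flow through a post-stenotic expansion separates during deceleration", {
  fl <- blood()
  a <- 3e-3; L <- 0.04
  g <- bifurcation_geometry(list(
    vessel_spec("CFA", a, L, 0), vessel_spec("A", 2e-3, 0.01, 0.3),
    vessel_spec("B", 2e-3, 0.01, -0.3)),
    lesions = list(lesion_spec("CFA", 0.012, 0.012, "stenosis", 0.5)))
  afun <- function(s) halfwidth(g, "CFA", s)
  m <- mesh_channel(L, afun, a / 5)
  depth <- 1e-2
  tt <- seq(0, 1, length.out = 65)[1:64]
  # triphasic-like inflow, peak mean velocity ~0.25 m/s
  u <- synth_duplex_waveform(0.25, 0.25, T = 1, n = 64)
  Q <- flow_waveform(tt, u$u * 2 * a * depth, 1)
  cfg <- solver_config(dt = 1 / 200, fluid = fl, depth = depth, convection = TRUE,
                       cycles_max = 4, periodicity_tol = 0.05)
  h <- solve_pulsatile(m, Q, list(outlet = rcr_parameters(5e7, 3e-9, 5e8)), cfg)
  # per-step mass balance
  expect_lt(h$mass_residual, 1e-3)
  ws <- wall_shear(h, m, fl$mu)
  # deceleration phase: after the systolic peak but before flow reversal
  Qin <- h$inlet_flow$Q
  kpeak <- which.max(Qin)
  kdec <- which(seq_along(Qin) > kpeak & Qin > 0.3 * max(Qin))
  kdec <- kdec[kdec < min(which(seq_along(Qin) > kpeak & Qin < 0))]
  post <- ws$wall$s > 0.019 & ws$wall$s < 0.035  # expansion zone
  expect_true(any(ws$tau[post, kdec] < 0))
  # upstream of the stenosis the flow stays attached during early
  # deceleration (late deceleration can reverse near-wall flow even in a
  # straight channel - genuine pulsatile physics, not separation)
  kearly <- kdec[Qin[kdec] > 0.65 * max(Qin)]
  pre <- ws$wall$s > 0.002 & ws$wall$s < 0.005
  expect_true(all(ws$tau[pre, kearly] > 0))
})
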