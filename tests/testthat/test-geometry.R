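test_that("lesion severity maps to the configured local area reduction", {
  # identity: zero-severity lesion leaves the width untouched
  g0 <- default_geometry(lesions = list(lesion_spec("SFA", 0.02, 0.01, "stenosis", 0)))
  s <- seq(0, 0.06, length.out = 301)
  expect_equal(halfwidth(g0, "SFA", s), rep(3e-3, 301))
  # 50%-area stenosis halves the local cross-section at its center
  g <- default_geometry(lesions = list(lesion_spec("CFA", 0.02, 0.015, "stenosis", 0.5)))
  expect_equal(halfwidth(g, "CFA", 0.02), 4e-3 * 0.5, tolerance = 1e-12)
  # widening increases it
  gw <- default_geometry(lesions = list(lesion_spec("CFA", 0.02, 0.015, "widening", 0.3)))
  expect_equal(halfwidth(gw, "CFA", 0.02), 4e-3 * 1.3, tolerance = 1e-12)
  # C1 profile: width returns to nominal outside the support
  expect_equal(halfwidth(g, "CFA", c(0.012, 0.028)), c(4e-3, 4e-3))
  # severity reproduced to high relative accuracy at lesion center
  sev <- 1 - halfwidth(g, "CFA", 0.02) / 4e-3
  expect_lt(abs(sev - 0.5), 1e-6)
})

test_that("overlapping or out-of-range lesions are rejected with informative errors", {
  err <- tryCatch(default_geometry(lesions = list(
    lesion_spec("SFA", 0.02, 0.01, "stenosis", 0.4),
    lesion_spec("SFA", 0.024, 0.01, "stenosis", 0.3))), condition = identity)
  expect_s3_class(err, "graftflow_validation_error")
  expect_match(conditionMessage(err), "overlap")
  expect_error(default_geometry(lesions = list(
    lesion_spec("SFA", 0.059, 0.01, "stenosis", 0.4))),
    class = "graftflow_range_error")
  expect_error(lesion_spec("SFA", 0.02, 0.01, "stenosis", 1.0),
               class = "graftflow_validation_error")
})

test_that("virtual angioplasty restores nominal caliber, is local and idempotent", {
  g <- default_geometry(lesions = list(lesion_spec("SFA", 0.012, 0.012, "stenosis", 0.5)))
  s <- seq(0, 0.06, length.out = 601)
  # no lesion in the interval: identity
  g_id <- virtual_angioplasty(g, "DFA", c(0.01, 0.03))
  expect_equal(halfwidth(g_id, "DFA", seq(0, 0.04, length.out = 101)),
               halfwidth(g, "DFA", seq(0, 0.04, length.out = 101)))
  # lesion fully inside the interval: nominal radius throughout
  g2 <- virtual_angioplasty(g, "SFA", c(0.004, 0.02))
  expect_equal(halfwidth(g2, "SFA", seq(0.004, 0.02, length.out = 101)),
               rep(3e-3, 101))
  # outside the interval unchanged
  out <- s < 0.004 | s > 0.02
  expect_equal(halfwidth(g2, "SFA", s[out]), halfwidth(g, "SFA", s[out]))
  # input not mutated
  expect_equal(halfwidth(g, "SFA", 0.012), 1.5e-3)
  # idempotent
  g3 <- virtual_angioplasty(g2, "SFA", c(0.004, 0.02))
  expect_equal(halfwidth(g3, "SFA", s), halfwidth(g2, "SFA", s))
  # interval outside vessel
  expect_error(virtual_angioplasty(g, "SFA", c(0.05, 0.08)),
               class = "graftflow_range_error")
})

test_that("angioplasty strictly reduces the Stokes pressure drop of a stenosed channel", {
  fl <- blood()
  a0 <- 3e-3; L <- 0.03
  g <- bifurcation_geometry(list(
    vessel_spec("CFA", a0, L, 0), vessel_spec("A", 2e-3, 0.01, 0.3),
    vessel_spec("B", 2e-3, 0.01, -0.3)),
    lesions = list(lesion_spec("CFA", 0.015, 0.012, "stenosis", 0.5)))
  g_post <- virtual_angioplasty(g, "CFA", c(0.007, 0.023))
  afun_pre <- function(s) halfwidth(g, "CFA", s)
  afun_post <- function(s) halfwidth(g_post, "CFA", s)
  q <- 2e-3 * 2 * a0 * 1e-3  # deep Stokes regime
  dp_pre <- steady_dp(afun_pre, L, a0, q, fl, a0 / 10)
  dp_post <- steady_dp(afun_post, L, a0, q, fl, a0 / 10)
  expect_lt(dp_post, dp_pre)
  # lubrication oracle agrees on direction and approximate magnitude
  lub_pre <- lubrication_dp(afun_pre, L, q, fl$mu)
  lub_post <- lubrication_dp(afun_post, L, q, fl$mu)
  expect_lt(lub_post, lub_pre)
  expect_equal(dp_pre / dp_post, lub_pre / lub_post, tolerance = 0.25)
})

test_that("meshing produces a tagged, watertight, positively oriented disk", {
  g <- default_geometry(lesions = list(lesion_spec("SFA", 0.012, 0.012, "stenosis", 0.5)))
  m <- mesh_bifurcation(g, 1e-3)
  expect_setequal(unique(m$boundary$tag), c("inlet", "wall", "outlet_SFA", "outlet_DFA"))
  # all cells positively oriented
  expect_true(all(graftflow:::tri_signed_area(m$nodes, m$tri) > 0))
  # Euler characteristic of a disk
  ed <- unique(t(apply(rbind(m$tri[, 1:2], m$tri[, 2:3], m$tri[, c(3, 1)]), 1, sort)))
  expect_identical(nrow(m$nodes) - nrow(ed) + nrow(m$tri), 1L)
  # boundary tags partition the boundary edge set
  expect_identical(anyDuplicated(m$boundary[, c("a", "b")]), 0L)
  expect_gt(m$min_angle_deg, 10)
})

test_that("straight-tube mesh has consistent topology and arc-length convergence", {
  a <- 3e-3; L <- 0.024
  m1 <- mesh_channel(L, a, a / 8)
  expect_setequal(unique(m1$boundary$tag), c("inlet", "wall", "outlet"))
  ed <- unique(t(apply(rbind(m1$tri[, 1:2], m1$tri[, 2:3], m1$tri[, c(3, 1)]), 1, sort)))
  expect_identical(nrow(m1$nodes) - nrow(ed) + nrow(m1$tri), 1L)
  m2 <- mesh_channel(L, a, a / 16)
  # 2x refinement at least quadruples the cell count
  expect_gte(nrow(m2$tri), 4 * nrow(m1$tri))
  # wall arc length: both resolutions agree with the analytic perimeter piece
  for (m in list(m1, m2)) {
    upper <- m$wall[m$wall$side == "upper", ]
    expect_equal(max(upper$arc), L, tolerance = 1e-9)
    expect_equal(sum(upper$w_arc), L, tolerance = 1e-9)
  }
  expect_error(mesh_channel(L, a, 2 * a), class = "graftflow_validation_error")
})

test_that("a symmetric bifurcation meshes mirror-symmetrically", {
  g <- symmetric_geometry()
  m <- mesh_bifurcation(g, 0.5e-3)
  # reflect nodes about y = 0 and match against the original set
  key <- function(P) paste(round(P[, 1], 9), round(abs(P[, 2]), 9))
  expect_setequal(key(m$nodes), key(cbind(m$nodes[, 1], -m$nodes[, 2])))
  # inner wall shear stencils of the two daughters mirror each other
  wa <- m$wall[m$wall$vessel == "A" & m$wall$side == "inner", ]
  wb <- m$wall[m$wall$vessel == "B" & m$wall$side == "inner", ]
  expect_equal(wa$d1, wb$d1, tolerance = 1e-9)
  expect_equal(wa$arc, wb$arc, tolerance = 1e-9)
})

test_that("geometry configs from plain lists and degenerate cases are validated", {
  cfg <- fixture_occlusion_config("ci")
  g <- build_geometry(cfg$geometry)
  expect_s3_class(g, "bifurcation_geometry")
  expect_identical(g$endograft$vessel, "SFA")
  expect_true("SFA_proximal" %in% names(g$wall_segments))
  # resolution coarser than the narrowest lumen is refused
  expect_error(mesh_bifurcation(g, 2e-3), class = "graftflow_validation_error")
  # near-total occlusion is refused as degenerate for meshing
  g2 <- default_geometry(lesions = list(lesion_spec("SFA", 0.02, 0.01, "stenosis", 0.97)))
  err <- tryCatch(mesh_bifurcation(g2, 0.5e-3), condition = identity)
  expect_s3_class(err, "graftflow_validation_error")
  expect_match(conditionMessage(err), "SFA")
})
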