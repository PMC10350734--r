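# Structured multiblock triangulation of the planar bifurcation: one mapped
# block per vessel, conforming at the junction plane, quads split into
# triangles. Wall nodes carry arc-length coordinates and the sampling
# stencil used later for wall shear recovery.

# Build one mapped block. centers: ns x 2, crossdir: ns x 2 (unit), hw: ns,
# eta: m in [-1, 1]. Returns ns x m index grid and node coordinates.
block_nodes <- function(centers, crossdir, hw, eta) {
  ns <- nrow(centers); m <- length(eta)
  X <- matrix(0, ns * m, 2)
  for (i in seq_len(ns)) {
    rows <- (i - 1L) * m + seq_len(m)
    X[rows, 1L] <- centers[i, 1L] + eta * hw[i] * crossdir[i, 1L]
    X[rows, 2L] <- centers[i, 2L] + eta * hw[i] * crossdir[i, 2L]
  }
  X
}

block_tris <- function(idx) {
  ns <- nrow(idx); m <- ncol(idx)
  tri <- matrix(0L, 2L * (ns - 1L) * (m - 1L), 3L)
  k <- 1L
  for (i in seq_len(ns - 1L)) for (j in seq_len(m - 1L)) {
    n00 <- idx[i, j]; n10 <- idx[i + 1L, j]; n01 <- idx[i, j + 1L]; n11 <- idx[i + 1L, j + 1L]
    tri[k, ] <- c(n00, n10, n11); tri[k + 1L, ] <- c(n00, n11, n01)
    k <- k + 2L
  }
  tri
}

tri_signed_area <- function(nodes, tri) {
  x1 <- nodes[tri[, 1L], 1L]; y1 <- nodes[tri[, 1L], 2L]
  x2 <- nodes[tri[, 2L], 1L]; y2 <- nodes[tri[, 2L], 2L]
  x3 <- nodes[tri[, 3L], 1L]; y3 <- nodes[tri[, 3L], 2L]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

tri_min_angle <- function(nodes, tri) {
  p1 <- nodes[tri[, 1L], , drop = FALSE]
  p2 <- nodes[tri[, 2L], , drop = FALSE]
  p3 <- nodes[tri[, 3L], , drop = FALSE]
  e <- function(a, b) sqrt(rowSums((a - b)^2))
  a <- e(p2, p3); b <- e(p1, p3); c <- e(p1, p2)
  ang <- cbind(acos(pmin(pmax((b^2 + c^2 - a^2) / (2 * b * c), -1), 1)),
               acos(pmin(pmax((a^2 + c^2 - b^2) / (2 * a * c), -1), 1)),
               acos(pmin(pmax((a^2 + b^2 - c^2) / (2 * a * b), -1), 1)))
  min(ang) * 180 / pi
}

polyline_arclen <- function(P) {
  d <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Wall-node table for one wall polyline of a structured block.
# idx: ns x m block index grid; wall_j: the eta row index on the wall;
# inward: +1 if interior lies at larger j, -1 if at smaller j.
wall_table <- function(nodes, idx, wall_j, inward, vessel, side, s_axial, wall_id) {
  ns <- nrow(idx)
  wn <- idx[, wall_j]
  P <- nodes[wn, , drop = FALSE]
  arc <- polyline_arclen(P)
  # downstream tangent via central differences
  tx <- numeric(ns); ty <- numeric(ns)
  ip <- pmin(seq_len(ns) + 1L, ns); im <- pmax(seq_len(ns) - 1L, 1L)
  tx <- P[ip, 1L] - P[im, 1L]; ty <- P[ip, 2L] - P[im, 2L]
  tl <- sqrt(tx^2 + ty^2); tx <- tx / tl; ty <- ty / tl
  n1 <- idx[, wall_j + inward]; n2 <- idx[, wall_j + 2L * inward]
  # inward unit normal (perpendicular to tangent, oriented toward n1)
  nx <- -ty; ny <- tx
  d1v <- nodes[n1, , drop = FALSE] - P
  flip <- (d1v[, 1L] * nx + d1v[, 2L] * ny) < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  d1 <- d1v[, 1L] * nx + d1v[, 2L] * ny
  d2v <- nodes[n2, , drop = FALSE] - P
  d2 <- d2v[, 1L] * nx + d2v[, 2L] * ny
  # arc-length weight: half of adjacent segment lengths
  seg <- diff(arc)
  w <- c(seg / 2, 0) + c(0, seg / 2)
  data.frame(node = wn, vessel = vessel, side = side, wall_id = wall_id,
             s = s_axial, arc = arc, tx = tx, ty = ty, nx = nx, ny = ny,
             n1 = n1, n2 = n2, d1 = d1, d2 = d2, w_arc = w,
             stringsAsFactors = FALSE)
}

boundary_edge_df <- function(idx_seq, tag) {
  n <- length(idx_seq)
  data.frame(a = idx_seq[-n], b = idx_seq[-1L], tag = tag, stringsAsFactors = FALSE)
}

outlet_info <- function(nodes, idx_seq, normal) {
  P <- nodes[idx_seq, , drop = FALSE]
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  wts <- c(seg / 2, 0) + c(0, seg / 2)
  list(nodes = idx_seq, normal = normal, wts = wts)
}

finalize_mesh <- function(nodes, tri, boundary, walls, outlets, inlet,
                          resolution, geom = NULL, min_quality = 10) {
  area <- tri_signed_area(nodes, tri)
  bad <- which(area <= 0)
  if (length(bad)) {
    tri[bad, c(2L, 3L)] <- tri[bad, c(3L, 2L)]
    area <- tri_signed_area(nodes, tri)
  }
  if (any(area <= 0))
    stop_graftflow("validation_error", "meshing produced degenerate (zero-area) cells")
  qual <- tri_min_angle(nodes, tri)
  if (qual < min_quality)
    stop_graftflow("validation_error",
                   sprintf("mesh quality too low: min angle %.2f deg < %.1f deg (refine or reduce branch angles)",
                           qual, min_quality))
  structure(list(nodes = nodes, tri = tri, boundary = boundary, wall = walls,
                 outlets = outlets, inlet = inlet, resolution = resolution,
                 geom = geom, min_angle_deg = qual),
            class = "mesh2d")
}

#' @export
print.mesh2d <- function(x, ...) {
  cat(sprintf("<mesh2d> %d nodes, %d triangles, min angle %.1f deg, resolution %.3g mm\n",
              nrow(x$nodes), nrow(x$tri), x$min_angle_deg, x$resolution * 1e3))
  cat(sprintf("  boundary tags: %s\n", paste(unique(x$boundary$tag), collapse = ", ")))
  invisible(x)
}

#' Mesh a bifurcation geometry
#'
#' Triangulates the planar bifurcation with a conforming multiblock mapped
#' grid (one block per vessel, quads split into triangles). Boundary edges
#' are tagged `inlet`, `outlet_<name>` for each daughter, and `wall`; wall
#' nodes carry the vessel-wise axial coordinate `s`, the true wall arc
#' length, and the wall-normal sampling stencil used for shear recovery.
#'
#' @param geom a [bifurcation_geometry()].
#' @param resolution target edge length m; must be positive and smaller
#'   than the smallest local half-width.
#' @param min_quality minimum acceptable triangle angle in degrees.
#' @return object of class `mesh2d`.
#' @export
mesh_bifurcation <- function(geom, resolution, min_quality = 10) {
  assert_that(inherits(geom, "bifurcation_geometry"), "validation_error",
              "geom must be a bifurcation_geometry")
  assert_that(is_scalar_number(resolution) && resolution > 0,
              "validation_error", "resolution must be > 0")
  vs <- geom$vessels
  inlet_v <- vs[[1L]]; up_v <- vs[[2L]]; lo_v <- vs[[3L]]
  assert_that(up_v$angle > lo_v$angle, "validation_error",
              "the second vessel must branch above the third (angle order)")
  # degenerate-geometry guard: resolution below the narrowest local lumen
  for (v in vs) {
    sgrid <- seq(0, v$length, length.out = 257L)
    amin <- min(halfwidth(geom, v$name, sgrid))
    if (amin <= 0)
      stop_graftflow("validation_error",
                     sprintf("vessel '%s' closes completely (non-positive width)", v$name))
    if (resolution >= amin)
      stop_graftflow("validation_error",
                     sprintf("resolution %.3g m must be smaller than the minimum local half-width %.3g m (vessel '%s')",
                             resolution, amin, v$name))
  }
  ncross <- function(v) max(4L, ceiling(2 * v$nominal_radius / resolution)) + 1L
  nlong <- function(v) max(4L, ceiling(v$length / resolution)) + 1L
  m_s <- ncross(up_v); m_d <- ncross(lo_v)
  m_c <- m_s + m_d - 1L
  Lc <- inlet_v$length
  ns_c <- nlong(inlet_v)
  s_c <- seq(0, Lc, length.out = ns_c)
  a_end <- halfwidth(geom, inlet_v$name, Lc)
  a_s0 <- halfwidth(geom, up_v$name, 0)
  a_d0 <- halfwidth(geom, lo_v$name, 0)
  y_apex <- -a_end + 2 * a_end * a_d0 / (a_d0 + a_s0)
  zeta_apex <- y_apex / a_end
  zeta <- c(seq(-1, zeta_apex, length.out = m_d),
            seq(zeta_apex, 1, length.out = m_s)[-1L])
  # inlet-vessel block
  a_c <- halfwidth(geom, inlet_v$name, s_c)
  idx_c <- matrix(seq_len(ns_c * m_c), ns_c, m_c, byrow = TRUE)
  nodes_c <- matrix(0, ns_c * m_c, 2)
  for (i in seq_len(ns_c)) {
    rows <- (i - 1L) * m_c + seq_len(m_c)
    nodes_c[rows, 1L] <- s_c[i]
    nodes_c[rows, 2L] <- zeta * a_c[i]
  }
  nodes <- nodes_c
  n_total <- nrow(nodes)

  daughter_block <- function(v, y_lo, y_hi, shared_first_col) {
    ns_v <- nlong(v); m_v <- length(shared_first_col)
    s_v <- seq(0, v$length, length.out = ns_v)
    h_j <- (y_hi - y_lo) / 2
    P0 <- c(Lc, (y_lo + y_hi) / 2)
    th <- v$angle
    d <- c(cos(th), sin(th))
    Lb <- min(3 * h_j, 0.5 * v$length)
    w <- smoothstep(s_v / Lb)
    phi <- pi / 2 + w * th
    crossdir <- cbind(cos(phi), sin(phi))
    hw <- (1 - w) * h_j + w * halfwidth(geom, v$name, s_v)
    centers <- cbind(P0[1L] + d[1L] * s_v, P0[2L] + d[2L] * s_v)
    eta <- seq(-1, 1, length.out = m_v)
    Xb <- block_nodes(centers, crossdir, hw, eta)
    idx <- matrix(0L, ns_v, m_v)
    idx[1L, ] <- shared_first_col
    new_ids <- n_total + seq_len((ns_v - 1L) * m_v)
    idx[-1L, ] <- matrix(new_ids, ns_v - 1L, m_v, byrow = TRUE)
    nodes <<- rbind(nodes, Xb[-(seq_len(m_v)), , drop = FALSE])
    n_total <<- nrow(nodes)
    list(idx = idx, s = s_v, d = d)
  }

  # upper branch shares rows m_d..m_c of the last inlet column (eta -1 = apex)
  sfa <- daughter_block(up_v, y_apex, a_end, idx_c[ns_c, m_d:m_c])
  # lower branch shares rows 1..m_d (eta +1 = apex)
  dfa <- daughter_block(lo_v, -a_end, y_apex, idx_c[ns_c, 1:m_d])

  tri <- rbind(block_tris(idx_c), block_tris(sfa$idx), block_tris(dfa$idx))

  boundary <- rbind(
    boundary_edge_df(idx_c[1L, ], "inlet"),
    boundary_edge_df(idx_c[, 1L], "wall"),
    boundary_edge_df(idx_c[, m_c], "wall"),
    boundary_edge_df(sfa$idx[, ncol(sfa$idx)], "wall"),
    boundary_edge_df(sfa$idx[, 1L], "wall"),
    boundary_edge_df(dfa$idx[, 1L], "wall"),
    boundary_edge_df(dfa$idx[, ncol(dfa$idx)], "wall"),
    boundary_edge_df(sfa$idx[nrow(sfa$idx), ], paste0("outlet_", up_v$name)),
    boundary_edge_df(dfa$idx[nrow(dfa$idx), ], paste0("outlet_", lo_v$name))
  )

  walls <- rbind(
    wall_table(nodes, idx_c, m_c, -1L, inlet_v$name, "upper", s_c, 1L),
    wall_table(nodes, idx_c, 1L, +1L, inlet_v$name, "lower", s_c, 2L),
    wall_table(nodes, sfa$idx, ncol(sfa$idx), -1L, up_v$name, "outer", sfa$s, 3L),
    wall_table(nodes, sfa$idx, 1L, +1L, up_v$name, "inner", sfa$s, 4L),
    wall_table(nodes, dfa$idx, 1L, +1L, lo_v$name, "outer", dfa$s, 5L),
    wall_table(nodes, dfa$idx, ncol(dfa$idx), -1L, lo_v$name, "inner", dfa$s, 6L)
  )

  outlets <- list()
  outlets[[paste0("outlet_", up_v$name)]] <-
    outlet_info(nodes, sfa$idx[nrow(sfa$idx), ], sfa$d)
  outlets[[paste0("outlet_", lo_v$name)]] <-
    outlet_info(nodes, dfa$idx[nrow(dfa$idx), ], dfa$d)

  inlet_nodes <- idx_c[1L, ]
  inlet <- outlet_info(nodes, inlet_nodes, c(-1, 0))
  inlet$y <- nodes[inlet_nodes, 2L]
  inlet$halfwidth <- a_c[1L]

  finalize_mesh(nodes, tri, boundary, walls, outlets, inlet, resolution,
                geom = geom, min_quality = min_quality)
}

#' Mesh a straight channel
#'
#' Single-vessel analogue of [mesh_bifurcation()] used for verification
#' cases and virtual single-segment runs: a straight channel along `+x` of
#' length `L` with half-width `a(s)` (constant or a function of `s`).
#' Boundary tags are `inlet`, `outlet`, `wall`.
#'
#' @param L channel length m.
#' @param a half-width m, or a function `a(s)`.
#' @param resolution target edge length m.
#' @param min_quality minimum triangle angle deg.
#' @export
mesh_channel <- function(L, a, resolution, min_quality = 10) {
  afun <- if (is.function(a)) a else function(s) rep(a, length(s))
  assert_that(is_scalar_number(L) && L > 0, "validation_error", "L must be > 0")
  sgrid <- seq(0, L, length.out = 257L)
  amin <- min(afun(sgrid))
  assert_that(is_scalar_number(resolution) && resolution > 0 && resolution < amin,
              "validation_error",
              "resolution must be positive and smaller than the minimum half-width")
  a0 <- afun(0)
  m <- max(4L, ceiling(2 * a0 / resolution)) + 1L
  ns <- max(4L, ceiling(L / resolution)) + 1L
  s <- seq(0, L, length.out = ns)
  hw <- afun(s)
  centers <- cbind(s, 0)
  crossdir <- matrix(rep(c(0, 1), each = ns), ns, 2)
  eta <- seq(-1, 1, length.out = m)
  nodes <- block_nodes(centers, crossdir, hw, eta)
  idx <- matrix(seq_len(ns * m), ns, m, byrow = TRUE)
  tri <- block_tris(idx)
  boundary <- rbind(
    boundary_edge_df(idx[1L, ], "inlet"),
    boundary_edge_df(idx[, 1L], "wall"),
    boundary_edge_df(idx[, m], "wall"),
    boundary_edge_df(idx[ns, ], "outlet")
  )
  walls <- rbind(
    wall_table(nodes, idx, m, -1L, "channel", "upper", s, 1L),
    wall_table(nodes, idx, 1L, +1L, "channel", "lower", s, 2L)
  )
  outlets <- list(outlet = outlet_info(nodes, idx[ns, ], c(1, 0)))
  inlet <- outlet_info(nodes, idx[1L, ], c(-1, 0))
  inlet$y <- nodes[idx[1L, ], 2L]
  inlet$halfwidth <- a0
  finalize_mesh(nodes, tri, boundary, walls, outlets, inlet, resolution,
                geom = NULL, min_quality = min_quality)
}

#' Export a mesh (and optional fields) as legacy ASCII VTK
#'
#' Writes an unstructured-grid VTK file with the triangulation, a
#' `boundary_tag` point array (0 interior, 1 inlet, 2+ outlets, 9 wall) and
#' any additional per-node scalar/vector fields.
#'
#' @param mesh a `mesh2d`.
#' @param file output path.
#' @param point_data named list of numeric vectors (scalars, length n) or
#'   2-column matrices (vectors) defined per node.
#' @export
write_vtk <- function(mesh, file, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "graftflow mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1L] - 1L, mesh$tri[, 2L] - 1L,
                     mesh$tri[, 3L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  tagv <- integer(n)
  tags <- unique(mesh$boundary$tag)
  codes <- stats::setNames(seq_along(tags), tags)
  codes[grepl("^wall$", names(codes))] <- 9L
  for (tg in tags) {
    e <- mesh$boundary[mesh$boundary$tag == tg, ]
    tagv[unique(c(e$a, e$b))] <- codes[[tg]]
  }
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines(c("SCALARS boundary_tag int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", tagv), con)
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.matrix(v)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(sprintf("%.10g %.10g 0", v[, 1L], v[, 2L]), con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", v), con)
    }
  }
  invisible(file)
}
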