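# Pulsatile incompressible Newtonian flow on the 2D meshed bifurcation.
#
# Discretization: P1-P1 triangles with PSPG pressure stabilization and SUPG
# streamline stabilization; semi-implicit (Oseen) backward-Euler stepping
# for convective runs, Crank-Nicolson with a constant factorized matrix for
# Stokes runs. Momentum is solved in kinematic form (pressure/rho); output
# pressures are physical. Outlet boundaries carry either a 3-element
# Windkessel (coupled implicitly through the trapezoidal update, entering
# the matrix as a rank-one boundary term) or a prescribed pressure, with
# backflow stabilization during reverse flow.

#' Solver configuration
#'
#' @param dt time step s; must satisfy `dt <= T/200` for the cardiac period
#'   being simulated.
#' @param cycles_max maximum number of cardiac cycles (>= 2).
#' @param periodicity_tol relative L2 cycle-to-cycle change of outlet flows
#'   below which the run is periodic (default 0.01).
#' @param fluid a [fluid_properties()].
#' @param depth out-of-plane depth m used to convert volumetric flows to the
#'   planar channel's per-depth flows.
#' @param backflow_beta backflow-stabilization coefficient in `[0, 1]`
#'   (default 0.2).
#' @param convection `TRUE` for full Navier-Stokes, `FALSE` for Stokes
#'   (constant-matrix Crank-Nicolson path).
#' @param harmonics Womersley harmonics for the inlet profile.
#' @param ramp ramp the inlet over the first half cycle from rest.
#' @param store_stride stride for exported field snapshots (wall shear is
#'   always recorded at every step of the final cycle).
#' @export
solver_config <- function(dt, cycles_max = 6L, periodicity_tol = 0.01,
                          fluid = fluid_properties(), depth,
                          backflow_beta = 0.2, convection = TRUE,
                          harmonics = 10L, ramp = TRUE, store_stride = 5L) {
  assert_that(is_scalar_number(dt) && dt > 0, "validation_error", "dt must be > 0")
  assert_that(cycles_max >= 2L, "validation_error", "cycles_max must be >= 2")
  assert_that(is_scalar_number(periodicity_tol) && periodicity_tol > 0,
              "validation_error", "periodicity_tol must be > 0")
  assert_that(is_scalar_number(backflow_beta) && backflow_beta >= 0 && backflow_beta <= 1,
              "validation_error", "backflow_beta must lie in [0, 1]")
  assert_that(is_scalar_number(depth) && depth > 0, "validation_error", "depth must be > 0")
  structure(list(dt = dt, cycles_max = as.integer(cycles_max),
                 periodicity_tol = periodicity_tol, fluid = fluid, depth = depth,
                 backflow_beta = backflow_beta, convection = isTRUE(convection),
                 harmonics = as.integer(harmonics), ramp = isTRUE(ramp),
                 store_stride = as.integer(store_stride)),
            class = "solver_config")
}

# ---------------------------------------------------------------------------
# FEM precomputation

build_fem <- function(mesh) {
  tri <- mesh$tri
  x <- matrix(mesh$nodes[tri, 1L], ncol = 3L)
  y <- matrix(mesh$nodes[tri, 2L], ncol = 3L)
  A <- ((x[, 2L] - x[, 1L]) * (y[, 3L] - y[, 1L]) -
          (x[, 3L] - x[, 1L]) * (y[, 2L] - y[, 1L])) / 2
  b <- cbind(y[, 2L] - y[, 3L], y[, 3L] - y[, 1L], y[, 1L] - y[, 2L]) / (2 * A)
  cc <- cbind(x[, 3L] - x[, 2L], x[, 1L] - x[, 3L], x[, 2L] - x[, 1L]) / (2 * A)
  h <- sqrt(4 * A / sqrt(3))
  n <- nrow(mesh$nodes)
  wall_nodes <- sort(unique(mesh$wall$node))
  inlet_nodes <- mesh$inlet$nodes
  diri_ux <- sort(unique(c(wall_nodes, inlet_nodes)))
  diri_uy <- diri_ux
  list(tri = tri, A = A, b = b, c = cc, h = h, n = n,
       wall_nodes = wall_nodes, inlet_nodes = inlet_nodes,
       diri = c(diri_ux, n + diri_uy))
}

# Accumulate triplets for all 3x3 combinations of one scalar block.
# entry(i, j) must return an ntri-length vector (or a scalar).
block_triplets <- function(fem, roff, coff, entry, acc) {
  for (i in 1:3) for (j in 1:3) {
    v <- entry(i, j)
    if (length(v) == 1L) v <- rep(v, length(fem$A))
    acc$i[[length(acc$i) + 1L]] <- roff + fem$tri[, i]
    acc$j[[length(acc$j) + 1L]] <- coff + fem$tri[, j]
    acc$x[[length(acc$x) + 1L]] <- v
  }
  acc
}

new_acc <- function() list(i = list(), j = list(), x = list())

acc_add <- function(acc, i, j, x) {
  acc$i[[length(acc$i) + 1L]] <- i
  acc$j[[length(acc$j) + 1L]] <- j
  acc$x[[length(acc$x) + 1L]] <- x
  acc
}

# Assemble the step matrix. ubar: ntri x 2 advection velocity per element
# (NULL for Stokes), theta: implicitness of the viscous term, idt: 1/dt
# (0 for steady). outlet_beta: named list of scalar kinematic coupling
# coefficients; bf_coef: named list of per-edge backflow coefficients.
assemble_system <- function(fem, mesh, nu, idt, theta, ubar = NULL,
                            outlet_beta = list(), bf = NULL) {
  n <- fem$n
  A <- fem$A; b <- fem$b; cc <- fem$c; h <- fem$h
  acc <- new_acc()
  # stabilization parameter (no 1/dt term; see vignette)
  if (is.null(ubar)) {
    tau <- 1 / (12 * nu / h^2)
  } else {
    un <- sqrt(ubar[, 1L]^2 + ubar[, 2L]^2)
    tau <- 1 / sqrt((2 * un / h)^2 + (12 * nu / h^2)^2)
  }
  d <- if (is.null(ubar)) NULL else
    lapply(1:3, function(i) ubar[, 1L] * b[, i] + ubar[, 2L] * cc[, i])

  # momentum diagonal blocks (identical for ux-ux and uy-uy)
  mom_entry <- function(i, j) {
    v <- idt * A / 12 * (1 + (i == j)) + theta * nu * A * (b[, i] * b[, j] + cc[, i] * cc[, j])
    if (!is.null(ubar)) {
      v <- v + A / 3 * d[[j]] +                      # Galerkin convection
        tau * A * d[[i]] * (idt / 3 + d[[j]])        # SUPG (time + advection)
    }
    v
  }
  acc <- block_triplets(fem, 0L, 0L, mom_entry, acc)
  acc <- block_triplets(fem, n, n, mom_entry, acc)
  # pressure gradient (momentum rows), with SUPG pressure part
  acc <- block_triplets(fem, 0L, 2L * n, function(i, j) {
    v <- -A * b[, i] / 3
    if (!is.null(ubar)) v <- v + tau * A * d[[i]] * b[, j]
    v
  }, acc)
  acc <- block_triplets(fem, n, 2L * n, function(i, j) {
    v <- -A * cc[, i] / 3
    if (!is.null(ubar)) v <- v + tau * A * d[[i]] * cc[, j]
    v
  }, acc)
  # continuity rows: Galerkin divergence + PSPG
  acc <- block_triplets(fem, 2L * n, 0L, function(i, j) {
    v <- A * b[, j] / 3 + tau * A * b[, i] * idt / 3
    if (!is.null(ubar)) v <- v + tau * A * b[, i] * d[[j]]
    v
  }, acc)
  acc <- block_triplets(fem, 2L * n, n, function(i, j) {
    v <- A * cc[, j] / 3 + tau * A * cc[, i] * idt / 3
    if (!is.null(ubar)) v <- v + tau * A * cc[, i] * d[[j]]
    v
  }, acc)
  acc <- block_triplets(fem, 2L * n, 2L * n, function(i, j) {
    tau * A * (b[, i] * b[, j] + cc[, i] * cc[, j])
  }, acc)

  # outlet Windkessel rank-one coupling:  + beta_kin * m w^T
  for (tag in names(outlet_beta)) {
    beta <- outlet_beta[[tag]]
    if (beta == 0) next
    o <- mesh$outlets[[tag]]
    dof <- c(o$nodes, n + o$nodes)
    mv <- c(o$wts * o$normal[1L], o$wts * o$normal[2L])
    ij <- expand.grid(r = seq_along(dof), c = seq_along(dof))
    acc <- acc_add(acc, dof[ij$r], dof[ij$c], beta * mv[ij$r] * mv[ij$c])
  }
  # backflow stabilization:  - beta_bf * (u^n . n)_- (u, v) on outlet edges
  if (!is.null(bf)) {
    for (tag in names(bf)) {
      coefs <- bf[[tag]]  # per-node value of -beta*(u.n)_- >= 0, mass-lumped
      o <- mesh$outlets[[tag]]
      keep <- coefs > 0
      if (!any(keep)) next
      nd <- o$nodes[keep]; v <- coefs[keep] * o$wts[keep]
      acc <- acc_add(acc, nd, nd, v)
      acc <- acc_add(acc, n + nd, n + nd, v)
    }
  }

  i <- unlist(acc$i); j <- unlist(acc$j); x <- unlist(acc$x)
  # Dirichlet rows: drop and replace by identity
  drop <- i %in% fem$diri
  i <- i[!drop]; j <- j[!drop]; x <- x[!drop]
  i <- c(i, fem$diri); j <- c(j, fem$diri); x <- c(x, rep(1, length(fem$diri)))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(3L * n, 3L * n))
}

# Right-hand side for one step (kinematic units). uxn/uyn: previous step.
assemble_rhs <- function(fem, mesh, nu, idt, theta, uxn, uyn, ubar,
                         outlet_alpha, diri_vals) {
  n <- fem$n
  A <- fem$A; b <- fem$b; cc <- fem$c; h <- fem$h
  rhs <- numeric(3L * n)
  tri <- fem$tri
  if (idt > 0) {
    if (is.null(ubar)) {
      tau <- 1 / (12 * nu / h^2)
    } else {
      un <- sqrt(ubar[, 1L]^2 + ubar[, 2L]^2)
      tau <- 1 / sqrt((2 * un / h)^2 + (12 * nu / h^2)^2)
    }
    uxe <- matrix(uxn[tri], ncol = 3L); uye <- matrix(uyn[tri], ncol = 3L)
    mean_ux <- rowMeans(uxe); mean_uy <- rowMeans(uye)
    # Galerkin mass term: idt * M u^n  (rowwise accumulation)
    for (i in 1:3) {
      mx <- idt * A / 12 * (uxe[, i] + mean_ux * 3) # sum_j M_ij u_j = A/12 (u_i + sum u)
      my <- idt * A / 12 * (uye[, i] + mean_uy * 3)
      if (!is.null(ubar)) {
        d_i <- ubar[, 1L] * b[, i] + ubar[, 2L] * cc[, i]
        mx <- mx + tau * A * d_i * idt * mean_ux
        my <- my + tau * A * d_i * idt * mean_uy
      }
      rhs[seq_len(n)] <- rhs[seq_len(n)] + unname(tapply0(mx, tri[, i], n))
      rhs[n + seq_len(n)] <- rhs[n + seq_len(n)] + unname(tapply0(my, tri[, i], n))
      # PSPG time term on continuity rows
      px <- tau * A * b[, i] * idt * mean_ux
      py <- tau * A * cc[, i] * idt * mean_uy
      rhs[2L * n + seq_len(n)] <- rhs[2L * n + seq_len(n)] +
        unname(tapply0(px + py, tri[, i], n))
    }
    if (theta < 1) {
      # Crank-Nicolson explicit half of the viscous term: -(1-theta) nu K u^n
      for (i in 1:3) {
        kx <- numeric(length(A)); ky <- numeric(length(A))
        for (j in 1:3) {
          Kij <- A * (b[, i] * b[, j] + cc[, i] * cc[, j])
          kx <- kx + Kij * uxe[, j]; ky <- ky + Kij * uye[, j]
        }
        rhs[seq_len(n)] <- rhs[seq_len(n)] - (1 - theta) * nu * unname(tapply0(kx, tri[, i], n))
        rhs[n + seq_len(n)] <- rhs[n + seq_len(n)] - (1 - theta) * nu * unname(tapply0(ky, tri[, i], n))
      }
    }
  }
  for (tag in names(outlet_alpha)) {
    o <- mesh$outlets[[tag]]
    al <- outlet_alpha[[tag]]
    rhs[o$nodes] <- rhs[o$nodes] - al * o$wts * o$normal[1L]
    rhs[fem$n + o$nodes] <- rhs[fem$n + o$nodes] - al * o$wts * o$normal[2L]
  }
  rhs[fem$diri] <- diri_vals
  rhs
}

# grouped sum into a length-n vector (rowsum without names overhead)
tapply0 <- function(x, g, n) {
  out <- numeric(n)
  r <- rowsum(x, g)
  out[as.integer(rownames(r))] <- r
  out
}

# boundary flux (per-depth) through a tagged boundary, outward positive
boundary_flux <- function(o, ux, uy) {
  sum(o$wts * (ux[o$nodes] * o$normal[1L] + uy[o$nodes] * o$normal[2L]))
}

# centroid velocity per element
elem_ubar <- function(fem, ux, uy) {
  cbind(rowMeans(matrix(ux[fem$tri], ncol = 3L)),
        rowMeans(matrix(uy[fem$tri], ncol = 3L)))
}

normalize_outlets <- function(mesh, outlets) {
  tags <- names(mesh$outlets)
  out <- list()
  for (nm in names(outlets)) {
    tag <- if (nm %in% tags) nm else paste0("outlet_", nm)
    assert_that(tag %in% tags, "validation_error",
                sprintf("no mesh outlet matches '%s' (available: %s)", nm,
                        paste(tags, collapse = ", ")))
    out[[tag]] <- outlets[[nm]]
  }
  assert_that(length(out) == length(tags), "validation_error",
              "every mesh outlet needs an outlet model")
  out[tags]
}

#' Detect cycle periodicity of outlet flow waveforms
#'
#' Returns the smallest cycle index `k >= 2` such that, for every outlet,
#' the relative L2 change between cycle `k` and cycle `k - 1` is below
#' `tol`; or `NA` when not converged.
#'
#' @param flows_by_cycle list per outlet of matrices (cycles x samples).
#' @param tol relative tolerance.
#' @param scale optional problem flow scale (e.g. the inlet flow
#'   amplitude): the change denominator is floored at a sliver of it so
#'   that numerically-zero flows count as periodic; a zero scale means the
#'   whole run carries no flow and is periodic from the second cycle.
#' @export
check_periodicity <- function(flows_by_cycle, tol, scale = NULL) {
  ncyc <- nrow(flows_by_cycle[[1L]])
  assert_that(ncyc >= 2L, "validation_error", "need at least two cycles")
  if (is.null(scale)) scale <- max(vapply(flows_by_cycle, function(M) max(abs(M)), 0))
  if (scale == 0) return(2L)
  for (k in 2:ncyc) {
    ok <- vapply(flows_by_cycle, function(M) {
      d <- sqrt(sum((M[k, ] - M[k - 1L, ])^2))
      s <- max(sqrt(sum(M[k - 1L, ]^2)), 1e-9 * scale * sqrt(ncol(M)))
      d / s < tol
    }, logical(1))
    if (all(ok)) return(k)
  }
  NA_integer_
}

#' Solve pulsatile flow through a meshed geometry
#'
#' Advances incompressible Newtonian flow (no body force, rigid no-slip
#' walls) with a Womersley channel velocity profile reproducing the inlet
#' flow waveform, Windkessel-coupled (or prescribed-pressure) outlets with
#' backflow stabilization, from rest with a half-cycle inlet ramp, until
#' the outlet flow waveforms are cycle-to-cycle periodic.
#'
#' @param mesh a `mesh2d`.
#' @param inlet inlet [flow_waveform()] (volumetric m^3/s; converted to the
#'   planar channel via `cfg$depth`).
#' @param outlets named list (by outlet vessel or tag) of
#'   [rcr_parameters()] or `list(type = "pressure", P = <Pa>)`.
#' @param cfg a [solver_config()].
#' @param init optional initial state: `list(ux=, uy=)` nodal velocities.
#' @return object of class `flow_history`: times of the final cycle, full
#'   per-step nodal velocity and pressure of the final cycle, inlet/outlet
#'   flow waveforms, periodic cycle index and mass-balance residual.
#' @export
solve_pulsatile <- function(mesh, inlet, outlets, cfg, init = NULL) {
  assert_that(inherits(mesh, "mesh2d"), "validation_error", "mesh must be a mesh2d")
  assert_that(inherits(inlet, "flow_waveform"), "validation_error",
              "inlet must be a flow_waveform")
  assert_that(inherits(cfg, "solver_config"), "validation_error",
              "cfg must be a solver_config")
  T <- inlet$T
  if (cfg$dt > T / 200 * (1 + 1e-9))
    stop_graftflow("validation_error",
                   sprintf("dt = %.3g s exceeds T/200 = %.3g s", cfg$dt, T / 200))
  outlets <- normalize_outlets(mesh, outlets)
  fem <- build_fem(mesh)
  n <- fem$n
  nu <- cfg$fluid$nu; rho <- cfg$fluid$rho
  nst <- max(200L, round(T / cfg$dt))
  dt <- T / nst
  theta <- if (cfg$convection) 1 else 0.5

  # inlet profile per step (per-depth flow -> channel Womersley profile)
  qpd <- flow_waveform(inlet$t, inlet$Q / cfg$depth, T)
  ycen <- mesh$inlet$y - mean(range(mesh$inlet$y))
  a_in <- mesh$inlet$halfwidth
  tgrid <- (seq_len(nst)) * dt
  prof <- inlet_profile_channel(qpd, a_in, cfg$fluid, tgrid, ycen, N = cfg$harmonics)
  # clamp interpolated profile to exact zero on wall-corner nodes
  prof[abs(abs(ycen) - a_in) < 1e-12, ] <- 0

  is_rcr <- vapply(outlets, inherits, logical(1), "rcr_parameters")
  Qin_mean_phys <- mean(inlet$Q)
  Pd <- list(); Qprev <- list()
  if (any(is_rcr)) {
    Rtot <- vapply(outlets[is_rcr], function(p) p$Rp + p$Rd, 0)
    share <- (1 / Rtot) / sum(1 / Rtot)
    for (tag in names(outlets)[is_rcr]) {
      p <- outlets[[tag]]
      Pd[[tag]] <- p$P_ref + Qin_mean_phys * share[[tag]] * p$Rd
      Qprev[[tag]] <- Qin_mean_phys * share[[tag]]
    }
  }

  ux <- numeric(n); uy <- numeric(n)
  if (!is.null(init)) { ux <- init$ux; uy <- init$uy }

  lu_const <- NULL
  if (!cfg$convection) {
    outlet_beta <- list()
    for (tag in names(outlets)) {
      outlet_beta[[tag]] <- if (is_rcr[[tag]])
        rcr_step_coefs(outlets[[tag]], dt, 0, 0)$b * cfg$depth / rho +
          outlets[[tag]]$Rp * cfg$depth / rho
      else 0
    }
    Amat <- assemble_system(fem, mesh, nu, 1 / dt, theta, ubar = NULL,
                            outlet_beta = outlet_beta)
    lu_const <- Matrix::lu(Amat)
  }

  flows_by_cycle <- stats::setNames(
    lapply(names(outlets), function(tag) matrix(0, 0, nst)), names(outlets))
  inflow_by_cycle <- matrix(0, 0, nst)
  mass_resid_max <- 0
  UX <- matrix(0, n, nst); UY <- matrix(0, n, nst); PR <- matrix(0, n, nst)

  for (cyc in seq_len(cfg$cycles_max)) {
    Qout_cycle <- stats::setNames(rep(list(numeric(nst)), length(outlets)), names(outlets))
    Qin_cycle <- numeric(nst)
    for (k in seq_len(nst)) {
      tnow <- (cyc - 1) * T + k * dt
      ramp <- if (cfg$ramp && cyc == 1L) smoothstep(tnow / (T / 2)) else 1
      uin <- prof[, k] * ramp
      # Dirichlet values: ux = inlet profile on inlet nodes, 0 on walls; uy = 0
      dv <- numeric(length(fem$diri))
      half <- length(fem$diri) / 2
      idx_in <- match(mesh$inlet$nodes, fem$diri[seq_len(half)])
      dv[idx_in] <- uin
      # outlet coupling coefficients for this step
      alpha <- list(); beta <- list()
      for (tag in names(outlets)) {
        if (is_rcr[[tag]]) {
          p <- outlets[[tag]]
          cf <- rcr_step_coefs(p, dt, Pd[[tag]], Qprev[[tag]])
          alpha[[tag]] <- cf$a / rho             # kinematic
          beta[[tag]] <- (cf$b + p$Rp) * cfg$depth / rho
        } else {
          alpha[[tag]] <- outlets[[tag]]$P / rho
          beta[[tag]] <- 0
        }
      }
      if (cfg$convection) {
        ubar <- elem_ubar(fem, ux, uy)
        bf <- NULL
        if (cfg$backflow_beta > 0) {
          bf <- list()
          for (tag in names(outlets)) {
            o <- mesh$outlets[[tag]]
            un_out <- ux[o$nodes] * o$normal[1L] + uy[o$nodes] * o$normal[2L]
            bf[[tag]] <- -cfg$backflow_beta * pmin(un_out, 0)
          }
        }
        Amat <- assemble_system(fem, mesh, nu, 1 / dt, theta, ubar = ubar,
                                outlet_beta = beta, bf = bf)
        rhs <- assemble_rhs(fem, mesh, nu, 1 / dt, theta, ux, uy, ubar, alpha, dv)
        sol <- Matrix::solve(Amat, rhs)
      } else {
        rhs <- assemble_rhs(fem, mesh, nu, 1 / dt, theta, ux, uy, NULL, alpha, dv)
        sol <- Matrix::solve(lu_const, rhs)
      }
      sol <- as.numeric(sol)
      ux <- sol[seq_len(n)]; uy <- sol[n + seq_len(n)]
      pk <- sol[2L * n + seq_len(n)] * rho
      if (!all(is.finite(ux)) || !all(is.finite(uy)))
        stop_graftflow("solver_error",
                       sprintf("solution diverged at cycle %d, step %d (t = %.4g s)", cyc, k, tnow))
      Qin_pd <- -boundary_flux(mesh$inlet, ux, uy)  # inward positive
      Qout_sum <- 0
      for (tag in names(outlets)) {
        qo <- boundary_flux(mesh$outlets[[tag]], ux, uy)
        Qout_cycle[[tag]][k] <- qo * cfg$depth
        Qout_sum <- Qout_sum + qo
        if (is_rcr[[tag]]) {
          cf <- rcr_step_coefs(outlets[[tag]], dt, Pd[[tag]], Qprev[[tag]])
          Qphys <- qo * cfg$depth
          Pd[[tag]] <- cf$a + cf$b * Qphys
          Qprev[[tag]] <- Qphys
        }
      }
      Qin_cycle[k] <- Qin_pd * cfg$depth
      UX[, k] <- ux; UY[, k] <- uy; PR[, k] <- pk
      mass_resid_max <- max(mass_resid_max,
                            abs(Qin_pd - Qout_sum) / max(abs(qpd$Q)))
    }
    for (tag in names(outlets))
      flows_by_cycle[[tag]] <- rbind(flows_by_cycle[[tag]], Qout_cycle[[tag]])
    inflow_by_cycle <- rbind(inflow_by_cycle, Qin_cycle)
    if (cyc >= 2L) {
      kper <- check_periodicity(flows_by_cycle, cfg$periodicity_tol,
                                scale = max(abs(qpd$Q)) * cfg$depth)
      if (!is.na(kper) && kper <= cyc) break
    }
    if (cyc == cfg$cycles_max)
      stop_graftflow("convergence_error",
                     sprintf("outlet flows not periodic within %d cycles (tol %.3g)",
                             cfg$cycles_max, cfg$periodicity_tol))
  }

  roll <- function(v) c(v[nst], v[-nst])  # align step k (t = k dt) to t grid [0, T)
  tout <- (seq_len(nst) - 1L) * dt
  outlet_flows <- lapply(names(outlets), function(tag)
    flow_waveform(tout, roll(flows_by_cycle[[tag]][cyc, ]), T,
                  site = sub("^outlet_", "", tag)))
  names(outlet_flows) <- sub("^outlet_", "", names(outlets))
  ordk <- c(nst, seq_len(nst - 1L))
  structure(list(times = tout, ux = UX[, ordk, drop = FALSE],
                 uy = UY[, ordk, drop = FALSE],
                 pressure = PR[, ordk, drop = FALSE],
                 inlet_flow = flow_waveform(tout, roll(inflow_by_cycle[cyc, ]), T),
                 outlet_flows = outlet_flows,
                 periodic_cycle = cyc, mass_residual = mass_resid_max,
                 dt = dt, T = T, cfg = cfg),
            class = "flow_history")
}

#' @export
print.flow_history <- function(x, ...) {
  cat(sprintf("<flow_history> %d steps/cycle (dt=%.3g s), periodic at cycle %d, mass residual %.2e\n",
              length(x$times), x$dt, x$periodic_cycle, x$mass_residual))
  cat(sprintf("  mean inflow %.3g mL/s; outlet split: %s\n",
              mean(x$inlet_flow$Q) * 1e6,
              paste(sprintf("%s %.1f%%", names(x$outlet_flows),
                            100 * vapply(x$outlet_flows, function(f) mean(f$Q), 0) /
                              mean(x$inlet_flow$Q)), collapse = ", ")))
  invisible(x)
}

#' Solve steady flow (Stokes or Navier-Stokes by Picard iteration)
#'
#' Steady counterpart of [solve_pulsatile()] used for verification cases,
#' lubrication-theory comparisons and virtual-angioplasty screening: a
#' parabolic inlet profile carrying `Q_in`, fixed-pressure or resistive
#' (steady Windkessel, `P = P_ref + (Rp+Rd) Q`) outlets.
#'
#' @param mesh a `mesh2d`.
#' @param Q_in steady volumetric inflow m^3/s.
#' @param outlets named list of [rcr_parameters()] or
#'   `list(type="pressure", P=)`.
#' @param cfg a [solver_config()] (`dt` is ignored; `convection` selects
#'   Stokes vs Picard Navier-Stokes).
#' @param picard_max,picard_tol Picard iteration controls.
#' @return list with nodal `ux`, `uy`, `pressure`, outlet flows (m^3/s),
#'   and mean inlet/outlet pressures.
#' @export
solve_steady <- function(mesh, Q_in, outlets, cfg, picard_max = 25L,
                         picard_tol = 1e-8) {
  outlets <- normalize_outlets(mesh, outlets)
  fem <- build_fem(mesh)
  n <- fem$n
  nu <- cfg$fluid$nu; rho <- cfg$fluid$rho
  qpd <- Q_in / cfg$depth
  ycen <- mesh$inlet$y - mean(range(mesh$inlet$y))
  a_in <- mesh$inlet$halfwidth
  uin <- 3 * qpd / (4 * a_in) * (1 - (ycen / a_in)^2)
  uin[abs(abs(ycen) - a_in) < 1e-12] <- 0
  dv <- numeric(length(fem$diri))
  half <- length(fem$diri) / 2
  dv[match(mesh$inlet$nodes, fem$diri[seq_len(half)])] <- uin
  alpha <- list(); beta <- list()
  is_rcr <- vapply(outlets, inherits, logical(1), "rcr_parameters")
  for (tag in names(outlets)) {
    if (is_rcr[[tag]]) {
      p <- outlets[[tag]]
      alpha[[tag]] <- p$P_ref / rho
      beta[[tag]] <- (p$Rp + p$Rd) * cfg$depth / rho
    } else {
      alpha[[tag]] <- outlets[[tag]]$P / rho
      beta[[tag]] <- 0
    }
  }
  ux <- numeric(n); uy <- numeric(n)
  iters <- if (cfg$convection) picard_max else 1L
  for (it in seq_len(iters)) {
    ubar <- if (cfg$convection && it > 1L) elem_ubar(fem, ux, uy) else NULL
    Amat <- assemble_system(fem, mesh, nu, 0, 1, ubar = ubar, outlet_beta = beta)
    rhs <- assemble_rhs(fem, mesh, nu, 0, 1, ux, uy, ubar, alpha, dv)
    sol <- as.numeric(Matrix::solve(Amat, rhs))
    ux_new <- sol[seq_len(n)]; uy_new <- sol[n + seq_len(n)]
    dlt <- rel_l2(c(ux_new, uy_new), c(ux, uy) + 1e-300)
    ux <- ux_new; uy <- uy_new
    if (!all(is.finite(ux))) stop_graftflow("solver_error", "steady solve diverged")
    if (cfg$convection && it > 1L && dlt < picard_tol) break
  }
  p <- sol[2L * n + seq_len(n)] * rho
  qout <- lapply(mesh$outlets, function(o) boundary_flux(o, ux, uy) * cfg$depth)
  pin <- sum(p[mesh$inlet$nodes] * mesh$inlet$wts) / sum(mesh$inlet$wts)
  pout <- lapply(mesh$outlets, function(o) sum(p[o$nodes] * o$wts) / sum(o$wts))
  list(ux = ux, uy = uy, pressure = p, outlet_flows = qout,
       inlet_pressure = pin, outlet_pressures = pout)
}
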