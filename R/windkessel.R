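# Three-element Windkessel (RCR) outlet model: proximal resistance Rp in
# series with a parallel compliance C / distal resistance Rd pair against a
# distal reference pressure P_ref. Governing ODE for the distal pressure
# P_d:  C dP_d/dt = Q - (P_d - P_ref)/Rd,  with outlet pressure
# P = P_d + Rp Q.

#' RCR (3-element Windkessel) parameters
#'
#' @param Rp proximal resistance Pa s/m^3, > 0.
#' @param C compliance m^3/Pa, > 0.
#' @param Rd distal resistance Pa s/m^3, > 0.
#' @param P_ref distal reference pressure Pa.
#' @export
rcr_parameters <- function(Rp, C, Rd, P_ref = 0) {
  assert_that(is_scalar_number(Rp) && Rp > 0, "validation_error", "Rp must be > 0")
  assert_that(is_scalar_number(C) && C > 0, "validation_error", "C must be > 0")
  assert_that(is_scalar_number(Rd) && Rd > 0, "validation_error", "Rd must be > 0")
  assert_that(is_scalar_number(P_ref), "validation_error", "P_ref must be a number")
  structure(list(Rp = Rp, C = C, Rd = Rd, P_ref = P_ref), class = "rcr_parameters")
}

#' @export
print.rcr_parameters <- function(x, ...) {
  cat(sprintf("<rcr_parameters> Rp=%.4g  C=%.4g  Rd=%.4g (Pa s/m^3, m^3/Pa)  P_ref=%.4g Pa\n",
              x$Rp, x$C, x$Rd, x$P_ref))
  invisible(x)
}

# Implicit-trapezoid coefficients for one step of the RCR ODE:
# P_d^{n+1} = a + b * Q^{n+1}, given P_d^n and Q^n.
rcr_step_coefs <- function(p, dt, Pd_n, Q_n) {
  k <- dt / (2 * p$C)
  g <- dt / (2 * p$Rd * p$C)
  denom <- 1 + g
  a <- (Pd_n * (1 - g) + k * Q_n + 2 * g * p$P_ref) / denom
  b <- k / denom
  list(a = a, b = b)
}

#' Periodic pressure response of an RCR outlet to a flow waveform
#'
#' Integrates the Windkessel ODE with the implicit trapezoidal rule over
#' repeated cycles until the periodic steady state is reached
#' (cycle-to-cycle maximum pressure change below `tol` relative), then
#' returns the outlet pressure `P = P_d + Rp Q` over one cycle. At the
#' periodic state `mean(P) - P_ref = mean(Q) (Rp + Rd)`.
#'
#' @param Q a [flow_waveform()].
#' @param p an [rcr_parameters()].
#' @param tol relative cycle-to-cycle convergence tolerance (default 1e-8).
#' @param max_cycles maximum cycles before a convergence error.
#' @return list with `t`, `P` (Pa), `Pd`, `cycles` used.
#' @export
rcr_pressure <- function(Q, p, tol = 1e-8, max_cycles = 200L) {
  assert_that(inherits(Q, "flow_waveform"), "validation_error", "Q must be a flow_waveform")
  assert_that(inherits(p, "rcr_parameters"), "validation_error", "p must be rcr_parameters")
  n <- length(Q$t)
  dt <- Q$T / n
  Qs <- Q$Q
  Pd <- p$P_ref + mean(Qs) * p$Rd  # start at the periodic mean
  Pd_prev_cycle <- NULL
  scale <- max(abs(p$P_ref) + abs(mean(Qs)) * (p$Rp + p$Rd), 1e-12)
  for (cyc in seq_len(max_cycles)) {
    Pd_cycle <- numeric(n)
    for (k in seq_len(n)) {
      Qn <- Qs[k]
      Qnp <- Qs[if (k == n) 1L else k + 1L]
      cf <- rcr_step_coefs(p, dt, Pd, Qn)
      Pd <- cf$a + cf$b * Qnp
      Pd_cycle[k] <- Pd
    }
    if (!is.null(Pd_prev_cycle)) {
      if (max(abs(Pd_cycle - Pd_prev_cycle)) / scale < tol) {
        Pd_out <- c(Pd_cycle[n], Pd_cycle[-n])  # align Pd with sample times
        return(list(t = Q$t, P = Pd_out + p$Rp * Qs, Pd = Pd_out, cycles = cyc))
      }
    }
    Pd_prev_cycle <- Pd_cycle
  }
  stop_graftflow("convergence_error",
                 sprintf("RCR response not periodic after %d cycles", max_cycles))
}

#' Frequency-domain impedance of the 3-element Windkessel
#'
#' `Z(omega) = Rp + Rd / (1 + i omega Rd C)`: equals `Rp + Rd` at DC,
#' decreases monotonically in magnitude, and tends to `Rp` at high
#' frequency.
#'
#' @param omega angular frequency rad/s (vectorized, >= 0).
#' @param p an [rcr_parameters()].
#' @return complex impedance Pa s/m^3.
#' @export
rcr_impedance <- function(omega, p) {
  assert_that(all(omega >= 0), "domain_error", "omega must be >= 0")
  p$Rp + p$Rd / (1 + 1i * omega * p$Rd * p$C)
}

# ---------------------------------------------------------------------------
# 0D junction surrogate: inlet flow Q_in(t) splits at a common junction
# pressure P_j(t) into two branches, each a lumped viscous branch resistance
# in series with its RCR outlet. Used for Windkessel tuning and for
# generating synthetic ground-truth outlet flows.

# Lubrication (locally fully developed) viscous resistance of a planar
# channel vessel: R = int 3 mu / (2 a(s)^3 depth) ds (Pa s / m^3).
lubrication_resistance <- function(geom, vessel, mu, depth, nquad = 513L) {
  L <- geom$vessels[[vessel]]$length
  s <- seq(0, L, length.out = nquad)
  a <- halfwidth(geom, vessel, s)
  trapz(s, 3 * mu / (2 * a^3 * depth))
}

#' Lumped (0D) bifurcation surrogate
#'
#' Distributes an inlet flow over the two outlet branches through a common
#' junction pressure: each branch is its vessel's lubrication-theory viscous
#' resistance in series with its RCR outlet. The coupled system is stepped
#' with the implicit trapezoidal rule over cycles to periodicity. This is
#' the fast surrogate used for Windkessel tuning and for generating
#' synthetic ground-truth outlet flows.
#'
#' @param Q_in inlet [flow_waveform()].
#' @param outlets named list of [rcr_parameters()], one per branch (names
#'   are vessel labels).
#' @param branch_R named numeric: series viscous resistance Pa s/m^3 per
#'   branch (e.g. from the geometry via lubrication theory).
#' @param tol periodicity tolerance on junction pressure.
#' @param max_cycles cycle cap.
#' @return list with `t`, `P_j`, and `flows`: named list of outlet
#'   [flow_waveform()]s.
#' @export
surrogate_split <- function(Q_in, outlets, branch_R, tol = 1e-8, max_cycles = 200L) {
  assert_that(inherits(Q_in, "flow_waveform"), "validation_error", "Q_in must be a flow_waveform")
  nm <- names(outlets)
  assert_that(length(nm) == 2L && all(nm %in% names(branch_R)), "validation_error",
              "outlets and branch_R must be two named branches")
  n <- length(Q_in$t)
  dt <- Q_in$T / n
  Rtot <- vapply(nm, function(k) branch_R[[k]] + outlets[[k]]$Rp + outlets[[k]]$Rd, 0)
  share <- (1 / Rtot) / sum(1 / Rtot)
  Pd <- vapply(nm, function(k) outlets[[k]]$P_ref + mean(Q_in$Q) * share[[k]] * outlets[[k]]$Rd, 0)
  Qb <- vapply(nm, function(k) mean(Q_in$Q) * share[[k]], 0)
  names(Pd) <- nm; names(Qb) <- nm
  Pj_prev <- NULL
  scale <- max(abs(mean(Q_in$Q)) * max(Rtot), 1e-12)
  for (cyc in seq_len(max_cycles)) {
    Pj_cycle <- numeric(n)
    Qcyc <- matrix(0, n, 2, dimnames = list(NULL, nm))
    for (k in seq_len(n)) {
      Qin_np <- Q_in$Q[if (k == n) 1L else k + 1L]
      ab <- lapply(nm, function(j) rcr_step_coefs(outlets[[j]], dt, Pd[[j]], Qb[[j]]))
      names(ab) <- nm
      # P_j = (R_br + Rp + b) Q_j + a + P offsets; solve sum(Q_j) = Q_in
      num <- 0; den <- 0
      for (j in nm) {
        Rser <- branch_R[[j]] + outlets[[j]]$Rp + ab[[j]]$b
        num <- num + ab[[j]]$a / Rser
        den <- den + 1 / Rser
      }
      Pj <- (Qin_np + num) / den
      for (j in nm) {
        Rser <- branch_R[[j]] + outlets[[j]]$Rp + ab[[j]]$b
        Qnew <- (Pj - ab[[j]]$a) / Rser
        Pd[[j]] <- ab[[j]]$a + ab[[j]]$b * Qnew
        Qb[[j]] <- Qnew
        Qcyc[k, j] <- Qnew
      }
      Pj_cycle[k] <- Pj
    }
    if (!is.null(Pj_prev) && max(abs(Pj_cycle - Pj_prev)) / scale < tol) {
      flows <- lapply(nm, function(j)
        flow_waveform(Q_in$t, c(Qcyc[n, j], Qcyc[-n, j]), Q_in$T, site = j))
      names(flows) <- nm
      return(list(t = Q_in$t, P_j = c(Pj_cycle[n], Pj_cycle[-n]),
                  flows = flows, cycles = cyc))
    }
    Pj_prev <- Pj_cycle
  }
  stop_graftflow("convergence_error",
                 sprintf("surrogate split not periodic after %d cycles", max_cycles))
}

#' Tuning target for one outlet
#'
#' @param outlet outlet (vessel) label.
#' @param Q_target target [flow_waveform()] at the outlet.
#' @param mean_pressure_target mean outlet pressure Pa (default 100 mmHg).
#' @param tolerance relative mean-flow tolerance in (0, 0.2].
#' @export
tuning_target <- function(outlet, Q_target, mean_pressure_target = 13332,
                          tolerance = 0.05) {
  assert_that(inherits(Q_target, "flow_waveform"), "validation_error",
              "Q_target must be a flow_waveform")
  assert_that(is_scalar_number(tolerance) && tolerance > 0 && tolerance <= 0.2,
              "validation_error", "tolerance must lie in (0, 0.2]")
  structure(list(outlet = outlet, Q_target = Q_target,
                 mean_pressure_target = mean_pressure_target,
                 tolerance = tolerance),
            class = "tuning_target")
}

#' Tune RCR outlet parameters to match target outlet flows
#'
#' Two-stage tuning of per-outlet 3-element Windkessel parameters. Stage 1
#' (analytic initialization): total resistance per outlet from the target
#' mean pressure and mean flow, split `Rp:Rd = split:(1-split)`, and
#' compliance from the pulse-decay heuristic `Rd C = T/3`. Stage 2:
#' Nelder-Mead refinement (on log-parameters, all outlets jointly) of the
#' L2 mismatch between target flows and the flows produced by the lumped
#' junction surrogate driven by the inlet flow. Tuning succeeds when each
#' outlet's relative mean-flow error is within its target tolerance.
#'
#' @param targets list of [tuning_target()]s (one per outlet).
#' @param Q_in inlet [flow_waveform()].
#' @param geom a [bifurcation_geometry()] providing branch resistances.
#' @param fluid a [fluid_properties()].
#' @param depth out-of-plane depth m used to lump the planar branches.
#' @param P_ref distal reference pressure Pa.
#' @param split Rp fraction of total resistance (default 0.09).
#' @param maxit Nelder-Mead iteration cap.
#' @param refine set `FALSE` to stop after the analytic initialization.
#' @return named list of [rcr_parameters()] with attributes
#'   `mean_flow_error` (per outlet) and `mismatch` (final L2 objective).
#' @export
tune_rcr <- function(targets, Q_in, geom, fluid, depth, P_ref = 0,
                     split = 0.09, maxit = 400L, refine = TRUE) {
  nm <- vapply(targets, `[[`, "", "outlet")
  names(targets) <- nm
  mean_in <- mean(Q_in$Q)
  mean_tg <- vapply(targets, function(tg) mean(tg$Q_target$Q), 0)
  tolv <- vapply(targets, `[[`, 0, "tolerance")
  if (mean_in < sum(mean_tg) * (1 - max(tolv)))
    stop_graftflow("validation_error",
                   sprintf("target outlet mean flows (%.3g m^3/s) exceed inlet mean flow (%.3g m^3/s)",
                           sum(mean_tg), mean_in))
  branch_R <- vapply(nm, function(v) lubrication_resistance(geom, v, fluid$mu, depth), 0)
  T <- Q_in$T
  init <- lapply(nm, function(v) {
    Rtot <- (targets[[v]]$mean_pressure_target - P_ref) / mean_tg[[v]]
    Rd <- (1 - split) * Rtot
    rcr_parameters(Rp = split * Rtot, C = T / (3 * Rd), Rd = Rd, P_ref = P_ref)
  })
  names(init) <- nm

  mismatch <- function(pars) {
    sim <- tryCatch(surrogate_split(Q_in, pars, branch_R, tol = 1e-7),
                    graftflow_convergence_error = function(e) NULL)
    if (is.null(sim)) return(list(obj = Inf, err = rep(Inf, 2)))
    obj <- 0; err <- numeric(length(nm)); names(err) <- nm
    for (v in nm) {
      tgt <- targets[[v]]$Q_target$Q
      obj <- obj + sum((sim$flows[[v]]$Q - tgt)^2) / sum(tgt^2)
      err[v] <- abs(mean(sim$flows[[v]]$Q) - mean(tgt)) / abs(mean(tgt))
      # outlet flows constrain only impedance ratios; the mean outlet
      # pressure target anchors the absolute resistance level
      meanP <- pars[[v]]$P_ref + mean(sim$flows[[v]]$Q) * (pars[[v]]$Rp + pars[[v]]$Rd)
      obj <- obj + ((meanP - targets[[v]]$mean_pressure_target) /
                      targets[[v]]$mean_pressure_target)^2
    }
    list(obj = obj, err = err)
  }

  pack <- function(pl) unlist(lapply(pl, function(p) log(c(p$Rp, p$C, p$Rd))))
  unpack <- function(x) {
    out <- lapply(seq_along(nm), function(i) {
      v <- unname(exp(x[(3 * (i - 1) + 1):(3 * i)]))
      rcr_parameters(v[1], v[2], v[3], P_ref = P_ref)
    })
    names(out) <- nm
    out
  }

  best <- init
  if (refine) {
    opt <- stats::optim(pack(init), function(x) mismatch(unpack(x))$obj,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    best <- unpack(opt$par)
  }
  res <- mismatch(best)
  if (any(res$err > tolv))
    stop_graftflow("tuning_error",
                   sprintf("tuning failed to reach mean-flow tolerance: errors %s vs tolerances %s",
                           paste(signif(res$err, 3), collapse = ", "),
                           paste(tolv, collapse = ", ")),
                   best = best, mean_flow_error = res$err)
  attr(best, "mean_flow_error") <- res$err
  attr(best, "mismatch") <- res$obj
  best
}
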