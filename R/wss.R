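# Wall shear stress extraction and TAWSS analytics.
#
# Signed wall shear tau(s, t) = mu * d(u_t)/dn at the wall (n the inward
# normal, u_t the velocity component along the local downstream wall
# tangent): positive where the fluid drags the wall downstream. Shear is
# recovered by a one-sided quadratic fit through the no-slip wall value and
# the two interior grid layers along the wall-normal stencil stored in the
# mesh, which is exact for locally parabolic profiles.

#' Wall shear stress history along the walls
#'
#' @param history a `flow_history` from [solve_pulsatile()] (or a list with
#'   `ux`, `uy` matrices nodes x times).
#' @param mesh the `mesh2d` the history was computed on.
#' @param mu dynamic viscosity Pa s.
#' @return object of class `wall_shear_record`: the mesh wall table plus a
#'   matrix `tau` (wall nodes x times) in Pa and the cycle period.
#' @export
wall_shear <- function(history, mesh, mu) {
  w <- mesh$wall
  if (max(c(w$node, w$n1, w$n2)) > nrow(history$ux))
    stop_graftflow("consistency_error", "history and mesh have mismatched node counts")
  ut1 <- history$ux[w$n1, , drop = FALSE] * w$tx + history$uy[w$n1, , drop = FALSE] * w$ty
  ut2 <- history$ux[w$n2, , drop = FALSE] * w$tx + history$uy[w$n2, , drop = FALSE] * w$ty
  # quadratic through (0, 0), (d1, ut1), (d2, ut2): du/dn at the wall
  denom <- w$d1 * w$d2 * (w$d2 - w$d1)
  dudn <- (w$d2^2 * ut1 - w$d1^2 * ut2) / denom
  tau <- mu * dudn
  if (!all(is.finite(tau)))
    stop_graftflow("consistency_error", "non-finite wall shear (degenerate wall stencil?)")
  structure(list(wall = w, tau = tau, times = history$times, T = history$T),
            class = "wall_shear_record")
}

#' @export
print.wall_shear_record <- function(x, ...) {
  cat(sprintf("<wall_shear_record> %d wall nodes x %d times, tau range [%.3g, %.3g] Pa\n",
              nrow(x$tau), ncol(x$tau), min(x$tau), max(x$tau)))
  invisible(x)
}

# Map wall nodes to named reporting segments via (vessel, s) intervals.
segment_labels <- function(wall, wall_segments) {
  lab <- rep(NA_character_, nrow(wall))
  for (nm in names(wall_segments)) {
    sg <- wall_segments[[nm]]
    hit <- wall$vessel == sg$vessel & wall$s >= sg$s0 & wall$s <= sg$s1
    lab[hit & is.na(lab)] <- nm
  }
  lab
}

#' Time-averaged wall shear stress map
#'
#' `TAWSS(s) = (1/T) int_0^T |tau(s, t)| dt`, integrated with the periodic
#' trapezoidal rule over the stored (uniform) steps of one cycle.
#'
#' @param rec a [wall_shear_record][wall_shear()] spanning exactly one cycle.
#' @param wall_segments named reporting intervals (as in
#'   [bifurcation_geometry()]); defaults to the geometry's segments when the
#'   record's mesh carried one, else a single `"wall"` segment.
#' @return object of class `tawss_map`: data frame `map` (node, vessel,
#'   side, s, arc, w_arc, segment, tawss) and per-segment minima.
#' @export
tawss <- function(rec, wall_segments = NULL) {
  assert_that(inherits(rec, "wall_shear_record"), "validation_error",
              "rec must be a wall_shear_record")
  nt <- ncol(rec$tau)
  span <- (rec$times[nt] - rec$times[1L]) + (rec$times[2L] - rec$times[1L])
  if (abs(span - rec$T) > 1e-6 * rec$T)
    stop_graftflow("domain_error",
                   sprintf("record spans %.4g s, not one cycle (T = %.4g s)", span, rec$T))
  vals <- rowMeans(abs(rec$tau))  # uniform periodic sampling: trapezoid == mean
  w <- rec$wall
  if (is.null(wall_segments)) {
    wall_segments <- stats::setNames(
      lapply(unique(w$vessel), function(v)
        list(vessel = v, s0 = min(w$s[w$vessel == v]), s1 = max(w$s[w$vessel == v]))),
      unique(w$vessel))
  }
  seg <- segment_labels(w, wall_segments)
  map <- data.frame(node = w$node, vessel = w$vessel, side = w$side,
                    wall_id = w$wall_id, s = w$s, arc = w$arc, w_arc = w$w_arc,
                    segment = seg, tawss = vals, stringsAsFactors = FALSE)
  keep <- !is.na(map$segment)
  minima <- tapply(map$tawss[keep], map$segment[keep], min)
  structure(list(map = map, segment_minima = minima, T = rec$T,
                 wall_segments = wall_segments),
            class = "tawss_map")
}

#' @export
print.tawss_map <- function(x, ...) {
  cat(sprintf("<tawss_map> %d wall nodes; global min %.4g Pa\n",
              nrow(x$map), min(x$map$tawss)))
  for (nm in names(x$segment_minima))
    cat(sprintf("  %-14s min %.4g Pa\n", nm, x$segment_minima[[nm]]))
  invisible(x)
}

#' @export
plot.tawss_map <- function(x, thresholds = c(0.4, 0.15, 0.05), ...) {
  sp <- split(x$map, x$map$wall_id)
  graphics::plot(NULL, xlim = range(x$map$s) * 1e3, ylim = range(c(x$map$tawss, thresholds)),
                 xlab = "s along vessel [mm]", ylab = "TAWSS [Pa]", log = "y", ...)
  for (i in seq_along(sp)) graphics::lines(sp[[i]]$s * 1e3, sp[[i]]$tawss, col = i)
  graphics::abline(h = thresholds, lty = 3)
  invisible(x)
}

#' Low-TAWSS report against clinical thresholds
#'
#' For each threshold (default the clinically referenced 0.4, 0.15 and
#' 0.05 Pa levels), reports the fraction (and absolute amount) of wall arc
#' length whose TAWSS lies below it, per reporting segment and overall,
#' plus the location of the global minimum. Fractions are non-decreasing in
#' the threshold by construction.
#'
#' @param map a [tawss()] map.
#' @param thresholds positive thresholds Pa.
#' @return list with `overall` and `by_segment` data frames, `global_min`
#'   (value Pa, segment, vessel, s).
#' @export
low_tawss_report <- function(map, thresholds = c(0.4, 0.15, 0.05)) {
  assert_that(all(thresholds > 0), "validation_error", "thresholds must be > 0")
  thresholds <- sort(thresholds)
  m <- map$map
  tot <- sum(m$w_arc)
  overall <- data.frame(
    threshold = thresholds,
    fraction = vapply(thresholds, function(th) sum(m$w_arc[m$tawss < th]) / tot, 0),
    arc_length = vapply(thresholds, function(th) sum(m$w_arc[m$tawss < th]), 0))
  segs <- unique(m$segment[!is.na(m$segment)])
  by_segment <- do.call(rbind, lapply(segs, function(sg) {
    mm <- m[!is.na(m$segment) & m$segment == sg, ]
    data.frame(segment = sg, threshold = thresholds,
               fraction = vapply(thresholds, function(th)
                 sum(mm$w_arc[mm$tawss < th]) / sum(mm$w_arc), 0),
               arc_length = vapply(thresholds, function(th)
                 sum(mm$w_arc[mm$tawss < th]), 0),
               min_tawss = min(mm$tawss))
  }))
  imin <- which.min(m$tawss)
  list(overall = overall, by_segment = by_segment,
       global_min = list(tawss = m$tawss[imin], segment = m$segment[imin],
                         vessel = m$vessel[imin], side = m$side[imin], s = m$s[imin]),
       thresholds = thresholds)
}

#' Compare TAWSS maps before and after an intervention
#'
#' Pairs two TAWSS maps over the same wall segmentation (e.g. pre and post
#' virtual angioplasty under identical boundary conditions) and reports
#' per-segment minima, their deltas, threshold-fraction deltas, and flags
#' where a segment minimum crosses a threshold.
#'
#' @param before,after [tawss()] maps with identical segment labeling.
#' @param thresholds thresholds Pa for crossing flags.
#' @return list with `segments` data frame (min_before, min_after, delta,
#'   thresholds_crossed) and `fractions` data frame of per-threshold
#'   fraction deltas per segment.
#' @export
compare_interventions <- function(before, after, thresholds = c(0.4, 0.15, 0.05)) {
  sb <- names(before$segment_minima); sa <- names(after$segment_minima)
  if (!identical(sort(sb), sort(sa)))
    stop_graftflow("consistency_error",
                   "before/after maps have incompatible segmentations")
  thresholds <- sort(thresholds)
  segs <- sort(sb)
  mb <- before$segment_minima[segs]; ma <- after$segment_minima[segs]
  crossed <- vapply(segs, function(sg) {
    paste(thresholds[mb[[sg]] < thresholds & ma[[sg]] >= thresholds], collapse = ",")
  }, "")
  segments <- data.frame(segment = segs, min_before = as.numeric(mb),
                         min_after = as.numeric(ma),
                         delta = as.numeric(ma) - as.numeric(mb),
                         thresholds_crossed = crossed, stringsAsFactors = FALSE)
  rb <- low_tawss_report(before, thresholds)$by_segment
  ra <- low_tawss_report(after, thresholds)$by_segment
  fr <- merge(rb, ra, by = c("segment", "threshold"), suffixes = c("_before", "_after"))
  fr$fraction_delta <- fr$fraction_after - fr$fraction_before
  list(segments = segments,
       fractions = fr[, c("segment", "threshold", "fraction_before",
                          "fraction_after", "fraction_delta")],
       thresholds = thresholds)
}

#' Export a TAWSS map as CSV
#'
#' Columns: s (m), arc (m), vessel, side, segment, tawss (Pa).
#' @param map a [tawss()] map.
#' @param path output path.
#' @export
write_tawss_csv <- function(map, path) {
  utils::write.csv(map$map[, c("s", "arc", "vessel", "side", "segment", "tawss")],
                   path, row.names = FALSE)
  invisible(path)
}
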