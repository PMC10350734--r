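# Parametric planar femoral-bifurcation geometry: one inlet vessel (CFA)
# splitting into two daughters (SFA, DFA), each a channel whose half-width
# varies along an axial coordinate s through smooth lesion profiles.
#
# Coordinates: s is arc length in meters measured from the inlet plane for
# the inlet vessel and from the bifurcation apex for daughters, 0-based.
# "Area" severity in this planar analogue maps to a width factor: a
# stenosis of severity sigma reduces the local channel width (and hence the
# cross-sectional area, at fixed out-of-plane depth) by the factor
# (1 - sigma); a widening increases it by (1 + sigma).

#' Vessel specification
#'
#' @param name vessel label: `"CFA"`, `"SFA"`, `"DFA"` or a custom label.
#' @param nominal_radius lesion-free channel half-width m, > 0.
#' @param length vessel length m, > 0.
#' @param angle branch angle in radians from the parent axis (0 for the
#'   inlet vessel); must satisfy `|angle| < pi/2`.
#' @export
vessel_spec <- function(name, nominal_radius, length, angle = 0) {
  assert_that(is_scalar_number(nominal_radius) && nominal_radius > 0,
              "validation_error", "nominal_radius must be > 0")
  assert_that(is_scalar_number(length) && length > 0,
              "validation_error", "length must be > 0")
  assert_that(is_scalar_number(angle) && abs(angle) < pi / 2,
              "validation_error", "|angle| must be < pi/2")
  structure(list(name = as.character(name), nominal_radius = nominal_radius,
                 length = length, angle = angle),
            class = "vessel_spec")
}

#' Lesion specification
#'
#' A smooth (C1 cosine-bump) local change of cross-sectional area on one
#' vessel: a stenosis of severity `sigma` reduces the local area to
#' `(1 - sigma)` of nominal at the lesion center; a widening increases it to
#' `(1 + sigma)`.
#'
#' @param vessel vessel label the lesion sits on.
#' @param center_s lesion center, arc length m along the vessel.
#' @param length lesion extent m (the bump support is
#'   `[center_s - length/2, center_s + length/2]`).
#' @param kind `"stenosis"` or `"widening"`.
#' @param severity dimensionless in `[0, 1)`.
#' @param profile bump shape identifier; only `"cosine"` is implemented.
#' @export
lesion_spec <- function(vessel, center_s, length, kind = c("stenosis", "widening"),
                        severity, profile = "cosine") {
  kind <- match.arg(kind)
  assert_that(is_scalar_number(severity) && severity >= 0 && severity < 1,
              "validation_error", "severity must lie in [0, 1)")
  assert_that(is_scalar_number(center_s) && is_scalar_number(length) && length > 0,
              "validation_error", "center_s and length must be numbers, length > 0")
  assert_that(identical(profile, "cosine"), "validation_error",
              "only the 'cosine' lesion profile is implemented")
  structure(list(vessel = as.character(vessel), center_s = center_s,
                 length = length, kind = kind, severity = severity,
                 profile = profile, cleared = list()),
            class = "lesion_spec")
}

lesion_support <- function(l) c(l$center_s - l$length / 2, l$center_s + l$length / 2)

#' Bifurcation geometry
#'
#' Assembles vessels and lesions into a validated planar bifurcation tree:
#' exactly one inlet vessel (angle 0, first in the list) and two outlet
#' vessels. Lesions must be fully contained in their vessel and must not
#' overlap on the same vessel.
#'
#' @param vessels list of three [vessel_spec()]s: inlet first, then the two
#'   daughters.
#' @param lesions list of [lesion_spec()]s.
#' @param endograft optional annotation `list(vessel=, s_start=, s_end=)`
#'   marking the stented wall segment (rigid smooth wall; reporting only).
#' @param wall_segments optional named list of reporting intervals
#'   `list(name = list(vessel=, s0=, s1=))`; a default segmentation (CFA,
#'   proximal/distal SFA, DFA) is derived when `NULL`.
#' @param proximal_length length m of the "proximal" daughter reporting
#'   segment (default 0.03, i.e. the first 3 cm after the bifurcation).
#' @return object of class `bifurcation_geometry`.
#' @export
bifurcation_geometry <- function(vessels, lesions = list(), endograft = NULL,
                                 wall_segments = NULL, proximal_length = 0.03) {
  assert_that(length(vessels) == 3L, "validation_error",
              "need exactly three vessels: one inlet and two outlets")
  for (v in vessels) assert_that(inherits(v, "vessel_spec"), "validation_error",
                                 "vessels must be vessel_spec objects")
  assert_that(vessels[[1L]]$angle == 0, "validation_error",
              "the first vessel is the inlet and must have angle 0")
  nm <- vapply(vessels, `[[`, "", "name")
  assert_that(!anyDuplicated(nm), "validation_error", "vessel names must be unique")
  names(vessels) <- nm
  for (l in lesions) {
    assert_that(inherits(l, "lesion_spec"), "validation_error",
                "lesions must be lesion_spec objects")
    assert_that(l$vessel %in% nm, "validation_error",
                sprintf("lesion references unknown vessel '%s'", l$vessel))
    sup <- lesion_support(l)
    if (sup[1L] < 0 || sup[2L] > vessels[[l$vessel]]$length)
      stop_graftflow("range_error",
                     sprintf("lesion on '%s' [%.4g, %.4g] m lies outside the vessel extent [0, %.4g] m",
                             l$vessel, sup[1L], sup[2L], vessels[[l$vessel]]$length))
  }
  # non-overlap per vessel
  if (length(lesions) > 1L) {
    for (i in seq_len(length(lesions) - 1L)) for (j in (i + 1L):length(lesions)) {
      a <- lesions[[i]]; b <- lesions[[j]]
      if (a$vessel == b$vessel) {
        sa <- lesion_support(a); sb <- lesion_support(b)
        if (sa[1L] < sb[2L] && sb[1L] < sa[2L])
          stop_graftflow("validation_error",
                         sprintf("lesions %d and %d overlap on vessel '%s' ([%.4g, %.4g] vs [%.4g, %.4g])",
                                 i, j, a$vessel, sa[1L], sa[2L], sb[1L], sb[2L]),
                         pair = c(i, j))
      }
    }
  }
  if (!is.null(endograft)) {
    assert_that(all(c("vessel", "s_start", "s_end") %in% names(endograft)),
                "validation_error", "endograft needs vessel, s_start, s_end")
    assert_that(endograft$vessel %in% nm, "validation_error",
                "endograft references unknown vessel")
    assert_that(endograft$s_start >= 0 &&
                  endograft$s_end <= vessels[[endograft$vessel]]$length &&
                  endograft$s_start < endograft$s_end,
                "range_error", "endograft extent outside vessel")
  }
  geom <- structure(list(vessels = vessels, lesions = lesions,
                         endograft = endograft, wall_segments = wall_segments),
                    class = "bifurcation_geometry")
  if (is.null(wall_segments)) geom$wall_segments <- default_wall_segments(geom, proximal_length)
  geom
}

default_wall_segments <- function(geom, proximal_length = 0.03) {
  v <- geom$vessels
  segs <- list()
  segs[[v[[1L]]$name]] <- list(vessel = v[[1L]]$name, s0 = 0, s1 = v[[1L]]$length)
  for (k in 2:3) {
    nmk <- v[[k]]$name
    pl <- min(proximal_length, v[[k]]$length)
    segs[[paste0(nmk, "_proximal")]] <- list(vessel = nmk, s0 = 0, s1 = pl)
    if (pl < v[[k]]$length)
      segs[[paste0(nmk, "_distal")]] <- list(vessel = nmk, s0 = pl, s1 = v[[k]]$length)
  }
  segs
}

#' @export
print.bifurcation_geometry <- function(x, ...) {
  cat("<bifurcation_geometry>\n")
  for (v in x$vessels)
    cat(sprintf("  %-4s R=%.3g mm  L=%.3g mm  angle=%.1f deg\n",
                v$name, v$nominal_radius * 1e3, v$length * 1e3, v$angle * 180 / pi))
  for (l in x$lesions)
    cat(sprintf("  lesion: %s on %s, severity %.2f, s=[%.3g, %.3g] mm%s\n",
                l$kind, l$vessel, l$severity,
                (l$center_s - l$length / 2) * 1e3, (l$center_s + l$length / 2) * 1e3,
                if (length(l$cleared)) " (post-angioplasty mask applied)" else ""))
  if (!is.null(x$endograft))
    cat(sprintf("  endograft: %s s=[%.3g, %.3g] mm\n", x$endograft$vessel,
                x$endograft$s_start * 1e3, x$endograft$s_end * 1e3))
  invisible(x)
}

#' Build a geometry from a plain config list
#'
#' Constructs a validated [bifurcation_geometry()] from the nested-list form
#' used in YAML pipeline configs: `vessels` (list of name/radius/length/angle
#' entries), `lesions` (vessel/center_s/length/kind/severity), optional
#' `endograft` and `proximal_length`. All units SI.
#'
#' @param spec nested list (e.g. from [yaml::read_yaml()]).
#' @export
build_geometry <- function(spec) {
  assert_that(is.list(spec) && !is.null(spec$vessels), "validation_error",
              "geometry spec must be a list with a 'vessels' entry")
  vessels <- lapply(spec$vessels, function(v)
    vessel_spec(v$name, v$radius %||% v$nominal_radius, v$length, v$angle %||% 0))
  lesions <- lapply(spec$lesions %||% list(), function(l)
    lesion_spec(l$vessel, l$center_s, l$length, l$kind %||% "stenosis", l$severity))
  bifurcation_geometry(vessels, lesions, endograft = spec$endograft,
                       wall_segments = spec$wall_segments,
                       proximal_length = spec$proximal_length %||% 0.03)
}

# Angioplasty mask for one cleared interval: 0 on the interval core, rising
# C1-smoothly to 1 across bands of width delta just inside the interval
# ends, 1 outside the interval. Lesion contributions are multiplied by the
# mask, so a cleared lesion's wall is restored to nominal caliber.
clear_mask <- function(s, interval) {
  s0 <- interval[1L]; s1 <- interval[2L]
  delta <- (s1 - s0) / 10
  m <- rep(1, length(s))
  inside <- s >= s0 & s <= s1
  m[inside] <- 0
  lo <- s >= s0 & s < s0 + delta
  m[lo] <- 1 - smoothstep((s[lo] - s0) / delta)
  hi <- s > s1 - delta & s <= s1
  m[hi] <- smoothstep((s[hi] - (s1 - delta)) / delta)
  m
}

# Width factor (local width / nominal width) along a vessel.
width_factor <- function(geom, vessel, s) {
  f <- rep(1, length(s))
  for (l in geom$lesions) {
    if (l$vessel != vessel) next
    xi <- (s - l$center_s) / (l$length / 2)
    bump <- cos_bump(xi)
    lf <- if (l$kind == "stenosis") 1 - l$severity * bump else 1 + l$severity * bump
    mask <- rep(1, length(s))
    for (iv in l$cleared) mask <- mask * clear_mask(s, iv)
    f <- f * (1 + (lf - 1) * mask)
  }
  f
}

#' Local channel half-width along a vessel
#'
#' Nominal half-width modulated by the vessel's lesions (and any virtual
#' angioplasty applied to them). At a stenosis center of severity `sigma`
#' the local width, and hence the local cross-sectional area of the planar
#' channel, equals `(1 - sigma)` of nominal.
#'
#' @param geom a [bifurcation_geometry()].
#' @param vessel vessel label.
#' @param s arc-length positions m.
#' @export
halfwidth <- function(geom, vessel, s) {
  assert_that(vessel %in% names(geom$vessels), "validation_error",
              sprintf("unknown vessel '%s'", vessel))
  geom$vessels[[vessel]]$nominal_radius * width_factor(geom, vessel, s)
}

#' Virtual angioplasty (cylindrical inflation)
#'
#' Restores the wall within `s_interval` on `vessel` to the nominal,
#' lesion-free caliber, blending C1-smoothly across narrow bands just inside
#' the interval ends; geometry outside the interval is unchanged and the
#' input object is not mutated. Applying the same interval twice is a no-op
#' (idempotent).
#'
#' @param geom a [bifurcation_geometry()].
#' @param vessel vessel label.
#' @param s_interval numeric length-2, `c(s0, s1)` with `0 <= s0 < s1 <=`
#'   vessel length.
#' @return the modified geometry.
#' @export
virtual_angioplasty <- function(geom, vessel, s_interval) {
  assert_that(inherits(geom, "bifurcation_geometry"), "validation_error",
              "geom must be a bifurcation_geometry")
  assert_that(vessel %in% names(geom$vessels), "validation_error",
              sprintf("unknown vessel '%s'", vessel))
  assert_that(is.numeric(s_interval) && length(s_interval) == 2L &&
                s_interval[1L] < s_interval[2L],
              "validation_error", "s_interval must be c(s0, s1) with s0 < s1")
  if (s_interval[1L] < 0 || s_interval[2L] > geom$vessels[[vessel]]$length)
    stop_graftflow("range_error",
                   sprintf("interval [%.4g, %.4g] m outside vessel '%s' extent [0, %.4g] m",
                           s_interval[1L], s_interval[2L], vessel,
                           geom$vessels[[vessel]]$length))
  for (i in seq_along(geom$lesions)) {
    l <- geom$lesions[[i]]
    if (l$vessel != vessel) next
    sup <- lesion_support(l)
    if (sup[1L] >= s_interval[2L] || sup[2L] <= s_interval[1L]) next
    dup <- any(vapply(l$cleared, function(iv) isTRUE(all.equal(iv, s_interval)), logical(1)))
    if (!dup) geom$lesions[[i]]$cleared <- c(l$cleared, list(as.numeric(s_interval)))
  }
  geom
}
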