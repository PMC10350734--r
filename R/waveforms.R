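# Periodic one-cycle waveforms: duplex-like centerline velocity and
# volumetric flow, their Fourier (harmonic) representation, and CSV I/O.

#' Construct a centerline-velocity waveform
#'
#' A velocity waveform is one cardiac cycle of centerline velocity sampled
#' uniformly on `[0, T)` (the endpoint is not duplicated; the series is
#' treated as `T`-periodic), as measured by duplex ultrasound at a named
#' arterial site.
#'
#' @param t sample times in seconds, uniform on `[0, T)`.
#' @param u centerline velocity in m/s, same length as `t`.
#' @param T cardiac period in seconds.
#' @param site site label, e.g. `"CFA"`, `"SFA"`, `"DFA"`.
#' @return an object of class `velocity_waveform` with fields `t`, `u`, `T`,
#'   `site`.
#' @export
velocity_waveform <- function(t, u, T, site = "CFA") {
  assert_that(is_scalar_number(T) && T > 0, "validation_error", "period T must be a positive number")
  assert_that(length(t) == length(u), "validation_error", "t and u must have equal length")
  assert_that(length(t) >= 32L, "validation_error",
              sprintf("waveform needs >= 32 samples per cycle, got %d", length(t)))
  assert_that(all(diff(t) > 0), "format_error", "time samples must be strictly increasing")
  assert_that(all(is.finite(u)), "validation_error", "velocities must be finite")
  assert_that(max(t) < T, "validation_error", "samples must lie in [0, T) (no duplicated endpoint)")
  structure(list(t = as.numeric(t), u = as.numeric(u), T = as.numeric(T),
                 site = as.character(site)),
            class = "velocity_waveform")
}

#' Construct a volumetric-flow waveform
#'
#' Same sampling contract as [velocity_waveform()], but carrying volumetric
#' flow in m^3/s.
#'
#' @param t sample times s, uniform on `[0, T)`.
#' @param Q volumetric flow m^3/s.
#' @param T cardiac period s.
#' @param site optional site label.
#' @export
flow_waveform <- function(t, Q, T, site = NULL) {
  assert_that(is_scalar_number(T) && T > 0, "validation_error", "period T must be a positive number")
  assert_that(length(t) == length(Q), "validation_error", "t and Q must have equal length")
  assert_that(length(t) >= 32L, "validation_error",
              sprintf("waveform needs >= 32 samples per cycle, got %d", length(t)))
  assert_that(all(diff(t) > 0), "format_error", "time samples must be strictly increasing")
  assert_that(all(is.finite(Q)), "validation_error", "flows must be finite")
  assert_that(max(t) < T, "validation_error", "samples must lie in [0, T)")
  structure(list(t = as.numeric(t), Q = as.numeric(Q), T = as.numeric(T), site = site),
            class = "flow_waveform")
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf("<velocity_waveform> site=%s  T=%.3g s  n=%d  mean=%.4g m/s  range=[%.4g, %.4g]\n",
              x$site, x$T, length(x$t), mean(x$u), min(x$u), max(x$u)))
  invisible(x)
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("<flow_waveform>%s  T=%.3g s  n=%d  mean=%.4g m^3/s (%.3g mL/s)\n",
              if (is.null(x$site)) "" else paste0(" site=", x$site),
              x$T, length(x$t), mean(x$Q), mean(x$Q) * 1e6))
  invisible(x)
}

# Periodic sum of Gaussian lobes: amplitude a, center c (fraction of T),
# width sd (fraction of T); wrapped over +-1 neighbouring periods.
gauss_lobe <- function(t, T, a, c, sd) {
  v <- 0
  for (k in -1:1) v <- v + a * exp(-((t / T - c - k)^2) / (2 * sd^2))
  v
}

#' Synthesize a duplex-like femoral velocity waveform
#'
#' Generates a one-cycle centerline-velocity waveform emulating the femoral
#' duplex morphologies relevant to endograft hemodynamics: a triphasic
#' template (forward systolic peak, early-diastolic reverse lobe, small late
#' forward wave) or a monophasic, everywhere non-negative template. The
#' triphasic template is a sum of three Gaussian lobes centered at 0.12, 0.30
#' and 0.55 of the cycle; the lobes are narrow enough that the systolic peak
#' equals `psv` and the reverse trough equals `-reverse_fraction * psv` to
#' well under 1e-3 relative.
#'
#' @param psv peak systolic velocity m/s (> 0).
#' @param reverse_fraction ratio of reverse-lobe peak magnitude to `psv`
#'   (>= 0; must be 0 for monophasic waveforms).
#' @param T cardiac period s.
#' @param phase `"triphasic"` or `"monophasic"`.
#' @param noise_sd additive Gaussian sample noise, m/s.
#' @param seed integer seed controlling the noise; the output is
#'   deterministic given the seed.
#' @param n samples per cycle (>= 32).
#' @param site site label attached to the waveform.
#' @return a [velocity_waveform()].
#' @export
synth_duplex_waveform <- function(psv, reverse_fraction = 0, T = 1,
                                  phase = c("triphasic", "monophasic"),
                                  noise_sd = 0, seed = 1L, n = 256L,
                                  site = "CFA") {
  phase <- match.arg(phase)
  assert_that(is_scalar_number(psv) && psv > 0, "validation_error", "psv must be > 0")
  assert_that(is_scalar_number(reverse_fraction) && reverse_fraction >= 0,
              "validation_error", "reverse_fraction must be >= 0")
  if (phase == "monophasic" && reverse_fraction > 0)
    stop_graftflow("validation_error",
                   "monophasic waveforms cannot have reverse_fraction > 0")
  t <- seq(0, T, length.out = n + 1L)[seq_len(n)]
  if (phase == "triphasic") {
    u <- gauss_lobe(t, T, psv, 0.12, 0.035) -
      gauss_lobe(t, T, reverse_fraction * psv, 0.30, 0.045) +
      gauss_lobe(t, T, 0.12 * psv, 0.55, 0.07)
  } else {
    # forward systolic lobe riding on a broad forward diastolic component
    u <- gauss_lobe(t, T, psv, 0.12, 0.045) +
      gauss_lobe(t, T, 0.15 * psv, 0.55, 0.20)
  }
  if (noise_sd > 0) {
    u <- u + withr::with_seed(as.integer(seed), stats::rnorm(n, 0, noise_sd))
  }
  if (phase == "monophasic") u <- pmax(u, 0)  # duplex envelope is non-negative
  velocity_waveform(t, u, T, site = site)
}

#' Fourier (harmonic) decomposition of a periodic waveform
#'
#' Decomposes a uniformly sampled one-cycle waveform into complex harmonic
#' amplitudes `coeffs[n+1]` for harmonics `n = 0..N`, with the convention
#' `x(t) = c0 + Re sum_n c_n exp(i n w0 t)`. `c0` is the cycle mean.
#'
#' @param w a [velocity_waveform()] or [flow_waveform()].
#' @param N highest harmonic retained; must satisfy `N < n_samples / 2`.
#' @return object of class `harmonic_series` with fields `omega0`, `coeffs`
#'   (complex, length `N + 1`), `T`, `N`.
#' @export
fourier_decompose <- function(w, N = 10L) {
  x <- if (inherits(w, "velocity_waveform")) w$u else if (inherits(w, "flow_waveform")) w$Q
  else stop_graftflow("validation_error", "w must be a velocity or flow waveform")
  n <- length(x)
  if (N >= n / 2)
    stop_graftflow("validation_error",
                   sprintf("N = %d harmonics would alias: need N < samples/2 = %g", N, n / 2))
  F <- stats::fft(x) / n
  coeffs <- complex(length.out = N + 1L)
  coeffs[1L] <- Re(F[1L])
  if (N >= 1L) coeffs[2:(N + 1L)] <- 2 * F[2:(N + 1L)]
  structure(list(omega0 = 2 * pi / w$T, coeffs = coeffs, T = w$T, N = as.integer(N)),
            class = "harmonic_series")
}

#' Evaluate a harmonic series at arbitrary times
#'
#' @param hs a `harmonic_series`.
#' @param t times s.
#' @return real-valued reconstruction at `t`.
#' @export
harmonic_eval <- function(hs, t) {
  out <- rep(Re(hs$coeffs[1L]), length(t))
  if (hs$N >= 1L) {
    for (n in seq_len(hs$N)) {
      out <- out + Re(hs$coeffs[n + 1L] * exp(1i * n * hs$omega0 * t))
    }
  }
  out
}

#' @export
print.harmonic_series <- function(x, ...) {
  cat(sprintf("<harmonic_series> N=%d  omega0=%.4g rad/s  |c|=%s\n",
              x$N, x$omega0, paste(signif(Mod(x$coeffs), 3), collapse = " ")))
  invisible(x)
}

#' Read a centerline-velocity waveform from CSV
#'
#' Expects a header row with columns `time_s` and `velocity_m_per_s`
#' (comma-separated, SI units, one measurement site per file). The period is
#' inferred as the last sample time plus the (uniform) sample step.
#'
#' @param path CSV file path.
#' @param site site label to attach (default taken from an optional `site`
#'   column, else "CFA").
#' @export
read_waveform_csv <- function(path, site = NULL) {
  if (!file.exists(path))
    stop_graftflow("format_error", sprintf("waveform file does not exist: %s", path))
  if (file.size(path) == 0L)
    stop_graftflow("format_error", sprintf("waveform file is empty: %s", path))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop_graftflow("format_error",
                   sprintf("cannot parse %s as CSV: %s", path, conditionMessage(e))))
  need <- c("time_s", "velocity_m_per_s")
  if (!all(need %in% names(df)))
    stop_graftflow("format_error",
                   sprintf("%s: missing required header columns %s", path,
                           paste(setdiff(need, names(df)), collapse = ", ")))
  t <- df$time_s
  if (length(t) < 2L || any(diff(t) <= 0))
    stop_graftflow("format_error",
                   sprintf("%s: time_s must be strictly increasing", path))
  dt <- diff(t)
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt))
    stop_graftflow("format_error", sprintf("%s: time_s must be uniformly sampled", path))
  T <- t[length(t)] + mean(dt)
  if (is.null(site)) site <- if ("site" %in% names(df)) as.character(df$site[1L]) else "CFA"
  velocity_waveform(t, df$velocity_m_per_s, T, site = site)
}

#' Write a centerline-velocity waveform to CSV
#'
#' Inverse of [read_waveform_csv()]: writing then reading reproduces the
#' waveform to better than 1e-9 (values are written with full precision).
#'
#' @param w a [velocity_waveform()].
#' @param path output CSV path.
#' @export
write_waveform_csv <- function(w, path) {
  df <- data.frame(time_s = format(w$t, digits = 17, scientific = TRUE, trim = TRUE),
                   velocity_m_per_s = format(w$u, digits = 17, scientific = TRUE, trim = TRUE),
                   site = w$site)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
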