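test_that("triphasic synthesis hits the prescribed peak, trough and timing", {
  w <- synth_duplex_waveform(0.8, 0.3, T = 1, phase = "triphasic")
  expect_s3_class(w, "velocity_waveform")
  expect_equal(max(w$u), 0.8, tolerance = 1e-3)
  expect_equal(min(w$u), -0.24, tolerance = 1e-3)
  expect_equal(w$t[which.max(w$u)], 0.12, tolerance = 0.01)
  expect_equal(w$t[which.min(w$u)], 0.30, tolerance = 0.01)
  # scaled period keeps the relative morphology
  w2 <- synth_duplex_waveform(0.8, 0.3, T = 0.8, phase = "triphasic")
  expect_equal(w2$t[which.max(w2$u)] / 0.8, 0.12, tolerance = 0.01)
})

test_that("monophasic synthesis is everywhere non-negative and rejects reverse flow", {
  w <- synth_duplex_waveform(0.8, 0, T = 1, phase = "monophasic", noise_sd = 0.02, seed = 7L)
  expect_true(min(w$u) >= 0)
  expect_equal(max(w$u), 0.8, tolerance = 0.1)  # noise on top of the peak
  expect_error(synth_duplex_waveform(0.8, 0.3, phase = "monophasic"),
               class = "graftflow_validation_error")
  expect_error(synth_duplex_waveform(-1, 0, phase = "monophasic"),
               class = "graftflow_validation_error")
})

test_that("noisy synthesis is deterministic given the seed", {
  a <- synth_duplex_waveform(0.8, 0.3, noise_sd = 0.05, seed = 42L)
  b <- synth_duplex_waveform(0.8, 0.3, noise_sd = 0.05, seed = 42L)
  c <- synth_duplex_waveform(0.8, 0.3, noise_sd = 0.05, seed = 43L)
  expect_identical(a$u, b$u)
  expect_false(identical(a$u, c$u))
})

test_that("fourier_decompose recovers DC and single-tone signals", {
  tt <- seq(0, 1, length.out = 65)[1:64]
  const <- velocity_waveform(tt, rep(0.5, 64), 1)
  hs <- fourier_decompose(const, N = 10)
  expect_equal(Re(hs$coeffs[1]), 0.5, tolerance = 1e-12)
  expect_true(all(Mod(hs$coeffs[-1]) < 1e-12))
  tone <- velocity_waveform(tt, cos(2 * pi * tt), 1)
  hs2 <- fourier_decompose(tone, N = 5)
  expect_equal(Mod(hs2$coeffs[2]), 1, tolerance = 1e-12)
  expect_true(all(Mod(hs2$coeffs[c(1, 3:6)]) < 1e-12))
  expect_error(fourier_decompose(tone, N = 40), class = "graftflow_validation_error")
})

test_that("band-limited signals round-trip through the harmonic series", {
  # independent oracle: direct summation of a known harmonic synthesis
  set.seed(11)
  tt <- seq(0, 0.8, length.out = 129)[1:128]
  coef <- complex(real = stats::rnorm(6, 0, 0.2), imaginary = stats::rnorm(6, 0, 0.2))
  x <- rep(0.3, 128)
  for (n in 1:6) x <- x + Re(coef[n] * exp(2i * pi * n * tt / 0.8))
  w <- velocity_waveform(tt, x, 0.8)
  hs <- fourier_decompose(w, N = 10)
  expect_lt(max(abs(harmonic_eval(hs, tt) - x)), 1e-10)
})

test_that("Parseval and time-shift invariance hold for the decomposition", {
  set.seed(5)
  for (rep in 1:5) {
    tt <- seq(0, 1, length.out = 129)[1:128]
    hsrc <- complex(real = stats::rnorm(8, 0, 0.3), imaginary = stats::rnorm(8, 0, 0.3))
    x <- rep(stats::rnorm(1), 128)
    for (n in 1:8) x <- x + Re(hsrc[n] * exp(2i * pi * n * tt))
    w <- velocity_waveform(tt, x, 1)
    hs <- fourier_decompose(w, N = 8)
    # Parseval: mean square = c0^2 + sum |cn|^2 / 2
    ms <- Re(hs$coeffs[1])^2 + sum(Mod(hs$coeffs[-1])^2) / 2
    expect_equal(ms, mean(x^2), tolerance = 1e-9)
    # time shift multiplies harmonic n by a unit-modulus factor
    shift <- 17
    xs <- c(x[-seq_len(shift)], x[seq_len(shift)])
    hss <- fourier_decompose(velocity_waveform(tt, xs, 1), N = 8)
    expect_equal(Mod(hss$coeffs), Mod(hs$coeffs), tolerance = 1e-10)
  }
})

test_that("waveform CSV round-trips and rejects malformed files", {
  w <- synth_duplex_waveform(0.7, 0.25, noise_sd = 0.01, seed = 3L, site = "SFA")
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, f)
  w2 <- read_waveform_csv(f)
  expect_equal(w2$u, w$u, tolerance = 1e-9)
  expect_equal(w2$t, w$t, tolerance = 1e-9)
  expect_equal(w2$T, w$T, tolerance = 1e-9)
  expect_identical(w2$site, "SFA")

  shuffled <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(f)
  utils::write.csv(df[sample(nrow(df)), ], shuffled, row.names = FALSE)
  expect_error(read_waveform_csv(shuffled), class = "graftflow_format_error")

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  err <- tryCatch(read_waveform_csv(empty), condition = identity)
  expect_s3_class(err, "graftflow_format_error")
  expect_match(conditionMessage(err), basename(empty), fixed = TRUE)

  noheader <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), noheader)
  expect_error(read_waveform_csv(noheader), class = "graftflow_format_error")
})
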