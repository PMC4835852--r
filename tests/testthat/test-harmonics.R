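test_that("closed-form Fourier coefficients match numerical quadrature", {
  # the independent oracle integrates F(t) e^{i 2 pi n t / T0} adaptively
  for (seed in 1:8) {
    p <- random_params(seed)
    for (n in c(1, 2, 3, 7)) {
      cf <- fourier_coefficient(p, n)
      or <- cn_quadrature(p, n)
      expect_lt(Mod(cf - or) / Mod(or), 1e-8)
    }
  }
  p <- fig2_params()
  for (n in 1:3)
    expect_lt(Mod(fourier_coefficient(p, n) - cn_quadrature(p, n)) /
                Mod(cn_quadrature(p, n)), 1e-8)
})

test_that("DC coefficient is the time average, baseline included", {
  p <- fig2_params(amplitude = 3, baseline = 2)
  avg <- stats::integrate(function(t) 2 + 3 * eval_waveform(p, t),
                          0, 24, subdivisions = 2000L)$value / 24
  expect_equal(Re(fourier_coefficient(p, 0)), avg, tolerance = 1e-6)
  expect_equal(Im(fourier_coefficient(p, 0)), 0, tolerance = 1e-12)
  # baseline touches only n = 0
  p0 <- fig2_params(amplitude = 3, baseline = 0)
  expect_equal(fourier_coefficient(p, 1:4), fourier_coefficient(p0, 1:4))
})

test_that("degenerate-rate coefficients agree with quadrature", {
  p <- waveform_params(1e-9, 0.5, -1e-9, 3, 5, 3.5, 24)
  for (n in 1:3) {
    or <- cn_quadrature(p, n)
    expect_lt(Mod(fourier_coefficient(p, n) - or) / Mod(or), 1e-7)
  }
})

test_that("Parseval's identity closes as harmonics accumulate", {
  p <- fig2_params()
  c0 <- Re(fourier_coefficient(p, 0))
  v <- stats::integrate(function(t) (eval_waveform(p, t) - c0)^2, 0, 24,
                        subdivisions = 2000L)$value / 24
  partial <- function(nmax)
    2 * sum(Mod(fourier_coefficient(p, seq_len(nmax)))^2)
  expect_lt(abs(partial(3000) - v) / v, 1e-6)
  expect_lt(abs(partial(300) - v), abs(partial(30) - v))
})

test_that("peak heights equal the FFT oracle at harmonic bins", {
  # one full period sampled at 2 s: the DFT bin n is the n-th harmonic
  # (fine sampling keeps the rectangle-rule aliasing below the tolerance)
  p <- fig2_params()
  x <- sample_waveform(p, 24, 2)
  N <- length(x)
  X <- fft(as.numeric(x)) / N
  hs <- peak_heights(p, n_max = 8)
  expect_equal(hs$height, Mod(X[2:9])^2, tolerance = 1e-6)
  expect_true(all(diff(hs$period) < 0))
  expect_equal(hs$period, p$t0 / hs$n)
})

test_that("peak heights scale quadratically with amplitude and vanish at zero", {
  h1 <- peak_heights(fig2_params(amplitude = 1), 6)$height
  h2 <- peak_heights(fig2_params(amplitude = 2), 6)$height
  h0 <- peak_heights(fig2_params(amplitude = 0), 6)$height
  expect_equal(h2, 4 * h1, tolerance = 1e-12)
  expect_true(all(h0 == 0))
})

test_that("power spectrum is invariant under time shift of the waveform", {
  # |FFT|^2 of the sampled waveform at harmonic bins must not depend on
  # where in the cycle the record starts
  p <- fig2_params()
  t <- seq(0, 24 - 1 / 120, by = 1 / 120)
  X0 <- Mod(fft(eval_waveform(p, t)) / length(t))^2
  X7 <- Mod(fft(eval_waveform(p, t + 7.3)) / length(t))^2
  expect_equal(X0[2:9], X7[2:9], tolerance = 1e-9)
})

test_that("small-period peak heights fall off with the fourth power", {
  sl <- small_period_exponent(fig2_params())
  expect_equal(sl, 4, tolerance = 0.1)
  # slope is invariant to amplitude rescaling
  expect_equal(small_period_exponent(fig2_params(amplitude = 5)), sl,
               tolerance = 1e-6)
  expect_error(small_period_exponent(fig2_params(), n_max = 200),
               "raise n_max")
})

test_that("harmonic ranking matches the FFT of a multiday sampled record", {
  p <- fig2_params()
  x <- sample_waveform(p, 5 * 24, 60)
  N <- length(x)
  X <- Mod(fft(as.numeric(x)) / N)^2
  fft_h <- X[5 * (1:8) + 1] # five cycles: harmonic n sits at bin 5n
  hs <- peak_heights(p, 8)$height
  expect_equal(order(fft_h), order(hs))
  expect_equal(which.max(hs), 2) # the 12 h harmonic dominates
})

test_that("Dirichlet side peaks obey the finite-record geometry", {
  sp1 <- dirichlet_sidepeaks(120, 12)
  sp2 <- dirichlet_sidepeaks(240, 12)
  expect_equal(sp1$freq - 1 / 12,
               sp1$side * (2 * sp1$m + 1) / (2 * 120))
  # side-lobe spacing halves when the record doubles
  off1 <- sort(abs(sp1$freq - 1 / 12))
  off2 <- sort(abs(sp2$freq - 1 / 12))
  expect_equal(off1[1], 2 * off2[1])
  expect_true(all(diff(sp1$rel_height[sp1$side == 1]) < 0))
  expect_error(dirichlet_sidepeaks(10, 12))
})

test_that("predicted side peaks line up with the minor spectral peaks", {
  # LS of the noise-free 5-day record, keeping side lobes
  x <- sample_waveform(fig2_params(), 120, 20)
  pg <- lomb_scargle(x)
  # raw grid maxima: side lobes are kernel structures, so no line-centre
  # refinement is appropriate here
  pw <- pg$power
  i <- which(pw[2:(length(pw) - 1)] > pw[1:(length(pw) - 2)] &
               pw[2:(length(pw) - 1)] >= pw[3:length(pw)]) + 1
  fmax <- pg$freq[i]
  sp <- dirichlet_sidepeaks(120, 12, m_max = 2)
  for (f in sp$freq) {
    near <- min(abs(fmax - f))
    expect_lt(near, 1 / (2 * 120))
  }
})

test_that("harmonic spectrum serializes as tab-delimited text", {
  hs <- peak_heights(fig2_params(), 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonic_spectrum(hs, path)
  back <- utils::read.delim(path)
  expect_equal(back$height, hs$height, tolerance = 1e-12)
  expect_equal(back$n, 1:5)
})
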