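test_that("LS of an evenly sampled series matches the classical periodogram", {
  set.seed(11)
  n <- 1200
  dt_h <- 1 / 12 # 5-min bins
  t <- (seq_len(n) - 1) * dt_h
  x <- sin(2 * pi * t / 24) + 0.4 * cos(2 * pi * t / 7) + rnorm(n)
  pg <- lomb_scargle(x, period_range = c(2, 35), bin_width_s = 300)
  xc <- x - mean(x)
  s2 <- sum(xc^2) / (n - 1)
  # interior natural Fourier frequencies of the record
  span <- n * dt_h
  fk <- (ceiling(span / 30):floor(span / 3)) / span
  classical <- vapply(fk, function(f)
    Mod(sum(xc * exp(-2i * pi * f * t)))^2 / (n * s2), 0)
  ls_at <- pg$power[match(round(fk * span * pg$oversample),
                          round(pg$freq * span * pg$oversample))]
  expect_equal(ls_at, classical, tolerance = 1e-6)
})

test_that("a pure sinusoid yields one significant peak at its period", {
  t <- (0:8639) * 50 / 3600
  x <- sin(2 * pi * t / 24)
  pg <- lomb_scargle(x, bin_width_s = 50)
  pk <- detect_peaks(pg, p = 0.005)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$period, 24, tolerance = 24 / (24 * 5))
})

test_that("constant and degenerate inputs are rejected", {
  expect_error(lomb_scargle(rep(3, 1000), bin_width_s = 60), "variance")
  expect_error(lomb_scargle(1:3, bin_width_s = 60), "short")
  expect_error(significance_threshold(mesa(rnorm(2000) + 5,
                                           bin_width_s = 300,
                                           rebin_s = NULL)),
               "LS")
})

test_that("false-alarm calibration is consistent with white noise", {
  # Monte-Carlo: fraction of pure-noise records with any peak above the
  # p = 0.05 line should be near 0.05 under the independent-frequencies
  # approximation
  set.seed(42)
  hits <- vapply(1:200, function(i) {
    x <- rnorm(576)
    pg <- lomb_scargle(x, period_range = c(2, 35), bin_width_s = 300)
    any(pg$power > significance_threshold(pg, p = 0.05))
  }, TRUE)
  frac <- mean(hits)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.12)
})

test_that("MESA density of an AR(1) process matches the closed form", {
  set.seed(7)
  n <- 10000
  phi <- 0.6
  x <- as.numeric(stats::arima.sim(list(ar = phi), n)) + 10
  # Burg coefficient against the Yule-Walker closed form (lag-1
  # autocorrelation), both near the truth
  phi_burg <- stats::ar.burg(x, aic = FALSE, order.max = 1)$ar
  r1 <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(phi_burg, r1, tolerance = 0.01)
  expect_equal(phi_burg, phi, tolerance = 0.02)
  pg <- mesa(x, order = 1, rebin_s = NULL, bin_width_s = 300,
             period_range = c(0.5, 20))
  dt <- 300 / 3600
  theory <- stats::var(x) * (1 - phi^2) * dt /
    Mod(1 - phi * exp(-2i * pi * pg$freq * dt))^2
  expect_equal(pg$power, theory, tolerance = 0.1)
})

test_that("MESA and LS peak positions agree on rhythmic records", {
  agree <- vapply(1:3, function(s) {
    rec <- simulate_activity("wt", days = 5, seed = 100 + s)
    pkl <- detect_peaks(lomb_scargle(rec))
    pkm <- detect_peaks(mesa(rec), threshold = 0, sidelobes = "keep")
    # the dominant harmonics (12, 6, 8 h) must agree within 2%
    top <- pkl[order(-pkl$power), ][1:3, ]
    max(vapply(top$period, function(p) {
      j <- which.min(abs(pkm$freq - 1 / p))
      abs(pkm$period[j] - p) / p
    }, 0))
  }, 0)
  expect_lt(max(agree), 0.02)
})

test_that("MESA of white noise is flat and unstable fits are caught", {
  set.seed(3)
  pg <- mesa(rnorm(4000) + 8, order = 12, rebin_s = NULL,
             bin_width_s = 300)
  expect_lt(max(pg$power) / min(pg$power), 3)
  expect_error(mesa(rnorm(50), order = 30, rebin_s = NULL,
                    bin_width_s = 300), "order")
})

test_that("autocorrelation is exact at lag zero and bounded", {
  rec <- simulate_activity("wt", days = 3, seed = 5)
  ac <- autocorrelation(rec, max_lag_h = 30)
  expect_equal(ac$correlation[1], 1)
  expect_equal(ac$lag_h[1], 0)
  expect_true(all(abs(ac$correlation) <= 1 + 1e-12))
  expect_equal(ac$sig_bound, 2 / sqrt(ac$N))
  expect_error(autocorrelation(rec, max_lag_h = 40), "half")
})

test_that("the model waveform autocorrelation peaks near 12 and 24 h", {
  x <- sample_waveform(fig2_params(), 120, 20)
  ac <- autocorrelation(x, max_lag_h = 30)
  locmax <- which(diff(sign(diff(ac$correlation))) == -2) + 1
  sig <- locmax[ac$correlation[locmax] > ac$sig_bound]
  lags <- ac$lag_h[sig]
  expect_true(any(abs(lags - 12) < 0.25))
  expect_true(any(abs(lags - 24) < 0.25))
})

test_that("white-noise autocorrelations stay inside the 2/sqrt(N) bound", {
  set.seed(9)
  frac <- vapply(1:20, function(i) {
    ac <- autocorrelation(rnorm(2000), max_lag_h = 10,
                          bin_width_s = 60)
    mean(abs(ac$correlation[-1]) < ac$sig_bound)
  }, 0)
  expect_gt(mean(frac), 0.90) # ~95% expected
})

test_that("peak detection handles flat spectra and rescaling", {
  set.seed(21)
  x <- rnorm(2000)
  pg <- lomb_scargle(x, bin_width_s = 300)
  expect_equal(nrow(detect_peaks(pg, threshold = max(pg$power) + 1)), 0)
  # invariance under joint rescaling of power and threshold
  pg2 <- pg
  pg2$power <- pg$power * 37
  pk1 <- detect_peaks(pg, threshold = 2)
  pk2 <- detect_peaks(pg2, threshold = 74)
  expect_equal(pk2$period, pk1$period)
  expect_equal(pk2$power, 37 * pk1$power)
})

test_that("two injected sinusoids give exactly two significant peaks", {
  t <- (0:8639) * 50 / 3600
  x <- sin(2 * pi * t / 24) + 0.8 * sin(2 * pi * t / 5 + 1)
  pk <- detect_peaks(lomb_scargle(x, bin_width_s = 50), p = 0.005)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$period), c(5, 24), tolerance = 0.02)
})

test_that("side lobes of a strong line are excluded, not reported", {
  x <- sample_waveform(fig2_params(), 120, 20)
  pg <- lomb_scargle(x)
  kept <- detect_peaks(pg, sidelobes = "drop")
  full <- detect_peaks(pg, sidelobes = "keep")
  expect_gt(nrow(full), nrow(kept))
  # every kept peak is a harmonic of 24 h; dropped ones include
  # off-harmonic side lobes
  dev_kept <- abs(kept$period - 24 / round(24 / kept$period)) /
    (24 / round(24 / kept$period))
  expect_lt(max(dev_kept), 0.05)
  sl <- attr(kept, "sidelobes")
  expect_gt(nrow(sl), 0)
})

test_that("periodograms serialize to tab-delimited text", {
  rec <- simulate_activity("wt", days = 2, bin_width_s = 300, seed = 2)
  pg <- lomb_scargle(rec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(pg, path)
  back <- utils::read.delim(path)
  expect_equal(back$power, pg$power, tolerance = 1e-12)
})
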