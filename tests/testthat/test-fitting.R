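# synthetic periodogram whose only structure is exact analytic harmonic
# peaks, for testing the spectral stage in isolation
synthetic_harmonic_pg <- function(params, scale = 1e6, span = 120,
                                  oversample = 8) {
  df <- 1 / (oversample * span)
  k <- seq.int(ceiling(1 / (35 * df)), floor(1 / (2 * df)))
  freq <- k * df
  power <- rep(1e-6, length(freq))
  hs <- peak_heights(params, n_max = floor(params$t0 / 2))
  for (i in seq_len(nrow(hs))) {
    j <- which.min(abs(freq - 1 / hs$period[i]))
    power[j] <- scale * hs$height[i]
  }
  structure(list(freq = freq, period = 1 / freq, power = power,
                 method = "LS", N = span * 180, span_h = span,
                 oversample = oversample, period_range = c(2, 35)),
            class = "periodogram")
}

test_that("primary period estimation follows the regime conventions", {
  rec <- waveform_record()
  pg <- lomb_scargle(rec)
  expect_equal(estimate_primary_period(pg, "DD"), 24, tolerance = 0.03)
  # LD: the 12 h harmonic is the strongest line; its doubled period is T0
  expect_equal(estimate_primary_period(pg, "LD"), 24, tolerance = 0.01)
  # a mutant preset record recovers its own period
  rec2 <- simulate_cohort("perS", n_flies = 1, days = 6,
                          t0_jitter_sd = 0, seed = 2)[[1]]
  expect_equal(estimate_primary_period(lomb_scargle(rec2), "DD"), 19,
               tolerance = 0.02 * 19)
})

test_that("arrhythmic records raise a catchable condition", {
  rec <- simulate_activity("per0", days = 5, baseline_rate = 0.25,
                           seed = 3)
  pg <- lomb_scargle(rec)
  expect_error(estimate_primary_period(pg, "DD"),
               class = "flyrhythm_arrhythmic")
  caught <- tryCatch(estimate_primary_period(pg, "DD"),
                     flyrhythm_arrhythmic = function(e) "arrhythmic")
  expect_equal(caught, "arrhythmic")
})

test_that("percent error follows the signed formula", {
  expect_equal(percent_error(10, 10), 0)
  expect_equal(percent_error(10, 9), 10)
  expect_equal(percent_error(8, 10), -25)
  expect_equal(percent_error(c(10, 8), c(9, 10)), c(10, -25))
  expect_error(percent_error(0, 1), "positive")
})

test_that("harmonic matching is greedy, tolerant, and conventioned", {
  harm <- 24 / (1:8)
  hm <- harmonic_match(harm, 24)
  expect_equal(hm$fraction, 100)
  expect_equal(hm$matches$n, 1:8)
  # peaks 12% off the low harmonics (whose neighbours are well separated)
  # match nothing at 10% tolerance
  hm2 <- harmonic_match(24 / (1:4) * 1.12, 24, period_range = c(5, 35))
  expect_equal(hm2$fraction, 0)
  # each harmonic absorbs at most one peak: a near-exact and a 7%-off
  # peak compete for the 12 h harmonic; only the nearer one matches
  hm3 <- harmonic_match(c(12.01, 12.84), 24, period_range = c(10, 14))
  expect_equal(hm3$fraction, 50)
  expect_equal(hm3$matches$period, 12.01)
  # empty list: arrhythmic convention
  hm4 <- harmonic_match(numeric(0), 24)
  expect_equal(hm4$fraction, 100)
  expect_equal(attr(hm4, "flag"), "no_peaks")
})

test_that("area accuracy spans its extremes", {
  p <- fig2_params()
  pg <- synthetic_harmonic_pg(p)
  hs <- peak_heights(p, 12)
  expect_equal(area_accuracy(pg, hs$period), 100, tolerance = 0.01)
  expect_equal(area_accuracy(pg, numeric(0)), 0)
  # flat white spectrum: two windows capture just the window fraction of
  # the band, 2 * (4/span) / (1/2 - 1/35) ~ 14%
  pg$power <- rep(1, length(pg$power))
  aa <- area_accuracy(pg, c(12, 8))
  expect_equal(aa, 100 * 2 * (4 / 120) / (1 / 2 - 1 / 35),
               tolerance = 0.02)
})

test_that("the time-domain stage recovers noise-free parameters", {
  rec <- waveform_record()
  ip <- initial_time_domain_fit(rec, 24)
  expect_equal(ip$t_m, 5.3, tolerance = 1 / 3 / 5.3) # one 20-min bin
  expect_equal(ip$t_e, 3.6, tolerance = 1 / 3 / 3.6)
  expect_equal(ip$b_md, -0.81, tolerance = 0.05)
  expect_equal(ip$b_mr, 0.486, tolerance = 0.05)
  expect_equal(ip$b_ed, 3.6, tolerance = 0.1)
  expect_lt(abs(ip$b_er - 0.09), 0.05)
  expect_lt(abs(attr(ip, "phase")), 0.2)
})

test_that("folding at a wrong period degrades the fit", {
  rec <- waveform_record()
  sse_right <- attr(initial_time_domain_fit(rec, 24), "sse")
  sse_wrong <- attr(initial_time_domain_fit(rec, 26.4), "sse")
  expect_gt(sse_wrong / sse_right, 2)
})

test_that("noisy records still constrain the exponential rates", {
  truth <- c(-0.81, 0.486, 0.09, 3.6)
  est <- vapply(0:7, function(s) {
    rec <- simulate_activity("wt", days = 5, seed = s)
    ip <- initial_time_domain_fit(rec, 24)
    c(ip$b_md, ip$b_mr, ip$b_er, ip$b_ed)
  }, numeric(4))
  rel <- abs(est - truth) / abs(truth)
  # well-scaled rates are recovered to ~25% on average; b_er ~ 0.09 1/h
  # is in its near-linear regime, so only an absolute bound is sensible
  expect_lt(mean(rel[1, ]), 0.25)
  expect_lt(mean(rel[2, ]), 0.25)
  expect_lt(mean(rel[4, ]), 0.25)
  expect_lt(mean(abs(est[3, ] - truth[3])), 0.25)
  # rise and evening-decay rates stay positive, as the model demands
  expect_true(all(est[2, ] > 0))
  expect_true(all(est[4, ] > 0))
})

test_that("the spectral stage reproduces exact analytic peak heights", {
  p <- fig2_params()
  pg <- synthetic_harmonic_pg(p, scale = 1e6)
  init <- waveform_params(-0.6, 0.6, 0.05, 3, 4.5, 4, 24,
                          amplitude = 30, baseline = 1)
  sf <- spectral_fit(pg, init, 24)
  sig <- sf$harmonics[sf$harmonics$significant, ]
  expect_gte(nrow(sig), 8)
  expect_lt(max(abs(sig$pe)), 0.5)
  expect_equal(sf$scale, 1e6, tolerance = 0.01)
  # objective never increased relative to the starting point
  expect_lte(sf$sse, sf$sse_init)
  # fewer than 3 significant harmonics is an error
  pg0 <- pg
  pg0$power <- pg0$power * 1e-9
  expect_error(spectral_fit(pg0, init, 24), "significant")
})

test_that("rate bounds are honoured by the spectral stage", {
  p <- fig2_params()
  pg <- synthetic_harmonic_pg(p)
  init <- waveform_params(-50, 55, 40, 58, 5, 3.6, 24,
                          amplitude = 30, baseline = 1)
  sf <- spectral_fit(pg, init, 24, b_max = 60)
  cf <- sf$params
  expect_true(all(abs(c(cf$b_md, cf$b_mr, cf$b_er, cf$b_ed)) <= 60))
})

test_that("the full model object behaves like an R fit", {
  rec <- simulate_activity("wt", days = 5, seed = 42)
  fit <- fit_activity_model(rec, regime = "LD")
  expect_s3_class(fit, "activity_fit")
  expect_equal(fit$t0, 24, tolerance = 0.05 * 24)
  cf <- coef(fit)
  expect_named(cf, c("b_md", "b_mr", "b_er", "b_ed", "t_m", "t_e",
                     "t0", "amplitude", "baseline"))
  expect_true(cf["b_mr"] > 0 && cf["b_ed"] > 0)
  expect_true(all(abs(cf[1:4]) <= 60))
  # predictions live on the folded-profile scale
  pr <- predict(fit)
  expect_length(pr, nrow(fit$profile))
  expect_equal(fitted(fit) + residuals(fit), fit$profile$y)
  # prediction correlates strongly with the day-folded data
  expect_gt(stats::cor(pr, fit$profile$y), 0.9)
  # simulate() round-trips through the same machinery
  sims <- stats::simulate(fit, nsim = 2, seed = 1, days = 2)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "activity_record")
  expect_false(identical(sims[[1]]$counts, sims[[2]]$counts))
  out <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("Harmonic peak table", out)))
  expect_true(any(grepl("P.E.", out, fixed = TRUE)))
})

test_that("amplitude-period fits recover planted relations", {
  t0 <- c(19, 24, 27, 29.5, 21, 26)
  fit <- amplitude_vs_period_fit(1.4 * t0, t0)
  expect_equal(fit$C, 1.4, tolerance = 1e-9)
  expect_equal(fit$adj_r2_linear, 1, tolerance = 1e-9)
  # saturating law with small k*t0 looks linear with slope
  # ~ c*k*(1 - k*t0bar/2) from the series expansion
  h <- 120 * (1 - exp(-0.012 * t0))
  fit2 <- amplitude_vs_period_fit(h, t0)
  expect_equal(fit2$C, 120 * 0.012 * (1 - 0.012 * mean(t0) / 2),
               tolerance = 0.02)
  expect_equal(fit2$c, 120, tolerance = 0.05 * 120)
  expect_equal(fit2$k, 0.012, tolerance = 0.05 * 0.012)
  expect_gt(fit2$adj_r2_exp, fit2$adj_r2_linear)
  expect_error(amplitude_vs_period_fit(h[1:2], t0[1:2]), "3")
  expect_error(amplitude_vs_period_fit(c(1, 2, 3), c(24, 24, 24)),
               "degenerate")
})

test_that("a mixed cohort shows the positive amplitude-period relation", {
  # flies with rate constants held fixed and widths scaling with the
  # period must show larger activity amplitude at longer periods
  h <- c(); t0s <- c()
  for (pre in c("perS", "wt", "timUL", "perL")) {
    rec <- simulate_cohort(pre, n_flies = 2, days = 5,
                           t0_jitter_sd = 0, seed = 21)
    for (r in rec) {
      tp <- attr(r, "true_params")
      ip <- initial_time_domain_fit(r, tp$t0)
      h <- c(h, attr(ip, "amplitude_h"))
      t0s <- c(t0s, tp$t0)
    }
  }
  fit <- amplitude_vs_period_fit(h, t0s)
  expect_gt(fit$C, 0)
  expect_gt(stats::cor(t0s, h), 0.5)
})
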