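# Shared fixtures: the reference parameter set used throughout (the
# published wild-type simulation parameters) and small record builders.

fig2_params <- function(t0 = 24, amplitude = 1, baseline = 0, ...) {
  waveform_params(b_md = -0.81, b_mr = 0.486, b_er = 0.09, b_ed = 3.6,
                  t_m = 5.3 * t0 / 24, t_e = 3.6 * t0 / 24, t0 = t0,
                  amplitude = amplitude, baseline = baseline, ...)
}

# random-but-valid parameter sets for property tests; morning and evening
# windows kept disjoint (t_m < t0/2 - t_e), as in all observed profiles
random_params <- function(seed) {
  set.seed(seed)
  t0 <- runif(1, 16, 32)
  t_m <- runif(1, 0.08, 0.35) * t0
  waveform_params(b_md = runif(1, -3, 3),
                  b_mr = runif(1, 0.1, 3),
                  b_er = runif(1, -3, 3),
                  b_ed = runif(1, 0.1, 5),
                  t_m = t_m,
                  t_e = runif(1, 0.08, 0.48 - t_m / t0) * t0,
                  t0 = t0)
}

# noise-free model record (real-valued counts are allowed in records)
waveform_record <- function(params = fig2_params(), days = 5,
                            bin_width_s = 20, amplitude = 30,
                            baseline = 1, regime = "LD") {
  x <- sample_waveform(params, days * 24, bin_width_s)
  activity_record(baseline + amplitude * as.numeric(x),
                  bin_width_s = bin_width_s, light_regime = regime,
                  genotype = "model")
}

# numerical quadrature oracle for the Fourier coefficient of the
# four-exponential waveform (independent of the closed form under test)
cn_quadrature <- function(params, n) {
  f <- function(t) params$baseline +
    params$amplitude * eval_waveform(params, t)
  re <- stats::integrate(function(t) f(t) * cos(2 * pi * n * t / params$t0),
                         0, params$t0, subdivisions = 2000L,
                         rel.tol = 1e-12)$value
  im <- stats::integrate(function(t) f(t) * sin(2 * pi * n * t / params$t0),
                         0, params$t0, subdivisions = 2000L,
                         rel.tol = 1e-12)$value
  complex(real = re, imaginary = im) / params$t0
}
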