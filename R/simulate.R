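# Inhomogeneous Poisson simulation of activity-monitor recordings.
#
# Counts per 20-s bin are small integers, so Poisson noise around the
# deterministic waveform mean is the natural generative model; a
# negative-binomial overdispersion hook is provided but off by default.
# The rate scale default puts 20-min-binned peak counts at roughly 30-60,
# matching the scale of real population recordings.

# run expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Genotype presets for the activity simulator
#'
#' Waveform parameter presets emulating the canonical genotypes: wild
#' type (primary period 24 h, the reference rate and width set), the
#' short- and long-period clock mutants `perS` (19 h) and `perL`
#' (29.5 h), `timUL` (27 h), and the arrhythmic controls `per0` (DD) and
#' `ll` (wild type in constant light), both simulated as constant-rate
#' (zero-amplitude) records.  Mutant peak widths scale with the period as
#' `t_m = 0.19 t0` and `t_e = 0.29 t0`; rates are genotype-independent.
#'
#' @param preset Preset name.
#' @return List with elements `params` ([waveform_params]) and
#'   `light_regime`.
#' @export
genotype_preset <- function(preset = c("wt", "perS", "perL", "timUL",
                                       "per0", "ll")) {
  preset <- match.arg(preset)
  base <- list(b_md = -0.81, b_mr = 0.486, b_er = 0.09, b_ed = 3.6)
  mk <- function(t0, t_m = 0.19 * t0, t_e = 0.29 * t0, amplitude = 1)
    waveform_params(base$b_md, base$b_mr, base$b_er, base$b_ed,
                    t_m, t_e, t0, amplitude = amplitude)
  switch(preset,
    wt    = list(params = mk(24, t_m = 5.3, t_e = 3.6),
                 light_regime = "LD"),
    perS  = list(params = mk(19), light_regime = "DD"),
    perL  = list(params = mk(29.5), light_regime = "DD"),
    timUL = list(params = mk(27), light_regime = "DD"),
    per0  = list(params = mk(24, t_m = 5.3, t_e = 3.6, amplitude = 0),
                 light_regime = "DD"),
    ll    = list(params = mk(24, t_m = 5.3, t_e = 3.6, amplitude = 0),
                 light_regime = "LL"))
}

#' Simulate an activity-monitor recording
#'
#' Draws counts independently per bin from a Poisson law with mean
#' `baseline_rate + rate_scale * F(t)`, where `F` is the model waveform
#' of the chosen genotype preset (or custom parameters).  Arrhythmic
#' presets have zero amplitude, i.e. a constant mean.  Deterministic
#' under a fixed seed.
#'
#' @param preset Genotype preset name (see [genotype_preset]); ignored
#'   when `params` is given.
#' @param days Recording length in days (>= 2).
#' @param bin_width_s Bin width in seconds (default 20).
#' @param rate_scale Expected counts per bin where the waveform is at its
#'   unit maximum.  The default 0.8 puts 20-min-binned peaks at ~40-50
#'   counts.
#' @param baseline_rate Expected counts per bin where the waveform is
#'   zero (default 0.05).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param params Optional [waveform_params] overriding the preset shape.
#' @param t0 Optional primary-period override (peak widths are rescaled
#'   proportionally).
#' @param dispersion If given, counts are negative binomial with this
#'   `size` parameter instead of Poisson (overdispersion hook).
#' @param light_regime,genotype Annotation overrides.
#' @return An [activity_record].
#' @examples
#' rec <- simulate_activity("wt", days = 2, bin_width_s = 300, seed = 1)
#' rec
#' @export
simulate_activity <- function(preset = "wt", days = 5, bin_width_s = 20,
                              rate_scale = 0.8, baseline_rate = 0.05,
                              seed = NULL, params = NULL, t0 = NULL,
                              dispersion = NULL, light_regime = NULL,
                              genotype = NULL) {
  stopifnot(days >= 2, rate_scale >= 0, baseline_rate >= 0)
  pre <- if (is.null(params)) genotype_preset(preset)
         else list(params = params, light_regime = "DD")
  wp <- pre$params
  if (!is.null(t0)) {
    sc <- t0 / wp$t0
    wp <- waveform_params(wp$b_md, wp$b_mr, wp$b_er, wp$b_ed,
                          wp$t_m * sc, wp$t_e * sc, t0,
                          amplitude = wp$amplitude,
                          baseline = wp$baseline, e_ratio = wp$e_ratio)
  }
  t <- (seq_len(round(days * 86400 / bin_width_s)) - 1) * bin_width_s / 3600
  lam <- baseline_rate +
    rate_scale * wp$amplitude * eval_waveform(wp, t)
  counts <- .with_seed(seed, {
    if (is.null(dispersion)) stats::rpois(length(lam), lam)
    else stats::rnbinom(length(lam), size = dispersion, mu = lam)
  })
  rec <- activity_record(counts, bin_width_s = bin_width_s,
                         light_regime = light_regime %||% pre$light_regime,
                         lights_on_h = 0,
                         genotype = genotype %||%
                           (if (is.null(params)) preset else "custom"))
  attr(rec, "true_params") <- wp
  attr(rec, "rate_scale") <- rate_scale
  attr(rec, "baseline_rate") <- baseline_rate
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of flies
#'
#' Generates `n_flies` records from one genotype preset with per-fly
#' circadian periods drawn from a normal distribution around the preset
#' period.  Peak widths follow the period (`t_m = 0.19 t0`,
#' `t_e = 0.29 t0`); rates stay at the preset values.  A single master
#' seed deterministically derives per-fly substream seeds.
#'
#' @param preset Genotype preset name.
#' @param n_flies Number of flies.
#' @param days Recording length in days.
#' @param t0_jitter_sd SD of the per-fly period, h (default 0.3, a
#'   typical within-genotype spread).
#' @param seed Master seed.
#' @param rate_scale Peak count rate of a fly at the preset period (see
#'   [simulate_activity]).
#' @param amplitude_scaling Scale each fly's activity amplitude with its
#'   period (default `TRUE`).  With the exponential rates held fixed, a
#'   process that accumulates over a window growing with the period
#'   reaches a higher level before release, so the per-fly peak rate is
#'   multiplied by the evening-accumulation ratio
#'   `(1 - exp(-b_er * t_e(t0))) / (1 - exp(-b_er * t_e(24)))`
#'   (referenced to the 24 h wild-type period so that the law is shared
#'   across genotypes), which grows roughly linearly with `t0`.
#' @param ... Further arguments to [simulate_activity] (bin width,
#'   baseline rate, ...).
#' @return List of [activity_record] objects; each carries its generating
#'   parameters in the `true_params` attribute.
#' @export
simulate_cohort <- function(preset = "wt", n_flies = 10, days = 6,
                            t0_jitter_sd = 0.3, seed = 0,
                            rate_scale = 0.8, amplitude_scaling = TRUE,
                            ...) {
  stopifnot(n_flies >= 1, t0_jitter_sd >= 0)
  pre <- genotype_preset(preset)
  draws <- .with_seed(seed, list(
    t0 = stats::rnorm(n_flies, pre$params$t0, t0_jitter_sd),
    sub = sample.int(.Machine$integer.max - 1L, n_flies)))
  accum <- function(t0) -expm1(-pre$params$b_er * 0.29 * t0)
  lapply(seq_len(n_flies), function(i) {
    rs <- if (amplitude_scaling)
      rate_scale * accum(draws$t0[i]) / accum(24)
    else rate_scale
    rec <- simulate_activity(preset, days = days, seed = draws$sub[i],
                             t0 = draws$t0[i], rate_scale = rs, ...)
    rec$channel_id <- sprintf("ch%02d", i)
    rec
  })
}
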