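# Periodic four-exponential model of daily locomotor activity.
#
# The waveform F(t) is the superposition of a morning (M) component -- an
# exponential decay with rate b_md over (0, T_M) preceded by an exponential
# rise with rate b_mr over (T_M, T0) of the previous cycle -- and an evening
# (E) component -- an exponential rise with rate b_er over (T0/2 - T_E, T0/2)
# followed by a decay with rate b_ed after T0/2.  Each branch is normalized
# to run between 0 and 1; b_mr and b_ed must be positive while b_md and b_er
# may take either sign (convex or concave flanks).

#' Parameters of the periodic four-exponential activity waveform
#'
#' Bundles the six shape parameters of the daily activity model -- four
#' exponential rates and the two peak widths -- together with the primary
#' period, an amplitude, a baseline, and an optional evening/morning
#' amplitude ratio.
#'
#' The waveform is built from two unit-amplitude components: the morning
#' peak, with maximum at `t = 0` (lights-on), decays with rate `b_md` over
#' `(0, t_m)` and is rebuilt by a rise with rate `b_mr` over `(t_m, t0)`;
#' the evening peak rises with rate `b_er` over `(t0/2 - t_e, t0/2)` to a
#' maximum at `t = t0/2` (lights-off) and decays with rate `b_ed`
#' afterwards.  `b_mr` and `b_ed` must be strictly positive; `b_md` and
#' `b_er` can take either sign, flipping the corresponding flank between
#' concave and convex.
#'
#' @param b_md Morning-decay rate, 1/h.  Any sign.
#' @param b_mr Morning-rise rate, 1/h.  Must be positive.
#' @param b_er Evening-rise rate, 1/h.  Any sign.
#' @param b_ed Evening-decay rate, 1/h.  Must be positive.
#' @param t_m Morning peak width, h; `0 < t_m < t0`.
#' @param t_e Evening peak width, h; `0 < t_e <= t0/2`.
#' @param t0 Primary period, h.
#' @param amplitude Non-negative scale factor applied to the unit waveform
#'   when sampling (counts scale).
#' @param baseline Non-negative offset added when sampling (counts scale).
#' @param e_ratio Amplitude of the evening component relative to the
#'   morning component.  Default 1 (equal unit amplitudes); fitted rates
#'   normally absorb any M/E asymmetry.
#'
#' @return An object of class `waveform_params`.
#' @examples
#' wp <- waveform_params(b_md = -0.81, b_mr = 0.486, b_er = 0.09,
#'                       b_ed = 3.6, t_m = 5.3, t_e = 3.6, t0 = 24)
#' eval_waveform(wp, c(0, 5.3, 12, 14))
#' @export
waveform_params <- function(b_md, b_mr, b_er, b_ed, t_m, t_e, t0 = 24,
                            amplitude = 1, baseline = 0, e_ratio = 1) {
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0), t0 > 0)
  vals <- c(b_md = b_md, b_mr = b_mr, b_er = b_er, b_ed = b_ed,
            t_m = t_m, t_e = t_e, amplitude = amplitude,
            baseline = baseline, e_ratio = e_ratio)
  if (!all(is.finite(vals)))
    stop("all waveform parameters must be finite")
  if (b_mr <= 0 || b_ed <= 0)
    stop("b_mr and b_ed must be strictly positive")
  if (t_m <= 0 || t_m >= t0)
    stop("t_m must lie in (0, t0)")
  if (t_e <= 0 || t_e > t0 / 2)
    stop("t_e must lie in (0, t0/2]")
  if (amplitude < 0 || baseline < 0)
    stop("amplitude and baseline must be non-negative")
  structure(list(b_md = b_md, b_mr = b_mr, b_er = b_er, b_ed = b_ed,
                 t_m = t_m, t_e = t_e, t0 = t0, amplitude = amplitude,
                 baseline = baseline, e_ratio = e_ratio),
            class = "waveform_params")
}

#' @export
print.waveform_params <- function(x, ...) {
  cat("Activity waveform parameters (T0 =", format(x$t0), "h)\n")
  cat(sprintf("  rates  [1/h]: b_md = %.4g, b_mr = %.4g, b_er = %.4g, b_ed = %.4g\n",
              x$b_md, x$b_mr, x$b_er, x$b_ed))
  cat(sprintf("  widths [h]  : t_m = %.4g, t_e = %.4g\n", x$t_m, x$t_e))
  cat(sprintf("  amplitude = %.4g, baseline = %.4g, E/M ratio = %.4g\n",
              x$amplitude, x$baseline, x$e_ratio))
  invisible(x)
}

# rate magnitudes below this are evaluated by their linear-ramp limit
.rate_eps <- 1e-6

# morning-decay branch (e^{b t_m} - e^{b t})/(e^{b t_m} - 1) on [0, t_m),
# written to avoid overflow for either sign of b
.branch_md <- function(t, b, t_m) {
  if (abs(b) < .rate_eps) return(1 - t / t_m)
  if (b > 0) {
    # divide through by e^{b t_m}
    (1 - exp(b * (t - t_m))) / (-expm1(-b * t_m))
  } else {
    (exp(b * t_m) - exp(b * t)) / expm1(b * t_m)
  }
}

# morning-rise branch (e^{b(t - t_m)} - 1)/e^{b(t0 - t_m)} on [t_m, t0); b > 0
.branch_mr <- function(t, b, t_m, t0) {
  exp(b * (t - t0)) - exp(-b * (t0 - t_m))
}

# evening-rise branch (1 - e^{-b(t - t0/2 + t_e)})/(1 - e^{-b t_e})
# on [t0/2 - t_e, t0/2); either sign of b
.branch_er <- function(t, b, t_e, t0) {
  x <- t - (t0 / 2 - t_e)
  if (abs(b) < .rate_eps) return(x / t_e)
  if (b > 0) {
    expm1(-b * x) / expm1(-b * t_e)
  } else {
    # multiply through by e^{b t_e}; exponents stay non-positive
    (exp(b * t_e) - exp(b * (t_e - x))) / expm1(b * t_e)
  }
}

# evening-decay branch e^{-b(t - t0/2)} on [t0/2, t0); b > 0
.branch_ed <- function(t, b, t0) exp(-b * (t - t0 / 2))

#' Evaluate the periodic activity waveform
#'
#' Evaluates the unit-amplitude model waveform `F(t)` at arbitrary times.
#' Times are reduced modulo the primary period; branch domains are
#' half-open `[start, end)`, so at `t = t0/2` the evening-decay branch
#' (value 1) applies and the evening-rise branch does not.  The branch
#' domains overlap (the morning rise spans `(t_m, t0)` and contains the
#' whole evening component); by default all branches active at `t` are
#' summed, which superposes a unit morning and a unit evening component
#' and produces the characteristic two-peaked daily profile.  Rates with
#' magnitude below 1e-6 1/h are evaluated by their analytic linear-ramp
#' limit rather than the 0/0 ratio.
#'
#' @param params A [waveform_params] object.
#' @param t Times in hours (any real values).
#' @param overlap `"sum"` (default) superposes all branches active at `t`;
#'   `"last"` keeps only the last-starting branch, for comparison.
#' @return Numeric vector of dimensionless activity levels (amplitude and
#'   baseline are *not* applied; see [sample_waveform]).
#' @seealso [sample_waveform], [fourier_coefficient]
#' @export
eval_waveform <- function(params, t, overlap = c("sum", "last")) {
  stopifnot(inherits(params, "waveform_params"))
  overlap <- match.arg(overlap)
  p <- params
  tt <- t %% p$t0
  md <- mr <- er <- ed <- rep(0, length(tt))
  i <- tt < p$t_m
  if (any(i)) md[i] <- .branch_md(tt[i], p$b_md, p$t_m)
  i <- tt >= p$t_m
  if (any(i)) mr[i] <- .branch_mr(tt[i], p$b_mr, p$t_m, p$t0)
  i <- tt >= (p$t0 / 2 - p$t_e) & tt < p$t0 / 2
  if (any(i)) er[i] <- .branch_er(tt[i], p$b_er, p$t_e, p$t0)
  i <- tt >= p$t0 / 2
  if (any(i)) ed[i] <- .branch_ed(tt[i], p$b_ed, p$t0)
  if (overlap == "sum") {
    md + mr + p$e_ratio * (er + ed)
  } else {
    # last-starting branch wins: ED from t0/2, ER from t0/2 - t_e,
    # MR from t_m, MD from 0
    out <- md
    out[tt >= p$t_m] <- mr[tt >= p$t_m]
    i <- tt >= (p$t0 / 2 - p$t_e) & tt < p$t0 / 2
    out[i] <- p$e_ratio * er[i]
    out[tt >= p$t0 / 2] <- p$e_ratio * ed[tt >= p$t0 / 2]
    out
  }
}

#' Sample the model waveform on a uniform grid
#'
#' Returns `baseline + amplitude * F(t)` evaluated at bin start times
#' `i * dt`, `i = 0, 1, ...`, emulating a multiday activity recording of
#' the noise-free model.
#'
#' @param params A [waveform_params] object.
#' @param duration_h Record length in hours.
#' @param dt_s Sampling interval in seconds (default 20, the standard
#'   activity-monitor bin).
#' @return Numeric vector of length `floor(duration_h * 3600 / dt_s)` with
#'   attributes `dt_s` and `time_h` (sample times in hours).
#' @examples
#' wp <- waveform_params(-0.81, 0.486, 0.09, 3.6, 5.3, 3.6, 24)
#' x <- sample_waveform(wp, duration_h = 48, dt_s = 300)
#' @export
sample_waveform <- function(params, duration_h, dt_s = 20) {
  stopifnot(inherits(params, "waveform_params"),
            duration_h > 0, dt_s > 0)
  dt_h <- dt_s / 3600
  if (dt_h > params$t0)
    stop("sampling interval exceeds the primary period; fundamental is beyond Nyquist")
  n <- floor(duration_h / dt_h)
  t <- (seq_len(n) - 1) * dt_h
  x <- params$baseline + params$amplitude * eval_waveform(params, t)
  attr(x, "dt_s") <- dt_s
  attr(x, "time_h") <- t
  x
}

#' Comparison waveforms: square and sawtooth
#'
#' Unit-amplitude periodic reference waveforms used to contrast the
#' harmonic content of simpler shapes with the four-exponential model: a
#' square wave only carries odd harmonics, a sawtooth carries all
#' harmonics with power falling as `1/n^2`.
#'
#' @param t0 Period in hours.
#' @param duty Fraction of the period spent at 1 (square wave only).
#' @return A function of time (hours) returning values in `[0, 1]`,
#'   suitable for [sample_series].
#' @examples
#' sq <- square_wave(24, duty = 0.5)
#' mean(sq(seq(0, 24, by = 1 / 60)))
#' @export
square_wave <- function(t0, duty = 0.5) {
  stopifnot(t0 > 0, duty > 0, duty < 1)
  function(t) as.numeric((t %% t0) < duty * t0)
}

#' @rdname square_wave
#' @export
sawtooth_wave <- function(t0) {
  stopifnot(t0 > 0)
  function(t) (t %% t0) / t0
}

#' Sample an arbitrary waveform function on a uniform grid
#'
#' Same sampling contract as [sample_waveform] for plain functions of
#' time, e.g. the [square_wave] and [sawtooth_wave] comparison waveforms.
#'
#' @param fun Function of time in hours.
#' @param duration_h Record length in hours.
#' @param dt_s Sampling interval in seconds.
#' @return Numeric vector with attributes `dt_s` and `time_h`.
#' @export
sample_series <- function(fun, duration_h, dt_s = 20) {
  stopifnot(is.function(fun), duration_h > 0, dt_s > 0)
  dt_h <- dt_s / 3600
  n <- floor(duration_h / dt_h)
  t <- (seq_len(n) - 1) * dt_h
  x <- fun(t)
  attr(x, "dt_s") <- dt_s
  attr(x, "time_h") <- t
  x
}

#' Export a sampled waveform as two-column plain text
#'
#' Writes `time_h<TAB>value` lines, the package's plotting interchange
#' format for waveforms.
#'
#' @param x A vector from [sample_waveform] or [sample_series].
#' @param path Output file path.
#' @export
write_waveform <- function(x, path) {
  t <- attr(x, "time_h")
  if (is.null(t)) stop("'x' must come from sample_waveform()/sample_series()")
  utils::write.table(data.frame(time_h = t, value = as.numeric(x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
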