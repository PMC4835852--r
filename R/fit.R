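# Two-stage parameter estimation.
#
# Stage 1 (time domain): the record is folded at the primary period into
# 20-min bins; peak widths are read off the folded profile and all shape
# parameters are refined by bounded nonlinear least squares against
# baseline + amplitude * F(t).
# Stage 2 (spectral domain): measured periodogram peak heights at the
# harmonics t0/n are fitted with the analytic heights H(T_n) times a
# single free scale, rates bounded to +-60 1/h.
# fit_activity_model() chains period estimation, both stages and the
# accuracy metrics into one classed model object.

#' Estimate the primary period from a periodogram
#'
#' In constant darkness the primary period is the position of the tallest
#' significant peak in the circadian band (16--35 h).  Under a 12:12
#' light/dark cycle the 12 h harmonic is typically the strongest line, so
#' the period is set by doubling the position of the tallest significant
#' peak in the 8--16 h band.
#'
#' @param pg A `periodogram` (Lomb-Scargle).
#' @param regime `"DD"` (or `"LL"`) or `"LD"`.
#' @param p False-alarm probability for significance.
#' @param circadian_band,harmonic_band Search bands in h.
#' @return Primary period `t0` in h.  If no significant peak lies in the
#'   band, an error of class `flyrhythm_arrhythmic` is signalled; callers
#'   may catch it to declare the record arrhythmic.
#' @export
estimate_primary_period <- function(pg, regime = c("DD", "LD", "LL"),
                                    p = 0.005,
                                    circadian_band = c(16, 35),
                                    harmonic_band = c(8, 16)) {
  regime <- match.arg(regime)
  # no side-lobe exclusion here: the tallest peak in the band is never a
  # side lobe (lobes are <5% of their parent line), while a weak
  # circadian fundamental could be mistaken for one and discarded
  pk <- detect_peaks(pg, p = p, sidelobes = "keep")
  band <- if (regime == "LD") harmonic_band else circadian_band
  pk <- pk[pk$period >= band[1] & pk$period <= band[2], , drop = FALSE]
  if (!nrow(pk))
    stop(errorCondition(
      sprintf("no significant peak in the %g-%g h band: record appears arrhythmic",
              band[1], band[2]),
      class = c("flyrhythm_arrhythmic", "error", "condition")))
  if (regime == "LD") 2 * pk$period[1] else pk$period[1]
}

#' Fold a record at the primary period
#'
#' Rebins to `bin_s` (default 20 min) and averages counts over cycles,
#' assigning each bin midpoint to a phase bin modulo `t0`.  Because the
#' fold bins need not align with the rebinned grid, multiday records fill
#' the profile densely even for non-integer `t0`.
#'
#' @param record An [activity_record].
#' @param t0 Fold period, h.
#' @param bin_s Rebin width in seconds before folding.
#' @return Data frame with columns `t` (phase-bin midpoints, h) and `y`
#'   (mean counts per rebinned bin).
#' @export
fold_profile <- function(record, t0, bin_s = 1200) {
  stopifnot(inherits(record, "activity_record"), t0 > 0)
  rb <- if (record$bin_width_s < bin_s) rebin(record, bin_s) else record
  if (length(rb$counts) * rb$bin_width_s / 3600 < 3 * t0)
    warning("fewer than 3 full periods of data; folded profile will be noisy")
  mid <- record_times_h(rb) + rb$bin_width_s / 7200
  ph <- mid %% t0
  nb <- max(24L, round(t0 * 3))
  idx <- pmin(nb, floor(ph / (t0 / nb)) + 1)
  agg <- tapply(rb$counts, idx, mean)
  data.frame(t = (as.numeric(names(agg)) - 0.5) * t0 / nb,
             y = as.numeric(agg))
}

# phase of lights-on: circular cross-correlation of the folded profile
# against a canonical waveform template
.estimate_phase <- function(prof, t0) {
  tmpl_p <- waveform_params(-0.81, 0.486, 0.09, 3.6,
                            0.19 * t0, 0.29 * t0, t0)
  best <- c(shift = 0, cor = -Inf)
  for (s in prof$t) {
    v <- eval_waveform(tmpl_p, (prof$t - s) %% t0)
    cc <- suppressWarnings(stats::cor(prof$y, v))
    if (is.finite(cc) && cc > best["cor"]) best <- c(shift = s, cor = cc)
  }
  unname(best["shift"])
}

# threshold-crossing width estimates for the morning and evening peaks
.init_widths <- function(prof, t0, phase) {
  t <- (prof$t - phase) %% t0
  o <- order(t)
  t <- t[o]; y <- prof$y[o]
  base <- stats::quantile(y, 0.05, names = FALSE)
  thr <- base + 0.2 * (max(y) - base)
  above <- y > thr
  # morning: scan forward from phase 0 until the profile drops below
  i <- 1
  while (i <= length(t) && above[i]) i <- i + 1
  t_m0 <- if (i > 1) t[min(i, length(t))] else 0.1 * t0
  # evening: scan backward from t0/2 while above
  j <- max(which(t < t0 / 2))
  k <- j
  while (k >= 1 && above[k]) k <- k - 1
  t_e0 <- t0 / 2 - (if (k >= 1) t[k] else 0.3 * t0)
  c(t_m = min(max(t_m0, 0.05 * t0), 0.45 * t0),
    t_e = min(max(t_e0, 0.05 * t0), 0.49 * t0),
    baseline = base, height = max(y) - base)
}

#' Stage-1 time-domain fit of the activity waveform
#'
#' Folds the record at `t0` into 20-min bins, reads initial peak widths
#' off the folded profile (the span above baseline + 20% of the peak
#' height around each activity peak -- an automated surrogate for reading
#' the widths off the binned data by eye), and then fits
#' `baseline + amplitude * F(t)` to the profile by bounded
#' Levenberg-Marquardt least squares, refining rates, widths, amplitude,
#' baseline and a small phase offset.  Five jittered restarts guard
#' against local minima; the best solution by residual sum of squares is
#' returned.
#'
#' @param record An [activity_record] (any bin width; rebinned to 20 min
#'   internally).
#' @param t0 Primary period, h (from [estimate_primary_period]).
#' @param phase Lights-on phase in h; `NULL` (default) estimates it by
#'   template cross-correlation of the folded profile.
#' @param n_starts Number of jittered restarts.
#' @param seed Seed for the restart jitter.
#' @return A [waveform_params] object (amplitude and baseline on the
#'   counts-per-20-min scale) with attributes `phase`, `profile`,
#'   `sse` and `amplitude_h` (mean of the two folded peak heights).
#' @export
initial_time_domain_fit <- function(record, t0, phase = NULL,
                                    n_starts = 5, seed = 0) {
  prof <- fold_profile(record, t0)
  if (is.null(phase)) phase <- .estimate_phase(prof, t0)
  w0 <- .init_widths(prof, t0, phase)
  t_adj <- (prof$t - phase) %% t0
  y <- prof$y

  lower <- c(b_md = -60, b_mr = 1e-3, b_er = -60, b_ed = 1e-3,
             tm = 0.02 * t0, te = 0.02 * t0, A = 0, B = 0,
             dphi = -t0 / 8)
  upper <- c(b_md = 60, b_mr = 60, b_er = 60, b_ed = 60,
             tm = 0.6 * t0, te = 0.5 * t0, A = Inf, B = Inf,
             dphi = t0 / 8)
  start0 <- list(b_md = -0.8, b_mr = 0.5, b_er = 0.1, b_ed = 3.6,
                 tm = unname(w0["t_m"]), te = unname(w0["t_e"]),
                 A = max(unname(w0["height"]), 1e-3),
                 B = unname(w0["baseline"]), dphi = 0)
  fmod <- function(b_md, b_mr, b_er, b_ed, tm, te, A, B, dphi) {
    wp <- waveform_params(b_md, b_mr, b_er, b_ed, tm, te, t0)
    B + A * eval_waveform(wp, (t_adj - dphi) %% t0)
  }
  starts <- .with_seed(seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1) return(start0)
    s <- start0
    for (nm in c("b_md", "b_er"))
      s[[nm]] <- s[[nm]] + stats::rnorm(1, 0, 0.5)
    for (nm in c("b_mr", "b_ed"))
      s[[nm]] <- s[[nm]] * exp(stats::rnorm(1, 0, 0.4))
    for (nm in c("tm", "te"))
      s[[nm]] <- min(max(s[[nm]] * stats::runif(1, 0.8, 1.25),
                         lower[[nm]]), upper[[nm]])
    s
  }))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(y ~ fmod(b_md, b_mr, b_er, b_ed, tm, te, A, B,
                                 dphi),
                        start = s, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
      best <- fit
  }
  if (is.null(best))
    stop("time-domain fit failed to converge from any start")
  cf <- as.list(stats::coef(best))
  out <- waveform_params(cf$b_md, cf$b_mr, cf$b_er, cf$b_ed,
                         cf$tm, cf$te, t0,
                         amplitude = cf$A, baseline = cf$B)
  phase_tot <- (phase + cf$dphi) %% t0
  # activity amplitude h: mean of the morning and evening peak heights
  tp <- (prof$t - phase_tot) %% t0
  m_pk <- max(prof$y[tp < 0.2 * t0 | tp > 0.8 * t0])
  e_pk <- max(prof$y[tp > 0.3 * t0 & tp < 0.7 * t0])
  attr(out, "phase") <- phase_tot
  attr(out, "profile") <- prof
  attr(out, "sse") <- stats::deviance(best)
  attr(out, "amplitude_h") <- mean(c(m_pk, e_pk))
  out
}

# measured periodogram heights at the harmonics t0/n within period_range:
# local maximum nearest each harmonic frequency, parabolic-refined
.harmonic_heights <- function(pg, t0, p = 0.005,
                              period_range = c(2, 35)) {
  z <- significance_threshold(pg, p)
  n_set <- seq.int(max(1, ceiling(t0 / period_range[2])),
                   floor(t0 / period_range[1]))
  hw <- max(2L, as.integer(round(pg$oversample / 2)))
  res <- lapply(n_set, function(n) {
    fn <- n / t0
    j <- which.min(abs(pg$freq - fn))
    win <- max(2, j - hw):min(length(pg$freq) - 1, j + hw)
    jloc <- win[which.max(pg$power[win])]
    r <- .refine_peak(pg$freq, pg$power, jloc)
    data.frame(n = n, period = t0 / n, freq_meas = r["freq"],
               height = r["power"], significant = r["power"] > z)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Stage-2 spectral fit of the analytic harmonic heights
#'
#' Extracts the measured periodogram peak heights at the harmonics
#' `t0/n` inside the analysis range, and minimizes the squared error
#' between the significant measured heights and `scale * H(T_n)`, where
#' `H` is the closed-form harmonic spectrum ([peak_heights]) and the
#' scale factor is profiled out analytically (equivalent to anchoring
#' relative heights to the reference peak).  Rates are bounded to
#' `+-b_max`; widths to `(0, t0)` and `(0, t0/2]`.  Multiple jittered
#' starts around the stage-1 estimate are used because the objective is
#' sensitive to the initial guess.
#'
#' @param pg A Lomb-Scargle `periodogram` covering the analysis range.
#' @param init Stage-1 [waveform_params] (see
#'   [initial_time_domain_fit]).
#' @param t0 Primary period, h.
#' @param p False-alarm probability defining which harmonic peaks are
#'   significant.
#' @param period_range Analysis range, h (default 2--35).
#' @param b_max Rate bound, 1/h (default 60).
#' @param n_starts,seed Restart control.
#' @return List of class `spectral_fit`: `params` (final
#'   [waveform_params]), `scale`, `harmonics` (measured vs fitted table
#'   with signed percent errors), `sse`, `sse_init`.
#' @export
spectral_fit <- function(pg, init, t0, p = 0.005,
                         period_range = c(2, 35), b_max = 60,
                         n_starts = 5, seed = 0) {
  stopifnot(inherits(init, "waveform_params"))
  meas <- .harmonic_heights(pg, t0, p, period_range)
  sig <- meas[meas$significant, , drop = FALSE]
  if (nrow(sig) < 3)
    stop("fewer than 3 significant harmonic peaks: insufficient constraints for the spectral fit")
  P <- sig$height
  hfun <- function(th) {
    wp <- waveform_params(th[1], th[2], th[3], th[4], th[5], th[6], t0)
    Mod(fourier_coefficient(wp, sig$n))^2
  }
  obj <- function(th) {
    H <- hfun(th)
    sH2 <- sum(H^2)
    if (!is.finite(sH2) || sH2 == 0) return(sum(P^2))
    s <- max(0, sum(P * H) / sH2)
    sum((P - s * H)^2)
  }
  # the power spectrum is invariant under time reversal, which swaps the
  # roles of the peak widths; the time-domain stage identifies the branch
  # assignment, so the spectral refinement keeps each width within a
  # factor 2 of its stage-1 estimate rather than exploring mirror minima
  lower <- c(-b_max, 1e-3, -b_max, 1e-3,
             max(0.02 * t0, init$t_m / 2), max(0.02 * t0, init$t_e / 2))
  upper <- c(b_max, b_max, b_max, b_max,
             min(0.95 * t0, init$t_m * 2), min(t0 / 2, init$t_e * 2))
  th0 <- pmin(pmax(c(init$b_md, init$b_mr, init$b_er, init$b_ed,
                     init$t_m, init$t_e), lower), upper)
  starts <- .with_seed(seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1) return(th0)
    th <- th0
    th[c(1, 3)] <- th[c(1, 3)] + stats::rnorm(2, 0, 0.5)
    th[c(2, 4)] <- th[c(2, 4)] * exp(stats::rnorm(2, 0, 0.4))
    th[5:6] <- th[5:6] * stats::runif(2, 0.8, 1.25)
    pmin(pmax(th, lower), upper)
  }))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, obj, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(maxit = 500,
                                              parscale = c(1, 1, 1, 1,
                                                           t0 / 10, t0 / 10))),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("spectral fit failed from every start")
  th <- best$par
  H <- hfun(th)
  s <- max(0, sum(P * H) / sum(H^2))
  params <- waveform_params(th[1], th[2], th[3], th[4], th[5], th[6], t0,
                            amplitude = init$amplitude,
                            baseline = init$baseline)
  # scale is defined against the unit-amplitude harmonic spectrum
  unit <- waveform_params(th[1], th[2], th[3], th[4], th[5], th[6], t0)
  meas$height_model <- s * Mod(fourier_coefficient(unit, meas$n))^2
  meas$pe <- ifelse(meas$height > 0,
                    percent_error(pmax(meas$height, 1e-300),
                                  meas$height_model), NA_real_)
  structure(list(params = params, scale = s, harmonics = meas,
                 sse = best$value, sse_init = obj(th0)),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat("Spectral fit of analytic harmonic heights (T0 =",
      format(x$params$t0), "h)\n")
  sig <- x$harmonics[x$harmonics$significant, ]
  cat(sprintf("  %d significant harmonic peaks, mean |P.E.| = %.1f%%\n",
              nrow(sig), mean(abs(sig$pe))))
  print(x$params)
  invisible(x)
}

#' Fit the activity waveform model to a recording
#'
#' The full two-stage pipeline: compute the Lomb-Scargle periodogram,
#' estimate the primary period (circadian peak in DD; doubled second
#' harmonic in LD), initialize parameters from the day-folded 20-min
#' profile, fit the analytic harmonic heights to the measured spectral
#' peaks, and attach the accuracy metrics (per-peak percent error,
#' harmonic-match fraction, area accuracy).
#'
#' @param record An [activity_record].
#' @param regime `"DD"`, `"LD"` or `"LL"`; defaults to the record's
#'   annotation.
#' @param t0 Optional known primary period (skips estimation).
#' @param period_range Analysis range in h (default 2--35).
#' @param p False-alarm probability (default 0.005).
#' @param oversample LS frequency oversampling factor.
#' @param b_max Rate bound for the spectral stage, 1/h.
#' @param seed Seed for fit restarts.
#' @return An object of class `activity_fit` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `simulate` and `plot`
#'   methods.  Records without a significant circadian peak raise a
#'   `flyrhythm_arrhythmic` error.
#' @examples
#' rec <- simulate_activity("wt", days = 5, seed = 42)
#' \donttest{
#' fit <- fit_activity_model(rec, regime = "LD")
#' fit
#' }
#' @export
fit_activity_model <- function(record, regime = NULL, t0 = NULL,
                               period_range = c(2, 35), p = 0.005,
                               oversample = 8, b_max = 60, seed = 0) {
  stopifnot(inherits(record, "activity_record"))
  regime <- regime %||% record$light_regime
  pg <- lomb_scargle(record, period_range = period_range,
                     oversample = oversample)
  if (is.null(t0))
    t0 <- estimate_primary_period(pg, regime, p = p)
  init <- initial_time_domain_fit(record, t0, seed = seed)
  sfit <- spectral_fit(pg, init, t0, p = p, period_range = period_range,
                       b_max = b_max, seed = seed)
  peaks <- detect_peaks(pg, p = p)
  hm <- harmonic_match(peaks, t0, period_range = period_range)
  aa <- area_accuracy(pg, hm$matches$period, period_range = period_range)
  structure(list(params = sfit$params, initial_params = init,
                 t0 = t0, regime = regime, scale = sfit$scale,
                 periodogram = pg, peaks = peaks,
                 harmonics = sfit$harmonics,
                 per_peak_pe = sfit$harmonics$pe[sfit$harmonics$significant],
                 peak_fraction = hm$fraction,
                 area_accuracy = aa, match = hm,
                 amplitude_h = attr(init, "amplitude_h"),
                 phase = attr(init, "phase"),
                 profile = attr(init, "profile"),
                 record_meta = record[c("channel_id", "genotype",
                                        "light_regime", "bin_width_s")],
                 n_bins = length(record$counts),
                 call = match.call()),
            class = "activity_fit")
}

#' @export
print.activity_fit <- function(x, ...) {
  cat(sprintf("Activity waveform fit: %s %s (%s), T0 = %.2f h\n",
              x$record_meta$genotype, x$record_meta$channel_id,
              x$regime, x$t0))
  print(x$params)
  cat(sprintf("  mean |P.E.| over %d significant harmonics: %.1f%%\n",
              length(x$per_peak_pe), mean(abs(x$per_peak_pe))))
  cat(sprintf("  peaks matched to harmonics: %.1f%%; area accuracy: %.1f%%\n",
              x$peak_fraction, x$area_accuracy))
  invisible(x)
}

#' @export
summary.activity_fit <- function(object, ...) {
  structure(object, class = c("summary.activity_fit", "activity_fit"))
}

#' @export
print.summary.activity_fit <- function(x, ...) {
  print.activity_fit(x)
  cat("\nHarmonic peak table:\n")
  print(x$harmonics, digits = 4, row.names = FALSE)
  cat(sprintf("\nInitial (time-domain) parameters: b = (%.3g, %.3g, %.3g, %.3g), widths = (%.3g, %.3g) h\n",
              x$initial_params$b_md, x$initial_params$b_mr,
              x$initial_params$b_er, x$initial_params$b_ed,
              x$initial_params$t_m, x$initial_params$t_e))
  cat(sprintf("Activity amplitude h = %.3g counts/20-min bin; phase = %.2f h\n",
              x$amplitude_h, x$phase))
  invisible(x)
}

#' @export
coef.activity_fit <- function(object, ...) {
  p <- object$params
  c(b_md = p$b_md, b_mr = p$b_mr, b_er = p$b_er, b_ed = p$b_ed,
    t_m = p$t_m, t_e = p$t_e, t0 = p$t0,
    amplitude = p$amplitude, baseline = p$baseline)
}

#' @export
predict.activity_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$profile$t
  p <- object$params
  p$baseline + p$amplitude *
    eval_waveform(p, (t - object$phase) %% p$t0)
}

#' @export
fitted.activity_fit <- function(object, ...) {
  predict(object, object$profile$t)
}

#' @export
residuals.activity_fit <- function(object, ...) {
  object$profile$y - fitted(object)
}

#' @export
simulate.activity_fit <- function(object, nsim = 1, seed = NULL,
                                  days = 5, bin_width_s = 20, ...) {
  p <- object$params
  # convert the fitted 20-min-scale amplitude/baseline to per-bin rates
  sc <- bin_width_s / 1200
  unit <- waveform_params(p$b_md, p$b_mr, p$b_er, p$b_ed, p$t_m, p$t_e,
                          p$t0)
  seeds <- if (is.null(seed)) vector("list", nsim)
           else as.list(seed + seq_len(nsim) - 1)
  lapply(seeds, function(s)
    simulate_activity(params = unit, days = days,
                      bin_width_s = bin_width_s,
                      rate_scale = p$amplitude * sc,
                      baseline_rate = p$baseline * sc, seed = s,
                      light_regime = object$record_meta$light_regime,
                      genotype = paste0(object$record_meta$genotype,
                                        "_sim")))
}

#' @export
plot.activity_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  prof <- x$profile
  o <- order(prof$t)
  graphics::plot(prof$t[o], prof$y[o], type = "h", col = "grey40",
                 xlab = "Time (h)", ylab = "Counts / 20 min",
                 main = "Day-folded profile and fitted waveform")
  graphics::lines(prof$t[o], predict(x, prof$t[o]), col = "red", lwd = 2)
  pg <- x$periodogram
  graphics::plot(pg$period, pg$power, type = "l", log = "y",
                 xlab = "Period (h)", ylab = "Normalized power",
                 main = "Periodogram and fitted harmonic heights")
  sig <- x$harmonics[x$harmonics$significant, ]
  graphics::points(sig$period, sig$height_model, col = "red", pch = 5)
  graphics::abline(h = significance_threshold(pg, 0.005), lty = 2)
  invisible(x)
}
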