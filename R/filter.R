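# Demonstration that low-pass filtering an aperiodic series manufactures
# statistically significant spectral peaks.  Filtering colours the noise:
# the variance removed above the cutoff inflates the variance-normalized
# power of every surviving fluctuation in the passband, so the white-noise
# false-alarm calibration no longer holds.

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) application of a Butterworth low-pass
#' filter, as used by earlier studies that filtered activity data before
#' spectral analysis.  Provided for the spurious-peak demonstration; the
#' package's own pipeline never filters raw data.
#'
#' @param series An [activity_record], sampled waveform, or numeric
#'   vector with `bin_width_s`.
#' @param cutoff_h Cutoff period in hours (components with periods below
#'   this are attenuated).  Must exceed twice the sampling interval.
#' @param order Filter order (default 2).
#' @param bin_width_s Bin width for plain numeric input, seconds.
#' @return Filtered numeric series with the `time_h`/`dt_s` attributes of
#'   [sample_waveform].
#' @export
butterworth_lowpass <- function(series, cutoff_h = 1, order = 2,
                                bin_width_s = NULL) {
  s <- .series_input(series, bin_width_s)
  nyq <- 1 / (2 * s$dt_h)          # cycles per hour
  fc <- 1 / cutoff_h
  if (fc >= nyq)
    stop("cutoff frequency is at or above the Nyquist frequency")
  bf <- signal::butter(order, fc / nyq, type = "low")
  # demean and reflect-pad so the forward-backward pass has no startup
  # transient at the record edges
  x0 <- s$x
  n <- length(x0)
  m <- mean(x0)
  np <- min(n - 1, ceiling(3 * cutoff_h / s$dt_h))
  xp <- c(rev((x0 - m)[2:(np + 1)]), x0 - m,
          rev((x0 - m)[(n - np):(n - 1)]))
  xf <- signal::filtfilt(bf, xp)
  x <- xf[(np + 1):(np + n)] + m
  attr(x, "dt_s") <- s$dt_h * 3600
  attr(x, "time_h") <- s$t
  x
}

#' Spurious significant peaks from filtering white noise
#'
#' Paired Monte-Carlo demonstration: white Gaussian noise is analysed
#' with the Lomb-Scargle periodogram before and after zero-phase
#' Butterworth low-pass filtering, and the fraction of runs with at least
#' one significant peak (false-alarm probability `p`) is compared.  Raw
#' noise produces false peaks at about the nominal rate; filtered noise
#' produces them in nearly every run, because the removed high-frequency
#' variance inflates the normalized power in the passband.
#'
#' @param n_reps Number of noise realizations (>= 20).
#' @param days Length of each series in days.
#' @param bin_width_s Sampling interval, seconds.
#' @param cutoff_h,order Filter settings (defaults mirror typical prior
#'   usage: order 2, 1 h cutoff).
#' @param p False-alarm probability (default 0.005).
#' @param period_range Analysis range in h.
#' @param seed Seed.
#' @return List of class `spurious_peak_report`: fractions of runs with
#'   at least one significant peak and mean significant-peak counts, raw
#'   vs filtered.
#' @export
spurious_peak_demo <- function(n_reps = 50, days = 3, bin_width_s = 60,
                               cutoff_h = 1, order = 2, p = 0.005,
                               period_range = c(2, 35), seed = 0) {
  stopifnot(n_reps >= 20)
  n <- round(days * 86400 / bin_width_s)
  counts <- .with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      x <- stats::rnorm(n)
      xf <- butterworth_lowpass(x, cutoff_h = cutoff_h, order = order,
                                bin_width_s = bin_width_s)
      raw <- detect_peaks(lomb_scargle(x, period_range,
                                       bin_width_s = bin_width_s), p = p)
      fil <- detect_peaks(lomb_scargle(as.numeric(xf), period_range,
                                       bin_width_s = bin_width_s), p = p)
      c(nrow(raw), nrow(fil))
    }, numeric(2))
  })
  structure(list(n_reps = n_reps,
                 raw_fraction = mean(counts[1, ] > 0),
                 filtered_fraction = mean(counts[2, ] > 0),
                 raw_mean_peaks = mean(counts[1, ]),
                 filtered_mean_peaks = mean(counts[2, ]),
                 p = p, cutoff_h = cutoff_h, order = order),
            class = "spurious_peak_report")
}

#' @export
print.spurious_peak_report <- function(x, ...) {
  cat(sprintf("Spurious-peak demonstration (%d runs, order-%d Butterworth, %g h cutoff)\n",
              x$n_reps, x$order, x$cutoff_h))
  cat(sprintf("  runs with >=1 significant peak (p = %g): raw %.1f%%, filtered %.1f%%\n",
              x$p, 100 * x$raw_fraction, 100 * x$filtered_fraction))
  cat(sprintf("  mean significant peaks per run: raw %.2f, filtered %.2f\n",
              x$raw_mean_peaks, x$filtered_mean_peaks))
  invisible(x)
}
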