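# Spectral estimation for activity records: variance-normalized
# Lomb-Scargle periodogram with a false-alarm significance level, maximum
# entropy spectral analysis (Burg autoregressive coefficients evaluated
# with the Andersen recursion), autocorrelation with a 2/sqrt(N) bound,
# and side-lobe-aware peak detection.

# coerce record / sampled waveform / numeric to (x, t hours)
.series_input <- function(series, bin_width_s = NULL) {
  if (inherits(series, "activity_record")) {
    list(x = series$counts, t = record_times_h(series),
         dt_h = series$bin_width_s / 3600)
  } else if (is.numeric(series) && !is.null(attr(series, "time_h"))) {
    t <- attr(series, "time_h")
    list(x = as.numeric(series), t = t, dt_h = t[2] - t[1])
  } else if (is.numeric(series)) {
    if (is.null(bin_width_s))
      stop("bin_width_s is required for a plain numeric series")
    dt_h <- bin_width_s / 3600
    list(x = as.numeric(series), t = (seq_along(series) - 1) * dt_h,
         dt_h = dt_h)
  } else stop("unsupported series type")
}

.new_periodogram <- function(freq, power, method, N, span_h, oversample,
                             period_range) {
  structure(list(freq = freq, period = 1 / freq, power = power,
                 method = method, N = N, span_h = span_h,
                 oversample = oversample, period_range = period_range),
            class = "periodogram")
}

# oversampled frequency grid aligned with the natural Fourier frequencies
# m/span, so spectral lines of records holding an integer number of cycles
# fall on grid points
.freq_grid <- function(span_h, period_range, oversample) {
  df <- 1 / (oversample * span_h)
  k <- seq.int(ceiling(1 / (period_range[2] * df)),
               floor(1 / (period_range[1] * df)))
  k * df
}

#' Lomb-Scargle periodogram of an activity record
#'
#' Computes the classical Scargle least-squares periodogram, normalized
#' by the sample variance, on an oversampled frequency grid aligned with
#' the natural Fourier frequencies of the record.  For evenly sampled
#' data it coincides with the classical periodogram at the Fourier
#' frequencies, and its false-alarm significance level is available from
#' [significance_threshold].
#'
#' @param series An [activity_record], a vector from [sample_waveform],
#'   or a plain numeric series with `bin_width_s` supplied.
#' @param period_range Periods analysed, h (default 2--35, the model's
#'   validity range; widen for display).
#' @param oversample Frequency oversampling factor relative to `1/span`
#'   spacing (default 8, enough to resolve Dirichlet side lobes).
#' @param bin_width_s Bin width for plain numeric input, seconds.
#' @return An object of class `periodogram` with elements `freq` (1/h),
#'   `period` (h), `power`, `method`, `N`, `span_h`.
#' @references Scargle (1982) ApJ 263:835; Horne & Baliunas (1986) ApJ
#'   302:757.
#' @export
lomb_scargle <- function(series, period_range = c(2, 35), oversample = 8,
                         bin_width_s = NULL) {
  s <- .series_input(series, bin_width_s)
  x <- s$x
  N <- length(x)
  if (N < 4) stop("series too short")
  if (stats::var(x) == 0)
    stop("constant series: Lomb-Scargle power is undefined (zero variance)")
  span <- N * s$dt_h
  stopifnot(period_range[1] > 0, period_range[2] > period_range[1])
  if (period_range[1] < 2 * s$dt_h)
    period_range[1] <- 2 * s$dt_h
  if (period_range[2] > span) period_range[2] <- span
  freq <- .freq_grid(span, period_range, oversample)
  x <- x - mean(x)
  s2 <- sum(x^2) / (N - 1)
  t <- s$t
  p <- numeric(length(freq))
  for (j in seq_along(freq)) {
    w <- 2 * pi * freq[j]
    wt <- w * t
    tau_w <- 0.5 * atan2(sum(sin(2 * wt)), sum(cos(2 * wt)))
    ct <- cos(wt - tau_w)
    st <- sin(wt - tau_w)
    p[j] <- (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2)) /
      (2 * s2)
  }
  .new_periodogram(freq, p, "LS", N, span, oversample, period_range)
}

#' False-alarm significance level of a Lomb-Scargle periodogram
#'
#' Power level exceeded with probability `p` anywhere on the scanned
#' range under the white-noise null.  Under the independent-frequencies
#' approximation each of `M` independent frequencies carries
#' exponentially distributed power, giving the threshold
#' `z = -log(1 - (1 - p)^(1/M))`.  `M` defaults to the number of
#' independent Fourier spacings in the scanned band,
#' `span * (f_max - f_min)`; the oversampled grid adds no independent
#' frequencies.  The exact multiple-testing correction is a modelling
#' choice, so `M` can be overridden.
#'
#' @param pg A `periodogram` from [lomb_scargle].
#' @param p False-alarm probability in (0, 1) (default 0.005, the
#'   conventional line drawn on activity spectra).
#' @param M Effective number of independent frequencies (default as
#'   above).
#' @return The power threshold.
#' @export
significance_threshold <- function(pg, p = 0.005, M = NULL) {
  stopifnot(inherits(pg, "periodogram"), p > 0, p < 1)
  if (pg$method != "LS")
    stop("significance levels are only defined for the LS periodogram")
  if (is.null(M)) M <- max(1, pg$span_h * (max(pg$freq) - min(pg$freq)))
  -log(1 - (1 - p)^(1 / M))
}

#' Maximum entropy (Burg/Andersen) power spectrum
#'
#' Fits an autoregressive model of order `m` by Burg's method and
#' evaluates the corresponding all-pole spectral density on the same
#' period grid as [lomb_scargle], so peak positions are directly
#' comparable between the two estimators.  MESA has no convenient
#' significance metric; only peak positions should be compared with LS.
#'
#' Because the AR filter must span at least one full period to represent
#' it, finely binned records are rebinned (default 5-min bins) before the
#' Burg fit; the spectrum is still evaluated on the fine period grid.
#'
#' @param series As in [lomb_scargle].
#' @param order AR model order `m` (default `min(N/3, 1000)` after
#'   rebinning).
#' @param rebin_s Bin width used for the AR fit, seconds; input binned
#'   more finely is rebinned (set to `NULL` to fit at the native
#'   resolution).
#' @param period_range,oversample,bin_width_s As in [lomb_scargle].
#' @return A `periodogram` with `method = "MESA"`.
#' @export
mesa <- function(series, order = NULL, rebin_s = 300,
                 period_range = c(2, 35), oversample = 8,
                 bin_width_s = NULL) {
  s <- .series_input(series, bin_width_s)
  if (!is.null(rebin_s)) {
    k <- rebin_s / (s$dt_h * 3600)
    if (k > 1 && abs(k - round(k)) < 1e-9) {
      k <- as.integer(round(k))
      n <- length(s$x) %/% k
      s$x <- colSums(matrix(s$x[seq_len(n * k)], nrow = k))
      s$dt_h <- s$dt_h * k
      s$t <- (seq_len(n) - 1) * s$dt_h
    }
  }
  x <- s$x
  N <- length(x)
  if (is.null(order)) order <- min(floor(N / 3), 1000L)
  if (order >= N / 2) stop("AR order must be below N/2")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  if (any(!is.finite(fit$ar)) ||
      (length(fit$partialacf) && max(abs(fit$partialacf)) >= 1))
    stop("unstable AR fit (reflection coefficient magnitude >= 1)")
  span <- N * s$dt_h
  if (period_range[2] > span) period_range[2] <- span
  freq <- .freq_grid(span, period_range, oversample)
  # Andersen evaluation: S(f) = sigma^2 dt / |1 - sum_k a_k z^k|^2,
  # z = exp(-2 pi i f dt); Horner recursion over the AR polynomial
  z <- exp(-2i * pi * freq * s$dt_h)
  acc <- complex(length.out = length(freq))
  a <- fit$ar
  for (k in rev(seq_along(a))) acc <- (acc + a[k]) * z
  p <- fit$var.pred * s$dt_h / Mod(1 - acc)^2
  out <- .new_periodogram(freq, p, "MESA", N, span, oversample,
                          period_range)
  out$ar <- a
  out$var_pred <- fit$var.pred
  out$dt_h <- s$dt_h
  out
}

#' Autocorrelation of an activity record with significance bound
#'
#' Biased-normalized autocorrelation (covariance of the demeaned series
#' with itself, divided by `N`) at 1-minute lags, with the conventional
#' `2/sqrt(N)` bound above which a correlation is considered strong.
#' Records binned finer than 1 minute are rebinned first.
#'
#' @param series An [activity_record], sampled waveform, or numeric
#'   vector with `bin_width_s`.
#' @param max_lag_h Largest lag, h (must be below half the record
#'   length).
#' @param lag_step_s Lag resolution, seconds (default 60).
#' @param bin_width_s Bin width for plain numeric input.
#' @return An object of class `autocorrelogram`: list with `lag_h`,
#'   `correlation`, `sig_bound`, `N`.
#' @export
autocorrelation <- function(series, max_lag_h = 30, lag_step_s = 60,
                            bin_width_s = NULL) {
  s <- .series_input(series, bin_width_s)
  x <- s$x
  dt_s <- s$dt_h * 3600
  if (dt_s < lag_step_s && abs(lag_step_s / dt_s -
                               round(lag_step_s / dt_s)) < 1e-9) {
    k <- as.integer(round(lag_step_s / dt_s))
    n <- length(x) %/% k
    x <- colSums(matrix(x[seq_len(n * k)], nrow = k))
    dt_s <- dt_s * k
  }
  N <- length(x)
  span_h <- N * dt_s / 3600
  if (max_lag_h >= span_h / 2)
    stop("max_lag_h must be below half the record length")
  lag_max <- floor(max_lag_h * 3600 / dt_s)
  ac <- stats::acf(x, lag.max = lag_max, type = "correlation",
                   demean = TRUE, plot = FALSE)
  structure(list(lag_h = as.numeric(ac$lag) * dt_s / 3600,
                 correlation = as.numeric(ac$acf),
                 sig_bound = 2 / sqrt(N), N = N),
            class = "autocorrelogram")
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat(sprintf("Autocorrelogram: %d lags up to %.1f h, bound 2/sqrt(N) = %.4f\n",
              length(x$lag_h) - 1, max(x$lag_h), x$sig_bound))
  invisible(x)
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("%s periodogram: %d frequencies, periods %.3g-%.3g h, N = %d (%.1f h record)\n",
              x$method, length(x$freq), min(x$period), max(x$period),
              x$N, x$span_h))
  invisible(x)
}

#' @export
plot.periodogram <- function(x, p = 0.005, log = "", ...) {
  graphics::plot(x$period, x$power, type = "l", xlab = "Period (h)",
                 ylab = "Normalized power", log = log, ...)
  if (x$method == "LS")
    graphics::abline(h = significance_threshold(x, p), lty = 2)
  invisible(x)
}

#' Serialize a periodogram or autocorrelogram as tab-delimited text
#'
#' @param x A `periodogram` or `autocorrelogram`.
#' @param path Output file path.
#' @export
write_spectrum <- function(x, path) {
  df <- if (inherits(x, "periodogram")) {
    data.frame(period_h = x$period, freq_per_h = x$freq, power = x$power)
  } else if (inherits(x, "autocorrelogram")) {
    data.frame(lag_h = x$lag_h, correlation = x$correlation)
  } else stop("unsupported object")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Line-position refinement at the record's natural Fourier spacing.
#
# The oversampled grid samples the Dirichlet kernel between the natural
# frequencies m/span, where the ripple of neighbouring strong lines
# displaces the continuous maximum of a weak line (by up to ~1.5 grid
# steps for the circadian fundamental next to a dominant 12 h line).  At
# Fourier spacing the kernel is critically sampled, and for a rectangular
# window the amplitude-ratio interpolator
#   delta = a1 / (a0 + a1),  a = sqrt(power) at adjacent Fourier bins
# recovers the line frequency exactly for a noise-free isolated line at
# any inter-bin offset.  Falls back to parabolic interpolation at the
# grid edges.
.refine_line <- function(pg, i) {
  osf <- as.integer(round(pg$oversample))
  k <- as.integer(round(pg$freq * pg$span_h * osf)) # grid indices
  km <- as.integer(round(pg$freq[i] * pg$span_h))   # nearest Fourier index
  ic <- match(km * osf, k)
  if (is.na(ic) || ic - osf < 1 || ic + osf > length(k))
    return(.refine_peak(pg$freq, pg$power, i))
  # the broadband noise floor biases the interpolation outward for weak
  # lines, so it is subtracted first; the median power over the scanned
  # band estimates the floor mean robustly (exponentially distributed
  # noise power has mean = median / ln 2) and keeps the refinement
  # invariant under uniform rescaling of the spectrum
  floor_p <- stats::median(pg$power) / log(2)
  a0 <- sqrt(max(pg$power[ic] - floor_p, 0))
  am <- sqrt(max(pg$power[ic - osf] - floor_p, 0))
  ap <- sqrt(max(pg$power[ic + osf] - floor_p, 0))
  if (a0 + max(am, ap) == 0) return(.refine_peak(pg$freq, pg$power, i))
  d <- if (ap >= am) ap / (a0 + ap) else -am / (a0 + am)
  h <- .refine_peak(pg$freq, pg$power, i)[["power"]]
  c(freq = (km + d) / pg$span_h, power = h)
}

# MESA all-pole lines can be much narrower than the grid step, so the
# continuous AR spectrum is maximized within one grid step of the grid
# maximum
.refine_mesa <- function(pg, i) {
  f_lo <- pg$freq[max(1, i - 1)]
  f_hi <- pg$freq[min(length(pg$freq), i + 1)]
  dens <- function(f) {
    z <- exp(-2i * pi * f * pg$dt_h)
    acc <- 0 + 0i
    for (k in rev(seq_along(pg$ar))) acc <- (acc + pg$ar[k]) * z
    pg$var_pred * pg$dt_h / Mod(1 - acc)^2
  }
  o <- stats::optimize(dens, c(f_lo, f_hi), maximum = TRUE,
                       tol = (f_hi - f_lo) * 1e-4)
  c(freq = o$maximum, power = o$objective)
}

# parabolic refinement of a local maximum at grid index i (frequency space)
.refine_peak <- function(freq, power, i) {
  if (i <= 1 || i >= length(freq))
    return(c(freq = freq[i], power = power[i]))
  y1 <- power[i - 1]; y2 <- power[i]; y3 <- power[i + 1]
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(c(freq = freq[i], power = power[i]))
  d <- 0.5 * (y1 - y3) / den
  d <- max(-0.5, min(0.5, d))
  c(freq = freq[i] + d * (freq[i + 1] - freq[i]),
    power = y2 - 0.25 * (y1 - y3) * d)
}

#' Detect significant peaks in a periodogram
#'
#' Finds local power maxima above the false-alarm threshold, refines
#' their position by 3-point parabolic interpolation, and (by default)
#' removes Dirichlet-kernel side lobes of stronger peaks.  A finite
#' record of span `L` smears every line over lobes spaced `1/L` in
#' frequency ([dirichlet_sidepeaks]), so a weaker local maximum within
#' two lobe spacings of a stronger peak is not a resolvable independent
#' periodicity and is absorbed into it; between 2 and `m_max + 0.5` lobe
#' spacings a weaker peak is dropped when its height lies below
#' `cap / (pi * D)^2` times the stronger peak (the sinc-squared side-lobe
#' envelope at `D` lobe spacings, with headroom factor `cap` for noise
#' riding on the lobes).  The conventional significance cut alone does
#' not remove side lobes of strong lines, which would otherwise
#' masquerade as independent periodicities.  If two adjacent maxima are
#' equal to within 1e-9 the longer period is kept.
#'
#' @param pg A `periodogram`.
#' @param p False-alarm probability defining the threshold (LS only).
#' @param threshold Absolute power threshold; overrides `p`, and is
#'   required for MESA spectra (use 0 to keep all local maxima).
#' @param sidelobes `"drop"` (default) or `"keep"`.
#' @param m_max Side lobes per side considered for exclusion.
#' @param cap Headroom factor of the side-lobe envelope test.
#' @return Data frame with columns `period`, `freq`, `power`, sorted by
#'   decreasing power; dropped side lobes are in the `sidelobes`
#'   attribute.
#' @export
detect_peaks <- function(pg, p = 0.005, threshold = NULL,
                         sidelobes = c("drop", "keep"), m_max = 6,
                         cap = 6) {
  stopifnot(inherits(pg, "periodogram"))
  sidelobes <- match.arg(sidelobes)
  if (is.null(threshold)) {
    if (pg$method != "LS")
      stop("an absolute threshold is required for non-LS spectra")
    threshold <- significance_threshold(pg, p)
  }
  pw <- pg$power
  n <- length(pw)
  empty <- data.frame(period = numeric(0), freq = numeric(0),
                      power = numeric(0))
  if (n < 3) return(empty)
  i <- which(pw[2:(n - 1)] > pw[1:(n - 2)] &
               pw[2:(n - 1)] >= pw[3:n]) + 1
  # plateau tie: drop a maximum whose right neighbour maximum is equal
  # to within 1e-9 (longer period = lower frequency index is kept)
  if (length(i) > 1) {
    adj <- which(diff(i) == 1 & abs(diff(pw[i])) < 1e-9)
    if (length(adj)) i <- i[-(adj + 1)]
  }
  i <- i[pw[i] > threshold]
  if (!length(i)) return(empty)
  # Fourier-spacing refinement presumes the Dirichlet kernel line shape,
  # so it applies to LS; MESA lines are maximized on the continuous
  # all-pole spectrum, which can be narrower than the grid step
  ref <- if (pg$method == "LS")
    t(vapply(i, function(j) .refine_line(pg, j), numeric(2)))
  else if (pg$method == "MESA" && !is.null(pg$ar))
    t(vapply(i, function(j) .refine_mesa(pg, j), numeric(2)))
  else t(vapply(i, function(j) .refine_peak(pg$freq, pw, j), numeric(2)))
  pk <- data.frame(period = 1 / ref[, 1], freq = ref[, 1],
                   power = ref[, 2])
  pk <- pk[order(-pk$power), , drop = FALSE]
  dropped <- empty
  if (sidelobes == "drop" && nrow(pk) > 1) {
    keep <- rep(TRUE, nrow(pk))
    for (k in seq(2, nrow(pk))) {
      # side-lobe kernels of several stronger lines overlap; their
      # leakage powers add incoherently (random relative phases), so the
      # envelope test sums power contributions
      env <- 0
      for (j in seq_len(k - 1)) {
        if (!keep[j]) next
        # distance in units of the lobe spacing 1/span
        D <- abs(pk$freq[k] - pk$freq[j]) * pg$span_h
        if (D < 2) { env <- Inf; break }
        if (D <= m_max + 0.5) env <- env + pk$power[j] / (pi * D)^2
      }
      if (pk$power[k] < cap * env) keep[k] <- FALSE
    }
    dropped <- pk[!keep, , drop = FALSE]
    pk <- pk[keep, , drop = FALSE]
  }
  rownames(pk) <- NULL
  attr(pk, "sidelobes") <- dropped
  attr(pk, "threshold") <- threshold
  pk
}
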