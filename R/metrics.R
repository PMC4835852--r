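# Accuracy metrics for the harmonic model: signed percent error of peak
# heights, the fraction of significant peaks explained as harmonics, and
# the fraction of spectral area captured by the predicted peak windows.

#' Signed percent error between a measured and a predicted peak height
#'
#' `P.E. = (P_data - P_model) / P_data * 100`.
#'
#' @param peak_data Measured peak height(s); must be positive.
#' @param peak_model Predicted peak height(s).
#' @return Signed percent error(s).
#' @export
percent_error <- function(peak_data, peak_model) {
  if (any(peak_data <= 0)) stop("peak_data must be positive")
  (peak_data - peak_model) / peak_data * 100
}

#' Match detected spectral peaks to harmonics of the primary period
#'
#' Assigns detected peak periods to the harmonic series `t0/n`
#' (`n = 1, 2, ...`) greedily by increasing relative deviation, each
#' harmonic absorbing at most one peak, and reports the percentage of
#' peaks matched within the tolerance.  An empty peak list (an arrhythmic
#' record) returns 100% flagged `"no_peaks"`.
#'
#' @param peaks Numeric vector of peak periods (h), or a data frame from
#'   [detect_peaks].
#' @param t0 Primary period, h.
#' @param tolerance Maximum relative deviation counted as a match
#'   (default 0.10).
#' @param period_range Harmonics considered, h.
#' @return List with `fraction` (%), `matches` (data frame: `period`,
#'   `n`, `harmonic`, `deviation`), and `unmatched` (periods).
#' @export
harmonic_match <- function(peaks, t0, tolerance = 0.10,
                           period_range = c(2, 35)) {
  if (is.data.frame(peaks)) peaks <- peaks$period
  peaks <- peaks[peaks >= period_range[1] & peaks <= period_range[2]]
  empty <- data.frame(period = numeric(0), n = integer(0),
                      harmonic = numeric(0), deviation = numeric(0))
  if (!length(peaks)) {
    return(structure(list(fraction = 100, matches = empty,
                          unmatched = numeric(0)),
                     flag = "no_peaks"))
  }
  stopifnot(t0 > 0, tolerance > 0)
  n_set <- seq.int(max(1, ceiling(t0 / period_range[2])),
                   floor(t0 / period_range[1]))
  harm <- t0 / n_set
  dev <- abs(outer(peaks, harm, function(p, h) (p - h) / h))
  cand <- which(dev <= tolerance, arr.ind = TRUE)
  matches <- empty
  if (nrow(cand)) {
    cand <- cand[order(dev[cand]), , drop = FALSE]
    used_p <- rep(FALSE, length(peaks))
    used_h <- rep(FALSE, length(harm))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (used_p[i] || used_h[j]) next
      used_p[i] <- used_h[j] <- TRUE
      matches <- rbind(matches,
                       data.frame(period = peaks[i], n = n_set[j],
                                  harmonic = harm[j],
                                  deviation = (peaks[i] - harm[j]) / harm[j]))
    }
  }
  list(fraction = 100 * nrow(matches) / length(peaks),
       matches = matches,
       unmatched = setdiff(round(peaks, 10), round(matches$period, 10)))
}

#' Fraction of spectral area captured by predicted harmonic windows
#'
#' Integrates periodogram power (trapezoidal rule in frequency) inside
#' windows centred on the matched harmonic peaks and divides by the total
#' area over the analysis range.  The default window half-width is the
#' Dirichlet main-lobe width of the finite record, `2/span` in frequency:
#' a finite-record line deposits ~90% of its energy inside the main lobe
#' (zeros at +-1/span) and its near side lobes bring the window capture
#' to ~95%, so the window covers the line's kernel footprint without
#' absorbing the noise floor between harmonics.
#'
#' @param pg A `periodogram`.
#' @param matched_periods Periods (h) of the matched peaks, e.g.
#'   `harmonic_match(...)$matches$period`.
#' @param window_hw Window half-width in frequency (1/h); default
#'   `2/span`.
#' @param period_range Integration range, h.
#' @return Area accuracy in percent (0 if no matched peaks).
#' @export
area_accuracy <- function(pg, matched_periods, window_hw = NULL,
                          period_range = c(2, 35)) {
  stopifnot(inherits(pg, "periodogram"))
  if (is.null(window_hw)) window_hw <- 2 / pg$span_h
  sel <- pg$period >= period_range[1] & pg$period <= period_range[2]
  f <- pg$freq[sel]; pw <- pg$power[sel]
  o <- order(f); f <- f[o]; pw <- pw[o]
  trap <- function(keep) {
    if (sum(keep) < 2) return(0)
    # integrate only over sub-intervals with both ends kept
    w <- which(keep[-length(keep)] & keep[-1])
    sum((f[w + 1] - f[w]) * (pw[w + 1] + pw[w]) / 2)
  }
  a_total <- trap(rep(TRUE, length(f)))
  if (!length(matched_periods) || a_total == 0) return(0)
  inwin <- rep(FALSE, length(f))
  for (p0 in matched_periods)
    inwin <- inwin | abs(f - 1 / p0) <= window_hw
  100 * trap(inwin) / a_total
}

#' Relation between activity amplitude and circadian period
#'
#' Fits the per-fly activity amplitude `h` (average of the morning and
#' evening peak heights) against the circadian period with both the
#' saturating form `h = c (1 - exp(-k t0))` and its small-`k t0` linear
#' approximation `h = C t0` (through the origin), reporting adjusted R^2
#' for each; model selection is reported, not enforced.
#'
#' @param h Per-fly activity amplitudes (counts scale).
#' @param t0 Per-fly circadian periods, h.
#' @return An object of class `amp_period_fit`: list with `C`,
#'   `adj_r2_linear`, `c`, `k`, `adj_r2_exp` (NA if the exponential fit
#'   fails), `preferred`, and `n`.
#' @export
amplitude_vs_period_fit <- function(h, t0) {
  stopifnot(length(h) == length(t0))
  if (length(h) < 3) stop("at least 3 (h, t0) pairs are required")
  if (diff(range(t0)) < 1e-9) stop("degenerate input: all t0 equal")
  adj <- function(res, p) {
    n <- length(h)
    1 - (sum(res^2) / (n - p)) / (sum((h - mean(h))^2) / (n - 1))
  }
  lin <- stats::lm(h ~ 0 + t0)
  out <- list(C = unname(stats::coef(lin)), adj_r2_linear = adj(stats::residuals(lin), 1),
              c = NA_real_, k = NA_real_, adj_r2_exp = NA_real_,
              n = length(h))
  ex <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(h ~ cc * (1 - exp(-kk * t0)),
                      start = list(cc = max(h) * 1.5,
                                   kk = 1 / mean(t0)),
                      lower = c(cc = 0, kk = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (!is.null(ex)) {
    cf <- stats::coef(ex)
    out$c <- unname(cf["cc"]); out$k <- unname(cf["kk"])
    out$adj_r2_exp <- adj(stats::residuals(ex), 2)
  }
  out$preferred <- if (!is.na(out$adj_r2_exp) &&
                       out$adj_r2_exp > out$adj_r2_linear + 0.01)
    "exponential" else "linear"
  structure(out, class = "amp_period_fit")
}

#' @export
print.amp_period_fit <- function(x, ...) {
  cat(sprintf("Amplitude-period relation (n = %d)\n", x$n))
  cat(sprintf("  linear      h = %.3g * t0           adj R^2 = %.3f\n",
              x$C, x$adj_r2_linear))
  if (!is.na(x$adj_r2_exp))
    cat(sprintf("  exponential h = %.3g (1 - e^(-%.3g t0))  adj R^2 = %.3f\n",
                x$c, x$k, x$adj_r2_exp))
  cat("  preferred:", x$preferred, "\n")
  invisible(x)
}
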