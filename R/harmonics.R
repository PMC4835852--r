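# Closed-form Fourier analysis of the four-exponential waveform.
#
# Every branch of F(t) is of the form alpha + beta * exp(gamma * (t - s)),
# or a linear ramp in the degenerate-rate limit, so the Fourier integral
# (1/T0) int_0^T0 F(t) exp(i 2 pi n t / T0) dt is evaluated exactly
# branch by branch.  The reference shift s is chosen so that the real part
# of the exponent is non-positive over the branch, which keeps the closed
# form finite for rates up to the +-60 1/h fitting bounds.

# int_u^v exp(z (t - s)) dt for complex z, with a series for small |z| w
.intexp <- function(z, u, v, s = 0) {
  w <- v - u
  small <- abs(z) * w < 1e-6
  out <- z # complex vector shape
  if (any(small)) {
    zs <- z[small]
    out[small] <- exp(zs * (u - s)) * w *
      (1 + zs * w / 2 + zs^2 * w^2 / 6 + zs^3 * w^3 / 24)
  }
  if (any(!small)) {
    zb <- z[!small]
    out[!small] <- (exp(zb * (v - s)) - exp(zb * (u - s))) / zb
  }
  out
}

# int_u^v (p + q t) exp(i w t) dt, used for degenerate (linear-ramp) branches
.intpoly <- function(w, u, v, p, q) {
  out <- complex(length.out = length(w))
  zero <- abs(w) < 1e-12
  if (any(zero)) out[zero] <- p * (v - u) + q * (v^2 - u^2) / 2
  if (any(!zero)) {
    ww <- w[!zero]
    iw <- 1i * ww
    anti <- function(t) exp(iw * t) * ((p + q * t) / iw - q / iw^2)
    out[!zero] <- anti(v) - anti(u)
  }
  out
}

#' Closed-form Fourier coefficient of the activity waveform
#'
#' Evaluates the complex Fourier coefficient
#' \deqn{\tilde F(T_n) = \frac{1}{T_0}\int_0^{T_0} F(t)\,
#'   e^{i 2\pi n t / T_0}\, dt}
#' of the periodic model waveform exactly, branch by branch, including the
#' amplitude scale and (for `n = 0`) the baseline offset.  Degenerate
#' rates (`|b| < 1e-6` 1/h) use the analytic linear-ramp limit.
#'
#' @param params A [waveform_params] object.
#' @param n Vector of non-negative integer harmonic indices.
#' @return Complex vector of coefficients; `n = 0` gives the time average
#'   of `baseline + amplitude * F`.
#' @seealso [peak_heights] for the squared magnitudes at the harmonics.
#' @export
fourier_coefficient <- function(params, n) {
  stopifnot(inherits(params, "waveform_params"),
            all(n >= 0), all(n == round(n)))
  p <- params
  t0 <- p$t0
  w <- 2i * pi * n / t0
  wr <- 2 * pi * n / t0 # real angular frequency
  tot <- complex(length.out = length(n))

  # morning decay on [0, t_m)
  b <- p$b_md
  if (abs(b) < .rate_eps) {
    tot <- tot + .intpoly(wr, 0, p$t_m, 1, -1 / p$t_m)
  } else if (b > 0) {
    A <- -expm1(-b * p$t_m) # 1 - e^{-b t_m}
    tot <- tot + .intexp(w, 0, p$t_m) / A -
      exp(w * p$t_m) * .intexp(b + w, 0, p$t_m, s = p$t_m) / A
  } else {
    E1 <- expm1(b * p$t_m) # e^{b t_m} - 1
    tot <- tot + exp(b * p$t_m) / E1 * .intexp(w, 0, p$t_m) -
      .intexp(b + w, 0, p$t_m) / E1
  }

  # morning rise on [t_m, t0): e^{b(t - t0)} - e^{-b (t0 - t_m)}
  b <- p$b_mr
  tot <- tot + exp(w * t0) * .intexp(b + w, p$t_m, t0, s = t0) -
    exp(-b * (t0 - p$t_m)) * .intexp(w, p$t_m, t0)

  # evening rise on [s0, t0/2), s0 = t0/2 - t_e
  b <- p$b_er
  s0 <- t0 / 2 - p$t_e
  ev <- complex(length.out = length(n))
  if (abs(b) < .rate_eps) {
    ev <- .intpoly(wr, s0, t0 / 2, -s0 / p$t_e, 1 / p$t_e)
  } else if (b > 0) {
    D <- -expm1(-b * p$t_e) # 1 - e^{-b t_e}
    ev <- .intexp(w, s0, t0 / 2) / D -
      exp(w * s0) * .intexp(-b + w, s0, t0 / 2, s = s0) / D
  } else {
    D <- expm1(b * p$t_e) # e^{b t_e} - 1
    ev <- exp(b * p$t_e) / D * .intexp(w, s0, t0 / 2) -
      exp(w * t0 / 2) * .intexp(-b + w, s0, t0 / 2, s = t0 / 2) / D
  }

  # evening decay on [t0/2, t0)
  b <- p$b_ed
  ev <- ev + exp(w * t0 / 2) * .intexp(-b + w, t0 / 2, t0, s = t0 / 2)

  tot <- (tot + p$e_ratio * ev) / t0 * p$amplitude
  tot[n == 0] <- tot[n == 0] + p$baseline
  tot
}

#' Analytic harmonic peak heights H(T_n)
#'
#' Squared magnitudes of the waveform's Fourier coefficients at the
#' harmonics `T_n = t0 / n` of the primary period -- the model's
#' prediction for the relative heights of the peaks in a power spectrum
#' of rhythmic activity.  The absolute scale linking `H` to a
#' variance-normalized periodogram is not fixed here; the spectral fit
#' ([spectral_fit]) estimates a single global scale factor, equivalent to
#' anchoring relative heights to the tallest (reference) peak.
#'
#' @param params A [waveform_params] object.
#' @param n_max Largest harmonic index (default 17, which covers the
#'   2--35 h analysis range for any `t0` up to 35 h).
#' @return An object of class `harmonic_spectrum`: a data frame with
#'   columns `n`, `period` (h) and `height`, plus attributes `t0` and
#'   `params`.
#' @examples
#' wp <- waveform_params(-0.81, 0.486, 0.09, 3.6, 5.3, 3.6, 24)
#' peak_heights(wp, n_max = 12)
#' @export
peak_heights <- function(params, n_max = 17) {
  stopifnot(n_max >= 1)
  n <- seq_len(n_max)
  h <- Mod(fourier_coefficient(params, n))^2
  out <- data.frame(n = n, period = params$t0 / n, height = h)
  structure(out, class = c("harmonic_spectrum", "data.frame"),
            t0 = params$t0, params = params)
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  cat("Analytic harmonic spectrum, T0 =", format(attr(x, "t0")), "h\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a harmonic spectrum as tab-delimited text
#'
#' @param x A `harmonic_spectrum` from [peak_heights].
#' @param path Output file path.
#' @export
write_harmonic_spectrum <- function(x, path) {
  stopifnot(inherits(x, "harmonic_spectrum"))
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Power-law exponent of peak heights in the small-period regime
#'
#' For periods well below `2*pi/b`, where `b` is the largest rate
#' magnitude in the model, the analytic peak heights fall off as a power
#' of the period with exponent 4.  This fits `log H(T_n) ~ log T_n` by
#' least squares over harmonics spanning one decade of periods starting
#' one decade below `2*pi/b` and returns the slope.
#'
#' @param params A [waveform_params] object.
#' @param n_max Optional largest harmonic index.  The default covers one
#'   full decade of the asymptotic regime; a value too small to span at
#'   least a factor 4 in period is an error.
#' @return Fitted log--log slope (dimensionless, approximately 4).
#' @export
small_period_exponent <- function(params, n_max = NULL) {
  b_max <- max(abs(c(params$b_md, params$b_mr, params$b_er, params$b_ed)))
  t_hi <- 0.1 * 2 * pi / b_max # one decade below 2 pi / b
  n_min <- ceiling(params$t0 / t_hi)
  if (is.null(n_max)) n_max <- 10 * n_min
  if (n_max < 4 * n_min)
    stop("too few harmonics in the asymptotic regime; raise n_max to at least ",
         4 * n_min)
  n <- n_min:n_max
  h <- Mod(fourier_coefficient(params, n))^2
  Tn <- params$t0 / n
  keep <- h > 0
  unname(stats::coef(stats::lm(log(h[keep]) ~ log(Tn[keep])))[2])
}

#' Predicted Dirichlet-kernel side peaks around a spectral line
#'
#' A finite record of length `L` smears every spectral line with the
#' Dirichlet (periodic sinc) kernel, whose side lobes sit at frequency
#' offsets of odd multiples of `1/(2L)` from the line centre and decay as
#' `(2/((2m+1)*pi))^2` relative to the main peak.  This predicts where the
#' minor peaks flanking a true harmonic appear in period space.
#'
#' @param record_length_h Record length `L` in hours.
#' @param t_n Period of the spectral line, h (must be below
#'   `record_length_h`).
#' @param m_max Number of side lobes per side.
#' @return Data frame with columns `m`, `side` (-1/+1), `freq` (1/h),
#'   `period` (h) and `rel_height` (ideal sinc-squared lobe height
#'   relative to the main peak).
#' @export
dirichlet_sidepeaks <- function(record_length_h, t_n, m_max = 6) {
  stopifnot(record_length_h > t_n, t_n > 0, m_max >= 1)
  f0 <- 1 / t_n
  m <- rep(seq_len(m_max), each = 2)
  side <- rep(c(-1, 1), m_max)
  freq <- f0 + side * (2 * m + 1) / (2 * record_length_h)
  keep <- freq > 0
  data.frame(m = m[keep], side = side[keep], freq = freq[keep],
             period = 1 / freq[keep],
             rel_height = (2 / ((2 * m[keep] + 1) * pi))^2)
}
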