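---
title: "Modeling fly locomotor activity and its harmonic power spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling fly locomotor activity and its harmonic power spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyrhythm)
```

## The model and its assumptions

Fruit fly locomotion, recorded as infrared beam-crossing counts in 20-s
bins, has a stereotyped daily shape: a morning (M) activity peak with a
maximum at lights-on and an evening (E) peak with a maximum at
lights-off. `flyrhythm` describes one cycle as the superposition of a
unit M component and a unit E component, each made of normalized
exponential flanks:

* M: decay at rate $b_{MD}$ over $(0, T_M)$, rebuilt by a rise at rate
  $b_{MR}$ over $(T_M, T_0)$;
* E: rise at rate $b_{ER}$ over $(T_0/2 - T_E, T_0/2)$, decay at rate
  $b_{ED}$ after $T_0/2$.

$T_0$ is the primary (circadian) period and $T_M, T_E$ the peak widths.
Each branch runs from 0 to 1, so the rates control only the *shape*
(concave or convex) of the flanks; $b_{MR}, b_{ED} > 0$ while $b_{MD}$
and $b_{ER}$ may take either sign. The model assumes a **single**
oscillatory period; everything else in the spectrum follows from the
non-sinusoidal shape.

Two conventions required a decision because the branch domains overlap
(the morning rise spans $(T_M, T_0)$ and contains the whole evening
window):

* **Superposition.** All branches active at $t$ add. This reproduces the
  observed two-peaked profile; the alternative, letting the
  latest-starting branch win, is available via
  `eval_waveform(..., overlap = "last")` for comparison. We do not
  renormalize the sum: the E peak then slightly exceeds 1 (by the value
  of the morning rise at $T_0/2$), which is immaterial because fits
  carry a free amplitude.
* **Half-open intervals.** Each branch owns $[{\rm start}, {\rm end})$;
  at $t = T_0/2$ exactly, the evening decay (value 1) applies, not the
  evening rise.

Rates with magnitude below $10^{-6}\,h^{-1}$ are evaluated by their
analytic linear-ramp limit instead of a 0/0 ratio, and every branch is
computed in a form whose exponents are non-positive, so the model stays
finite over the whole $\pm 60\,h^{-1}$ search range of the fits.

```{r waveform}
wp <- genotype_preset("wt")$params
wp
curve(eval_waveform(wp, x), 0, 48, n = 2000, xlab = "Time (h)",
      ylab = "F(t)")
```

## The analytic harmonic spectrum

Because $F$ is periodic, its power spectrum is a line spectrum at the
harmonics $T_n = T_0/n$. Each branch is of the form
$\alpha + \beta e^{\gamma t}$, so the Fourier coefficient
$\tilde F(T_n) = T_0^{-1}\int_0^{T_0} F(t)\,e^{i 2\pi n t/T_0} dt$ has
an exact closed form per branch; `fourier_coefficient()` evaluates it
(with series fallbacks where $|\gamma + i\omega|$ is small) and
`peak_heights()` returns $H(T_n) = |\tilde F(T_n)|^2$. The closed form
is validated in the test suite against adaptive numerical quadrature to
better than $10^{-8}$ relative error, and against an FFT of the densely
sampled waveform; Parseval's identity closes to $10^{-6}$.

Two analytic consequences drive the scientific argument:

* For the reference parameters the 12 h harmonic is ~34 times stronger
  than the 24 h fundamental — the M and E peaks half a period apart
  nearly cancel the odd harmonics. A dominant "12 h rhythm" is thus a
  shape property, not a second oscillator.
* For periods below $2\pi/b$, with $b$ the largest rate magnitude,
  $H(T) \propto T^4$ (`small_period_exponent()` measures the log-log
  slope over one decade of harmonics starting one decade below
  $2\pi/b$). Measured spectra flatten below ~2 h instead, which is why
  all model-based analysis is restricted to 2–35 h.

The absolute scale linking $H$ to a variance-normalized periodogram is
not fixed analytically; the spectral fit profiles out a single global
scale factor, which is equivalent to anchoring relative heights to the
tallest (reference) peak.

## Spectral estimation

`lomb_scargle()` implements the classical variance-normalized Scargle
periodogram on a frequency grid of multiples of $1/(\text{oversample}
\times \text{span})$ (default oversample 8, analysis range 2–35 h). The
grid therefore contains the record's natural Fourier frequencies — for
evenly sampled data the estimator coincides with the classical
periodogram there, which the tests assert to $10^{-6}$.

**Significance.** The false-alarm level for probability $p$ is
$z = -\ln(1 - (1-p)^{1/M})$ with $M$, the effective number of
independent frequencies, taken as the number of independent Fourier
spacings in the scanned band, $\text{span}\cdot(f_{\max} - f_{\min})$;
oversampling adds no independent frequencies. The multiple-testing
correction behind the conventional $p = 0.005$ line is a modelling
choice, so `M` is exposed as a parameter. A Monte-Carlo test confirms
the white-noise calibration.

**Peak positions.** A finite record smears every line with the
Dirichlet kernel, and on the oversampled grid the kernel ripple of a
strong line displaces the continuous maximum of a weak neighbour: for
the noise-free reference waveform, the apex of the circadian
fundamental (34 times weaker than the 12 h line five lobe-spacings
away) sits anywhere between 22.5 and 25.1 h depending on where in the
cycle the record starts. Line positions are therefore refined at the
natural Fourier spacing, where the kernel is critically sampled, using
the amplitude-ratio interpolator $\delta = a_{+1}/(a_0 + a_{+1})$ that
is exact for an isolated rectangular-window line, after subtracting a
robust (median-based) noise-floor estimate that would otherwise bias
the interpolation outward for weak lines. With this refinement the
noise-free spectrum puts every detected peak exactly on a harmonic.

**Side lobes.** The kernel also produces side lobes at odd multiples of
$1/(2\cdot\text{span})$ around strong lines (`dirichlet_sidepeaks()`
predicts them); at realistic count rates they exceed the $p = 0.005$
line and would masquerade as ultradian periodicities. `detect_peaks()`
removes them with an incoherent envelope test: a weaker local maximum
within two lobe spacings of a stronger peak is absorbed (unresolvable),
and between 2 and 6.5 spacings it is dropped if its power lies below
`cap` (default 6) times the summed $1/(\pi D)^2$ sinc-squared envelope
of the stronger peaks. The defaults keep every genuine harmonic in all
simulated genotypes — the tightest case is the long-period mutant,
whose adjacent harmonics sit ~4–5 lobe spacings apart at 5–6 days —
while removing the observed lobes. `estimate_primary_period()`
deliberately skips this exclusion: the tallest in-band peak is never a
side lobe, but a weak circadian fundamental could be mistaken for one.

**MESA.** `mesa()` estimates Burg autoregressive coefficients (via
`stats::ar.burg`) and evaluates the all-pole spectral density on the
same period grid. The AR filter must span at least one full period to
represent it, so finely binned records are rebinned to 5-min bins
before the fit (order $\min(N/3, 1000)$ after rebinning); peak
positions are refined by maximizing the continuous AR spectrum, whose
lines can be narrower than the display grid. MESA has no convenient
significance metric, so only peak *positions* are compared with LS.
On noise-free (perfectly predictable) input, Burg estimation is
degenerate; method comparisons are made on noisy records.

`autocorrelation()` uses the biased (divide by $N$) estimator at 1-min
lags — positive semidefinite by construction — with the conventional
$2/\sqrt{N}$ strong-correlation bound.

## Two-stage fitting

`fit_activity_model()` chains the stages:

1. **Primary period.** In constant darkness, the tallest significant
   peak in the 16–35 h band; under a light/dark cycle the 12 h harmonic
   is usually the strongest line, so the period is twice the tallest
   peak in 8–16 h. Records with no significant in-band peak raise a
   `flyrhythm_arrhythmic` condition that callers may catch.
2. **Time domain.** The record is folded at $T_0$ into 20-min bins.
   The lights-on phase defaults to a template cross-correlation
   estimate. Initial widths are the span of the folded profile above
   baseline + 20% of the peak height around each activity peak — an
   automated surrogate for reading the widths off the binned data by
   eye. Threshold spans are biased for exponential flanks (a 20%
   threshold reads ~1.2 h for a true $T_E = 3.6$ h), so the widths are
   *refined* together with the rates, amplitude, baseline and a small
   phase offset by bounded Levenberg–Marquardt least squares
   (`minpack.lm`), with five jittered restarts; noise-free recovery of
   the generating parameters is exact to within a fold bin.
3. **Spectral domain.** The measured periodogram heights at the
   harmonics $T_0/n$ inside 2–35 h (local maxima within half a
   Rayleigh width of each harmonic, parabolic-interpolated) are fitted
   with $s\,H(T_n)$ by L-BFGS-B, the scale $s$ profiled out
   analytically. Rates are bounded to $\pm 60\,h^{-1}$; at least three
   significant harmonic peaks are required. Because the power spectrum
   is invariant under time reversal — mirror solutions swap the width
   roles — the stage-2 widths are kept within a factor 2 of their
   stage-1 estimates, which carry the branch identification that the
   spectrum cannot.

The spectral objective is nearly flat in directions that barely change
$H$ (for example $b_{ER}$ near zero, where the evening rise is close to
linear), so individual parameters can be recovered much less precisely
than the peak heights themselves; the tests assert height reproduction
and the well-conditioned parameters separately.

Accuracy metrics follow the estimation: the signed per-peak percent
error $(P_{data} - P_{model})/P_{data}\times 100$; the fraction of
significant 2–35 h peaks within ±10% of a harmonic (greedy,
nearest-first, each harmonic absorbing at most one peak; an empty peak
list counts as 100% and is flagged); and the fraction of spectral area
inside windows around the matched harmonics. The window half-width
(unspecified in the underlying method) defaults to $2/\text{span}$, the
full Dirichlet main-lobe width, which covers ~95% of a line's kernel
footprint without absorbing the noise floor between harmonics;
`window_hw` exposes it.

## The synthetic-data generator

`simulate_activity()` draws counts per bin independently from a Poisson
law with mean $\text{baseline} + \text{rate}\cdot F(t)$. Poisson noise
is the natural model for small per-bin event counts and makes the
per-bin mean/variance ratio 1, which the tests check; a
negative-binomial overdispersion hook exists but is off by default. The
default peak rate (0.8 counts per 20-s bin at the waveform maximum,
baseline 0.05) puts 20-min-binned peaks at ~40–50 counts, the scale of
real population recordings. Genotype presets fix the primary period at
24 (wild type; the reference rate and width set), 19, 29.5, and 27 h
(clock mutants; widths $T_M = 0.19\,T_0$, $T_E = 0.29\,T_0$, rates
genotype-independent), and zero amplitude for the arrhythmic controls.

`simulate_cohort()` draws per-fly periods from a normal law (SD 0.3 h,
a typical within-genotype spread) and derives per-fly substream seeds
from a single master seed. By default it also scales each fly's
amplitude with the evening accumulation factor
$(1 - e^{-b_{ER} T_E(T_0)})$ referenced to 24 h: if the underlying
process accumulates at a fixed rate over a window that grows with the
period, a slower clock releases a larger amplitude. This is the
mechanism required for the cohort to exhibit the positive
amplitude–period relation that `amplitude_vs_period_fit()` measures; a
fixed rate scale would make the amplitude flat in $T_0$ by
construction.

What the generator does **not** emulate: light-driven startle
responses, sleep-bout microstructure, within-fly day-to-day parameter
drift, beam-position effects that miss small movements, and weekly
non-stationarities. Passing tests on these simulations therefore show
that the estimation machinery is correct and well calibrated under the
stated noise model — not that real flies satisfy the model; the
flattening of measured spectra below 2 h is a documented regime where
they do not.

## The filtering artifact

`spurious_peak_demo()` reproduces the argument against low-pass
filtering before spectral analysis: zero-phase Butterworth filtering
(order 2, 1 h cutoff by default — settings mirroring prior literature
and exposed as options) removes most of a white-noise series' variance,
so the variance-normalized power of every surviving passband
fluctuation is inflated and the white-noise false-alarm calibration
breaks. Raw noise triggers a significant peak in a few percent of runs;
filtered noise in essentially all of them, without moving genuine
peaks. The filter itself (`butterworth_lowpass()`) demeans and
reflection-pads the series so the forward-backward pass has no edge
transient.

## Problem sizes and numerical choices

Simulation-based tests and the acceptance script use 5–6 day records at
20-s bins (21600–25920 samples), cohorts of 10 flies per genotype, 10
records for fit-error averages, 20 seeds for method agreement, and
20–25 Monte-Carlo replicates for calibration checks — sizes at which
all stochastic summaries are stable at the tolerances asserted.
Optimizer settings (five restarts, 200–500 iteration caps), the
$10^{-6}\,h^{-1}$ degeneracy threshold, the quarter-bin tie-break that
keeps the longer period when adjacent maxima are equal within
$10^{-9}$, and all bounds above are fixed defaults, exposed as
arguments where a practitioner might reasonably vary them.

## Known limitations

* The circadian fundamental of the near-symmetric reference waveform is
  intrinsically hard to localize: its spectral energy is smeared by
  kernel interference from the dominant 12 h line, and LS and MESA
  summarize that energy differently (positions can disagree by ~2% at
  realistic noise even though both are internally consistent). Spectra
  with stronger fundamentals do not show this.
* Parameters that barely move the harmonic heights (small $|b_{ER}|$,
  near-saturated rises) are reported with correspondingly wide
  uncertainty; the spectral stage guarantees the heights, not every
  parameter.
* The analytic spectrum treats noise only through simulation; there is
  no closed-form noise floor.
* The pipeline assumes one primary period per record; split-rhythm or
  multi-oscillator records are outside the model class.
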