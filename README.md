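# flyrhythm

Waveform modeling and harmonic spectral analysis of *Drosophila*
locomotor activity.

## The problem

Multiday beam-crossing recordings of fruit fly locomotion are strongly
non-sinusoidal: activity rises and falls around a morning (M) and an
evening (E) peak every circadian cycle. Power spectra of such recordings
therefore show many statistically significant peaks at periods below
24 h, which have repeatedly been read as evidence for independent
ultradian oscillators. `flyrhythm` implements the competing
interpretation quantitatively: a single-period waveform with realistic
peak shapes predicts *all* of those secondary peaks as harmonics of the
circadian period T₀.

The package is for chronobiologists and quantitative biologists who
analyze activity-monitor data and want to (i) test whether a spectrum is
explained by circadian harmonics, (ii) extract kinetic shape parameters
from recordings, or (iii) simulate realistic activity data with known
ground truth.

## The model

Daily activity is the superposition of a unit M component and a unit E
component, each built from normalized exponentials:

    F(t) = { (e^{b_MD·T_M} − e^{b_MD·t}) / (e^{b_MD·T_M} − 1),      0 < t < T_M
           { (e^{b_MR(t−T_M)} − 1) / e^{b_MR(T_0−T_M)},             T_M < t < T_0
           { (1 − e^{−b_ER(t−T_0/2+T_E)}) / (1 − e^{−b_ER·T_E}),    T_0/2−T_E < t < T_0/2
           { e^{−b_ED(t−T_0/2)},                                    T_0/2 < t < T_0

with morning-decay/rise rates b_MD, b_MR, evening-rise/decay rates
b_ER, b_ED (1/h), peak widths T_M, T_E (h), and primary period T₀ (h);
branches active at the same t add. b_MR and b_ED are positive; b_MD and
b_ER may take either sign. The Fourier coefficients of F are available
in closed form, so the power-spectral peak heights at the harmonics
T_n = T₀/n,

    H(T_n) = | (1/T₀) ∫₀^{T₀} F(t) e^{i 2π n t / T₀} dt |²,

are an analytic prediction that can be fitted directly to a measured
periodogram. For periods below 2π/b (b the largest rate magnitude),
H(T) ∝ T⁴.

Estimation is two-stage, mirroring how the quantities are identified in
practice: a time-domain fit of `baseline + amplitude·F(t)` to the
day-folded 20-min profile initializes the parameters, then the analytic
heights `scale·H(T_n)` are fitted to the significant periodogram peaks
at the harmonics (rates bounded to ±60 h⁻¹, fit range 2–35 h).

## Worked example

```r
library(flyrhythm)

rec <- simulate_activity("wt", days = 5, seed = 42) # Poisson counts, 20-s bins
fit <- fit_activity_model(rec, regime = "LD")
fit
```

```
Activity waveform fit: wt ch01 (LD), T0 = 24.00 h
Activity waveform parameters (T0 = 24 h)
  rates  [1/h]: b_md = -0.7552, b_mr = 0.5386, b_er = 0.02992, b_ed = 3.377
  widths [h]  : t_m = 6.762, t_e = 3.518
  amplitude = 48, baseline = 3.163, E/M ratio = 1
  mean |P.E.| over 9 significant harmonics: 4.1%
  peaks matched to harmonics: 100.0%; area accuracy: 96.1%
```

Reading the output: the primary period recovered from the spectrum is
24.00 h (the generating value is 24); the fitted rates and widths are
close to the generating parameters (−0.81, 0.486, 0.09, 3.6 h⁻¹; 5.3,
3.6 h); the analytic harmonic heights reproduce the measured significant
peak heights with a mean absolute error of 4.1%; every significant
spectral peak between 2 and 35 h lies within 10% of a harmonic T₀/n;
and windows around those harmonics capture 96.1% of the spectral area —
i.e. essentially the whole spectrum is circadian harmonics, with no
residual "ultradian" structure.

`plot(fit)` shows the day-folded profile with the fitted waveform and
the periodogram with the fitted harmonic heights; `coef`, `predict`,
`residuals` and `simulate` behave as for any R model object.

Other entry points: `lomb_scargle()`, `mesa()` and `autocorrelation()`
for spectral estimation with significance levels; `detect_peaks()` with
Dirichlet side-lobe exclusion; `peak_heights()` for the analytic
spectrum; `read_dam_monitor()`/`write_dam_monitor()` for TriKinetics
monitor files; `spurious_peak_demo()` for the filtering-artifact
demonstration; `run_pipeline()` (and `inst/scripts/flyrhythm.R`) for
batch analysis.

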