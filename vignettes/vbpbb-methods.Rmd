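---
title: "Periodic mean bands for periodically correlated series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Periodic mean bands for periodically correlated series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hourly air-pollutant records such as urban NO~2~ concentrations are
*periodically correlated*: their mean and covariance structure repeats on
several nested cycles at once — daily traffic rhythms, weekly commuting
patterns, and an annual weather-driven cycle — superimposed on a slow trend
and heavy, strongly autocorrelated noise. The scientific question is
whether the mean concentration truly varies over a given cycle, and by how
much, with uncertainty statements that respect the correlation structure.

Ordinary bootstrap resampling destroys that structure. A seasonal block
bootstrap (GSBB) preserves the periodic structure at *one* period by only
swapping blocks between positions of the same phase, but every other
component — the other cycles, the trend, the noise — rides along in each
block and inflates the spread of the resampled statistic. The Variable
Bandpass Periodic Block Bootstrap (VBPBB) removes that interference first:
the series is bandpass-filtered with a Kolmogorov–Zurbenko Fourier
Transform (KZFT) filter so that only the component at the frequency under
study survives, and the phase-preserving block bootstrap then runs on the
filtered component. The resulting confidence bands are dramatically
narrower and can reveal periodic structure the unfiltered bootstrap cannot.

## The KZFT bandpass filter

The filter of order $(m, k)$ centred at frequency $\nu$ (cycles per
sample) applies the iterated moving-average weights
$a^{m,k}_u / m^k$ — the normalized polynomial coefficients of
$(1 + z + \cdots + z^{m-1})^k$, equivalently the $k$-fold self-convolution
of the uniform kernel of length $m$ — modulated by a complex exponential:

$$
z(t) \;=\; e^{-i 2 \pi \nu t} \sum_{u=-k(m-1)/2}^{k(m-1)/2}
\frac{a^{m,k}_u}{m^k}\, e^{-i 2 \pi \nu u}\, X(t+u) .
$$

`kz_coefficients()` builds the weights by iterated convolution (exact to
floating-point for these magnitudes; an O($L^2$) convolution oracle in the
test suite confirms agreement to $10^{-13}$). The weights are symmetric,
strictly positive, and sum to one, so the transfer function
$\left|\sum_u w_u e^{-i2\pi(f-\nu)u}\right|$ equals 1 at $f=\nu$ and is the
$k$-th power of the moving average's Dirichlet kernel elsewhere —
iterating the filter ($k\uparrow$) can only deepen off-band suppression.

Two conventions deserve a note because the filter appears with both signs
in the literature:

* **Demodulated output.** We include the carrier factor
  $e^{-i2\pi\nu t}$, so `kzft_transform()` returns the slowly varying
  *complex envelope*: for $X(t)=A\cos(2\pi\nu t + \varphi)$ the output is
  approximately $(A/2)e^{i\varphi}$ on the valid region.
  `reconstruct_component()` then re-modulates,
  $2\,\mathrm{Re}\!\left(e^{+i2\pi\nu t} z(t)\right)$, recovering
  $A\cos(2\pi\nu t+\varphi)$. The pairing is verified by a least-squares
  sinusoid-fit oracle (amplitude within 5%, phase within 0.1 rad).
* **Window rule.** For a target period of $p$ samples the default window
  is $m = 2p + 1$ (`window_for_period()`): the smallest odd window whose
  first transfer null sits at $|f - \nu| = 1/m \approx 1/(2p)$, i.e.
  halfway to the neighbouring frequencies one would want separated. The
  iteration count defaults to $k = 2$, trading a near-Gaussian kernel
  shape against window length ($k(m-1)/2$ samples are incompletely
  filtered at each end).

**Edges and gaps.** The first and last $k(m-1)/2$ samples exhaust the
window. By default they are flagged invalid and excluded downstream
(`edges = "mask"`); an optional mode renormalizes the weights over the
available samples and keeps any sample retaining at least 80% of the
coefficient mass (`edges = "renormalize"`). Isolated interior gaps are
always handled by the same renormalization, with a configurable tolerance
(`max_missing`, default 0.2) interpreted as the missing fraction of
*coefficient mass* — a centre-weighted criterion, so a gap under the bulk
of the kernel counts for more than one at its tail. Windows missing more
than the tolerance yield invalid samples rather than biased ones.

## Periodogram screening

`periodogram()` computes the classical raw periodogram
$I(f_j) = |\mathrm{FFT}(x)|^2/n$ at the Fourier frequencies, after
demeaning; no taper or smoothing, since the screen is visual/ranked peak
picking (`peak_candidates()`, ties broken toward the lower frequency).
Missing values are filled with the series mean first; that choice is
deliberately simple — it slightly damps all line powers equally and is
adequate for deciding *which* frequencies to test, which is all the
periodogram is used for here. Gap-aware spectral estimation is out of
scope.

## Bootstrap bands

### Resampling

`gsbb_resample()` implements the phase-preserving block bootstrap: the
series is rebuilt from blocks (default length = one full period) whose
start positions are drawn uniformly among positions of the same phase
modulo the period. Blocks may wrap circularly; overhanging indices are
wrapped modulo the largest whole number of cycles so the wrap is
phase-neutral even when the period does not divide the series length. For
VBPBB the same resampling runs on the KZFT-filtered component over its
edge-valid region, with phases still referred to the original series'
indexing.

### From resamples to a band

Each resampled block of one period length carries one bootstrap estimate
of the periodic pattern: its value at phase $s$, taken as a deviation from
the grand mean of the pseudo-series it belongs to. The band at phase $s$
is the $(\alpha/2, 1-\alpha/2)$ percentile interval (linear-interpolation
quantiles) of these per-cycle deviations pooled over all blocks within and
across the `n_boot` replicates; the band centre is the periodic-mean point
estimate of the unresampled input.

This cycle-level construction is a genuine design decision, so we spell
out the alternative and why it was rejected. One could instead record, per
replicate, the *per-phase mean* of the whole pseudo-series and take
percentile intervals of those replicate means. That band is narrower — it
scales like the standard error of a mean — but it interacts degenerately
with the horizontal-line significance criterion below: with $d$ phases the
range of $d$ independent phase means is about $5\,\mathrm{se}$ while two
pointwise interval half-widths allow only about $3.9\,\mathrm{se}$, so the
criterion would reject a *flat* series almost surely once $d$ is large
(empirically ~95% of pure-noise series at $d = 100$). The cycle-level band
instead reflects the cycle-to-cycle variability of the periodic component;
under it the criterion keeps its error control (0/200 pure-noise
rejections in the acceptance suite), and the GSBB band approaches the
per-phase spread of the raw data while the VBPBB band shrinks to the
spread of the filtered component — which is precisely the contrast the
method is designed to expose, and the scale on which its published
comparisons operate.

### Significance and summaries

A band indicates significant periodic mean variation when **no horizontal
line fits inside it**: $\max_s \text{lower}_s > \min_s \text{upper}_s$
(`significance()`, which also reports the percentage of phases whose
interval excludes zero). `band_extremes()` reports the intervals at the
phases of the minimum and maximum centre (ties to the earliest phase);
`width_ratio()` summarizes the per-phase GSBB/VBPBB width ratios by median
and quartiles; `r_squared()` is the squared correlation between the
filtered component and the source series on their joint valid region. No
multiple-testing adjustment is applied across tested frequencies —
a caveat for users screening many candidates.

### Reproducibility

All resampling randomness flows from one integer seed; replicate $r$
derives its own stream from $(\text{seed}, r)$, so bands are bit-identical
under a fixed configuration and independent of replicate evaluation order.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `m` | $2p+1$ | samples | first null halfway to neighbouring frequencies |
| `k` | 2 | iterations | suppression vs. edge loss; near-Gaussian kernel |
| `n_boot` | 1000 | replicates | standard for 95% percentile intervals |
| `block_length` | period $d$ | samples | one full cycle per block |
| `alpha` | 0.05 | — | two-sided 95% band |
| `circular` | TRUE | — | uses all phases as block starts |
| `max_missing` | 0.2 | coefficient mass | isolated gaps should not void a window |

## The synthetic generator

`synthetic_spec()` describes an hourly series as level + centred linear
trend + cosine components + AR(1) noise, then missingness and coded-error
sentinels. The defaults emulate an urban hourly NO~2~ record: about
$10^5$ samples at a mean near 20.6 ppb; a dominant winter-high annual
cosine (amplitude 6 ppb, peaking at the January start of the series); a
daily cycle (3 ppb) peaking at the morning rush hour with a second
harmonic (1.5 ppb); a weekly cycle (1 ppb); a slight negative trend
($-3\times10^{-5}$ ppb/h, centred so the configured mean is exact); noise
with marginal standard deviation 8 ppb and lag-1 autocorrelation 0.9
(hourly pollutant residuals are strongly autocorrelated); 2% missing
hours; and 5 coded-error readings written as a sentinel value that the
cleaning stage (`clean_series()`, or the AQS reader's qualifier handling)
must strip. `true_periodic_mean()` returns the analytic per-phase truth at
any period — a component contributes exactly when its period divides the
queried period — which is the recovery oracle used throughout the tests.

**What the generator does not emulate.** Real records are nonstationary:
component amplitudes drift with holidays, weather regimes and events such
as the 2020 shutdowns, and meteorology (wind, temperature) modulates
everything. The generator is deliberately stationary, so passing tests
demonstrate the estimator's behaviour under clean periodic correlation —
they do not certify behaviour under regime shifts, and a fixed-amplitude
component that a stationary analysis finds significant may be washed out
in real data by amplitude variability.

## Problem sizes used in the tests

Desk-scale runs shorten the "annual" period to 720 samples (30 days) so a
full pipeline completes in about a minute: $n = 20{,}000$ gives the same
~28 cycles of the longest period as 11.4 years of hourly data gives of the
true annual cycle, which is the quantity that matters for band estimation.
Type-I behaviour is measured on 200 pure-noise series ($n = 5000$, period
100); recovery accuracy on 50 replicates at amplitude 4 against noise
standard deviation 8. Periodogram tests pick lengths that are common
multiples of the component periods so every line falls exactly on the
Fourier grid.

## Numerical choices

* Coefficients and the windowed transform use FFT convolution
  (`stats::convolve`); agreement with direct summation is part of the test
  suite (below $10^{-10}$).
* Band quantiles use R's default type-7 (linear interpolation) quantiles.
* Peak ties in the periodogram and centre ties in `band_extremes()` break
  toward the lower frequency / earlier phase.
* Degenerate inputs are errors, not guesses: a phase with no valid
  observations, a zero-width VBPBB interval in `width_ratio()`, a series
  too short for its filter. A constant component yields $R^2 = 0$ with a
  warning.
* Frequencies in `frequency_registry()` are exact rationals
  (numerator/denominator in hours) and must correspond to whole-sample
  periods.

## Known limitations

* No systematic optimization of $m$ and $k$ is attempted; they are
  exposed as parameters with the $2p+1$ / $k=2$ defaults.
* The bands are pointwise percentile assemblies, not simultaneous bands.
* Mean-imputation in the periodogram is a screening device only.
* The AQS reader matches sites by printed coordinates within a tolerance
  and treats any non-empty qualifier as a coded error; it does not
  interpret individual AQS qualifier codes.
* With block length equal to the period and circular wrapping, the
  cycle-level band converges (in `n_boot`) to the per-phase empirical
  spread of the analysed series; the bootstrap machinery earns its keep in
  the filtered (VBPBB) path and in propagating grand-mean uncertainty.
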