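# vbpbb

Confidence bands for the periodic mean of periodically correlated time
series, via bandpass-filtered block bootstrapping.

## What problem this solves

Long, regularly sampled environmental records — the motivating case is an
hourly urban NO<sub>2</sub> series — carry several nested cycles at once
(daily, weekly, annual), a slow trend, and heavy autocorrelated noise.
The question "does the mean truly vary over this cycle, and by how much?"
needs uncertainty statements that respect the correlation structure.

The package implements two phase-preserving bootstrap approaches and their
comparison:

* **GSBB** (General Seasonal Block Bootstrap): resamples blocks of the raw
  series only between positions of the same phase modulo the period, so
  the tested periodicity is preserved — but every other component rides
  along in the blocks and widens the bands.
* **VBPBB** (Variable Bandpass Periodic Block Bootstrap): first isolates
  the component at the tested frequency with a Kolmogorov–Zurbenko Fourier
  Transform (KZFT) bandpass filter, then block-bootstraps the filtered
  component. Interfering frequencies and noise are suppressed before
  resampling, giving far narrower bands and more power.

The KZFT filter of order (m, k) at centre frequency ν applies the iterated
moving-average weights a<sub>u</sub><sup>m,k</sup>/m<sup>k</sup> — the
coefficients of (1 + z + … + z<sup>m−1</sup>)<sup>k</sup> — modulated by
e<sup>−i2πνu</sup>:

    KZFT_{m,k,ν}(X)(t) = Σ_u  (a_u^{m,k} / m^k) · e^{−i2πνu} · X(t+u),
    u = −k(m−1)/2 … k(m−1)/2

with window m = 2p + 1 for a target period p and k = 2 by default. A band
is significant when no horizontal line fits inside it (the largest
per-phase lower limit exceeds the smallest upper limit).

The package also provides a raw-periodogram frequency screen, a synthetic
hourly-series generator with recorded ground truth, and a reader for EPA
AQS pre-generated hourly CSV files (site selection by coordinates, hourly
averaging of replicate readings, coded-error stripping).

## Worked example

Simulate a 20,000-hour series with a 30-day "annual" cycle (amplitude
6 ppb) and a daily cycle (3 ppb) buried in AR(1) noise of standard
deviation 8 ppb, then test both frequencies:

```r
library(vbpbb)

spec <- synthetic_spec(n = 20000,
  components = data.frame(label = c("annual", "daily"),
                          period = c(720, 24),
                          amplitude = c(6, 3),
                          phase = c(0, -2 * pi * 8 / 24)),
  seed = 42)
x <- clean_series(synthetic_series(spec))
x
#> <periodic_series> 20000 samples every 1 h from 2010-01-01 00:00 (388 missing, 1.9%)

peak_candidates(periodogram(x), 1, min_frequency = 0.02)
#>   frequency    power  period
#> 1   0.04165 26238.01 24.0096

reg <- frequency_registry(labels = c("annual", "daily"),
                          numerators = c(1, 1), denominators = c(720, 24))
res <- run_vbpbb_analysis(x, reg, config = bootstrap_config(n_boot = 1000, seed = 1))
#>   annual (period 720): VBPBB significant, median width ratio 9.47, R^2 0.218
#>   daily (period 24): VBPBB not significant, median width ratio 4.07, R^2 0.186

res$results$annual$vbpbb
#> <confidence_band> VBPBB, period 720, 95% level, 1000 replicates
#>   center range [-5.834, 5.929]; median width 3.413

band_extremes(res$results$annual$vbpbb)$max_range
#>    lower    upper
#> 4.449559 7.304907
```

Reading the output: the periodogram screen finds the daily line at
0.0417 cycles/hour. The slow cycle's VBPBB band is significant — at its
highest phase the mean sits 4.4–7.3 ppb above the series mean, and no
horizontal line fits inside the band — while the GSBB band at the same
frequency, about 9.5 times wider phase-by-phase (it still contains the
daily cycle and all the noise), detects nothing. The daily component, with
amplitude 3 against the band width produced by the strongly autocorrelated
noise admitted into its passband, does not reach significance in this
realization.

Analyzing a real EPA AQS hourly extract works the same way:

```r
x <- read_aqs_hourly("hourly_42602_2010.csv",
                     site_selector(-118.22688, 34.06659))
cleaning_report(x)
res <- run_vbpbb_analysis(x)   # default eight-frequency registry, periods in hours
```

A thin command-line wrapper with `simulate` and `analyze` subcommands is
installed at `inst/scripts/vbpbb-cli.R`.

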