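# nusquant

Non-uniform sampling (NUS) schedules for **quantitative NOESY** NMR: generate
them, score them without reference data, and measure — on fully synthetic
data — how well each schedule preserves NOE build-up rates and the interproton
distances derived from them, relative to uniform sampling.

## The problem

NUS acquires only a subset of the indirect-dimension (t1) increments of a 2D
experiment and reconstructs the rest computationally, halving (or better) the
acquisition time. For qualitative work this is routine; for *quantitative*
NOESY it is contentious, because NOESY spectra have a high dynamic range
(diagonal peaks can be 10^4 times stronger than the cross peaks of long
interproton contacts) and reconstruction artefacts preferentially corrupt the
weak peaks — exactly the ones carrying distances beyond 3.5 Å. The choice of
sampling schedule, and even of the random seed used to draw it, decides
whether the resulting distances are trustworthy.

`nusquant` implements the machinery to study this question end to end:

- **Schedules** on an N-point Nyquist grid (default 512, 50% coverage =
  exactly 256 sampled increments): Poisson-gap with sinusoidal forward
  weighting, random-shuffle, uniform, and the US-NUS *hybrid* — an unbroken
  uniformly sampled prefix (e.g. the first 30% of the grid) followed by a
  Poisson-gap tail, labelled `N-cov-us-seed` (e.g. `512-50-30-0`). Bruker-style
  `nuslist` files are read and written.
- **Reference-free metrics** from the point-spread function (PSF) of the
  sampling mask: peak-to-sidelobe ratio, relative sensitivity (fraction of a
  decaying signal envelope captured), signal apex-to-artefact ratio (SAAR)
  from a toy-signal reconstruction, and a forward-weighting fraction.
- **Reconstruction** of subsampled interferograms by iterative soft
  thresholding (IST), with the processing chain (first point 0.5, squared
  sine-bell apodization, zero filling, FT).
- **A synthetic NOESY simulator**: spin systems with known distances, a
  mixing-time series (default 7 mixing times, 100–700 ms) of diagonal and
  cross-peak integrals whose cross-relaxation rates scale as r^-6, optional
  full 2D time-domain data with additive noise, and schedule-driven
  subsampling.
- **Quantitation**: PANIC normalization
  I_norm = sqrt(cross_AB x cross_BA) / sqrt(diag_A x diag_B),
  outlier-trimmed linear build-up fits (valid when R^2 > 0.90 and n > 4), and
  the sixth-root distance law

      r_AB = r_ref * (sigma_ref / sigma_AB)^(1/6)

  with r_ref = 1.78 Å (geminal methylene protons) as the reference.
- **Evaluation**: US-versus-NUS fidelity reports — retained fraction of valid
  distances, percentage of distances deviating by more than each cutoff
  (1–9%), signed/absolute mean deviation, L2 norm — plus difference-spectrum
  artefact integration and a one-call experiment driver.

## Worked example

```r
library(nusquant)

h <- generate_hybrid(512, 0.5, 0.30, seed = 0)
h
#> <sampling_schedule 512-50-30-0> kind=hybrid, 256/512 points (50.0%), forward fraction 0.809

m <- schedule_metrics(h)
#> peak_to_sidelobe=2.38 relative_sensitivity=51.92 saar=12.90 forward_fraction=0.809

ex <- run_experiment(list(hybrid = h, rs = generate_random_shuffle(512, 0.5, 0)),
                     direct_size = 256L, seed = 1)
ex
#> <nus_experiment> 2 schedules, 39 reference-valid distances
#>        label           kind retained_percent mean_abs_deviation l2_norm
#>  512-50-30-0         hybrid            94.87             0.8995  0.2427
#>   512-50-0-0 random_shuffle            61.54             5.5863  1.3283
```

Reading the output: both schedules sample 256 of 512 increments, but the
hybrid places 80.9% of them in the first half of the grid where the decaying
signal lives, so it captures 51.9% of the envelope (above its 50% sampling
density) — and after subsampling the same synthetic uniformly sampled NOESY,
IST reconstruction and the full distance pipeline, it retains 94.9% of the
reference-valid interproton distances with a mean absolute deviation of 0.9%.
The random-shuffle schedule at identical coverage retains 61.5% with a 5.6%
mean deviation. That ordering (uniform >= hybrid >= Poisson-gap >=
random-shuffle) is asserted as a median property over seeds in the test
suite.

## Command line

```sh
inst/cli/nusq generate --kind hybrid --grid 512 --coverage 0.5 --us 0.30 --seed 0 -o sched.nus
inst/cli/nusq score sched.nus --grid 512 --json metrics.json
inst/cli/nusq compare ref_distances.csv test_distances.csv --cutoffs 1,2,3,4,5
```

See the methods vignette (`vignettes/quantitative-nus-noesy.Rmd`) for the
model, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical conventions.
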