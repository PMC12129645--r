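---
title: "Sampling schedules for quantitative NOESY: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling schedules for quantitative NOESY}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nusquant)
```

## The model

A 2D NOESY experiment acquired at mixing time $t_m$ yields, for every proton
pair (A, B), two cross peaks and two diagonal peaks. Dipolar cross-relaxation
transfers magnetization at a rate proportional to the inverse sixth power of
the interproton distance,

$$\sigma_{AB} = \sigma_{ref}\left(\frac{r_{ref}}{r_{AB}}\right)^{6},$$

so in the initial-rate regime the PANIC-normalized cross-peak intensity

$$I_{norm}(t_m) = \frac{\sqrt{\text{cross}_{AB}\,\text{cross}_{BA}}}
                      {\sqrt{\text{diag}_A\,\text{diag}_B}}$$

grows linearly, $I_{norm} \approx \sigma_{AB}\, t_m$. Fitting the build-up
over a mixing-time series and referencing the fitted gradient against a pair
of known separation (geminal methylene protons, $r_{ref} = 1.78$ Å) inverts
to the distance:

$$r_{AB} = r_{ref}\left(\frac{\sigma_{ref}}{\sigma_{AB}}\right)^{1/6}.$$

PANIC normalization exists to cancel any factor common to a whole spectrum —
overall scale, common leakage decay — and the package asserts that
invariance as a property test. The sixth root makes distances forgiving of
intensity errors (a 6% rate error is a ~1% distance error), which is why
build-up-based distances survive moderate reconstruction artefacts at all.

Non-uniform sampling enters upstream: only a subset of t1 increments is
acquired, the rest are reconstructed, and any reconstruction bias propagates
into $\sigma_{AB}$ and hence $r_{AB}$. The package's purpose is to measure
that propagation per schedule, against a uniformly sampled reference
processed through the identical chain.

## Schedules

All generators guarantee `count(indices) == round(coverage * grid_size)`
exactly (256 of 512 at 50%), sorted unique 0-based indices, and bit-identical
regeneration from the same seed (one `withr::with_seed` stream per call, no
global state).

- **Poisson-gap**: gaps between samples are drawn as
  $g \sim \text{Poisson}(\lambda \sin\theta)$ with $\theta$ advancing from 0
  to $\pi/2$ across the grid — small gaps early, large gaps late (forward
  weighting). The rate $\lambda$ is rescaled multiplicatively and the
  schedule redrawn until the count is exact; a seeded add/drop repair of the
  closest draw guarantees termination for degenerate regions. Index 0 is
  always sampled (it anchors phasing and reconstruction).
- **Random-shuffle**: a uniform draw without replacement, sorted. Index 0 is
  *not* forced: forcing it would bias the mean sampled index and break the
  unbiasedness property (mean index over seeds equals $(N-1)/2$) that the
  test suite checks against the analytic value.
- **US-NUS hybrid**: a uniform prefix of $k = \text{round}(us \cdot N)$
  increments followed by a Poisson-gap tail over the remaining $N - k$ points
  with the sinusoidal weighting applied over the tail only. `us = 0`
  degenerates bit-identically to Poisson-gap; `us = coverage` to truncated
  uniform sampling. The prefix length uses symmetric rounding
  (round(0.30 × 512) = 154), chosen because it matches the "x% US" naming
  convention most closely; it is centralized in one place. The last grid
  point is not forced to be sampled (configurable nowhere on purpose — no
  convention in the field demands it, and forcing it would perturb the exact
  count logic).

## Reference-free metrics

**Point-spread function.** The PSF is the DFT of the 0/1 sampling mask,
zero-filled (default 4x) so sidelobes are resolvable between grid bins, and
normalized so the main lobe equals the sampling density. Sidelobes predict
where a single resonance smears. Two conventions deserve note:

- The main lobe is taken as `zerofill_factor` bins either side of zero
  frequency — this separates the self-peak from true sidelobes at any
  zero-filling.
- A *complete* schedule has no missing samples and therefore no sampling
  sidelobes: `peak_to_sidelobe` (and `saar`) return an `Inf` sentinel for it.
  The finite-acquisition-window wiggles visible between bins of a complete
  mask are present identically in uniform acquisition and are not counted as
  sampling artefacts.

**Relative sensitivity** weights each grid point by a decaying envelope
$e^{-d\,i/N}$ and reports the captured percentage. Under a flat envelope
($d = 0$) it is exactly 100 x coverage for every schedule kind (an invariant
in the suite). The default $d = 0.2$ is a mild decay consistent with
50%-coverage schedules scoring just above 50% — the regime of a
constant-time-like acquisition; it is exposed via `envelope_model()`.

**SAAR** synthesizes a noiseless toy interferogram (default three decaying
complex cosinusoids at incommensurate frequencies with amplitudes 1, 0.1,
0.01 — a high-dynamic-range caricature), subsamples, reconstructs, and
reports apex over tallest out-of-region magnitude. A caveat found while
validating: with the zero-fill "reconstructor" (the PSF limit),
forward-weighted Poisson-gap schedules score decisively above random-shuffle
(medians 8.0 vs 5.8 over 100 seeds); under IST the ordering *inverts
slightly* (12.8 vs 13.2), because soft thresholding cleans random-shuffle's
incoherent aliasing marginally better on a noiseless sparse signal — the
standard compressed-sensing effect. The distance-fidelity ranking on
realistic synthetic data (below) still favours Poisson-gap. This is a useful
reminder that SAAR rankings are reconstructor-relative.

**NUSscore is not reimplemented** — its formula is unpublished. The
`forward_fraction` descriptor plus the metrics above are offered as
documented surrogates, and `run_experiment` output is a plain data frame so
externally computed scores can be joined and correlated with `pearson_r2()`.

## Reconstruction

The proprietary reconstruction engine used in commercial processing software
is substituted by a standard iterative soft-thresholding (IST) scheme:
transform, shrink magnitudes at a threshold decaying geometrically from
`threshold_start` x max|spectrum| (defaults 200 iterations, 0.99, 0.97),
inverse transform, re-impose measured points. Measured points are preserved
exactly; at full coverage the whole chain is the identity bit for bit. All
comparisons in this package are uniform-versus-NUS *through the same
reconstructor*, so conclusions about schedules do not hinge on the engine.

Numerical behaviour worth knowing: the iteration-to-iteration spectral change
decays as an *envelope*, with small transient upticks (~10% of the current
level) when a component first crosses the falling threshold. The suite
therefore asserts decreasing 25-iteration block maxima rather than strict
monotonicity.

Processing uses first-point scaling 0.5, squared-cosine apodization over the
acquired grid, zero filling (default 2x) and FT; synthetic data are phase 0,
so the real part is the absorption spectrum.

## The synthetic generator: what it emulates, what it does not

`simulate_integrals()` produces the mixing-time series directly at the
integral level. Defaults state the emulated world: 7 mixing times 0.1–0.7 s;
$\sigma_{ref} = 0.05\,s^{-1}$ and leakage $1.0\,s^{-1}$ (arbitrary scales —
only ratios enter the distance law); multiplicative Gaussian noise per
integral. The `relaxation_matrix` model adds spin diffusion via the matrix
exponential of the full rate matrix and serves as the curvature ground truth
(it agrees with the initial-rate model within 5% at 0.1 s on a three-spin
chain and diverges with $t_m$, as a test verifies).

`simulate_fids()` goes one level deeper: each peak becomes a 2D decaying
complex cosinusoid with its integral as amplitude, additive complex Gaussian
noise per time-domain point (default sd 0.001 in units where a diagonal peak
has amplitude ~1 — a high-signal-to-noise small-molecule regime), direct
dimension always fully sampled. The default desk-scale size is 512 x 512
rather than an instrument-scale 2048 x 1024; the indirect grid stays at 512
because every schedule convention here lives on it. The default 12-proton
system spans 1.78–4.5 Å with many pairs beyond 3.5 Å — deliberately, because
long distances are the fragile ones; its distance matrix is a fixed
deterministic assignment and is *not* required to be embeddable as 3D
coordinates, since only pairwise rates enter the physics.

Peak integration subtracts a local bilinear background estimated from
flanking bins in both dimensions. This is the desk-scale analogue of
polynomial baseline correction and matters for the same reason it does on
real spectra: Lorentzian absorption tails of 10^4-stronger diagonal peaks
fall only quadratically and would otherwise swamp the weakest cross peaks.
With it, the noiseless uniform FID round trip recovers all 66 default-system
distances within 0.05%.

For efficiency, `quantify_fids()` reconstructs only the direct-dimension
columns inside peak integration windows — IST along t1 is independent per f2
column, so columns never integrated need not be completed.

Not emulated: chemical-exchange effects, scalar-coupling fine structure,
phase errors, solvent/t1-noise ridges, temperature drift between mixing
times. A green test here establishes that a schedule preserves build-up
linearity and distance accuracy *under ideal phasing and integration*; it
cannot certify robustness to pathologies the generator does not contain.

## Fits, validity and fidelity bookkeeping

Build-up fits use ordinary least squares with a free intercept — the
constraint through the origin is deliberately not imposed; an intercept
absorbs small baseline offsets (including residual integration background).
The outlier rule removes, at most twice, the point with the largest absolute
studentized residual, and only while the fit fails the $R^2$ criterion with
more than five points in hand — so 7 mixing times can shrink to 5, and
already-good fits are never trimmed. A curve is valid when $R^2 > 0.90$ and
more than 4 points were used; validity is a pure function of those two
numbers. Non-positive cross or diagonal integrals exclude that mixing time's
point rather than being imputed.

Fidelity reports compare only pairs valid in *both* tables; pairs valid only
in the NUS table are listed separately and excluded from deviation
statistics. Signed and absolute mean deviations are both reported (hybrids
can show near-zero signed deviation while individual pairs deviate in both
directions); cutoff classification uses magnitudes. Failed runs — a NUS
table that cannot even validate the reference pair — are scored as retained
0% and infinite deviation in ranking tests: such a schedule has failed
maximally, and dropping it as missing would flatter it.

## Measured behaviour of the stated world

With all defaults (10 seeds per kind, 512 x 256 synthetic data, noise
0.001), the median fidelity ordering is

| kind | retained % | mean abs deviation % |
|---|---|---|
| uniform | 100 | 0 |
| hybrid 512-50-30 | 100 | 0.44 |
| Poisson-gap | 89.2 | 4.4 |
| random-shuffle | 10 | Inf |

computed by the acceptance suite itself (`test-acceptance.R`, criterion 7).
Random-shuffle frequently destroys even the reference build-up — its
artefacts scale with the dominant diagonal peaks — while the hybrid's
uniform prefix protects the strong early increments that carry most of the
quantitative information.

## Known limitations

- The IST stand-in is not the proprietary engine used with real data; no
  numeric agreement with commercial software output is claimed or tested.
- PSF metric values are convention-dependent (main-lobe width, envelope
  decay, amplitude vs power ratios) and are treated as qualitative anchors;
  only their documented invariants are asserted.
- Small cramped spin systems (few protons on a small direct grid) can place
  a weak cross peak within the background-curvature reach of a strong
  diagonal, where bilinear baseline subtraction overcorrects; the default
  512-point direct dimension keeps all default-system peaks out of that
  regime.
- Schedules are one-dimensional; no multi-indirect-dimension support.
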