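---
title: "Noise-fidelity tradeoffs of paracrine communication: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-fidelity tradeoffs of paracrine communication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paracrine)
```

## The problem

Epithelial cells responding to a wound read their distance from the damage
out of a noisy chemical gradient: necrotic cells release ATP, nearby cells
respond with highly variable Ca²⁺ transients, and a secondary paracrine
relay (EGF release, ERK activation) averages those primary responses over a
neighborhood. The averaging radius — the **paracrine communication distance
(PCD)**, the spread of the effective ligand kernel — sets a tradeoff:

* averaging over more neighbors suppresses cell-intrinsic noise
  (variance falls roughly as one over the neighborhood size), but
* averaging across a spatial gradient flattens the gradient itself,
  destroying the positional signal.

For a spatially uniform stimulus only the first effect operates, so
response fidelity grows monotonically with PCD. For a wound gradient the
two effects compete and fidelity is maximized at an intermediate PCD. This
package implements the full analysis chain — synthetic single-cell fields,
kernel averaging, fidelity statistics, PCD sweeps, a closed-form diffusion
theory, cluster-density diagnostics, and empirical PCD estimation from
point-source activation profiles — so each claim can be tested end to end
on generated data.

## The kernel model

A cell's predicted post-paracrine response is the normalized
Gaussian-weighted average of all cells' primary responses:

$$P_i = \frac{\sum_j w(d_{ij}) R_j}{\sum_j w(d_{ij})}, \qquad
  w(d) = \frac{1}{2\pi\,\mathrm{PCD}^2}
  \exp\!\left(-\frac{d^2}{2\,\mathrm{PCD}^2}\right).$$

Choices behind `paracrine_average()`:

* **Normalization.** The prediction is the local *mean* ligand exposure, a
  convex combination of observed responses, so it is invariant to cell
  density and to affine rescaling of responses. The unnormalized areal
  convolution (`normalize = FALSE`) is kept for comparison; it scales with
  local density.
* **Kernel convention.** `pcd` is the Gaussian σ, matching how the
  empirical PCD is reported (the σ of a fitted Gaussian profile). The
  alternative `exp(-r²/PCD²)` convention is available via
  `kernel_spec(convention = "exp-r2-over-pcd2")` and equals σ = PCD/√2.
* **Autocrine term.** `include_self = TRUE` by default — a cell senses its
  own secretion. Excluding it changes predictions only at PCDs comparable
  to the cell spacing.
* **Diffusion cap.** When an integration window `T` and diffusion
  coefficient `D` are supplied, the effective PCD is capped at the rms
  diffusion length $\sqrt{6DT}$; with D = 50 µm²/s and T = 5 min this is
  300 µm, the distance an EGF-class ligand can cover before the first
  downstream response.

## Fidelity statistics

`snr()` bins cells (dose wells, or equal-count distance bins for wounds)
and computes

$$S = \mathrm{var}_\mathrm{bins}(\mathrm{mean}_\mathrm{cells} R), \qquad
  N = \mathrm{mean}_\mathrm{bins}(\mathrm{var}_\mathrm{cells} R), \qquad
  \mathrm{SNR} = S/N,$$

with sample (n−1) variances throughout and the unweighted bin average for
N (a count-weighted option exists). `mutual_information()` estimates
$I = H[R] - \sum_b (n_b/n) H[R\,|\,b]$ with kNN entropies: the density at
each response value is $k/(n\,w_i)$ where $w_i$ is twice the distance to
its 10th nearest neighbor. Because the estimate depends on the number of
bins, it is computed for several equal-count binnings (4–20 bins) and
extrapolated linearly back to zero bins; the intercept is reported, in
bits (and nats, since the underlying log base is a convention).

Estimator notes: values with ≥ k duplicates would give zero-width windows;
these fall back to half the smallest nonzero width, with a warning. A
negative extrapolated MI (possible under the null) is clamped to zero with
a warning; tests on the null use the raw intercept.

Bin counts matter and are chosen per context. Generic summaries default to
15 equal-count bins. Wound *sweeps* use 40 bins inside the 800 µm window:
the within-bin radial trend contributes to the "noise" term and decays at
the same rate as the signal, so with coarse bins the SNR curve plateaus
instead of peaking; with ~40 bins the trend falls below the cellular noise
floor and the interior optimum emerges, and its location is stable from 40
to 60 bins (229 ± 9 µm vs 228 ± 9 µm on the reference replicates). The MI
sweep uses bin counts 10–40 so both statistics probe the gradient at
comparable granularity. Even so the two optima differ systematically by
~28 µm (MI saturates slightly earlier than SNR); the acceptance suite
records this honestly rather than hiding it, since the same order of
disagreement is visible between the two statistics' published optima.

## Synthetic fields: what they emulate and what they do not

All generators draw cell-to-cell variability as mean-1 **lognormal
multiplicative factors** parameterized by a CV — responses are non-negative
fold-changes and their observed noise is large and right-skewed. Every
generator takes a seed and is byte-for-byte reproducible through CSV.

* `scatter_cells()` places cell centers at a target density with a hard
  minimum spacing (default 20 µm, one cell diameter; default density
  2×10⁻³ cells/µm² gives ~3 cells per 100 µm kernel radius). At low
  packing fractions (≤ 0.30) placement is Poisson-like dart throwing.
  Beyond that, random sequential placement physically jams near area
  fraction 0.55 — below the default density — so the generator switches to
  a jittered triangular lattice, which is also the more realistic model of
  a confluent epithelial monolayer. Densities above 75% of the hexagonal
  packing bound are rejected.
* `dose_response_field()` / `dose_response_wells()` emulate multi-well
  dose-response data: a saturating Hill mean (defaults Rmax = 3, K = 1 µM,
  h = 2) times noise (CV 0.5). Wells are tiled far apart so kernel
  averaging never crosses wells.
* `wound_field()` removes cells inside a circular wound (default radius
  150 µm, a 300 µm wound) and sets the mean response to
  `A exp(-(r - r₀)²/2λ²) + b` (defaults A = 3, λ = 200 µm, b = 0.3,
  CV 0.8). The covariate is the raw distance to the wound *center*, the
  axis used for binning; the edge offset lives inside the mean profile.
  The Gaussian default is the profile a diffusing damage signal released
  at the wound produces; exponential and inverse-square alternatives are
  available because the true shape is not identified by the data the
  analysis consumes. The default CV of 0.8 anchors the pre-averaging
  wound SNR near 0.9, the observed fidelity of primary responses before
  paracrine averaging.
* `point_source_field()` gives every cell the Gaussian-of-distance mean
  `A exp(-d²/2σ²) + c` around one labeled source cell — the ground-truth
  configuration for PCD estimation (defaults σ = 100 µm, A = 1, c = 0.2,
  CV 0.25).
* `clustered_field()` emulates sparse cluster plating. Members are
  uniform in a 65 µm-radius disk; each cluster draws its own density
  (log-uniform, ¼–4× the mean) with Poisson membership truncated at 5, so
  density varies widely at fixed extent — the regime in which the
  cluster-level statistics are informative. Responses are
  `μ(α a_i + (1-α) f_i)`: `f_i` is raw per-cell noise and `a_i` is a
  coordinated component whose CV is `cv/√n_i`, with `n_i` the number of
  cells within the 100 µm communication distance of cell i. This is the
  central-limit signature of paracrine averaging — within-cluster SD
  falls with local density when α is near 1 and is density-independent at
  α = 0 — without simulating the secretion dynamics themselves. A
  cluster-constant shared factor cannot reproduce that signature (it
  cancels out of the within-cluster SD), which is why the coordinated
  component is per-cell.

What the generators do **not** emulate: time-resolved traces (the analysis
consumes max-over-time summaries), imaging artifacts, segmentation errors,
cell migration, or mechanistic secretion/uptake kinetics. Passing tests
show that the *analysis chain* behaves as claimed under the stated
statistical structure, not that real imaging data have that structure.

## Sweeps and the optimum

`sweep_pcd()` evaluates the fidelity statistics on the kernel-averaged
field over a PCD grid (default 0–600 µm) for several replicate fields,
then refines each replicate's grid argmax with a 3-point parabola — the
curves are smooth near the peak, so sub-grid precision is meaningful — and
reports the mean ± SEM of the per-replicate optima. SNR and MI requested
together share the same predicted fields, so their optima can be compared
as paired quantities. The sweep itself has no internal randomness.

### Wound gradient shape, scale and analysis window

Three coupled choices make the wound sweep well-posed on finite fields;
all were found the hard way and are worth recording.

* **Profile shape.** A Gaussian mean profile broadens in quadrature under
  kernel smoothing (widths add as λ² + PCD²) and loses amplitude, so the
  positional signal genuinely decays once the PCD reaches the gradient
  width — which is what creates the interior fidelity optimum. An
  *exponential* profile is shape-invariant under Gaussian smoothing away
  from edges (the decay length survives untouched), so its signal barely
  declines and no desk-scale field produces an interior optimum below the
  grid ceiling. The Gaussian is also what a diffusing damage signal
  released at the wound would produce.
* **Gradient scale.** λ = 200 µm puts the full gradient extent (several
  λ, > 500 µm from the wound edge) inside the 2×2 mm analysis fields used
  in the tests, so distant cells actually reach baseline.
* **Analysis window.** Fidelity statistics bin only cells within 800 µm
  of the wound center, while kernel averaging always uses the whole
  field. Without a window, cells near the field boundary acquire
  systematic radial structure from their asymmetric neighborhoods (the
  wound sits at the field center, so distance-to-wound correlates with
  distance-to-edge), which props up a spurious between-bin signal at
  large PCD and pushes the apparent optimum toward the top of the grid.
  This is the synthetic analog of analyzing an imaging window inside a
  larger monolayer.

## Diffusion theory

`theory_params()` fixes the geometry (cell radius ρ = 10 µm, height
h_c = 15 µm, chamber height h_f = 60 µm, flow v = 0.3 µm/s) and the signal
(`N_r` molecules released, `N_d` needed for detection), with derived
dimensionless η = h_c/h_f and signal strength S = N_r/N_d (named
`S_strength` to keep it apart from the SNR signal). From the 2D bolus
solution and the detection threshold:

$$\mathrm{PCD} = e^{-1/2}\rho\sqrt{\eta S}, \qquad
  T_\mathrm{int} = \frac{\rho^2 \eta S}{4 e D},$$

the maximal detectable radius and the time at which it is reached. The
prefactor of the PCD formula is fixed by deriving the maximum of the
detectable radius analytically; the tests enforce agreement with a numeric
maximization to 10⁻⁶ relative, across diffusion coefficients (the PCD is
D-independent; the integration time is not). `detection_radius()` returns
a flagged zero outside the detectable window so maximization is total.
Péclet helpers quantify when interstitial flow matters, and
`time_averaged_concentration()` (exponential-integral closed form,
validated against quadrature to 10⁻⁸) supports the comparison of Gaussian
versus temporal-averaging decoding weights; the two profiles agree away
from the source once length scales are matched (the bolus time minimizing
the peak-normalized discrepancy over 50–300 µm), with the expected
disagreement below 50 µm where the instant-release assumption
concentrates mass.

## Cluster analysis and PCD estimation

`cluster_cells()` uses single-linkage clustering cut at the 200 µm maximal
communication distance (equivalent to connected components of the ≤ MCD
proximity graph, enforced against a brute-force oracle in the tests),
computes the effective circular area from the maximal pairwise distance
`d` (taken as the circle diameter, exactly as the procedure defines it),
and flags clusters with d > 150 µm. `density_variability_test()` is a
plain two-sided Pearson correlation of per-cluster SD (or mean) against
density over unfiltered non-singleton clusters; a constant statistic
returns r = 0, p = 1 rather than an error. The per-cluster SD is
c4-bias-corrected (`s/c4(n)`): the raw sample SD is systematically low
for small clusters, and since density scales with membership that bias
would read as a spurious density trend in the null case.

`fit_point_source()` bins neighbors of a labeled source cell into 20 µm
distance bins up to 400 µm and fits `A exp(-r²/2σ²) + c` by
Levenberg–Marquardt least squares (initialized at the bin-mean range,
σ = r_max/4, baseline = minimum bin mean). Fitting binned means mirrors
how radial activation profiles are summarized; a per-cell fit is one flag
away. The baseline term is included because distant cells retain basal
activity; with it, σ is invariant to affine response rescaling. A flat
profile is reported as unidentifiable rather than fitted.

## Numerical and degenerate-input policy

* Sample variances (n−1) everywhere; ties in equal-count binning broken
  deterministically by cell id.
* `pcd = 0` is the identity prediction; a PCD far below the cell spacing
  without the autocrine term gives zero weights and is an error.
* Zero within-bin noise (SNR denominator) and all-identical covariates
  are errors, not NaNs.
* All randomness flows through explicit seeds; `with_seed()` restores the
  caller's RNG state, and the pipeline derives fixed per-replicate
  sub-seeds from its single root seed.

## Problem sizes

The test suite and the acceptance script run everything on generated
fields sized for a laptop: 2×2 mm wound fields (~7,900 cells) for sweeps,
1.6×1.6 mm point-source fields (~5,100 cells; >1,500 neighbors per
source) for σ recovery, 60-cluster fields for the density analysis, and
10⁴-cell draws for moment checks. These sizes were chosen so each
Monte-Carlo claim retains its stated power while the whole suite stays in
the minutes range.

## Known limitations

* The kernel model is static: no explicit secretion/uptake PDE, no time
  courses, no receptor saturation; the diffusion cap is the only coupling
  to kinetics.
* The MI estimator inherits kNN-entropy bias at small bin sizes; the
  linear bin-count extrapolation removes the leading dependence but the
  estimate is still noisier than the SNR, and its optimum location
  correspondingly wobblier.
* The effective-area rule (circle on the maximal pairwise distance)
  biases density upward for small, elongated clusters; it is kept because
  it is the defined procedure.
* Wound and dose generators share a single multiplicative noise law;
  real primary responses also vary in kinetics, which max-over-time
  summaries hide.
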