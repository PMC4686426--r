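# paracrine

Analysis of the noise-fidelity tradeoff in paracrine cell-cell
communication. When cells relay a noisy primary response (e.g. ATP-driven
Ca²⁺ transients after an epithelial wound) through a secreted ligand
(e.g. EGF driving ERK), each cell effectively reads the *local average* of
its neighbors' responses over a characteristic length — the **paracrine
communication distance (PCD)**. Averaging over a larger PCD suppresses
cell-to-cell noise but flattens the spatial gradient that encodes position
relative to the wound, so response fidelity is maximized at an
intermediate PCD. This package is for quantitative cell biologists who
want to run that analysis end to end on single-cell response tables, or to
study its statistical behavior on synthetic fields.

## The model and statistics

Post-paracrine responses are predicted by normalized Gaussian kernel
averaging over cells:

P_i = Σ_j w(d_ij) R_j / Σ_j w(d_ij),  w(d) = exp(−d²/(2·PCD²))/(2π·PCD²)

Fidelity of the binned response (dose wells or distance-to-wound bins) is
quantified as

SNR = S/N,  S = var_bins(mean_cells R),  N = mean_bins(var_cells R),

and, independently, as mutual information between bin and response with
kNN-entropy estimates extrapolated to zero bin count. `sweep_pcd()`
locates the fidelity-maximizing PCD (mean ± SEM across replicate fields).
A closed-form diffusion theory gives the maximal detectable radius
PCD = e^(−1/2)·ρ·√(ηS) for a point-source bolus, the integration time
T_int = ρ²ηS/(4eD) needed to realize it, and Péclet-number bounds on when
interstitial flow matters. `cluster_cells()` + `density_variability_test()`
test the footprint of paracrine coordination (within-cluster SD falling
with cluster density), and `fit_point_source()` estimates the empirical
PCD as the σ of a Gaussian fit to activation versus distance from a
single secreting cell.

Synthetic generators (`scatter_cells()`, `dose_response_wells()`,
`wound_field()`, `point_source_field()`, `clustered_field()`) produce
single-cell fields with the statistical structure these analyses assume,
so the whole chain is testable without imaging data.

## Worked example

Estimate the PCD from a simulated point-source field and compare the
sweep optimum against it:

```r
library(paracrine)

# one secreting cell in a 1.6 x 1.6 mm monolayer, true sigma 99.5 um
pos <- scatter_cells(1600, 1600, 2e-3, 20, seed = 1)
ps  <- point_source_field(pos, profile = list(A = 1, sigma = 99.5, c = 0.2),
                          noise = noise_model(0.25), seed = 2)
fit <- fit_point_source(ps, bin_width = 20, r_max = 400)
fit
#> <pcd_fit> sigma (PCD) = 101.1 um, A = 0.972, c = 0.201 (972 cells)

# closed-form theory: signal strength needed for a 100 um PCD, and the
# integration time this requires at D = 10 um^2/s
p <- theory_params(rho = 10, h_c = 15, h_f = 60, D = 10)
s <- signal_strength_for_pcd(100, p)
p2 <- theory_params(rho = 10, h_c = 15, h_f = 60, D = 10,
                    N_r = s * 100, N_d = 100)
c(S_strength = s, T_int_min = integration_time(p2) / 60)
#>  S_strength   T_int_min
#> 1087.312731    4.166667
```

The fitted σ recovers the generating 99.5 µm spread to within its
sampling error; the theory says a 100 µm PCD needs a released-to-detected
molecule ratio of ~1100 and about 4.2 min of signal integration at
D = 10 µm²/s — inside the ~5 min window before the first downstream ERK
response.

A full wound analysis is one call:

```r
b <- run_pipeline(list(scenario = "wound", seed = 1, n_replicates = 5,
                       grid = seq(0, 600, by = 50)), out_dir = "out")
b$result
```

which generates replicate wound fields, sweeps the PCD, and reports the
fidelity-maximizing PCD with its SEM (fields, results and a manifest are
written under `out/`).

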