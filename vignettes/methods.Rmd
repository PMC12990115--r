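---
title: "Methods: from labeled-peptide trajectories to FRET observables and looping kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from labeled-peptide trajectories to FRET observables and looping kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretmd)
```

This vignette documents the models behind each analysis stage, the
tunable parameters and their defaults, the numerical choices made where
the underlying methods leave freedom, and what the synthetic generators
do and do not emulate.

## Geometric observables

A trajectory is an `md_frames` object (frames × 3·atoms, nm, ps); the
labeled atom groups live in a `label_map`. The donor–acceptor distance
R_ee is the distance between the midpoint of the Trp indole fusion bond
and the midpoint of the Dbo diazo group; R_CαCα is the terminal Cα–Cα
distance; R_g is the mass-weighted radius of gyration about the center
of mass. Distances are computed on unwrapped coordinates with no
minimum-image correction: intramolecular separations of short peptides
are far below half of a typical 5 nm box, so periodic wrapping never
enters.

The orientational factor is the standard Förster expression

$$\kappa^2 = (\cos\theta_T - 3\cos\theta_D\cos\theta_A)^2,$$

with θ_D, θ_A the angles of the donor and acceptor transition dipoles to
the end-to-end vector and θ_T the inter-dipole angle. This is the only
form bounded in [0, 4] whose isotropic dynamic average is 2/3, and the
package's Monte-Carlo test verifies that limit to ±0.002 at 10⁶ draws.
A variant with sin θ_T sometimes appears in print; it fails both
properties and is not implemented. Dipole direction is the normalized
vector between the two atoms of each dipole pair; κ² is even under
dipole inversion, so the sign convention is immaterial (tested). Which
atoms best represent the Trp and Dbo transition dipoles is a
spectroscopic modeling choice the user makes through the label map.

Trajectory input is multi-model PDB or DCD + PDB topology (via bio3d,
Å converted to nm on read). Neither format carries physical time, so
frame times are `(0:(n-1)) * dt` with user-supplied `dt`.

## Distance-distribution model

The R_ee density is modeled as a sum of Jacobian-weighted Gaussians,

$$P(R) = \sum_{j=1}^{3} A_j\,R^2\exp\!\left[-\tfrac12\left(\frac{R - r_j^0}{\sigma_j}\right)^2\right].$$

The R² prefactor is read as the polymer end-to-end Jacobian (the volume
element that skews each component toward larger R), which is the usual
convention for FRET-derived distance distributions of flexible chains.
Three components are the default because compact disordered ensembles
are multimodal at short distances — exactly the region that dominates
donor–acceptor contact — and a two-component model demonstrably fits
bimodal data no better (asserted as a regression-style test:
3-component residual ≤ 2-component residual).

Fitting choices, none of which the model itself dictates:

- **Binning**: Freedman–Diaconis bin width on a density-normalized
  histogram. FD adapts to sample size and spread without tuning.
- **Optimizer**: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`)
  with 10 multi-starts: the first seeded from histogram local maxima,
  the rest from deterministic quantile-based spreads with per-start
  jitter. Bounds: centers in (10⁻⁴, max sample) nm, widths in
  (10⁻³, range) nm, amplitudes positive. The best residual wins.
- **Identifiability**: components are returned sorted by center
  (ties by width), so the labeling is deterministic.
- **Degenerate input**: zero-variance samples are rejected outright
  rather than returning a collapsed fit.

## Free-energy landscape and block averaging

ΔF(R_g, SASA) = −RT ln(n/N) on a 50×50 grid spanning the data ranges
(R = 8.314 J mol⁻¹ K⁻¹, T defaulting to 300 K). Empty cells are masked
(`NA`), not set to +∞: downstream statistics and plotting then ignore
them naturally. SASA is consumed as a precomputed input column; the
package does not compute surface areas. The most-populated cell attains
the minimum ΔF by construction, and duplicating the whole sample leaves
the surface unchanged (n and N scale together) — both tested.

Statistical errors of correlated means use block averaging: block sizes
geometrically spaced from 1 to N/4, error(b) = sd(block means)/√(blocks).
The reported error is taken at the largest block size with ≥ 4 blocks —
the plateau end, where blocks are longer than the correlation time. For
i.i.d. data this reduces to σ/√N; for an Ornstein–Uhlenbeck series it
recovers the √(2τ_c/dt) inflation of the naive error (both tested, to
within the considerable sampling noise of a 4-block estimate).

## Conformational clustering

Daura-style greedy clustering: repeatedly take the structure with the
most neighbors within the RMSD cutoff as a center, remove it and its
neighbors as a cluster, iterate. Choices:

- **RMSD with superposition** (translation + rotation, Kabsch via
  `bio3d::fit.xyz`), so clusters group shapes, not poses. The package's
  tests check it against an independent SVD Kabsch implementation.
- **Tie-breaking**: equal neighbor counts resolve to the lower
  structure index, making assignments fully deterministic; the test
  suite verifies exact agreement with an exhaustive O(N²) reference
  implementation on 200 random structures.
- **Cluster ids** are 0-based and ordered by population (stable on
  ties); a `stride` parameter supports the usual practice of clustering
  a subsampled trajectory (e.g. 100 ps spacing).
- Typical cutoffs for peptide heavy-atom RMSD are 0.2–0.35 nm; the
  cutoff is always explicit, never defaulted silently.

The cumulative cluster curve (distinct ids seen up to each time) is the
standard convergence diagnostic: a plateau means no new conformations
are being discovered.

## Contact kinetics

A contact event is the first passage of R_ee(t) below the sink radius
r: sample i is an event when R_ee(t_{i−1}) > r and R_ee(t_i) ≤ r. The
intercontact intervals Δ_k are the times between successive events
(the trace necessarily re-crosses r upward in between, so no separate
debouncing rule is applied beyond smoothing). The estimator

$$T = \frac{\langle\Delta^2\rangle}{2\langle\Delta\rangle}$$

is the mean time between contacts of a diffusion-limited process: for
exponential intervals (Poissonian contacts) it equals the mean interval;
for constant intervals it is half of one. Its standard error is
propagated by the delta method from the variance and covariance of the
two interval moments, treating intervals as independent; a bootstrap
cross-check in the tests agrees within 25% on 10⁴ exponential
intervals. By Cauchy–Schwarz T ≥ ⟨Δ⟩/2 always.

Traces are prefiltered with a Savitzky–Golay filter before detection
(defaults: window 51 frames, polynomial order 3, both configurable).
The window choice removes sub-ps noise while leaving ns-scale barrier
crossings intact; the filter's defining property — polynomials up to the
filter order pass through unchanged — is tested directly.

The viscosity correction is the Kramers-type linear rescaling
T_corr = T × η_target/η_model. With η(D₂O) = 1.10 mPa s and the SPC
model's 0.445 mPa s the factor is 2.472 — always computed from the two
viscosities, never hard-coded. Uncertainties scale by the same factor.

Sink-radius optimization is an explicit grid search (default
0.40–0.55 nm in 0.001 nm steps, bracketing the 0.44–0.50 nm optima
typical of Trp/Dbo peptides with the grid step matching the 3-decimal
reporting precision) minimizing |T_corr(r) − T_exp|/T_exp. Ties resolve
to the smallest radius; an optimum on the grid boundary is flagged
rather than trusted. Radii yielding fewer than two intervals are
skipped; if no radius qualifies, the optimizer refuses rather than
extrapolating.

## Time-series indicators

**ACF**: mean-subtracted, variance-normalized, via zero-padded FFT (no
circular wrap); the biased (divide-by-N) normalization keeps the
estimate positive semidefinite. The integrated correlation time is the
trapezoidal integral to the first zero crossing τ₀, with the crossing
located by linear interpolation; an ACF that never crosses zero is
integrated to the maximum lag and flagged, since truncating at a
noise-induced crossing is the standard way to keep the integral from
wandering.

**Hurst exponent**: classical rescaled-range analysis on disjoint
windows, sizes log-spaced from 16 to N/4 (12 sizes). The default
estimate applies the Anis–Lloyd finite-sample correction — the expected
R/S of an uncorrelated series deviates from the asymptotic √n law at
small windows, which biases the raw slope upward by several hundredths
even at 2¹⁶ samples. The raw slope is returned alongside. Recovery of
H = 0.5 (white) and H = 0.8 (fractional Gaussian noise with known H) is
tested to ±0.05 and ±0.07 respectively.

**Spectral exponent**: Welch PSD (Hann windows, 50% overlap,
per-segment mean removal; default segment 1024 samples) with
S(f) ∝ f^−α fitted by log–log regression over the high-frequency
region. Two fit-band choices matter and are both parameters: the band
is the upper half of the log-frequency span (`fit_fraction = 0.5`),
and it is capped below half the Nyquist frequency
(`fmax_fraction = 0.5`) because the discrete-time spectrum of Brownian
noise, ∝ 1/sin²(πf dt), flattens near Nyquist and would otherwise bias
α low. Noise classes follow the conventional regimes — white for
α < 0.5, 1/f for 0.5 ≤ α < 1.5, Brownian for α ≥ 1.5 — the thresholds
being midpoints between the nominal exponents 0, 1, 2.

Both H and α are invariant under affine transforms of the series
(tested), as scale-free indicators must be.

## NEMD shear viscosity

A cosine acceleration field a_z(x) = A cos(2πx/L_x) (reference
amplitude A = 0.025 nm ps⁻²) drives a steady velocity profile whose
amplitude V follows from steady-state Navier–Stokes as
V = ρA/(ηk²), k = 2π/L_x. The analysis half implemented here projects
each measured profile onto cos(kx) (exact least squares for a single
basis function), converts to instantaneous inverse viscosity
1/η = Vk²/(ρA) — with nm/ps units this is (Vk²/A)·10⁶/ρ in m s kg⁻¹ —
and reports η as the reciprocal of the block-averaged mean inverse
viscosity, with the block error propagated through the reciprocal.
The unit conversion is pinned by a hand-converted constant in the
tests, and the generator/analysis round trip is exact to machine
precision without noise.

## Synthetic generators: what they emulate, and what they do not

Every stage has a seeded generator providing ground truth:

- `gen_ou_trace`: exact-discretization Ornstein–Uhlenbeck process
  (default mean 0.9 nm, σ 0.2 nm, τ 100 ps — the scale of a compact
  labeled peptide's R_ee fluctuations). Positivity is enforced by
  clipping at 10⁻³ nm; for the default parameterization clipping is a
  > 4σ event and the clip count is reported. An OU trace is Markovian:
  it emulates relaxation and crossing statistics but not the long-range
  memory (H > 0.5) or 1/f spectra of real peptide dynamics — those are
  exercised by `gen_fgn` and `gen_powerlaw_noise` instead.
- `gen_fgn`: fractional Gaussian noise by Davies–Harte circulant
  embedding (exact stationary covariance, unit variance; the fGn
  eigenvalue spectrum is non-negative so the embedding never fails).
- `gen_powerlaw_noise`: spectral synthesis with amplitudes f^(−α/2) and
  random phases, rescaled to unit variance.
- `gen_mixture_samples`: rejection sampling from the R²-weighted
  mixture density, with amplitudes derived from requested component
  probabilities by numeric normalization.
- `gen_random_dipoles`: i.i.d. uniform orientations on the sphere —
  the Monte-Carlo oracle for ⟨κ²⟩ = 2/3.
- `gen_bead_chain`: overdamped Euler–Maruyama dynamics of a harmonic
  chain with angular stiffness. It is deliberately schematic — no
  excluded volume, no solvent, bonds ~0.38 nm — and exists to exercise
  the geometry/clustering/landscape code paths end to end; low vs high
  stiffness reproduces the flexible-vs-rigid (GS-like vs
  polyproline-like) extension contrast qualitatively only.
- `gen_velocity_profile`: inverts the same Navier–Stokes closed form
  the analysis uses (density default 972 kg m⁻³, a typical SPC value),
  so the noiseless round trip is exact by construction; noisy profiles
  test the error propagation instead.

Consequently, passing tests demonstrate estimator correctness on
processes with known truth; they do not demonstrate that microsecond
peptide trajectories are well described by these processes. Real R_ee
series are non-Markovian, non-Gaussian near contact, and have
state-dependent noise; the indicator set (τ_corr, H, α) is designed to
measure exactly those departures.

## Problem sizes and determinism

Test and acceptance runs use: 10⁶ orientations for the κ² limit, 2¹⁶
samples for Hurst/PSD recovery, 10⁵ exponential intervals for the MFCT
law, 5·10⁴ samples for mixture recovery, 200 structures for the
clustering equivalence, 2·10⁵-step OU traces for kinetics — sizes at
which each estimator's sampling error is several times smaller than its
acceptance band, while the whole suite runs in well under a minute.
All generators are bit-reproducible given a seed; the pipeline report
is byte-identical across reruns of the same configuration.

## Known limitations

- No XTC/TRR/GRO readers: supported inputs are multi-model PDB,
  DCD + PDB, and delimited traces. Conversion from other formats is
  left to standard tools upstream.
- The mixture fit offers no model-selection machinery beyond comparing
  residuals at user-chosen component counts.
- The delta-method MFCT error assumes independent intervals; strongly
  correlated successive intervals would need a blocked variant.
- R/S Hurst estimation, even corrected, carries O(0.05) uncertainty at
  2¹⁶ samples; DFA or wavelet estimators are out of scope.
- The bead-chain generator is a code-path exerciser, not a peptide
  model; quantitative ensemble claims require real trajectories.
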