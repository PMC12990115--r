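# fretmd

Analysis of fluorophore-labeled peptide MD trajectories for quantitative
comparison with time-resolved FRET experiments.

Short peptides carrying a donor/acceptor pair (e.g. Trp at the N-terminus
and the Dbo fluorophore at the C-terminus) are standard model systems for
intrinsically disordered protein segments. MD simulations of such peptides
produce two things an experiment can check: the **equilibrium ensemble**
(end-to-end distance distributions, κ², free-energy landscapes,
conformational clusters) and the **looping kinetics** (how often the chain
ends meet). `fretmd` implements the full trajectory-to-table analysis:

- **Geometry**: per-frame donor–acceptor end-to-end distance R_ee (midpoint
  of the Trp indole fusion bond to midpoint of the Dbo diazo group),
  terminal Cα–Cα distance, mass-weighted radius of gyration, and the FRET
  orientational factor κ² = (cos θ_T − 3 cos θ_D cos θ_A)², whose isotropic
  dynamic average is 2/3.
- **Ensemble descriptors**: the R_ee distribution fitted by a sum of three
  Jacobian-weighted ("skewed") Gaussians
  P(R) = Σ_j A_j R² exp[−½((R − r_j⁰)/σ_j)²]; Boltzmann-inversion
  free-energy surfaces ΔF(R_g, SASA) = −RT ln(n/N) on a 50×50 grid;
  block-averaging errors for correlated series.
- **Clustering**: Daura (GROMOS-style) greedy RMSD neighbor-count
  clustering with deterministic tie-breaking, plus cumulative-cluster
  convergence curves.
- **Contact kinetics**: Savitzky–Golay prefiltering, first-passage contact
  detection below a sink radius r, the mean first-contact time estimator
  T = ⟨Δ²⟩ / 2⟨Δ⟩ with delta-method uncertainties, Kramers-type viscosity
  correction T_corr = T × η_target/η_model, and grid-search optimization of
  r against an experimental contact time.
- **Time-series indicators**: FFT autocorrelation with integrated
  correlation time, rescaled-range Hurst exponent (Anis–Lloyd corrected),
  Welch power spectral density with power-law exponent α and
  white / 1/f / Brownian noise classification, zero-lag cross-correlation.
- **NEMD viscosity**: shear viscosity from cosine-perturbation velocity
  profiles, 1/η = V k² / (ρA), summarized with block-averaged errors.
- **Synthetic data**: seeded generators (Ornstein–Uhlenbeck traces,
  fractional Gaussian noise, power-law noise, mixture samples, isotropic
  dipoles, bead chains, velocity profiles) giving every stage a known
  ground truth without microsecond MD output.

Units are nm and ps throughout; readers convert Å-based formats on
ingestion. Supported trajectory input: multi-model PDB, or DCD with a PDB
topology; scalar traces travel as two-column delimited text
(`time_ps`, `value_nm`).

## Worked example

Estimate looping kinetics from a distance trace (here a synthetic
Ornstein–Uhlenbeck stand-in for R_ee(t); a real trace would come from
`extract_traces()` or `read_trace()`):

```r
library(fretmd)
tr <- gen_ou_trace(mean = 0.65, relaxation_time = 200, stationary_std = 0.12,
                   n = 2e5, dt = 1, seed = 11)
sm <- smooth_trace(tr, window = 51, polyorder = 3)
ev <- detect_contacts(sm, r = 0.47)
ev
#> <contact_events: 209 events, 208 intervals, r = 0.47 nm>
mfct(ev); mfct_uncertainty(ev)
#> T_sim  = 1.455 ns +/- 0.152 ns
viscosity_correct(mfct(ev), eta_target = 1.10, eta_model = 0.445)
#> f      = 2.472
#> T_corr = 3.596 ns
spectral_summary(tr)
#> tau_corr = 174 ps, H = 0.83, alpha = 1.92 (brownian)
```

The smoothed trace crosses below the 0.47 nm sink radius 209 times; the
interval moments give a simulated mean first-contact time of 1.46 ns,
which the D₂O/SPC viscosity ratio (f = 2.472) rescales to 3.60 ns for
comparison with experiment. The indicator block shows the OU trace's
short memory (τ_corr ≈ its 200 ps relaxation time) and diffusive spectrum
(α ≈ 2), as expected for a Markovian stand-in.

`run_pipeline(analysis_config(...))` chains all stages (traces →
distribution fit → clustering → kinetics → indicators) into one
`peptide_report`, serializable with `write_report()`.

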