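# glycopmf

Analysis machinery for biased and unbiased molecular-dynamics studies of
glycoside hydrolase catalysis — and, more generally, for any workflow that
turns sampled collective variables (CVs) into Gibbs-energy profiles and
conformational bookkeeping.

Glycosidases such as α-amylase cleave their substrate in a glycosylation
step whose free-energy barrier, reaction coordinate and ring-puckering
itinerary are routinely characterized with umbrella-sampling QM/MM MD plus
the weighted-histogram analysis method (WHAM), and with long classical MD
plus histogram projections and RMSd clustering. `glycopmf` implements that
entire analysis layer as a tested R package, together with a synthetic
biased-dynamics generator with analytically known free energies, so every
stage can be validated end-to-end without any enzyme trajectory.

## What is implemented

- **Synthetic data** (`simulate_langevin`, `generate_umbrella_set`,
  `generate_ring_conformer`, `generate_active_site_series`): overdamped
  Langevin sampling on analytic potentials (harmonic, quartic double well
  `U(x) = ΔU‡((x/b)² − 1)²`, tabulated), fixed and moving harmonic biases,
  ideal six-ring geometries at any canonical pucker, and Gaussian-mixture
  active-site distance series. All generators are pure functions of their
  seed.
- **Free energy** (`direct_projection`, `wham_solve`,
  `conformation_weights`, `reweighted_projection`, `convergence_check`,
  `tst_convert`): binned projections `ΔG_i = −k_B T ln(k_i/k_0)`; the
  self-consistent binned WHAM equations

      ρ(x) = Σ_j h_j(x) / Σ_j N_j exp(−β(U_j^bias(x) − F_j))
      F_j  = −k_B T ln Σ_x ρ(x) exp(−β U_j^bias(x))

  with per-conformation weights `p_i ∝ 1/Σ_j N_j exp(β(F_j − U_ij^bias))`
  for reweighted projections onto arbitrary CVs; direct/reverse cumulative
  time-block convergence analysis against the 1 kcal·mol⁻¹ criterion; and
  the Eyring conversion `k = (k_B T/h) exp(−ΔG‡/RT)`.
- **Ring puckering** (`cremer_pople`, `classify_conformer`,
  `pucker_series`): Cremer–Pople `(Q, φ, θ)` from the classical mean-plane
  construction and nearest-vertex classification into the 38 canonical
  conformers (²S_O, ²H₃, E₃, B₃,O, ⁴C₁, ...), with the table generated
  programmatically from ideal displacement patterns.
- **Collective variables** (`pair_distance`, `nearest_solvent_distance`,
  `reaction_coordinate`, `d_actsite`, `d_react`, `contact_occupancy`):
  heavy-atom and min-pair distances, the glycosylation reaction coordinate
  `d_glyc − d_acid`, the composite variables
  `d_actsite = d_acid + d_nuc + d_Glu233–WAT` and
  `d_acid − d_glyc–WAT + d_nuc`, and contact-occupancy fractions.
- **Conformations** (`superpose`, `rmsd_series`, `gromos_cluster`,
  `select_seed`, `kmeans_representatives`): Kabsch superposition, Gromos
  clustering with an RMSd cutoff (default 1.2 Å) and the occupancy-gated
  (>10%) farthest-centroid seeding rule, plus seeded k-means
  representatives.
- **Workflow/IO** (`read_cv_table`, `read_trajectory`, `run_pipeline`,
  `glycopmf_cli`): tab-separated CV tables, multi-model PDB / XYZ, JSON run
  configs with up-front validation, two chained workflows
  (`cmd_projection`, `umbrella_wham`) with provenance logs, and a CLI
  (`simulate`, `pucker`, `cvs`, `wham`, `project`, `cluster`, `run`).

## Worked example

Recover a known 5 kcal·mol⁻¹ double-well barrier from 26 umbrella windows
(0.10 Å spacing, k = 150 kcal·mol⁻¹·Å⁻², 20 000 samples each):

```r
library(glycopmf)

dw <- potential_spec("double_well", list(barrier = 5, half_separation = 1))
windows <- generate_umbrella_set(dw, centers = seq(-1.25, 1.25, by = 0.1),
                                 force_constant = 150,
                                 steps_per_window = 20000, seed = 7,
                                 dt = 5e-4)
wh <- wham_solve(windows, n_bins = 200, range = c(-1.25, 1.25))
wh$solution
#> <wham_solution> 26 windows, 200 bins; 916 iterations; converged: TRUE
x <- wh$profile$centers[[1]]
wh$profile$dG[which.min(abs(x))]      # barrier at x = 0
#> 4.99  (analytic: 5.00)

convergence_check(windows, "direct", n_blocks = 4,
                  range = c(-1.25, 1.25))$deviations
#> 0.37 0.12 0.07   # successive cumulative-PMF deviations, kcal/mol

cremer_pople(generate_ring_conformer("2SO", Q = 0.57))
#> <pucker_state> 2SO  Q = 0.570 Å, phi = 150.0°, theta = 90.0°

tst_convert(14.4, "barrier_to_rate", 310)
#> 455 s^-1
```

The recovered barrier agrees with the analytic surface to 0.01
kcal·mol⁻¹ here; the acceptance tests require ±0.3 over the whole profile.
The convergence deviations fall below the 1 kcal·mol⁻¹ criterion, the
generated skew-boat measures exactly on the canonical ²S_O vertex of the
puckering sphere, and a 14.4 kcal·mol⁻¹ barrier corresponds to ~455 s⁻¹ at
310 K under transition-state theory.

The same analysis from the command line:

```sh
glycopmf simulate --potential double_well --barrier 5.0 --wells 1.0 \
    --windows -1.25:1.25:0.1 --k 150 --steps 20000 --seed 42 --out windows/
glycopmf wham --manifest windows/manifest.json --bins 200 --tol 1e-6 \
    --out pmf.tsv
```

(the `glycopmf` wrapper is installed at
`system.file("bin", "glycopmf", package = "glycopmf")`).

## Documentation

Function-level documentation is in the roxygen comments under `R/`; the
methods vignette (`vignettes/methods.Rmd`) describes the statistical model,
the synthetic world and its limitations, and the numerical choices.
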