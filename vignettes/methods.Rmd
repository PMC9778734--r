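---
title: "Methods: free-energy reconstruction, ring puckering and clustering in glycopmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(glycopmf)
```

# Scope

`glycopmf` implements the analysis layer of two standard workflows in
computational enzymology, exemplified by glycoside hydrolases such as
α-amylase:

1. long classical MD → named active-site distances → binned Gibbs-energy
   projections → Gromos clustering with occupancy-gated re-seeding;
2. umbrella-sampling (QM/MM-style) MD along a reaction coordinate → WHAM →
   per-conformation reweighting onto arbitrary collective variables →
   time-block convergence analysis → ring-puckering itinerary.

It does **not** run any dynamics engine. Instead a synthetic generator
produces biased trajectories on analytic potentials whose free energy is
known in closed form, which is what makes every downstream stage testable
to stated tolerances.

Units are fixed throughout: Å, ps, K, kcal·mol⁻¹, with
k~B~ = 0.0019872041 kcal·mol⁻¹·K⁻¹ and a default temperature of 310 K.

# The synthetic world

## Overdamped Langevin sampling

`simulate_langevin()` integrates Brownian (overdamped Langevin) dynamics
with the first-order Euler–Maruyama scheme

$$x \leftarrow x - \frac{\Delta t}{\gamma}U'(x)
  + \sqrt{2 k_B T \Delta t / \gamma}\;\xi,\qquad \xi \sim \mathcal N(0,1).$$

This choice is deliberate: the engine that produced the data is irrelevant
to the analysis mathematics, and overdamped dynamics samples the Boltzmann
distribution of $U$ exactly in the small-step, long-time limit, so the
generating potential doubles as the exact PMF. Reflecting walls at the
potential-domain edges prevent escape from tabulated surfaces without
disturbing interior statistics.

**Time step.** With stiffness $\kappa$ (potential curvature plus bias force
constant) the scheme is accurate and stable for
$r = \Delta t\,\kappa/\gamma < 0.1$. The default picks $r = 0.05$. Two
competing errors govern this choice:

- the discrete chain's stationary variance is inflated by a factor
  $\approx (1 - r/2)^{-1}$, i.e. a *systematic* error of about $r/2$;
- successive samples decorrelate over $\tau \approx 1/r$ steps, so a run of
  $n$ steps carries $n_\mathrm{eff} \approx n\,r/2$ independent samples —
  the *statistical* error shrinks with $r$.

For statistical checks of the sampler itself (equipartition to 5%) the
default $r = 0.05$ keeps the systematic part at ~2.5%. For PMF
reconstruction the systematic part is worth only
$\sim k_B T\,r/2 \approx 0.03$ kcal·mol⁻¹ — far below the statistical
noise — so the umbrella tests run at the ceiling, $\Delta t = 5\times
10^{-4}$ ps for a 150 kcal·mol⁻¹·Å⁻² restraint ($r \approx 0.1$),
maximizing effective samples per window. This trade-off is why `dt` is
user-overridable everywhere.

**Seeds.** Every generator is a pure function of its integer seed
(`set.seed` internally); `generate_umbrella_set()` derives per-window seeds
deterministically from the master seed, so a window ladder is reproducible
window by window.

## Umbrella windows

Windows follow the common QM/MM protocol defaults: harmonic restraints of
100–200 kcal·mol⁻¹·Å⁻² (150 when unspecified) centered every 0.10 Å. A
warning is raised when the spacing exceeds $2\sqrt{k_BT/k}$ (≈ 2 standard
deviations of the restrained coordinate), the point at which neighboring
histograms stop overlapping. A moving-harmonic bias reproduces the steered
runs used to seed window ladders; because real protocols rarely print their
pulling amplitudes, the schedule is always user-specified.

## Active-site distance series

`generate_active_site_series()` draws frames from a Gaussian mixture over
named distances (`d_acid`, `d_nuc`, `d_glyc`, `d_Glu233_WAT`,
`d_glyc_WAT`, ...), emulating the multi-basin structure of real active-site
data (e.g. a reactive basin with d~nuc~ ≈ 4.7–5.5 Å and d~acid~ ≈ 4.3–5.0
Å next to a wider unreactive one). Negative draws are rejected and
resampled, since distances are nonnegative; the induced truncation bias is
negligible while basin means sit several σ above zero, which the generator
asserts indirectly through its mean-positivity precondition.

## What the synthetic world does not emulate

Green tests establish that the *mathematics* — WHAM fixed point,
reweighting identities, puckering geometry, clustering rules — is
implemented correctly. They do not establish anything about force-field
quality, electronic-structure accuracy, sampling of slow orthogonal degrees
of freedom, periodic-boundary artifacts, or hysteresis of real steered
trajectories. The generator is 1D (plus independent mixture coordinates):
there is no coupling between the biased coordinate and hidden slow modes,
which in real systems is the dominant failure mode that block-convergence
analysis is meant to expose.

# Free-energy estimators

## Direct projections

`direct_projection()` bins samples and applies
$\Delta G_i = -k_BT\,\ln(k_i/k_0)$ with $k_0$ the most occupied bin, so the
minimum is anchored at exactly zero. Empty bins carry `Inf` — an explicit
"undefined" marker — never zero. The automatic bin count is
$\lceil\sqrt{N}\rceil$ per axis: the protocols this package mirrors bin
"data of size N along *(expression lost in the typeset source)* bins", and
$\sqrt N$ is the conventional default consistent with that form; it is
always user-overridable. 2D projections bin independently per axis; when
weights are present, probability mass rather than counts feeds ΔG.

Out-of-range samples are *dropped*, never clamped into edge bins — clamping
silently piles the entire out-of-range tail onto the boundary bin and
corrupts the profile there (this is also why the WHAM histogram below drops
them).

## WHAM

`wham_solve()` implements the standard binned self-consistent iteration
over window histograms $h_j$:

$$\rho(x_m) = \frac{\sum_j h_j(x_m)}
  {\sum_j N_j\,e^{-\beta\,(U^{bias}_j(x_m) - F_j)}},\qquad
  F_j = -k_BT\,\ln\sum_m \rho(x_m)\,e^{-\beta U^{bias}_j(x_m)},$$

iterated until $\max_j|\Delta F_j|$ falls below the tolerance, with the
gauge fixed by $F_1 = 0$ (profiles are invariant to a constant shift of all
$F_j$; a fixed gauge makes runs comparable). The histogram form (rather
than a binless estimator) matches the WHAM implementations these protocols
cite; 200 bins is the default for the biased coordinate. Windows with zero
force constant are legal and reduce WHAM algebraically to the pooled
histogram — a property the tests assert bitwise on counts.

**Reporting range.** The default histogram range is the pooled sample
range. For quantitative comparison against a reference profile the
recommended (and acceptance-test) choice is the span of the window centers:
beyond the outermost restraint center the density is carried by a single
window's tail and the estimator noise grows without bound.

**Equilibration.** `equilibration_discard()` removes frames with
$t < t_{eq}$ (default 2 ps, the usual discard for 10 ps QM/MM windows).

## Per-conformation weights

`conformation_weights()` computes
$p_i \propto \big(\sum_j N_j e^{\beta(F_j - U^{bias}_j(x_i))}\big)^{-1}$,
normalized **globally** over all retained samples of all windows
($\sum_i p_i = 1$). A per-window normalization is the other conceivable
reading of the protocol formula, but only the global one makes the
reweighted projection $\Delta G = -k_BT \ln p$ consistent with the WHAM
density itself, so it is adopted. Two evaluation modes exist: at the exact
sample position (default; correct for projecting onto auxiliary CVs) and at
the sample's bin center, which makes the accumulated weights per bin
algebraically identical to the binned WHAM density — the identity the test
suite checks to 1e-6.

## Convergence diagnostic

`convergence_check()` recomputes the PMF on cumulative time blocks (first
$1/n$, $2/n$, ... of every window; the same fractions from the end of the
series for the reverse scheme) and reports the maximum |ΔG| difference
between successive cumulative PMFs over bins occupied in both (max-norm
over occupied bins only: a difference involving an empty bin is ∞ − ∞ and
means "not yet sampled", not "not converged"). Convergence is declared when
the final successive deviation is below the tolerance, default 1
kcal·mol⁻¹. Note the diagnostic is necessary, not sufficient: a smooth 1D
synthetic surface converges with surprisingly little data, which is why the
acceptance suite had to construct a genuinely starved set (100
samples/window) to exercise the failure branch.

## Transition-state theory

`tst_convert()` applies the Eyring relation
$k = (k_BT/h)\,e^{-\Delta G^\ddagger/RT}$ with the prefactor ≈ 6.46 ×
10¹² s⁻¹ at 310 K, and its exact inverse. No transmission-coefficient or
recrossing corrections are applied.

# Ring puckering

`cremer_pople()` follows the classical construction: center the six ring
atoms, build the mean-plane normal from the two trigonometrically weighted
lattice sums, project the out-of-plane displacements $z_j$ onto the two
puckering modes, and convert $(q_2, \phi_2, q_3)$ to $(Q, \phi, \theta)$.
$\sum_j z_j = 0$ holds by construction and is asserted per frame.

**Convention.** The ring oxygen (O5) is atom 1, then C1…C5; the generator
lays the hexagon clockwise when viewed from +z so that the measured normal
is +z and the α-D-glucopyranose chair with C4 above / C1 below classifies
as ⁴C₁ at θ = 0, matching standard carbohydrate usage. Cycling the atom
order shifts φ by a fixed 120° multiple and mirrors θ — a property the
suite tests — so obeying the convention matters and the readers enforce it.

**Canonical table.** The 38 canonical vertices (2 chairs, 6 boats, 6
skews, 12 half-chairs, 12 envelopes) are *generated*, not transcribed: each
conformer's ideal displacement pattern (chair: alternating; boat: para pair
+2u with −u elsewhere; skew: ±u pairs with one para pair in plane;
half-chair: adjacent ±u; envelope: single flap) is projected onto the
puckering modes. This reproduces the canonical θ bands — 0/180°, 90°,
50.8/129.2°, 54.7/125.3° — exactly, and eliminates transcription error
across 38 entries. Twist-boats each admit two equivalent descriptors
(e.g. ⁴S~O~ ≡ ¹S₃); aliases resolve to the canonical entry.

**Classification** is nearest-canonical-vertex under the great-circle
metric on the puckering sphere, with lexicographic tie-break — total,
unambiguous, and checkable against a brute-force scan, unlike banded-θ
rules. Rings with Q < 0.01 Å are flagged planar: below that amplitude φ
and θ are numerically meaningless, and the classifier returns the
`"planar"` sentinel rather than an arbitrary label.

# Collective variables

Distances use heavy atoms by convention; hydrogen-bond-style distances use
the minimum over donor/acceptor oxygen pair sets (`min_pair`), while
explicit single-atom variants (e.g. a hydroxyl hydrogen for the QM/MM
reaction coordinate) use `mode = "single"`. The glycosylation reaction
coordinate is $d_{glyc} - d_{acid}$: negative on the reactant side,
positive on the product side. Composite variables
$d_{actsite} = d_{acid} + d_{nuc} + d_{Glu233\text{–}WAT}$ and
$d_{acid} - d_{glyc\text{–}WAT} + d_{nuc}$ are exact linear maps and
vectorize over series.

Solvent distances are frame-wise nearest-water (with the attaining molecule
reported), not a tracked single molecule: over microseconds the identity of
a "buried" water can change, and the nearest-distance surrogate is what
distance-projection plots actually use. Water distances default to
oxygen–oxygen, overridable in the selection config. Frames are assumed
whole and unwrapped — there is no minimum-image handling, which is safe for
active-site distances far smaller than any box.

# Clustering

RMSd is computed after least-squares superposition on the clustered
selection (a no-fit mode exists for pre-aligned input); superposition is
the Kabsch SVD solution with the determinant correction, so reflections are
never applied. Clustering RMSd is unweighted — protocols rarely state mass
weighting, and unweighted is the reproducible default.

Gromos clustering counts neighbors within the cutoff (default 1.2 Å),
promotes the most-connected frame to centroid, removes its neighborhood and
repeats; ties break to the lower frame index, making the result
deterministic. Occupancies are percentages of input frames. The re-seeding
rule selects, among clusters with occupancy **strictly** above 10%, the
centroid with maximal fitted RMSd to the starting structure, returning
nothing when no cluster qualifies.

`kmeans_representatives()` is a small deterministic Lloyd loop with
k-means++ seeding from the user seed and deterministic re-seeding of empty
clusters; `stats::kmeans` was not used because it contracts neither
deterministic seeded initialization nor empty-cluster policy. The distance
is Euclidean in whatever feature space is supplied (reaction-coordinate
values, CV tuples), and the representative is the member closest to the
cluster mean.

# Workflow and I/O

Configuration is a single JSON document validated before any compute
(undefined CV references, missing files and nonpositive temperatures are
rejected up front with exit code 2 from the CLI; numerical failures exit
3). Every pipeline artifact is listed in a provenance manifest with the
config hash, seed, temperature and package version, sufficient to
regenerate it exactly. CV tables are tab-separated with a `# time_ps ...`
header; trajectories are plain-text multi-model PDB or XYZ (for PDB altloc
duplicates the first variant is kept with a logged warning). Binary engine
formats are out of scope.

# Known limitations

- 1D WHAM only; no 2D umbrella biasing, MBAR/binless estimators, or
  bootstrap error bars beyond the block analysis.
- Six-membered rings only; no furanose pseudorotation.
- The Langevin generator is overdamped and one-dimensional; it cannot
  emulate inertial effects or hidden-slow-mode hysteresis.
- Statistical acceptance checks are seeded; they validate typical-case
  behavior at fixed seeds, not worst-case tail behavior.
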