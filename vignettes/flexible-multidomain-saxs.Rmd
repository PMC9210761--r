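---
title: "Modeling the deformability of multidomain proteins against SAXS data"
author: "flexsaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the deformability of multidomain proteins against SAXS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexsaxs)
```

## The problem

Cellulosomal scaffoldins and designer-cellulosome complexes are
beads-on-a-string proteins: folded cohesin, CBM, dockerin and catalytic
modules joined by disordered linkers of roughly 5–40 residues. In solution
they are not one shape. Size-exclusion-coupled SAXS measures the
orientationally and conformationally averaged intensity I(q), so a single
rigid model often cannot reproduce the curve even when every domain
structure is known. The productive question is ensemble-level: how compact
is the molecule on average (Guinier Rg, Kratky shape, P(r)/Dmax), and is
the curve consistent with one dominant conformer or only with a mixture —
typically one compact plus one extended state at comparable weights?

`flexsaxs` implements that workflow end to end: standard curve analytics, a
coarse-grained conformational sampler, per-conformer Debye profiles, and
χ²-based single-model and minimal-ensemble selection, plus a synthetic-data
module that provides ground truth for validation.

## Curve analytics

**Guinier.** I(q) = I(0)·exp(−q²Rg²/3) holds at low q, conventionally for
qRg below roughly 1.1–1.2. `guinierFit()` performs a weighted linear fit of
ln I against q² (first-order error propagation, σ_lnI = σ/I), starting at
the first point, estimating Rg from the first ten points and iterating
truncation to qRg ≤ `qrg_limit` (default 1.2, configurable) to a fixed
point. If a noise-dominated short window slopes upward the window is
widened; an upward slope over the whole curve is reported as non-Guinier
behavior. No automatic removal of aggregation-affected low-q points is
attempted, because SEC-purified curves do not normally need it. One known
systematic is intrinsic to the approximation, not the implementation: for
an ideal homogeneous sphere the ln-linear fit over qRg ≤ 1.2 overestimates
Rg by ~1.4% (about 1% at qRg ≤ 1.1); the tests document this bias rather
than hide it.

**Kratky.** `kratkyTransform()` returns q²I(q) or, in dimensionless form,
(qRg)²I(q)/I(0) against qRg, which peaks at (√3, 3/e) for an ideal compact
particle and rises without a clear maximum for extended, flexible chains —
the standard compactness diagnostic for scaffoldins.

**P(r) and Dmax.** `pairDistribution()` inverts
I(q) = 4π Σⱼ P(rⱼ)·sinc(q rⱼ)·Δr on a uniform grid (201 points by default)
with enforced boundary values P(0) = P(Dmax) = 0, non-negativity, and a
second-difference smoothness penalty with weight α. Non-negativity is
imposed by an exact active-set non-negative least-squares solve
(Lawson–Hanson); iterative box-constrained optimizers proved too loosely
converged along the smoothest modes to keep the solution reproducible.
The automatic α follows the discrepancy principle: the strongest smoothing
whose non-negative solution still fits within the stated errors (weighted
misfit ≤ N_q), found by bisection on log α. A "balance the data and
smoothness terms at the unregularized solution" rule was tried first and
abandoned: the unregularized non-negative solution is spiky and nearly
interpolating, which makes that balance degenerate in the small-noise
limit, whereas the discrepancy rule is well defined at any noise level and
makes the IFT exactly scale-equivariant (the intensity scale is normalized
out internally). `estimateDmax()` codifies a reproducible stand-in for the
perceptual criteria of interactive IFT programs: scan a candidate grid and
take the smallest Dmax whose data-fit χ² is within 5% of the best and whose
unconstrained-solution tail stays non-negative.

## The coarse-grained model

One bead per residue at the Cα position; unit bead weights for Rg
(residue-mass weighting changes Rg by under 2% for typical compositions and
is available through per-bead form-factor weights). Folded domains are
rigid bodies — their internal distance matrices are bitwise invariants of
the sampler. Linkers are chains with virtual bond length 3.8 Å (the trans
Cα–Cα distance; glycosylation is ignored, appropriate for E. coli-expressed
constructs). Cohesin–dockerin pairs are fused into single rigid units via
`attachments`; the binding interface itself is treated as rigid.

The energy, in units of kT at the 300 K reference temperature, is

E = Σ ½k_s(r−r₀)² + Σ ½k_b(θ−θ₀)² + Σₙ cₙ(1+cos(nφ−φₙ)) over linker
degrees of freedom, plus a hard core: any bead pair that is neither
directly bonded nor inside one rigid unit must stay beyond 2×1.9 Å, else
the energy is +∞ (a rejection sentinel, not an error). The hard core
deliberately applies *within* a linker as well — a lone disordered linker
must be self-avoiding for its temperature response to be physical.

Defaults (all exposed): k_s = 100 kT/Å², r₀ = 3.8 Å, k_b = 2 kT/rad²,
θ₀ = 2.12 rad, a single torsion term c₁ = 0.5 kT with phase π, hard radius
1.9 Å. The phase-π choice puts the torsional ground state at the compact
cis rotamer, so the 300 K ensemble is mildly compact-biased and heating
toward 500 K expands the chain — the response the replica ladder is meant
to exploit. These are generic serial-linker statistics, not fitted force
field parameters; all quantitative validation is therefore
parameter-recovery-based (planted ground truth) rather than
force-field-based.

## Replica-exchange Monte Carlo

One sweep attempts one move per mobile degree of freedom (the counted bond
+ angle + torsion terms of all linkers). The move menu mixes four fixed
amplitude move types: single-bead displacement of linker beads (45%), pivot
of the downstream segment about a linker bead (30%), crankshaft rotation of
interior linker beads (15%), and whole-body rigid moves of each connected
component (10%). Pivot and crankshaft moves preserve bond lengths, so the
displacement move is what samples the stretching degrees of freedom — with
only the rotation moves the bond-length Boltzmann statistics would be
frozen. Amplitudes are fixed, not adaptive, to keep runs exactly
reproducible.

Replicas sit on a geometric temperature ladder (equal β ratios; default 20
temperatures from 300 to 500 K with reduced β = 300/T). Every 10 sweeps,
alternating even/odd adjacent pairs attempt a swap accepted with
probability min(1, exp((βᵢ−βⱼ)(Eᵢ−Eⱼ))). Every replica saves its structure
every `saveEvery` sweeps, so a run yields nReplicas × nSweeps / saveEvery
models — at the production schedule (20, 10⁷, 10³) that is 2×10⁵; the
count alone implies structures are saved from all replicas, which is the
convention adopted here. Each replica draws from its own counter-derived
random stream seeded from the master seed, so results are independent of
scheduling and identical seeds give identical pools.

## Scattering profiles and ensemble selection

Per-conformer intensities use the Debye formula with sin(x)/x → 1 as x → 0,
so I(0) = (Σfᵢ(0))². The default form factor is a constant 1 per residue:
the χ² fit's free scale absorbs the overall amplitude, and the analysis
compares shapes, not absolute intensities. No solvent-excluded-volume or
hydration-shell correction is applied; this is a known systematic at
q ≳ 0.25 Å⁻¹ and one reason the default q grid (101 points, 0.005–0.5 Å⁻¹)
stops at 0.5 Å⁻¹. For large bead counts the pair sum is evaluated over a
distance histogram (bin width ≤ 0.1 Å) carrying per-bin first and second
distance moments; the second-order correction keeps the approximation
within ~10⁻⁷ of the exact sum, far inside the 10⁻⁴ contract.

χ² uses the displayed two-parameter form with scale a and offset b solved
in closed form; b absorbs buffer-subtraction uncertainty and is
unconstrained in sign (a ≤ 0 raises a warning). The sum is divided by N_q —
the reduced convention that makes the reported 0.9–1.1 goodness band
meaningful; whether N_q or N_q−3 is used is immaterial at N_q ≈ 10²–10³
but is fixed and documented here. Model profiles are linearly interpolated
onto the experimental grid and never extrapolated.

`minimalEnsemble()` searches member sets of size s = 1, 2, … whose weighted
mean intensity minimizes χ², with equal weights 1/s by default (optimized
simplex weights available via bounded least squares). A larger ensemble is
accepted only if it improves χ² by more than 5% — a parsimony rule that
reduces to "two models fit where singles do not" on genuinely two-state
data and keeps the planted single model on one-state data. The pair search
precomputes the error-weighted Gram matrix of the profile pool, which makes
each candidate pair O(1); exhaustive search is therefore affordable up to
~10³-model pools (5×10⁵ pairs) and is preferred, because on strongly
two-state data the true end states can rank poorly as *single* fits and
would be lost by aggressive pre-filtering. Beyond the budget, Rg-stratified
pre-clustering (best singles per stratum) plus greedy forward selection
with restarts takes over; ties always break toward the lowest model index.

## Synthetic ground truth

`makeTwoStateSystem()` builds domains as 120-bead spherical shells (radius
15 Å) so no structure files are needed; two tiny synthetic helical-trace
PDBs ship only to exercise the PDB reader. The extended reference has all
linkers straight; the compact reference is produced by a short
low-temperature Monte Carlo collapse under a harmonic attraction between
domain centroids, which is clash-free and linker-consistent by
construction. The canonical truth is a 50:50 compact/extended mixture —
the equal-statistical-weights scenario the ensemble analysis targets.
Simulated measurements add Gaussian noise with
σ(q) = noiseFrac · I(q) · (1 + q/0.2 Å⁻¹), mimicking SEC-SAXS counting
error that grows toward high q; with noiseFrac = 0 the curve is exact and
σ is a tiny positive placeholder so the container stays valid.

What the generator does *not* emulate: real domain form factors and
hydration, SEC elution-frame structure and inter-frame merging,
concentration effects, and aggregation. Passing recovery tests therefore
demonstrate that the sampling/fitting machinery is correct and calibrated,
not that any particular real construct is two-state.

Problem sizes in the test-suite and acceptance runs are deliberately
scaled: two-domain systems (259 beads), 10³-model pools, reduced
replica-exchange schedules (e.g. 4 replicas × 10⁴ sweeps), and 10–20
random seeds per statistical claim. These sizes were chosen so the full
validation remains a desk-scale computation while every mechanism of the
production schedule (exchange, saving, pooling, pair search) is exercised.

## Numerical choices and degenerate inputs

* q is always Å⁻¹ internally; nm⁻¹ input is converted only on an explicit
  flag, never guessed (silent misdetection corrupts Rg tenfold).
* Guinier windows below 10 points, all-constant curves (Rg = 0), rising
  curves, and σ ≤ 0 rows all have defined outcomes (error or documented
  value) rather than silent behavior.
* The IFT warns when Dmax is below the π/q_max resolvable scale and
  reports singular systems with advice to raise α.
* Infinite energy is a value: overlap rejection needs no exception path.
* All randomness flows through named substreams of one master seed
  (system, noise, sampler), so any reported number is bisectable.

## Limitations

Absolute-scale calibration, molecular-weight estimation from I(0),
hydration-layer contrast fitting, maximum-entropy reweighting of full
pools, and Bayesian weight posteriors are out of scope. The minimal
ensemble is a parsimony construct: it identifies the smallest set of
conformers consistent with the data, not the complete conformational
distribution.
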