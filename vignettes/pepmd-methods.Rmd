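---
title: "pepmd: methods, parameter choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepmd: methods, parameter choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmd)
```

pepmd analyses protein–peptide MD ensembles along two tracks: a
conformational-ensemble track (pool → pairwise RMSD → greedy clustering →
transition statistics, plus RMSF, inter-domain dihedrals and polar
contacts) and an energetics track (per-λ-window free-energy perturbation
with an autocorrelation-aware error model and thermodynamic-cycle
assembly).  This vignette records the models behind each stage, the
defaults and why they were chosen, what the synthetic generators do and do
not emulate, and the numerical decisions a maintainer would want written
down.

## Units and constants

Coordinates and distances are in Å, times in ps, energies in kcal/mol,
temperatures in K.  A single molar gas constant R = k_B in molar units =
1.987204×10⁻³ kcal/(mol·K) (`kb_kcal()`) is used everywhere, so
per-molecule and per-mole expressions cannot drift apart.

## The ensemble track

### Two-selection RMSD

The difference between two bound-peptide conformations is measured in two
steps: a least-squares (Kabsch) superposition on a *fit* selection — by
default the backbone N, CA, C atoms of the three C-terminal residues
(positions 0, −1, −2), the anchor that stays bound in the PDZ groove — and
then the RMSD over a *measure* selection, by default the whole peptide
backbone.  Fitting on the anchor and measuring on everything makes the
metric sensitive to exactly the motion of interest: the upstream tail
rearranging while the anchor stays put.  "Backbone" here means {N, CA, C};
the carbonyl O can be included via `backbone_selection(include_o = TRUE)`.

The Kabsch rotation is computed from the SVD of the 3×3 covariance matrix
with the determinant sign corrected, so reflections are never returned.
Fewer than three fit atoms, or collinear fit atoms, raise an error rather
than returning one of the infinitely many degenerate solutions.

The O(n²) pairwise matrix is computed in compiled code (RcppArmadillo).
The fitted RMSD is mathematically symmetric in the pair, so only the upper
triangle is evaluated and mirrored; the R-level contract still validates
symmetry on input matrices from other sources.

### Greedy maximum-neighbor clustering

Clustering follows the greedy rule standard for MD ensembles (the
GROMOS/Daura algorithm): among unassigned conformations, the one with the
most unassigned neighbors within the cutoff becomes a center; it and its
neighbors form a cluster and are removed; repeat.  Singletons are allowed.
The cutoff default is 1.5 Å, the customary choice for peptide-backbone
ensembles at this size.  Two decisions the algorithm description leaves
open are fixed here:

* **Tie-break.**  Equal neighbor counts are broken toward the lowest
  conformation index.  Any total order works; this one is deterministic and
  stable under re-runs, which makes partitions byte-reproducible.
* **Representatives.**  The cluster representative is the center (the
  max-neighbor conformation), not a recomputed medoid — it is what the
  greedy rule naturally yields, and every member is within the cutoff of
  it by construction (asserted on every run).

**A property the greedy rule does *not* have:** the number of clusters is
not monotone in the cutoff.  Raising the cutoff usually merges clusters,
but occasionally the first (largest) cluster absorbs conformations that
would otherwise have seeded mid-sized clusters, and the scattered remainder
fragments into *more* clusters.  On random metric configurations this
happens in a few percent of instances; the test suite carries a frozen
counterexample, cross-checked against an independent exhaustive
implementation of the same rule, to document that this is a property of
the algorithm rather than of this code.

### Transition statistics

A transition is a change of cluster label between consecutive frames of
one trajectory+site series.  Because conformations from several sites and
trajectories are pooled before clustering, labels carry provenance, and
transitions are never counted across pooling boundaries.  The rate is
transitions per ps of elapsed (post-stride) time.

### RMSF

Each frame is superposed on the mean structure over the fit selection; the
mean is obtained by one fit–average–refit iteration seeded from the raw
time-averaged coordinates.  Seeding from the raw mean (rather than from
frame 1) makes the procedure invariant to frame order, which is the
natural property of a per-atom moment.  Whether to fit on the protein
core, on the peptide anchor, or not at all is left to the caller — both
conventions appear in practice and the choice changes what "fluctuation"
means; `fit = FALSE` supports trajectories already in a common frame,
where isotropic noise of sd σ per coordinate gives the closed-form RMSF
σ√3 used in the tests.

### Polar contacts

Geometric criteria only, with the common literature defaults, all exposed
in `contact_params()`: hydrogen bond = donor–acceptor heavy-atom distance
≤ 3.5 Å and donor–H–acceptor angle ≥ 120° (when hydrogens are absent the
angle cannot be checked; the record is flagged `angle_checked = FALSE`);
salt bridge = any opposing side-chain N⁺/O⁻ pair within 4.0 Å.
Phosphoserine (residue names SEP or PSE) is registered as an anionic
residue through its phosphate oxygens, and the C-terminal carboxylate
(O/OXT) as an anion, so peptide-terminus and phosphate-driven contacts are
expressible.  Occupancy counts a residue pair once per frame however many
atom pairs satisfy the criterion.

### Inter-domain dihedral

For a two-domain (e.g. domain-swapped dimer) structure, the relative
domain orientation is summarized by the signed dihedral through
(MC1, hinge1, hinge2, MC2), where MC1/MC2 are mass-weighted domain centers
and the hinges are one atom per protomer at the interface.  The convention
is IUPAC: right-handed, cis = 0°, range (−180°, 180°].  The synthetic
constructor `generate_two_domain_frame()` builds point geometries whose
dihedral equals the request exactly, which is the oracle for the metric's
tests.

## The energetics track

### Zwanzig estimator

For window k with energy differences ΔU sampled from the λ_from ensemble,

$$\Delta G_k = -k_BT \,\ln\left\langle e^{-\Delta U/k_BT}\right\rangle_k,$$

computed with a max-shifted log-sum-exp so arbitrarily large |ΔU| cannot
overflow.  The estimator is exact for constant ΔU, and for Gaussian ΔU the
closed form μ − σ²/2k_BT provides the recovery target used throughout the
tests (verified independently against numerical quadrature).

### Error model

Windows are treated as independent observables.  Within a window the error
of the exponential ensemble average is propagated through the logarithm to
first order (delta method):

$$\sigma_k = k_BT\,\frac{\mathrm{sd}(w)}{\mathrm{mean}(w)}
  \sqrt{\frac{1+2\tau}{N}},\qquad w_i = e^{-\Delta U_i/k_BT},$$

where (1+2τ) is the sampling ratio accounting for autocorrelation.  τ is
estimated as the sum of normalized autocovariances from lag 1 up to the
first lag at which C(t)/C(0) drops below 0.05 — a standard
initial-sequence-style truncation; the threshold is an argument of
`statistical_inefficiency()`.  τ is in sample steps; multiply by the
collection interval for time units.  Zero-variance series return ratio 1
with a degenerate flag, and results backed by fewer than 10 effective
samples are flagged.  Calibration is tested directly: over 200 synthetic
replicates the ±1σ interval covers the truth close to the nominal 68 %.

Two bookkeeping aspects of alchemical setups are deliberately outside the
estimator: dual-topology construction and counterion co-transformations
that keep the box neutral are sampling-side concerns, and the ΔU series
consumed here is assumed to come from a well-posed, neutral
transformation.  Each window may carry a discard-prefix count in its YAML
sidecar for equilibration trimming; the default is 0 because the synthetic
series are stationary from the first sample.

### λ schedules and accumulation

`accumulate()` validates that windows tile [0, 1] exactly (each λ_to equals
the next λ_from) and then sums free energies and variances.
`lambda_schedule()` produces breakpoints as the image of a uniform grid
under the symmetric incomplete-beta warp `pbeta(u, a, a)` with
a = `endpoint_density`: a = 1 is the uniform grid, a > 1 narrows windows
toward λ = 0 and 1, where alchemical transformations approach
singularities.  Realistic window counts (69 and 118 are typical for free
and complexed legs) generate valid tilings.

### Cycle and Kd conversion

ΔΔG_bind = ΔG_alchemy(bound) − ΔG_alchemy(free), errors in quadrature;
legs must share a temperature.  For experimental comparison,
ΔΔG = R·T·ln(Kd_b/Kd_a): 7.2 µM versus 100 µM at 300 K gives
`r round(ddg_from_kd(7.2e-6, 100e-6, 300), 2)` kcal/mol.

## Synthetic generators: what they emulate, and what they do not

`generate_multistate_trajectory()` emulates the one feature of a bound
flexible peptide that the ensemble track measures: interconversion among a
small set of well-separated conformations with known stationary
populations, on top of harmonic positional noise.  Frame t is the
reference conformation of a Markov state plus i.i.d. Gaussian displacement
(σ default 0.3 Å).  The default transition matrix has every row equal to
the stationary vector — i.i.d. labels — so binomial sampling theory applies
exactly to occupation counts; persistence is opt-in via an explicit
row-stochastic matrix (the initial state is always drawn from the
stationary vector, keeping occupation statistics unbiased at any length).
The spec validator enforces separability (inter-state RMSD > 3× noise σ),
without which cluster recovery is not a well-posed target.

The packaged reference motifs (`reference_conformations()`) are idealized
backbone traces — N/CA/C per residue, a 3-residue C-terminal anchor
identical across states, upstream arcs in four distinct planes (hairpin-,
L-, extended-arc- and V-like).  Two geometric properties matter and are
deliberate; biological realism is not.  First, the anchor zig-zags in
three dimensions: a least-squares fit on a nearly collinear anchor is
rotationally ill-conditioned, and noise then swings the far end of the
peptide by many Å (an early collinear design inflated same-state RMSDs
past the cutoff).  Second, the free arcs are compact, keeping lever arms
short, because a fit on 9 noisy atoms carries an orientation error of
order σ/√N per unit of fit-atom gyration radius that multiplies distance
from the anchor.  Real bound peptides are anchored the same way, but real
ensembles have continuous conformational spread, anharmonic noise, and no
guarantee of separability — passing recovery tests here shows the pipeline
is correct, not that four clusters exist in any particular real system.

`generate_fep_samples()` draws each window's ΔU as a stationary AR(1)
process with Gaussian marginals (first sample from the stationary
marginal, so no burn-in is needed).  AR(1) is the minimal model with a
scalar correlation time, which is all the (1+2τ) error formula resolves;
real alchemical ΔU series can be non-Gaussian and multi-timescale, which
is precisely when exponential averaging degrades — the generator validates
the estimator and its error bars, not the hard tails of real insertions.

## Problem sizes

The recovery analyses run at sizes chosen to make sampling error small
relative to the tolerances while staying desk-scale: 20 000 generated
frames (5 000 pooled conformations after the stride-4 picking that is part
of the pipeline) for cluster recovery; 10⁶ samples for the Gaussian
closed-form check; 10⁵ for autocorrelation recovery; 200 replicates of
2 000 samples for error-bar coverage; 5 000 frames for the RMSF noise law.

## Known limitations

* Cluster count vs cutoff is not monotone (see above) — report partitions
  at the cutoff of interest rather than scanning for a "stable" count.
* Exponential averaging is biased at small N for broad ΔU; the error model
  reports statistical, not bias, error.  With σ(ΔU) ≫ k_BT prefer more,
  narrower windows.
* Contact detection is geometric only; no energetic scoring, no
  secondary-structure or SASA terms.
* The PDB reader keeps the first altloc and reads no header chemistry;
  binary trajectory formats are out of scope (convert to multi-model PDB).
* Percentages are reported to 0.1 %; sizes below n ≈ 1000 conformations
  make that last digit sampling noise.
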