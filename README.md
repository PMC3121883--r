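# pepmd

Post-simulation analysis of protein–peptide molecular-dynamics ensembles in
R: conformational clustering of bound-peptide ensembles, structural metrics
(RMSF, inter-domain orientation dihedrals, polar contacts), and free-energy
perturbation (FEP) with an autocorrelation-aware error model and
thermodynamic-cycle assembly.

The package targets the analysis workflow used to study short peptides
bound to PDZ-family domains — for example the connexin43 C-terminal tail in
the ZO-1 PDZ2 groove — where the bound peptide keeps its C-terminal anchor
fixed while its upstream tail interconverts among distinct conformations,
and where phosphorylation of an upstream serine shifts the binding free
energy.  It is equally usable for any trajectory of a flexible ligand bound
to a rigid receptor.

## What it computes

**Ensemble track.**  Peptide conformations are pooled from multiple binding
sites and trajectories (with stride subsampling), superposed by a least-RMSD
(Kabsch) fit on the backbone of the three C-terminal residues (positions 0,
−1, −2), and compared by the RMSD of the whole peptide backbone.  The
pairwise distance matrix is clustered with the greedy maximum-neighbor
(GROMOS/Daura) rule at a cutoff (default 1.5 Å):

> iteratively, the conformation with the most neighbors within the cutoff
> becomes a cluster center; it and its neighbors are removed; repeat.

Outputs: per-conformation labels with provenance, cluster sizes and
percentages, representative (center) structures, and inter-cluster
transition rates counted only along each source series.

**Energetics track.**  Per λ-window free energies by Zwanzig exponential
averaging,

    ΔG_k = −k_B T · ln ⟨ exp(−ΔU/k_B T) ⟩_k ,

with first-order (delta-method) errors inflated by the sampling ratio
(1 + 2τ), where τ is the autocorrelation time of the exponential terms.
Window totals add; variances add in quadrature.  A thermodynamic cycle
closes as ΔΔG_bind = ΔG_alchemy(bound) − ΔG_alchemy(free), and dissociation
constants convert by ΔΔG = R·T·ln(Kd_b/Kd_a).

**Synthetic generators.**  Both tracks come with ground-truth generators —
multi-state Markov peptide trajectories with Gaussian positional noise, and
stationary AR(1) ΔU window series whose exact free energy is known in
closed form (μ − σ²/2k_BT per Gaussian window) — so every stage is testable
by parameter recovery.

## Worked example

```r
library(pepmd)

## four-state bound-peptide ensemble with known populations
rc   <- reference_conformations(4)
spec <- multistate_spec(rc$frames, rc$topology,
                        stationary_populations = c(0.4, 0.3, 0.2, 0.1),
                        noise_sigma = 0.3, n_frames = 20000, seed = 1)
sim  <- generate_multistate_trajectory(spec)

pool <- pool_and_subsample(list(sim$trajectory),
                           list(list(backbone_selection())), stride = 4)
fit  <- position_selection(rc$topology, "P", c(0, -1, -2),
                           atom_names = c("N", "CA", "C"))
mat  <- build_rmsd_matrix(pool, fit_sel = fit)
cl   <- gromos_cluster(mat, cutoff = 1.5)
cl
#> GROMOS clustering: 5000 conformations, 4 clusters (cutoff 1.5 A)
#>   largest: 41.2%, 29.6%, 18.8%, 10.5%

## free-energy window with a known Gaussian truth
fs <- fep_synthetic_spec(mu = 1.0, sigma = 0.5, n_samples = 1e6,
                         temperature = 300, seed = 1)
w  <- generate_fep_samples(fs)$windows[[1]]
zwanzig_window_dg(w)        # 0.7904 (exact: 1.0 - 0.5^2/2RT = 0.7903)
window_error(w)$sigma       # ~0.0006 kcal/mol

## experimental comparison: Kd 7.2 uM (wild type) vs 100 uM (phospho)
ddg_from_kd(7.2e-6, 100e-6, temperature = 300)
#> [1] 1.568553   # kcal/mol
```

The cluster percentages recover the generator's stationary populations
within binomial sampling error; the window estimate sits within its
reported error of the closed-form truth; and the Kd ratio of 100/7.2 µM at
300 K corresponds to a binding penalty of 1.57 kcal/mol.

## Command line

A thin wrapper over the same functions lives at `inst/cli/pepmd.R`:

```sh
Rscript inst/cli/pepmd.R simulate-traj --n-states 4 --n-frames 2000 --out traj.pdb --labels labels.csv
Rscript inst/cli/pepmd.R cluster --traj traj.pdb --peptide-chain P --stride 4 --cutoff 1.5 --out run
Rscript inst/cli/pepmd.R simulate-fep --n-windows 20 --out windows/
Rscript inst/cli/pepmd.R fep-estimate --windows windows/ --out fep
Rscript inst/cli/pepmd.R kd2ddg --kd-wt 7.2e-6 --kd-mut 100e-6 --temp 300
```

See `vignettes/pepmd-methods.Rmd` for the full account of the models,
parameter choices, numerical decisions, and known limitations.
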