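# lipdyn

Trajectory post-analysis and enzyme characterization for a thermolabile
*Bacillus subtilis* lipase.

Lipases that hydrolyze residual yolk lipid can restore the foaming
properties of egg-white liquid, but their activity collapses above ~40 °C.
Understanding why requires looking at the enzyme's conformational ensemble:
which residues become flexible as temperature rises, how their motions
correlate, and whether the internal interaction network loosens. `lipdyn`
packages that analysis chain for R users — structural bioinformaticians
post-processing molecular-dynamics ensembles and enzymologists reducing
assay data — with every stage testable against closed-form oracles.

## What it computes

**Ensemble statistics** (Cα-level, lengths in nm):

* Kabsch least-squares superposition and per-frame
  RMSD = √(Σᵢ|xᵢ−yᵢ|²/N) after optimal rigid fitting;
* per-residue RMSF about the iterated ensemble mean;
* Shrake–Rupley SASA (golden-spiral quadrature, 0.14 nm probe, 960 points,
  exact cell-list neighbour search);
* the dynamic cross-correlation matrix, c(i,j) = ⟨ΔRᵢ·ΔRⱼ⟩ normalized to
  c(i,j)/√(c(i,i)c(j,j)) ∈ [−1, 1];
* a residue network gated by mean Cα distance (≤ 1.5 nm) and |c| ≥ 0.05,
  edge weight −ln|c|, scored by counting Dijkstra shortest paths per
  ordered residue pair (the shortest-path map), with density summaries.

**Enzyme characterization**:

* Michaelis–Menten fits v = Vmax·S/(Km+S) by damped nonlinear least squares
  on log parameters, with asymptotic standard errors;
* catalytic efficiency kcat/Km on the M⁻¹ s⁻¹ scale;
* relative-activity normalization and the foaming indices
  FA = (m₀−m₁)/m₁·100 and FS = mₚ/mᵢ·100.

**Synthetic data**: a Gaussian-network-model generator whose displacement
covariance is the scaled pseudo-inverse of the contact Kirchhoff matrix —
an analytic oracle for the whole DCCM/RMSF pipeline — plus deterministic
backbone fixtures and noisy kinetic datasets.

## Worked example

Generate a 50-residue ensemble with three planted flexible sites, recover
them, and summarize the interaction network:

```r
library(lipdyn)

ref   <- make_fixture_structure(50, "helix")
model <- gnm_model(ref, temperature_scale = 1)   # ~kT; 2 would be "hotter"
damp  <- rep(1, 50); damp[c(10, 25, 40)] <- 3    # plant flexible residues
traj  <- sample_trajectory(model, 2000, seed = 42, damping = damp)

head(flexible_regions(rmsf(traj), fraction = 0.1), 5)
#>    resseq  rmsf
#> 10     10 0.274
#> 40     40 0.269
#> 25     25 0.238
#> 50     50 0.121
#> 1       1 0.119

mean(rmsd_series(traj, reference = mean_structure(traj)))
#> [1] 0.105   # nm

net <- build_graph(mean_distance_matrix(traj), dccm_matrix(traj),
                   cutoff = 1.5, min_abs_corr = 0.05)
net
#> residue_graph: 50 nodes, 396 edges (cutoff 1.5 nm)
spm_density(shortest_path_map(net), usage_floor = 0.2)
#> $n_nodes_retained
#> [1] 26
#> $n_edges_retained
#> [1] 26
```

The three damped residues (10, 25, 40) head the fluctuation profile — the
synthetic analogue of spotting flexible loop sites — followed by the chain
termini; the RMSD sits at the ~0.1 nm scale of a stable fold. On the
kinetics side:

```r
fit <- fit_michaelis_menten(make_mm_dataset(232.69, 3.92, noise_sd = 0))
fit
#> Michaelis-Menten fit: Vmax = 232.7 +/- 2e-14 uM/min, Km = 3.92 +/- 1e-15 mM

catalytic_efficiency(0.61, 9.26)   # kcat [1/s], Km [mM] -> 1/(M s)
#> [1] 65.87473
foaming_ability(5.75, 1);  foaming_stability(0.48, 1)
#> [1] 475
#> [1] 48
```

A noiseless fit returns the generating constants to machine precision; the
efficiency call reproduces a published long-chain-substrate worked example
to 2 dp. A command-line wrapper (`inst/cli/lipdyn`) exposes the same
pipeline as subcommands (`synth`, `rmsd`, `rmsf`, `sasa`, `dccm`, `spm`,
`kinetics`, `foam`), all emitting CSV.

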