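---
title: "Ensemble analysis and enzyme characterization with lipdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble analysis and enzyme characterization with lipdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipdyn)
```

## Scope

`lipdyn` implements the post-simulation analysis chain used to judge the
conformational stability of a *Bacillus subtilis* lipase across its working
temperature range, together with the arithmetic of its wet-lab
characterization. The molecular half consumes an ensemble of conformations
(a trajectory) and produces per-frame RMSD, per-residue RMSF, Shrake–Rupley
solvent-accessible surface area (SASA), the dynamic cross-correlation matrix
(DCCM), and a correlation-weighted residue network scored by shortest-path
traversal (the shortest-path map, SPM). The wet-lab half fits
Michaelis–Menten kinetics, derives catalytic efficiency, normalizes activity
profiles, and computes egg-white foaming indices. A Gaussian-network-model
(GNM) generator supplies synthetic ensembles whose statistics are known in
closed form, so every stage can be validated at desk scale.

All lengths are nm internally (PDB ångström are converted on read); residue
identity is carried as the author's 1-based numbering so flexible sites can
be reported directly, while a dense 0-based index is used for bookkeeping.

## Superposition, RMSD, RMSF

Rigid-body superposition is the Kabsch algorithm: with both coordinate sets
centred, the SVD of the 3×3 cross-covariance gives the proper rotation
minimizing $\mathrm{RMSD} = \sqrt{\tfrac1N \sum_i |x_i - y_i|^2}$; a
reflection, when favoured by the SVD, is corrected so $\det R = +1$. Weights
are uniform — the statistics are computed on Cα atoms only, so mass
weighting would be a constant. Per-residue fluctuation is
$\mathrm{RMSF}_i = \sqrt{\langle |r_i(t) - \langle r_i\rangle|^2 \rangle}$.
Its reference is the ensemble mean structure, obtained by one fixed-point
iteration: fit every frame to frame 1, average, refit every frame to that
average, and average again. The first frame can be used as reference instead
(`fit = "first"`), and fitting can be disabled (`fit = "none"`) for
generator output, which carries no global tumbling by construction.

## SASA

`shrake_rupley()` places `n_points` quasi-uniform points (golden-spiral
construction) on each atom's expanded sphere of radius $r_i + r_{probe}$ and
counts the fraction not buried inside any neighbour's expanded sphere.
Defaults are a 0.14 nm water probe and 960 points, the conventions of the
standard trajectory tools. Radii come from a fixed element table (C 0.170,
N 0.155, O 0.152, S 0.180, H 0.120 nm); unknown elements fall back to the
carbon radius with a warning. Cα-only ensembles therefore get 0.17 nm beads
automatically. Neighbour search uses an exact cell list (27-cell stencil at
cell size ≥ the largest interaction distance). Two numerical caveats are
inherent to any fixed-grid point-sampling scheme: totals converge at roughly
the 1% level between 1024 and 4096 points, and the quadrature grid is fixed
in the lab frame, so SASA is exactly invariant under translation but only
quadrature-exact (≲0.5% at 960 points) under rotation.

## DCCM

The displacement covariance is
$c(i,j) = \langle \Delta R_i(t) \cdot \Delta R_j(t) \rangle$ with
$\Delta R_i(t) = r_i(t) - \langle r_i \rangle$ taken as the full 3-vector
displacement and a scalar dot product; the normalized matrix is
$c(i,j)/\sqrt{c(i,i)\,c(j,j)}$, bounded by $[-1, 1]$ with +1 for fully
correlated and −1 for anti-correlated motion. Frames are superposed onto the
mean structure first (otherwise rigid tumbling dominates the covariance);
the same alignment backs `rmsf()`, so the raw diagonal equals RMSF² exactly.
A residue with zero variance would make the normalization divide by zero;
its row and column are set to 0 off-diagonal (1 on the diagonal) with a
warning. `correlated_regions()` reports maximal contiguous off-diagonal
blocks whose mean |correlation| clears a threshold, by exhaustive
enumeration over contiguous range pairs with 2-D prefix sums — O(n⁴) blocks,
intended for residue-scale matrices (hundreds of residues), not generic
matrices.

## Residue network and shortest-path map

The mean Cα–Cα distance matrix is averaged over frames without superposition
(distances are rigid-motion invariant). An edge joins residues whose mean
distance is within the truncation cutoff — default 1.5 nm, the customary
truncation for this network analysis, although that is large for a contact
map; it is configurable — and whose |correlation| is at least `min_abs_corr` (default 0.05, which
keeps weights finite near $c = 0$). The edge weight is $-\ln |c(i,j)|$, so
strongly correlated pairs give short paths; the originating SPM methodology
weights by correlation but leaves the functional form open, and this choice
is declared, not reconstructed. Sequence-adjacent residues are kept by
default (`exclude_neighbors` drops them if their trivial correlation is
unwanted).

For every ordered source–target pair in a connected component one
minimum-weight path is counted. Determinism is guaranteed by the
reconstruction rule: from the Dijkstra distance field rooted at the target,
walk from the source always choosing the smallest-index next node that stays
on a shortest path. This yields the lexicographically smallest shortest
path; repeated runs are bit-identical. Edge and node usages are normalized
by their maximum, and `spm_density()` counts nodes/edges above a normalized
floor — the "density of points and bonds" reading in which a tighter network
indicates a more stable conformation.

One property one might expect — that uniformly damping all correlations
lowers the retained-edge count at a fixed normalized floor — does **not**
hold under this weighting: damping by a factor $\alpha$ adds the constant
$-\ln\alpha$ to every edge weight, which re-ranks multi-hop against few-hop
paths and flattens the usage distribution, often *raising* the count above a
normalized floor. What is monotone, and what the tests assert, is the edge
set itself: weaker correlations can only lose edges at the |c| gate, and
surviving weights shift by exactly $-\ln\alpha$.

## Synthetic ensembles: the GNM generator

The generator is a Gaussian network model on a Cα backbone: the Kirchhoff
(contact Laplacian) matrix $\Gamma$ is built from contacts within 0.7 nm —
the customary GNM cutoff, deliberately independent of the 1.5 nm analysis
cutoff — and the per-coordinate displacement covariance is
$(\tau/\gamma)\,\Gamma^{+}$, the Moore–Penrose pseudo-inverse scaled by a
temperature factor $\tau$ over a spring constant $\gamma$. Frames are the
reference plus i.i.d. Gaussian displacements per axis drawn through the
eigen-factorization of that covariance (translational null mode excluded),
so the expected 3-D dot-product covariance is exactly $3(\tau/\gamma)\,
\Gamma^{+}$ — a closed-form oracle for the whole DCCM pipeline. A
per-residue damping profile $d$ rescales the covariance to
$\mathrm{diag}(d)\,C\,\mathrm{diag}(d)$, planting high-RMSF "flexible
regions" analogous to the loop sites that light up in a thermally stressed
ensemble.

Defaults were chosen once, for realism at the amplitude scale of a folded
protein: $\gamma = 100$ (energy/nm²) with $\tau = 1$ puts per-residue RMSF
at roughly 0.08–0.15 nm on a compact helix, matching the sub-0.2 nm
fluctuation scale a stable globular enzyme shows in solvent simulations.
$\tau$ is a unitless stand-in for $k_BT$: doubling it doubles every
covariance entry. Comparing e.g. 277 K against 313 K ensembles means
comparing $\tau$ in that ratio (or any monotone mapping); the generator
makes no claim to reproduce the real lipase's force field, solvent, or
anharmonicity. Two consequences matter for interpreting green tests: GNM
correlations are temperature-*invariant* by construction (only amplitudes
scale), so temperature ordering of RMSD/SASA variability is reproduced but
temperature-driven decorrelation is not; and displacements are isotropic
Gaussians, so nothing anharmonic (partial unfolding, two-state hopping) is
represented. Passing tests demonstrate the estimators are correct, not that
real trajectories behave like the generator.

Validation problem sizes, chosen to make Monte-Carlo error comfortably
smaller than the tolerances they are checked against: 50-residue fixtures
with 20,000 frames for the DCCM-vs-analytic check (max-abs tolerance 0.05),
2,000–4,000 frames for RMSF identities and flexibility ranking, and 200
seeded replicates for kinetic parameter recovery.

## Kinetics and foam indices

`fit_michaelis_menten()` minimizes $\sum_k (v_k - V_{max} S_k/(K_m+S_k))^2$
by Levenberg–Marquardt (damped least squares) on $(\log V_{max}, \log K_m)$,
which keeps both parameters positive without explicit bounds. Starting
values are $V_{max,0} = \max v$ and $K_{m,0}$ = the concentration whose
observed rate is nearest $V_{max,0}/2$. Convergence uses a relative-SSE
tolerance of 1e-10 (parameter step 1e-12, cap 1000 iterations).
Non-convergence and boundary collapse are *flagged*, not thrown: a design
with only saturating concentrations leaves $K_m$ unidentifiable, the log
parameterization drives it toward zero, and the fit is returned with
`converged = FALSE`. Reported ± values are asymptotic standard errors from
the Jacobian at the optimum (delta method from the log scale); they are not
replicate standard deviations.

Turnover requires the total enzyme concentration, which assay tables often
omit; `kcat` ($V_{max}/[E]_{tot}$, converted to s⁻¹) and the efficiency are
therefore filled in only when `enzyme_conc_uM` is supplied. Catalytic
efficiency is $k_{cat}/K_m$ on the M⁻¹ s⁻¹ scale — per-substrate efficiency
columns in the characterization literature are sometimes labelled
s⁻¹ µM⁻¹ while being numerically $k_{cat}[\mathrm{s}^{-1}]/K_m[\mathrm{M}]$,
and the numerically consistent scale is the one implemented (0.61 s⁻¹ at
9.26 mM gives 65.87).

The synthetic assay generator adds Gaussian noise to model rates and clips
at zero, as a plate reader's non-negative readings would. At 2% - of -
$V_{max}$ noise this clipping visibly truncates the near-zero rates at the
lowest concentrations of a 0.01–30 mM log grid; the median estimate stays
on target while per-replicate spread in $K_m$ is wide — which is why
recovery is judged on medians.

Foaming ability is the whipping expansion index
$FA = (m_0 - m_1)/m_1 \times 100$ (unwhipped mass over the whipped mass of
an equal volume); foaming stability $FS = m_p/m_i \times 100$ is the liquid
precipitation rate after standing — *larger means less stable*, and
`foaming_stability()` rejects $m_p > m_i$ as a measurement inconsistency.
Relative activity is $100\,x/x_{ref}$ with the profile maximum as the
default reference (optimum-temperature/pH profiles) or a control index
(ion/solvent treatments).

## Degenerate inputs and tie-breaks, collected

* Kabsch: < 3 atoms is underdetermined (error); reflections corrected.
* RMSF/covariance: < 2 frames is an error; frozen residues normalize to a
  zeroed row with a warning.
* Graph: |c| below `min_abs_corr` is gated out rather than producing a huge
  weight; $|c| = 1$ gives weight exactly 0; equal-weight shortest paths are
  resolved by the smallest-next-index rule.
* Multi-model PDB: inconsistent atom counts across MODELs, unparseable
  coordinates (reported with line number), and insertion codes are hard
  errors; the first alternate location is kept.
* Matrix CSV: values are written with 15 significant digits so round trips
  are faithful to 1e-12 relative.

## Known limitations

The generator's limitations are described above. Beyond those:
`correlated_regions()` is exhaustive and slows past a few hundred residues;
SASA has no analytic-surface mode (point sampling only); the kinetics module
fits the single-substrate hyperbola only (no inhibition terms, no
linearization diagnostics); and the network analysis operates on mean
distances, so transient contacts shorter than the averaging window are
smoothed away.
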