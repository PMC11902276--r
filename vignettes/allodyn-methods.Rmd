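---
title: "Methods: allosteric dynamics analysis with allodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allosteric dynamics analysis with allodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(allodyn)
```

`allodyn` post-processes coarse-grained coordinate ensembles — one node per
protein residue (Cα) and one per nucleotide (P) — to ask how a local
perturbation, such as a chemical modification of a single residue, changes
the collective dynamics and the allosteric communication of a protein or
protein–DNA complex. This vignette documents the model behind each stage,
the default parameters, and the numerical choices, in the order the pipeline
runs them.

## The synthetic test bed

Real trajectories are large and their "true" correlations unknown, so the
package ships a generator whose answers are known in closed form. A toy
complex is built from an ideal helical Cα trace (rise 3.8 Å, helix radius
2.3 Å, pitch 5.4 Å, with the axial step solved so consecutive nodes are
exactly one rise apart) plus an optional straight phosphate trace (spacing
7 Å, offset 12 Å from the helix axis). Frames are then drawn from the
Boltzmann distribution of an anisotropic network model (ANM) built on that
geometry: displacements are sampled independently in each non-rigid normal
mode with variance `temperature_scale / eigenvalue`, so the exact ensemble
covariance is the mode-truncated pseudo-inverse of the ANM Hessian. Every
simulated quantity therefore has an analytic ground truth
(`ground_truth$true_covariance`, `ground_truth$true_lmi_correlation`)
against which the analysis stages are validated in the test suite.

```{r}
model <- build_toy_complex(toy_complex_spec(20, 4))
sim <- sample_anm_ensemble(model, n_frames = 500, seed = 1)
n_frames(sim$ensemble)
```

A "perturbed" state is produced from the same network with the springs
touching designated nodes stiffened (`make_demo()`, default multiplier 8),
emulating the local rigidification that a bulky covalent modification
imposes. These defaults are study conditions — chosen to mimic a
residue-scale modification in a mid-sized protein–DNA complex — not values
tuned to any test.

## Structural metrics

RMSD and RMSF use Kabsch superposition: the optimal rotation comes from the
SVD of the weighted cross-covariance of centered coordinates, with the
smallest singular direction flipped when needed so the rotation is proper.
Degenerate (collinear) geometries are rejected rather than silently fitted.
RMSF is measured about the ensemble mean after iteratively superposing all
frames onto that mean (tolerance 1e-6 Å, at most 20 iterations).

Interaction occupancies count frames satisfying a geometric criterion.
Hydrogen bonds use the donor–acceptor distance ≤ 3.5 Å together with the
hydrogen–donor–acceptor deviation angle ≤ 30° (distance alone when no
hydrogen position is available); salt bridges use a minimum
side-chain-nitrogen to carboxylate-oxygen distance ≤ 4.0 Å. Both boundaries
are inclusive. Occupancies are exact integer counts and are reported either
as a percentage ("73.0%") or in interaction-table form ("label (73.00)").

```{r}
ev <- make_event_series(100, 0.73, seed = 2)
format_occupancy(hbond_occupancy(ev$donor, ev$acceptor, ev$hydrogen))
```

## Essential dynamics and free-energy landscapes

The 3N × 3N Cartesian covariance (population divisor) is accumulated after
the iterative fit above. Because a least-squares fit is only equivariant —
the fitted ensemble inherits the arbitrary orientation of its input — the
fitted frames are additionally rotated into a canonical frame (principal
axes of the mean structure, signs fixed by the largest projection, third
axis by cross product) so that the covariance, and everything derived from
it, is bitwise invariant under rigid transformation of the input ensemble.

Eigenvectors are sign-fixed (largest-magnitude component positive).
Sampling convergence of each projection is screened by the cosine content
`c = (2/F) (Σ p_t cos(πt/F))² / Σ p_t²`; values near 1 indicate
random-diffusion-like drift, and a component passes at `c ≤ 0.1`. The
free-energy landscape over the first two passing components is
`G = -kT ln(P / Pmax)` on a 32 × 32 histogram, with never-visited bins left
as `NA` rather than given an arbitrary cap.

## Linear mutual information and generalized correlation

Pearson cross-correlation misses correlated motion at right angles. The
package instead computes linear mutual information between the 3-D
fluctuation vectors of node pairs under a Gaussian model,
`I = H_i + H_j - H_ij` with `H = ½ ln[(2πe)^k det Σ]`, and maps it to a
generalized correlation coefficient `C = (1 - exp(-2I/3))^(1/2)` in [0, 1].
For isotropic per-axis coupling `C` equals `|ρ|` exactly, which the tests
verify against the closed form `I = -(3/2) ln(1 - ρ²)`.

Two numerical choices matter. Determinants are taken through Cholesky
log-determinants after adding a relative jitter `1e-8 · tr(Σ)/3N` to the
diagonal, keeping nearly-rank-deficient blocks finite. And a genuinely
degenerate joint block — one node an exact linear copy of another, detected
by `det Σ_ij < 1e-12 · det Σ_i det Σ_j` — is mapped to `I = ∞` and hence
`C = 1` exactly, the supremum of the coefficient, rather than to a
jitter-dependent value.

```{r}
pair <- make_correlated_pair(200, rho = 1, seed = 3)
lmi_matrix(pair, fit = FALSE)$C[1, 2]
```

## Correlation-weighted network and betweenness

Nodes are connected when within 10 Å in at least 75% of frames (or in the
mean structure when no ensemble is supplied), and each edge carries the
weight `-ln C`, so high correlation means low cost. Correlations are
clipped to [1e-6, 1 - 1e-6] before the logarithm. Betweenness centrality —
the fraction of weighted shortest paths passing through a node, with
fractional splitting over ties — is delegated to `igraph`'s Brandes
implementation and normalized by `(N-1)(N-2)/2`; the suite cross-checks it
against an exhaustive all-simple-paths enumeration on small graphs. State
differences beyond `|ΔBC| > 0.1` are flagged as rewired.

## ANM and perturbation response scanning

The ANM Hessian uses 3 × 3 super-elements
`-γ/|d_ij|² · d_ij d_ijᵀ` for pairs within 12 Å, diagonal blocks closing
each block row to zero. A connected three-dimensional structure has exactly
six zero modes; the builder errors only when the contact graph is truly
disconnected and otherwise records the zero-mode count, since deliberately
collinear test geometries have more than six. The covariance is the
pseudo-inverse truncated to the 20 slowest non-zero modes.

Perturbation response scanning applies a unit force at each node and reads
displacements through `ΔR = C F`. The response of node j to forcing node i,
averaged over isotropic force directions, has the closed form
`(1/3) Σ (C_ji)²` over the entries of the 3 × 3 coupling block; Monte-Carlo
direction sampling is retained purely for validation. Rows are normalized
by their self-response (diagonal ≡ 1, and the map becomes independent of
γ), effector/sensor profiles are the off-diagonal row/column means, and the
production map averages the normalized maps of 100 evenly spaced
representative frames, skipping (with a warning) frames whose instantaneous
geometry is disconnected at the cutoff.

```{r}
m <- build_anm(model_coords(model), cutoff = 12)
p <- prs_scan(m)
range(diag(p$normalized))
```

## Pipeline

`run_pipeline()` ties the stages together from a YAML config naming a
reference structure, per-state ensembles and the reference state. Stages
run in dependency order (`network` implies `lmi`, recorded in the
manifest), per-state tables and matrices are written as CSV/plain text,
state-minus-reference difference reports follow, and a JSON manifest
records parameters and md5 checksums of every output so runs are verifiably
reproducible.

## Limitations

The generator samples a Gaussian, so anharmonic and multi-basin effects —
the very things a free-energy landscape of a real trajectory would show —
are absent; FEL correctness is instead validated on analytic Gaussian
references. Node-level granularity ignores side-chain detail, the H-bond
demonstration uses designed event series rather than all-atom geometry, and
PRS inherits the harmonic approximation of the ANM. Problem sizes in the
bundled analysis scripts (≈70 nodes, hundreds of frames) are chosen to keep
desk-scale runtimes, not to match any particular production study.
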