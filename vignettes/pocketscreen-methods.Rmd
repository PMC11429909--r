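---
title: "PocketScreen: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PocketScreen: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented by PocketScreen, the
assumptions behind them, the default parameters and why they were chosen,
what the synthetic generators do and do not cover, and the numerical
decisions that matter for reproducibility.

## 1. Pocket detection

### Model

A protein is modelled as a union of van der Waals spheres, rasterized on a
cubic grid. The detection pipeline is purely geometric:

1. **Occupancy.** A voxel is protein when its center lies within the van der
   Waals radius of any atom. Radii follow standard element values
   (C 1.70, N 1.55, O 1.52, S 1.80 Å, …); unknown elements fall back to
   1.70 Å with a warning.
2. **Probe opening.** Free space is morphologically opened with a spherical
   solvent probe (1.4 Å, the effective radius of water): a free voxel
   survives only if it belongs to some probe-sized ball that fits entirely
   outside the protein. This removes crevices a water molecule cannot enter.
3. **Bulk solvent.** Probe-accessible free space connected (26-connectivity)
   to the bounding-box boundary, re-dilated by the probe, is bulk solvent.
4. **Enclosure (sky occlusion).** From each free voxel, rays are cast along
   all 26 grid directions. A voxel is pocket-like when at least `minEnclosed`
   of the 26 rays hit protein before leaving the grid.
5. **Components.** Pocket-like voxels are grouped by 26-connectivity;
   components with fewer than `minVoxels` voxels are noise and discarded.
   Components are ordered by volume (ties: lowest linear voxel index), so
   output order is deterministic.

A fully sealed internal cavity has all 26 directions blocked and is reported
with mouth count 0; a shallow dent has most of its sky open and is not
reported.

### Measurements

- Volume: voxel count × spacing³.
- Surface area: exposed voxel faces × spacing² × **0.894**. A staircase
  (voxelized) surface systematically overestimates the area of the smooth
  surface it approximates; 0.894 is the standard correction factor for
  face-counting estimators, applied uniformly.
- Mouths: connected clusters of pocket voxels 6-adjacent to bulk solvent.
- Lining residues: residues owning the nearest atom of any protein voxel
  adjacent to the pocket.

### Defaults and rationale

| Parameter | Default | Rationale |
|---|---|---|
| `spacing` | 0.5 Å | Error of the volume estimator on an analytic hemisphere is under 7% at 0.5 Å and about 1% at 0.25 Å; 0.5 Å balances accuracy against an 8× cost factor. Valid range 0.25–1.5 Å. |
| `probe` | 1.4 Å | Water effective radius; standard in accessibility analysis. |
| `minEnclosed` | 14 / 26 | A strict majority of the sky must be occluded. Chosen a priori as "more enclosed than open"; empirically gives rotation-invariant volumes (ratio within 1% for a rotated fixture) because the 26-direction census is nearly isotropic, unlike single-axis line-of-sight tests. |
| `minVoxels` | 30 | 3.75 Å³ at default spacing, well below any bindable site; removes single-voxel noise only. |
| `minArea` (filter) | 500 Å² | Empirical lower bound for sites able to bind a drug-like molecule. |
| `minPolar` (filter) | 2 | At least two polar lining residues for directional ligand interactions. |

Multi-mouth pockets are *deprioritized*, not removed: tunnels can still be
real sites, but single-mouth closed pockets are better targets.

### Assumptions and limitations

- Rigid, static structure: no side-chain flexibility, no conformational
  ensembles.
- Hydrogens are ignored (heavy-atom radii absorb them).
- The voxel estimator's area correction is calibrated for smooth surfaces;
  very rough pockets may deviate more than the volume does.
- Pockets straddling the margin of the bounding box (margin default 5 Å) are
  not supported; the margin guarantees bulk solvent surrounds the structure.

## 2. Shape signatures

The signature is the full multiset of pairwise Euclidean distances between
lining atoms. It is exactly invariant under rigid motions and reflections,
and scales with pocket size, so similar shape at different scale is
*distinguished* (a deliberate choice: binding is size-sensitive).

Comparison uses the exact two-sample Kolmogorov–Smirnov statistic: both
empirical CDFs are evaluated at every pooled sample point via
`findInterval`, and D is the maximum absolute difference — no histogram
approximation is involved (histograms are attached to signature objects for
display only). The p-value is the asymptotic Kolmogorov series
$Q(\lambda) = 2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2\lambda^2}$ at
$\lambda = \sqrt{n_{\mathrm{eff}}}\,D$, which is approximate for effective
sample sizes below ~35. Signatures serialize to JSON with 17 significant
digits, which round-trips doubles bit-exactly.

The library-search candidate threshold (D < 0.25) is a toolkit decision: at
that distance the pooled CDFs differ by less than a quarter at every
distance scale, our operational definition of "similar enough to test the
same chemistry".

## 3. Surface alignment

- **Correspondence**: greedy nearest-neighbour matching restricted to
  chemical classes (N, O, S, other), deterministic given the input order.
- **Superposition**: closed-form least-squares rotation via SVD with the
  determinant correction that excludes reflections. The coordinate RMSD
  (cRMSD) of the superposed correspondence is the primary distance.
- **Orientation RMSD (oRMSD)**: angular disagreement of unit side-chain
  orientation vectors (CA → side-chain centroid), capturing chemistry
  direction that cRMSD ignores.
- **Significance**: the observed cRMSD is compared against `nNull` random
  rotations (uniform quaternions) of one pocket;
  $p = (1 + \#\{\text{null} \le \text{obs}\})/(1 + n_{\mathrm{null}})$.
  The add-one form is conservative and never returns 0. The RNG state is
  saved and restored, so calling the function does not perturb the caller's
  stream. `nNull` defaults to 99 (p resolution 0.01); values below 19 are
  rejected as meaningless.
- **Volume overlap**: both pockets' voxel sets on a common grid give a
  Tanimoto score $|A\cap B|/|A\cup B|$.
- **Composite**: geometric mean of $(1-D)$, $(1-p)$, and the Tanimoto,
  clamped to $[10^{-6}, 1]$ so a single zero term cannot annihilate the
  product before logging.

## 4. Compound funnel

Drug-likeness windows (MW 160–480, TPSA < 140, HBD < 5, HBA < 10) are
closed on the MW bounds and open on the rest, matching the conventional
phrasing "between 160 and 480" vs "fewer than 5". Records with missing
properties are rejected with reason `missing_property`; every violated rule
is reported, not just the first.

The funnel consumes externally produced score tables (docking is *not*
reimplemented): stage 1 may union several method tables; later stages rank
survivors (dense ranks, ties share a rank) and keep `keepCount` or
`ceiling(keepFraction × n)`; a survivor missing a later-stage score is
dropped with a message and recorded in the `dropped` attribute. `finalK`
truncates the final ranking. The result is by construction identical to
composing exhaustive top-N cuts, and the test suite asserts exactly that
against the generator's ground truth.

## 5. Screening analytics

Percent-of-control divides the treated colony-count mean by the
matched-control mean (same cell line, same day — mismatches are errors, not
warnings). The activity cutoff (efficacy ratio < 0.5) is strict, as is the
marrow-toxicity threshold (> 10%, > 30% inhibition). Percentages shown in
reports are rounded **half-up** (62.5% → 63%), matching how screening tables
are conventionally printed, rather than R's banker's rounding.

Site summaries pool the sub-cutoff ratios of all active compounds at a
site; the SEM of a single pooled value is reported as 0 (not NA) to
distinguish "one observation" from "no observations".

The four-parameter logistic is fit by Levenberg–Marquardt least squares
(minpack.lm) with box constraints: asymptotes within the response range
± one range, log IC50 within the tested dose range ± 2 decades, |hill| ≤ 10.
The constraints keep the search out of degenerate plateaus (they stall an
unbounded search when a curve bottoms out at exactly 0) without affecting
well-conditioned fits. Zero doses are excluded (log scale); the fitted
parameters are canonicalized to bottom ≤ top using the model's
(bottom, top, hill) → (top, bottom, −hill) symmetry. Non-convergence is an
error, never a silently returned estimate.

## 6. Synthetic generators: scope

The generators produce fixtures with *analytic* ground truth and are the
package's test bed; their defaults are fixed study conditions, not tuning
knobs.

- `makePocketStructure`: a protein-like atom lattice with a hemispherical
  surface pocket (open) or a buried spherical cavity (sealed) of exactly
  known volume and mouth count. It covers smooth, single-pocket geometry
  only — no real-protein roughness, no multi-pocket interference.
- `makeCompoundTable`: property distributions straddling every filter
  boundary, with the survivor set recorded by an independent inline
  predicate (dual route to the filter implementation).
- `makeColonyData`: integer colony counts from a 4PL curve with
  multiplicative log-normal noise (mean 1, given CV); `cv = 0` gives exact
  rounded expectations.
- `makeScoreTables`: stage scores sharing a latent signal plus noise, with
  the exhaustive cut composition recorded as ground truth.

All generators derive child seeds from the user seed, write byte-identical
output for the same seed, and restore the caller's RNG state.

## 7. Reproducibility decisions

- Deterministic ordering everywhere a set is returned (pockets by volume
  then voxel index; search hits by D, then p, then id).
- Seeded Monte-Carlo with save/restore of `.Random.seed`.
- JSON emitted with explicit precision; repeated CLI runs on identical
  inputs produce byte-identical reports.
- Rounding to printed precision happens only at the reporting boundary;
  internal statistics are never rounded before use.
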