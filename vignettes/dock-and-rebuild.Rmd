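---
title: "Docking and density-guided rebuilding of predicted protein models"
author: "dockrebuild"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking and density-guided rebuilding of predicted protein models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Machine-learning structure predictors produce remarkably accurate protein
models, but almost always with weak spots: flexible loops, low-information
regions, and — most importantly — inter-domain arrangements that cannot be
inferred from sequence alone. A cryo-EM density map carries exactly the
complementary information: where the mass actually is. `dockrebuild`
implements an automated procedure that reconciles the two. Given a
predicted model whose per-residue confidence (plDDT semantics, 0–100)
is stored in the B-value field, and a density map with a nominal
resolution, one cycle performs five stages:

1. **Trim and split.** Residues whose smoothed confidence falls below 70
   (the conventional boundary for a good prediction) are removed, and the
   remainder is grouped into up to `maximum_domains` compact domains, by
   spatial proximity or by blocks of low predicted aligned error.
2. **Dock.** Each domain is placed in the map independently, first by
   secondary-structure matching (SSM) against helix/strand rods detected
   in the density, falling back to an exhaustive rotation/translation
   correlation search when SSM does not reach `ssm_search_min_cc` (0.3).
   Candidate placements are expanded across domains (domains often share a
   transform) and by user-supplied symmetry operators, and the final
   combination is chosen by an empirical score described below.
3. **Morph.** The full-length model — including trimmed residues — is
   distorted smoothly onto the docked domains with a shift field, then
   adjusted by restrained real-space refinement.
4. **Rebuild.** Residues with low confidence or low density fit are
   flagged, and each flagged segment is rebuilt by up to six strategies;
   every strategy that succeeds yields a full-length candidate model.
5. **Assemble.** For every segment the best candidate (by segment map
   correlation) is spliced into a single model, which is refined once
   more.

`run_iterative()` wraps this cycle in a loop with a pluggable predictor:
the rebuilt model of one cycle becomes the template for the next
prediction. The real inference engine is out of scope; the
`stub_predictor()` satisfies the same contract deterministically so that
the loop itself is testable.

## Map-model correlation and the density kernel

All docking and assembly decisions are ranked by a masked map-model
correlation: the Pearson correlation between the experimental map and a
model-computed map, over the union of spheres of `mask_radius` (2.5 Å,
configurable) about the model's atoms. A single mask radius — rather
than atom-type-dependent radii — is sufficient because the procedure only
ever *ranks* alternatives computed with the same convention.

Model density places an isotropic Gaussian on every atom, with integral
equal to the element's electron count and width `sigma = 0.425 *
resolution`, i.e. a full width at half maximum equal to the nominal
resolution. This reproduces the visual blob width of experimental maps
at that resolution and, just as importantly, gives the correlation a
capture basin of roughly the resolution: with a much sharper kernel the
conventional thresholds used throughout the pipeline (0.15 to accept a
docked pose, 0.25 for an SSM candidate, 0.5 for a confidently placed
domain) would be unreachable for poses a couple of ångströms off, and
docking would have nothing to climb. Contributions beyond 3.5 sigma are
truncated; per-atom B-values are ignored in synthesis because the B
column of predicted models carries confidence, not displacement.

## Docking

**SSM.** Rod-like regions of high density are detected by sweeping
thresholds over the map, keeping connected components that are straight
(small second principal moment), long enough (≥ 10 Å), and classifying
them as helices or strands by cross-sectional thickness relative to the
kernel width. Two domain SSEs paired with two map rods define a
transform; all sliding alignments and both rod directions are tried, a
least-squares superposition is accepted when the paired-CA r.m.s. is
within `match_distance_high` (5 Å), and surviving poses are scored by
map correlation, refined and deduplicated. Dense loop regions can
masquerade as rods in compact folds — one reason the correlation search
exists as a fallback.

**Correlation search.** A quasi-uniform rotation grid (super-Fibonacci
sampling, about 24° spacing at the default `rotation_count = 300`) is
scanned; for each rotation the domain density is cross-correlated with
the map by FFT over all translations on a grid coarsened to about half
the resolution. Peak scores are normalized by the local map energy under
a spherical domain-support mask; without this normalization plain
cross-correlation peaks always land on the heaviest density region, and a
small domain docks onto a larger neighbour's site. Top peaks are
polished by rigid-body refinement (Nelder–Mead over the six pose
parameters, two rounds with the correlation mask frozen per round).

**Choosing the combination.** The empirical score starts at zero. If
every placed domain reaches `minimum_docking_cc` (0.15), 200-unit bonuses
are added for: lowest cc above `acceptable_docking_cc` (0.5); all
placements sharing similar transforms (r.m.s. coordinate difference at
most the resolution — granted only when at least two domains are placed,
since a lone placement is no evidence of rigid-body consistency); all
domains docked; overlap fraction below `allowed_fraction_overlapping`
(0.1, counting CA pairs within `overlap_ca_ca_distance` = 3 Å); and all
sequence-consecutive domains within the distance their intervening
residues can span (taken as 3.8 Å per virtual CA–CA bond, i.e.
`3.8 * (gap + 1)`). Exceeding the spannable distance by more than twice
the resolution plus `maximum_connectivity_deviation` (15 Å) costs 200
units. Finally the lowest and mean cc are added and the fractions of
dissimilar transforms, overlapping CAs, and normalized connectivity
deviations are subtracted. The search over combinations is exhaustive up
to 10,000 combinations (top-5 placements per domain plus "unplaced"),
with a beam search beyond that.

## Shift-field morphing

A shift field is a set of (anchor, vector) pairs plus a distance scale
`shift_field_distance` (10 Å): one anchor per docked CA, sitting at the
CA's position in the full predicted model, carrying the docked-minus-
predicted displacement. The field at any point is the Gaussian-weighted
mean of all vectors, with weights `exp(-d^2 / D^2)`. Every atom — not
only CA — is displaced by the field at its own position, so side-chain
and backbone atoms ride smoothly with their residue. The 10 Å default
trades geometry preservation (large `D`) against tight matching of the
docked domains (small `D`); distortions occur on roughly that length
scale. The same machinery performs splice grafts (anchors on three
residues at each end of a segment) and the windowed morph used in
rebuilding.

## Refinement

`simple_real_space_refine()` is a deliberately simple restrained
refinement: gradient ascent on the interpolated density at CA positions
with three restraint classes — harmonic CA–CA virtual bonds (target
3.8 Å), an elastic network of springs between CA pairs initially within
8 Å, and optional harmonic reference restraints. The elastic network is
essential: fitting point atoms to density at ~3 Å resolution otherwise
collapses a helix onto its own tube axis, because the density maximum
near each CA lies inward of the spiral. Spring weights are scaled by the
geometric mean of the two residues' confidences, so confidently predicted
geometry is preserved while low-confidence loops remain free to move into
density. A guard recomputes the map correlation and returns the input
coordinates if refinement would lower it. Iterative-resolution
refinement repeats this against maps low-pass filtered to 6, 5, 4, ... Å
down to the map resolution, widening the capture basin to a few
ångströms.

## Rebuilding strategies

Residues are flagged for rebuilding when their smoothed (window 10, the
`minimum_domain_length`) confidence is below 70 or their smoothed CA
density falls below an outlier threshold: discard the lower half of the
per-CA density values, and take the mean of the remainder minus
`cc_sd_ratio` (3) standard deviations. Each contiguous flagged segment
is attacked by:

* **iterative-resolution refinement** of the whole model (above);
* **loop fitting** — 200 seeded directional random walks closed onto the
  flanking anchors by cyclic-coordinate-descent pivots, scored by mean CA
  density with a smoothness tie-break;
* **retracing** — the widest path through the density between the flank
  anchors: binary search over density thresholds with 26-connected
  flood-fill connectivity tests (exact for grid minima), shortest path at
  the optimal threshold as tie-break, resampled to the segment's residue
  count;
* **combination** — clear sub-runs (density above the outlier threshold)
  are retraced, unclear runs keep the refined conformation and are
  grafted on with 3-residue splices;
* **windowed morphing** — six residues from each end at a time are
  rigidly shifted to increase density (seeded random-restart hill climb
  under 2.9–4.3 Å consecutive-CA constraints), the remainder is
  superimposed through a shift field, and the window steps inward;
* **external fragments** — a contiguous run of exactly the segment's
  length from a user-supplied model qualifies when its terminal CAs
  deviate at most `ca_distance` (3.8 Å) from the segment's end residues.

Strategies keep a fixed order (the list above) so that ties in assembly
break deterministically. Every stochastic strategy takes an explicit
seed (default 0). Candidates are refined before their per-segment
correlations are measured; the assembled chimera is refined once more,
so its pre-refinement per-segment correlation equals the per-candidate
maximum exactly by construction.

## The synthetic test system

Nothing in the package requires experimental data; the `fixtures` module
builds complete test systems. `make_toy_fold()` lays out canonical
helices (2.3 Å radius, 1.5 Å rise, 100°/residue) and strands (3.3 Å
rise, 0.8 Å zigzag) as antiparallel bundles, joined by smooth seeded
connectors with near-3.8 Å CA spacing, with backbone N, CA, C, O atoms
only. `make_predicted_like()` derives a "prediction": whole domains are
rigid-body perturbed, loops receive chain-correlated Gaussian noise, and
per-residue confidence emulates plDDT as `100 * exp(-err / 4)` (clipped
to [20, 98]) where `err` is the *local* (non-rigid) error — a rigidly
misplaced domain keeps high confidence, exactly as a confidently
predicted but wrongly packed domain does in real predictions.
`make_synthetic_map()` synthesizes the map from the truth on a padded
grid, optionally with seeded Gaussian noise.

The standard benchmark (`fixture_two_domain()`) is a 112-residue chain:
a 12/12/12-helix bundle and a 16/14/10-helix bundle joined by a
20-residue linker, with the second domain rotated 15° and translated
4 Å, 3 Å loop noise, and a noiseless 3 Å map on a 1 Å grid. The two
domains are given different helix lengths deliberately: identical twin
domains make correct and swapped docking genuinely indistinguishable —
even the connectivity and overlap terms cannot separate them — which is
a property of the fixture, not of real proteins.

What the fixtures do *not* emulate: real cryo-EM noise spectra (CTF,
B-factor falloff, anisotropy), side chains, sequence-register errors,
neighbouring chains in a crowded map, and genuine plDDT calibration.
Passing the suite therefore demonstrates the machinery — detection,
docking, morphing, rebuilding, assembly, and their interplay — under
controlled conditions, not performance on deposited maps.

## Numerical choices and degenerate inputs

* Residue intervals are half-open `[start, end)` on 0-based positions;
  residue numbers are labels and survive every operation unchanged.
* MRC maps: the ORIGIN header wins when nonzero, else NSTART × voxel;
  axis order is normalized on read; non-orthogonal cells and skewed
  frames are rejected.
* Confidence columns with maximum ≤ 1 are treated as the 0–1 scale.
* Zero-variance density regions give cc = 0 with a warning; an empty
  mask is an error.
* Exactly-spannable domain gaps are not penalized (1 ns epsilon in the
  connectivity comparison).
* Out-of-grid interpolation returns the map minimum, flagged.
* All randomness (fixtures, loop sampling, window morphing, the stub
  predictor) flows from explicit integer seeds; two identical runs are
  bit-identical.
* Problem sizes throughout the test suite — ~40–110 residues, maps up to
  about 100 × 70 × 50 voxels at 1 Å — were chosen so the full suite
  exercises every stage, including twenty docking fixtures and a
  four-cycle iterative run, in well under half an hour on one core.

## Known limitations

* The map SSE detector is a functional component-analysis stand-in, not
  a reimplementation of any published rod finder; compact folds whose
  turns are as dense as their helices defeat it, and the pipeline then
  relies on the correlation search.
* Refinement is CA-driven; other atoms ride rigidly with their residue.
  There are no torsion restraints, no Ramachandran term, no side chains.
* Symmetry operators must be supplied; the package does not detect map
  symmetry.
* The iterative loop's benefit depends on the predictor actually using
  templates; with the deterministic stub it demonstrates stability
  (non-degradation), not the synergy a learned predictor provides.
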