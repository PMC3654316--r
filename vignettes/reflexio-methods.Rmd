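---
title: "reflexio: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{reflexio: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexio)
```

This vignette is the package's own account of its science: what the
statistics and decision rules assume, which conventions were genuinely
open choices, and what a green test does and does not establish.

## The setting

An automated MX reduction pipeline receives unmerged reflection
observations — Miller indices, an intensity on an arbitrary linear scale,
its standard deviation, the source image, and a dataset label — together
with a unit cell and a symmetry assignment from upstream programs.
`reflexio` implements the decision layer around those observations. It
deliberately does **not** integrate images, refine geometry, scale with
per-image models, determine space groups from scratch, or run substructure
searches; those belong to the specialist programs the pipeline wraps, and
here they are represented by their *inputs and outputs* only.

## Symmetry model

The registry (`inst/extdata/symmetry_groups.txt`) carries one
representative group per relevant Laue class (P1, P2, C2, P222, P212121,
P4, P422, P3, P321, P6, P23, P213) as explicit integer matrices acting on
column vectors of Miller indices. Screw axes and centring translations do
not act on (h,k,l), so P212121 shares its rotations with P222; the loader
verifies closure, determinant ±1, and that the declared indexing-ambiguity
operators lie outside the Laue group while normalizing it. This is point
group machinery sufficient for merging, counting and reindexing — not a
230-space-group library: systematic absences are ignored everywhere, which
biases theoretical completeness denominators slightly high for screw-axis
groups (a documented, small effect concentrated in axial reflections).

A caught pitfall worth recording: Miller indices transform by the
*transpose* of the real-space rotation, which differs from the coordinate
matrix for the hexagonal 3- and 6-folds. The registry generator uses the
hkl action, and a d-spacing-invariance test over every registry operator
guards the convention.

**Canonical representative.** Each reflection maps to the
lexicographically greatest index triple in its orbit (including −hkl when
Friedel mates are merged). When mates are kept separate, both mates share
that merged representative and carry a sign: +1 for the mate whose
rotation-only representative coincides with it, −1 for its partner;
centric reflections are always +1. The literature has no single canonical
asymmetric-unit convention across programs, so this repo fixes a cheap,
deterministic, order-independent one and uses it consistently.

## Shell statistics

Bins are equal-volume in reciprocal space (equal width in 1/d³, default
10 shells) between the data's own resolution extremes — the convention
approximating the "bins chosen by the integration program". Within each
shell:

- 〈I/σ〉 is the mean over unmerged observations (the merged,
  inverse-variance-weighted variant is available behind a flag, because
  which quantity the production system parsed is not documented);
- R_merge uses only multiply-observed canonical groups in both numerator
  and denominator, R_meas adds √(n_h/(n_h−1)); negative intensities are
  retained in all sums (no truncation);
- completeness is `100 · n_unique / n_theoretical` with the denominator
  from a full enumeration of index triples in the shell (in-shell, not
  cumulative); a shell with no theoretically possible reflections reports
  `NA`, never a silent 0.

One numerical subtlety: shell edges are computed in 1/d³ space and the two
end edges are pinned to the exact data extremes, because `(1/d³)^(−1/3)`
reintroduces float error that can push the single lowest-resolution
reflection outside the theoretical enumeration window (observed as a
completeness of 100.6% before the fix).

## The resolution-limit rule

Shells are walked from low to high resolution and retained while
〈I/σ〉 is **strictly** greater than the cutoff (default 2, so a shell at
exactly 2.0 triggers the cutoff branch). At the first failing shell the
branch is decided by that shell's completeness against the second
threshold (default 80%): below it, the limit is the previous shell's
high-resolution edge; at or above it, the limit is interpolated linearly
in d between the two shells' high-resolution edges. Open choices decided
here: interpolation is linear in d (not 1/d or 1/d²), matching the
documented assumption of a linear 〈I/σ〉–resolution dependence, and the
known slight over-estimation of the attainable limit is accepted behavior;
completeness is tested only at the failing shell, not cumulatively; a
first shell already below the cutoff returns the low-resolution edge with
a warning flag rather than aborting, because a pipeline must report
something even for very weak data.

## Wilson fit and outlier rejection

The fit is ordinary least squares of ln⟨I⟩ per shell against s² = 1/(2d)²
(slope −2B). All reflections are treated as acentric, so under the model
intensities are exponential with P(I/E[I] > z) = e^(−z); the centric
distribution is omitted for simplicity (a documented bias — centric zones
are a small minority and the tail test tolerances absorb it). Z is
intensity over the fitted expectation at that resolution; rows with Z > 10
(strict) are listed REMOVE.HKL-style and removed, and statistics are
recomputed once on the cleaned table — a single rejection/re-merge cycle,
not an iteration to convergence, mirroring the single re-run the
production flow performs. Note that heavy outliers inflate the
pre-rejection fit itself (50 outliers at Z = 100 among n observations
raise the mean by ≈ 5000/n), which is why the acceptance test classifies
rows near the threshold with a tolerance band instead of pretending the
contaminated fit equals the truth.

## Grouped merging

Sub-datasets are screened against the consensus lattice (symbol equality
plus metric constraints at 3% / 2° tolerances; cells whose edges miss the
consensus by more than 10% are excluded outright). The reference is the
first dataset, in collection order, whose lattice matched; the indexing
ambiguity of every other dataset is resolved by trying the identity and
each registry ambiguity operator and keeping the one maximizing the
Pearson correlation of merged intensities on common canonical indices
(≥ 10 common reflections required, ties to the identity). Groups with no
ambiguity operators skip the search — there is nothing to resolve and no
overlap is needed, which matters for disjoint-coverage sub-datasets.
Scaling to the reference is a single multiplicative factor (ratio of mean
merged intensities on common reflections); per-image or B-factor scaling
is deliberately out of scope. After each addition the per-shell and
overall statistics are recorded, yielding the incremental-improvement
series; completeness and multiplicity are non-decreasing in k by
construction over fixed shell edges. The final merged statistics are
exactly order-invariant only with rescaling disabled, because the
estimated scale depends on which dataset is the reference — the property
test asserts the exact version and this caveat is the reason.

## Anomalous triage

With Friedel mates kept separate, each side of each unique index is
inverse-variance merged; pairs with both sides yield d″ = |F⁺ − F⁻| with
F = √max(I, 0) and σ_F = σ_I / (2·max(F, √σ_I)) — the max() guard keeps
the linearized error propagation from blowing up for weak or negative
merged intensities, standing in for a proper intensity-to-amplitude
treatment that is out of scope. The per-shell statistic is
mean(d″)/mean(σ_d″) (ratio of means; the mean-of-ratios variant is a
flag), and the submission trigger fires when **any** shell strictly
exceeds 1.3 — the resolution range to test being unspecified upstream,
all shells are tested. Under pure noise the statistic concentrates near
√(2/π) ≈ 0.80, comfortably below the trigger.

The molecular-weight guess assumes 47% solvent: MW = V·(1−s)/(Z·ν̄) with
ν̄ = 1.23 ų/Da and Z the rotation-operator count of the (primitive)
registry group. The trial grid is deterministic: solvent 37/47/57% ×
both enantiomorph hands = 6 trials. The solved-structure flag demands
CC > 25 **and** mean fragment length > 10, both strict — a high bar chosen
to suppress false positives at the cost of overlooking marginal solutions;
the assessments themselves are accepted from a results file since the
dual-space search programs are not reimplemented.

## Wedge planning

The first wedge is images 1–20 (or all, if fewer). The second, 10-image
wedge starts at the image whose start angle is `start + sep`, with sep
walked down from 90° in 5° steps until the wedge exists and does not
overlap wedge 1; placement is by the wedge's *start* angle ("away from
the starting angle"), not its center, and the fallback terminates once
sep drops below one oscillation step. Overlap with wedge 1 is forbidden —
duplicated spot lists add nothing to indexing.

## The synthetic world

The generator emulates exactly the statistical structure the decision
rules assume: acentric Wilson intensities with mean
`scale·exp(−2B·s²)`, per-observation Gaussian noise with
σ = √(max(I,0) + floor²) approximating counting statistics, observations
carried on random symmetry mates (so canonicalization is genuinely
exercised), cyclic image assignment, optional non-Wilson outliers at a
chosen multiple of the Wilson mean, and optional Friedel amplitude
differences F± = F·(1 ± δ/2). Sub-datasets share one set of true
intensities — one structure — and differ only in coverage, noise stream,
scale and indexing convention; `k = 1` reproduces the single-dataset
generator bit-exactly. Defaults (B = 20 Å², multiplicity 4, noise floor 5)
are ordinary well-diffracting-crystal values; tests that state a
condition (50k reflections, SNR ≥ 5, 5× noise differences) size their
configs to meet it and assert that they did.

What the generator does **not** emulate: partiality and mosaicity,
radiation damage, absorption, ice rings, detector gaps (so completeness
reaches 100% by construction), per-image scale drift, and centric
statistics. A green test therefore establishes that the decision logic is
correct *for data obeying its stated model*, not that the thresholds are
optimal on real beamline data — the production constants are taken as
given, not re-derived.

## Determinism and numerics

A single seed drives named sub-streams (one per generator stage), so
adding a stage never perturbs another's draws and identical inputs yield
byte-identical reports; execution is strictly serial. Canonicalization
compares orbit members through an exact integer lexicographic key;
statistics are plain double sums over data.table groups (no compensated
summation — the 1e-12 oracle-equivalence tolerance reflects this).
Full-mode candidate ranking treats R-meas values within 10% relative of
the minimum as statistical ties broken toward higher symmetry, because on
data truly possessing the higher symmetry the subgroup's R-meas differs
only by sampling noise and a strict float sort would choose arbitrarily.

## Known limitations

Point-group-only symmetry (no absences, no non-standard settings);
acentric-only intensity statistics; one rejection cycle; scalar
inter-dataset scaling; amplitude-based d″ with a heuristic σ guard; no
CC½/CC* criterion (left to future work upstream as well); the XML schema
is this package's own, the production database schema being unpublished.
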