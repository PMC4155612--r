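---
title: "Profiling residue-level biophysical deviation from a protein family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling residue-level biophysical deviation from a protein family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famdev)
```

## The problem and the model

A protein family mostly tolerates substitutions: homologues with quite
different sequences perform the same function. Occasionally a handful of
substitutions breaks function. Frequency-based diagnostics ask only "is this
residue common at this position?"; famdev instead asks "how *biophysically
unusual* is this residue here?", using amino-acid index scales — numeric
scores assigning each of the 20 standard residues a value for a property
such as hydrophobicity or helix propensity.

Given a multiple sequence alignment containing a reference protein and its
family, and an index scale $p$, the deviation score (c-score) of the
reference at aligned position $r$ is

$$ c_{p,r} \;=\; \frac{i^{\mathrm{ref}}_{p,r} - \overline{i^{\mathrm{fam}}_{p,r}}}{\sigma\!\left(i^{\mathrm{fam}}_{p,r}\right)} , $$

where $i^{\mathrm{ref}}_{p,r}$ is the reference residue's index value and
the mean and standard deviation are taken over the family residues in
column $r$ (gaps, `X` and missing index entries excluded). Dividing by the
family spread weights deviations by conservation: the same absolute
difference counts for more in a column the family keeps nearly fixed. Large
$|c|$ in conserved columns flags candidate function-breaking residues.

Assumptions worth keeping in mind: columns are treated independently; the
family is taken as given (no phylogenetic down-weighting of redundant
sequences); and no multiple-testing correction is applied — the scores are
a ranking and triage device, not calibrated p-values.

## Conventions and tunable parameters

* **Positions are 1-based** reference positions after cropping: only
  alignment columns where the reference is non-gap are retained
  (`crop_to_reference()`), so position $r$ is the reference's $r$-th
  residue. Cropping is idempotent and `colmap` records the original
  (0-based) column of each position.
* **Reference exclusion.** The family statistics exclude the reference by
  default (`include_reference = FALSE`); including it shrinks every
  deviation toward zero. A switch restores inclusion for users who want
  the reference treated as a family member.
* **Population standard deviation** (divisor $n$) is used both across the
  20 residues when standardizing a scale and down alignment columns: the
  residue types of a scale and the observed family column are treated as
  complete populations, not samples.
* **σ floor** (`sigma_floor_frac`, default 0.01). A perfectly conserved
  column has $\sigma = 0$ and the ratio diverges. The divisor is floored
  at $f \cdot \mathrm{median}(\sigma > 0)$ over the sequence, so a
  deviation in a fully conserved column still ranks (very) high without
  producing infinities; floored cells are flagged
  (`sigma_floored`) and survive into the exported bundle. In the
  degenerate case where *no* column has positive σ the floor falls back
  to $f \cdot 1$ — on standardized scales 1 is the natural σ unit — which
  keeps the fully conserved family well-defined (all c-scores are then 0
  wherever the reference matches the family).
* **Histogram cap** at ±3 score units with 40 equal bins: outliers beyond
  the cap are counted in the edge bins and tallied separately
  (`n_clamped_low/high`), so axes stay stable and nothing is dropped.
  Stacked-bar magnitudes clamp at the same cap, with raw values preserved
  alongside.
* **Chord threshold** 0–8 Å by default — a conventional Cα–Cα contact
  range — and fully adjustable; the proximity histogram (2 Å bins) shows
  the distance distribution so users can brush their own range.

## Six characteristic classes and their representatives

Index databases contain hundreds of scales, grouped here into six
characteristic classes: alpha/turn propensity, beta propensity,
hydrophobicity, composition, physicochemical, and a catch-all *other*.
Rather than forcing a choice of index, `pc1_scale()` collapses each class
to a representative: the scales of a class, standardized to mean 0 / sd 1
over the 20 residues, are points in a 20-dimensional residue space, and
the first principal axis of their second-moment matrix is the
representative scale (unit-norm loadings, one value per amino acid).

Two design choices deserve explanation:

* **Uncentered PCA.** Because each standardized scale already has zero
  mean across residues, the second-moment matrix is used without further
  centering across scales. This makes the degenerate cases behave
  sensibly: a class of identical scales is exactly rank one (variance
  explained 1, loadings proportional to the scale), which column-centering
  would instead map to the zero matrix. Eigenvalues below
  $10^{-12}\lambda_1$ are treated as numerical zeros.
* **Sign convention.** A principal axis is defined up to sign; it is
  oriented to correlate positively with the elementwise mean of the input
  scales (tie broken by making the largest-magnitude loading positive), so
  "high" on the representative means high on the class consensus.

The alternative reading — PCA over per-residue profiles along a specific
family's sequences — would weight residues by their composition in that
family; the residue-space reading was chosen because it yields one value
per amino acid independent of any particular family, which is exactly what
the c-score formula consumes.

Class membership ships two ways: a small curated table of well-known
accessions (`default_class_map()`) and a description-keyword classifier
(`build_class_map()`) for arbitrary AAindex snapshots. Both are
best-effort reconstructions — the historical clustering of the full
database is not redistributable — and both are user-overridable; unknown
accessions fall to *other* rather than erroring. Keyword grouping is
coarser than a correlation-based clustering, so the variance explained by
class representatives on a full real snapshot is systematically lower than
within purpose-built classes (the heterogeneous *other* class especially).

## Conservation heat map

The conservation row reported per characteristic is the per-position
family σ of the index values — the denominator the c-score already
computes — min-max normalized per row to [0, 1] (0 = conserved/bright,
1 = most variable/dark; a constant row renders fully conserved). Variation
*of the family itself* is the quantity of interest here: the deviation of
the reference is already carried by the c-score, and reporting its
denominator separately lets users judge conservation independently of
effect size.

## Structure linkage

`parse_pdb_calpha()` reads Cα atoms from ATOM records (first model,
HETATM ignored, altloc resolved to highest occupancy). `map_structure()`
aligns the structure's residue letters to the reference by sliding it
ungapped along the sequence and choosing the offset with the most
identities, accepted at ≥95% identity over the overlap; offsets whose
overlap is shorter than half the shorter sequence are not considered, as
a dangling one- or two-residue overlap can be 100% identical by chance.
An explicit offset bypasses the check. Distances are Euclidean Cα–Cα in
Å; positions without a mapped Cα carry missing distances.

A focus region (≤15 residues, keeping per-residue detail readable) defines
per-residue focus distances: the *minimum* distance to any focus residue
(region-minimum rather than region-mean — the sphere-of-influence question
is "does anything in the region touch this residue"). Qualifying residues
inside the threshold range are bundled into chords: maximal runs of
consecutive positions become single arches carrying the run's minimum
distance and a darkness rank. Sequence neighbours of the focus are kept by
default (they are genuinely proximate); `min_seq_separation` filters them
for contact-map-style analyses. The proximity histogram uses half-open
bins $[kw, (k+1)w)$ from 0; the top edge is the smallest multiple of $w$
strictly above the maximum, so a maximum lying exactly on a bin boundary
is still counted.

## Synthetic data: what it emulates, and what it does not

The generators make the whole pipeline testable without downloads:

* `synth_scales()` draws scales around a latent class prototype with
  within-class correlation 0.7, so class representatives dominate
  (variance explained ≈ 0.7 + 0.3/k) the way coherent real index classes
  do.
* `synth_family()` draws a uniform consensus; each family sequence
  substitutes each position independently with a per-position probability
  (default: uniform on [0.05, 0.5], spanning near-conserved to typically
  variable columns). The reference equals the consensus except in the
  anomaly interval, where each residue is greedily chosen to maximize its
  summed absolute standardized-index deviation from the family column
  mean over one designated scale per class — implanting a
  multi-characteristic anomaly of the kind the method is meant to find.
  Family-insertion columns (reference gapped, rate 2%) exercise cropping
  without disturbing reference numbering. The default conditions are
  L = 248, N = 200, a 7-residue anomaly at 150–156.
* `synth_pdb()` writes a Cα-only self-avoiding random walk (3.8 Å steps,
  ≥3.0 Å pairwise separation) as valid PDB text.

What passing tests on these fixtures show: the scoring machinery
localizes a genuine multi-characteristic anomaly, end to end, under
realistic column variability. What they do not show: robustness to
phylogenetic structure (sequences are exchangeable here, real families
are tree-correlated), to alignment error, to biased amino-acid
composition, or to real protein geometry (a random walk has no secondary
structure); and the implanted anomaly is by construction aligned with the
index classes used to score it. Findings on real data still require the
usual scrutiny.

## Problem sizes and numerical tolerances

The shipped tests run the full default conditions (248 × 200 family, six
classes of five scales) in a few seconds; property checks use smaller
alignments (tens of columns, 5–15 records) and 30–50-residue traces,
which are large enough to exercise every code path while keeping the
suite fast. Equality oracles are checked to 1e-12 (scoring arithmetic),
1e-9 (PCA vs explicit eigendecomposition, affine invariance), and 1e-6 Å
(geometry); exported JSON carries six significant digits.

## Known limitations

* Family insertions relative to the reference are cropped, not analysed.
* One structure stands in for the family; no per-member structural
  variation.
* The class maps are reconstructions; users with a trusted assignment
  should supply their own TSV.
* No correction for family redundancy or multiple testing; c-scores are
  exploratory rankings.
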