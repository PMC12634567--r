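---
title: "Shape fingerprints for TCR specificity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape fingerprints for TCR specificity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrfp)
```

## The model

An αβ T-cell receptor contacts its peptide–MHC ligand almost exclusively
through six hypervariable loops, the CDRs (three per chain). `tcrfp`
represents the geometry and surface chemistry of those loops with an
ElectroShape-style descriptor in five dimensions. Every CDR atom `a` is
embedded as

\[ (x_a, y_a, z_a,\; C\,q_a,\; P\,\ell_a) \]

where `q_a` is its partial charge (e), `ℓ_a` its Wildman–Crippen atomic
logP contribution, and `C`, `P` are scale factors that decide how strongly
electrostatics and lipophilicity influence the shape description relative
to geometry (Å). Six reference points (*centroids*) are placed in the same
5D space, and for each centroid the distribution of atom–centroid Euclidean
distances over **all** CDR atoms, pooled across the six loops, is summarised
by three moments: the mean, the population standard deviation and a
third-moment statistic. Concatenated in the fixed loop order CDR1α, CDR2α,
CDR3α, CDR1β, CDR2β, CDR3β this yields a vector of 18 numbers — the
fingerprint. A per-loop-restricted variant (each centroid seeing only its
own loop's atoms) was considered and rejected: pooling lets every centroid
see the whole binding site, so relative loop placement is encoded too.

Two fingerprints are compared with a Manhattan-based similarity
\( S = (1 + \frac1n\sum_i |x_i^A - x_i^B|)^{-1} \), `n = 18`, which is 1
exactly for identical vectors and decreases monotonically with the mean
absolute difference. `S` carries no calibration: 0.8 means "mean coordinate
difference of 0.25 Å-equivalents", not a probability; the logistic
combiner (below) is the calibrated layer.

### Centroid placement

Two modes are implemented:

* **Tip-of-loop (TOL, default).** Each centroid sits on the Cα of its
  loop's middle residue — for even-length loops the *lower* of the two
  middle positions — and inherits that Cα's weighted charge and
  lipophilicity. Because the centroids move with the structure, TOL
  fingerprints are invariant under rigid motions of the input and no
  superposition is needed.
* **Universal.** All TCRs are first superposed into a canonical frame, and
  a single set of six 5D centroids (plus `C` and `P`) — typically the
  output of the genetic algorithm — describes every TCR. The 32 numbers
  (6 × 5 + 2) form the GA genome.

The canonical frame centers all atoms (unit masses) at the origin and
aligns the principal axes of the coordinate covariance with x, y, z in
order of decreasing eigenvalue. Eigenvectors are sign-ambiguous, so a
deterministic convention is applied: the first two axes are flipped so that
the Cα of the lowest-numbered α-chain CDR1 residue gets non-negative first
and second coordinates, and the third axis sign keeps the rotation proper.
Any fixed convention works; this one only needs an atom that every
annotated TCR has. Near-collinear atom sets (second eigenvalue ≲ 1e-10 of
the first) are rejected as degenerate.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `C` | 25 | Å per e | weight of the charge dimension |
| `P` | 4 | Å per logP unit | weight of the lipophilicity dimension |
| CDR ranges | 27–38, 56–65, 105–117 | IMGT numbers | loop annotation when no table is given |
| QC band | mean ± 4·SD | Å | accepted conserved-residue distances |
| gap penalties | −3 open, −1 extend | score | BLOSUM62 CDR alignment |
| LR preset | −4.4545, 7.3739 (seq), 0.5752 (fp) | — | published combiner coefficients |
| classifier threshold | 0.5 | probability | same-specificity call |

`C = 25` and `P = 4` are the established defaults for this descriptor
family; both are recorded in every fingerprint's metadata along with the
property-table tag, hydrogen policy, centroid mode and third-moment
convention, and `fp_similarity()` refuses to compare fingerprints whose
metadata differ — an apples-to-oranges guard, not a convenience.

### Atomic properties

The bundled property table maps (residue, atom name) to a partial charge
and a Wildman–Crippen logP contribution for all atoms — backbone, side
chain and hydrogens — of the 20 standard amino acids. It was computed once
on Gly-X-Gly tripeptide templates (so every residue is in a peptide-bonded
context), with Asp/Glu deprotonated and Lys/Arg protonated, and each
residue's charges renormalized to sum exactly to its formal charge. The
table is data, not code: `read_property_table()` accepts any file with the
same columns, and the provenance tag travels with every fingerprint.
Structures lacking hydrogens are processed heavy-atom-only and flagged;
heavy-only and all-atom fingerprints never compare.

## Quality control of structural models

Homology-modelled TCRs occasionally come out with a misplaced chain
segment. Four framework residues that IMGT numbering pins to fixed
positions — CYS23, LEU89, CYS104, TRP118 — serve as an internal ruler:
Cα–Cα distances among them are measured per chain and must fall inside
mean ± 4·SD bands calibrated on reference structures. The methods-level
description of the published filter set is internally inconsistent about
*which* pairs were used ("9 combinations" vs five per chain), so the
definition list is shipped as configurable data and defaults to all six
unordered pairs of the four residues on each chain (12 distances); users
with the exact published list can supply it. Bounds are closed — ±4·SD is
a tolerance band and edge cases pass. A model on which any distance cannot
be measured is rejected as "unmeasurable" rather than silently skipped.

## Sequence comparator and combiner

The sequence route aligns each of the six CDR strings separately
(Needleman–Wunsch with end gaps penalized — CDRs are short and local
alignment would inflate similarity), sums the six raw BLOSUM62 scores and
normalizes by the geometric mean of the two self-scores, clamped at zero:
`max(0, S_AB)/√(S_AA·S_BB)`. The normalization itself is not specified by
the published description beyond its endpoints (0 for unrelated, 1 for
identical); the geometric-mean form guarantees both and is swappable. The
affine gap convention is "first gap residue costs 3, each further residue
1"; per-loop alignment (rather than one concatenated alignment) prevents
gaps from leaking across loop boundaries.

The logistic regression `p = σ(b0 + W_fp·S_fp + W_seq·S_seq)` combines the
two similarities. In the published coefficient pair (7.3739, 0.5752) the
mapping of weights to features is ambiguous in the source description; the
preset binds the *larger* weight to the sequence score, consistent with the
reported observation that the sequence term dominates, and the model file
records `feature_order` explicitly so the opposite binding is loadable.
Fitting uses `stats::glm` (binomial); perfectly separable inputs fall back
to a weakly L2-penalized fit (λ = 1e-4) with a warning, so coefficients
stay finite.

## Evaluation statistics

*Peptide identity* at rank k and threshold t: a TCR is **clustered** if it
has ≥ 1 neighbor with similarity strictly above t; it is correctly paired
if any of its k most-similar clustered neighbors binds the same peptide.
Accuracy is correct/clustered and coverage clustered/total, which
reproduces the trade-off semantics of threshold-based repertoire analyses
(raising t raises accuracy, shrinks coverage). Neighbor ties are broken by
lexicographic TCR id — the source is silent on ties and determinism
matters more than any particular choice. *Sequence recapitulation*
averages the residue identity between each TCR's peptide and its rank-1
neighbor's peptide (positional for equal lengths, otherwise an unpenalized
global alignment with identities counted against the longer peptide).

AUCs are computed as the rank (Mann–Whitney) statistic with ties averaged,
either over all unordered pairs or over each TCR's rank-1 pair only; the
5-fold 70/30 cross-validation draws independent random splits, evaluates
the held-out 30 % and redraws (with a message) when a split is
single-class. Statistical significance against chance is assessed by label
permutation (default 10⁴ resamples) rather than a named parametric test.
UPGMA clustering converts similarities to distances `1 − S` and delegates
to average-linkage `hclust`, exported as a `phylo`/newick tree.

## The genetic algorithm

The GA searches the 32-dimensional genome of universal centroids plus
weights. Defaults mirror the published search: 400 random initial
individuals, the best 200 selected as parents, 200 children per generation
built by exchanging 1–6 centroids between two parents (whole centroids by
default; a partial mode swaps a random subset of a centroid's 5
coordinates), optional independent exchange of `C` and `P`, one of the two
complementary children kept at random, then 2–4 genome entries incremented
by U(−1, 1). Parents and children are merged, ranked and truncated to 200 —
elitist, so the best-so-far fitness trace is non-decreasing — and the run
stops after 20 generations without improvement (hard cap 500). Random
initialization samples positions in a 30 Å box about the superposed-
structure center; weight initialization draws `C` from (0.5, 50) and `P`
from (0.5, 8), a decade around their defaults, since the source specifies
the spatial box only. Mutation applies to all entries uniformly, with
`C`, `P` reflected at zero to stay positive.

Two objectives are provided. MATCH is the mean rank-1, no-threshold
peptide identity over the training sets. For MaxD the source description
oscillates between the "highest" and the "average" inter-specificity
distance; the implementation adopts the **mean** Manhattan fingerprint
distance over all differently-labeled pairs (the max of a single pair is a
degenerate objective that one outlier saturates), and the wording conflict
is documented here rather than hidden.

## The synthetic-data generator

`fixture_spec()`/`make_repertoire()` build idealized two-chain structures:
a hand-constructed framework template (not derived from any deposited
structure) carrying the four conserved residues at fixed positions on both
chains, six CDR loops laid out as arcs with configurable lengths, and
per-family loop placements displaced by `family_spread` along random
family-specific directions with family-specific sequences. Members of a
family differ only by Gaussian coordinate jitter. Defaults — 2 families ×
5 TCRs, jitter 0.3 Å, spread 6 Å, loop lengths 6/6/13 per chain — are
chosen so that within-family structural variation is small against
between-family variation, the regime in which specificity families are
well defined; 9-mer peptides label the families. Everything is
bit-reproducible from the spec seed, and each member can be regenerated
standalone.

What the generator does **not** emulate: real loop conformational
ensembles, correlated backbone/side-chain geometry, hydrogens, crystal
contacts, or the sequence–structure coupling of real CDRs (sequences and
coordinates are drawn independently). Tests passing on these fixtures
therefore demonstrate the *correctness of the computations* — moments,
similarity algebra, filter arithmetic, ranking and ROC bookkeeping — and
the qualitative family-separation behaviour, not the biological accuracy
of specificity prediction on real repertoires, which depends on modelling
quality and data that are outside this package's scope.

## Numerical choices

* **Third moment.** Implemented as the signed cube root of the third
  central moment, so all 18 entries carry distance units and no single
  block dominates the Manhattan sum; the raw central moment is available
  (`third_moment = "raw"`) and the choice is recorded in the metadata.
* **Population SD** (divisor n), the moment-descriptor convention;
  deterministic even for two atoms.
* **Degenerate inputs.** Fingerprinting needs ≥ 2 CDR atoms; superposition
  needs ≥ 3 non-collinear atoms; empty loops after annotation resolution
  are fatal with the loop named; residues missing *inside* a range are
  skipped silently (partial models are the norm, and a hole in a loop
  should not kill a repertoire run).
* **Insertion codes** order after their parent number, lexicographically.
* **Alternate locations** resolve to the highest-occupancy conformer.
* **CDR anchor residues:** whatever the annotation covers is encoded; the
  default ranges include the loop-flanking positions, and users who prefer
  anchor-free loops simply narrow the ranges.
* Problem sizes in the shipped tests are deliberately small — repertoires
  of 6–20 synthetic TCRs, 5000 simulated pairs for coefficient recovery,
  10⁴ label permutations, full-size (400/200/200) GA runs only on a cheap
  analytic objective — which keeps the whole suite tractable while still
  exercising every code path at its production configuration.

## Known limitations

* Fingerprints require a consistent property table; mixing tables,
  hydrogen policies or centroid modes is refused rather than silently
  averaged, which means heterogeneous inputs need a harmonization pass
  first.
* The QC filters assume IMGT numbering; structures numbered otherwise must
  be renumbered upstream (annotation is an input by design).
* The similarity scale is not transferable across weight settings: scores
  computed at `C = 25` are not comparable to scores at `C = 35`.
* mmCIF input, antibody-style numbering conversion and homology modelling
  itself are out of scope.
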