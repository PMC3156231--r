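---
title: "Two-level nuclear receptor prediction: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level nuclear receptor prediction: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpred)
```

## The problem and the method

Nuclear receptors (NRs) are ligand-activated transcription factors whose
superfamily splits into subfamilies (NR0–NR6) by conserved-domain phylogeny;
a receptor's subfamily strongly constrains its function, so assigning new
sequences matters for annotation and drug-target triage. `nrpred` treats
this as a two-level classification problem over fixed-length sequence
encodings: level 1 separates NRs from arbitrary other proteins, level 2
assigns the subfamily. The cascade matters because an unfiltered subfamily
classifier silently produces a subfamily call for any input, including
proteins that are not receptors at all.

### The 881-D encoding

Each validated sequence is encoded once, deterministically, as a weighted
pseudo amino acid composition with five blocks (layout
`pseaac_layout()`):

| block | size | content |
|-------|------|---------|
| AAC | 20 | residue frequencies, sum 1 |
| DC0 | 400 | adjacent ordered-pair frequencies, sum 1 |
| DC1 | 400 | one-gap ordered-pair frequencies, sum 1 |
| CF  | 1  | Lempel–Ziv complexity (integer component count) |
| FSC | 60 | 10 DFT amplitudes + 10 phases per property scale × 3 scales |

Assumptions worth stating: the encoding is permutation-sensitive only
through DC, CF and FSC (AAC is composition alone); all blocks are defined
over the 20 canonical residues, so non-canonical characters must be removed
before featurization; and FSC requires L ≥ 21 so that the 10 retained
frequencies lie strictly below the conjugate-symmetry fold-over of an
L-point transform — this is why the global minimum validated length is 21.

### The classifier

The fuzzy K-nearest-neighbor rule computes graded memberships from the K
nearest Euclidean neighbors, weighting each by `d^(-2/(m-1))`, and takes the
argmax. Both parameters are data-driven per level via the jackknife grid
search; the surface is typically flat near its optimum, so the tie rule
(smallest K, then smallest m) keeps the choice reproducible.

## Tunable parameters

* `w_dc = 20` (dimensionless): weight on the 800 dipeptide components. The
  dipeptide blocks are the strongest sequence-order signal and the
  up-weighting makes them comparable to the rest of the vector despite each
  component being a small frequency.
* `w_cf = 1`, `w_fsc = 1` (dimensionless): weights on the complexity and
  Fourier blocks. These are deliberately plain defaults, exposed in the
  configuration (`weights.cf`, `weights.fsc`) rather than fixed, because no
  principled universal value exists: CF is an integer that grows with
  sequence length and the FSC amplitudes scale like √L, so their natural
  magnitude depends on the sequence-length regime of the data.
* `K` (count, ≥ 1) and `m` (> 1, dimensionless): FKNN neighbors and fuzzy
  coefficient. As m → 1⁺ the rule collapses to the crisp nearest neighbor;
  as m → ∞ it approaches the unweighted K-vote. Default search grid
  K = 1..15, m = 1.1, 1.2, …, 3.0 — wide enough to include both regimes,
  small enough that the full surface is computed in seconds at reference
  sizes of a few hundred.
* `min_length = 21` residues: hard floor required by the Fourier block (see
  above), applied at validation.

## Numerical choices

* **DFT origin.** The spectrum keeps k = 1..10. The k = 0 term is excluded:
  for a real signal its phase is identically zero and its amplitude is L
  times the mean property value — composition information AAC already
  carries.
* **Phases at vanishing amplitude.** `arg(X(k))` is numerically meaningless
  when |X(k)| < 1e-12 (e.g. homopolymers, whose standardized property signal
  is constant), so the phase is reported as 0 there.
* **Scale standardization.** Each property scale is standardized to zero
  mean and unit standard deviation over the 20 residues with the population
  divisor (20), the PseAAC convention; otherwise hydrophobicity (unitless,
  ±2), hydrophilicity (unitless, ±3) and side-chain mass (Da, 1–130) would
  contribute on wildly different scales.
* **Dipeptide denominator.** DC(g) divides by L − 1 − g, the exact number of
  g-gapped pairs, so each 400-vector is a probability vector; "normalized
  occurrence frequency" is otherwise ambiguous at short lengths.
* **Fusion form.** Fusion is weighted concatenation, not a sum-normalized
  composition: phase components are signed, so a denominator of summed
  components would be ill-defined and could even vanish.
* **CF normalization.** The complexity factor enters raw (not divided by
  length); it is a single counted quantity and any length correction would
  be an extra modeling assumption.
* **Zero-distance neighbors.** If a query coincides with reference points
  (distance < 1e-12) the inverse-distance weight diverges; memberships are
  then a uniform vote over the coincident neighbors only, which is the exact
  limit of the rule as the distance goes to zero.
* **Numerical range of the membership weights.** For m near 1 the exponent
  −2/(m−1) is large; distances are divided by the row minimum before
  powering (relative weights are invariant under that rescaling), so the
  nearest neighbor always has weight 1 and farther ones underflow harmlessly
  to 0.
* **Ties.** Neighbor ties at the K boundary break by reference insertion
  order; membership ties break toward the nearest neighbor's class, then by
  class order. Both rules exist purely for determinism.
* **Degenerate MCC.** When a marginal of the confusion table is empty the
  MCC denominator is 0; the value is reported as 0 with a `degenerate` flag,
  and a class with no test members at all is reported as NA rather than 0.
* **Ambiguous residues.** Characters outside the 20-letter alphabet are
  removed (with a logged count), not remapped: every descriptor formula is
  defined only over the native types, and removal keeps the composition
  denominators exact. This is a policy of this package, not a property of
  the method.

## The synthetic family generator

`generate_fixture()` emulates the structure of a curated benchmark: each
receptor family shares a private conserved core (a planted random motif, by
default 85 of 90–110 residues, mimicking the conserved DBD+LBD of real
receptors with variable flanks and variable motif position), and the
negative class is a pool of unrelated background *families* — mutated
copies of random ancestral sequences carrying no receptor motif — because
real negative sets are drawn from protein families, not from uniform-random
sequence space. A uniform i.i.d. background would make every background
query equidistant from everything, an artifact no real screen shows. The
default sizes (7 families × 20, 420 background) mirror the class imbalance
of a realistic benchmark (roughly 1 receptor : 3 background), and per-residue
substitution noise (`mutation_rate`, default 0.01) is the single dial for
within-family divergence.

What the generator does **not** emulate: realistic amino-acid usage
(backgrounds are uniform over the alphabet), insertions/deletions and length
divergence within a family, shared homology *between* receptor families
(real NR subfamilies are related to each other), or database redundancy
structure. Passing tests on the fixture therefore demonstrate that the
pipeline recovers planted family structure under substitution noise and
class imbalance — not that it attains any particular accuracy on curated
receptor data; the acceptance tests that score the published benchmark
learning set run only when that dataset's FASTA is supplied.

Problem sizes used by the test-suite and the acceptance script: 560
sequences of 90–110 residues for cascade-level checks, a 4-family
40-sequence set for classifier unit tests, 1,000 random sequences of length
1–200 for the complexity-oracle sweep, and 3 seeds × 5 noise levels for the
monotone-degradation property.

## Evaluation design

The jackknife (leave-one-out) test is the primary quality measure: it is
deterministic for a given reference set, unlike subsampling. Level-1
evaluation runs over the combined set, level-2 over the receptors only, and
the two-level jackknife routes every held-out protein through both levels
(a background protein mistakenly called NR *is* forwarded to level 2 and
scored as wrong). Per-class MCC at the subfamily level is computed
one-vs-rest, the natural reduction when classes are reported separately. No
class-imbalance correction is applied at level 1; the imbalance is part of
the problem being emulated. The descriptor-ablation study re-optimizes
(K, m) per feature mode — comparing modes at a parameter setting tuned for
one of them would bias the comparison.

## Known limitations

* Euclidean FKNN scans all references per query; fine for reference sets of
  ~1,000, not designed for proteome-scale references.
* The CF and FSC default weights are honest but unoptimized; on data with
  very heterogeneous sequence lengths these blocks can dominate distances,
  and tuning `weights.cf` / `weights.fsc` (or working at the ablation modes)
  is advisable.
* Subfamily calls are only as good as the labeled reference; subfamilies
  absent from training cannot be predicted.
* Sequences shorter than 21 residues cannot be featurized at all.
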