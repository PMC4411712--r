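---
title: "Statistical information similarity for transcription-factor prediction"
author: "sisTF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical information similarity for transcription-factor prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sisTF)
```

## The model

`sisTF` classifies proteins into four functional categories — transcription
factors (TFS), transmembrane proteins (MEM), enzymes (ENZ), and all other
proteins (OTS) — from binary annotation profiles, and reports a
TF-versus-rest call as the headline result. The representation is
deliberately simple: a protein is the set of its Pfam domain families and
transferred GO terms, encoded as a 0/1 vector over the sorted universe of
feature identifiers (ascending byte order, so coordinates are
locale-independent).

The signal lives in how features distribute across categories. With
$C_{ij}$ the number of category-$j$ training genes carrying feature $i$,
$N_j$ the size of category $j$, and $C_i = \sum_j C_{ij}$:

$$P_{ij} = \frac{C_{ij}}{N_j}\cdot\frac{C_{ij}}{C_i}
         = \frac{C_{ij}^2}{N_j\,C_i},\qquad
  IC_{ij} = -\log_2 P_{ij},\qquad
  w_{ij} = \begin{cases}1/IC_{ij} & P_{ij}>0\\ 0 & P_{ij}=0\end{cases}$$

$P_{ij}$ balances the within-category rate ($C_{ij}/N_j$) against the
category share ($C_{ij}/C_i$): a feature common inside one category *and*
concentrated there gets $P$ near 1, low information content, and a large
weight in that category. A gene carrying several category labels contributes
to every category it belongs to, both in $C_{ij}$ and $N_j$; consequently
$C_i$ is the sum of the per-category counts rather than a plain gene count.

Feature selection ranks each feature by the gap between its best category
and the rest. Sorting the four weights descending into
$w_{(1)}\ge\dots\ge w_{(4)}$,

$$MWD_i = w_{(1)} - \tfrac{1}{3}\left(w_{(2)}+w_{(3)}+w_{(4)}\right),$$

and features with $w_{(1)} < w_{(2)}+w_{(3)}+w_{(4)}$ — features without a
clearly dominant category — are pruned outright. Classification is nearest
neighbour on a weighted cosine score: for query $a$ and training gene $b$
belonging to category $j$,

$$\mathrm{SCORE}(a,b,j) = \frac{a\cdot b}{\lVert a\rVert\,\lVert b\rVert}
  \sum_{k\,\in\,a\cap b} w_{kj},$$

the sum running over features present in *both* genes (not over the whole
space — a query is never rewarded for features it lacks). The query takes
the category of the maximising $(b, j)$ pair. A leave-one-out
cross-validation sweep over top-$k$ cutoffs of the MWD ranking selects the
working feature count by TF-versus-rest accuracy.

### Assumptions

The method assumes (i) the training labels are trustworthy at the category
level, (ii) category identity is expressed through the *presence* of
annotation features rather than their absence or order, and (iii) the
feature universe is shared between training and query genes. It makes no
distributional assumptions; everything reduces to counting.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| Pfam E-value | 1e-3 | full-sequence E-value cutoff for domain features (inclusive) |
| GO E-value / top hits / majority | 1e-10 / 10 / 0.5 | a GO term transfers when it occurs in at least half of the top BLAST hits that pass the E-value cut |
| feature occupancy floor | 20 genes | features seen in fewer genes are dropped, then featureless genes are dropped |
| homology propagation | identity ≥ 25%, E ≤ 1e-20, ≥ 2 hits, majority 0.5 | label transfer for genes the metadata rules leave unlabeled |
| weight cap `wMax` | 1e6 | weight assigned where $IC = 0$ ($P = 1$) |
| k grid | powers of two up to the pruned ranking length | LOOCV sweep cost is $O(M^2 N)$ per k, so the grid is logarithmic |
| maternal fold | 4 (linear scale) | egg-versus-somatic threshold, inclusive |

All thresholds read as "no less than"/"threshold of x" are implemented
inclusively (`<=` for E-values, `>=` for counts and fractions).

## Numerical choices

* **$P = 1$ features.** A feature exclusive to one category and universal
  within it has $IC = 0$ and an undefined reciprocal. Its weight is set to
  the cap `wMax` (default $10^6$), preserving "more informative ⇒ larger
  weight" without infinities. (Implementation note: $-\log_2 1$ is IEEE
  negative zero, whose reciprocal is $-\infty$; the code computes
  $0 - \log_2 P$ so the cap is reached.)
* **Exact cosine.** For binary vectors the similarity is computed as
  $a\cdot b / \sqrt{|a|\,|b|}$ with a single square root of the integer
  product, so identical supports score exactly 1 and hand-computable values
  (e.g. 0.5) are reproduced bit-exactly.
* **Deterministic accumulation.** Shared-weight sums accumulate over
  ascending feature index; score ties are broken by the fixed category
  order TFS > ENZ > MEM > OTS, then by neighbour id ascending; ranking ties
  by feature id ascending; equal-accuracy k by the smaller k. Reruns are
  byte-identical.
* **Degenerate queries.** A query with none of the selected features, or
  sharing no positively weighted feature with any training gene, is
  *unclassifiable*: it is reported as such and counted as a non-TF
  prediction in the evaluation. Training genes that lose all features under
  a small k are likewise excluded as neighbours.
* **Weights are estimated once** on the full feature set and restricted
  during the k sweep. Because weights are per-feature counts, restriction
  changes nothing unless genes drop out of the restricted space entirely;
  `reweightPerK = TRUE` re-estimates within each top-k space for users who
  want the stricter protocol. The default favours speed and makes the sweep
  a pure ranking question.

## Design decisions that were genuinely open

* **Cofactor veto.** Transcription cofactors ("cofactor", "coregulator",
  "coactivator", "corepressor") are forced to OTS even when the phrase
  "transcription factor" also matches; the veto outranks the keyword. The
  alternative (keyword wins) would plant cofactors among TFS exemplars and
  dilute the very signal the classifier learns.
* **TF-activity phrase list.** The canonical description list for
  "transcription factor activity" terms is shipped as an editable text file
  (`inst/extdata/tf_activity_phrases.txt`) with documented defaults, since
  no single authoritative list exists at the annotation level this package
  consumes.
* **Enzyme detection from free text** uses an EC-number pattern or an
  "-ase" word suffix. The suffix rule has known false positives in natural
  prose ("database", "decrease"); it is configurable, and the EC flag
  column takes precedence in curated inputs.
* **Homology majority denominator.** The "half of the top ten hits" rule is
  evaluated against the hits that *pass* the identity/E-value filters, not
  against a fixed 10, mirroring the GO-transfer rule which divides by the
  kept hits.
* **Maternal comparison per sample.** The egg statistic (mean over egg
  replicates by default, `min` available) must exceed fold × *each* somatic
  sample individually — the strictest reading — rather than a somatic mean,
  which would let one silent tissue mask expression elsewhere.

## What the synthetic generators emulate

`simulateGeneSet()` plants, per category, a block of signature features that
appear in their own category's genes with high probability (0.9 by default)
and leak into other categories with low probability (0.05), plus
category-agnostic noise features (presence 0.3). That reproduces the
*structure* the weighting scheme keys on — category-concentrated features —
with a dial (`leak_prob`) that degrades separability continuously. One RNG
substream per category, consumed in a documented order, makes every draw
independently replayable.

`simulateMetadata()` writes descriptions that trigger exactly one labeling
rule per gene, leaves a seeded fraction labelable only through BLAST
homology, and gives some OTS genes descriptions that fire the TF keyword
*and* the cofactor veto.

`simulateExpression()` draws log2-normal expression, exponentiates, and
plants maternal genes whose egg replicates sit at least `mf_fold` above the
maximum somatic value by construction; the first planted gene sits exactly
on the fold boundary, samples from excluded classes (early embryos, gonads,
ES cells) are given expression that *would* violate the rule if counted,
and non-planted genes have one somatic sample pinned to the egg level.

What these generators do **not** emulate: realistic protein sequences or
domain co-occurrence structure, correlated annotation errors (a wrong BLAST
hit propagates many wrong GO terms at once), category imbalance at the
scale of real proteomes, probe-level effects, or batch structure in
expression data. Passing tests therefore demonstrate that the *algorithms*
are implemented exactly and behave correctly across the regimes the dials
cover — not that real-proteome accuracy will match the synthetic benchmark.

## Problem sizes

The test-suite and acceptance benchmarks use four categories × 100 genes
with 40 signature + 60 noise features for the classifier (LOOCV over a
powers-of-two k grid), 100-gene instances for the exact brute-force
equivalence checks, and 500-gene × 2-probe expression matrices for the
maternal caller. These sizes exercise every code path, keep the naive
$O(M^2 N)$ reference oracles tractable, and finish in seconds.

## Known limitations

* The labeling rules are substring heuristics over English annotation text;
  they are not an ontology-aware classifier and inherit the vocabulary of
  the curated databases they were designed around.
* GO terms are used exactly as transferred — no ancestor propagation over
  the ontology graph — so two genes annotated at different granularity
  share fewer features than an ontology-aware encoding would find.
* Redundancy removal (CD-HIT-style clustering) is consumed as a precomputed
  cluster table; the package does not cluster sequences itself.
* The maternal caller trusts the provided normalization and refuses input
  that looks log-transformed (all values < 30) rather than guessing.
* Multi-label training genes count fully in every category they belong to;
  with heavily overlapping categories this inflates $C_i$ and damps the
  weights of shared features, which is intended but worth knowing.
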