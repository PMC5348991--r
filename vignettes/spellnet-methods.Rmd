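---
title: "Methods: network construction, connector prediction and scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network construction, connector prediction and scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spellnet)
```

## The model

`spellnet` treats a differential-expression experiment and a co-regulation
knowledge base as two independent views of the same transcriptional
program. The knowledge base — a SPELL-style sheet — stores for each gene an
ordered list of up to 50 co-regulators, ranked by correlation across a
large array compendium. Only the rank order is used; correlation scores are
kept for provenance but never enter the algorithm, because every downstream
step consumes a rank prefix ("the top *k* co-regulators").

The central assumption is that genes responding together to a perturbation
are enriched for pairs that are also correlated across the compendium.
Under that assumption, the per-hit sets {hit} ∪ {its top-*k*
co-regulators} of a genuine transcriptional module overlap heavily, and the
pair co-occurrence matrix — every unordered pair of genes co-occurring in a
per-hit set, weighted by its multiplicity — concentrates weight inside the
module. For a random hit list the sets are nearly disjoint and the weight
spreads thinly.

### Pair enumeration convention

Each hit with *k*ᵍ co-regulators found contributes the full
(1 + *k*ᵍ)² grid of ordered pairs, self-pairs included, as its raw record
count; deduplication then drops self-pairs and merges ordered duplicates
into the occurrence count. The convention matters only for the bookkeeping
identity it produces — one hit with 20 co-regulators yields exactly 441 raw
records, 100 such hits 44,100, and 40 co-regulators per hit 168,100 — and
the package preserves it so that raw record counts remain comparable across
tools that report them. The resulting edge weight between genes a and b is
2 × (number of per-hit sets containing both), which is what the
deduplication of the ordered grid produces.

### Connectivity parameters

*Percent included* is the share of hit nodes with at least one incident
edge (to a hit or, after expansion, to a connector). *Connections per hit*
is the occurrence-weighted degree summed over hit nodes divided by the
number of hits, isolated hits included in the denominator. The weighted
version is deliberate: with 100 hits and k = 20 the characteristic scale is
hundreds of connections per hit for a coherent module, single digits for
random lists, so the weighted statistic separates the two regimes far more
sharply than percent included, which saturates quickly (random lists also
get included through scattered weight-2 edges; see the worked example in
the README).

### Connector selection

All non-hit genes of the matrix are candidates, scored by the sum of the
occurrence counts of their pairs with hit genes (`weighting = "occurrence"`;
a distinct-hit count is available by flag). Given the user's cap `max_c`,
the threshold *T* is the smallest count with at most `max_c` candidates
strictly above it, and exactly the strictly-above genes are selected. The
strict inequality can leave the selection under-filled when ties straddle
the cut — weakly connected (e.g. randomized) inputs often yield only a
handful of connectors although 50 were requested. This behavior is kept
because it is the selection rule's natural tie policy: admitting tied genes
would overshoot the cap in an order-dependent way.

### CoRegScore

With connector ranks r₁…r_C in the full ranking of all N genes (hits are
ranks 1…h), S = Σ rᵢ is mapped affinely so that the best packing
(ranks h+1…h+C) scores +100, the worst (bottom C ranks) −100, and the
uniform-random expectation 0:

$$\mathrm{score} = 100\,\frac{S_{mid} - S}{S_{mid} - S_{best}},\qquad
S_{mid} = \frac{C\,(h+1+N)}{2}.$$

These three anchors determine the affine map uniquely; linearity in S is
the only additional assumption. The score depends on the rank multiset
only, is strictly decreasing when any connector moves down the list, and
has exact expectation 0 under uniform placement without replacement (the
mean non-hit rank is (h+1+N)/2). Connectors are always scored in the
ranking of the same direction as the hit list they extend. A connector
absent from the expression data is an error by default; `missing = "skip"`
drops it and reduces C, which also shrinks S_best — silent skipping would
change the score's calibration invisibly, so it must be opted into.

### Null distributions and significance

Both connectivity parameters are calibrated against random hit lists:
uniform samples, without replacement, of the same size from the gene
universe restricted to genes with a co-regulation entry (about 10–15% of a
real yeast genome lacks one and is excluded from sampling). The CoRegScore
is calibrated against randomized expression datasets analyzed by the
identical pipeline. Two randomization modes exist: `permute_genes`
(default) reassigns gene labels to expression rows, preserving the value
distribution exactly while destroying gene identity; `iid` draws every
value from a log-normal fitted to the pooled template values, for when a
fully synthetic matrix is wanted. `permute_genes` is the default because it
is assumption-free. Randomized sets that select only one or two connectors
are retained — they widen the null honestly — and only sets with zero
selectable connectors are skipped (no score exists), with the count
reported.

Each null is summarized by its mean µ and sample standard deviation σ
(n − 1 denominator; the default 100 sets make the distinction immaterial),
and an experimental reading X is reported as Z = (X − µ)/σ with the
upper-tailed standard-normal p — the probability that a random set beats X.
The normal tail is a convenient large-sample summary; for 100 sets the
extreme tail (p below ~10⁻³) should be read as "far outside the null" rather
than as an exact frequency.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `h` | 100 | hit-list size (top differentially expressed genes, one direction) |
| `k` | 20 | co-regulators per hit (prefix of the ranked list; 5–40 is the useful range, larger k inflates random networks too) |
| `max_connectors` | 50 | cap on predicted connectors per direction |
| `noise_floor` | 15 | MAS5 intensity below which values are clamped up (≈ background); clamping, not removal, keeps N stable |
| `n_null_sets` | 100 | random sets per null distribution |
| `null_mode` | `permute_genes` | expression randomization for the score null |
| `method` | `log2` | differential statistic: difference of mean log2 intensities |
| `seed` | 1 | master seed; every random draw derives from it |

The differential statistic is the difference of mean log2 intensities,
computed after the noise floor so logs are defined; genes whose values are
all at the floor get delta 0 and sink to mid-ranking rather than being
dropped, keeping the CoRegScore denominator N equal to the array size.
Ranking ties are broken by gene identifier, making every ranking, and hence
every downstream artifact, bit-reproducible.

## The synthetic generator

`generate_fixture()` emulates the data the method assumes: a gene universe
(default 2000 genes) with planted co-regulated modules (default three
modules of 30), where each module gene's co-regulator list leads with
`round(0.7 × 20)` same-module partners and is padded with genes drawn
uniformly from the rest of the genome; background genes get fully random
lists. Expression values are log-normal baselines (median ≈ 150, a MAS5-like
scale), multiplied by 2^effect (default effect 2 log2 units) for module
genes in condition A, with multiplicative log-normal noise
(`sdlog = 0.5`) and three replicates per condition. The pad pool
deliberately includes the gene's own module (minus the already-planted
prefix): padding strictly from outside the module would make same-module
hits unable to list each other and push a structure-free fixture
(`coreg_within_module_fraction = 0`) *below* the random-hit-list null,
whereas with this choice a fraction of zero is statistically
indistinguishable from random lists, which is the property the generator is
meant to have.

What the generator does **not** emulate: correlated noise between arrays,
probe-level effects, the heavy inter-module correlation structure of a real
compendium, overlapping modules, and SPELL's actual correlation ranking.
Passing tests on fixtures therefore demonstrate algorithmic correctness and
statistical calibration, not biological performance on real arrays.

One property of real SPELL data is worth flagging: in a dense synthetic
universe (2000 genes, every gene carrying a full 20-long list) random hit
lists are already ~80%+ "included", with a spread of several percentage
points — percent included saturates and loses discriminative power, exactly
as it does for large k on real data. Connections per hit and the CoRegScore
remain sharply discriminative in this regime, which is why they carry the
recovery tests.

## Numerical and design choices

- **Pair counting** is integer-exact throughout; pair keys are coded as
  doubles a·n + b with n the gene count, exact far beyond any realistic
  genome size.
- **Threshold scan** iterates candidate counts upward from zero; the first
  count satisfying the cap is the threshold. Deterministic and independent
  of candidate order.
- **Degenerate inputs**: hits absent from the co-regulation table stay in
  the network (they can gain edges through other hits' lists) but
  contribute only their self-record to the raw count; empty candidate sets
  yield an empty selection with a log note; a null with σ = 0 refuses the
  Z-test rather than dividing by zero.
- **Determinism**: a single master seed drives child seeds for each
  pipeline stage; rerunning an identical configuration reproduces
  byte-identical summaries, reports and export files (nodes and edges are
  written in lexicographic order; the GraphML writer is hand-rolled so the
  serialization is stable).
- **Problem sizes in the test suite** were chosen so the full suite runs in
  about a minute: module-level tests use universes of 60–600 genes;
  statistical tests (recovery, calibration) use the default 2000-gene
  fixture with 100-set nulls and 10 generator seeds.

## Known limitations

- The SIF/attribute/GraphML files are exports only; graph layout and
  cluster isolation happen in Cytoscape.
- No iterative expansion (connectors of connectors) and no community
  detection.
- The one-tailed p-values are raw; no multiple-testing correction across
  directions or datasets is applied.
- Identifier mapping (systematic vs common names) is a data-preparation
  concern: identifiers are opaque, case-sensitive strings and must match
  across the expression table, the co-regulation sheet and the universe.
- Percent included saturates for dense co-regulation tables or large k;
  prefer connections per hit and the CoRegScore for discrimination there.
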