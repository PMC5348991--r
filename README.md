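# spellnet

Database-guided construction and statistical evaluation of yeast
co-expression networks.

## The problem

A microarray (or other genome-wide expression) experiment yields a list of
*hits* — the genes most differentially expressed between two conditions. A
flat hit list says nothing about which hits act together. Large expression
compendia such as SPELL (Serial Pattern of Expression Levels Locator)
already know, for every yeast gene, which other genes are transcriptionally
correlated with it across thousands of arrays. `spellnet` combines the two:
it clusters a hit list into a weighted co-expression network using per-gene
ranked co-regulator lists, predicts additional co-regulated genes
(*connectors*) that the experiment ranked just below the hits, and
quantifies how non-random the resulting network is.

It is aimed at yeast systems biologists who have a normalized expression
table (MAS5/RMA TSV or a SPELL PCL file) or a pre-made hit list, plus a
SPELL-style co-regulation sheet, and who visualize networks in Cytoscape.

## Method

For each of the top *h* hits (default 100), the top *k* co-regulators
(default 20) are looked up, and the per-hit set of 1 + *k* genes is
enumerated as all (1+*k*)² ordered gene pairs — 441 for one hit with 20
co-regulators, 44,100 raw pair records for 100 hits. Records are
deduplicated into unordered pairs; the surviving multiplicity *X* of each
pair is its *occurrence count* and becomes the edge weight. Two parameters
summarize the network over the hits:

- **percent included** — share of hits with at least one network edge;
- **connections per hit** — occurrence-weighted degree averaged over all
  hits.

Non-hit genes with many weighted connections to the hits are *connector
candidates*. Given a cap `max_connectors`, the selection threshold *T* is
the smallest count such that at most `max_connectors` candidates lie
strictly above it; exactly those genes are added as connectors.

Connector quality is scored by where the connectors fall in the full
ranking of all *N* genes. With connector ranks r₁…r_C and S = Σ rᵢ:

    S_best = Σ_{i=h+1}^{h+C} i     (connectors immediately after the hits)
    S_worst = Σ_{i=N-C+1}^{N} i    (connectors at the bottom)
    S_mid  = (S_best + S_worst)/2 = C(h+1+N)/2

    CoRegScore = 100 · (S_mid − S) / (S_mid − S_best)

so +100 is a perfect prediction, −100 an entirely wrong one, and 0 the
expectation for random placement. Every parameter is calibrated against an
empirical null — 100 random hit lists (drawn from the genes covered by the
co-regulation table) for the connectivity parameters, 100 randomized
expression datasets for the CoRegScore — via Z = (X − µ)/σ and the
one-tailed normal p-value.

Networks are exported as Cytoscape SIF + node/edge attribute tables and as
GraphML.

## Worked example

The package ships a synthetic-fixture generator with planted co-regulated
modules, so everything runs without any download:

```r
library(spellnet)

fix <- generate_fixture(synthetic_spec(seed = 7))   # 2000 genes, 3 modules
cfg <- run_config(h = 90, k = 20, max_connectors = 30,
                  n_null_sets = 100, seed = 42)
report <- run_pipeline(fix$expression, fix$coreg, cfg,
                       universe = fix$universe, out_dir = "example_out")
print(report)
#> <pipeline_report> 2000 genes, directions: up, down
#>   up: 95.6% included, 243.4 conn/hit, 27 connectors, CoRegScore 59.3
#>   down: 95.6% included, 5.3 conn/hit, 30 connectors, CoRegScore 9.6
```

The three planted modules are up-regulated, so the `up` direction carries
the signal: 95.6% of its 90 hits join the network at 243.4 weighted
connections per hit, against a random-hit-list null of 5.01 ± 0.68
(Z = 351.8) — random lists are also often *included* (null 83.2 ± 4.4,
Z = 2.83) but only via scattered low-weight edges. The 27 selected
connectors score CoRegScore 59.3 against a permuted-dataset null of
1.7 ± 12.0 (Z = 4.80, p = 7.9e-07): the predicted genes sit far closer to
the top of the ranking than chance allows. The `down` direction, which
contains no planted signal, stays at null-level connections per hit (5.3)
and a null-level score (9.6). `example_out/` then contains `up.sif`,
`up.graphml`, attribute tables, a connector report, `score_report.tsv`,
`summary.json` and `run_log.txt`.

Real data enter through `read_expression_table()` (TSV or PCL),
`read_coreg_sheets()` (wide or long SPELL-style sheets),
`read_hit_list()` and `read_gene_universe()` (FASTA or plain list).

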