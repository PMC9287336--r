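# gcevo — gene content evolution on species trees

`gcevo` quantifies how gene repertoires change across a phylum-level
phylogeny. It is built for comparative genomicists analysing panels of
(often incomplete) metagenome-assembled genomes: given a rooted species
tree and per-genome gene-family copy numbers, it infers where
originations, duplications, intra-phylum lateral transfers (intra-LGT) and
losses happened, reconstructs ancestral gene content, and summarizes how
evenly genome change was spread over the tree.

## What it computes

* **Parsimony duplication–transfer–loss reconciliation.** A dynamic
  program over per-node copy numbers finds the minimum-cost event history
  for each family (defaults: duplication 2, transfer 3, loss 1,
  origination free and unique). Genome incompleteness can discount the
  loss explanation: an absent copy in genome *g* may be "present but
  unobserved" at cost −log₂(completeness₍g₎) · c_loss. Readers ingest
  externally produced reconciliation summary tables (real-valued
  posterior-mean event counts) and donor/recipient transfer records with
  their transfer posterior probabilities (TPP).
* **Branch × mechanism event maps** with gain composition (integer
  percentages, half-up rounding) and the **punctuation score**

  PS = Σ events on the top 10% of branches ⁄ (0.1 · Σ events on all branches),

  which is 1 for a uniform spread and 10 for complete concentration.
* **Ancestral genome content** (thresholded per-node copy numbers),
  KO-level functional gains/losses between parent and child ancestors, and
  trait-gain mapping that counts independent acquisitions of a metabolism.
* **Gene-tree acquisition counting**: maximal focal-group clades on a
  (MAD-rooted) gene tree give the minimum number of independent lateral
  acquisitions; monophyly ⟺ a single acquisition. Family medoids
  (BLOSUM62-distance minimizers) provide search representatives.
* **Tree utilities**: Newick I/O with deterministic internal labels,
  relative evolutionary divergence (RED), minimal-ancestral-deviation
  (MAD) rooting with a per-branch closed form, population z-scores.
* **Taxonomy statistics**: average amino acid identity (AAI) from
  reciprocal best hits, average-linkage rank clustering at 70%/95% with
  polyphyly splitting against the species tree, completeness/contamination
  QC with strict thresholds, completeness-adjusted genome size and CDS
  counts, proteome novelty, single-copy marker selection, and genome panel
  summaries (including 16S rRNA recovery).
* **A synthetic-data generator** — Yule species trees, Gillespie
  simulation of families under origination/duplication/transfer/loss with
  per-copy completeness censoring, and proteome pairs at controlled
  amino-acid identity — providing ground truth for every inference stage.

## Worked example

```r
library(gcevo)
study <- run_simulation_study(list(seed = 1, censor_completeness = 0.7))
print(study)
#> simulation study: 200 families on 16 tips (seed 1 )
#>   observable families: 193
#>   per-branch dup+loss totals exact: FALSE
#>   families with exact dup+loss maps: 96.9%
#>   origination node recovered: 97.4%
#>   origination stable under censoring: 79.9%

punctuation_scores(study$inferred_table)
#>    mechanism  k    score
#>         loss  3 4.444444
#>  duplication  3 3.750000
#>  origination  3 1.606218
#>     transfer NA       NA
```

Reading the output: 200 families were simulated on a 16-tip Yule tree with
sparse duplication/loss (0.05 events per unit branch length each); 193
survived to be observed. For 96.9% of them the parsimony reconciliation
recovers the exact per-branch duplication and loss map, and it recovers
the simulated origination node for 97.4%. The shortfall is an
identifiability limit, not an engine defect: when a loss erases an entire
child clade of the origination node, originating in the surviving clade is
strictly cheaper than the true history, so any parsimony relocates the
origination (the DP itself is verified exact against exhaustive
enumeration). The same effect explains why, after censoring each gene copy
at 70% completeness, only ~80% of origination placements stay put.
Punctuation scores on the inferred map show losses most concentrated
(4.44) and originations most evenly spread (1.61) on this small synthetic
panel; the transfer row is `NA` because no transfers were simulated.

On real data, the entry point is `run_event_analysis()`: point it at a
Newick species tree and a reconciliation summary table (plus, optionally,
transfer records, a family→KO map and trait KO sets) and it returns the
branch event table, gain composition, punctuation scores, transfer matrix,
ancestral genomes, functional deltas and trait-gain report.

```r
g <- gain_composition(c(transfer = 13025, origination = 4947,
                        duplication = 3211, loss = 16374))
print(g)
#> Gene content gains: 21,183 total
#>   transfer         13,025  (61% of gains)
#>   origination       4,947  (23% of gains)
#>   duplication       3,211  (15% of gains)
#> Losses: 16,374
```

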