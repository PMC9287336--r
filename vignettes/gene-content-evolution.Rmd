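---
title: "Quantifying gene content evolution on a species tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene content evolution on a species tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Phylum-level archaeal groups such as the Thermoplasmatota assemble their
gene repertoires through four mechanisms: *origination* (arrival of a new
family, by transfer from outside the sampled phylum or by de novo
formation), *duplication* of an existing gene, *intra-phylum lateral
transfer* (intra-LGT) between sampled lineages, and *loss*. Given a rooted
species tree and per-genome gene-family copy numbers, `gcevo` infers where
on the tree these events happened, reconstructs the gene content of
ancestral genomes, and summarizes how evenly change was spread over the
phylogeny. It is aimed at comparative genomicists working with panels of
metagenome-assembled genomes (MAGs), where incompleteness of the observed
genomes is a first-class modelling concern.

# The model

## Reconciliation by parsimony

`reconcile_parsimony()` explains one family's observed copy-number profile
with a minimum-cost event history. The state is the copy number (0 to
`c_max`) at every node of the species tree; along a branch from parent
state $a$ to child state $b$ the engine pays

* $(b-a)\,c_D$ for gains while present ($a>0$, duplications),
* $(b-a)\,c_T$ for gains from absence ($a=0$): the copy must have arrived
  laterally from a branch that is neither ancestral nor descendant,
* $(a-b)\,c_L$ for shrinkage (losses),

and exactly one free origination is placed at the cost-minimizing node.
Default costs are $c_D=2$, $c_T=3$, $c_L=1$: losses cheapest, transfers
dearest, the usual ordering that prefers vertical explanations (for a
family present in three of four genomes, one loss beats origination in a
subclade plus a transfer). Ties are broken toward fewer transfers, then by
preorder position of the origination node, so results are deterministic.
The dynamic program is exact: on small trees it equals exhaustive
enumeration over every origination node and internal state assignment, and
the test suite verifies this on every profile over 4-, 5- and 6-tip trees
with copy numbers capped at 2 (1,050 profiles).

Donor identities are not identified by parsimony; transfer records carry a
deterministic convention (the smallest-preorder non-lineal branch with
copies) and support 1.0, while ingested probabilistic reconciliations carry
their own transfer posterior probabilities (TPP).

## Genome incompleteness

MAGs miss genes for observational, not evolutionary, reasons. When a
completeness fraction per genome is supplied, an absent copy in genome $g$
may alternatively be explained as *present but unobserved* at cost
$-\log_2(\mathrm{completeness}_g)\cdot c_L$ per copy. At completeness 0.5
this equals one loss; at 0.7 it costs $\approx 0.515$, so unobserved
explanations are preferred to losses there. A genome with completeness 1 is
fully observed, so for it the unobserved explanation is unavailable
(infinite cost) rather than free — the raw formula would degenerate at that
boundary. This cost form is a deliberate, simple discount of the loss
explanation; it is not a calibrated observation model, and its behaviour
as completeness varies should be read as a design choice of this package
(see "Known limitations").

## Branch statistics

`aggregate_events()` sums per-family events into a branch-by-mechanism
table. Two statistics summarize it:

* **Gain composition**: total gains split into intra-LGT, originations and
  duplications, with integer percentages rounded half-up (base R's
  round-half-to-even does not reproduce conventionally printed
  percentages; `round_half_up()` does).
* **Punctuation score**: for one mechanism with per-branch counts $x$,
  $$\mathrm{PS} = \frac{\sum_{\text{top }10\%\text{ of branches}} x}
  {0.1 \sum_{\text{all branches}} x}.$$
  PS is 1 for a perfectly uniform spread and 10 when everything falls on a
  single branch (of at least ten). "10% of branches" is
  $\max(1,\mathrm{round}(0.1n))$ with half-up rounding; floor and ceiling
  are available because the convention for fractional branch counts is
  genuinely underdetermined. Ties at the $k$-th largest value are resolved
  by taking exactly $k$ branches, largest-first in stable order. PS is
  scale-invariant, so it can be compared across mechanisms with very
  different event totals; `zscore_normalize()` (population $\sigma$,
  because the branches of one tree are the whole population, not a sample)
  serves the same purpose for event maps.

## Ancestral content and traits

Presence at a node is called when the reconciled copy number reaches a
threshold (default 0.5, chosen so that parsimony integer counts behave as
expected while fractional posterior-mean copy numbers from probabilistic
reconciliations round sensibly; it is configurable). Functional gains and
losses between a parent and child ancestor are computed on KEGG ortholog
(KO) sets, not family sets: a KO is lost only when no family carrying it
remains. A trait (a set of KOs, "any" or "all" semantics for multi-subunit
complexes) is *gained* on every branch where it appears without being
present in the parent; the number of such branches is the count of
independent acquisitions implied by the reconstruction, and a
gain–loss–regain along one lineage deliberately counts twice.

## Gene-tree acquisition counting

For a single gene family, `min_acquisitions()` counts the maximal clades of
the (rooted) gene tree consisting entirely of focal-group sequences. Under
a gains-only model with no transmission between those clades this is the
minimum number of independent acquisitions, and it equals 1 exactly when
the group is monophyletic. Gene trees without outgroup information are
rooted by minimal ancestral deviation (MAD) first. Likelihood-based
topology tests are outside the scope of this package; the clade count is
the computable lower bound that such analyses report ("at least $N$
independent acquisitions").

## MAD rooting and RED

`mad_root()` evaluates every branch of the unrooted topology. For a
candidate root, each tip pair induces an ancestor (the point of their path
closest to the root) and a relative deviation $|2d(i,\mathrm{anc})/d_{ij} -
1|$ from the clocklike midpoint; the root minimizes the root-mean-square
deviation over all pairs. Within a branch the objective is quadratic in
the root position, so the optimum is closed-form (clamped to the branch);
ties between branches break lexicographically on the branch identifier.
Zero-length branches are nudged to $10^{-8}$ with a warning. Relative
evolutionary divergence (`compute_red()`) interpolates node depth from root
(0) to tips (1) via $\mathrm{RED}(v) = \mathrm{RED}(p) + (b/u)(1 -
\mathrm{RED}(p))$ with $u$ the mean parent-to-tip distance through $v$.

## AAI and taxon delimitation

`compute_aai()` aligns all protein pairs locally (BLOSUM62, affine gaps),
keeps reciprocal best hits by score, and averages their percent identities;
zero RBH pairs yield an explicit "undefined" flag, never a silent 0.
`cluster_taxa()` applies average-linkage agglomerative clustering to the
AAI matrix — "amalgamative" demarcation is interpreted as average linkage,
the common practice for AAI rank cutoffs — cut at 70% (genus) or 95%
(species), then splits any cluster that is polyphyletic on the species
tree into its maximal monophyletic components, judging monophyly on the
induced subtree of the clustered genomes so outgroups do not interfere.

# The synthetic-data generator

`simulate_species_tree()` draws pure-birth (Yule) trees: with $k$ lineages
the next split waits $\mathrm{Exp}(k\lambda_b)$, and a final interval at
the full rate separates the last split from the present, so the expected
root-to-tip depth is $\sum_{k=2}^{n} 1/(k\lambda_b)$. Defaults used by the
simulation study: 16 tips, birth rate 1.

`simulate_family()` runs a Gillespie simulation: one copy originates at a
uniformly drawn node and every extant copy then experiences duplication,
transfer and loss as Poisson processes *per unit branch length* (rates
must scale with divergence so that punctuated behaviour can emerge from
the tree shape rather than being hard-coded). Transfer recipients are
drawn uniformly among branches neither ancestral nor descendant to the
donor — the simplest null consistent with an undated reconciliation model.
Default study rates are $\delta=\lambda=0.05$, $\tau=0$ per unit length:
sparse enough that most families carry at most one event, which is the
regime where parsimony recovery can be assessed cleanly. Completeness
censoring (`censor_by_completeness()`) thins each copy independently with
the genome's completeness, leaving truth tables untouched.

`simulate_divergent_proteomes()` substitutes each site independently with
probability $1-t$, drawing replacements uniformly over all 20 amino acids,
so realized identity is $t + (1-t)/20$ in expectation (90.5% at the
nominal 90% setting) and named ortholog pairs stay one-to-one.

What the generator does *not* emulate: realistic substitution processes
along gene trees, rate heterogeneity, gene-tree discordance from
incomplete lineage sorting, biased transfer highways, or correlated
missingness in MAGs (real assembly gaps are not independent per gene).
Green tests on synthetic data therefore demonstrate internal correctness
of the inference machinery — not that real Thermoplasmatota-scale data
would be recovered at the same rates.

# Numerical choices

* Newick: lengths optional, internal labels after ")", quoted labels and
  comments rejected; missing internal labels become `N<k>` by preorder, a
  stable join key across modules. Polytomies are kept as parsed; every
  engine here (DP, MAD, clade counting) handles them directly.
* Tie-breaks are deterministic everywhere: fewer transfers then preorder
  (reconciliation), lexicographic branch id (MAD), lexicographically
  smallest id (medoids), first-index (argmin scans).
* The DP breaks transfer/cost ties through a $10^{-9}$-scaled penalty on
  transfer counts; with the default integer-ish costs this cannot reorder
  genuinely different costs.
* Medoid distance: $d(a,b) = 1 - S(a,b)/\max(S(a,a),S(b,b))$ with $S$
  summed BLOSUM62 scores over columns ungapped in both sequences — the
  exact normalization of the distance calculators used in practice is not
  standardized, so this one is documented and oracle-tested against
  exhaustive pairwise tables.
* Degenerate inputs fail loudly: all-zero profiles, empty vectors for
  z-scores or punctuation, all-zero event maps, fewer than 3 tips for MAD,
  completeness outside $[0,1]$, copy numbers above `c_max`.

# Problem sizes

The bundled study and checks run at sizes a laptop handles in about two
minutes: 200 families on 16-tip trees for recovery studies; exhaustive
reconciliation oracles on trees of up to 6 tips with copy cap 2; 100
random trees of up to 8 tips for MAD-versus-grid comparisons; all $2^n-1$
focal labelings of up to 8-tip trees for acquisition counting; proteomes
of 15-25 proteins of length 150-200 for AAI panels. These sizes were
chosen because each check is already exhaustive or statistically stable
there; everything scales up by configuration.

# Known limitations

* **Origination-adjacent losses are unidentifiable.** If a loss removes an
  entire child clade of the origination node, the true history
  (origination higher, plus the loss) is strictly dominated by origination
  at the surviving child. Parsimony — and any method without a prior
  favouring deeper originations — relocates the origination and the loss
  disappears. At the default study rates this affects roughly 3-5% of
  simulated families, which is exactly the shortfall the recovery metrics
  report. The same mechanism makes origination placements move when
  censoring wipes out every observed copy on one side of the origination
  node: with 0.7 completeness per copy, a cherry loses one side with
  probability 0.42, and measured origination stability under censoring
  sits near 80-85%, not at 100%.
* The completeness cost is a discount on losses, not a likelihood; its
  dependence on completeness is monotone in the "wrong" direction at the
  extremes (a nearly complete genome gets a nearly free unobserved
  explanation, guarded only at exactly 1). Treat inferences that hinge on
  it as sensitivity analyses.
* Parsimony reports one optimal history; posterior uncertainty (e.g. TPP)
  only enters through ingested probabilistic reconciliation tables.
* Transfer donors are a labelling convention under parsimony.
* AAI depends on alignment parameters; defaults (BLOSUM62, gap open 10,
  extension 0.5, score floor 0) are exposed, and the 70/95 rank cutoffs
  are conventions, not fitted values.

# A worked run

```{r study}
library(gcevo)
study <- run_simulation_study(list(
  n_leaves = 16, n_families = 200,
  duplication = 0.05, transfer = 0, loss = 0.05,
  censor_completeness = 0.7, seed = 1
))
print(study)
punctuation_scores(study$inferred_table)
```

```{r analysis}
# ingest an external reconciliation summary instead
res <- run_event_analysis(list(
  tree = "species_tree.nwk",
  events = "reconciliation_events.tsv",
  ko_map = "family_ko.tsv",
  trait_kos = c("K02274")      # e.g. heme-copper oxidase subunit A
))
res$composition
res$traits$count
```
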