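---
title: "Genomic metabolons: model, scores, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic metabolons: model, scores, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabolons)
library(dplyr)
```

## The problem

More than a quarter of the enzymatic activities catalogued by the IUBMB are
*sequence orphans*: no nucleic or protein sequence is known to encode them.
Sequence-similarity annotation tools are useless for them by definition, so
candidate genes must come from *context*: in prokaryotes, genes of one
metabolic process tend to sit next to each other (operons), and their
reactions tend to be adjacent in the metabolic network (consecutive pathway
steps share metabolites). This package detects such joint contexts —
**genomic metabolons** — and exploits them to propose and rank candidate
genes for gap and orphan reactions, per organism and integrated across many
organisms.

## The data graph

Three tables define one analysis:

* **genes**: one row per protein-coding gene with its organism, replicon and
  rank position. Consecutive genes are adjacent, *ignoring strand and
  intergenic distance* (bidirectionally transcribed operons exist, so strand
  is deliberately not a criterion). Positions are ranks, not coordinates.
* **reaction links**: the global, organism-independent metabolic network.
  Two reactions are adjacent when the product of one is the substrate of the
  other **and** the shared metabolite is a *main compound* of both reactions
  in at least one common pathway. Restricting to main compounds (e.g.
  phosphoenolpyruvate, but not water, in glycolysis) avoids hub metabolites
  that would make the network nearly complete.
* **Known associations**: curated gene–reaction annotations. A gene may
  carry several (bifunctional enzymes), and a reaction several genes
  (multi-subunit enzymes).

Together these form a two-layer graph with two vertex kinds and three edge
kinds (gene–gene, reaction–reaction, gene–reaction).

## Finding metabolons

Gap tolerance is introduced by **g-partial transitive closure**: an extra
edge joins every vertex pair separated by at most *g* intermediate vertices.
The defaults are `g_gene = 3` and `g_rxn = 2`. These values carry an
empirical motivation: typical multi-gene transcription units span about 3
genes, and most reaction pairs in a main-compound network are within 2
intermediates of each other. Both are `pipeline_config()` fields.

On the closed graphs, the Known associations of each organism are
partitioned into maximal **common connected components** (CCCs): blocks in
which the gene side is connected, the reaction side is connected, every gene
touches a reaction of the block and vice versa, and no block can absorb
another association without breaking these conditions. The implementation
uses alternating refinement — split blocks by gene-side components, then by
reaction-side components, until a fixed point. Because valid blocks
containing a given association are closed under union, the coarsest valid
partition is unique; the fixed point therefore does not depend on the split
order, a property the test suite checks by permuting it.

Closure edges are bookkeeping, not biology, so each CCC is post-processed to
**recover its gaps**: for every pair of member genes at original distance
between 2 and `g_gene + 1`, the interior vertices of *all* shortest original
paths join the metabolon as gap genes (likewise for reactions with
`g_rxn`). Taking all shortest paths rather than one makes the result
deterministic and order-independent, and errs toward including plausible
candidates. Only original adjacency edges are exported in results and
GraphML — closure edges never appear downstream, so path lengths and
drawings reflect real adjacency.

A metabolon is retained when it has at least 2 genes, 2 reactions and 2
Known associations (gap members count towards the first two); all three
thresholds are configurable. Requiring two independent Known anchors is what
makes the metabolon trustworthy evidence rather than a single-annotation
artifact.

Finally, one **Potential** association is generated per (gap gene, gap
reaction) pair. A gap gene is not a candidate when it is flagged
non-metabolic or already holds a Known association elsewhere in its genome —
it stays in the metabolon as a connectivity gap, but proposing it would
contradict what is already known about it.

## Weights and scores

Every Known/Potential association receives a **Minimal Path Length**: the
shortest path between its gene and its reaction inside the metabolon,
traversing gene–gene edges, reaction–reaction edges and *Known* association
edges only; a Known association may not use its own edge. MPL paths may pass
through gap members — gaps are genuine metabolon vertices. Two floors follow
from the construction and are asserted corpus-wide in the tests: Known
associations have MPL ≥ 2 (2 is attainable only via a bifunctional gene or a
multi-subunit reaction), Potential associations have MPL ≥ 3 (their path
must use at least one gene edge, one Known edge and one reaction edge). A
pair with no admissible path has undefined MPL; such associations are
dropped with a warning rather than given weight zero, so score denominators
stay well defined.

The weight of an association is `alpha / MPL` with `alpha_known = 1`,
`alpha_potential = 0.1` and `alpha_inferred = alpha_known`: topologically
tight pairs are favored, and curated knowledge outweighs generated
hypotheses tenfold. Per-genome **gene-level scores** are weight shares: the
gene-to-reaction score divides w(G,R) by the total weight of G's
associations; the reaction-to-gene score divides it by the total weight of
R's associations in the organism. Each family of scores sums to 1 by
construction (checked at tolerance 1e-12).

## Cross-organism integration

Genes are tied together across organisms by families. Families are an
*input* here — curators or an external clustering supply them; the bundled
`naive_families_from_similarity()` (single-linkage components of a
thresholded similarity graph) is a deliberately simple convenience, not an
ortholog-detection method. Families serve only to pool evidence, so
integration proceeds in a fixed order:

1. **Non-metabolic filtering** removes Potential associations of genes whose
   family is flagged non-metabolic (transporters, regulators commonly
   embedded in metabolic operons). Known rows are never touched.
2. **Promotion**: a Potential (g, r) becomes **Inferred** when another gene
   of g's family is Known for r. The conserved metabolic context makes this
   transfer safer than plain similarity-based transfer. Promotions are
   decided against the pre-promotion Known set only — no chaining within a
   pass — which makes the operation deterministic and idempotent. The
   promoted gene and reaction cease to be gaps, so their other Potential
   associations in that metabolon are removed.
3. **Family scores** over Known + Potential + Inferred, all organisms:
   coverage (fraction of members associated), family-to-reaction and
   reaction-to-family weight shares. Genes without a family contribute to
   reaction denominators but to no family numerator: the reaction-to-family
   scores of a reaction then sum to less than 1, which is informative
   (unassigned evidence exists) rather than an artifact.

Candidates for each (organism, reaction) are ranked by the reaction-to-family
score by default. Genes without a family fall back to their gene-level
reaction-to-gene score and rank after every family-scored gene — a
cross-organism consensus should not be outranked by a single-genome signal
of equal magnitude. Ties share the minimum (competition) rank, 1, 1, 3; at a
rank cutoff *k* an association counts if its competition rank is ≤ *k*.

## The orphanization benchmark

`run_benchmark()` takes every reaction with Known metabolon evidence,
deletes all its associations in all organisms (making it a synthetic
sequence orphan), recomputes everything from scratch, and asks at which rank
the genuine gene reappears. Recomputation is deliberately full rather than
incremental — correctness over speed at this scale. Counts are pooled over
reactions; recall is TP/(TP+FN), precision TP/(TP+FP), per rank cutoff and
per ranking score. At `k = Inf` ranking no longer filters, so both scores
give identical TP and FP by construction.

## What the synthetic generator emulates

`simulate_dataset()` builds corpora with planted structure: a global network
of main-compound chains (10 chains of 6 reactions by default), and per
organism a circular 200-gene replicon carrying 6 cluster templates — each a
contiguous window of 4–6 chain reactions whose coding genes sit
consecutively, with a 0.2 per-junction chance of one unannotated spacer.
Templates recur across the 5 organisms with probability 0.9, and the genes
coding one reaction share a family, so family-level integration has real
signal. Background genes are unannotated; 10% join flagged non-metabolic
decoy families so the filtering step has real work; 2% of cluster genes get
a corrupted family label. Planted clusters are separated by at least 4
background genes so neighboring clusters cannot merge through the gap
tolerance.

`withhold_orphans()` creates recoverable targets: only interior template
positions are eligible, no two withheld positions in a template are
adjacent, and every template keeps ≥ 2 annotated genes. By construction
each withheld gene remains flanked by anchors within the gene-gap tolerance
and each withheld reaction within the reaction-gap tolerance, so a correct
implementation recovers essentially all of them — the end-to-end regression
test asserts ≥ 90% recovery and ≥ 70% rank-1 under the reaction-to-family
score.

What these corpora do **not** emulate: uneven genome sizes and annotation
density, multi-replicon genomes, bifunctional genes, multi-subunit enzymes,
horizontally transferred rearrangements, or realistic ortholog-family noise
beyond the simple label-corruption rate. Passing tests show algorithmic
correctness under planted structure, not expected performance on real
genomes — on real corpora most annotated genes are *not* clustered, and
recall is intrinsically limited to clustered contexts.

## Numerical choices and conventions

* Floating-point score checks use absolute tolerance 1e-12; output tables
  print scores to 4 decimals.
* All iteration is over sorted identifiers, so outputs are byte-stable for
  fixed inputs, configuration and seed (tested).
* Metabolon ids are assigned by sorted (organism, smallest member gene id).
* Replicons are circular by default (prokaryote chromosomes usually are):
  the last and first gene of a replicon with ≥ 3 genes are adjacent. Whether
  a given dataset warrants this is the user's call — it is a single
  `pipeline_config(circular_replicons = )` flag, off for the linear toy
  examples in the tests.
* Inferred associations inherit the MPL of the Potential they were promoted
  from; only their `alpha` changes.
* Test and acceptance problem sizes: property tests run on random instances
  of ≤ 12 genes / ≤ 10 reactions where exhaustive enumeration is the oracle;
  end-to-end checks use the 5 × 200-gene default corpus, a size at which a
  full benchmark (one pipeline re-run per eligible reaction) completes in
  about a minute.

## Limitations

Gap genes lie, by construction, *between* annotated genes: metabolon-
flanking genes are never proposed, even though the next operon gene over may
be a fine candidate. Processes whose genes are not chromosomally clustered
produce no metabolons and hence no proposals. Families are only as good as
their input clustering; the bundled single-linkage convenience is coarse.
The CLI's `score`, `integrate` and `rank` subcommands share the full
pipeline's output writer — each stage's tables are a subset of `run-all`'s.
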