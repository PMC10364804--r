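---
title: "Neighborhood enrichment: model, choices, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood enrichment: model, choices, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genehood)
```

## The model

genehood tests whether a *target* protein domain occurs in the genomic
neighborhoods of a *query* domain (or gene list) more often than random
placement would predict. A neighborhood is the set of genes on the query
gene's contig whose `[start, end]` span overlaps the window
`[query_start - r, query_end + r]`, with `r = radius_bp` (default 5,000 bp;
at typical bacterial gene density of roughly one gene per kilobase this is
about a 10–12 gene window, a scale that covers most operon-like functional
units).

For a target domain carried by `Nod` of the `Sd` genes in the database, each
of the `Nn * Nl` gene slots inspected across the `Nn` neighborhoods (mean
size `Nl` genes) is, under the null, a Bernoulli trial with success
probability `Nod / Sd`. The total count `k` is approximated by a Poisson law
with mean

$$\lambda = N_n \, N_l \, \frac{N_{od}}{S_d},$$

and the reported *P score* is the upper tail $P(X \ge k)$. Counting `k` as
per-gene presence summed over neighborhoods (a domain in three neighbor
genes of one neighborhood contributes 3) makes $E[k] = \lambda$ exact under
the null by construction; repeated hits of one domain *within one protein*
count once, which keeps `Nod <= Sd` provable and the two counters consistent.

Assumptions worth keeping in mind:

* Gene slots are treated as exchangeable; local gene-density variation,
  composition biases, and phylogenetic correlation between genomes all
  violate this to some degree. The binomial-to-Poisson step and the fact
  that the background frequency `Nod / Sd` is estimated from data containing
  the neighborhoods themselves both push the test toward *conservatism*,
  which is the direction we validate (see below).
* Neighborhoods of clustered query genes overlap and are deliberately not
  merged; each query gene contributes one neighborhood, as in a
  per-neighborhood sampling model.
* The query gene itself is a member of its own neighborhood, so the query
  domain's row always shows 100% presence; it is flagged `is_query` rather
  than removed, for transparency.

Domains with `k < lambda` — occurring less often than in a random
neighborhood — are excluded *before* multiple-testing correction, so the
correction family `m` is the retained set. The default reporting rule is a
(corrected) P score below `1e-5` together with presence in at least 5% of
neighborhoods; presence guards against domains that pile up in a handful of
neighborhoods only.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `radius_bp` | 5000 | window half-width, bp each side of the gene body |
| `strand_mode` | `"all"` | keep all neighbors, or only same/opposite strand |
| `pscore_cutoff` | `1e-5` | significance threshold on the (corrected) P score |
| `min_presence` | 0.05 | minimum fraction of neighborhoods containing the domain |
| `correction` | `"none"` | `"bonferroni"` or `"benjamini_hochberg"` over retained domains |
| `average_rank` | `NULL` | taxonomic rank for subtaxon averaging |
| `min_genomes` | 25 | database genomes a subtaxon needs to enter averaging |
| `seed` | 1 | RNG seed for the averaging draws (recorded in the result) |

`Nl` is the *empirical mean* neighborhood size of the extracted
neighborhoods, not a constant derived from `radius_bp`: no formula is
implied by the model, and the empirical mean makes `lambda` self-calibrating
across gene-dense and gene-sparse taxa. This is a documented design choice.

## Subtaxon averaging

Genome collections are heavily skewed toward much-sequenced taxa, which lets
a single oversampled genus dominate the neighborhood set. With
`average_rank` set, neighborhoods are grouped by the query genome's lineage
at that rank; subtaxa with fewer than `min_genomes` genomes *in the
database* (not neighborhood count — the rule is about how well a taxon is
sampled) are dropped with a report, the largest group's neighborhood count
`n_max` is identified, and every other group is topped up to `n_max` by
drawing neighborhoods *with replacement* from within the group. Replacement
is required: the deficit `n_max - n_sub` routinely exceeds `n_sub`.
Resampled entries are exact copies and never cross groups.

Only the neighborhoods are balanced. The background `Nod`/`Sd` is recomputed
over the genomes of the retained subtaxa, unweighted. Balancing the
background per subtaxon as well would be a defensible alternative; we chose
the simpler contract and flag it prominently, since the two differ when
domain frequencies vary strongly between subtaxa. The per-subtaxon
contribution table (rank, subtaxon, genome count, neighborhood count,
contributed count, seed) is attached to every averaged result so the
balancing is auditable.

## Neighborhood clustering

Neighborhood composition is compared with the Jaccard index on domain
*presence sets* (not multisets): $J(A,B) = |A \cap B| / |A \cup B|$. Two
empty sets get $J = 0$ with a warning — unannotated neighborhoods carry no
evidence of similarity, and 0/0 must not silently become 1. Clustering is
genuine single (minimum) linkage on $d = 1 - J$; note that "farthest point"
names *complete* linkage, a different method — we implement and validate
minimum linkage, checking it against the minimum-spanning-tree cut property
on random instances. The tree is cut either at a distance threshold or into
a target number of clusters; cluster labels are renumbered by order of first
appearance so output is deterministic in the input order. Clusters are
annotated with genus/family composition percentages and "featured" domains
present in at least 90% (configurable) of member neighborhoods.

## The synthetic generator

`fixture_spec()` / `simulate_genome_db()` define the validation conditions:

* one contig per genome; gene lengths gamma-distributed (shape 4, mean 900
  bp, floor 50 bp), intergenic gaps geometric with mean ~100 bp — about one
  gene per kilobase, so the default window holds 10–12 genes;
* strands follow a Markov chain with probability 0.6 of keeping the
  predecessor's strand, so strand filtering is exercisable;
* background domains are independent Bernoulli per (gene, domain) — exact,
  via a binomial carrier count and a uniform choice of carrier genes — with
  a power-law frequency spectrum ($f_j \propto j^{-0.7}$, scaled to one
  domain per gene on average) in the standard fixture;
* the query domain is placed in a fraction of genomes (default 75%), one
  gene per genome, away from contig ends; each planted partner is placed
  within `max_offset` genes of the query with the stated probability, else
  at a random other gene of the same genome. Planting can be restricted to
  chosen genera to create taxon-private associations;
* `taxon_skew` fixes genus sizes exactly, and genera nest deterministically
  into family/order/class/phylum.

What the generator does *not* emulate: real operon structure, phylogenetic
correlation between genomes, annotation error, multi-contig drafts, and
non-uniform gene density. Passing the validation suite therefore shows the
statistics, bookkeeping and corrections are implemented correctly at
realistic scales — not that the Poisson null is well calibrated on real
genome collections, where conservatism from the binomial approximation and
anti-conservatism from phylogenetic correlation both come into play.

## Validation design and problem sizes

The acceptance suite (and `scripts/acceptance.R`) uses these study
conditions, chosen once:

* **Standard fixture**: 200 genomes × 1,000 genes, 300-domain pool, query in
  150 genomes, one partner within ±3 genes at probability 0.8; 20 seeded
  replicates. The partner must reach P < 1e-5 with presence ≥ 0.5 in at
  least 19 of 20, and non-planted domains' raw P scores must not exceed the
  nominal level at α = 0.01 by more than three binomial standard errors.
* **Null fixture**: 100 genomes × 500 genes, no planted association, 20
  seeds, with background frequencies in three tiers (0.12 / 0.08 / 0.002).
  The tiers put every domain's expectation either well above or well below
  the λ ≥ 5 line at which the mean-count calibration is checked: the
  Monte-Carlo standard error of a 20-replicate mean count is
  $1/\sqrt{20\lambda}$ relative, so checking a 10% band is meaningful at
  λ ≈ 80–120 but would be dominated by noise just above λ = 5.
* **Skewed fixture**: 80 genomes in two genera (50 with the association, 30
  without); genus averaging must equalize contributions exactly and strictly
  dilute the partner's presence fraction.
* **Clustering**: two 25-neighborhood archetype blocks (within-block J = 1,
  cross-block J = 0) must be recovered exactly; 50 random instances of
  n ≤ 50 are compared against the MST oracle.

## Numerical choices and degenerate inputs

* P scores go through the Poisson survival function, never `1 - sum` in
  double precision, so large-λ scores do not suffer catastrophic
  cancellation; extreme tails below ~1e-308 underflow cleanly to 0.
* Output ordering is fully deterministic: ascending P score, ties broken by
  descending `k`, then accession; identical inputs and seed give
  byte-identical tables.
* A query domain absent from the database is a *status*
  (`"query_not_found"`, empty table), not an error; an entirely unknown
  gene list is an error, a partially unknown one reports the unmatched IDs.
* Coordinates are 1-based inclusive (GFF convention); the loader rejects
  `start > end`, `start < 1`, unknown strands, and duplicate gene IDs with
  typed conditions that the CLI maps to distinct exit codes.
* Missing taxonomy ranks are explicit `NA` sentinels; they never match a
  taxon filter and their neighborhoods are dropped (with a report) from
  averaging.

## Known limitations

* Per-gene domain presence discards copy-number within a protein; tandem
  repeat expansions of a domain are under-weighted by design.
* The Poisson null ignores between-genome correlation; on real collections
  of near-identical strains the averaging step mitigates but does not
  remove this (that is its purpose), and P scores are best read as ranking
  scores rather than calibrated probabilities.
* Only protein-coding, Pfam-annotated genes are considered; RNA genes are
  out of scope.
* Taxonomy matching is exact-string per rank; no name normalization or
  taxid resolution is attempted.
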