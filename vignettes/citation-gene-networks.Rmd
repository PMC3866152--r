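---
title: "Explicit and citation-mediated gene networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explicit and citation-mediated gene networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citegene)
```

## The model

The unit of observation is an abstract annotated with a *set* of
normalized gene symbols, embedded in a 1-depth citation corpus: seed
articles plus the references they cite. Two pair constructions are
extracted from such a corpus:

* **GG (explicit)**: every unordered pair of distinct genes appearing in
  one document contributes 1 per document. Counting is document-level —
  an abstract mentioning a gene five times contributes as if it mentioned
  it once, because the corpus model stores gene *sets* per abstract and
  within-abstract multiplicity is not observable at this level.
* **GCG (implicit)**: for every citation link, every unordered pair with
  one gene on the citing side and the other on the cited side contributes
  1 per link. Counting is binary per link: a pair realized by both
  orientations of the same link still counts once, which keeps GG and
  GCG weights on the same "number of supporting contexts" scale. Citation
  direction is ignored throughout — a citation indicates a topical
  relation, not a gene-to-gene direction. A gene appearing on both sides
  of a link forms no self-pair.

A pair co-occurring inside the citing document itself contributes to GG
only; GCG is strictly cross-document. Both extractors are invariant to
document and link order, and satisfy exact conservation identities
(total GG weight = Σ over documents of C(|genes|, 2); total GCG weight =
Σ over links of the link's distinct cross pairs) that the test suite
asserts against brute-force enumeration.

## Normalization

Entity recognition is out of scope; the package starts from raw mention
strings and a lexicon mapping mention → (preferred symbol, semantic
type, ontology-backed flag). A mention survives only if its semantic
type is `gene` or `genome` *and* it is ontology-backed — the conjunctive
reading of a two-stage vocabulary filter; synonyms collapsing to one
preferred symbol yield one set element. Gene identity everywhere is the
canonical uppercase symbol string.

## Network measures

Networks are weighted, undirected, with no self-loops. The five ranking
measures are degree, weighted degree (sum of incident co-occurrence
frequencies), closeness, betweenness, and PageRank.

Shortest-path measures run on the *unweighted skeleton* by default:
co-occurrence frequencies are similarities, not distances, so treating
them as edge lengths would invert their meaning. An `inverse_weight`
distance mode (length 1/weight) is available for closeness but off by
default. Closeness for a node `v` reaching `r` others is `r / Σ d(v, u)`
computed within `v`'s connected component, with no whole-graph
rescaling; isolated nodes score 0. Published closeness tables produced
by GUI network tools of the period print average-path-length-style
values that exceed 1; these raw values are not reproducible from the
formula above, so the packaged closeness fixture is used for set-level
aggregates (list overlap, category counts) only — its `value` column is
kept verbatim but never recomputed.

Betweenness is Brandes' algorithm, endpoints excluded, each unordered
pair counted once. PageRank treats each edge as two opposite arcs
carrying the edge weight and runs power iteration with damping 0.85 (the
conventional default; teleportation is uniform) to an L1 tolerance of
1e-10, erroring rather than returning a non-converged vector. All four
path/flow measures are property-tested against independent oracles
(Floyd–Warshall closeness, explicit path-counting betweenness, a dense
linear-system PageRank solve) on hundreds of random graphs of up to 8
nodes.

Top-`k` gene lists (default `k = 25`) optionally apply a minimum measure
value — by default 10, applied to degree, weighted degree and
betweenness, whose large tie groups at small values would otherwise
flood a truncated list; closeness and PageRank lists are unthresholded.
Ties always break lexicographically so every ranking is deterministic.

Communities come from weighted Louvain modularity (resolution 1, seeded
sweep order; the reported modularity is re-derivable from the partition
and adjacency, which a test asserts). The "combined measure" pair set
pools the five top-25 node lists and returns the network edges with both
endpoints in the pool — the edge-among-top-nodes reading of combining
rankings into pairs; it is one consistent interpretation of turning five
node lists into a pair set, recorded here as a design choice.

## Evaluation

The matching rate of a candidate pair set against an interaction
reference is `100 · |candidates ∩ reference| / |candidates|` after
canonicalization and deduplication. `gcg_only_pairs()` applies the
implicit-discovery filter: in GCG, absent from GG, present in the
reference, weight ≥ 100 (the default heavy-pair cut-off). The temporal
holdout builds both tables on documents with `year ≤ split_year` (links
kept only when both endpoints survive; undated documents are excluded
from the slice and counted), takes the GCG-only pairs, intersects with
the reference, and counts how many later appear in the full-corpus GG
table — implicit signals that became explicit. By construction the
GCG-only set is disjoint from early GG, and early GG is a subset of full
GG; both identities are asserted.

For rank agreement between the two networks' weights over common pairs,
Spearman's rho uses average ranks with the t-approximation p-value, and
refuses fewer than 3 common pairs.

## The synthetic corpus generator

The generator emulates the structural features the method depends on:
a heavy-tailed background of gene mentions, a seed-plus-references
citation skeleton with bibliographic reuse, and a planted set of true
interactions visible through two distinct channels.

* **Background**: each document draws `Poisson(λ)` i.i.d. mentions from
  a rank-Zipf distribution (`p_k ∝ k^-s`) over `n_genes` symbols, then
  deduplicates. Poisson thinning makes gene `g`'s presence Bernoulli
  with `q_g = 1 − exp(−λ p_g)`, independent across genes and documents —
  the key to exact closed-form expectations.
* **Citation skeleton**: each of `n_seed_docs` seeds cites
  `refs_per_seed` distinct references; each reference slot reuses an
  existing reference with probability 0.2, mimicking shared bibliography.
* **Planted truth**: `n_planted_pairs` vertex-disjoint pairs. Per
  document, a pair is co-injected with probability `p_within` (explicit
  channel); per link, with probability `p_cross` one gene goes to the
  citing and one to the cited side, side by fair coin (implicit
  channel). Vertex-disjointness keeps pair-level expectations from
  entangling and the recovery metric unambiguous.

`expected_pair_rates()` gives the closed forms
`E[GG] = n_docs (p_within + (1 − p_within) q_a q_b)` and
`E[GCG] = n_links (p_cross + (1 − p_cross)(2 q_a q_b − (q_a q_b)²))`,
which neglect presence inflation from cross-injection via *other* links
incident to a document; they are exact when `refs_per_seed = 1` with no
reference reuse and the untested channel switched off, which is exactly
how the Monte-Carlo agreement test (200 replicates, 3-standard-error
band) is configured.

### Why the defaults look the way they do

Defaults: 1000 seeds × 1 reference (reuse 0.2, so ≈ 1800 documents and
1000 links), 800 genes, `s = 1.8`, `λ = 1.5`, 25 planted pairs,
`p_within = p_cross = 0.3`. The injection rates are the regime in which
both channels are meant to be identifiable; the rest follows from an
identifiability condition. A rank-Zipf head is extremely heavy
(`p_1 ≈ 0.44` at `s = 1.8` regardless of `n_genes`), so the strongest
background GCG pair has per-link rate ≈ `2 q_1 q_2`, and pairs of the
head gene with a *planted* gene have rate ≈ `2 q_1 · π`, where `π` is
the planted gene's per-document presence — which grows with seed
out-degree (each incident link injects its gene with probability
`p_cross / 2`). For the planted signal `p_cross` to dominate, documents
must be mention-sparse (`λ = 1.5` gives `q_1 ≈ 0.48`; most documents
carry few or no background genes, as in real abstract collections,
where only about a third of articles carry any gene mention) and the
citation fan-out small (one reference per seed caps `π` at
`≈ p_cross / 2`). With these values the planted per-link rate 0.3 is
roughly double the strongest contaminant and recovery of the planted
pairs in the top-25 of either network is complete at the tested seeds.
Real corpora differ in ways the generator deliberately ignores — longer
reference lists, topical clustering of both genes and citations,
mention-level burstiness, and entity-recognition noise — so passing
recovery tests demonstrates correctness of the machinery under the
generative model, not performance on literature data.

## Numerical and degenerate-input choices

* Self-citations, duplicate links and dangling links are dropped at read
  time and counted, never erred on: the pairing concept requires two
  distinct resolvable articles.
* Documents with no genes (and undated documents, outside temporal
  splits) stay in the corpus; they simply contribute nothing.
* Empty pair tables: `build_network` returns an empty graph;
  `frequency_share` and `matching_rate` on empty input raise
  undefined-result errors rather than returning NaN.
* All rankings break ties lexicographically; all randomized routines
  (generator, Louvain sweep) take explicit integer seeds and restore the
  caller's RNG state, so equal configuration means byte-identical output
  — the pipeline report is tested for byte identity across reruns.
* PageRank scores are renormalized to sum to exactly 1 on return and
  conservation is asserted to 1e-9.

## Packaged fixtures and their aggregates

The three published top-25 tables (pair frequency with curation remarks,
weighted degree and closeness with dominant disease categories) ship as
commented TSV fixtures. Every printed aggregate derivable from them —
intersection/union of the pair lists, the count of common pairs heavier
on the GCG side, repository-reported and known-interaction percentages
(the latter crediting same-family and literature-confirmed pairs),
gene-list overlaps, and disease-category counts — is recomputed by
`pair_fixture_aggregates()` and `gene_list_aggregates()`; nothing is
hard-coded. One transcription normalization (DIO_2 → DIO2) and one
kept-first annotation (CHL1) are noted in the fixture headers; neither
affects any aggregate.

## Problem sizes

The test suite runs the oracle comparisons on 500+ random graphs of ≤ 8
nodes, conservation identities on dozens of random corpora, Monte-Carlo
expectation checks on 400 small simulated corpora, and recovery and
determinism checks on corpora of roughly 1,800 documents — sizes at
which every statistical property is already stable and the whole suite
completes in well under a minute.

## Known limitations

* The generator's citation skeleton is bipartite (seeds cite references,
  references cite nothing), a strict 1-depth structure; chains and
  co-citation are out of scope.
* Disease annotation uses only each gene's dominant category, as in the
  packaged fixtures; full per-gene category profiles are supported by
  the map format but not exploited beyond cluster labeling.
* Interaction-reference matching ignores interaction type and throughput
  metadata.
* The published raw closeness values are not reproducible from a
  documented formula (see above) and are deliberately not targeted.
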