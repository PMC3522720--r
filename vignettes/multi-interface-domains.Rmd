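---
title: "Mining structural fingerprints of multi-interface protein domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining structural fingerprints of multi-interface protein domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miDomains)
```

## The problem

Some protein domains present several distinct binding sites to different
partners: the same domain surface hosts one interface for partner B and a
second, spatially separate interface for partner C. Such *multi-interface
domains* act as hubs in domain–domain interaction networks, and their
individual interfaces usually carry different molecular functions. The
question this package addresses is how to find those domains in a
collection of multi-chain crystal structures, how to characterise each
binding site by recurring residue-contact patterns (*fingerprints*), and
how to quantify the relations between a domain's sites: which patterns are
unique to one site, which co-occur across sites of the same protein, and
whether fingerprints differ between domains more than chance would allow.

## The pipeline

The analysis runs in seven stages, each exposed as ordinary functions and
orchestrated by `runPipeline()`:

1. **Preprocess** (`readComplex()`, `filterComplexes()`). Structures are
   kept when they are X-ray entries with resolution strictly better than
   3.0 Å ("better" read literally as smaller; configurable). Within each
   biological unit, chains carrying a non-identity transformation matrix
   in the assembly definition are removed rather than transformed —
   applying the matrix would be an alternative, but deposited transformed
   chains are rare and removal keeps coordinate provenance simple. Chains
   shorter than 30 residues are removed, then chains left without any
   interaction partner (no heavy atom within 5 Å of another surviving
   chain of the same unit, iterated to a fixed point), and finally units
   with fewer than two chains. Chain length counts residues with at least
   one heavy atom, which is exactly what the geometry stages can use.

2. **Cluster** (`alignChainPair()`, `buildChainClusters()`). Instances of
   the same protein chain across entries are grouped by local
   Smith–Waterman alignment (BLOSUM62, gap open 11 / extend 1) with
   similarity defined as identical aligned residues over the *aligned*
   length, so a shared domain inside a longer multi-domain chain still
   counts as identical. Pairs at or above 0.975 (mutation rate ≤ 2.5%)
   become edges; connected components are the clusters. Single-linkage
   chaining is accepted, and the per-cluster minimum pairwise similarity
   is reported as a diagnostic rather than enforced.

3. **Interfaces** (`detectInterfaces()`, `centerStarMSA()`,
   `mapInterfaces()`, `dedupInterfaces()`, `clusterBindingSites()`). An
   interface residue has at least one heavy atom within 5 Å (inclusive)
   of a partner chain's heavy atom; chain pairs in different biological
   units are never considered. Within a cluster, residue positions are
   made comparable through a center-star multiple alignment — the center
   is the member minimising summed alignment distance, and member
   insertions are right-aligned within merged gap runs. Because cluster
   members are ≥ 97.5% identical the center-star alignment is nearly
   trivial, which is why no external MSA program is needed. Interface
   similarity is the count of identical (column, residue type) pairs over
   the smaller interface; pairs at or above 0.8 are merged and each
   connected component keeps the representative from the best-resolution
   entry (ties: first encountered). Representatives are then remapped
   onto the cluster's single best-resolution chain. Binding sites are
   single-linkage components of the representatives at similarity ≥ 0.5.
   Using alignment-column similarity as a stand-in for spatial similarity
   is a deliberate simplification: within a cluster the chains are
   near-identical, so sequence position is a faithful proxy for position
   in space.

4. **Graphs** (`delaunayAtomEdges()`, `buildInterfaceGraph()`). Heavy
   atoms of the host chain's surface residues are tessellated (3D
   Delaunay, implemented as an incremental Bowyer–Watson construction and
   validated against an exhaustive empty-circumsphere oracle in the test
   suite); only tessellation edges of length ≤ 5 Å survive. Atom contacts
   within one residue are ignored and multiple atom contacts between two
   residues merge into a single edge — connectivity is recorded, not
   contact multiplicity. Nodes are the interface's residues labeled by
   amino-acid type (Kyte–Doolittle hydropathy is attached for plotting
   but never used as a mining label); non-standard residues map to X and
   are excluded so that the label alphabet stays at 20 letters.

5. **Mine** (`supportThreshold()`, `mineClosedFrequent()`). All interface
   graphs of one binding site form a graph database. The support of a
   connected labeled pattern is the number of database graphs containing
   it under subgraph *monomorphism* (label-preserving injection, host may
   have extra edges), counted once per graph. The threshold is 20% of the
   database size, rounded up and floored at 2. Only *closed* patterns are
   reported: no extension by one edge, or one node plus an edge, has the
   same support — for connected pattern languages this one-step check is
   equivalent to full closedness. The miner grows patterns breadth-first
   along embeddings actually present in the database and de-duplicates by
   canonical code. "Non-trivial" fingerprints are flagged as those with
   at least two edges; single-node and single-edge patterns are mined but
   marked trivial in `fingerprintIndex()`.

6. **Relations** (`buildTransactions()`, `mineClosedItemsets()`,
   `cooperativePairs()`, `distinctiveFingerprints()`,
   `functionAssociation()`). Fingerprint occurrences are re-encoded as
   transactions (one per fingerprint, items = interfaces containing it)
   and closed frequent itemsets are mined with an LCM-style closure
   search for multi-way co-occurrence reporting. Cooperative pairs are
   additionally quantified at the protein level — the fraction of
   proteins possessing both sites in which both fingerprints occur —
   because that is the quantity a practitioner asks about ("this pattern
   pair is present in two thirds of the proteins"). Distinctive
   fingerprints of a site have no label-isomorphic counterpart among
   other sites' fingerprints *and* never occur in other sites' graphs.
   Function labels are consumed from an input table, never inferred.

7. **Stats** (`countIsomorphicPairs()`, `randomNullPvalue()`,
   `degreeAssortativity()`, `labelAssortativity()`, `compareDomains()`,
   `subsampleDisparity()`). Isomorphism counts between two sites'
   fingerprint sets are referred to a random-graph null: per replicate,
   each fingerprint is replaced by a random connected graph of the same
   node and edge count (a random spanning tree plus uniformly drawn extra
   edges) with labels drawn i.i.d. from the database's amino-acid
   frequencies; the p-value is the fraction of replicates reaching the
   observed count, reported as "< 1/n_reps" when none does. The default
   of 2000 replicates makes the smallest reportable p-value 5.0e-4.
   Between-domain comparisons use two-sided Welch t-tests on the
   per-fingerprint degree and label assortativity (undefined values —
   regular graphs, single-label graphs — are dropped with counts logged).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| contact cutoff | 5.0 Å (inclusive) | heavy-atom distance defining both interface residues and residue contacts |
| resolution bound | < 3.0 Å | X-ray entries only |
| minimum chain length | 30 residues | with ≥ 1 heavy atom |
| cluster similarity | ≥ 0.975 | mutation rate ≤ 2.5% over the aligned region |
| dedup similarity | ≥ 0.8 | interface duplicate threshold |
| site threshold | ≥ 0.5 | single-linkage binding-site clustering |
| local support | 20% | support threshold = ceil(0.2 · |DB|), floored at 2 |
| null replicates | 2000 | smallest reportable p = 5.0e-4 |
| surface criterion | RSA ≥ 5% | Shrake–Rupley, Tien et al. max-ASA normalisation; `"all"` fallback |

All cutoff comparisons are inclusive, following the definitions ("within
5 Å", "equal to or larger than 0.8"). Alignment columns are 0-free:
columns are 1-based everywhere in file outputs.

## Numerical and design choices

- **Delaunay degeneracies.** Tessellation of fewer than four points, or a
  collinear/coplanar set (detected by a singular-value threshold), falls
  back to the complete graph, leaving the 5 Å cutoff as the only contact
  criterion — the cutoff is the physical constraint, the tessellation
  only sparsifies it. Cospherical ties are broken by a deterministic
  jitter of 1e-9 Å, far below the 1e-3 Å round-trip tolerance of the
  coordinate format; the test suite checks rigid-motion invariance of the
  resulting graphs.
- **Canonical codes.** Label-isomorphism classes are identified by a
  canonical vertex labeling (BLISS, with residue labels as vertex
  colors) serialised to a string, rather than a hand-rolled minimum DFS
  code. Code equality ⇔ labeled isomorphism is property-tested against an
  exhaustive permutation oracle up to 8 nodes. This choice reuses a
  vetted canonicaliser, is exact at every size the pipeline produces, and
  keeps `isIsomorphic()` a pure string comparison.
- **Embedding caps.** Extension enumeration walks all embeddings of a
  pattern in each occurrence graph, capped at 5000 per (pattern, graph)
  to bound pathological automorphism blow-up; the cap is never reached on
  sparse, label-diverse interface graphs.
- **Ties.** Alignment ties follow `pairwiseAlignment`'s deterministic
  choice; representative ties go to the first interface in input order;
  cluster ids and site ids are numbered by first appearance. Mining
  output is sorted (nodes desc, edges desc, support desc, code), making
  every stage reproducible byte for byte.
- **Obligate vs transient.** Whether an interaction is an oligomer
  (permanent) or a complex (transient) is consumed as an input flag
  (`classifyInteraction()`); predicting interaction permanence is a
  separate problem this package does not re-solve. Interactions without a
  flag are labeled "unknown" and excluded from preference counts.
- **Disparity p-value.** `subsampleDisparity()` refers the mean
  cross-domain isomorphism count of k-sized resamples to the pooled
  within-domain resampling distribution and reports a two-sided,
  add-one-smoothed p-value. Two-sided is the conservative reading:
  identical sets then give p ≈ 1 and topologically disjoint sets an
  extreme p, which is the behaviour the statistic's sanity checks pin
  down.

## The synthetic generator

`generateComplex()`, `generateClusterCohort()` and `generateGraphDB()`
produce every input the pipeline needs without downloads.

Chains are idealized extended traces: Cα atoms at 3.8 Å steps along
separated lanes with one pseudo-side-chain atom per residue, self-avoiding
with a 3 Å clash check. Planned interface segments are routed to 4.2 Å of
their partner segment; every unplanned inter-chain residue pair stays
above 5.5 Å, so detection at the 5 Å cutoff recovers exactly the planted
residue sets. Cohorts apply exactly `round(rate · length)` interior
substitutions per chain per copy (the first copy stays unmutated), which
realises the stated mutation rate deterministically: at the 2% default
every copy keeps similarity ≥ 0.975 to the base copy and the planted
single-linkage cluster is always recovered, while 10% splits the cohort —
both regimes are asserted in the tests. Resolutions are drawn without
ties from a 0.05 Å grid, so the planted best-resolution representative is
unique. Graph databases embed planted motifs disjointly and attach them
by a single bridge edge, guaranteeing `subgraphOccurs()` on the receiving
graphs; backgrounds are random connected graphs with roughly 1.2 edges
per node over a uniform 20-letter alphabet.

What the generator does **not** emulate: real stereochemistry (bond
angles, side-chain packing), crystallographic artifacts, sequence
composition bias, or structurally divergent interfaces within a cluster.
Passing the end-to-end recovery tests therefore shows that the pipeline's
logic is correct under its own definitions, not that those definitions
are optimal for any particular real complex.

Problem sizes in the shipped tests and acceptance checks are chosen to
keep every oracle exhaustive: mining is cross-checked against brute-force
enumeration on databases of up to 5 graphs of up to 6 nodes (200 random
databases), itemset mining against power-set enumeration on up to 10
items (100 databases), the tessellation against the O(n⁴) circumsphere
oracle on 5–8 atom configurations (50 draws), motif recovery over 50
seeded simulations, and the full pipeline on cohorts of 3–5 entries with
2–5 chains of 40 residues.

## Worked example

```{r example, eval = FALSE}
library(miDomains)

## a 5-entry cohort of a two-site hub protein with two partners per site
plan <- list(
  list(host = "A", partner = "B", host_range = 6:13,  partner_range = 6:13),
  list(host = "A", partner = "C", host_range = 10:17, partner_range = 10:17),
  list(host = "A", partner = "D", host_range = 24:31, partner_range = 24:31),
  list(host = "A", partner = "E", host_range = 28:35, partner_range = 28:35))
co <- generateClusterCohort(
  complexSpec(nChains = 5, chainLength = 40, interfacePlan = plan,
              seed = 3),
  nCopies = 4, seed = 11)
dir.create("structures")
for (e in names(co$complexes))
  writeComplexPDB(co$complexes[[e]], file.path("structures",
                                               paste0(e, ".pdb")))

cfg <- pipelineConfig("structures", "out", nullReps = 200, seed = 7)
runPipeline(cfg)
```

## Known limitations

- Input is PDB format only; mmCIF is not read.
- Binding-site clustering uses alignment-column similarity, not a
  structural superposition; across-cluster (same-domain, different
  protein) site pooling therefore requires caller-provided domain
  annotations and shared numbering.
- The surface-residue criterion (RSA ≥ 5%) is a reconstruction; the
  `"all"` mode sidesteps it where solvent accessibility is not
  meaningful, as for the cartoon-geometry synthetic chains.
- Closed-set mining is exact but exponential in the worst case; it is
  intended for the sparse, label-diverse graphs interfaces produce, not
  for dense near-unlabeled graphs.
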