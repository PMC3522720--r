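# miDomains

Structural analysis of **multi-interface protein domains** — domains that
present two or more distinguishable binding sites to different partners.
From a directory of multi-chain crystal structures, the package

- filters entries and chains (X-ray, resolution < 3.0 Å, chain length
  ≥ 30, biological-unit membership, identity transforms only, at least
  one interaction partner);
- clusters near-identical chains across entries by Smith–Waterman local
  alignment (similarity = identical aligned residues / aligned length,
  edge at ≥ 0.975, single-linkage components);
- detects interface residues at a 5 Å heavy-atom cutoff, maps them
  through a per-cluster center-star multiple alignment, de-duplicates
  similar interfaces (similarity ≥ 0.8, best-resolution representative)
  and groups representatives into binding sites;
- builds residue contact graphs as the intersection of the 3D Delaunay
  tessellation of heavy atoms with the 5 Å cutoff, merging multiple atom
  contacts between two residues into one edge;
- mines **closed frequent subgraphs** ("fingerprints") per binding site:
  connected amino-acid-labeled patterns occurring in at least
  `ceil(0.20 · |DB|)` database graphs (transaction support, subgraph
  monomorphism) with no equal-support one-step extension;
- derives relations between sites: cooperative fingerprint pairs
  (protein-level co-occurrence plus an LCM-style closed-itemset view),
  distinctive fingerprints, isomorphism counts with random-graph null
  p-values, and between-domain Welch t-tests on fingerprint degree/label
  assortativity.

The statistic behind the headline summary is the per-type preference of
multi-interface interactions,

```
preference_t = (n_multi_t / n_all_t) / (Σ_t n_multi_t / Σ_t n_all_t),
```

the enrichment of interaction type *t* (homo-/hetero-oligomer/complex)
among interactions involving multi-interface proteins over its background
share.

A synthetic-structure generator (`generateComplex()`,
`generateClusterCohort()`, `generateGraphDB()`) produces multi-chain
complexes with planted interfaces, near-identical chain cohorts at a
controlled mutation rate, and labeled graph databases with planted
motifs, so the entire pipeline runs and is tested without any downloads.

## Worked example

```r
library(miDomains)

## a 4-entry cohort of a two-site hub protein (sites built from two
## overlapping partner interfaces each)
plan <- list(
  list(host = "A", partner = "B", host_range = 6:13,  partner_range = 6:13),
  list(host = "A", partner = "C", host_range = 10:17, partner_range = 10:17),
  list(host = "A", partner = "D", host_range = 24:31, partner_range = 24:31),
  list(host = "A", partner = "E", host_range = 28:35, partner_range = 28:35))
co <- generateClusterCohort(
  complexSpec(nChains = 5, chainLength = 40, interfacePlan = plan, seed = 3),
  nCopies = 4, seed = 11)
dir.create("structures")
for (e in names(co$complexes))
  writeComplexPDB(co$complexes[[e]], file.path("structures", paste0(e, ".pdb")))

m <- runPipeline(pipelineConfig("structures", "out", nullReps = 100, seed = 7))
str(m$stages$stats)
```

which prints

```
List of 6
 $ n_entries                 : int 4
 $ n_chains                  : int 20
 $ n_clusters                : int 5
 $ n_multi_interface_proteins: int 1
 $ site_histogram            :'data.frame':  1 obs. of  2 variables:
  ..$ n_interfaces: int 2
  ..$ n_proteins  : int 1
 $ seed                      : int 7
```

— the four entries contribute 20 chain instances grouped into 5 clusters
(one per distinct protein); the hub chain A is the single multi-interface
protein, carrying 2 binding sites (the overlapping B/C and D/E interface
pairs each merge into one site). `out/` then holds the chain manifest,
cluster tables, interface table, contact graphs, mined fingerprints with
their canonical codes and supports, cooperative/isomorphism relation
tables and a JSON stats report; `out/run_manifest.json` records config,
input checksums and seeds, and a rerun with the same config is
byte-identical.

Preference from published interaction counts:

```r
computePreference(data.frame(
  type   = c("homo-oligomer", "homo-complex", "hetero-oligomer", "hetero-complex"),
  n_all  = c(647, 13, 38, 6695),
  n_multi = c(127, 3, 4, 890)))
#>              type n_all n_multi preference
#> 1   homo-oligomer   647     127       1.42
#> 2    homo-complex    13       3       1.67
#> 3 hetero-oligomer    38       4       0.76
#> 4  hetero-complex  6695     890       0.96
```

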