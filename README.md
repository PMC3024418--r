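# HaploPop

Haplotype-based population genetics for plastid spacer alignments.

Plastid intergenic spacers (here the *trnS*–*trnG* spacer and the
*trnL*–*trnF* region) are effectively haploid and non-recombining, so every
individual carries a single haplotype defined by the joint states of all
mutational events in the alignment: point substitutions, insertion/deletion
events (each unique gap span treated as one unordered event, up to tens of
base pairs), and microsatellite repeat-count changes (e.g. a TA dinucleotide
varying between 6 and 15 repeats). HaploPop takes pre-aligned regions plus a
sample-to-population map and carries that event model through a complete
comparative analysis, of the kind used to ask whether an island endemic
sampled as a single population (n = 54) is more or less diverse than a
continental relative sampled as five populations (n = 100):

* **Variant scan and haplotype calling** — a typed event catalog
  (substitution / indel / microsatellite) with 1-based alignment
  coordinates; individuals collapse to haplotypes by event-state identity;
  sharing summaries between species.
* **Diversity** — Nei's unbiased haplotype diversity
  *h* = n(1 − Σp²)/(n − 1) with its sampling variance, nucleotide diversity
  π (per counted site, substitution columns only) with Nei's variance,
  individual-based (Hurlbert) rarefaction of haplotype richness with Heck
  SEs, one-sample *t* comparisons, and the expected waiting time for a
  single substitution, 1/(μL).
* **Structure** — Hudson's nearest-neighbour statistic Snn with an exact or
  Monte-Carlo permutation test over any grouping of the sample map.
* **Neutrality** — Tajima's D, Fu & Li's D\* and F\* (no outgroup, corrected
  variance coefficients), p-values by beta approximation (D) or fixed-S
  coalescent simulation (D\*/F\*), and the observed mismatch distribution.
* **Genealogical network** — statistical parsimony: a probabilistic
  connection limit at a chosen confidence, then a minimum-spanning network
  retaining all co-minimal edges, built under the constraint that
  substitutions are homoplasy-free (single origin) while indels and
  microsatellites may recur; median nodes for multi-step edges; GraphML/DOT
  export.
* **Parsimony** — simple indel coding (unique spans as binary characters,
  containment scored missing), Fitch lengths, the Σmᵢ lower bound with
  optimality certification, CI / CI excluding uninformative characters /
  RI, and a random-addition + leaf-SPR heuristic search with exhaustive
  search for small matrices.
* **Synthetic data** — a structured-coalescent generator for the
  island/mainland two-species design with full truth records (genealogy,
  true events, true haplotypes, realized h and π), so the entire pipeline
  is testable end to end with known answers.

The central objects are S4: `AlignmentSet` (multi-region alignments),
`VariantCatalog`, `HaplotypeTable` (a `SummarizedExperiment` of
haplotype × population counts), `HaploNetwork` (an igraph-backed network)
and `CharacterMatrix`.

## Worked example

A simulated island/mainland dataset with the packaged study design, run
through the main stages:

```r
library(HaploPop)

sim <- simulateIslandMainland(42)          # two regions, 54 + 5x20 samples
catalog <- scanVariableSites(sim$aln, sim$microsat)
catalog
#> VariantCatalog: 8 events (7 substitutions, 0 indels, 1 microsatellites) over 1559 columns

ht <- callHaplotypes(catalog, sim$map)
div <- diversityReport(ht, sim$aln)
div[div$level == "species_pooled", ]
#>            level       group   n S_obs     h   h_sd       pi    pi_sd
#> 7 species_pooled   island_sp  54     5 0.359 0.0804 2.96e-04 0.000295
#> 8 species_pooled mainland_sp 100     4 0.116 0.0436 7.74e-05 0.000136

idm <- individualDistanceMatrix(ht, grouping = "species")
snnTest(idm$d, idm$localities, K = 999, seed = 42)[c("snn", "p")]
#> $snn
#> [1] 0.9616498
#> $p
#> [1] 0.001

buildHaploNetwork(ht)
#> HaploNetwork: 8 haplotypes, 1 median nodes, 8 edges; limit 12 steps (95%), constraint 'substitutions'
```

Reading the numbers: this replicate realized 8 events collapsing 154
individuals into 8 haplotypes; the island sample is the more diverse
(h = 0.359 ± 0.080 vs 0.116 ± 0.044; π about four-fold higher), Snn = 0.96
with p = 0.001 says individuals' nearest neighbours are almost always
conspecific (strong between-species structure), and all haplotypes connect
into one network at the 95% connection limit of 12 steps for a 1559-column
alignment. Because a non-recombining locus is a single genealogical draw,
individual replicates vary widely around the design's expectations
(island h ≈ 0.70 on average); `simulateIslandMainland()$truth` carries each
replicate's realized truth for comparison.

Real data enter the same way via `readAlignment()` (FASTA / NEXUS / relaxed
PHYLIP), `concatenateRegions()` and `readSampleMap()` (3-column TSV), with
microsatellite windows declared by `microsatWindow()`. `runPipeline()`
orchestrates every stage and writes per-stage tables plus a JSON report.

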