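---
title: "Methods: haplotype-based population genetics of plastid spacers"
author: "HaploPop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based population genetics of plastid spacers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HaploPop)
```

HaploPop analyzes pre-aligned, non-recombining (plastid) intergenic spacers
sampled from one or more populations. The haploid, non-recombining setting
means every individual carries a single haplotype defined jointly by all
mutational events in the alignment, and every statistic downstream is a
function of the haplotype partition and the per-site differences. This
vignette records the models, the tunable parameters, and the numerical and
design choices behind each stage.

## The event model

A `VariantCatalog` assigns every polymorphic column to exactly one typed
event:

* **Substitutions** occupy one column each; the per-sample state is the base
  (a gap or `N` at that column leaves the state unresolved for that sample).
* **Indels** are contiguous gap runs. Two gap runs are the *same* event iff
  they share both endpoints; nested or overlapping runs with different
  endpoints are distinct events. This "single, unordered event" treatment is
  what makes simple indel coding and single-step network edges well defined:
  a 43-bp deletion is one event, not 43. A taxon whose own gap strictly
  contains another's span cannot be scored for the contained event and is
  recorded as missing.
* **Microsatellites** are declared column windows (e.g. a TA repeat between
  region-local columns 381 and 410) whose per-sample state is the maximal
  tandem repeat count of the motif in the ungapped window. A repeat-count
  difference is one event regardless of magnitude by default (a stepwise
  option exists for distance computations). Auto-detection (runs of a 2-mer
  with at least 4 repeats) is available but off by default, because window
  boundaries in real alignments are an alignment-editorial decision.

Two individuals share a haplotype iff their event-state vectors are
identical. Individuals with an `N` inside any event are reported as
ambiguous and excluded from counts, never silently dropped. Haplotype IDs
are assigned by first occurrence in sample order, so the labelling is
deterministic and invariant to region order.

Coordinates are 1-based alignment columns throughout; region-local and
concatenated coordinates interconvert through recorded region offsets.

## Diversity

Haplotype (gene) diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}\,(1 - \sum_i p_i^2)$ with its sampling variance
$V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 - (\sum p_i^2)^2\right]
+ \sum p_i^2 - (\sum p_i^2)^2\right\}$; $h$ equals the probability that two
individuals drawn without replacement differ, which is how the test suite
verifies it by enumeration.

Nucleotide diversity $\pi$ is the mean number of pairwise differences per
counted site. Counted sites exclude microsatellite windows and indel spans,
and any column that is not pure `A/C/G/T` in the analyzed samples (complete
deletion). Counting substitution columns only is the standard convention
for a per-site quantity when indels are treated as single events of
arbitrary span; an option to add indel events as single differences exists
in the distance metric used for the network and the Snn test, where events,
not sites, are the natural unit. The reported SD is the square root of
Nei's total (stochastic plus sampling) variance,
$V(\pi)=\frac{n+1}{3(n-1)}\frac{\pi}{L}+\frac{2(n^2+n+3)}{9n(n-1)}\pi^2$,
matching what the field's standard software prints alongside $\pi$.

Display convention: $h$ to 3 decimals and $\pi$ to 5 in the written
reports; full precision is retained in every returned object.

Species-level summaries are computed **both** pooled over populations and
as per-population values (for the one-sample *t* comparison), and labelled
explicitly — the two differ whenever populations are differentiated, and
conflating them is a common source of irreproducible "species h" values.

Rarefaction of haplotype richness is individual-based (Hurlbert):
$E[S(n')] = \sum_i \left[1 - \binom{N-N_i}{n'}\big/\binom{N}{n'}\right]$,
with the Heck et al. variance and normal-approximation intervals at 95% and
99%. The implementation delegates to `vegan::rarefy`; the suite checks it
against exhaustive subsample enumeration for $N \le 10$. The default
standardized sample size is $n' = 50$, appropriate for comparing a
single-population island sample ($n = 54$) against a pooled mainland sample
($n = 100$).

## Geographic structure: Hudson's Snn

For each individual, its nearest neighbours are all other individuals at
minimal event distance; the per-individual score is the fraction of those
neighbours from the same locality (ties contribute fractionally), and Snn
is the mean score. Localities are any grouping column of the sample map —
the test is run both among populations within a species and between
species; the package never guesses the grouping.

Significance comes from random reassignment of locality labels preserving
locality sizes. When the number of distinct label arrangements is at most
10,000 the test enumerates all of them and reports an exact fraction;
otherwise it uses Monte-Carlo permutations (default $K = 1000$) with a
recorded seed and the $(1 + \#\{\ge\})/(K+1)$ estimator, which can never
return exactly zero — a deliberate divergence from software that prints
"p = 0.0000".

## Neutrality tests

From the masked substitution columns the package computes $S$, total
mutations $\eta$, singletons $\eta_s$ (a variant carried by exactly one
sequence — without an outgroup, derived and ancestral singletons are
indistinguishable), and the mean pairwise difference $\bar k$. Tajima's D
follows the 1989 constants; Fu & Li's D* and F* use the corrected
(post-erratum) variance coefficients as adopted by the standard
implementations. Both are flagged "not evaluable" rather than computed when
$S = 0$.

For significance, Tajima's D uses the beta approximation over its
theoretical range $[D_{\min}, D_{\max}]$. For D*/F* no closed-form null is
usable, and printed critical-value tables are a transcription hazard, so the
package simulates the fixed-$S$ coalescent null (trees from the Kingman
coalescent, exactly $S$ mutations placed proportionally to branch length)
and reports empirical two-sided p-values. The acceptance suite verifies the
whole chain by measuring realized type-I error on 2,000 neutral replicates
(target 5%, accepted 2–8%).

The mismatch analysis reports the observed histogram of pairwise
differences only; fitting an expansion model to it is out of scope.

## The statistical-parsimony network

The connection limit is the largest step count $j$ whose parsimony
probability reaches the confidence level (default 0.95). The parsimony
probability asks: given that two sequences of $m$ sites visibly differ at
$j$ sites, what is the probability they are separated by exactly $j$
mutations? We model the unknown mutation count with the geometric
distribution implied by the pairwise coalescent (mean set to $j$, the
pairwise moment estimate of $\theta$), and the visible-difference count as
a Markov chain in which a mutation hitting a matching site always creates a
difference and one hitting a differing site reverts it with probability
1/3. The posterior probability of "no superimposed hits" reproduces the
expected qualitative behaviour of statistical-parsimony software — roughly
ten steps at ~600 bp and about 12 at 1559 bp at 95% — and is verified
against a second, independently coded transcription of the same model. A
fixed integer override is accepted, since published analyses rarely state
the realized limit.

Construction is a minimum-spanning network: candidate haplotype pairs are
processed in nondecreasing event distance; at each distance level every
pair not already connected at a smaller distance is eligible, and **all**
co-minimal alternatives are retained, so the result is a network, not an
arbitrarily tie-broken tree, and output is order-independent. Under the
default constraint an edge is skipped if any substitution event on it
(same event, same unordered state pair) already labels an accepted edge —
substitutions are assumed homoplasy-free and must have a single origin —
while indel and microsatellite events may recur freely. Multi-step edges
materialize intermediate median (unsampled) nodes so rendered step counts
match standard network figures. Haplotypes farther than the limit from
every connected component are reported as separate subnetworks.

## Parsimony analysis

Simple indel coding turns each unique gap span into a binary
presence/absence character, with strictly containing gaps scored as
missing. The character matrix holds the variable nucleotide columns (gaps
and `N` as missing) plus, in SIC mode, the appended binary block; each
character carries its minimum steps $m_i$ (observed states − 1) and maximum
steps $g_i$ (non-missing taxa − modal state count).

Scoring is Fitch optimization over bitmask state sets; missing data are the
full state set and force no steps. $\sum m_i$ is a universal lower bound on
tree length, so a search that attains it has **certified** the global
optimum and CI = 1 without enumeration. Indices: CI $= \sum m_i / \sum s_i$
over variable characters, CI excluding parsimony-uninformative characters,
and RI $= (\sum g_i - \sum s_i)/(\sum g_i - \sum m_i)$, flagged undefined
when $\sum g = \sum m$.

The heuristic search uses random stepwise addition followed by
leaf-reinsertion (leaf-SPR) hill climbing, repeated across random addition
orders, stopping early on bound attainment. We chose leaf moves over full
TBR because, at the matrix sizes this package targets (a few dozen
haplotypes with mostly compatible characters), bound certification and
multiple starts already identify the optimum — the suite checks equality
with exhaustive topology enumeration at 5 taxa and with the Fitch oracle at
6 — and the implementation stays simple enough to verify. Distinct best
trees are counted by canonical newick form up to a configurable cap
(default 10,000). An outgroup, when present in the matrix, is used only for
display rooting; all scores are computed on unrooted topologies.

## The synthetic-data generator

`simulateIslandMainland()` emulates a two-species sampling design: one
island species sampled as a single population of 54, and one mainland
species sampled as five populations of 20. The genealogy is a structured
Kingman coalescent with no migration (plastid DNA): five mainland demes
merge into a mainland ancestor at $t = 0.15$, which meets the island deme
in a common ancestral population at $t = 0.8$ (times in units of the
reference deme size). Mutations are placed on branches proportionally to
length: substitutions on unique free columns (infinite sites),
indels as single non-overlapping spans of 1–43 bp (rejection-sampled so
simple indel coding stays unambiguous; a nested-span mode exists to
exercise the missing-data rule), and a TA microsatellite performing ±1
steps clamped to 6–15 repeats but recorded as repeat counts, so downstream
single-event coding is exact.

The default deme sizes (island 6, mainland demes 0.4, ancestor 2.5) and
event rates (substitution 0.175, indel 0.06, microsatellite 0.12 per
lineage per unit time) were chosen so the preset's expectations match the
field situation the design emulates: island $h \approx 0.70$ and $\pi
\approx 7\times10^{-4}$ versus pooled mainland $h \approx 0.33$ and $\pi
\approx 2\times10^{-4}$, roughly ten substitution events per dataset, and
ancestral haplotypes shared across species through incomplete lineage
sorting in most replicates. The island's diversity excess is driven by its
larger effective size and by retention of ancestral polymorphism, not by
migration. Under these conditions the island sample shows higher $h$ than
the mainland sample in about 94% of replicates, and at least one haplotype
is shared between species in about 88% — both measured over hundreds of
replicates during development and asserted (with margins) in the test
suite. With equal deme sizes and the mainland substructure removed the
contrast disappears (the island "wins" about half the time), which the
suite uses as a null check on the design itself.

The truth record keeps the genealogy, the realized event list, the true
per-individual haplotype partition and the *realized* (sample-level) $h$
and $\pi$, so estimator-recovery tests are exact-target: when haplotype
calling is correct, $\hat h$ equals the truth value identically rather than
asymptotically.

What the generator does **not** emulate: sequencing error and base
ambiguity beyond clean `N`s, alignment uncertainty (inputs are emitted
pre-aligned), microsatellite interruption or motif turnover,
recombination, selection, and migration after the species split. Passing
tests on synthetic data therefore validate the statistical machinery and
bookkeeping, not robustness to alignment or base-calling artifacts in real
data.

## Numerical and degenerate-input choices

* Monomorphic input propagates cleanly: an empty catalog, one haplotype,
  $h = \pi = 0$, neutrality statistics flagged rather than NaN, a
  single-node network, and an empty parsimony matrix.
* $n < 2$ for $h$, zero countable sites for $\pi$, a single locality for
  Snn, and a sample/taxon mismatch for Fitch are errors, not warnings.
* Exact enumeration replaces Monte-Carlo wherever it is affordable
  (Snn label arrangements ≤ 10,000; parsimony bound certification).
* All Monte-Carlo paths (permutation test, simulation p-values, searches,
  the generator) take an explicit seed and record it in their results; the
  pipeline reuses one seed for every stage so reruns are byte-identical.
* Problem sizes in the shipped tests were chosen to keep the full suite
  near five minutes: 2,000 replicates for the statistical-calibration
  checks, 200 for preset recovery, exhaustive oracles capped at $n \le 8$
  (diversity), $N \le 10$ (rarefaction), 6 leaves (Fitch) and 15
  topologies (search).

## Known limitations

* The per-site neutrality machinery assumes the substitution-only site
  mask; datasets whose variation is mostly indels or repeat-count changes
  will show small $S$ and weak tests even when haplotype structure is rich.
* The connection-limit model is a principled reconstruction of the
  statistical-parsimony probability, not a line-by-line transcription of
  any particular program; limits may differ by a step from other software
  at the same confidence.
* The search is not a full TBR implementation; for matrices far larger or
  far more homoplasic than this package's scope, a dedicated phylogenetics
  engine is the right tool.
* One non-recombining locus is one genealogical draw: single-dataset
  diversity contrasts have large variance (the preset's ~94% win rate, not
  100%, is the honest version of this fact).
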