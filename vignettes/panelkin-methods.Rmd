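---
title: "Methods: comparing a resequenced accession against a chip-genotyped panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing a resequenced accession against a chip-genotyped panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelkin)
```

## The problem

Germplasm collections are routinely genotyped on SNP arrays, while newly
collected accessions are increasingly characterized by low-coverage whole-genome
resequencing. The two data types do not meet naturally: the array reports one
IUPAC character per locus for thousands of accessions, the resequencing run
yields a consensus genome sequence for one. `panelkin` bridges them with a
simple idea used in crop genomics: locate each array probe on the consensus
genome, read off the base at the probe's SNP position, and concatenate those
bases — in the panel's fixed locus order — into a *pseudomolecule*, a synthetic
sequence with one character per locus. The query accession then becomes one
more row of the genotype matrix and can be compared with sequence-style tools:
pairwise distances, a neighbor-joining tree with bootstrap supports, and an
identity-by-state duplicate screen.

A parallel phenotypic placement uses the CPVO/UPOV morphological descriptors
(ordinal scores such as growth habit or glaucosity classes) summarized by PCA.

## Probe placement

Array probes are 50–100 bp of flanking sequence around a SNP. `place_all()`
finds each probe on the genome by **exact k-mer seeding** (default `k = 21`):
every k-mer of the probe is looked up in a hash index of the genome, on both
strands, and each candidate location is scored by **ungapped full-length
identity**. A genome `N` never counts as a match. Locations with identity at
least `min_identity` (default 0.95) are kept; one maximal location makes the
probe `unique`, several equally good ones make it `ambiguous`, none make it
`unplaced`.

Three consequences of this design are worth spelling out:

* *Ties are never broken arbitrarily.* An ambiguous probe contributes no
  genotype: a repeated region should produce a missing call, not a coin flip.
* *Equivalence with exhaustive search.* Seeding can only miss a location that
  shares no exact 21-mer with the probe. For a probe of length $L$ carrying
  $m$ mismatches against its true site, some mismatch-free stretch has length
  at least $\lceil (L-m)/(m+1) \rceil$. The synthetic generator therefore
  defaults to 91 bp probes: up to two background substitutions plus the
  SNP-site allele difference ($m = 3$) still guarantee a 22 bp exact stretch,
  so seeded placement provably equals a full Hamming scan under the test
  conditions — and the test suite checks exactly that against an
  independently written exhaustive scan.
* *Palindromic probes* match the same interval on both strands; that is one
  genomic location and is counted once (plus strand preferred), so `n_best`
  reflects distinct loci.
* *Gapped alignment is out of scope.* For probes this short, an indel inside
  the probe footprint almost always drops identity below the threshold; such
  loci are reported unplaced rather than rescued.

The SNP offset is projected into genome coordinates as
`start + snp_offset` on the plus strand and `end - 1 - snp_offset` on the
minus strand (all internal coordinates 0-based, half-open; reports print
1-based positions in columns named accordingly; BED exports stay 0-based).

## Genotype extraction and the pseudomolecule

`extract_call()` reads the genome base at each projected position and, for
minus-strand placements, complements it so every call is expressed in **chip
orientation** — the orientation the reference panel is assumed to use. A base
that matches neither chip allele nor their heterozygote ambiguity letter is an
`allele_mismatch` and is masked to `N` by default: with a single consensus
sequence as input, a third allele at a chip SNP more plausibly reflects a
placement or consensus artifact than a real tri-allelic site
(`keep_mismatch = TRUE` keeps the verbatim base for diagnosis).

`build_pseudomolecule()` always covers *all* panel loci, N-padding the ones
without a call. Equal length by construction means the "multiple alignment" of
pseudomolecules is the identity map — concatenated single-base loci cannot
produce meaningful gaps — so distances are computed positionally and no
alignment dependency is needed.

Loci that fail to place or call can be clustered along the chromosome with
`cluster_uncalled()` (single-linkage, gap threshold `max_gap`, default 10 Mb):
uncalled loci that form a few contiguous blocks suggest low coverage or a
structural variant in that region rather than random technical dropout.

## Distances, neighbor joining, bootstrap

`p_distance_matrix()` computes, for every accession pair, the fraction of
mismatching sites among sites where both calls are informative (pairwise
deletion of `N`; the 3/4-fold ambiguity letters are treated as missing).
Two comparison modes exist because a one-character heterozygote encoding
admits two reasonable conventions:

* **strict** (default): calls are compared as literal characters — `A` vs `R`
  is one mismatch; this is the convention a sequence tool applied to the
  pseudomolecule FASTA would use;
* **allele-aware** (`allele_aware = TRUE`): the mismatch weight is
  $1 - s/2$ where $s$ is the number of shared alleles, so `A` vs `R` scores
  0.5 — the identity-by-state convention.

Pairs with fewer than `min_sites` comparable sites (default 50) are an error
naming the pair: a distance estimated from a handful of loci would silently
poison the tree.

`nj_tree()` is a direct implementation of Saitou–Nei agglomeration: join the
pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, assign limb lengths
by the standard formulas, reduce the matrix, repeat. Determinism is part of
the contract: ties in $Q$ are broken by the lowest (row, column) index in the
current node order, and negative limb lengths are clamped to zero with a
message. On additive matrices NJ is consistent, and the suite verifies exact
recovery (topology and limb lengths) of hundreds of randomly generated trees.

`bootstrap_support()` resamples loci with replacement (default 1,000
replicates), recomputes distance matrix and tree, and scores each internal
bipartition of the full-data tree by its recurrence percentage. Replicates in
which some pair loses all comparable sites are skipped and counted in a
warning; supports are percentages of evaluable replicates. All resampling
derives from one integer seed, so supports are bit-reproducible. Newick
serialization (supports as internal node labels, the dialect FigTree and MEGA
read) is delegated to `ape` behind `read_newick()` / `write_newick()`, with a
pre-parse balance check that reports the character position of a malformed
input.

## The duplicate screen

`ibs_dedup()` reimplements the four-stage screen used to collapse duplicated
germplasm entries:

1. **Genotype missingness** — accessions with more than
   `max_genotype_missing` (default 10%) missing calls are dropped.
2. **Heterozygosity + Hardy–Weinberg** — `hwe_test()` is the df-1 chi-square
   goodness-of-fit test of genotype counts against $p^2, 2pq, q^2$ at the
   observed allele frequency; markers with $p$-value below `hwe_alpha`
   (default 0.05, no multiple-testing correction) are removed.
3. **LD pruning** — a window of `ld_window` loci (default 50) advances by
   `ld_step` (default 5); while any retained pair in the window has squared
   dosage correlation above `ld_r2_max` (default 0.8), the highest-$r^2$ pair
   is taken and its lower-MAF member removed (ties: the later locus).
   Undefined $r^2$ (zero variance, under two complete pairs) is treated as 1,
   so uninformative markers are pruned rather than trusted.
4. **Duplicate calling** — `hom_diff()` is the fraction of differing calls
   among loci where *both* accessions are homozygous; pairs strictly below
   `dup_homdiff_max` (default 0.001, i.e. "less than 0.1%"; exactly 0.001 is
   *not* a duplicate) are edges, duplicate groups are connected components,
   and each group is represented by its first member in panel order.

Two genuinely open design points were decided as follows:

* **Scope of the heterozygosity threshold.** The 0.1 threshold can be read
  per marker or per genotype. The per-marker reading degenerates on the small
  genotype sets this screen is built for: with six inbred genotypes, any
  marker with a single heterozygote already exceeds 1/6 > 0.1, and every
  het-free polymorphic marker fails the chi-square HWE test (inbreeding gives
  $\chi^2 = n$, $p \approx 0.014 < 0.05$), leaving only monomorphic markers —
  on which every pair has homozygous difference 0 and the screen collapses
  everything into one group. A published screen of six genotypes that retains
  hundreds of polymorphic markers is only consistent with the per-genotype
  reading, so `het_scope = "genotype"` is the default (accessions above 10%
  heterozygosity are dropped; markers are filtered by HWE alone). The
  per-marker reading remains available as `het_scope = "marker"`.
* **Stage order.** Published stage counts are sometimes reported LD-first,
  but the internal order of the original tool is not documented. The default
  applies het+HWE before LD (`filter_order = "het_hwe_then_ld"`), and the
  swapped order is one flag away; both are deterministic.

A caveat that follows from the statistics, not the code: on a *large* panel of
inbred lines the HWE filter is extremely aggressive (every polymorphic marker
deviates strongly from Hardy–Weinberg proportions), so the screen is most
meaningful for the small candidate sets it is designed for — a query plus a
handful of related entries — where the test has little power and informative
markers survive. The full-panel phylogeny does not pass through these filters.

## Descriptor PCA

`pca_descriptors()` wraps `stats::prcomp` (centering always; unit scaling by
default, because CPVO ordinal descriptors have heterogeneous ranges) and adds
a deterministic sign convention — the largest-magnitude loading of each
component is positive — so scores and loadings are comparable across runs and
implementations. Variance shares are $\sigma_i^2 / \sum_j \sigma_j^2$.
`biplot_coordinates()` returns accession scores and descriptor arrows
(loadings scaled by $\sigma^e$, default $e = 1$); `autoplot()` draws the
biplot. Whether the original descriptor analysis standardized is not
documented, so both settings are first-class and validation tries both.

## What the synthetic generators emulate

All inputs are generated, with ground truth recorded, so every stage is
testable without external downloads:

* `make_genome()` — uniform random A/C/G/T chromosomes. Real wheat genomes
  are repeat-rich; a uniform genome makes *spurious* probe hits vanishingly
  unlikely, which is the property placement tests need. Repeat-induced
  ambiguity is exercised separately with constructed repeated substrings.
* `implant_probes()` — random 91 bp probes written into non-overlapping
  genome slots on random strands, with a chosen allele at the SNP site and a
  controlled number of background substitutions (see the seeding argument
  above for why 91).
* `simulate_panel()` — per-locus biallelic genotypes at given allele
  frequencies with heterozygote rate 0.05 and missing rate 0.02 by default
  (selfing cereals run low heterozygosity; a couple of percent no-calls is
  typical chip quality). Duplicate accessions are made by copying a row and
  flipping **exactly** `round(noise × n_hom)` homozygous sites. A Bernoulli
  per-site flip at rate 5e-4 would leave roughly 9% of "duplicates" above the
  0.001 threshold by sampling noise alone; fixing the count realizes the
  intended truth condition (a pair *at* homozygous difference ≈ 5e-4)
  deterministically, which is what a truth-controlled fixture is for.
* `simulate_descriptors()` — multivariate normal scores around the ordinal
  midpoint with a controlled covariance (full matrix or eigenvalue spectrum
  rotated by a seeded orthogonal basis). `exact = TRUE` makes the *empirical*
  covariance equal the requested one, so the PCA report can be validated
  against a known spectrum; `ordinal = TRUE` rounds to the 1–9 scale, which
  perturbs the covariance the way real ordinal scoring does.

Every generator is a pure function of its seed (`withr::with_seed`; no global
RNG state leaks). What the generators deliberately do **not** emulate:
genome repeat structure, realistic wheat LD maps (LD in the panel arises only
from duplicated rows and chance), population structure, and read-level error
profiles (the input is a consensus, so there is no read model at all).
Passing tests therefore demonstrate correctness of the algorithms under
controlled conditions, not robustness to every artifact of real data.

## Numerical and policy details

* Percentages in `call_summary()` are rounded half-up to two decimals and
  reconciled so called + uncalled = 100.00 exactly.
* `hwe_test()` sums $(O-E)^2/E$ over cells with $E > 0$; monomorphic input
  returns $\chi^2 = 0$, $p = 1$.
* Undefined `ld_r2()` (zero variance or <2 complete pairs) is `NA`, treated
  as 1 by the pruner.
* Accession pairs with no dual-homozygous site have undefined `hom_diff()`
  and are excluded from duplicate edges, with a warning.
* Branch lengths are written to Newick at 6 significant digits by default;
  internal NJ construction carries full double precision.
* Test problem sizes: unit tests run panels of 6–26 accessions and 15–3,509
  loci, 20–200 bootstrap replicates, and 20 oracle genomes of 10 kb; these
  sizes keep the full suite in the low minutes while every property that
  matters (seeding equivalence, NJ consistency, filter idempotence and
  monotonicity, duplicate discrimination at full locus depth) is exercised at
  the scale where it binds.

## Known limitations

* Placement is ungapped; an indel inside a probe footprint makes its locus
  uncalled rather than shifted.
* The consensus input carries no genotype likelihoods, so a heterozygous
  genome position can only be recovered if the consensus caller wrote an
  ambiguity base.
* p-distances are uncorrected; no substitution-model distances (the distances
  feed a within-species comparison where saturation is negligible).
* The HWE chi-square is asymptotic; at very small $n$ an exact test would be
  less aggressive. The screen's defaults compensate by scoping the
  heterozygosity filter per genotype, but marker-retention *counts* at small
  $n$ remain sensitive to this choice.
* LD pruning retention depends on window geometry; with few genotypes, chance
  correlations dominate and retention counts should be read as order of
  magnitude, not as reproducible statistics.
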