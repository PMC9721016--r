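---
title: "Inferring fiber degradation capacity from metagenomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring fiber degradation capacity from metagenomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifdp)
```

## The model

Dietary fibers (DFs) are plant polysaccharides that host enzymes cannot
digest; their degradation is carried out by gut microbes using glycoside
hydrolases (GH, EC 3.2.1.\*) and polysaccharide lyases (PL, EC 4.2.2.\*).
The package estimates, for each metagenomic sample, a capacity score for
each of a catalog of dietary fibers, by combining three ingredients:

1. **A fiber catalog**: each fiber is annotated with the set of glycosidic
   bonds it contains, written in a canonical token grammar
   `"<anomeric><donor_pos>-<acceptor_pos>:<donor>-<acceptor>"`
   (e.g. cellulose is `b1-4:Glc-Glc`). Fibers that share a higher-level
   classification but identical bond content collapse into one entry.
2. **An enzyme catalog**: each GH/PL enzyme class (by EC number) is
   annotated with the bonds its reaction cleaves.
3. **A sample profile**: the per-sample abundance of each GH/PL enzyme
   class, obtained by mapping translated reads to a reference protein
   database and aggregating best hits by EC — the *functional
   fiber-specific profile* (FFP).

The two catalogs combine into a binary interaction matrix $M$ with
$M_{ij} = 1$ iff enzyme $i$ cleaves at least one bond present in fiber $j$.
The *inferred fiber degradation profile* (IFDP) is the matrix product

$$\mathrm{IFDP} = \mathrm{FFP} \cdot M,$$

i.e. per fiber, the summed abundance of every enzyme able to attack it.
The same product applied to a genome's EC copy-number vector gives a
genome-level capacity vector (`genome_ifdp()`).

Because the entries of $M$ are 0/1, the IFDP is linear in the FFP and each
fiber column is exactly the sum of the contributing enzyme columns; both
identities are enforced by tests against brute-force recomputation.

## The packaged catalog

The default catalog (`default_catalog()`) covers 24 dietary fibers —
inulin, levan, beta-glucan, cellulose, xylan, glucomannan, galactomannan,
mannan, arabinoxylan, galactan, arabinan, arabinogalactan, dextran, chitin,
rhamnogalacturonan, pectin, carrageenan, galactoglucomannan, alginate,
xanthan, xyloglucan, laminaran, gellan and resistant starch — with bond
sets curated from the standard structural chemistry of each polysaccharide,
and 41 GH/PL enzyme classes annotated with the bonds of their EC reaction.
Two deliberate conventions:

* Xylan and xyloglucan get distinct abbreviations (`Xyl`, `XG`);
  abbreviations are unique within a catalog by contract.
* Enzymes whose bonds match no cataloged fiber keep an all-zero matrix row,
  so the FFP remains a complete GH/PL profile and profile columns always
  align with matrix rows.

Catalogs are plain TSV (`fibers.tsv`, `enzymes.tsv` under `extdata/`), so
the curated content can be audited, extended or replaced; the bond grammar
and the controlled sugar vocabulary (`df_sugar_codes()`) make catalog
equality and matrix construction exactly testable. The catalog does not
model polymerization degree, side-chain accessibility, or accessory
proteins (esterases, transporters, binding proteins); capacity scores are
bond-level potential, not kinetics.

## From reads to profiles

The profiling path mirrors a standard translated-search pipeline:

* **Subsampling** (`subsample_reads()`): samples are rarefied to a fixed
  depth (default $4 \times 10^6$ reads) without replacement; shallower
  samples are flagged discarded. Mates of a pair are treated as independent
  reads.
* **Alignment**: production use feeds 12-column tabular output of an
  external translated aligner to `parse_alignment_table()`. For tests and
  simulations the package ships `translated_search_naive()`, a six-frame
  exact-peptide-seed matcher (seed length 10 by default, ungapped
  extension) with documented toy scoring: 2 bits per identical residue and
  e-value $= m \cdot n \cdot 2^{-\mathrm{bits}}$ for database size $m$ and
  peptide length $n$. It exists so no aligner binary is ever required; it
  is not a contribution and not a production aligner.
* **Best hits** (`select_best_hits()`): hits with e-value $\ge 10$ are
  dropped (the cutoff is strict `< 10`); per read the highest bitscore
  wins, with ties broken by lower e-value then lexicographic accession so
  selection is deterministic.
* **EC aggregation** (`aggregate_by_ec()`): reads assigned to a protein
  with exactly one EC annotation increment that EC; reads hitting multi-EC
  proteins are discarded and reported as an ambiguity fraction. Total reads
  are conserved: assigned = counted + ambiguous, plus unassigned.
* **Filtering** (`filter_low_abundance()`): a feature is removed when its
  within-sample relative abundance is strictly below 0.01% in at least 90%
  of samples. The same rule serves enzyme and taxon tables; both thresholds
  are parameters. "Strictly below" matters at the boundary and is pinned
  by enumerated fixtures.

### Copy-number normalization

`musicc_normalize()` converts counts into average-copy-number-like units:
each gene count is divided by gene length (amino acids), and each sample is
divided by the median length-corrected abundance of the universal
single-copy marker families in that sample. Two choices were genuinely
open:

* marker counts are length-corrected *before* taking the median, so the
  normalization variable is a coverage (copy-number) estimate and a
  single-copy gene at marker coverage scores exactly 1.0;
* the profile is reported as length-corrected abundance divided by the
  marker median, without an additional within-sample relative-abundance
  division — that alternative changes only a per-sample constant and can
  be applied downstream if desired.

The normalized profile is invariant to rescaling all counts in a sample.
The packaged marker list (`uscg_marker_ids()`) is a representative set of
76 universal single-copy families shipped as IDs only (the file is
explicitly labelled synthetic); marker sequences are user-supplied.

## The statistical layer

All stochastic procedures take explicit seeds and are reproducible
bit-for-bit.

* **Univariate comparisons** (`volcano_group_test()`): two-sided
  Mann-Whitney per feature, exact for small tie-free samples (verified
  against full enumeration), with a log2 fold change of group means using a
  pseudocount of half the smallest nonzero value, and Benjamini-Hochberg
  adjustment by default. Bonferroni is used where the analysis
  conventionally demands it (country tests below).
* **Stratified PERMANOVA** (`permanova_stratified()`): the pseudo-F is
  computed from Euclidean distances of the principal components (all
  components by default — equivalent to Euclidean distance on the centered
  profile; a top-$k$ option exists). The contribution is the two restricted
  permutation schemes for cluster-sampled designs: permuting the
  species-to-label map (all samples of a species move together) and
  permuting labels within phylogeny-class strata. The unrestricted mode is
  cross-checked against `vegan::adonis2`, and both restricted schemes are
  calibrated: over 200 null datasets drawn under each scheme's own sampling
  design, the rejection rate at $\alpha = 0.05$ must sit inside the 95%
  binomial interval. Permutation p-values use the add-one correction and
  are never zero.
* **Random-forest harness** (`rf_group_prediction()`): repeated holdout
  (default 500 iterations, 40% held out, validation class-balanced), a
  default-parameter forest per iteration, ROC-AUC per iteration plus a mean
  ROC curve. "Balanced" is implemented as a class-balanced validation set;
  the null check permutes labels anew each iteration, which is the
  permutation null for the harness.
* **In vitro agreement test** (`agreement_permutation_test()`): for
  clade-level capacity versus growth/no-growth assays, agreement means rank
  $\le 2$ (no growth) or rank $\ge n-1$ (growth) within a fiber; ties get
  average ranks and are flagged. Significance comes from shuffling each
  fiber's scores across clades (default 2000 shuffles), and the
  implementation is checked against exhaustive enumeration of all per-fiber
  permutations on small instances.
* **Country signatures** (`country_tstat_matrix()`): per country and fiber,
  a Welch two-sample t-test of the country against all others pooled,
  Bonferroni-corrected across all country-fiber tests, returning the
  t-statistic matrix for hierarchical clustering
  (`ordination_and_clustering()`, average linkage on Euclidean distances).
  Welch rather than pooled variance is a deliberate robustness choice.

Ordination offers deterministic PCA and hierarchical clustering; no
stochastic embedding (e.g. t-SNE) is wrapped.

## The simulator and what it does (not) show

`generate_community_reads()` draws reads from reverse-translated proteins
(fixed codon per amino acid — codon degeneracy is irrelevant after
translation back to peptide space), with source proteins chosen by the
abundance vector, uniform positions, both strands, and a uniform per-base
substitution model (default 0.5%). Every read's origin is recorded in a
truth table, so mapping accuracy is measurable exactly. The error model is
deliberately simple: it emulates planted composition, strandedness and
moderate sequencing noise, but not platform-specific error profiles,
indels, quality gradients, insert-size structure or real inter-genome
homology. Passing the planted-recovery tests therefore demonstrates
correctness of the bookkeeping and of translated matching under mild noise,
not performance on real stool metagenomes.

`mask_and_simulate_fdr()` reproduces the masked-genome false-discovery
design at desk scale: GH/PL coding intervals are masked (replaced by `N`
runs, which translate to `X` and can never seed a peptide match), reads are
simulated from masked and unmasked genomes, and the masked-run hit count
estimates the false-discovery rate of the mapping. On the packaged toy
fixtures the masked run yields zero hits and every unmasked hit is audited
against the truth table.

## Problem sizes and numerical choices

The test and acceptance workloads were chosen as the smallest sizes at
which each property is statistically meaningful: 200 random catalogs for
the matrix oracle; 50,000 reads for planted-composition recovery (binomial
3-SD band ±0.006); 200 null datasets × 199 permutations per stratification
scheme for type-I calibration; 500 iterations for the forest harness;
100,000 reads for the masked-genome experiment. Tolerances on permutation
p-values are three Monte-Carlo standard deviations. Degenerate inputs fail
loudly rather than silently: empty bond sets, all-zero sample rows, zero
normalization medians, profile ECs missing from the matrix, and truncated
FASTQ records are all errors with actionable messages.

## Known limitations

* Catalog content is curated, not learned; bond sets for some gums and
  algal fibers are simplified to their dominant linkages.
* Capacity scores aggregate enzyme abundance and ignore operon context,
  secretion, and substrate accessibility.
* The naive matcher is quadratic-ish in hit density and intended for
  fixtures only.
* Whether identical sequences shared between reviewed and unreviewed
  database sections should be deduplicated is left to the user; the
  builder keeps duplicates (under distinct accessions) and reports counts.
* 16S-based functional inference is out of scope; inputs are shotgun reads,
  alignments, or genome annotations.
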