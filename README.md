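# ifdp — inferred fiber degradation profiles from metagenomes

Dietary fibers (DFs) — inulin, arabinoxylan, pectin, resistant starch and
their kin — are plant polysaccharides that host enzymes cannot digest.
Their fate is decided by the gut microbiome, whose glycoside hydrolases
(GH, EC 3.2.1.\*) and polysaccharide lyases (PL, EC 4.2.2.\*) cleave
specific glycosidic bonds. `ifdp` is an R package for microbiome
researchers who want to quantify, directly from shotgun metagenomic data
(or from isolate-genome annotations), a sample's capacity to degrade each
of a broad catalog of dietary fibers — and to compare those capacities
across host groups.

## The model

Each fiber is annotated with the set of glycosidic bonds it contains, and
each GH/PL enzyme class with the bonds it cleaves, using a canonical bond
grammar (`b1-4:Glc-Glc` is the beta-1,4 glucose–glucose linkage of
cellulose). The catalogs combine into a binary enzyme–fiber interaction
matrix

&nbsp;&nbsp;&nbsp;&nbsp;*M<sub>ij</sub>* = 1 ⟺ enzyme *i* cleaves a bond present in fiber *j*,

and the **inferred fiber degradation profile** of a set of samples is the
matrix product

&nbsp;&nbsp;&nbsp;&nbsp;IFDP = FFP · *M*,

where the FFP (functional fiber-specific profile) is the samples × enzymes
abundance matrix obtained by mapping translated reads to a GH/PL protein
database, selecting best hits (e-value < 10, deterministic tie-breaks),
aggregating by EC (multi-EC hits discarded as ambiguous), filtering
features below 0.01% relative abundance in ≥ 90% of samples, and
optionally normalizing by universal single-copy marker genes into
copy-number-like units.

On top of the profiles the package ships the statistical layer used to
relate capacity to host diet: Mann-Whitney volcano tests, PERMANOVA with
cluster-restricted label permutations (by species cluster, or within
phylogeny-class strata), a repeated-holdout random-forest prediction
harness with ROC-AUC, an in vitro growth/capacity agreement permutation
test, country-versus-rest t-statistic matrices with Bonferroni correction,
plus PCA and hierarchical clustering. A seed-deterministic read simulator
with exact truth tables supports validation, including a masked-genome
false-discovery experiment.

## Worked example

The packaged catalog covers 24 dietary fibers and 41 GH/PL enzyme classes:

```r
library(ifdp)
cats <- default_catalog()
M <- build_interaction_matrix(cats$fibers, cats$enzymes)
dim(M)
#> [1] 41 24
```

A minimal two-sample profile over three enzymes, and its capacity profile:

```r
fx <- make_toy_fixture("minimal")
fx$ffp
#>    3.2.1.4 3.2.1.7 3.2.1.26
#> s1       2       3        0
#> s2       1       0        4
compute_ifdp(fx$ffp, fx$M)
#>    Cel Inu
#> s1   2   3
#> s2   1   4
```

Sample s2 scores 4 on inulin because both the inulinase (3.2.1.7) and the
beta-fructofuranosidase (3.2.1.26) rows of *M* hit the inulin column, and
s2 carries 0 + 4 counts of them; cellulose capacity is just the cellulase
count. On a 20-sample synthetic cohort with a planted 4× enzyme shift in
group B, the volcano test recovers exactly the planted fiber:

```r
fx2 <- make_toy_fixture("two_group_cohort", seed = 3)
capacity <- compute_ifdp(fx2$ffp, fx2$M)
res <- volcano_group_test(capacity, fx2$metadata, "group")
res[order(res$p_adjusted), ]
#>  feature log2_fold_change    p_raw p_adjusted direction
#>      Inu          -1.6776 0.000178   0.000888        -1
#>      Cel          -0.0175 0.705246   0.705246        -1
#>      Xyl           0.0155 0.649161   0.705246         1
#>      Pec           0.0219 0.471507   0.705246         1
#>      Man           0.0241 0.493517   0.705246         1
```

Only inulin survives adjustment (p_adj ≈ 9e-4); the negative fold change
says group A has lower inulin-degradation capacity than group B, where the
inulin-specific enzyme was planted at 4× abundance.

A shell entry point over the same functions ships at
`inst/scripts/ifdp.R` (subcommands `build-matrix`, `profile`, `ifdp`,
`stats-volcano`, `stats-permanova`, `simulate`, `fdr-sim`, ...), each
writing TSV artifacts plus a JSON run manifest.

## Package layout

- `R/` — catalogs and bond grammar, reference databases, profiling,
  statistics, simulation, fixtures, subcommands
- `inst/extdata/` — curated fiber/enzyme catalogs (TSV) and the
  single-copy marker ID list
- `vignettes/ifdp-methods.Rmd` — model, assumptions, parameter choices and
  limitations
- `tests/testthat/` — unit, property and acceptance suites (oracle-based:
  brute-force matrix checks, exact enumeration of permutation nulls,
  truth-table audits)
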