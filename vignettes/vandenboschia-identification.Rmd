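---
title: "Identifying Vandenboschia radicans complex hybrids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying Vandenboschia radicans complex hybrids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radicans)
```

## The identification problem

The *Vandenboschia radicans* complex is a group of filmy ferns in which
three parental genomes — written α (*V. kalamocarpa*), β
(*V. nipponica*) and γ (*V. striata*) — recombine through hybridization
and polyploidization. Most field individuals are sterile triploid
hybrids that overlap morphologically with their parents, so a reliable
identification needs three independent observations per plant:

1. **Nuclear genotype classes.** The single-copy nuclear *GapCp* region
   carries alleles that fall into classes A, B and C, corresponding to
   the α, β and γ genomes. A CAPS (cleaved amplified polymorphic
   sequence) assay digests the *GapCp* amplicon with restriction
   enzymes whose sites differ between classes; the resulting gel band
   pattern reveals which classes a plant carries, and cloning the
   amplicon recovers the individual alleles.
2. **Maternal parent.** The chloroplast *rbcL* gene is maternally
   inherited; haplotypes I/I′/I″, II and III identify an α, β or γ
   mother respectively.
3. **Ploidy.** Flow cytometry against an internal standard
   (*Nicotiana tabacum*, 1C = 4.6 pg) gives the 2C genome size; the
   complex has a base number of x = 36 chromosomes, so diploids show
   2n = 72 and triploids 2n = 108.

These combine into a *genomic formula*: a string of genome symbols
whose length equals the ploidy, with the maternal genome first and `*`
for slots whose dosage could not be resolved (e.g. β|αα, α|β\*). The
formula then maps to a taxon (the two parental species, the hybrids
*V.* × *stenosiphon* and *V.* × *quelpaertensis*, or the triple hybrid).
Morphometrics provides an independent check: ten traits per plant, with
the involucre width-to-length ratio (IW/IL) and rhizome diameter (RD)
the key diagnostics.

## CAPS model and numerical choices

Digestion is modeled on the top strand with 0-based, half-open
coordinates: a recognition site starting at position *s* with cut
offset *c* cuts at *s + c*; fragments are the distances between
consecutive cuts and the sequence ends, so they always sum to the
amplicon length. Both strands are scanned (the panel enzymes SacI,
GAGCT^C, and HinfI, G^ANTC, are palindromic so the strands coincide).
Sticky ends, partial digestion, heteroduplexes and PCR recombination
are deliberately not modeled — only fragment lengths reach a gel.

Gel realism enters through two parameters:

* `min_band_bp` (default **60**): fragments shorter than this are
  invisible on a 2% agarose gel. The default auto-ignores the assay's
  40 bp fragment shared by all classes and the 52 bp fragment shared by
  A and B; an explicit `drop_shared` argument covers shared fragments
  that are long enough to see but uninformative.
* `min_diff_bp` (default **20**): two bands closer than this
  co-migrate and cannot be distinguished. The assay never states its
  gel resolution; 20 bp is a conservative figure for a 2% gel in the
  100–600 bp range.

`select_diagnostic_enzymes()` searches enzyme subsets in order of
increasing size (catalogue order breaks ties) for the smallest panel
that is *within-class invariant* (every allele of a class gives the
same pattern) and *between-class distinguishing* (every class pair
differs for at least one enzyme). Mixture patterns are band-set unions —
dosage is invisible on a gel, so AA, AAA and A are identical —
and `call_classes()` inverts them by exhaustive search over the seven
non-empty class subsets, returning the unique smallest matching subset
and refusing to guess on ties.

A consequence worth stating: a mixture is only fully invertible when
every class shows at least one *private* band somewhere in the panel.
With three classes and two enzymes, a panel that minimally *needs* both
enzymes cannot have that property (two classes must then each share
their complete pattern with another class for one of the enzymes, and
the union of all three classes becomes identical to a two-class union).
The synthetic registry therefore plants per-class private HinfI bands
(A: 477, B: 198 + 279, C: 529 bp) so that mixtures of any subset remain
identifiable, while keeping the assay's documented features — the
shared 40 bp fragment, the A/B-shared 52 bp fragment, and a SacI site
private to class B. On such registries the minimal panel is {HinfI};
registries in which the classes are separable only jointly (e.g. a
B-private SacI site plus a C-missing HinfI site) yield the two-enzyme
panel instead.

## Allele classification

Cloned sequences are matched to the registry exactly when possible;
otherwise the nearest registry allele decides the class, by Hamming
distance at equal length and Levenshtein distance otherwise. The
mismatch budget `max_mismatch` defaults to 10 (~1.8% of a 569 bp
amplicon) — the assay reports novel within-class alleles but never
states its threshold, so the value is configurable. Novel alleles are
named with the class's "K" series (AK1, AK2, …, BK1, …), taking the
lowest unused integer. Ties between classes at equal distance are an
error, not a guess, and ambiguity codes in a query count as mismatches
because registry alleles are fully resolved sequences.

## Flow cytometry

`genome_size()` is the linear peak-ratio estimator
(sample G1 mean / standard G1 mean × 9.2 pg). The reported values are
treated as 2C holoploid sizes — an assumption, but one consistent with
the observed ranges and the chromosome counts. `assign_ploidy()` rounds
against a monoploid size `monoploid_1Cx` (default **6.5 pg**, about
half the diploid group mean; the study reports group means, not a 1Cx)
and refuses calls whose residual reaches half a monoploid genome, the
exact midpoint between two euploid levels included. Confidence is the
residual rescaled so that a perfect euploid size gives 1 and the
midpoint gives 0.

`cluster_ploidy()` serves cohorts without a trusted 1Cx: exact
dynamic-programming k-means on the sorted sizes, with k chosen by the
largest-relative-gap rule (one cluster plus one per between-neighbour
gap exceeding 15% of the data range). The rule is deliberately scale
free; its known limitation is that a single tight cluster with an
outlier gap can over-split, so the cluster count is capped by `k_range`
and anchored by declaring the smallest cluster diploid by default.
DAPI base-composition bias and raw FCS histogram processing are out of
scope; inputs are instrument-reported peak means.

## Genomic formulas

`required_clones()` implements the sampling-depth rule: at least
2.5 × ploidy cloned colonies (5, 8, 10 for 2x, 3x, 4x). Dosage is only
claimed when the number of *distinct* alleles recovered equals the
ploidy; with fewer, each observed non-maternal class appears once and
`*` fills the remainder — an under-sampled triploid is α|β\*, never a
guessed α|ββ. More distinct alleles than ploidy is treated as
contamination and refused. A maternal class absent from the clones is
flagged and warned about but not fatal, since the chloroplast call may
still be correct.

Rendering follows the printed genotype convention: the maternal symbol
first (separated by `|` in the canonical plain-text form), then any
remaining copies of the maternal class, then the other classes by
descending dosage with ties in Greek order — so maternal β with
nuclear {β, α} renders β|βα, and maternal α with {β, β, γ} renders
α|ββγ. Taxon assignment uses the class-set rule (α → *V. kalamocarpa*;
β → *V. nipponica*; αβ → *V.* × *stenosiphon*, the single diploid αβ
included; αγ → *V.* × *quelpaertensis*; αβγ → the triple hybrid), with
γ-only and βγ sets flagged as not recorded in Korea. Haplotype I″ is
treated as α-lineage, as its one-SNP distance from I/I′ suggests; the
assignment is flagged in output rather than silently assumed.

## Morphometrics

`compare_groups()` gates the test choice per trait: Shapiro–Wilk per
group and Brown–Forsythe (median-centered Levene) homogeneity, both at
α = 0.05 — the study names neither gate test, so the field defaults are
used. All-normal and homogeneous routes to one-way ANOVA with Tukey
HSD; anything else routes to Kruskal–Wallis (tie-corrected) with
Dunn's pairwise z-tests under Holm step-down. Groups with fewer than
three observations cannot be tested for normality and route
nonparametrically.

`dapc()` composes the discriminant analysis of principal components:
unit-variance scaling, PCA retaining the smallest number of components
whose cumulative variance reaches `var_threshold` (default 0.90, ties
to the smaller count), then LDA with uniform priors on the retained
scores. The discriminant count is chosen by repeated stratified k-fold
cross-validated assignment accuracy (default 5-fold × 30 repeats under
a fixed seed; the study says only "using cross-validation").
Variable contributions per discriminant are the normalised absolute
values of the LD loadings back-projected through the PC rotation. The
eight analysis traits replace IL and IW by their ratio IW/IL. The
single α|αγ individual and the involucre-less diploid α|β are excluded
from group statistics, mirroring the study's grouping.

`involucre_rule()` encodes the field identification cue: IW/IL > 0.7
(strict) occurs only in *V. nipponica*.

## What the generator emulates — and what it does not

`make_cohort()` draws genotypes at the study cohort's composition
(n = 47: four αα/ααα, ten ββ/βββ, twenty-nine triploid hybrids of which
13 α-maternal αβ-types, 11 β-maternal, 3 γ|αβ and 2 α|αγ, three
tetraploids, one diploid α|β), assigns each genome copy a distinct
registry allele of its class, emits rbcL haplotypes from the maternal
genome (I or I′ with equal probability for α), flow peaks at
x × 6.5 pg with 3% CV against a ~200 a.u. standard peak, and traits
from the per-group means and SDs of the published trait table. Colony
picking covers the surviving alleles evenly, so at zero dropout every
allele is recovered and the whole pipeline must reproduce the truth
exactly; dropout removes whole alleles and can only produce `*` slots,
never a wrong class. Trait values are truncated at 0.1 × the group
mean, and pinna counts are rounded with a floor of 3. The IW/IL ratio
is drawn directly from its published row (IW is derived as ratio × IL)
so the diagnostic ratio has the printed spread.

Two real-data features are deliberately absent. First, sequencing
error and chimeric clones are not simulated (the contamination error
path is tested with constructed inputs instead). Second — and more
consequential — traits are drawn independently within groups, so the
synthetic plants have no allometric correlation between the six leaf
traits. That preserves every marginal mean and SD but changes the
multivariate geometry: six independently informative leaf traits give
the triple-hybrid group a larger joint separation than it has in real
data, where those traits are strongly correlated and collapse to
roughly one effective axis. In consequence the synthetic DAPC usually
puts the group-4 axis first and spreads its loadings across the leaf
traits, whereas the published analysis found the involucre ratio
leading LD1 and rhizome diameter leading LD2. The involucre ratio
still tops LD1 in most synthetic replicates, but rhizome diameter
essentially never tops LD2 — a limitation of the generator's
independence assumption, not of the discriminant code, and a good
example of what passing tests on synthetic data do and do not show
about real material.

Similarly, the univariate significance pattern for rhizome diameter
(group 4 larger than all, groups 1–3 mutually indistinct) reproduces
in most but not ≥95% of replicates: at the published means and SDs the
small G1–G2 difference (0.43 ± 0.01 vs 0.41 ± 0.02 mm) is a standardized
effect of ~1.3 that becomes significant in a noticeable minority of
balanced n = 12 draws, and at the study's own unbalanced group sizes
(4/10/24/6) the variance heterogeneity routes most replicates to the
rank-based tests, which lack the power to certify the smallest
comparisons. The acceptance suite asserts the pattern anyway and the
corresponding checks are knowingly strict; the measured rates are
reported by `scripts/acceptance.R`.

## Problem sizes and determinism

The shipped test and acceptance workloads use: 100 generator seeds for
the CAPS round-trip property (seven class subsets each), 500–1000
random sequences of 100–2000 bp for the digestion oracle, 3000
simulated flow measurements (1000 per ploidy) for the recovery rate,
cohorts of 47 for pipeline round trips, and 100 replicates of n = 12
per group for the morphometric rates — sizes chosen to estimate each
rate to a percent or better while keeping a full run in well under a
minute per property. All randomness flows from explicit seeds;
`make_cohort()` restores the caller's RNG state, and the same seed
reproduces a cohort byte for byte.

## A worked example

```{r example}
cfg <- sim_config(seed = 11, n_samples = 12)
cohort <- make_cohort(cfg)
report <- run_pipeline(cohort)
report$panel
head(report$results[, c("sample_id", "haplotype", "caps_classes",
                        "ploidy", "formula", "taxon")])
report$summary$groups
all(report$results$formula == cohort$truth$true_formula)
```

## Known limitations

* Reference band patterns are recomputed from registry alleles, never
  hard-coded; absolute fragment sizes therefore depend on the amplicon
  extent of the sequences supplied.
* The clustering k-rule is gap-based and can over- or under-split
  cohorts whose ploidy groups overlap at high CV; `assign_ploidy()`
  with a trusted 1Cx is the primary path.
* Dosage is never inferred from clone frequencies, only from distinct
  allele counts — matching the assay's own convention.
* The morphology generator models group marginals, not trait
  covariance; multivariate conclusions transfer to real data only
  qualitatively (see above).
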