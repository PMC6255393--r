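---
title: "Models and methods in radpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in radpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

radpop analyses multi-species resequencing panels from rapid radiations:
one deeply sequenced diploid individual per species, mapped to a common
reference, with an outgroup individual for polarization. This vignette
explains the models the package implements, the parameters that matter, the
design choices made where the design was genuinely open, and what the
synthetic-data generator does and does not emulate.

## Site filtration and the callable genome

Cross-species mapping to a single reference is only trustworthy in the
single-copy, well-covered part of the genome, so all downstream statistics
are defined over a *callable* set of positions. `apply_site_filters()`
removes, in a fixed order: multiallelic sites; indels and every site within
`indel_pad` (default 10 bp) of one; sites in user-supplied repeat intervals;
sites with any sample below `min_depth` (default 15 reads); sites where any
sample's `|log10(depth / median depth)|` exceeds `cov_log_bound` (default
0.5; 0.15 for a stringent variant) — the log-ratio form catches collapsed
repeats (excess depth) and hemizygous or deleted regions (deficit)
symmetrically; and sites lacking a genotype call in any sample. Each removed
site is attributed to the *first* filter it fails; the surviving-site set is
order-invariant, only the attribution depends on order. Per-sample median
depth is computed over all assayed sites before any filtering, so the
coverage filter is not conditioned on the outcome of the others.

The base of the coverage and allele-balance logarithms is configurable and
defaults to 10, consistent with the ±0.3 read-ratio convention used for
heterozygous-call balance: `allele_balance_filter()` voids heterozygous
calls whose `log10(ref reads / alt reads)` lies outside ±0.3, a bound at
which a 2:1 read imbalance (log10 ≈ 0.30) is the last tolerated ratio.

Coordinates are 0-based half-open internally (masks, windows, BED);
VCF/GFF3 positions are 1-based on input and output.

## Diversity, divergence, FST

Nucleotide diversity is the percentage of pairwise sequence differences
over callable basepairs. Within an individual, each heterozygous site
contributes 1; between individuals the contribution is the expected
mismatch between one allele drawn from each diploid,
`d = (g_a(2−g_b) + g_b(2−g_a))/4` for alt dosages 0/1/2 — the unphased
convention, chosen because phase is unavailable in this design. Positions
inside the mask but absent from the variant table are invariant and count
only in the denominator; sites missing in either sample are excluded from
both. Consequently the *denominator must enumerate the callable genome*,
not just variant sites; the synthetic generator emits a `callable.bed` for
this purpose, while the mask returned by `apply_site_filters()` enumerates
surviving variant positions (useful for bookkeeping, not a diversity
denominator).

`hudson_fst()` implements FST = 1 − Hw/Hb with Hw the mean within-region
pairwise diversity (the two regions weighted equally) and Hb the mean over
between-region pairs. Regions here hold 1–4 individuals, so when a region
has a single sample its within-individual heterozygosity stands in for
within-region diversity — the one-individual limit of the same quantity.
Note that with this diploid metric FST is zero when all samples are
genotype-identical, but *negative* when one region is a copy of the other
(between-region pairs then include identical-individual pairs, making
Hb < Hw); exchangeability, not column identity, is the null.

`homozygosity_runs()` tiles chromosomes with 100 kb windows (the same
granularity as the tree windows), flags windows with heterozygosity
strictly below 0.1 %, and merges adjacent flags; windows with under 10 %
callable coverage are no-calls and break runs.

## Polarization, sharing depth, topology support

`polarize()` assigns ancestral state from a homozygous outgroup genotype.
Heterozygous-outgroup sites are dropped rather than frequency-polarized
(singleton outgroup, no frequency to use); sites where the outgroup allele
is absent from the ingroup, and sites monomorphic in the ingroup, carry no
sharing information and are dropped. Sharing depth
(`sharing_classification()`) is presence/absence (dosage > 0): for each
species and site, the variant is private, shared only within the species'
region, or shared across two or three regions. Presence coding was chosen
over dosage weighting because the classification is about geographic reach,
not frequency; a dosage-weighted variant of `topology_support()` exists
behind a flag.

`topology_support()` calls a site informative for a trio (a, b, c) when
exactly two species carry the derived allele; the carrying pair supports
T1 = ((b,c),a), T2 = ((a,c),b) or T3 = ((a,b),c). On panel data these
proportions mix trio-genealogy signal with backbone variants that happen to
hit two trio members, so T1 is inflated relative to the pure coalescent
expectation — visible in the synthetic panel, where observed support
proportions sit between the chain prediction and the species tree. The
grid fit consequently under-states m·N when fed raw panel support; this is
a property of the statistic, not the fit.

## The D statistic

`abba_baba()` uses frequency-weighted counting from diploid genotypes:
with derived-allele frequencies `f_i = dosage/2`,
`ABBA = Σ(1−f1)f2f3`, `BABA = Σf1(1−f2)f3`. This differs from
single-read sampling approaches; the estimator's defining properties —
exact antisymmetry under H1↔H2, invariance to sites with f3 = 0 — are
property-tested. Significance uses a block bootstrap: contiguous 100 kb
blocks resampled with replacement to the original count, SE = sd of the
replicate D values, Z = D/SE, |Z| ≥ 3 significant (the threshold is
configurable; 3 is the common field convention). Identical blocks give
SE = 0 and a degeneracy flag rather than an infinite Z.

## Window trees and subtree prevalence

Trees come from neighbor joining on Hamming distances (proportion of
jointly-called sites with different genotype codes; any difference counts
one, so het/hom differences are not half-weighted — a deliberate symbol
metric matching the concatenated-genotype input). NJ is implemented
in-package with the standard Q criterion; ties break by scan order over the
current node ordering (input taxa first, merged nodes appended), so results
are deterministic; negative branch lengths are clamped to zero with the
deficit moved to the sister branch, preserving the joined pair's distance.
NJ reconstructs additive matrices exactly, which the test suite checks
against 500 random trees (4–12 taxa) and cross-checks against ape's
implementation.

Windows are non-overlapping 100 kb tiles with at least 100 variant
positions. For prevalence testing each window tree is rooted on a declared
taxon (the outgroup by default in the pipeline) and every rooted clade of
size ≥ 2 (excluding the full set) is cataloged. Stage 1 tests each clade
for equal presence proportions across chromosomes (chi-square
equal-proportions test, no continuity correction, Bonferroni n = number of
clades); stage 2, applied to stage-1 survivors, tests each chromosome
against the genome-wide proportion (one-sample proportion test *with*
continuity correction, Bonferroni n = significant clades × chromosomes).
The two-stage structure means stage-2 p-values are conditional; family-wise
error of the combined procedure is verified by simulation to stay below
0.05 under the i.i.d.-window null.

## The two-phase Markov-chain coalescent with gene flow

The model asks how much migration (m) and population size (N, in alleles)
are needed to produce observed genealogy-topology proportions for a species
trio in which species A split first at t2 but exchanges migrants with C
between the present and the later split t1 of B and C (times in units of N
generations, t2 = 2·t1 by default). Assumptions: constant N everywhere, one
lineage sampled per species, migration only on the A–C pair, and a
discrete-generation approximation.

*Phase 1* (present → t1): a five-state chain tracks the locations of
lineages a and c over populations {A, C} plus an absorbing a–c-coalesced
state. Each generation both lineages migrate (A→C with m1, C→A with m2),
then a co-located pair coalesces with probability 1/N. *Phase 2*
(t1 → t2): B and C merge; migration stops, so locations freeze; four
transient states and three absorbing states record the first coalescing
pair — T1 (b,c) concordant, T2 (a,c), T3 (a,b). *Tail* (t2 → t2 + tail):
all remaining lineages are co-located. With k co-located pairs the
per-generation coalescence probability is k/N split uniformly among pairs
(the standard discrete coalescent; simultaneous-coalescence terms of order
1/N² are excluded). This choice makes the no-migration distribution exactly
pT1 = (1−q) + q(1−r)/3, pT2 = pT3 = q(1−r)/3, pNone = qr with
q = (1−1/N)^N, r = (1−3/N)^N, which the implementation reproduces to
1e-13. Phase horizons are round(t1·N), round((t2−t1)·N) (configurable,
since a fixed-N-generations reading of the middle phase is also defensible)
and round(tail·N); "no coalescence within the horizon" is reported as
pNone rather than silently renormalized.

Chain iteration uses exact matrix powers by repeated squaring — with 5–7
states this is microseconds, so grid fits over (m, N) are cheap.
`simulate_genealogies()` is an *event-level* simulator (per-generation
migration/coalescence draws in phase 1, geometric waiting times afterward)
that shares no code with the transition matrices; agreement between the two
within Monte-Carlo error is the core cross-validation. The simulator
completes every genealogy past the horizon, computes internal branch
lengths, drops Poisson mutations (theta per lineage per N generations), and
classifies each mutated locus: internal-branch mutations above pair (a,c)
are ABBA sites, above (a,b) BABA sites, above (b,c) concordant sites —
external-branch mutations are singletons and cancel from D. D is then
(ABBA−BABA)/(ABBA+BABA) with H1 = b, H2 = c, H3 = a. D rises steeply with
m·N and plateaus near 0.5 at the desk scale, reproducing the qualitative
saturation that makes D alone a poor estimator of migration intensity.

`fit_grid()` compares observed (T1,T2,T3) proportions to the chain's
distribution normalized over resolved genealogies, by summed squared error
(the distance metric was an open choice; squared error keeps the surface
smooth and the self-consistency property exact), with ties broken toward
smaller m then smaller N.

## Recombination maps and covariate analyses

`assign_bin_genotypes()` translates diagnostic-read ratios into
grandparental bin assignments: 0.4–0.6 assigns the diagnostic parent
(heterozygous carrier, expectation 0.5); 0.1–0.4 is a review flag
(possible breakpoint or reference discordance — left to manual review, not
auto-resolved); below 0.1 the other parent. Ratios above 0.6 are treated as
assignable with a warning; the band's upper tail is over-representation
noise, not evidence against carriage. A recombination event is an
assignment change between consecutive assigned bins, attributed to the
first assigned bin downstream of any skipped ones (attribution was an open
choice; downstream attribution keeps event totals invariant to inserted
no-calls, which is tested). Rates are (events / n haploid genomes) × 100 /
bin size in Mb, with n = 648 haploid genomes as the default panel size
(324 F2s × 2).

`chr4_regression()` fits y ~ x pooled and with a focal-chromosome contrast,
adding the interaction only when significant at α = 0.05; when the contrast
is significant, separate per-group fits are also returned.
`kendall_partial()` composes Kendall tau-b components (R's `cor()` with tie
correction) into the partial correlation, with a normal-approximation
p-value. `fisher_enrichment()` is a two-sided Fisher exact test per term
with Bonferroni correction over the term count. `repeat_permutation()`
places all insertions uniformly and reports a two-sided empirical p with
add-one smoothing `(k+1)/(n_sims+1)` — conservative and never exactly zero;
because the statistic is discrete, calibration is verified as type-I
coverage at thresholds rather than by a continuous-uniformity test.

## The synthetic-data generator

`simulate_radiation_vcf()` emulates the statistical structure the analyses
assume: 10 ingroup individuals in three regions (4 + 2 + 4) plus an
outgroup; per-species heterozygosity targets drawn from a 0.2–0.35 % band;
seven chromosomes with polymorphism doubled on `Chr_04`; clade-defining
variants on a fixed species-tree backbone; deep shared polymorphisms
(region-wide and genus-wide); outgroup-fixed divergent sites; and, per
100 kb window, one trio genealogy drawn from `simulate_genealogies()` so
ILS and gene flow are structurally correct, with its internal-branch
mutations planted as pair-shared derived variants. Reads are
negative-binomial (mean 60, size 15); heterozygous allele depths are
binomial around 0.5 with a 3 % skewed fraction; multiallelic records,
indels, missing calls and repeat intervals are planted so every filter has
work. Default problem size is 7 × 500 kb chromosomes (about 130,000 variant
rows), which keeps a full panel analysis under a few minutes while leaving
hundreds of variants per window.

Frozen generator conventions, and what they imply for recovery checks:

- The heterozygosity band applies to the baseline chromosomes; genome-wide
  heterozygosity includes the doubled chromosome and the (small) shared
  polymorphism classes, so band recovery is assessed on baseline
  chromosomes, and the diversity multiplier as focal chromosome over the
  mean of the others.
- The trio mutation density default (theta = 100 per lineage per N
  generations, roughly 100 informative sites per window) matches the order
  of variant density a deep-coverage panel shows per 100 kb. Because
  internal branch lengths are exponential, a fraction of windows deposit
  almost no pair mutations; their planted topology is unrecoverable in
  principle, so planted-topology recovery is assessed on windows whose
  truth record shows at least 60 deposited pair mutations (at the default
  density about two-thirds of windows), where recovery is essentially
  complete.
- Desk-scale trio model: N = 2000 with m·N = 0.25, preserving the product
  that governs the strength of the gene-flow signal at larger N.

What the generator does *not* emulate: linkage within windows (sites are
exchangeable given the window genealogy), mapping artifacts and paralogy
(depth noise is i.i.d. negative-binomial, not structured), realistic
divergence levels (outgroup-fixed sites are planted far below real
divergence to keep tables small), ancestral polymorphism on the backbone
(sharing depth comes from planted classes, not a full 11-taxon
coalescent), and base-composition or mutation-spectrum structure. Passing
the recovery suite therefore demonstrates estimator correctness under the
assumed statistical structure, not robustness to alignment or calling
artifacts in real data.

`simulate_f2_panel()` walks one recombinant haplotype per F2 per parent
along binned chromosomes with Poisson crossover counts (odd count =
switch), and draws diagnostic reads binomially (rate 0.5 when carrying,
0.02 otherwise, mean 100 informative reads per bin).
`simulate_bin_covariates()` generates per-bin covariates with specified
linear structure and a focal-chromosome offset; at zero noise the
regression coefficients are recovered exactly.

## Numerical and testing notes

Problem sizes in the test suite are chosen to finish in minutes on one
core: the chain/Monte-Carlo equivalence uses 1e5 loci at N = 2000; null
calibration of the D statistic uses 200 exchangeable datasets of 2500
sites; NJ additivity uses 500 random trees; subtree family-wise error uses
500 replicates of 210 windows. All simulations take explicit seeds;
resampling helpers (`block_significance`, `repeat_permutation`,
`simulate_genealogies`) save and restore the global RNG state so they
compose deterministically inside larger seeded runs. The pipeline writes
plain TSV/Newick/BED/JSON per stage; stage outputs are byte-identical under
a fixed seed and configuration (the manifest itself records wall-clock
timing and is exempt).

Known limitations: `hudson_fst` and `pairwise_diversity` recompute masks
per pair (quadratic in samples — fine at 11, slow at hundreds); the
coalescent model covers exactly three ingroup lineages and constant N; the
GFF3 reader expects CDS features with Parent attributes and selects one
primary transcript per gene by CDS length; `windowed_d` assumes
non-overlapping bins and 1-based site positions.
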