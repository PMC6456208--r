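---
title: "Sex-linked SNP discovery and X-Y divergence dating: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-linked SNP discovery and X-Y divergence dating: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinsex)
```

# The model

`spinsex` analyses RNA-seq variant data from the progeny of a single cross
in a dioecious XY species. The genetic model is a standard XY cross: the
mother contributes one of two X haplotypes per offspring, the father
contributes his X to daughters and his Y to sons. Genes in the
male-specific region of the Y (MSY) never exchange with the X, so a
nucleotide difference fixed between the father's X and Y shows a fully
informative segregation signature in the progeny; genes in the
pseudoautosomal regions (PARs) recombine with the sex-determining locus
and lose that signature in proportion to their map distance from it.

## Genotyping from allele depths

Each site x sample call uses only the `AD` allele depths. With total depth
$D$ and minor-allele depth $m$ over the two best-supported alleles, the
call is homozygous when $m/D < 0.1$ (for the majority allele), otherwise
heterozygous; $D < 10$ is missing. Two points deserve emphasis:

* The 10 % boundary is **strict**: a site with exactly 10 % minor reads is
  heterozygous. `hom_fraction` is configurable in `spinsex_config()`.
* The depth-fraction rule alone would happily "call" a 2-read site, so a
  minimum total depth (`min_total_depth`, default 10 reads) guards against
  low-coverage noise. This threshold is our addition — the fraction rule is
  only meaningful once depth is moderate — and is configurable.

Multiallelic sites are genotyped from the two best-supported alleles
(depth ties broken by allele index, REF first, so output is
deterministic); any further allele above the homozygosity fraction flags
the site as ambiguous rather than inventing a multinomial caller.

## Segregation patterns

Complete sites (callable in all progeny; `require_complete`) are matched
against three configurations, written with female genotypes first:

| pattern | females | males | interpretation |
|---|---|---|---|
| P1 | all $X^aX^a$ | all $X^aY^b$ | fixed X-Y difference |
| P2 | all $X^aX^b$ | all $X^aY^a$ or $X^aY^{\varnothing}$ | paternal-X variant; Y copy same or absent |
| P3 | all $X^aX^b$ | all $X^aY^c$ | third allele carried by Y |

P2 cannot distinguish a homozygous male from a hemizygous one without the
parental transcriptomes, so the classification records
`hemizygosity_unknown` instead of resolving it; both the X and Y slots
carry the male allele. Monoecious samples never enter classification (the
cross progeny are strictly male/female); parent columns, if present, are
not used for classification. When `require_complete = FALSE`, sites keep
their classifiable status down to `min_per_sex` (default 4) calls per sex —
the all-samples-consistent logic is preserved at reduced power.

Gene-level aggregation counts SNPs and genes per pattern; the distinct-gene
total counts a gene carrying both P1 and P2 SNPs once (set union).

## Exact association tests

Markers typed in a large unrelated panel are tested for genotype-by-sex
independence with a two-sided exact test on the 2 x k table (males vs
females-plus-monoecious; k = 2 or 3 genotype classes, zero columns
dropped). The two-sided p is the point-probability convention: the sum of
the probabilities of all margin-fixed tables whose point probability is at
most that of the observed table, with a $1+10^{-7}$ relative slack at the
boundary (the convention of standard statistical software; the 2 x 3 case
is the Freeman-Halton enumeration over the two free cells). All
probabilities are `lgamma`-based log-space quantities, so p-values around
$10^{-63}$ are computed exactly rather than reported as zero; no asymptotic
approximation is used anywhere, and no multiple-testing correction is
applied (thresholds are interpreted on raw p).

Classification uses three raw-p thresholds (`p_msy` $=10^{-60}$,
`p_significant` $=10^{-10}$, `p_weak` $=10^{-5}$): MSY, sex-associated,
recombining-or-recently-arrested, no association. Within-cross populations
use recombinant counting instead: an individual whose genotype contradicts
the expected sex-genotype coupling is a recombinant, and a marker
monomorphic in a population is reported "no variant" rather than zero.

## Substitution rates and dating

For each gene with P1 SNPs, the longest ATG-to-stop ORF over all six
frames (minimum 150 nt, configurable) hosts the phasing: the X allele
substitutes each SNP's X base into the ORF, the Y allele the Y base (for
P1 sites the Y base is the allele absent from female homozygotes). For
reverse-strand ORFs, positions are mapped and alleles complemented. The
pairs are coordinate-phased, never realigned.

Rates follow Nei-Gojobori (1986) with the standard nuclear genetic code
(hard-coded, not configurable):

* **Sites.** Per codon position, the synonymous share is the fraction of
  the three single-base changes that preserve the amino acid, excluding
  changes to stop codons from the denominator; $S$ is summed over codons
  and averaged between the two sequences, $N = 3 \times \text{codons} - S$.
* **Differences.** Codon pairs differing at $d$ positions are scored along
  all $d!$ minimal mutational pathways; pathways through stop codons are
  excluded and the synonymous/non-synonymous step counts averaged over the
  remaining ones. If every pathway is blocked the codon pair is skipped and
  counted, as are codons with non-ACGT symbols.
* **Correction.** $K_S = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p_S)$ with
  $p_S = S_d/S$ (likewise $K_A$); the correction is undefined at
  $p \ge 0.75$ and the functions raise a saturation error rather than
  returning `NaN`. Gapped/ambiguous codons are skipped per codon
  (pairwise deletion).

Divergence time is the molecular clock $T = K_S/2r$ (the factor 2 because
both lineages accumulate substitutions), with
$r = 6.5\times10^{-9}$ substitutions/site/generation and one year per
generation by default; both are configurable. Per-class summaries report
the mean and standard error of per-gene $K_S$/$K_A$ and the time **both**
ways — $T$ of the mean $K_S$, and the mean of per-gene $T$ — because the
two aggregations differ for skewed $K_S$ distributions and neither is
canonically "the" estimate; `summarise_rates()` returns both and asserts
neither.

Class comparisons (e.g. MSY vs PAR rates) use the exact two-sided
Wilcoxon rank-sum test with mid-ranks (`rank_sum_exact()`). The null
distribution is obtained by a counting recursion over integer-doubled
mid-ranks — mathematically identical to enumerating all
$\binom{N}{n_1}$ assignments, but feasible at $N = 30$ — so ties need no
normal approximation.

## Expression

RPKM is reads / (kb of transcript) / (millions of aligned reads in the
sample). Sex-biased expression uses a one-way ANOVA $F$-test on
log₂(RPKM + 0.01); the pseudocount (configurable) exists only because
log of zero is undefined, and with 4 + 4 samples the test has df = (1, 6).
The Y/X allele expression ratio pools raw read depths over male samples
and over the gene's qualifying SNPs (heterozygous in **every** male;
at least `min_snps` = 2 of them), then divides the pooled Y depth by the
pooled X depth — pooling, not averaging per-SNP ratios, weights SNPs by
their information content; per-SNP ratios are emitted for diagnostics.

# The synthetic-data generator

`sim_config()` / `generate_dataset()` simulate the statistical structure
the analysis assumes, with a single seeded RNG (the previous RNG state is
restored on exit) so datasets are byte-identical under a seed.

* **Reference genes**: ATG + uniform sense codons + stop; internal stops
  impossible by construction.
* **MSY genes** evolve an X and a Y lineage from the ancestor: each
  lineage proposes Poisson($L \cdot r \cdot T$) substitutions; synonymous
  proposals are always accepted, non-synonymous ones with probability
  `ka_ks_target`, stop-creating ones never. Realised synonymous divergence
  is therefore $2rT$ per synonymous site in expectation — the simulation
  substitution process is uniform across bases (Jukes-Cantor), exactly
  matching the analysis-side correction by design; richer substitution
  models are deliberately excluded.
* **PAR/autosomal genes** carry segregating polymorphism only: each site
  is polymorphic with probability `pi` and its derived allele is placed on
  a uniform non-empty proper subset of the four parental haplotypes.
* **The cross** fixes progeny counts at 8 + 8 (balanced panels, a
  conditioned draw, not Bernoulli sex). MSY genes never recombine; PAR
  genes switch between the paternal X and Y with probability
  `par_recomb`; autosomes segregate independently of sex.
* **Depths**: total Poisson(`depth_mean`); heterozygotes split reads
  Binomially at 1/2, shifted to $b/(1+b)$ for the Y allele at fixed X-Y
  sites in males (`allelic_bias` $b$); each read miscalls with probability
  `error_rate` to a uniformly chosen other base, and reads landing outside
  the site's allele list are not depth-counted (as real `AD` fields
  behave). Expression counts are negative binomial with an optional sex
  effect on a random gene subset.
* **The unrelated panel** (`simulate_panel()`) reuses the X/Y haplotypes
  with independent X draws per individual — sufficient to reproduce
  exact-test behaviour at panel scale without a coalescent engine.

Default parameter values and why: 50/100/200 genes across MSY/PAR/autosome
at 900 coding nt give a few hundred variant sites — enough for stable
recovery statistics while the full suite stays fast; X-Y divergence 0.4 My
and $r = 6.5\times10^{-9}$/site/year put ~1 synonymous fixed difference on
a typical MSY gene, the young-sex-chromosome regime this method targets;
depth 50 sits inside a realistic 30-65x transcriptome range; per-read
error 0.005 is typical post-filter short-read accuracy; heterozygosity
`pi` = 0.002 is a realistic transcriptome-wide diversity for an outcrossing
plant line; `par_recomb` = 0.2 places PAR genes at a plausible map distance
from the sex locus; `ka_ks_target` = 0.27 mirrors the weak purifying
regime observed for young sex-linked genes. These defaults are the study
conditions of the validation suite and are not tuned per run.

## What the simulation does not emulate

Truth MSY genes carry only fixed X-Y differences, and PAR/autosomal genes
only segregating polymorphism. Consequently pattern 2 arises in simulated
data only by chance (a maternal-het site whose 16 progeny calls happen to
split perfectly by sex, probability $2 \cdot 2^{-16}$ per informative
site) — in real data P2 is common, produced by paternal-X private alleles
and hemizygous deletions, which the truth model excludes. There is no
coalescent ancestry, linked selection, assembly error, mapping bias,
isoform structure or read-level simulation; passing recovery tests
demonstrates correctness of the inference chain under the stated model,
not robustness to those real-data artefacts.

# Numerical and design choices

* Coordinates are 1-based in all user-facing tables and VCF (internal ORF
  spans are 0-based half-open, as documented); `phase_alleles()` takes
  1-based CDS positions.
* Fisher p-values: log-sum-exp over enumerated log probabilities; the
  enumeration's total probability equals 1 to $10^{-9}$ (tested).
* ORF ties break to the forward strand, then lowest frame, then lowest
  start, making results deterministic on palindromic constructions.
* `evolve_pair()` refuses expected divergence $2rT \ge 0.75$ (clock
  saturation) instead of silently wrapping.
* Degenerate inputs: empty call vectors, empty alignments, all-pathways-
  blocked codon pairs, zero pooled X depth and monomorphic markers all
  have defined, tested behaviours (error, skip-with-count, or NA flag).
* Validation problem sizes: the acceptance suite simulates the full
  350-gene cross twice (allelic bias 1.0 and 0.5) and checks the NG86
  engine against an independent pathway-enumeration oracle on 1000 random
  300-codon pairs; both finish in seconds.

# Known limitations

* The exact test supports 2 x k for k <= 3 only (sufficient for
  biallelic/triallelic genotype classes); no network algorithm for general
  r x c tables.
* Maximum-likelihood codon models (dN/dS), transition/transversion-weighted
  pathway variants and multiple-sequence alignment are out of scope.
* ORF finding is a longest-ORF heuristic; genes whose true CDS is not the
  longest ORF will be phased in the wrong frame.
* Likelihood-based genotyping and genotype qualities are intentionally
  absent: the depth-fraction rule is the method under study.
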