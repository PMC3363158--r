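---
title: "Pedigree-aware QTL mapping: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-aware QTL mapping: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pedgwas implements four complementary association-mapping methods for
quantitative traits in pedigreed populations — the setting of livestock
half-sib designs, where family structure both creates the linkage signal
the methods exploit and the spurious associations they must guard
against — together with a self-contained simulator of such a population
and an evaluation layer that scores detections against the simulated
truth.

This vignette is the package's methods account: the models and their
assumptions, the simulator's design, the numerical choices, and the
decisions taken where the design was genuinely open.

## The population and the simulator

`simulate_qtlmas()` generates, under one seed, a three-tier pedigree of
unrelated founders and their progeny: by default 20 sires each mated to
10 dams, 15 progeny per full-sib family, with 10 progeny per family
phenotyped and genotyped — 2000 study animals.  Markers live on a
genetic map of 5 chromosomes with 1998 bi-allelic SNPs each at 0.05 cM
spacing (positions are genetic throughout; the package never uses base
pairs).

**Founder haplotypes.**  Founder LD is modelled by a first-order Markov
chain along each chromosome: site *j* copies site *j−1*'s allele with
probability `ld_strength` (default 0.95), otherwise draws from its base
frequency (uniform on a range respecting `maf_floor = 0.05`).  The chain
is cheap, seeds exact desk-scale tests, and produces haplotype blocks
whose length is tuned by a single number.  It does not reproduce a
coalescent's heavy-tailed block structure or allele-frequency spectrum —
a deliberate simplification, which is why passing recovery tests here
demonstrate correctness of the machinery, not field performance on real
genomes.

**Transmission.**  `gene_drop()` recombines each parent's two gametes
with a Poisson(map length in Morgans) crossover count per chromosome and
uniform crossover positions — the Haldane model, no interference —
preserving maternal/paternal phase labels.  Scans therefore run on true
phase; statistical phasing error is out of scope.

**The eight QTL** (`default_qtl_truth()`) follow the benchmark
architecture: a multi-allelic QTL of largest effect on chromosome 1 at
2.85 cM, two linked additive QTL on chromosome 2 (81.90, 93.75), two
additive QTL on chromosome 3 (5.00, 15.00), an imprinted QTL on
chromosome 4 (32.20), and an epistatic pair on chromosome 5 (36.30,
99.20).  Design choices, each configurable:

* the seven single-locus QTL sit exactly on map SNPs (every true
  position is a multiple of the 0.05 cM spacing), so their alleles are
  the SNP's own alleles;
* the multi-allelic QTL is a separate 3-allele label locus riding on
  founder haplotypes and transmitted with recombination, so no single
  bi-allelic SNP can tag it perfectly — the minimal allele count that
  makes single-SNP tagging imperfect;
* the imprinted QTL is expressed through the paternally inherited allele
  (`imprinting_parent`, configurable); parent-of-origin was an open
  choice;
* the epistatic pair contributes small marginal terms plus an
  additive-by-additive interaction, the product of centred dosages.

**Epistatic dependency.**  The two epistatic loci additionally receive
positively associated founder alleles (`epi_founder_ld = 0.6`: a founder
allele at the second locus is copied from the first with that
probability).  A small, drifted founder population accumulates exactly
this kind of long-range LD, and it is what makes the first member of the
pair absorb most of the pair's signal — without it the two loci are
independent and fitting one could never weaken the other.  The
`conditional_scan()` experiment (is the second signal still there once
the first is a covariate?) probes this masking.

**Effect sizes.**  The benchmark never published its effect sizes, so
the variance fractions here are declared defaults, not inferences:
multi-allelic 0.102 (the one anchored value: the largest QTL explains
about 10% of phenotypic variance), then 0.06, 0.04, 0.05, 0.03 for the
additive QTL, 0.04 imprinted, 0.03/0.015 marginal plus 0.04 interaction
for the epistatic pair, and a polygenic heritability of 0.30.  Each
term's coefficient is rescaled once against its realised sample variance
(one pass, no iteration), and realised fractions are reported back on
the truth table.  Realised fractions sit slightly below targets because
linked QTL terms covary; that is left visible rather than corrected.
Polygenic values follow the pedigree: founder values
N(0, σ²~u~), offspring = parent average + Mendelian-sampling
deviation N(0, σ²~u~/2).

## The additive relationship matrix

`additive_relationship()` builds Wright's numerator relationship matrix
A by the tabular method over the full pedigree (founders included);
analyses subset it to the 2000 phenotyped animals via
`kinship_submatrix()`.  Dense storage is used throughout — at n = 3220 a
dense A is 80 MB and every downstream operation wants it dense anyway.

## Mixed-model core

All three frequentist methods share one model family,

y = Xb + Σ~k~ Z~k~u~k~ + e,  u~k~ ~ N(0, K~k~σ²~k~),  e ~ N(0, Iσ²~e~),

fitted by REML.  The restricted likelihood is the standard criterion
−½[(n−p)log 2π + log|V| + log|X′V⁻¹X| + y′Py]; tests difference it, so
the convention constant is irrelevant.  Numerics:

* **single kernel** (polygenic only, or polygenic plus SNP covariates):
  rotate by the kernel's eigenvectors and profile the variance ratio —
  a 1-D optimisation bracketed on a log-ratio grid, then `optimize()` to
  tolerance 10⁻⁶; the σ²~u~ = 0 boundary is always evaluated and wins
  ties;
* **two kernels** (polygenic + haplotype/cluster effect): the polygenic
  kernel is eigendecomposed once per data set and the label effect —
  never more than 16 window labels or 6 genotype classes — is handled by
  the Woodbury identity on the q×q system; Nelder–Mead on the two
  log-ratios, with one evaluation pinned at the null fit's ratio and the
  label variance at its floor, which guarantees the full model's
  log-likelihood never falls below the null's (the nesting the LRT
  requires);
* components are clamped at 10⁻⁸; a flat profile (e.g. an identity
  kernel duplicating the residual) is flagged `identifiable = FALSE`
  rather than reported with fabricated precision.

Variance-component LRTs use the boundary null ½χ²(0) + ½χ²(1) by
default (`boundary = FALSE` switches to plain χ²(1)).  A consequence
worth knowing: under a null phenotype about *half* of all windows land
exactly on the σ²~h~ = 0 boundary with p = 1 — not 95% of them; the
boundary mass of this mixture is one half.  The tests assert that
calibrated behaviour.

## The four mapping methods

**MMA** (`scan_mma()`): per SNP, dosage (0/1/2) enters as a fixed
covariate next to the polygenic effect; the Wald statistic
(β̂/SE)² is referred to χ²(1).  By default the null model's variance
components are re-used for every SNP (the population-parameters-
previously-determined shortcut standard in mixed-model GWAS);
`refit = TRUE` re-estimates them per SNP, and the two agree closely when
individual SNP effects are small.  The reported allele substitution
effect is the dosage-coding slope (half the homozygote contrast).
Monomorphic SNPs are emitted flagged non-estimable and excluded from the
Bonferroni denominator — they contribute no test.  `joint_fit()` fits a
detected set simultaneously and reports per-SNP variance explained as
100·var(x~j~β̂~j~)/var(y) on the analysis sample — the definition is
stated because reported "effect %" columns are ambiguous in the
literature.

**RHM** (`scan_rhm()`): sliding windows of 4 SNPs; each individual's
maternal and paternal window haplotypes enter as two draws of one
i.i.d. random label effect with common variance σ²~h~ (equal maternal/
paternal variance), tested against the no-haplotype null by boundary
LRT, Bonferroni over the number of windows (the denominator was an open
choice; windows is the realised test count).  Rare labels are *not*
pooled by default — as random effects they shrink naturally, which is
the argument for random over fixed haplotype effects — but a
`min_label_count` pooling option exists.  Significant-window positions
are reported at the window midpoint.

**GENMIX** (`scan_genmix()`): per focal marker, the widest surrounding
region in which every site pair passes the four-gamete condition is
grown greedily (left neighbour tried first each pass); the result is
audited to be unextendable by one site at either end, though a greedy
interval need not be the globally widest one — with the audit, the
distinction is immaterial in practice and the greedy rule is
deterministic.  The local perfect phylogeny is built by inclusion
ordering of derived-carrier sets with the majority allele as ancestral
(allele 0 ancestral on an exact 50/50 tie), duplicate columns merged
into one edge, and multifurcations resolved by zero-length edges in site
order.  Cutting the tree at the root, its two children and its four
grandchildren yields up to 1 + 2 + 4 = 7 clusterings of the haplotypes
into 2 or 3 clusters.  Each clustering becomes a random effect: by
default indexed by the individual's unordered genotype class (11, 12,
13, 22, 23, 33) with a single variance — the literal reading of the
model this follows — with an alternative `mode = "hap"` where each
haplotype cluster's effect enters once per carried haplotype; both are
provided because the published model statement supports both readings.
A marker's p-value is the minimum over its clusterings, and the default
Bonferroni divides by the number of *markers*, not the roughly 7× larger
number of fitted models — deliberately mirroring the permissive
correction whose false-positive cost the evaluation layer measures;
`strict_mt = TRUE` divides by the realised test count.

**BVS** (`gibbs_bvs()`): all SNPs fitted simultaneously,
y = μ + Σ x~j~β~j~ + e, with a two-component normal mixture on effects:
with prior probability π = 0.02 a SNP is "large" (variance σ²₁), else
"small" (σ²₀), both variances estimated with scaled-inverse-χ²(df = 4)
priors.  The slab scale spreads an assumed 30% of phenotypic variance
over the π·M large SNPs, the spike 1% over the rest; the residual prior
scale is half the phenotypic variance.  Single-site Gibbs updates (in
compiled code, driven by R's RNG so a seed fixes the chain exactly)
draw each effect from its conditional normal and each indicator from the
conditional Bernoulli comparing the two components' marginal
likelihoods; a relabeling guard swaps the two variances if a draw
inverts their order.  The PIP is the post-burn-in indicator mean;
defaults 50 000 iterations, 10 000 burn-in, thin 10 (tests and examples
use shorter chains; the sampler mixes quickly at these sizes because
effects are redrawn every sweep).  No polygenic term is included by
default — the markers themselves absorb the polygenic signal — but
supplying the relationship matrix adds a pedigree polygenic effect,
sampled in the kinship eigenbasis with its own conjugate variance
update.  Calling:
SNPs with PIP > 0.10 (Bayes factor ≈ 5.4 against the 2% prior), with
runs of candidates closer than `prune_window_cM = 5` collapsed to their
PIP maximum, ties to the lowest position.

A calibration caveat the tests document: with π *fixed* and the slab
variance estimated, a pure-noise panel of 500 markers always hands its
luckiest marker a PIP well above 0.10 — the slab equilibrates to the
tail of the chance correlations.  Mean PIP stays at the prior level and
only ~1% of markers cross the threshold, but the method's null is
permissive, which is precisely how a spike-and-slab scan produces
occasional false positives in practice.

## Evaluation

`match_qtl()` matches calls to true QTL one-to-one, greedily by
ascending distance within chromosomes (ties toward the lower call
position), with a 10 cM identification tolerance by default.
One-to-one matching prevents two calls near one QTL from double
counting — the two linked chromosome-2 QTL need two distinct calls.
`score_method()` reports detected / missed / false-positive counts and
precision as the mean absolute cM error over matched QTL;
`calls_from_scan()` first collapses runs of consecutive significant
markers or windows to their most significant entry, one call per
region.  `compare_methods()` merges several methods into one report and
`autoplot()` draws the positions figure.

## Test and example scales

The correctness suite runs oracle comparisons at desk scale (n ≤ 50
REML against dense brute force, n = 12 GLS against explicit inverses,
2³ posterior enumeration for the Gibbs sampler, exhaustive interval
audits on 20×40 panels).  Calibration and recovery experiments use
reduced problem sizes chosen to keep the suite fast while leaving the
statistical claims comfortably powered: the Wald-scan type-I rate uses
200 animals × 200 SNPs × 200 replicates (one genotype panel, fresh
phenotypes); MMA, BVS and the conditional-masking experiments use the
full 2000-animal pedigree with one 100 cM chromosome of 300 SNPs;
RHM/GENMIX recovery uses a 400-animal pedigree with one 60 cM
chromosome, the planted effect attached to a local founder haplotype
string of frequency ≈ 1/3.  The full default configuration (9990 SNPs)
is exercised for the simulator itself; genome-wide scans at that scale
run in minutes-to-hours depending on the method and are intended for
scripted experiments, not the test suite.

## Known limitations

* Founder LD is a Markov chain, not a coalescent; allele-frequency
  spectra and long-range LD (beyond the deliberately planted epistatic
  dependency) are unrealistic.
* True phase is assumed; there is no missing-data or phasing-error
  handling (a trio-phasing utility exists for experiments).
* The BVS null is permissive under fixed π, as discussed above.
* GENMIX tree building assumes complete, error-free haplotypes; with
  recurrent mutation or genotyping error the four-gamete intervals
  collapse toward single markers.
* Dense linear algebra throughout: the design point is n ≈ 2000;
  nothing here is meant for biobank scale.
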