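---
title: "Phenotypic covariance across the relatedness spectrum: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic covariance across the relatedness spectrum: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(relspectrum)
```

## The scientific question

How much of the similarity between two people is genetic? The classical
answer regresses the pairwise phenotypic covariance on the genetic
relationship: for standardised phenotypes the slope is the heritability.
With dense SNP data the genomic relationship $\pi_{ij}$ can be computed for
*every* pair in a population sample — from nominally unrelated pairs
($\pi < 0.02$) through distant relatives ($0.02 < \pi < 0.05$) to full
sibs and identical twins — so the whole covariance-versus-relatedness curve
is observable. Its shape is informative:

* the slope among unrelated pairs estimates the **SNP-tagged heritability**
  $h^2_{SNP}$ (only variation in $\pi$ that reflects sharing at or near the
  markers contributes);
* the slope among close relatives ($\pi > 0.05$) approaches the full
  pedigree heritability, because close relatives share long chromosomal
  segments and hence causal variants the marker panel tags poorly;
* between the two regimes the covariance rises *faster* than
  $\pi\,\hat h^2_{SNP}$ — the signature of rare causal variants in
  imperfect linkage disequilibrium (LD) with the common markers used to
  build $\pi$;
* assortative mating (AM) bends the close-relative curve upward and lifts
  the intercept, because mate choice on the phenotype builds correlations
  between trait-increasing alleles at distant loci (gametic phase
  disequilibrium, GPD).

This package implements that analysis chain — phenotype preparation,
genomic relationships, relationship bins with blocked-jackknife errors,
Haseman–Elston (HE) regressions, an equilibrium AM model, full-sib IBD
regression, and inverse-variance meta-analysis — together with a
multi-generation cohort simulator that generates data with exactly these
features, standing in for access-controlled biobank data.

## Phenotype preparation

Raw trait values are adjusted by ordinary least squares for sex, genotyping
batch, age and year of birth (all as factors), optionally adding birth
contemporary group (CG, a geographic factor) and principal-component (PC)
scores — four nested models. Residuals more than 5 sample standard
deviations from the mean are excluded in a single pass, the model is refit,
and residuals are standardised to mean 0 and unit sample variance ($n-1$
denominator) within each sex. Because per-sex rescaling can reintroduce
minute covariate components when the two sexes receive different scale
factors, `prep_phenotype()` alternates refit and rescale until the values
are a fixed point; preparation is therefore idempotent to numerical
precision. Whether the outlier pass acts on residuals (default) or raw
values is configurable, since either order is defensible and the choice is
not determined by the analysis it feeds.

`partial_r2()` quantifies what a factor adds over a baseline model as
$(RSS_{base} - RSS_{full})/TSS$; with several hundred CG levels this
statistic carries an overfitting bias of roughly $(\mathrm{df})/n$, which
matters at simulation scale and is why recovery tests use modest level
counts.

## Relationships, bins, and the streaming tally engine

`compute_grm()` uses the standard frequency-weighted form
$\pi_{ij} = \frac{1}{m}\sum_l \frac{(x_{il}-2p_l)(x_{jl}-2p_l)}{2p_l(1-p_l)}$
with frequencies from the analysis sample unless supplied. Monomorphic
variants are dropped with a count. Binary GRM files use the GCTA dialect
(4-byte little-endian floats, lower triangle row-major) and round-trip
bit-exactly; genotypes can be exchanged as PLINK-1 bed/bim/fam triplets.

Pairs are assigned to half-open bins $[\ell_k, u_k)$ — ties go up — after
excising known parent–offspring pairs, whose expected covariance differs
under AM. The published analysis used 54 bins chosen from the observed
$\pi$ distribution; the exact edges are not printed anywhere, so
`published_bin_edges()` is an explicit *reconstruction* with the same
structure (40 unrelated bins, 6 distant-relative bins, 8 relative-peak
bins) and every function accepts user edges.

Two computational paths produce identical numbers: an explicit pair table
(fine to a few thousand individuals) and a streaming path that forms
$G = WW^\top/m$ in row blocks and never materialises the pair list, which
handles the $2\times 10^8$ pairs of a 20,000-individual analysis in a few
minutes on one core. Both paths accumulate sufficient statistics per
(bin, jackknife-block-pair) cell, so every leave-one-block-out replicate is
obtained by subtraction from one pass — the blocked jackknife (100 blocks
of individuals by default; a pair is deleted when either member's block is)
costs essentially nothing beyond the single sweep. Pair-level regressions
(`individual_he()`, `two_component_he()`) use the same trick with
closed-form normal equations.

## HE regressions and the $\pi^2$ epistasis term

`weighted_he()` fits mean cross-products on mean relationships by weighted
least squares (weights $N_k$), the bin-level equivalent of individual
cross-product HE regression; the two agree exactly when every bin holds one
pair, a property the tests assert. All fits carry an intercept — a nonzero
intercept is evidence of AM or shared environment, not a nuisance.
Additive-by-additive epistasis contributes covariance proportional to
$\pi^2$, so `epistasis_fit()` adds a quadratic term and reports a Wald test
from the jackknife standard error.

## The assortative-mating equilibrium model

Under phenotypic assortment with spousal correlation $r$, additive variance
grows over generations until gametic phase disequilibrium reaches a steady
state. For a relative pair separated by $d$ meioses, the equilibrium
phenotypic covariance is approximately
$(0.5)^d\, h^2_{EQ}\, (1 + r h^2_{EQ})^d$. Writing
$d_k = \log(\bar\pi_k)/\log(0.5)$ and $y_k = c_k/\bar\pi_k$ turns this into
the linear model $\log y_k = \alpha + \beta d_k$ with
$\alpha = \log h^2_{EQ}$ and $\beta = \log(1 + r h^2_{EQ})$, inverted as
$h^2_{EQ} = e^a$ and $r = (e^b - 1)/e^a$ (`fit_am()`). The fit is weighted
by $N_k$ by default — the weighting is a free choice and switchable —
and is exactly linear in $(d_k, \log y_k)$, so noiseless bins are recovered
to machine precision. Bins with non-positive covariance are dropped with a
warning (their log is undefined).

Design consequences (`expected_design_params()`): full-sib IBD regression
and the classic twin contrast $2(r_{MZ} - r_{DZ})$ both estimate
$h^2_{EQ}(1 - r h^2_{EQ})$ — the random-mating genetic variance scaled by
the equilibrium phenotypic variance — while the displaced variance
$h^2_{EQ} - h^2_{FS}$ appears as spurious "shared environment".
`equilibrium_from_design()` inverts the identity by solving
$r x^2 - x + h^2_{design} = 0$, taking the smaller root because it is the
branch continuous with the $r \to 0$ limit (the larger root diverges);
standard errors propagate by the delta method. The mapping between the
random-mating input heritability and $h^2_{EQ}$ is validated empirically
against the simulator rather than by a closed form.

## Full-sib IBD regression

Full sibs share half their genome on average, with segregation variance
around that mean (SD $\approx 0.037$ genome-wide). Regressing sib-pair
cross-products on realised IBD isolates within-family genetic variance —
immune to shared environment, which loads on the intercept.
`simulate_sib_ibd()` models each meiosis as a Haldane crossover process
(Poisson counts, mean $L/100$ per chromosome of $L$ cM) on a packaged
22-autosome map totalling ~3,546 cM; the sib-pair strand-equality process
is then a two-state telegraph process whose shared length is computed
exactly per chromosome and combined with length weights. A zero-length
chromosome degenerates to the two-coin-flip distribution
$\{0, \tfrac12, 1\}$ with probabilities $\tfrac14,\tfrac12,\tfrac14$.

`fit_variance_components()` fits the individual-level model
$y^* = \mathbf{1}\mu + a + c + e$ with $a \sim N(0, A\sigma^2_a)$ (A has
realised IBD off-diagonals), $c \sim N(0, C\sigma^2_c)$ and
$e \sim N(0, I\sigma^2_e)$ by direct maximisation of the restricted
likelihood over the three components: families are tiny independent
blocks, two-member families have closed-form determinants and inverses
(vectorised), larger sibships use Cholesky per block. Standard errors come
from the observed information at the optimum; negative components are
constrained at zero with a note, and all-singleton data triggers a
degeneracy warning rather than a spurious fit. Pair-level regression and
the variance-component fit are equivalent estimators of the same
quantities on pair-only data, and the tests check this over replicated
simulations. MZ pairs carry no segregation information (IBD exactly 1) and
are excluded from the pair regression by construction.

`fullsib_correlation()` converts components to the sib correlation
$r_{FS} = c^2_{FS} + \tfrac12 h^2_{FS}$ with the large-sample
approximation $se = \sqrt{(1 - r_{FS}^2)/N}$, and `ivw_meta()` combines
studies by fixed-effect inverse-variance weighting ($w_i = 1/se_i^2$),
reporting Cochran's Q for information only. Report tables round to two
decimals, half away from zero.

## The cohort simulator

The generator produces data with precisely the statistical structure the
analyses assume, at a scale a single core can handle:

* **Founders and LD.** Causal variants get one tagging marker each; on
  every haplotype the marker allele is drawn conditional on the causal
  allele from two-locus haplotype frequencies solving the target $r^2$ in
  closed form (the oracle used by the tests is the same closed form
  evaluated independently). The attainable $r^2$ between loci of unequal
  frequency is bounded — $D$ cannot exceed $\min(p(1-q), (1-p)q)$ — so tag
  frequencies are sampled from the feasible part of the marker MAF range
  and an explicit error names the bound when no feasible frequency exists.
  Perfect tagging forces equal frequencies and duplicates the causal
  haplotypes exactly.
* **Transmission.** Variants occupy positions on the autosomal genetic
  map; gametes are formed by Haldane crossovers, a causal variant and its
  tag sharing a position (complete linkage). Founders start in linkage
  equilibrium, so the marker panel carries no population LD structure
  beyond the designated causal–tag pairs; what linkage adds is realistic
  *co-segregation within families*, and with it the genome-wide sib IBD
  segregation SD of ~0.037 that full-sib IBD regression feeds on. Modelling
  transmission without linkage would shrink that SD by an order of
  magnitude and silently destroy the power of the within-family design —
  this is why the generator carries a genetic map at all.
* **Assortment.** Each generation, mates are paired by rank on phenotype
  plus noise whose scale is calibrated by bisection so the realised spousal
  correlation matches the target (deterministic given the seed); couples
  from the same family are separated by local rank swaps, as the
  equilibrium theory assumes no inbreeding. Interior generations have two
  offspring per couple (constant size); the final generation has a
  configurable sibship size with optional MZ/DZ twin pairs, MZ co-twins
  sharing gametes exactly. Realised spousal correlation, additive and
  phenotypic variance are logged per generation; equilibrium detection is
  deliberately *not* automatic — a fixed number of generations (default
  10) keeps runs reproducible, and the log shows the plateau.
* **Phenotypes.** Additive values are $\beta^\top(x - \bar x_0)$ over
  causal variants, scaled so the founder variance equals `h2_rm` exactly;
  additive-by-additive values are sums of products of centred dosages over
  disjoint causal pairs scaled to `v_aa`; shared environment is constant
  within family with variance `c2`; the residual fills founder variance
  to 1. Effects are drawn once and fixed, so later generations inherit the
  same genetic architecture while variances evolve under AM.
* **Stratification.** `simulate_covariate_stratification()` adds CG labels
  and batch effects with stated variance shares (relative to the
  pre-stratification variance), PC scores correlated with a familial
  ancestry gradient (founder draw, midparent-plus-noise transmission), and
  optionally shifts allele frequencies of designated markers along that
  gradient. The frequency shifts are applied as family-level haplotype
  perturbations — a deliberately coarse device that preserves MZ identity
  and the phenotype-side recovery tests but does not maintain exact
  Mendelian consistency at those markers; it is off by default.

### What the simulator does and does not emulate

It reproduces: the three-regime covariance curve (via rare, imperfectly
tagged causal variants), AM equilibrium behaviour and its design
consequences, realistic sib IBD segregation, ACE-style twin structure,
shared environment, $\pi^2$ epistatic covariance, and covariate
stratification. It does not model: population LD beyond causal–tag pairs
(no coalescent history), X-linked or dominance effects, selection,
genotyping error or missingness, indirect/associative genetic effects, or
social homogamy — so passing tests show the estimators behave correctly
under the stated model, not that real data are free of those additional
complications.

## Marker density, bin choice, and problem sizes

With $m$ markers, the IBS relationship of a truly unrelated pair has
sampling noise of SD $1/\sqrt m$. The published analysis used ~1.1M SNPs
(noise ~0.001), so its bins at $\pi > 0.05$ contain only genuine
relatives. At simulation scale ($m$ in the low thousands) the noise floor
is 0.02–0.035, and the enormous mass of unrelated pairs leaks into bins up
to several noise SDs — bins between 0.05 and ~0.09 become mixtures
dominated by displaced unrelated pairs. The AM fit in the shipped analyses
therefore uses bins with $\bar\pi > 0.09$ (relative-dominated at
$m = 2{,}500$), the analogue of the published choice of relative-pair bins
at the original marker density; the threshold is a function argument, not
a constant. The incomplete-LD demonstration, which needs clean
distant-relative bins at $\pi \approx 0.03$, uses $m = 16{,}000$ on a
smaller cohort instead.

The blocked jackknife itself deserves a calibration note. For pair
statistics, every pair is deleted in two replicates (one per member's
block), which double-counts the pair-noise variance component — a
$\sqrt 2$ conservatism on that slice of the variance — and statistics
sensitive to bin composition in the IBS-noise tail inherit a little more.
At real-data marker densities the pair-noise slice is negligible and the
jackknife is essentially exact; at simulation scale the calibration check
is therefore run where the individual-level variance component dominates
(the individual-pair slope on samples of 2,400 at 200 markers), and the
calibration target is the spread of the estimator across disjoint
subsamples of one population — the conditional sampling variance the
jackknife actually estimates — not across regenerated architectures.

Problem sizes used by the shipped tests and scripts — chosen as the
largest a single core handles comfortably while leaving the conclusions
unchanged: the AM end-to-end run breeds 8,000 founders for 10 generations
and analyses the last two (20,000 individuals, $2\times10^8$ pairs,
12,000 sib pairs); the LD demonstration uses 1,500 founders growing by
half each of 3 generations at 16,000 markers (dense cousin and
second-cousin classes); the epistasis check 4,000 founders with MZ twins;
the jackknife calibration 30 disjoint subsamples of a 72,000-founder
population. The jackknife uses 100 blocks of individuals throughout.

## Numerical and policy choices

* Sample ($n-1$) variances everywhere.
* Half-open bins, ties up; deterministic given edges.
* Jackknife block assignment is a seeded random near-equal partition (the
  assignment scheme is not dictated by anything; a seed makes it
  reproducible), deleting by individual — both members gone means the pair
  is gone.
* REML convergence tolerance $10^{-8}$ on the restricted log-likelihood;
  L-BFGS-B with lower bounds at zero.
* The equilibrium quadratic takes the smaller root; an inconsistent
  $(h^2, r)$ pair (negative discriminant) is an error, not a clamp.
* Intercept tests use Wald z from jackknife ses with Bonferroni adjustment
  across traits when several are analysed.
* Spousal correlations for published-estimate adjustments are required as
  inputs; nothing is hard-coded, because the appropriate $r$ depends on
  the trait and source.

## Known limitations

Bin means, not pair-level values, drive the AM fit, so very sparse bins
(e.g. an MZ bin with a handful of pairs) contribute little and can wobble;
the $N_k$ weighting keeps them harmless. The AM covariance formula is an
approximation that treats $\pi$ as $(0.5)^d$; sibs and grandparent pairs
with equal $\pi$ but different $d$ are merged by construction. The
simulator's marker panels are far smaller than real arrays, which is why
IBS noise management (above) is part of the analysis design rather than an
afterthought. REML standard errors come from the observed information and
are slightly optimistic near the zero boundary.
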