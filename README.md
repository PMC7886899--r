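# relspectrum

Tools for studying how the phenotypic covariance between pairs of
individuals changes with their genomic relationship ($\pi$) — from
nominally unrelated pairs ($\pi < 0.02$) through distant relatives
($0.02 < \pi < 0.05$) to full sibs and identical twins — and for
untangling what assortative mating does to heritability estimates from
different experimental designs.

The package is aimed at quantitative geneticists who want to run (or
teach, or stress-test) this analysis chain without access-controlled
biobank data: a multi-generation cohort simulator generates genotypes and
phenotypes with the relevant structure, and every estimator operates on
plain matrices and tables, so externally supplied data in PLINK-1 or GCTA
GRM binary layout can be substituted for the simulator's output.

## What it computes

* **Binned Haseman–Elston regression.** For standardised phenotypes the
  mean cross-product in relationship bin $k$ is
  $c_k = \frac{1}{N_k}\sum y_i y_j$, and the weighted regression of $c_k$
  on $\bar\pi_k$ (weights $N_k$) estimates heritability: the SNP-tagged
  heritability $\hat h^2_{SNP}$ over unrelated bins, the pedigree-scale
  $\hat h^2_{\pi>0.05}$ over close-relative bins. Standard errors come
  from a blocked jackknife over 100 blocks of individuals. Individual-pair,
  two-component (close-relative matrix) and quadratic ($\pi^2$,
  additive-by-additive epistasis) variants are included.
* **Assortative-mating equilibrium model.** Relative-pair covariance under
  equilibrium assortment is $(0.5)^d h^2_{EQ} (1 + r h^2_{EQ})^d$ for $d$
  meioses; with $d_k = \log\bar\pi_k/\log 0.5$ the model is log-linear and
  inverts to $\hat h^2_{EQ} = e^a$, $\hat r = (e^b - 1)/e^a$. Design
  expectations follow: full-sib IBD regression and twin designs estimate
  $h^2_{EQ}(1 - r h^2_{EQ})$, and the displaced variance masquerades as
  shared environment.
* **Full-sib IBD regression.** Genome-wide IBD sharing between sibs is
  simulated exactly under a Haldane crossover model on the 22 autosomes
  (mean 0.50, SD ≈ 0.037); regression of sib cross-products on realised
  IBD — or the equivalent three-component REML on family blocks —
  separates within-family genetic variance ($h^2_{FS}$) from shared
  environment ($c^2_{FS}$).
* **Meta-analysis.** Fixed-effect inverse-variance combination of
  published full-sib regression studies, and derived sib correlations
  $r_{FS} = c^2_{FS} + \tfrac12 h^2_{FS}$ with
  $se = \sqrt{(1-r_{FS}^2)/N}$.
* **Cohort simulator.** Multi-generation phenotypic assortment with a
  calibrated spousal correlation, Mendelian transmission with crossovers,
  configurable causal-variant/marker linkage disequilibrium (the
  distant-relative "bump" arises from rare, imperfectly tagged causal
  variants), sibships, MZ/DZ twins, shared environment,
  additive-by-additive epistasis, and covariate stratification.

## Worked example

```r
library(relspectrum)

# published full-sib IBD regression studies for height: IVW meta-analysis
st <- fullsib_studies()
h  <- st[st$trait == "height", ]
ivw_meta(h$h2, h$h2_se, labels = h$study)
#> meta_result: 3 studies, estimate 0.6571 (se 0.0673), Q = 0.33

# expectation under assortative mating: with equilibrium heritability 0.82
# and spousal correlation 0.24, a full-sib design should find
expected_design_params(h2_eq = 0.82, r = 0.24, design = "fullsib")$h2
#> [1] 0.658624

# and the inversion recovers the equilibrium value from the design estimate
str(equilibrium_from_design(0.66, r = 0.24, se_h2 = 0.07, se_r = 0.04))
#> List of 2
#>  $ h2_eq: num 0.822
#>  $ se   : num 0.124

# segregation variance of sib IBD on the default autosomal map
ibd <- simulate_sib_ibd(10000, seed = 1)
c(mean = mean(ibd), sd = sd(ibd))
#>       mean         sd
#> 0.50018402 0.03862052
```

The meta-analytic full-sib heritability for height (0.66, se 0.07) is the
same number the assortative-mating identity predicts from the
close-relative equilibrium estimate (0.82) and the inferred spousal
correlation (0.24): that agreement — within-family and between-family
designs telling one story once assortment is modelled — is the analysis
this package packages.

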