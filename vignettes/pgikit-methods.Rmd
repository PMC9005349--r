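---
title: "Models and methods behind pgikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pgikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgikit)
```

`pgikit` implements the statistical pipeline of large-scale GWAS of
behavioural phenotypes — dominance-deviation scans, LD-score regression,
clumping-and-thresholding polygenic indices, within-family effect
decomposition, mate-pair assortment tests, winner's-curse shrinkage and
inbreeding-depression estimation — together with a family-structured cohort
simulator that makes every stage testable. This vignette records the models,
the parameter choices, and the design decisions that were genuinely open.

## The generative model

### Genotypes and LD

Genotypes are biallelic allele counts formed from two haplotypes. SNPs are
grouped into blocks; within a block all SNPs share the block's founder
allele frequency $p_b$ (drawn uniformly from `freq_law`, default
$[0.05, 0.5]$), and each haplotype draws its alleles by a shared-indicator
mixture: with probability $\sqrt{r}$ a SNP copies a single block-level
Bernoulli($p_b$) draw, otherwise it draws independently. Two SNPs in a block
both copy the shared indicator with probability $r$, which makes the
pairwise allele correlation — and therefore the genotype correlation —
**exactly** `within_block_r`, and exactly 0 across blocks.

We chose this mixture construction over thresholding a block-correlated
Gaussian because the thresholded form's allele correlation is a tetrachoric
function of the latent correlation that would itself need numerical
inversion; the mixture gives the same block-diagonal, exchangeable LD with a
closed form, so the LD-score module can compute
$\ell_j = 1 + (m_b - 1) r^2$ (additive) and $1 + (m_b - 1) r^4$ (dominance)
analytically and tests can compare empirical panel estimates against exact
values. The price is that frequencies are block-shared; since blocks are
small (1–20 SNPs in our configurations) this mimics the local frequency
coherence of real haplotypes rather than contradicting it.

Meiosis copies whole parental blocks: for each child and each block one of
the parent's two haplotypes is chosen independently. Within-block LD is
preserved exactly; between blocks recombination is free. Real genomes have
crossover interference, recombination maps and LD decay within loci — none
of which is modelled, and none of which the downstream estimators use.

### Trait architecture

Per-SNP additive effects act on standardized genotypes; dominance deviations
act on the orthogonal coding $d(g) = \{0,\,2p,\,4p-2\}$ for
$g \in \{0,1,2\}$, which is uncorrelated with allele count under
Hardy–Weinberg equilibrium and has variance $(2p(1-p))^2$. Raw effects are
i.i.d. normal (optionally all-positive for directional dominance) and are
rescaled once so that the **realized founder-generation variances equal**
`h2_add` and `h2_dom` exactly; later generations drift from these values
only through the mechanisms under study (assortment inflates the additive
variance toward the equilibrium $V_0/(1-r_g)$). The phenotype is

$$ y_i = g^{A}_i + g^{D}_i + \eta\,(g^{A}_{f(i)} + g^{A}_{m(i)}) + e_i,
\qquad e_i \sim N(0,\, 1 - h^2_A - h^2_D), $$

with $\eta$ (`indirect_scale`) the indirect parental effect: the simplest
generative form that opens a gap between direct and population effects.
Founders have no indirect term.

### Mating

Each generation pairs all males with all females of the current generation
on a standardized composite score
$w_1\,\mathrm{std}(y) + w_2\,\mathrm{std}(\text{latent}) +
w_3\,\mathrm{std}(\text{ancestry})$. The latent factor is
$\rho\,\mathrm{std}(g^A) + \sqrt{1-\rho^2}\,z$ with `latent_cor` $\rho$
(default 0.5) — a knob for assortment on something *more* PGI-correlated
than the phenotype, which is what keeps mate-pair PGI correlations alive
after phenotype residualization. Pairing is a Gaussian-copula rank-noise
scheme: male normal scores are perturbed as
$\lambda z + \sqrt{1-\lambda^2}\varepsilon$ and rank-matched against sorted
female scores, with $\lambda$ calibrated by root-finding (`uniroot`,
tolerance $10^{-4}$, noise draw held fixed so the objective is deterministic
and monotone) on the correlation the matching actually induces. Targets in
$[0, 1)$ are hit to about $\pm 0.01$ at a few thousand pairs; a target of 1
with tied scores is unattainable exactly and reported as a warning with the
rank-sorted best effort. Each couple has exactly two children (one of each
sex), so generation size is constant, every family is a sibling pair, and
trios/mate pairs are available in every generation.

`inbred_fraction` forces that share of matings to be full-sibling couples
(drawn at random among families), producing offspring with pedigree
$F \ge 1/4$ for inbreeding-depression analyses. Background relatedness from
random mating in a finite population is tracked too: inbreeding
coefficients are propagated exactly by the generation-wise kinship
recursion, and the standalone `pedigree_inbreeding()` (memoized recursive
kinship on arbitrary acyclic pedigrees) reproduces them.

### What passing tests do and do not show

The simulator reproduces the *mechanisms* the estimators target (dominance
orthogonality, assortment equilibrium, genetic nurture, stratification,
directional dominance) under clean conditions: unrelated founders in HWE,
exchangeable LD, homoskedastic Gaussian noise, no genotyping error, no
missingness, no selection into the sample. Green tests therefore validate
the estimators' logic and calibration, not their robustness to the
measurement and ascertainment pathologies of real cohorts.

## Association and meta-analysis

`run_gwas()` projects covariates out of the phenotype and every coded
genotype column once (Frisch–Waugh) and then runs per-SNP univariate least
squares — identical estimates to per-SNP multiple regressions, in linear
time. The dominance coding uses the in-sample allele frequency, which is
what makes it orthogonal to the additive coding *in sample*. Mixed-model
association is deliberately not implemented; at simulation scale, OLS with
principal components is the appropriate default, and relatedness enters the
family module instead. Monomorphic SNPs are flagged, not estimated.

Sample-size-weighted meta-analysis uses $\sqrt{N}$ weights (the METAL
convention); the reported `beta`/`se` on the meta scale are the
standardized-effect equivalents $z/\sqrt{N}$ and $1/\sqrt{N}$
(`standardized_effects()` applies the same convention to any stat set).
Harmonization resolves allele swaps (sign and frequency flips) and strand
flips, drops palindromic SNPs with minor-allele frequency above 0.4
(default; configurable) as strand-ambiguous, and logs every drop.
Clumping is the standard greedy loop — smallest p first, remove everything
with $r^2$ above the cutoff (ties on p broken by chromosome, position, then
id; pairs absent from the LD table count as $r^2 = 0$) — and is tested
against an independent reference implementation on random instances.

## LD-score regression

With standardized effects, $E[\chi^2_j] = 1 + N h^2 \ell_j / M$; the
dominance analogue replaces $\ell_j = \sum_k r^2_{jk}$ by
$\sum_k r^4_{jk}$ because the correlation between the dominance codings of
two loci is the squared allele-count correlation under HWE. The fit is a
single-pass weighted regression with heteroskedasticity weights
$1/\max(\ell, 1)$ (no iterative reweighting — adequate at the scales used
here), with standard errors from a delete-one block jackknife. Jackknife
units are unions of whole LD blocks when the block assignment is supplied
(`ld_blocks`), because units that split an LD block understate the
between-block variance of the realized polygenic signal; the default of up
to 200 contiguous units (at least 10 SNPs each) applies otherwise. The
attenuation-ratio convention
$(\text{intercept} - 1)/(\text{mean}\,\chi^2 - 1)$, clipped to $[0,1]$, is
used for the confounding share.

Test conditions: heritability recovery uses cohorts of 2,000 unrelated
individuals × 2,000 SNPs in blocks of 1–9 SNPs ($r = 0.5$), 20 replicate
seeds, requiring ≥ 18/20 within three jackknife SEs; block-size
heterogeneity is what gives the regression leverage, so equal-size blocks
(constant $\ell$) are rejected as degenerate rather than silently fit.

## Family decomposition and the assortment transform

Trios: $y$ on child, father and mother PGIs jointly, with a family random
intercept (`lme4`); when every family contributes one observation the mixed
model is unidentified and the fit reduces to OLS. Sibs: $y$ on the deviation
of the individual's PGI from the sibship mean plus that mean; the deviation
coefficient is the direct effect. Sibling indirect effects are assumed
absent — a documented limitation, consistent with the small estimates
reported in the literature.

At assortative-mating equilibrium with mate-pair PGI correlation $r$, the
covariance between a standardized child PGI and either parent's PGI is
$(1+r)/2$, so the population effect implied by a trio fit is
$\beta_{pop} = \delta + \frac{1+r}{2}(\alpha_f + \alpha_m)$. Higher-order
equilibrium corrections are deliberately omitted; the first-order form is
validated in simulation, where it reproduces the marginal regression slope
on the same individuals within Monte-Carlo error under assortment strengths
up to $r_{mate} = 0.5$. The direct share is $100(\delta/\beta_{pop})^2$
with a delta-method SE. Cross-design combination is inverse-variance, with
an optional family-clustered bootstrap covariance when designs share data.

## Assortment tests

Under phenotypic assortment with a linear PGI–phenotype relationship, the
mate-pair PGI correlation equals $r_y r_p r_m$. Both the observed
correlation and the product get percentile bootstrap uncertainty (1,000
replicates by default, pairs as the resampling unit, seed recorded). The
residualization ladder regresses each partner's PGI on that partner's *own*
covariates only — never jointly — and reports the correlation of the
residuals rung by rung (rung 0 = raw), with cumulative regressor sets.
Residualizing only the PGIs (not the phenotype correlations) is the
construction implemented; a regressor collinear with the PGI leaves zero
residual variance and errors out rather than returning noise.

## PGI evaluation, accuracy curve and power

Clumping + thresholding weights are the meta-analysis betas of the
surviving lead SNPs. Scoring is a dosage–weight inner product with
swap-aware allele alignment and mean-dosage imputation of missing
genotypes. Incremental R² is the difference in R² with and without the PGI
on top of the baseline covariates (bootstrap CI over individuals);
the binary-outcome analogue is the incremental Nagelkerke R² from logistic
or probit fits, each Nagelkerke value computed against the intercept-only
model, with (quasi-)separation flagged instead of estimated.

The expected-accuracy curve $E(R^2) = A/(B + 1/N)$ is fitted by
Levenberg–Marquardt least squares started from the linearization
$1/R^2 = B/A + (1/A)(1/N)$; two points are solved exactly. Power uses the
1-df noncentral $\chi^2$ with $\mathrm{ncp} = N R^2$ — the
$N R^2/(1-R^2)$ refinement is immaterial at per-SNP effect sizes of
$10^{-5}$ — and `detectable_r2()` inverts it by root-finding; the two are
mutual inverses to $10^{-6}$.

## Winner's curse and inbreeding depression

The empirical-Bayes prior for standardized effects is fitted by moments:
$\hat\tau^2 = \max(0, \bar\chi^2_{adj} - 1)/\bar N$, where the
intercept-adjusted mean $\chi^2$ subtracts confounding inflation; a
point-normal (spike-and-slab) maximum-likelihood fit is available when
sparsity matters. Under a proper prior the posterior mean
$\hat\beta\,\tau^2/(\tau^2 + se^2)$ is valid conditional on the observed
estimate regardless of significance selection — selection acts on the data,
not the prior — so no truncation correction is applied; the calibration
test (adjusted lead-SNP effects unbiased where raw ones inflate) is the
empirical check of that argument. The fit demands 1,000 SNPs by default
(`min_snps`), relaxable only for demonstration-scale pipelines.

For inbreeding depression, a unit of genome-wide inbreeding shifts the mean
of the orthogonal dominance coding by $-2p(1-p)$ per locus, so the
summary-statistic estimator of the slope of $y$ on $F$ is
$\hat B = -\sum_j 2 p_j (1-p_j)\,\hat\delta_j$ (unlinked approximation; the
LD correction of the full published method is out of scope and the
approximation is labelled as such). The sign follows from the derivative of
the genotype distribution under inbreeding: positive $\delta$ (heterozygote
advantage) yields depression. The individual-level route regresses $y$ on
pedigree $F$ directly; both report the conventional first-cousin-offspring
summary $b/16$, in months when the phenotype is in years. The two routes
agree within sampling error on unlinked simulations — the package's
cross-method check.

## Numerical and scale choices

* Root-finding tolerances: pairing calibration $10^{-4}$ on $\lambda$;
  `detectable_r2` $10^{-14}$ on $R^2$.
* Jackknife: at least 2 and at most 200 blocks, at least 10 SNPs each,
  aligned to LD blocks when known.
* Tie-breaks: clumping ties on p by (chr, pos, snp_id); decile assignment
  by stable rank.
* Degenerate inputs error loudly: constant PGIs, all-singleton sibships,
  identical-twin-only sibships, constant $F$, monomorphic LD panels,
  equal-$\ell$ score sets, regressors collinear with the PGI.
* Test problem sizes (chosen as the smallest scales at which the targeted
  effects are comfortably resolved): cohorts of 1,000–1,500 founder pairs
  and 2,000 SNPs for calibration suites; 1,250 pairs × 9 generations for
  the assortment-equilibrium check; 1,500 mate pairs for the assortment
  tests; 3,000 trios for the family decomposition.
* The pipeline stages (`run_pipeline()`) derive all stage seeds from one
  root seed via named substreams, and the manifest fingerprints stage
  outputs (md5 of serialized objects) so reruns are verifiably identical.
  The command-line surface of the package is `scripts/acceptance.R` plus
  these exported functions; no separate binary is shipped.

## Known limitations

* No recombination maps, coalescent ancestry or haplotype-reference LD; LD
  is exchangeable within blocks by construction.
* No mixed-model association, imputation, INFO scores or logistic GWAS.
* The assortment transform is first-order in the equilibrium covariance.
* Sibling indirect effects are assumed zero in the family designs.
* The summary-statistic inbreeding-depression estimator ignores LD.
* X-chromosome support is limited to the male-0/2 coding contract and
  sex-stratified scans; no dosage-compensation model is simulated.
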