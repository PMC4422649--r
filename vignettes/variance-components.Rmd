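---
title: "From functional genetic effects to bias-corrected variance components"
author: "noiavar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From functional genetic effects to bias-corrected variance components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noiavar)
```

## The problem

Line-cross experiments with nearly isogenic lines (NILs) and double-NILs
(DNILs) estimate *functional* genetic effects: the phenotypic consequence of
substituting a donor allele at one locus, or at a pair of loci, in an
otherwise uniform inbred background. Such effects are defined as deviations
from a reference genotype and do not depend on any population's allele
frequencies. Population genetics, however, works with *variance components*
— the total genetic variance $V_G$ and the additive genetic variance $V_A$ —
which are properties of a population with particular allele frequencies.
`noiavar` implements the bridge between the two: it estimates functional
effects (single-locus and pairwise-epistatic) from NIL/DNIL phenotype data,
and maps them, for any vector of allele frequencies, to $V_G$, $V_A$ and
locus-specific average effects of substitution, with a correction for the
upward bias that estimation error in the effects would otherwise introduce.

## The linear model

For a plant with a multilocus genotype, the trait value is modelled as

$$Z = \mu + \sum_k \left( a_k X_{a,k} + d_k X_{d,k} \right)
  + \sum_{(i,j)} \left( aa_{ij} X_{a,i}X_{a,j} + ad_{ij} X_{a,i}X_{d,j}
  + da_{ij} X_{d,i}X_{a,j} + dd_{ij} X_{d,i}X_{d,j} \right)
  + C + F + \varepsilon,$$

with the functional coding $X_a \in \{0,1,2\}$ the donor-allele count and
$X_d \in \{0,1\}$ the heterozygosity indicator, so the fully homozygous
reference line is the model's zero point and every effect is a deviation
from it. One widely used presentation of this coding misprints the second
index variable (labelling both brace definitions as $X_a$); the
heterozygosity-indicator form used here is the standard functional
parameterization and is forced by the reference-point logic. The second sum
runs only over the modelled QTL pairs (the DNILs actually measured);
interactions of unmeasured pairs are taken to be exactly zero with zero
sampling variance, and three-way or higher interactions are assumed absent.

$C$ and $F$ are random intercepts for greenhouse cohort and for seed family
(a maternal environmental effect) nested within genotype; nesting is
enforced by composite family keys. Fitting is by REML through `lme4::lmer`,
one trait at a time, with missing trait values dropped per trait. The fit
returns the fixed-effect estimates $\hat b$ together with their full
model-based sampling (co)variance matrix $S$ — the object every later
computation consumes. For data in which the random-effect structure is
degenerate (a single cohort and family, or noiseless phenotypes for which a
residual variance cannot be profiled), `noia_fit()` falls back to ordinary
least squares, whose point estimates coincide when the random-effect
variances are truly zero.

The overall test for epistasis compares the full fixed-effect structure to
the reduced one (single-locus terms only) on the same records, using ML
refits (REML likelihoods are not comparable across fixed-effect
structures): $X^2 = 2(\ell_{full}-\ell_{reduced})$ on
$df = n_{full} - n_{reduced}$. Parameters are counted as the genetic-effect
columns plus one cohort and one family term, the intercept excluded — for 7
QTL and 11 DNIL pairs, $60$, $16$ and $df = 44$. Other counting conventions
exist; this one is used because it makes the arithmetic $58 + 2 = 60$ and
$14 + 2 = 16$ explicit.

Separately from the test, the *non-epistatic* genotypic values are predicted
from a reduced-model fit restricted to records non-reference at no more than
one locus (`scope = "single_locus"`, essentially the NIL subset). Because
both fits share the reference point, their $a$/$d$ estimates agree within
sampling error — a stability property the suite asserts.

## From effects to variances

Given effects $\hat b$ and donor-allele frequencies $p_k$, genotype
frequencies are Hardy–Weinberg within locus and independent across loci
(linkage equilibrium); non-random mating and LD are out of scope. The
genotypic value of genotype $u$ is $\hat Z_u = \sum_i \hat b_i X_{i,u}$ and

$$V_G = E[\hat Z^2] - E[\hat Z]^2 .$$

Because each design column touches each locus through at most one index
variable, both $E[X_i]$ and $E[X_i X_k]$ factorize into per-locus moments;
`total_genetic_variance()` therefore costs $O(B^2 L)$ rather than $O(3^L)$.
The exhaustive $3^L$ enumeration is retained (`method = "enumeration"`) and
the suite checks the two backends agree to $10^{-10}$.

**Bias correction.** Squaring and cross-multiplying noisy estimates inflates
variances: $E[\hat b_i \hat b_k] = b_i b_k + S_{ik}$. The corrected engine
replaces every product $\hat b_i \hat b_k$ by $\hat b_i \hat b_k - S_{ik}$
in the expansions of both $E[\hat Z^2]$ and $E[\hat Z]^2$. For the
$E[\hat Z]^2$ term an alternative published form subtracts the product of
standard errors $s_i s_k$ instead of the covariance $S_{ik}$; since
$E[\hat b_i \hat b_k] - b_i b_k = \mathrm{Cov}(\hat b_i, \hat b_k)$ whether
or not $i = k$, only the covariance form is unbiased, and it is the
default. The other form is available via `eq_mean_sq = "sd_product"` for
comparison, and a Monte-Carlo test in the suite demonstrates that only the
covariance form centres on the truth. Corrected variances can be negative;
they are reported as computed (with a warning), never truncated, because
truncation would reintroduce bias in ensemble averages.

**Average effects and $V_A$.** The average effect of substitution at locus
$k$ is $\alpha_k = \alpha_{k,1} - \alpha_{k,2}$ with
$\alpha_{k,1} = p_k E[Z|W_kW_k] + q_k E[Z|W_kw_k]$ and
$\alpha_{k,2} = p_k E[Z|W_kw_k] + q_k E[Z|w_kw_k]$, conditional means taken
over HW×LE genotypes at the other loci. $\alpha_k$ is linear in the
effects, $\alpha_k = c_k^\top \hat b$, and `average_effect()` returns the
coefficient vector $c_k$. Then $V_A = \sum_k 2 p_k q_k \alpha_k^2$, and the
corrected square is the quadratic-form identity
$(c_k^\top \hat b)^2 - c_k^\top S c_k$ — the exact multi-effect analogue of
the single-locus correction
$V_A^* = \hat V_A - 2pq\,(s_a^2 + 2(q-p)s_{ad} + (q-p)^2 s_d^2)$, whose
sums range over all loci except $k$. Without epistasis the engine reduces
to the classical $\alpha_k = a_k + d_k(q_k - p_k)$ and
$V_A = 2pq[a+d(q-p)]^2$, which the suite asserts against closed forms; an
independent oracle checks $\alpha_k$ against the weighted least-squares
regression of enumerated genotypic values on donor-allele counts.

The intercept $\mu$ enters genotypic values but cancels from every
variance; its row and column of $S$ contribute nothing because the
centered-moment factors of a constant column are zero.

## Allele-frequency models

`sample_frequencies()` draws frequency sets independently per locus and per
set under either U(0, 1) or a U-shaped density $\propto 1/(p(1-p))$
truncated to $[\epsilon, 1-\epsilon]$ — the neutral-theory form that places
most mass near fixation. The inverse CDF is linear in the logit, so draws
map a uniform deviate through `plogis`. The truncation defaults to
$\epsilon = 0.01$ (a configuration knob: the literature rarely prints it).
Ensembles carry their seed and serialize to CSV with a JSON sidecar.
Frequencies are always of the *donor* allele; scenarios quoted as reference
allele $q = 0.05$ translate to donor $p = 0.95$.

## Synthetic data and the parametric bootstrap

`simulate_phenotypes()` draws trait = genotypic value + cohort + family +
residual, all Gaussian, in either a balanced layout (all 9 two-locus classes
per modelled pair, replicated over cohorts and families) or a mirror of an
existing table's grouping structure — which is what `simulate()` on a fitted
model uses for parametric-bootstrap replicates. Gaussian components mirror
the mixed model's assumptions; heavy-tailed alternatives are out of scope.

`simulate_study_like()` builds the package's reference fixture: 7 QTL, the
first 11 of the 21 lexicographic pairs as DNILs, 12 cohorts with each DNIL
complete within a cohort, truncated-geometric family sizes (mean near 6,
capped at 25 — chosen to mimic realistic unbalance, not derived from any
dataset), and a target of roughly 10,500 records. Generating effects are
drawn once from priors $a,d \sim N(0, 0.5^2)$ and epistatic terms
$\sim N(0, 0.35^2)$ — interaction effects of the same order as single-locus
effects, as line-cross studies repeatedly find — with cohort, family and
residual variances 0.2, 0.1 and 1.0 on a millimetre-scale trait. The
skeleton (design and effects) is fixed by an internal design seed;
the user seed varies only the noise, so replicate datasets share one
skeleton. What this generator does *not* emulate: genotyping error,
selective removal of misgenotyped plants, non-Gaussian residuals, and any
correlation between traits; conclusions from passing tests therefore
concern the estimators, not the robustness of REML to violations of its
assumptions.

`run_bootstrap()` closes the loop: simulate → refit → predict corrected and
uncorrected $V_G$, $V_A$ at fixed frequencies → summarize as standardized
bias $(\bar x^* - x)/x$ and standardized MSE $\sum(\hat x - x)^2/(n x^2)$.
Per-replicate seeds derive from the master seed by a counter, so any
replicate can be reproduced alone. The expected (and observed) pattern:
uncorrected estimators biased upward, corrected ones centred within
Monte-Carlo error, with nearly identical sampling variances, so the MSE
advantage of the correction is due to bias removal.

## Numerical and design choices

* Column order is fixed (loci in declared order; pairs sorted
  lexicographically by locus indices) so covariance matrices align across
  fits; within a pair, `ad` puts the additive index at the first-declared
  locus.
* Genotype input accepts donor-allele counts 0/1/2 or strings ww/Ww/WW;
  unknown codes fail at parse time naming the offending record.
* Rank-deficient designs error naming the first column with no informative
  contrast rather than silently dropping it.
* Fixed loci ($p \in \{0,1\}$) are handled exactly: conditional means stay
  finite, the $2pq$ weight zeroes the contribution, and an all-fixed
  population has $V_G = V_A = 0$.
* The LRT for epistasis always uses ML log-likelihoods of nested
  fixed-effect structures on identical observations; mismatched record
  counts are refused.
* Problem sizes in the test suite are chosen so that each stochastic
  assertion sits at roughly three Monte-Carlo standard errors: 2,000 draws
  for the estimator-algebra unbiasedness check, 200 replicate fits for the
  bootstrap pattern, 500 datasets for the LRT size check, 12,000 groups for
  the variance-decomposition recovery.

## Known limitations

* Variance predictions assume Hardy–Weinberg proportions and linkage
  equilibrium; under non-random mating $V_A$ alone no longer predicts the
  selection response, and no LD option is provided.
* The orthogonal (statistical) decomposition into $V_D$, $V_{AA}$, … is not
  computed; the package's additive variance is the variance of the best
  allele-count linear predictor, and $V_G - V_A$ aggregates all non-additive
  remainder.
* Bias-corrected estimates are unbiased only insofar as the model-based
  covariance $S$ is itself accurate; with very small samples the REML
  fixed-effect covariance understates uncertainty and a small residual bias
  remains — visible as the few-percent residual bias in small bootstrap
  configurations.
* Only pairwise epistasis among the modelled pairs enters; unmeasured pairs
  are assumed non-interacting, which understates variance if they do
  interact.
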