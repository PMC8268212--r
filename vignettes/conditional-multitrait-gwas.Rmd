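---
title: "Conditional multi-trait GWAS: model, workflow and design notes"
author: "cmgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional multi-trait GWAS: model, workflow and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmgwas)
```

# The problem

In livestock populations with strong long-range linkage disequilibrium (LD),
sequence-level association scans produce broad significance peaks in which
hundreds of variants tag the same underlying causal variant, and many causal
variants act on several genetically correlated traits at once. `cmgwas`
implements a conditional multi-trait workflow for this setting, developed
around wool, breech-wrinkle and breech-cover phenotypes in Merino sheep but
applicable to any set of quantitative traits with shared genetic
architecture: single-trait mixed-model scans are combined into a multi-trait
chi-squared statistic, independent putative causal variants are selected
greedily per chromosome under an LD constraint, and the whole cycle is
repeated conditionally on the selected variants until no significant signal
remains.

# The single-trait mixed model

Each variant is tested one at a time in

$$y = 1_n\mu + s_i\alpha_i + Qq + g + e,$$

where $y$ holds phenotypes pre-adjusted for fixed effects, $s_i$ is the
vector of allele dosages (0–2) at variant $i$, $\alpha_i$ its effect, $Q$
the animal-by-strain proportion matrix with $q \sim N(0, I\sigma_q^2)$,
$g \sim N(0, G\sigma_g^2)$ the polygenic values with $G$ a VanRaden-style
genomic relationship matrix built from variants with MAF > 0.005, and
$e \sim N(0, I\sigma_e^2)$. Variance components are estimated once per trait
by REML *without* any variant in the model (`estimateVarComp`) and held
fixed for the scan; each variant's $\hat\alpha_i$ and standard error then
come from generalized least squares under
$V = G\sigma_g^2 + QQ'\sigma_q^2 + I\sigma_e^2$, giving the signed
$t_i = \hat\alpha_i / SE_i$ and a two-sided Wald P-value from the standard
normal reference (at thousands of records the difference from a t reference
is negligible).

Computationally, the engine diagonalizes $G$ once per missingness pattern
($G = U D U'$) and rotates phenotypes and dosages into that basis; the
strain term is handled by a low-rank Woodbury identity. Every REML iteration
and every per-variant GLS fit is then linear in the number of records, and
conditional scans reuse the same rotated dosage matrix.

# The multi-trait statistic and its conditional loop

For each variant, the signed t-values across the $k$ traits are combined as

$$\chi^2_{multi} = t_i' V^{-1} t_i, \qquad df = k,$$

where $V$ is the $k \times k$ correlation matrix of signed t-values,
estimated over **all** scanned variants (not only significant ones). The
conditional loop (`runCMGWAS`) is:

1. unconditional single-trait scans for all traits;
2. $V$, the multi-trait $\chi^2$ and its P-values;
3. per chromosome, greedy selection of the most significant variant with
   multi-trait $P < 10^{-5}$; every significant variant with $r^2 > 0.1$ to
   it (or to any variant selected in an earlier cycle on that chromosome) is
   considered to tag the same causal variant and becomes ineligible; repeat
   within the chromosome until no eligible significant variant remains;
4. conditional single-trait scans — only on chromosomes with selections —
   jointly fitting the selected dosages as fixed covariates;
5. the multi-trait statistic recomputed from the updated t-values, with
   selected variants keeping the t-values they had when selected;
6. repeat 3–5 until a cycle selects nothing (or `maxCycles`, default 20, is
   reached, which is reported as truncation in the audit log).

Each selected variant is then expanded into its strong-LD region (all
significant variants from the *unconditional* statistic with $r^2 > 0.8$)
and annotated with genes within 100 kb on either side (boundary inclusive).
LD is the squared Pearson correlation of dosage vectors over jointly
non-missing animals, the genotype-count convention of PLINK `--r2`.

Diagnostics follow standard GWAS practice: the genomic inflation factor is
the median 1-df chi-squared quantile of the P-values divided by
$\textrm{qchisq}(0.5, 1) \approx 0.4549$, and the closed-form FDR estimate
at threshold $P$ is $P(1 - A/T) / ((A/T)(1 - P))$ with $A$ significant of
$T$ tested (undefined at $A = 0$; values above 1 print as ">100%").

# Parameters that matter

| parameter | default | role |
|---|---|---|
| `pThreshold` | 1e-5 | multi-trait significance for selection and expansion |
| `r2Independence` | 0.1 | max LD between selected variants on a chromosome |
| `r2Expand` | 0.8 | strong-LD region membership |
| `mafThreshold` | 0.005 | GRM and scan MAF filter (strictly greater than) |
| `maxCycles` | 20 | safety cap on conditional cycles |
| `geneWindow` | 100000 bp | nearest-gene annotation window, inclusive |
| t reporting threshold | 1.96 (2.0 by flag) | masking of pleiotropy profiles |

The first three thresholds and the MAF rule are the workflow's defining
constants; `maxCycles` exists only to bound runtime on pathological inputs.
The scan MAF threshold reuses the GRM value by default since rarer variants
are both unreliably imputed and unstable in single-variant fits.

# What the simulator emulates — and what it does not

`simConfig`/`simulateStudy` generate: multi-chromosome genotypes as
two-state Markov-chain haplotype blocks (block-constant allele frequency
drawn log-uniformly toward the rare end, floored at `mafMin`; adjacent
within-block allele correlation $1 - 2 \cdot \texttt{switchProb}$, so 0
gives a perfectly correlated block and 0.5 independence); three-strain
population structure with mostly purebred animals; 16 correlated traits on a
unit-variance baseline with polygenic values drawn from the *realized* GRM
(so REML recovery is internally consistent), a strain random effect and
correlated residuals; planted pleiotropic QTL with mixed-sign effect vectors
in phenotypic SD units; and per-trait completely-at-random missingness
defaulting to a two-age pattern (yearling traits nearly complete, adult
traits about half missing).

It does **not** emulate realistic demography or coalescent LD decay,
imputation error, structural (age-class) missingness, dominance or
epistasis. Passing recovery tests therefore show that the selection logic
and the mixed model behave correctly under the stated generative
assumptions, not that power or FDR transfer quantitatively to real sequence
data.

# Numerical choices

* REML: average-information updates with two opening multiplicative
  fixed-point steps, step-halving on any log-likelihood decrease,
  non-negativity by projection, convergence at relative log-likelihood
  change below 1e-6, at most 200 iterations; non-convergence is an error
  carrying the last iterate. A GRM numerically proportional to the identity
  makes $\sigma_g^2$ and $\sigma_e^2$ inseparable and sets a boundary flag
  instead of failing.
* Scan skip rules: MAF at or below threshold, zero dosage variance, or (in
  conditional fits) a V-metric residual dosage variance below 0.1% of the
  marginal one (collinearity). Conditioning variants are not re-tested;
  their selection-time statistics are carried forward.
* A conditioning pair with $r^2 > 0.95$ drops the later-selected member
  from the joint fit only (it stays selected and reported), noted in the
  audit log.
* $V$ repair: eigenvalues floored at 1e-6 and the matrix re-normalized to
  unit diagonal before inversion; flagged.
* Variants untested for some trait enter the multi-trait statistic with
  $t = 0$ and $V$ unchanged (conservative — can only shrink the statistic);
  inverting the observed-trait submatrix is available via
  `multiTraitChisq(..., missing = "subset")`.
* Selection ties in P break by smaller position, then allele; undefined LD
  (zero variance) counts as $r^2 = 0$ and is logged.
* Missing dosages are mean-imputed for the GRM and the scan, pairwise
  deleted for LD.

# Open design points, resolved

* Whether variance components should be re-estimated inside each
  conditional cycle is left unstated by the workflow's description;
  `cmgwas` estimates them once per trait and holds them fixed across
  cycles, for determinism and because the selected covariates absorb little
  variance relative to the polygenic term.
* $V$ is likewise computed once, from the unconditional scan, and reused —
  the cycle updates t-values, and re-estimating a 16×16 correlation from
  mostly unchanged t-vectors would add noise, not information.
* The independence screen compares candidates against *all* previously
  selected variants on the chromosome, not only the current cycle's —
  the stricter reading, preventing re-tagging of already-claimed QTL.
* Conditional scans condition per chromosome only; selected variants on
  other chromosomes are (in expectation) uncorrelated with the test variant
  and would only burn degrees of freedom.
* The 100 kb gene window and the 1.96/2.0 t-reporting thresholds are
  boundary-inclusive.

# Validation problem sizes

The test suite validates the pipeline end-to-end at desk scale, chosen so
that each statistical check has the resolution it needs: null calibration
uses one simulated study of 1,000 animals by 5,000 independent variants and
16 traits (independence makes the exact binomial reference for the
multi-trait false-positive rate valid); QTL recovery uses 20 replicates of
2,000 animals by 5,000 variants in LD blocks with five planted pleiotropic
QTL of 0.4–0.45 SD on four traits each, requiring recovery (a selected
variant with $r^2 > 0.8$ to truth) in at least 80% of replicates with the
pairwise $r^2 \le 0.1$ invariant holding always; REML recovery averages
eight replicates of 400 animals. The simulator's defaults (16 traits,
heritability 0.4, strain variance 0.05, exchangeable residual correlation
0.3, two-age missingness) are the reference study conditions throughout.

# Known limitations

* Variance components fixed across cycles slightly overstate the residual
  covariance once strong QTL are fitted; with the effect sizes the workflow
  targets this is second-order.
* The Wald normal reference is anti-conservative below a few hundred
  records; the engine refuses traits with fewer than 30.
* The eigen-rotation engine is dense: memory grows as animals × variants
  per missingness pattern, which is the intended desk-scale regime, not a
  biobank one.
* The closed-form FDR estimator assumes P-values are uniform under the
  null and variants exchangeable; with strong LD it is an approximation,
  which is exactly why it is paired with the inflation factor and Q–Q data.
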