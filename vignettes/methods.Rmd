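---
title: "Methods: from plasma proteome to causal evidence tiers in heart failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from plasma proteome to causal evidence tiers in heart failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`proteomr` chains four statistical procedures — proteome-wide Cox
screening, collider-bias correction of a case-only outcome GWAS,
two-sample Mendelian randomization (MR) with correlated cis-pQTL
instruments, and Bayesian colocalization — into one gated pipeline for
heart-failure (HF) outcome studies. This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions taken
where the methodology is genuinely open. Nothing here reports an
empirical result beyond what the package's tests and
`scripts/acceptance.R` compute.

## 1. Survival screen

Protein abundances arrive as positive relative-fluorescence units and
are right-skewed, so each protein is natural-log-transformed before
centering and scaling to mean 0, SD 1 (`standardize_proteins()`); the
log transform is a package choice, conventional for fluorescence-unit
proteomics. Per protein we fit the Cox proportional-hazards model

$$ h_i(t) = h_0(t)\, \exp(\beta z_i + \gamma' c_i), $$

with $z$ the protein z-score and $c$ the adjustment covariates (a
composite clinical risk score and log natriuretic peptide, consumed as
precomputed columns). Hazard ratios are therefore per-SD. Fitting is
delegated to `survival::coxph()` with Efron tie handling; the test suite
cross-checks it against an independent brute-force partial-likelihood
grid oracle and against the Breslow fit on tie-free data, where the two
estimators coincide. Two outcomes are supported: all-cause death and the
composite of death or HF hospitalization (DHFA); by construction the
composite fires no later than death, an invariant `validate_cohort()`
enforces. Missing data are handled complete-case per protein, and the
per-model subject and event counts are reported.

Thousands of correlated proteins make a raw Bonferroni correction far
too severe. `effective_tests()` computes the number of principal
components of the protein correlation matrix needed to explain a
variance fraction `variance_threshold` (default 0.95, in line with
common practice for this correction; the threshold is exposed because
the literature uses values from 0.95 to 0.995) and sets
$\alpha^* = 0.05/n_\mathrm{eff}$. Two perfectly correlated blocks give
$n_\mathrm{eff} = 2$; identical proteins give 1; independent proteins
approach the raw count.

## 2. Collider-bias correction

Case-only progression GWAS condition on disease liability. For a variant
with incidence effect $b_\mathrm{inc}$, selection induces a spurious
progression effect approximately linear in $b_\mathrm{inc}$, so
incidence-only variants fall on a line
$b_\mathrm{out} = b\, b_\mathrm{inc}$ whose slope $b$ *is* the
correction factor. `fit_collider_slope()` fits a two-component mixture
to $(b_\mathrm{inc}, b_\mathrm{out})$ pairs of LD-independent variants
passing an incidence p-value cut (default `1e-3`; the threshold is a
package choice — it must admit enough variants, at least 30, while
keeping the working set genuinely incidence-associated):

* component 1 (incidence-only):
  $b_\mathrm{out} \mid b_\mathrm{inc} \sim N(b\, b_\mathrm{inc},\;
  \mathrm{se}_\mathrm{out}^2 + \tau^2)$;
* component 2 (direct progression effects):
  $b_\mathrm{out} \sim N(0, \sigma_2^2)$, independent of
  $b_\mathrm{inc}$.

EM with 10 seeded restarts maximizes the mixture likelihood
(deterministic given the seed). Three identifiability guards, adopted
after the estimator's unit tests exposed label degeneracy, are part of
the model definition:

1. $\sigma_2^2$ is bounded below at $4(\tau^2 +
   \overline{\mathrm{se}_\mathrm{out}^2})$ — the "diffuse" component must
   be at least twice as spread (in SD) as the line component, otherwise
   it swallows the middle of a single-cluster distribution and biases
   the slope away from zero;
2. the line cluster's mixing weight is constrained to at least 0.5 (the
   correction presumes incidence-only variants predominate among
   incidence-associated variants);
3. a one-component line-only fit is preferred whenever BIC judges the
   split spurious, which restores calibration when there are no direct
   progression effects at all.

The reported slope is corrected for regression dilution from sampling
noise in $b_\mathrm{inc}$ (attenuation
$\hat\sigma^2_{b}/(\hat\sigma^2_{b} + \overline{\mathrm{se}^2_\mathrm{inc}})$
from cluster-1 weighted moments). `adjust_collider_bias()` then applies

$$ \beta_\mathrm{adj} = \beta_\mathrm{out} - b\,\beta_\mathrm{inc},
\qquad
\mathrm{se}^2_\mathrm{adj} = \mathrm{se}^2_\mathrm{out}
 + b^2 \mathrm{se}^2_\mathrm{inc}
 + \beta_\mathrm{inc}^2 \mathrm{se}^2_{b}, $$

to every harmonizable variant genome-wide; the third variance term
propagates slope uncertainty, a deliberate choice so downstream MR
standard errors stay honest. Variants without an incidence record pass
through unchanged and flagged. Alternative corrections
(Dudbridge-style adjustment, inverse-probability weighting) are out of
scope.

## 3. Instruments and MR

cis-pQTLs are variants within ±500 kb of the protein-encoding gene body
(inclusive bounds; whether the anchor should be the gene body or the TSS
is ambiguous in source pQTL studies — the gene body is used, and the
window is configurable), retained at $p < 5\times10^{-8}$ with a strict
inequality. Trans variants in the extended MHC (chr6:25–34 Mb) are
excluded, common pQTL practice given the region's extreme LD. Greedy
clumping (best p first, accept if $r^2 < 0.1$ with everything accepted)
is a light pre-filter only: correlated instruments are *retained* and
modelled, the $r^2$ cap existing for numerical stability of the GLS
inverse. Instrument strength is summarized by the mean F statistic
$\overline{(b_x/\mathrm{se}_x)^2}$, with sets at mean F ≤ 10 flagged
weak.

Exposure and outcome records are harmonized to a shared effect allele:
sign flips for swapped alleles, strand flips (A↔T, C↔G) before declaring
a mismatch, palindromic variants kept only when both allele frequencies
are on the same side of 0.5 and outside 0.5 ± 0.08 (the band is the
package's convention; the source studies do not state one), indels
dropped. Harmonization is idempotent and fully audited.

Estimators (all reporting log-odds per SD protein, OR with 95% CI
$\exp(\theta \pm 1.96\,\mathrm{se})$, two-sided normal p-values):

* **Wald ratio** $\theta = b_y/b_x$, first-order SE
  $\mathrm{se}_y/|b_x|$ (second-order available);
* **Generalized IVW** with
  $\Omega = \mathrm{diag}(s_y)\, R\, \mathrm{diag}(s_y)$:
  $\hat\theta = (b_x'\Omega^{-1}b_x)^{-1} b_x'\Omega^{-1}b_y$, fixed
  effect, with Cochran's Q on $n-1$ df reported rather than inflating
  the variance (the variance model is a package choice); with $R = I$
  this is textbook IVW, with one instrument the Wald ratio. Singular
  LD is ridge-repaired ($|\lambda_{\min}| + 10^{-8}$ on the diagonal,
  rescaled to unit diagonal);
* **MR-Egger**: weighted regression with intercept after orienting all
  $b_x \ge 0$; the intercept is the directional-pleiotropy diagnostic;
* **Weighted median**: interpolated 50% crossing of the
  inverse-variance-weighted ratio distribution, SE by a seeded
  parametric bootstrap.

## 4. Colocalization

Per variant and trait, the Wakefield approximate Bayes factor
$\log\mathrm{ABF} = \tfrac12\log(1-r) + \tfrac12 r z^2$ with
$r = W^2/(W^2 + \mathrm{se}^2)$. Prior effect SDs default to $W = 0.15$
for the quantitative protein trait and $0.2$ for the case-control
outcome trait — conventional values; the per-SNP causal prior is
$p_1 = p_2 = 10^{-4}$ and the shared prior $p_{12} = 10^{-5}$ with a
mandatory sensitivity grid, since the sharing prior is the assumption a
reader will most want to stress. Under one causal variant per trait per
region, the hypothesis sums are combined in log space (the H3 sum
excludes same-variant pairs), and the test suite proves the
implementation equal to exhaustive enumeration over all causal
configurations for small regions. A region is flagged `colocalized` at
$PP_{H4} > 0.8$; the conditional posterior $PP_{H4}/(PP_{H3}+PP_{H4})$
is reported alongside. The region defaults to the cis window (the
alternative — the gene body only — is configurable via the window
parameter).

## 5. Pipeline gating and verdicts

Only proteins significant at the corrected alpha advance to MR; only
proteins with a nominally significant ($p < 0.05$) IVW estimate advance
to colocalization. The nominal MR threshold is justified by the prior
screen: the MR stage tests a pre-filtered hypothesis set. The evidence
tier uses the *conditional* coloc posterior (> 0.9) rather than the
marginal $PP_{H4} > 0.8$ flag: with a case-only outcome GWAS of a few
thousand subjects, the marginal $PP_{H4}$ is power-limited — the
"protein-only" hypothesis absorbs posterior mass even at a genuinely
shared variant — and the conditional posterior isolates the H3-vs-H4
contrast that matters for instrument validity. Both quantities are in
the coloc table. This gating inherits the design's known limitation:
a protein whose observational association is masked by confounding will
never reach MR.

## 6. The synthetic-data generator

`simulate_study()` emulates the three data roles the pipeline consumes,
with defaults mirroring a single-center HF cohort: ~2,000-subject case
cohort, ~50% composite (DHFA) and ~25% death event fractions, a
30,000-sample external pQTL study, and a 20,000-sample population for
the risk GWAS.

* **Genotypes**: latent AR(1) Gaussian haplotypes thresholded at each
  variant's MAF, summed to dosages (Hardy–Weinberg holds). Thresholding
  attenuates latent correlation — the maximum dosage correlation
  achievable from a latent 0.9 is about 0.71 — so the `ld_decay` dial
  targets the *dosage* scale: the latent parameter is
  $\sin(\tfrac{\pi}{2}\,\mathrm{ld\_decay})$, making realized adjacent
  dosage $r \approx$ `ld_decay` (exact at MAF 0.5).
* **Proteins**: cis genetic score scaled to heritability `h2_cis` plus
  Gaussian environment; causal cis variants are spread evenly across the
  locus so they represent independent association signals rather than
  one LD block.
* **Liability and selection**: $L = g_\mathrm{HF} + c'P + e$ with the
  HF-risk block explaining `hf_h2` of variance through equal-magnitude,
  random-sign effects (the block stands in for clumped
  genome-wide-significant risk loci, which are detectable by
  construction). Case inclusion is probit:
  $U = s\,L + \varepsilon$, top `case_frac` selected; $s = 0$ gives
  random sampling and no collider bias.
* **Progression**: the case-only GWAS outcome is drawn from a logistic
  model whose log-odds are $\theta' P + w_e e$ — so the true per-SD
  log-odds *is* `causal_theta`, the scale MR odds ratios are reported
  on, and the environmental-severity term $w_e e$ is what converts
  liability selection into collider bias. The survival cohort gets
  exponential proportional-hazards times with the same linear predictor
  and administrative censoring calibrated to the target event rates.
  Marginal GWAS effects for binary traits use the one-step score-test
  approximation to logistic regression
  ($\beta = \mathrm{cov}(g,y)/(\mathrm{var}(g)\bar p(1-\bar p))$),
  vectorized over variants.
* **Two populations**: the incidence GWAS comes from an independent
  population draw, as it would from an external consortium; sharing
  subjects with the outcome GWAS correlates the two error terms and
  makes the slope adjustment anti-conservative.
* **Truth**: every bundle carries the causal thetas, liability effects,
  causal variant indices, and the empirically realized collider slope.

What the generator does *not* emulate: assay cross-reactivity and batch
effects, population stratification, imputation uncertainty, multi-ancestry
LD, and non-proportional hazards. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated generative
model, not robustness to those real-data pathologies.

## 7. Problem sizes and numerical choices

The test suite and acceptance script run simulations at desk scale,
chosen as the package's own working sizes: collider-bias experiments use
a 12,000-subject population with a 3-variant cis locus and 40 HF-risk
variants; slope-recovery uses 5,000 summary-level variants; MR
calibration uses 2,000 null and 500 effect replicates at 5 instruments
with F ≈ 30; the end-to-end runs use 20 proteins with a single strong
cis signal (`h2_cis = 0.1`) and a causal log-OR of 0.8 — the
strong-instrument, strong-effect regime in which proteome-wide MR
positives are actually declared. Convergence: EM stops when the
log-likelihood stalls (rel. tol `1e-8`) or parameters stop moving; Cox
fitting uses `coxph` defaults tightened to `eps = 1e-11`; PSD repairs add
$|\lambda_{\min}|+10^{-8}$ ridges and rescale to unit diagonal;
p-values are floored at `1e-300` to keep them in $(0,1]$. Ties in
clumping are broken by p-value then variant id, making every ordering
deterministic. All randomness flows from explicit seeds through
`withr::with_seed`; R's default Mersenne-Twister generator is assumed.
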