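---
title: "Methods: operationalizing and validating the ND-PAE criteria"
author: "ndpae package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operationalizing and validating the ND-PAE criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndpae)
```

# The diagnostic model

ND-PAE (Neurobehavioral Disorder associated with Prenatal Alcohol
Exposure) is defined over 12 criteria in three domains:

* **NI** (neurocognitive, 5): global intellectual functioning, executive
  functioning, learning, memory, visual-spatial reasoning;
* **SR** (self-regulation, 3): mood/behavioral regulation, attention,
  impulse control;
* **AF** (adaptive functioning, 4): communication, social communication,
  daily living skills, motor skills.

Each criterion is assessed by one or more normed instrument scores. The
package reduces all of them to a single question per criterion — *is this
child impaired on this criterion at threshold τ?* — and then applies
boolean domain logic.

## Standardization and the impairment threshold

Every continuous score is mapped to a z-scale on which higher means
stronger functioning: standard scores via $(x-100)/15$, T-scores via
$(x-50)/10$, scaled scores via $(x-10)/3$; problem-scale T-scores (where
high raw scores mean *more* problems) are negated after rescaling. One
instrument family emits only a binary impairment flag, which bypasses the
threshold.

Impairment at threshold $\tau \in \{1.0, 1.5, 2.0\}$ is $z \le -\tau$,
**inclusive**. The inclusive boundary is forced by the one explicit
boundary the criteria state — an IQ standard score "of 70 or below", which
is exactly $-2$ SD — and is applied uniformly to every measure and
threshold rather than specially to IQ.

## Missing data semantics

Batteries differ across study phases, so most subjects lack some measures.
The package never imputes:

* a criterion with at least one observed measure is coded by the observed
  measures alone (impaired iff any observed measure is impaired);
* a criterion with no observed measure is *unobserved* (`NA`), and an
  unobserved criterion never endorses a domain or an AF clause;
* a subject with an entirely unobserved domain cannot be evaluated and is
  excluded up front (`apply_exclusions()` logs who and why).

One consequence worth knowing: a subject whose only AF observations are
communication and daily living can still satisfy AF 2/4 — the unobserved
motor criterion simply contributes nothing to its clause. And a criterion
observed through a single measure contributes to endorsement denominators
exactly like a fully measured one; denominators are per-criterion counts
of evaluable subjects, and a cell with zero evaluable subjects is reported
as `NaN`, never as 0.

## The three diagnosis models

With domain indicators NI, SR, AF, the classification is
$\mathrm{NDPAE} = \mathrm{NI} \wedge \mathrm{SR} \wedge \mathrm{AF}$,
where AF is one of:

* **AF 2/4** (original): $(\mathrm{comm} \vee \mathrm{social}) \wedge
  (\mathrm{daily} \vee \mathrm{motor})$;
* **AF 1** (modified): $\mathrm{comm} \vee \mathrm{social} \vee
  \mathrm{daily}$ — motor impairment is not a criterion here;
* **hybridIQ**: AF 2/4 logic on the 1.0-SD coding, except that global
  intellectual functioning keeps its original 2.0-SD cutoff. It is a
  first-class model token (not a flag) because it is reported as its own
  column in the classification sweep.

Since the first AF 2/4 clause implies AF 1, AF 1 endorsement is a superset
of AF 2/4 endorsement subject-by-subject; the test suite asserts this as
an invariant along with an exhaustive truth-table check over all $2^{12}$
binary criterion patterns.

# Validation statistics: choices that matter

* **χ² contrasts** use the uncorrected Pearson statistic
  $N(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]$. Reconstructing the published
  contrast values from the published percentages and group sizes succeeds
  only *without* the Yates correction, so none is applied.
* **Percentage-to-count reconstruction** (`counts_from_rates()`) rounds
  half away from zero. Print-rounding of percentages leaves ~±2% relative
  slack on reconstructed χ² values.
* **Accuracy** is the prevalence-weighted identity
  $(\mathrm{sens}\cdot n_{AE} + \mathrm{spec}\cdot n_{CON})/N$, which the
  implementation satisfies exactly by construction.
* **AUC** is the Mann–Whitney probability computed from midranks, so ties
  count ½ and a binary predictor yields $(\mathrm{TPR}+\mathrm{TNR})/2$.
  The standard error is Hanley–McNeil and the p-value is a normal
  approximation against AUC = 0.5; published values only report p-bands,
  so nothing downstream depends on the SE method.
* **Logistic regression** of diagnosis risk on age and sex is fitted by
  IRLS (`stats::glm`, tolerance $10^{-8}$, ≤ 50 iterations) with Wald 95%
  CIs on the odds-ratio scale. Sex is coded female = 1, male = 0 — the
  orientation implied by negative reported sex coefficients alongside a
  "males more likely" interpretation. Separation and non-convergence are
  errors, not silent large coefficients.

# Psychometrics: choices that matter

All reliability/structure analyses run on the 0/1 criterion indicators
with **listwise deletion** (subjects with any unobserved criterion drop
out), mirroring the complete-case design of the reference analysis.

* **α and KR-20.** Cronbach's α uses sample variances; KR-20 uses item
  $pq$ with the population total variance. The $n/(n-1)$ factors cancel in
  the ratio, so the two agree to machine precision on binary items — an
  identity the tests assert at $10^{-12}$.
* **PCA correlation matrix.** Components are extracted from the Pearson
  correlation matrix of the binary indicators, matching the standard
  workflow for this analysis in mainstream statistical packages. A
  tetrachoric-correlation variant was considered and deliberately left
  out: no installed dependency provides one, the reference workflow does
  not use one, and Pearson-based PCA on 0/1 items is the convention this
  analysis is compared against.
* **Retention.** "Kaiser" is read as both of its usual meanings: the
  eigenvalue > 1 retention rule (strict inequality; an eigenvalue of
  exactly 1 is not retained) *and* Kaiser row-normalization inside
  varimax. Retention is confirmed with Horn's parallel analysis using
  **mean** random eigenvalues (not the 95th percentile), 1000 replicates
  by default, seeded, and counting components until the first observed
  eigenvalue that fails to beat its random mean. On a single pure-noise
  dataset this procedure retains 0–1 components *typically* but can
  retain 2 on an unlucky draw; the tests therefore assert the behavior
  distributionally over independent draws rather than on one dataset.
* **Promax** follows the standard two-step: varimax (Kaiser-normalized,
  tolerance $10^{-6}$, ≤ 100 iterations), then an oblique procrustes fit
  to the $|\lambda|^\kappa$ target with $\kappa = 4$ (the conventional
  power; configurable), with the transform column-normalized so Φ has
  unit diagonal. Factor signs out of an eigendecomposition are arbitrary,
  so each factor is reflected to make its dominant loadings positive and
  the reflection is carried into Φ — without this, a recovered factor
  correlation of +0.5 can print as −0.5. With $\kappa = 1$ the procedure
  reduces to varimax (Φ = I), which the tests check. Items are assigned
  to their maximum-|pattern-loading| factor; exact ties go to the lower
  factor index and are flagged.

# The synthetic cohort generator

No subject-level data are distributed with the validation study, so the
generator exists to give every downstream stage a cohort with the
statistical structure the analysis assumes.

**Latent model.** Each subject draws a general deficit factor $g$ and one
factor per domain $d_{NI}, d_{SR}, d_{AF}$, all standard normal. A
measure's oriented z-score is

$$z = \mu_{m,\mathrm{group}} + 0.6\,g + 0.4\,d_{\mathrm{dom}(m)} +
      \varepsilon, \qquad \varepsilon \sim N(0,\, 1 - 0.6^2 - 0.4^2)$$

so the marginal variance is exactly 1. The 0.6/0.4 loadings produce the
moderate inter-item correlation that the observed reliability range
implies (α ≈ 0.7–0.83) and a correlated multi-factor structure of the kind
the reference factor analysis reports.

**Calibration.** With one simulated measure per criterion, endorsement at
threshold τ is $P(z \le -\tau) = \Phi(-\tau - \mu)$, so
`calibrate_to_rates()` sets $\mu = -\tau - \Phi^{-1}(p)$ per criterion and
group. The default configuration targets the published 1.0-SD
per-criterion endorsement percentages at the study's group sizes (486 AE /
679 CON). Targets of exactly 0 or 1 have no finite shift and are rejected.
The published table's duplicated SR domain row at the 1.5 and 2.0 SD
levels looks like a transcription artifact; the generator is *not* tuned
to force it — rates at higher thresholds follow from the latent model's
threshold monotonicity.

**Missingness** is missing-completely-at-random at 8% per measure, chosen
so that roughly 37% of subjects ($0.92^{12}$) are complete cases — at the
study's cohort size this lands near the reference analysis's complete-case
n of ~413. Masks leaving any subject without at least one observed measure
per domain are redrawn, enforcing the cohort-assembly rule. Ages are
uniform on 5–17 (mean 11, SD ≈ 3.5, matching the reported 10.9 ± 3.4) and
sex follows the reported female proportions; an optional `age_slope`
induces an age effect for exercising the logistic model.

**What it does and does not emulate.** Calibration guarantees
*per-criterion marginal* rates; it does not (and cannot, with fixed
loadings) reproduce the *joint* dependence of the real cohort. Real
domain-level endorsements behave as if inter-domain dependence were much
stronger: the published AE diagnosis rate at 1.0 SD under AF 2/4 (69.2%)
sits close to the published AF domain rate (70.8%), implying near-total
overlap of domain endorsements, whereas the latent model with 0.6/0.4
loadings yields an AE diagnosis rate in the mid-50s from the same
criterion margins. Passing tests therefore demonstrate that the coding,
engine, and statistics are correct, and that the generator delivers its
calibrated marginals — not that the synthetic joint distribution matches
the real cohort's. Instrument-level item responses, site effects, and
dysmorphology are likewise out of scope.

# Numerical and procedural details

* All thresholding is inclusive ($z \le -\tau$); binary flags ignore τ.
* Count reconstruction rounds half away from zero; base R's banker's
  rounding is deliberately not used.
* χ² requires all four margins positive; a zero margin is an error, not 0.
* KMO on an identity matrix is the undefined 0/0 and errors; Bartlett
  requires a positive determinant; PCA requires symmetry.
* Determinism: a single seed drives each generator run; the pipeline
  derives all randomness from the config seed, and identical config +
  seed produce byte-identical report files (asserted in tests).
* Problem sizes in the test suite are chosen to keep the full run around
  ten seconds while leaving comfortable statistical power: 4096-pattern
  exhaustive engine checks, 2000-subject factor-recovery simulations,
  5000-subject logistic recovery, and a 100 000-subject calibration check
  at 3-binomial-SD tolerance.

# Known limitations

* The 2.0-SD column of the published classification table and the
  published demographic IQ t-test are internally inconsistent as printed
  and are not used as reference points.
* The printed eigenvalue/variance-explained pairs of the reference factor
  analysis mix initial eigenvalues with post-rotation sums of squares;
  the package reports oblique SS loadings as variance explained and makes
  no attempt to reconcile the printed pair.
* Exact published loadings, eigenvalues, and reliability coefficients
  require the original subject-level data and are explicitly out of reach;
  the package validates against the arithmetic consequences of published
  aggregates instead.
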