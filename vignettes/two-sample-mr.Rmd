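---
title: "Two-sample Mendelian randomization with mrpath: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

## The statistical problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome from
observational data. Two-sample summary-data MR needs only per-variant
association statistics from two independent GWAS: for instrument $j$, the
exposure effect $\hat\gamma_j$ (SE $\sigma_{X j}$) and the outcome effect
$\hat\Gamma_j$ (SE $\sigma_{Y j}$). Under the three instrumental-variable
assumptions (relevance, no confounding of the instrument, exclusion
restriction), each variant supplies a Wald ratio
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard
error $\sigma_{Y j} / |\hat\gamma_j|$, and the estimators combine these
ratios under different assumptions about horizontal pleiotropy.

`mrpath` implements the full workflow: instrument construction
(significance filtering, LD clumping, proxy substitution, harmonization,
palindromic handling, radial outlier removal, Steiger filtering), five
estimators (IVW, MR-Egger, weighted median, weighted mode, a robust
profile-score estimator), the sensitivity suite (Cochran's and Rücker's Q,
Egger intercept, MR-PRESSO, leave-one-out, confounder-associated
instrument exclusion), two-step mediation, and a synthetic
summary-statistics generator with known ground truth that makes every
stage testable without external data.

## Standardization, instrument strength

When a GWAS reports only Z-scores, effects are standardized from the
Z-score, allele frequency $f$ and sample size $n$:
$$\beta = \frac{z}{\sqrt{2 f (1-f)\,(n + z^2)}}, \qquad
  se = \frac{1}{\sqrt{2 f (1-f)\,(n + z^2)}},$$
so $\beta / se = z$ exactly. Because $f$ enters only through $f(1-f)$,
folding to the minor allele frequency is immaterial; the package asserts
this symmetry in its tests. Per-variant variance explained reduces
algebraically to $R^2 = \beta^2 / (\beta^2 + n\,se^2)$ (the explicit
$2\,\mathrm{MAF}(1-\mathrm{MAF})$ factors cancel), and instrument strength
is summarized by $F = R^2 (n-2) / (1 - R^2)$, with the conventional $F >
10$ screen for weak instruments.

## Instrument construction

- **Selection**: strict genome-wide significance, $p < 5\times 10^{-8}$.
- **Clumping**: greedy by ascending p-value, discarding variants with
  $r^2 > 0.001$ to a kept variant within an inclusive 10,000 kb window on
  the same chromosome. Ties are broken by position then identifier, so the
  result is deterministic and independent of input order. Variants absent
  from the LD matrix are treated as unlinked (and logged); pairs on
  different chromosomes are always unlinked. The LD matrix is a user
  input; the package never computes LD from genotypes.
- **Proxies**: an instrument missing from the outcome dataset is replaced
  by the highest-$r^2$ available variant with $r^2 > 0.8$. Aligning a
  proxy's alleles needs the LD correlation *sign*; when the input matrix
  carries no sign information the proxy is ambiguous and the instrument is
  dropped with a recorded reason rather than guessed.
- **Harmonization**: outcome effects are expressed for the exposure's
  effect allele, flipping the sign (and frequency) when the allele order
  is swapped, and complementing first when the datasets report opposite
  strands. Incompatible allele pairs are dropped with a reason.
- **Palindromic variants** (A/T, C/G) cannot be oriented from alleles
  alone. Those with exposure effect-allele frequency inside the ambiguity
  window — (0.42, 0.58) by default, configurable; the choice of window is
  a judgment call about how far from 0.5 frequency-based inference is
  trustworthy — are removed; the rest are aligned by frequency
  concordance.
- **Radial filter**: the radial IVW slope is fitted with first-order
  weights $w_j = (\hat\gamma_j / \sigma_{Y j})^2$; each variant's
  contribution $Q_j = w_j (\hat\theta_j - \hat\beta)^2$ is referred to
  $\chi^2_1$, the single worst variant with $p < 0.05$ is removed, and the
  fit-and-remove cycle repeats until no outlier remains or fewer than
  three variants survive. One-at-a-time removal matters: a gross outlier
  distorts the slope enough to make innocent variants look heterogeneous,
  so removing all flagged variants at once can empty the instrument set.
- **Steiger filter**: a variant explaining more variance in the outcome
  than in the exposure contradicts the assumed causal direction and is
  removed. The default decision is the plain $R^2$ comparison; a
  significance-tested variant (Fisher-z) is available behind a flag.

Every removed variant lands in a dropped ledger with its stage and reason,
and each stage records its retained count, so the pipeline satisfies a
conservation invariant that the tests assert: candidates in = instruments
retained + variants ledgered.

## Estimators

**IVW.** $\hat\beta = \sum_j w_j \hat\theta_j / \sum_j w_j$, identical to
the zero-intercept WLS slope of $\hat\Gamma$ on $\hat\gamma$ with weights
$1/\sigma_Y^2$. The default is the multiplicative random-effects model:
the fixed-effect SE is inflated by $\sqrt{Q/(J-1)}$ when heterogeneity
exceeds its expectation, with the inflation floored at 1. This matches
dominant practice in the field's tooling; the fixed-effect variant is a
flag.

**MR-Egger.** WLS of $\hat\Gamma$ on $\hat\gamma$ *with* an intercept
after orienting all exposure effects non-negative. The intercept estimates
the mean directional pleiotropic effect; the slope is consistent under the
InSIDE assumption (pleiotropy independent of instrument strength).
Standard errors use the same dispersion-floor convention; p-values use the
normal reference by default (Student-t is a flag — the choice is
configurable because conventions differ between implementations).

**Weighted median.** Ratios are ordered and the standardized
mid-cumulative weights $s_j = (\sum_{k \le j} w_k - w_j/2)/\sum_k w_k$ are
interpolated at $s = 0.5$; consistent while valid instruments carry at
least half the total weight. The SE is a parametric bootstrap (ratios
resampled from $N(\hat\theta_j, se_j)$, 1000 replicates by default, seed
mandatory).

**Weighted mode.** A weighted normal-kernel density over the ratios with
bandwidth $\phi \times 0.9\,\min(sd, mad)\,J^{-1/5}$ (modified Silverman;
$sd$ is used when the $mad$ degenerates to zero), maximized by grid search
over the ratio range $\pm 3$ bandwidths at 10,000 points. Estimates the
effect of the largest cluster of agreeing instruments; bootstrap SE as for
the median. As $\phi \to \infty$ the kernel flattens and the estimate
approaches the weighted mean — a limit the tests assert.

**Robust profile score (MR-RAPS style).** The slope solves
$\sum_j \psi(t_j)\,\partial t_j/\partial\beta = 0$ with standardized
residuals
$t_j = (\hat\Gamma_j - \beta\hat\gamma_j)\big/
 \sqrt{\sigma_{Y j}^2 + \beta^2 \sigma_{X j}^2 + \tau^2}$,
which accounts for uncertainty in *both* coordinates (suitable for many
weak instruments). Optional overdispersion $\tau^2$ (systematic
pleiotropy) solves $\sum_j \psi(t_j) t_j = J\,\delta$ with $\delta =
E[\psi(Z)Z]$ under a standard normal; Huber ($k = 1.345$) and Tukey ($k =
4.685$) losses bound the influence of idiosyncratic pleiotropy.
Numerically, the slope is found by minimizing the robust objective from
the IVW starting value and polishing to a score root when one brackets
(redescending losses can have flat score tails, so pure root-bracketing is
fragile); the SE is sandwich-type from the score contributions. With L2
loss, no overdispersion and vanishing exposure SEs the estimating equation
collapses exactly to fixed-effect IVW — asserted to $10^{-8}$ in the
tests.

**Heterogeneity.** Cochran's $Q = \sum_j w_j (\hat\theta_j -
\hat\beta_{IVW})^2$ (df $J-1$) and Rücker's $Q$ about the Egger fit (df
$J-2$); the intercept absorbs heterogeneity, so Rücker's never exceeds
Cochran's — asserted on random instances.

## Sensitivity suite

The Egger intercept test calls directional pleiotropy at $p < 0.05$.
MR-PRESSO simulates the global residual-sum-of-squares statistic under the
fitted no-pleiotropy model (outcome effects redrawn around leave-one-out
IVW predictions), with add-one smoothing so the p-value is bounded below
by $1/(n_{sim}+1)$; per-variant outlier p-values are Bonferroni-corrected
and only reported when the global test is significant, and the distortion
test compares the post-removal slope change against random removals of the
same size. Leave-one-out refits IVW omitting each instrument and flags a
variant influential when its omission moves the p-value across the study
threshold. The confounder filter removes instruments associated with
measured risk factors below $0.05 / (\#IVs \times \#risk\ factors)$.

## Two-step mediation

With exposure $X$, mediator $M$ and outcome $Y$: step 1 estimates $a$
($X \to M$) using $X$'s instruments; step 2 estimates $b$ ($M \to Y$)
using $M$'s instruments (univariable, per the two-step design — no
multivariable adjustment for the exposure, a documented limitation). The
indirect effect is $a b$ with first-order delta SE
$\sqrt{a^2 se_b^2 + b^2 se_a^2}$ (the two steps come from non-overlapping
samples and are treated as independent, so no covariance term), the direct
effect is total minus indirect, and the mediated proportion is
indirect/total on the log-effect scale — flagged unreliable when
$|total|/se < 2$, since a noisy denominator destabilizes the ratio. For
binary traits all effects combine on the log-odds scale, stated explicitly
in the report. Mediation is only assessed when the exposure–outcome and
exposure–mediator IVW effects pass the significance gate (the family-wise
Bonferroni threshold by default; nominal 0.05 behind a flag), and a failed
gate is reported explicitly rather than silently omitted.

The family size for Bonferroni correction is user-declared (a study
testing 8 reciprocal pairs, 4 exposure–outcome pairs and 1
mediator–outcome pair declares 13, giving $0.05/13 = 3.85\times10^{-3}$);
the pipeline can also auto-count its configured tests, but the declaration
wins and both are recorded.

## The synthetic-data generator

`simulateGwasPair()` draws allele frequencies uniformly on (0.05, 0.5),
true exposure effects normal and rescaled so the instruments jointly
explain a configured heritability, and sets outcome effects to
$slope \times \gamma_j + \alpha_j$, with per-variant SEs
$1/\sqrt{2 f (1-f)\, n}$ per the standardization model and observed
effects equal to truth plus $N(0, se)$ noise. P-values are computed from
the observed Z, so emitted tables always satisfy the dataset validator.
Pleiotropy regimes: `balanced` (zero-mean), `directional` (non-zero mean,
applied relative to the exposure-increasing allele — the coding the Egger
intercept estimates), and `inside_violating` (pleiotropy proportional to
instrument strength, breaking InSIDE). `simulateMediationTriplet()` builds
the chain $X \to M \to Y$ with distinct instrument sets for $X$ and $M$;
all variants appear in all three datasets so instrument selection runs
exactly as on real data. `simulateLdMatrix()` emits block-diagonal LD for
clumping and proxy tests.

What the generator does *not* emulate: sample overlap between the two
GWAS, individual-level liability for binary traits (effects are generated
directly on the log-odds scale), population structure, relatedness, and
allele-frequency differences between datasets. Passing tests therefore
validate the estimators and the pipeline logic, not robustness to those
real-data complications.

### Default study conditions

The defaults emulate well-powered behavioural/psychiatric GWAS: exposure
$n = 300{,}000$, outcome $n = 130{,}000$, mediator $n = 85{,}000$, 100
instruments explaining 1% of exposure variance — per-instrument expected
$F \approx 30$, comfortably past the $F > 10$ screen and typical of
significant GWAS loci for complex behavioural traits.

Two validation scenarios deliberately depart from the defaults, for
reasons of experimental design rather than realism:

- **Weighted-median breakdown** uses per-instrument $F \approx 300$. The
  median's 50%-breakdown property is a strong-instrument statement: at
  moderate $F$ the Wald-ratio noise (which scales as
  $1/\sqrt{F}$) swamps the planted pleiotropic offset and the estimator's
  limiting value is the corresponding quantile of a noisy mixture, biased
  on both sides of the breakdown point. The recovery tolerance is a third
  of the planted offset of 0.3 on the ratio scale.
- **Mediation recovery** uses exposure $n = 2\times10^6$ with $h^2 =
  0.05$ and a mediator GWAS of $n = 10^5$ with its own instruments
  explaining 30% of mediator variance. Two constraints drive this: the
  ratio estimators carry a known $O(1/F)$ regression-dilution bias, which
  must sit below Monte-Carlo resolution for a consistency check over 200
  replicates, and the exposure-to-mediator transmission $a\,\gamma_j$ must
  stay below genome-wide significance in the mediator GWAS so the two
  instrument sets remain distinct, as the chain model specifies. At
  moderate instrument strength the same pipeline shows the expected
  percent-level attenuation — a property of two-sample IVW, not an
  implementation defect.

## Numerical and reproducibility choices

- Exactly collinear Egger inputs (zero residual dispersion) yield exact
  estimates with zero SEs and a unit intercept p-value when the intercept
  is numerically zero, rather than noise-driven inference.
- Two-sided p-values are floored at the smallest positive double so they
  remain in $(0, 1]$.
- All stochastic stages (median/mode bootstraps, MR-PRESSO) take explicit
  seeds. The pipeline derives per-stage seeds from the master seed as
  $(master + 104729 \times stage) \bmod (2^{31}-1)$ with fixed stage
  indices, so adding a stage never silently re-seeds earlier ones; reports
  contain no timestamps and reproduce byte-identically under a fixed
  configuration.
- The validator is permissive: malformed rows are dropped and counted
  rather than aborting a run, and reported p-values inconsistent with
  $|\beta/se|$ beyond 10% (relative) draw a warning, not a drop.
- Simulation sizes in the test suite (e.g. 1000 null replicates for the
  type-I check, 200 for recovery checks, 100 for detection rates) were
  chosen to give Monte-Carlo standard errors well inside the asserted
  bands while keeping the default test run short.

## Known limitations

- No multivariable MR, no correlated-instrument (generalized) IVW, no
  CAUSE/contamination-mixture estimators.
- Step 2 of mediation is univariable; with a strong direct path and shared
  instruments it would be biased (the generator's distinct instrument sets
  avoid this by construction).
- LD information is an input; without it, missing outcome variants are
  dropped rather than proxied, and clumping treats all pairs as unlinked.
- Proxy variants rely on the sign matrix for allele alignment; unsigned
  proxies are dropped rather than frequency-aligned.

## A worked example

```{r example}
cfg <- simConfig(trueSlope = 0.2, seed = 42)
sim <- simulateGwasPair(cfg)
res <- runMr(sim$exposure, sim$outcome,
             config = mrConfig(seed = 7, nBoot = 200, pressoNSim = 200))
res
res$heterogeneity$cochran$p
res$presso
```
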