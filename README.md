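# mrpath

Two-sample Mendelian randomization (MR) from GWAS summary statistics, with
a full sensitivity suite and two-step mediation.

MR uses genetic variants as instrumental variables to estimate the causal
effect of an exposure on an outcome from observational association data.
Given per-variant summary statistics from two independent GWAS — exposure
effects γ̂ⱼ and outcome effects Γ̂ⱼ with standard errors — each instrument
supplies a Wald ratio θ̂ⱼ = Γ̂ⱼ/γ̂ⱼ, and the package combines these under
different pleiotropy assumptions:

- **IVW** (primary): inverse-variance-weighted mean of the ratios,
  multiplicative random effects by default;
- **MR-Egger**: weighted regression with an intercept that estimates
  directional pleiotropy;
- **weighted median**: consistent while valid instruments hold ≥ 50% of
  the weight;
- **weighted mode**: the largest cluster of agreeing instruments;
- **MR-RAPS-style robust profile score**: accounts for uncertainty in both
  coordinates, with optional overdispersion and Huber/Tukey losses.

Around the estimators: instrument selection (p < 5×10⁻⁸), greedy LD
clumping (r² > 0.001, 10,000 kb), proxy substitution (r² > 0.8), allele
harmonization with palindromic-variant handling, radial outlier removal,
Steiger directionality filtering, Cochran's/Rücker's Q, the Egger
intercept test, MR-PRESSO, leave-one-out, confounder-associated instrument
exclusion, Bonferroni family-wise control, and two-step mediation
(product-of-coefficients indirect effect, delta-method SE, mediated
proportion). A synthetic summary-statistics generator with known ground
truth (true slope, pleiotropy regime, mediation chain, LD blocks) makes
the whole pipeline testable without any external data.

For whom: analysts running summary-data MR who want a self-contained,
deterministic, fully tested implementation whose every filtering decision
is recorded in a dropped-variant ledger.

## Worked example

```r
library(mrpath)

cfg <- simConfig(trueSlope = 0.2, seed = 42)   # known truth: slope 0.2
sim <- simulateGwasPair(cfg)
res <- runMr(sim$exposure, sim$outcome,
             config = mrConfig(seed = 7, nBoot = 200, pressoNSim = 200))
res
```

```
MrResult: sim_exposure -> sim_outcome
       stage n_retained
      select         32
       clump         32
   harmonize         32
 palindromic         32
      radial         32
     steiger         32
IVW estimate (32 SNPs): beta = 0.1851 (se 0.02932), p = 2.72e-10
  OR = 1.203, 95% CI [1.136, 1.275]
MR-RAPS estimate (32 SNPs): beta = 0.1867 (se 0.02258), p = 1.36e-16
  OR = 1.205, 95% CI [1.153, 1.26]
MR-Egger estimate (32 SNPs): beta = 0.1075 (se 0.1008), p = 0.286
  OR = 1.114, 95% CI [0.9138, 1.357]
  intercept = 0.002147 (se 0.00267), p = 0.421
weighted-median estimate (32 SNPs): beta = 0.1958 (se 0.04133), p = 2.17e-06
  OR = 1.216, 95% CI [1.122, 1.319]
weighted-mode estimate (32 SNPs): beta = 0.2008 (se 0.06077), p = 0.000953
  OR = 1.222, 95% CI [1.085, 1.377]
```

Reading this: 32 of 100 simulated variants reached genome-wide
significance and survived every filter (the stage ledger shows where any
would have been lost). All five estimators recover the true slope 0.2
within their uncertainty; the Egger intercept is null (no directional
pleiotropy was simulated, and none is found, p = 0.42). On this run the
instruments' F statistics are all > 30, Cochran's Q shows no
heterogeneity (p = 0.86), and MR-PRESSO flags no outliers (global
p = 0.85).

Bidirectional analysis, mediation and reports:

```r
both <- runBidirectionalMr(sim$exposure, sim$outcome, config = mrConfig(seed = 7))

tri <- simulateMediationTriplet(simConfig(
  nSnps = 100, exposureH2 = 0.05, mediatorH2 = 0.3,
  nExp = 2e6, nMed = 1e5, nOut = 1.3e5,
  mediation = list(a = 0.3, b = 0.5, cprime = 0.1), seed = 1))
med <- runMediationAnalysis(tri$exposure, tri$mediator, tri$outcome,
                            config = mrConfig(seed = 7))
med$mediation          # ACME, total, direct, mediated proportion

writeReport(med, "mr_report")   # estimates.tsv, report.json, plot tables
```

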