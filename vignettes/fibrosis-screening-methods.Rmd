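---
title: "Methods: simulated fibrosis screening in diabetic primary care and its cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated fibrosis screening in diabetic primary care and its cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimast)
```

# The problem

Type-2 diabetic patients in the community carry a substantial burden of
liver fibrosis due to metabolic dysfunction-associated steatotic liver
disease (MASLD), most of it undetected: established blood markers (FIB-4,
NFS, ELF) were derived in referral populations and miss a large share of
fibrotic patients when applied in primary care. This package implements a
complete, reproducible pipeline around that problem: a synthetic-cohort
generator with the statistical structure of a primary-care diabetic
population, the derivation and validation machinery for a simple
BMI+AST-based screening score (the BIMAST score), head-to-head diagnostic
comparison against FIB-4 / NFS / ELF / ultrasound+LFTs / transient
elastography (TE), and a decision-tree plus Markov cohort cost-utility
model comparing six screening strategies against standard of care (SOC).

Because the underlying patient-level data are not public, every analysis
runs on synthetic cohorts; the package's claims are therefore about the
correctness and calibration of the *machinery*, not about re-estimating the
clinical results.

# The synthetic cohort generator

Each subject carries a fibrosis state in {none/mild, significant, advanced,
cirrhosis}, drawn with default prevalences (83%, 6%, 8%, 3%). These were
chosen so that 17% of subjects have liver stiffness (LSM) at or above
8.1 kPa and 11% at or above 12.1 kPa — the significant- and
advanced-fibrosis prevalences of the target population. Conditional on
state, nine biomarkers (age, BMI, waist, AST, ALT, platelets, albumin, ELF,
LSM) are drawn from a Gaussian copula: a latent multivariate normal with a
fixed correlation matrix (BMI–waist 0.8, AST–ALT 0.7, ELF–LSM 0.4, LSM
positively coupled to enzymes and negatively to platelets and albumin) is
mapped through per-state marginal quantile functions. BMI, waist, age,
platelets, albumin and ELF use truncated normals; AST, ALT and LSM use
truncated log-normals, reflecting the right skew of liver enzymes.

Two structural choices deserve emphasis:

* **LSM ranges are disjoint per state** ([2, 8.0], [8.1, 12.0],
  [12.1, 25.0], [25.1, 75] kPa), so the state label and the stiffness
  thresholds can never disagree — the reference standard of the whole
  pipeline is internally consistent by construction.
* **Group-conditional locations are calibrated to the published group
  medians**: the mixture of the three fibrotic states reproduces BMI
  36.8 vs 30.3 kg/m², AST 37 vs 26 IU/L and waist 120 vs 105 cm between the
  LSM ≥ 8.1 and < 8.1 groups. Scale parameters (e.g. BMI sd 5.5 kg/m²,
  AST sdlog 0.35) were fixed once at values giving plausible interquartile
  ranges for a diabetic community population.

All subjects are diabetic (the study inclusion criterion), so the NFS
diabetes term is always active. MASLD is assigned to every fibrotic subject
and to 64% of non-fibrotic ones — a documented simplification: the score
concerns MASLD fibrosis, and non-MASLD aetiologies are excluded from the
generator entirely. A single RNG stream per cohort, seeded from the spec,
makes generation bit-reproducible.

## Spectrum shift

`spectrum_shift(spec, factor)` emulates referral (secondary/tertiary-care)
cohorts: the odds of the fibrotic states are multiplied by `1 + factor`,
fibrotic AST locations rise by 10% per unit factor, the non-fibrotic AST
location drifts towards the fibrotic range (referral case-mix compression),
and LSM is skewed upwards within each state's range. `solve_spectrum_factor`
inverts the prevalence map by bisection, e.g. to hit the 48% (105/218)
fibrosis prevalence of a referral validation cohort. The shift emulates
*prevalence and severity enrichment*; it deliberately does not attempt to
reproduce the full discrimination loss seen in real external cohorts, which
also involves BMI case-mix, different measurement protocols and referral
filtering on the very markers under study. Conclusions about external
performance should not be read off these simulations.

# Scores and screening strategies

`bimast_score` is the published linear score 0.17·BMI + 0.054·AST − 8.771.
FIB-4 (age·AST/(platelets·√ALT)) and NFS (−1.675 + 0.037·age + 0.094·BMI +
1.13·diabetes + 0.99·AST/ALT − 0.013·platelets − 0.66·albumin, albumin in
g/dL) use their standard published formulas, pinned in code and overridable
through the fitting API. ELF is treated as a measured input, not computed
from its analytes.

Positivity rules: FIB-4 > 1.3, NFS > −1.45, ELF ≥ 9.8 (9.5 is used by some
referral pathways and can be passed as an override), TE ≥ 8.1 kPa. The
BIMAST cut-offs 0.063 (significant) and 0.102 (advanced fibrosis) sit on
the **predicted-probability scale**, i.e. the linear score is passed through
the logistic function first. This is a deliberate design decision: the
published group-median linear scores are −0.517 (fibrotic) and −2.216
(non-fibrotic), both far below 0.063, so a linear-scale cut could never
yield the score's published high-sensitivity operating point (94%
sensitivity, 44% specificity), whereas logit(0.063) ≈ −2.70 does.

US+LFTs and SOC have no patient-level rule and are modelled as probabilistic
classifiers: abnormal LFTs carry 35% sensitivity and 65% specificity for
fibrosis; SOC is a configurable mixture (default 50/50) of abnormal-LFTs
screening and no screening (sensitivity 0, specificity 1). Their Bernoulli
draws are independent of the biomarkers given disease status.

# Derivation and validation machinery

* **Split**: seeded 2:1 random allocation with derivation size
  `round(2n/3)` — (191, 96) at n = 287. The source study reports (194, 93),
  which is not exactly 2:1 of 287; since the allocation scheme behind those
  numbers is unstated, the package uses the transparent rounding rule and
  documents the mismatch here.
* **Univariate screen**: Mann-Whitney (tie-corrected normal approximation)
  for continuous, Pearson chi-square for categorical variables, two-sided.
* **Logistic fit**: hand-written IRLS maximising the Bernoulli
  log-likelihood, converged when the score vector's max-norm falls below
  1e-8 (at most 100 iterations). Perfect separation — detected as fitted
  probabilities reproducing the outcomes to within 1e-6 — is flagged as
  non-convergence with the last iterate still returned. The fit is
  cross-checked against `stats::glm` in the test suite.
* **Calibration**: Brier score and the Hosmer-Lemeshow test on (by default)
  10 value-quantile risk bins. Binning by value quantiles (not by sorted
  record index) makes the statistic invariant to record order; bins with
  degenerate expected counts are merged with a message, and the statistic is
  referred to chi-square with bins − 2 degrees of freedom.
* **Discrimination**: AUROC as the Mann-Whitney concordance probability with
  ties counted 1/2, computed through the midrank identity so it is
  bit-identical to exhaustive pair counting; variance and 95% CI from the
  DeLong structural-components estimator with asymptotic-normal bounds
  (clamped to [0, 1]). Paired AUROCs are compared with the DeLong test;
  `pROC` serves as an independent cross-check in the tests, never as the
  implementation.
* **Cut-off selection**: Youden's J (sensitivity + specificity − 1)
  operationalises "maximise sensitivity and specificity"; ties break towards
  the higher-sensitivity point, matching the screening intent.

# The health-economic model

A decision tree allocates the cohort at screening: diseased subjects
(states SLD = significant/advanced fibrosis, CC = compensated cirrhosis at
entry; default prevalence 83/14/3% MLD/SLD/CC) who test positive enter
diagnosed states, those missed enter false-negative states, and
false-positive non-diseased subjects incur a one-off specialist referral
cost. The Markov model then runs annual cycles over a 40-year horizon on
nine states: MLD, SLD_dx, SLD_fn, CC_dx, CC_fn, DC (decompensated
cirrhosis), HCC, LT (transplant) and DEAD. Splitting SLD and CC by
diagnosis status makes the model's core assumption — management after
diagnosis slows progression — an explicit, validated parameter ordering:
every undiagnosed progression probability must be at least its diagnosed
counterpart. False negatives never transition back to the diagnosed arm
short of progressing to clinically evident end-stage disease.

Numerical conventions: rewards (life-years, QALYs, costs) accrue on the
occupancy at the start of each cycle, discounted by (1 + r)^−t with t = 0
for the first cycle and r = 3.5%/year; no half-cycle correction by default
(switchable via `half_cycle_correction` in the config); the one-off
screening and referral costs enter undiscounted at t = 0. Background
mortality is an age-independent annual probability folded into each state's
death transition — no life tables. Occupancy conservation is enforced to
1e-10 in the tests, and the transition matrix is validated (row-stochastic,
absorbing death) before iteration.

ICERs versus SOC are Δcost/ΔQALY with explicit `dominant` / `dominated` /
`undefined` flags instead of signed ratios. The correct-diagnosis increase
is the percentage-point difference in (TP+TN)/n against SOC. One-way
sensitivity re-runs the whole pipeline over a parameter grid addressed by a
dot-path into the config. The PSA draws probabilities and utilities from
beta distributions (moment-matched to the base value with effective sample
sizes 100 and 50) and costs from gamma distributions (CV 0.2), re-running
all strategies on each joint draw; degenerate settings (infinite effective
size, zero CV) reproduce the base case exactly. The CEAC reports, at each
willingness-to-pay threshold, the fraction of draws in which a strategy has
the maximal net monetary benefit.

## The placeholder parameter set

The packaged YAML config (`inst/extdata/econ_placeholder.yaml`) carries
**placeholder** transition probabilities, costs and utilities: plausible
values for a MASLD natural-history model, chosen once to satisfy every
structural invariant and to reproduce the qualitative base-case structure
(screening costs more than SOC and buys QALYs at ICERs well below the
£20,000/QALY threshold; TE, as the reference standard, gains the most
QALYs). They are *not* the study's supplementary parameter tables, which are
not redistributable here; transcribing those tables into the same YAML
schema is the supported path to reproducing published base-case numbers.
Consequently the package asserts ordering and invariance properties of the
economic model, never specific published ICER values.

# Problem sizes and what the tests show

The test suite and the acceptance analyses use: study-sized cohorts
(n = 287) for pipeline realism; n = 50,000 cohorts for calibration and
operating-characteristic checks (binomial tolerances); 500 random instances
(n ≤ 200) for exact AUROC/brute-force equivalence; 2,000 replicates at
n = 200 for the DeLong null-calibration check; 1,000 random configurations
for Markov conservation; and 500 PSA draws in the analysis scripts. These
sizes give tight Monte-Carlo error on everything asserted while keeping a
full run to a few minutes.

Passing tests demonstrate that the machinery is correct and calibrated on
data *with the generator's structure*: real cohorts have missingness,
measurement error in TE, non-Gaussian dependence, aetiological mixtures and
referral filtering that the generator does not emulate, so clinical
conclusions require the real data and the published supplementary
parameters.

# Known limitations

* The generator's dependence structure is a single Gaussian copula; tail
  dependence and subgroup structure (e.g. MetALD) are absent.
* External-cohort emulation enriches prevalence and shifts AST/LSM, which
  reproduces prevalence-driven PPV/NPV and false-negative behaviour but not
  the full AUROC degradation of real referral cohorts.
* The economic model is a cohort (not individual-level) simulation with
  age-independent background mortality and no cardiovascular co-outcomes.
* SOC's composition (share of abnormal-LFTs screening) is a modelling
  choice exposed in the config, not an estimate.
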