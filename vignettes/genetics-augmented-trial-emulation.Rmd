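---
title: "Auditing target trial emulations with polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing target trial emulations with polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgstrial)
```

## The problem

Target trial emulations reproduce the protocol of a randomized controlled
trial (RCT) inside observational registry data: eligibility criteria, an
active-comparator contrast, 1:1 propensity-score (PS) matching, on-treatment
follow-up, and a Cox analysis. Their Achilles heel is the exchangeability
assumption — no unmeasured confounding. Because doctors choose drugs partly
on patient characteristics that also drive outcomes (confounding by
indication), the treated and comparator groups can differ in ways the
measured covariates do not capture.

`pgstrial` operationalizes a genetics-based audit of that assumption.
Polygenic scores (PGS) are fixed at conception, cheap to compute for many
traits at once, and correlated with the clinical traits that drive
prescribing. The package provides four linked analyses:

1. **Balance diagnostics** — standardized mean differences (SMD) of a panel
   of PGS between arms at three successive stages of adjustment (plain
   observational contrast, after eligibility, after PS matching).
2. **Proxy-bias simulations** — directed-acyclic-graph simulations, with a
   closed-form oracle, of how much confounding bias remains when one
   *adjusts for* a PGS that is only an imperfect proxy of the confounder.
3. **MR confounder detection** — two-sample Mendelian randomization (MR)
   used as a screen: a trait causally associated with both treatment
   initiation and the outcome is a putative confounder.
4. **Enrichment evaluation** — whether an outcome PGS is prognostic inside
   the emulated cohort, and how recruiting the top PGS quantile would
   shrink a trial's required sample size.

Individual-level biobank data of the kind these methods target are
access-restricted, so the package ships a synthetic-data module that
generates registry-like cohorts and GWAS summary statistics with known
ground truth. Every downstream claim the package makes is testable against
that ground truth.

## The synthetic cohort model

`cohort_config()` + `generate_cohort()` draw, for each individual:

* standardized PGS, one per trait: $\mathrm{PGS}_k \sim N(0,1)$, explicitly
  re-standardized over the whole cohort (mean 0, sd 1), matching the
  convention that scores are standardized in the full study population;
* a latent clinical trait (the confounder)
  $C_k = \sqrt{r^2_k}\,\mathrm{PGS}_k + \sqrt{1-r^2_k}\,\varepsilon$, so the
  PGS explains exactly $r^2_k$ of the trait variance. Defaults recycle
  $r^2 \in \{0.5, 0.3, 0.2, 0.1, 0.05, 0.01\}$ — the realistic range from
  strong (e.g. lipids) to weak PGS;
* a dated binary diagnosis flag per trait from a logit model on $C_k$ —
  the registry's coarse, observable view of the trait;
* treatment status by two logit models on the prescription linear predictor
  $\sum_k w_k C_k$: one for *initiating* therapy at all, one for being
  channelled to the target drug rather than the active comparator. This is
  confounding by indication in its simplest form. The channelling step uses
  a damped coefficient (`choice_scale = 0.6` by default): two drugs
  prescribed interchangeably differ less in indication than users differ
  from non-users, which is exactly why active-comparator designs help.
  Defaults make three traits confounders (log-odds 1.0, 0.8, 0.6; outcome
  log-HR 0.3 each);
* an exponential proportional-hazards event time with hazard
  $\lambda_0 \exp(\beta_T T + \sum_k b_k C_k)$, with
  $\beta_T = \log 0.8$ by default, so the true treatment effect is known;
  a competing background death rate; an administrative registry end
  (day 3652, ten years);
* drug purchases every `package_days` (90) days with per-refill persistence
  0.9, plus a 5% chance of switching to the opposing drug.

Dates are integer days from cohort entry. What this generator deliberately
does **not** emulate: calendar time and secular prescribing trends, measured
covariates beyond one flag per trait, non-proportional hazards, LD between
the trait PGS, and misclassified registry codes. Green tests therefore show
the estimators and diagnostics are correct *under the stated model*, not
that any particular real-world emulation is unconfounded.

Genotypes (`generate_genotypes()`) are only needed where variant-level
machinery is exercised (PGS scoring, LD clumping). They use
block-exchangeable Gaussian-threshold haplotypes: one minor-allele
frequency per LD block, and a latent correlation calibrated by quadrature
so the realized *dosage* correlation equals the requested `within_block_r`.
This is not a population-genetic simulator; it provides exactly the two
properties clumping and scoring need — known pairwise LD and known allele
frequencies.

## The emulation stages

`staged_cohorts()` materializes the three contrasts the balance diagnostic
compares:

* **plain** — the naive observational question. For a placebo-controlled
  reference trial this is target-drug initiators versus everyone who did
  not initiate the target drug; for an active-comparator trial, target
  versus comparator initiators. (Reading "noninitiator" as "did not
  initiate the *target* drug" keeps the three stages nested by individual,
  which the package asserts.)
* **eligible** — target versus comparator initiators passing every
  eligibility rule at their initiation date, with per-rule attrition
  logging.
* **matched** — after 1:1 greedy nearest-neighbor PS matching without
  replacement. Treated individuals are processed in a seeded random order;
  ties in distance break toward the lowest comparator id; the caliper is
  0.1 on the PS scale, tightened to 0.01 when the arm-wise PS density
  overlap coefficient exceeds 0.98 (`"auto"`), since a near-complete
  overlap both permits and rewards the tighter caliper. Both the rule and
  the caliper are configurable.

The PS model is a main-effects logistic regression — the simplest
defensible choice; covariates can be diagnosis flags or measured continuous
traits (`conf_` prefix). Separation and aliasing are hard errors naming the
offending covariates rather than silent degeneracies.

On-treatment follow-up (`build_followup()`) starts at the first purchase
and ends at the earliest of outcome event, death, supply run-out (last
purchase date plus total purchased packages times `package_days`), switch
to the opposing drug (no grace period), or registry end. The event flag is
set only when the outcome is the earliest terminator; ties on the same day
count as events. Same-day termination is floored at half a day so survival
times stay positive. Cox models use Efron's tie handling throughout.
`estimate_agreement()` implements the conventional check that the
emulation's point hazard ratio falls inside the reference RCT's 95% CI
(closed interval).

## Balance diagnostics

For each PGS and stage, `compute_smd()` reports
$d = (\bar x_1 - \bar x_0)/s_\text{pooled}$ with the large-sample variance
$(n_1+n_0)/(n_1 n_0) + d^2/(2(n_1+n_0))$ for the CI, and a two-sided Welch
t-test p-value, flagged at the Bonferroni threshold $\alpha/K$ (0.05/20 =
2.5e-3 for the default 20-trait panel; strict inequality). Pooled-SD SMD
with a t-test is the field-standard balance metric; where a source computes
"SMD by logistic regression" the definition is ambiguous, and this package
deliberately uses the standard formula. `balance_trajectory()` summarizes
the stage-wise mean |SMD| and flags whether it decreases monotonically with
increasing adjustment — the expected signature when the adjustment set
really captures the indication.

Two calibration facts shape interpretation. First, $|{\rm SMD}|$ has a
sampling floor of roughly $\sqrt{2/n}$ per arm-pair, and the matched stage
is always the smallest; a decreasing mean |SMD| is evidence only when the
plain-stage imbalance clearly exceeds the matched-stage noise floor.
Second, under randomized arms the family-wise false-positive rate of the
panel at the Bonferroni threshold is controlled at $\alpha$; the test suite
verifies both properties by simulation.

## Proxy-bias simulations and their oracle

Adjusting for a PGS proxy is not the same as adjusting for the confounder.
Model 1 makes this quantitative with four standardized variables:

$$C = r\,\mathrm{PGS} + \sqrt{1-r^2}\,\varepsilon_C,\qquad
  X = b_{CX} C + \sqrt{1-b_{CX}^2}\,\varepsilon_X,\qquad
  Y = X + b_{CY} C,$$

so $\mathrm{Var}(\mathrm{PGS}) = \mathrm{Var}(C) = \mathrm{Var}(X) = 1$ and
the true $X\!\to\!Y$ effect is 1. The estimated bias is the X coefficient
of `lm(Y ~ X + PGS)` minus 1, in percent (identical to relative bias since
the truth is 1). Because the model is jointly Gaussian, the population
coefficient has a closed form from the 2×2 normal equations
(`analytic_bias_model1()`):

$$\beta_X = \frac{(1 + b_{CX}b_{CY}) - b_{CX} r \cdot r(b_{CX}+b_{CY})}
                 {1 - b_{CX}^2 r^2}.$$

This oracle anchors the Monte-Carlo machinery: `run_grid()` must reproduce
it within Monte-Carlo error over the whole default grid
($r^2 \in \{0.01, 0.05, 0.1, 0.2, 0.3, 0.5\}$ crossed with confounding
variance fractions $\{0.1, 0.2, 0.3, 0.5\}$ — small to large confounding).
Useful limits, all tested: bias is 0 when $b_{CX} = 0$ or $b_{CY} = 0$ (no
confounding path), 0 at $r = 1$ (the PGS *is* the confounder), equals the
fully unadjusted bias $100\,b_{CX}b_{CY}$ at $r = 0$, is non-increasing in
$r^2$, and remains strictly positive at $r^2 = 0.5$ — a realistically
strong PGS still leaves most of the bias in place.

Model 2 shows the residual bias is not a function of $r^2$ alone: PGS and
$C$ share a causal factor $G^*$
($\mathrm{PGS} = b_{G^*\mathrm{PGS}} G^* + \sqrt{1-b^2_{G^*\mathrm{PGS}}}\,G'$,
$C = b_{G^*C} G^* + \sqrt{1-b^2_{G^*C}}\,\varepsilon_C$ with
$b_{G^*C} = r/b_{G^*\mathrm{PGS}}$), while $G'$ feeds only the PGS — and
possibly $X$ and $Y$ directly. With $b^2_{G^*\mathrm{PGS}} = 0.8$ and
$r^2 = 0.3$ fixed, making $G'$'s effect on $X$ more negative inflates the
bias at constant $r^2$. The noise symbol in the source equation for $X$ is
read as an independent $\varepsilon_X$ (unit variance requires it). The
confounding-fraction parameterization is solved by `confounding_coefs()`:
$b_{CX} = \sqrt{f}$ and $b_{CY}$ from the quadratic
$b_{CY}^2(1-f) - 2fb_{CX}b_{CY} - f = 0$.

```{r proxy-demo}
cf <- confounding_coefs(0.3)
d <- simulate_model1(20000, r = sqrt(0.3), b_CX = cf$b_CX, b_CY = cf$b_CY,
                     seed = 1)
c(mc = estimate_bias(d),
  analytic = analytic_bias_model1(sqrt(0.3), cf$b_CX, cf$b_CY))
```

## MR-based confounder detection

`select_instruments()` builds the instrument set in the conventional order:
exposure significance ($p < 5\times10^{-8}$), greedy LD clumping
($r^2 < 0.001$, 10,000 kb center-to-center window, same chromosome only,
most significant variant kept), then exclusion of outcome-associated
variants ($p < 5\times10^{-8}$). Alleles are harmonized first; swapped
effect/other alleles flip the outcome beta's sign, irreconcilable variants
are dropped with a log message. `ivw_estimate()` is fixed-effect
inverse-variance-weighted MR — weighted least squares of Wald ratios
through the origin — with a multiplicative random-effects option; a single
instrument degenerates to a flagged Wald ratio with a delta-method SE.

The confounder screen is a conjunction: a trait whose MR is significant on
*both* treatment initiation and the trial outcome is a putative confounder
(`classify_confounder()`, evaluated at a nominal 0.05 and a Bonferroni
threshold, strict inequalities). Because the outcome itself can influence
prescribing, `direct_effect_adjustment()` subtracts the mediated path:
$\hat\beta_{\text{direct}} = \hat\beta_{CX} - \hat\beta_{CY}\hat\beta_{YX}$
with a delta-method SE under independence. The mediator-path estimate
$\hat\beta_{YX}$ is supplied by the user (or a second MR); the subtraction
form is the documented default since no canonical estimator exists for it.

Caveats by design: the exclusion of outcome-associated variants protects
against one form of pleiotropy but, under a strong true causal effect,
removes perfectly valid instruments; and selecting on the noisy exposure
p-value induces mild winner's-curse attenuation. Both behaviors are
exercised in the tests rather than hidden.

## Enrichment evaluation

`prognostic_association()` fits
$h(t\mid T,\mathrm{PGS}) = h_0(t)\exp(\beta_1 T + \beta_2\,\mathrm{PGS})$
inside the matched cohort (PGS hazard ratio per 1 sd, treatment-adjusted).
`population_association()` fits the same PGS in the full cohort with age as
the timescale, follow-up from birth to event, death or registry end; left
truncation at cohort entry is available as a flag but off by default, since
the reference design follows from birth. Comparing the two exposes the
selection effect of eligibility: when eligibility selects high-liability
individuals on a saturating liability-to-hazard map, the within-trial PGS
effect attenuates relative to the population — care is needed when
generalizing population PGS associations into a trial cohort (and the test
suite reproduces exactly this attenuation).

`enrichment_sample_size()` operationalizes "same statistical power" as
equal expected event counts:
$n_\text{required} = n_\text{original}\,
 \frac{\text{rate}_\text{all}}{\text{rate}_\text{top-}q}$,
with a Schoenfeld log-rank alternative (`method = "schoenfeld"`) that gives
the identical percentage reduction. The top-quantile cut (default
$q = 0.25$) is taken on the full-population standardized PGS scale
($\Phi^{-1}(1-q)$) to match a "top 25% genetic risk" recruitment rule;
cutting on the analyzed records' own distribution is available.
`predictive_interaction()` tests $T \times \mathrm{PGS}$ — predictive, as
opposed to prognostic, enrichment.

## Numerical choices and degenerate inputs

* All randomness flows from one seed through `split_seed()` (multiplicative
  hash modulo $2^{31}-1$); reruns are byte-identical.
* Standardization refuses zero-variance input; SMD refuses zero pooled
  variance; Cox fits require at least one event; matching requires both
  arms; instrument selection with an empty survivor set is an explicit
  error. Boundary conventions are documented where they matter: agreement
  intervals are closed, significance inequalities are strict.
* Problem sizes used by the shipped checks: single simulations at
  $n = 10^5$; the oracle-vs-Monte-Carlo grid at 25 iterations × $n =
  4\times10^4$ per condition (a 10× scaled-down replicate budget that
  leaves the Monte-Carlo standard error well below the effects checked);
  parameter-recovery suites at 100 replicates; coverage and family-wise
  error suites at 1,000 replicates. The staged-emulation fixture uses a
  30,000-person cohort, which puts the plain-stage imbalance an order of
  magnitude above the matched-stage SMD noise floor.

## Known limitations

* The cohort generator's two-logit prescription model and exponential
  hazards are the minimal structure for known ground truth; it makes no
  attempt at realistic incidence curves or covariate distributions.
* Greedy nearest-neighbor matching is order-dependent in principle; the
  seeded order makes runs reproducible but optimal matching is out of
  scope.
* The MR module implements fixed/multiplicative-random-effects IVW only;
  pleiotropy-robust estimators (Egger, weighted median) are deliberately
  out of scope.
* PGS weight derivation (shrinkage priors, reference-panel restriction)
  is out of scope; `score_pgs()` consumes an existing weight table.
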