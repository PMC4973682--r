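---
title: "Missing-data-aware provider profiling from PROMs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-data-aware provider profiling from PROMs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promperf)
```

## The problem

Patient-reported outcome measures (PROMs) such as the Oxford Hip Score
(OHS) are collected before (Q1) and after (Q2) elective surgery and used to
compare hospital providers: each provider's case-mix-adjusted post-operative
score is placed on a funnel plot against its volume, and providers outside
the control limits are flagged as alerts or alarms. A pay-for-performance
rule (the best-practice tariff, BPT) pays a bonus to providers that are not
significantly below the benchmark *and* collect PROMs for over half of their
eligible patients.

PROMs are however heavily incomplete — roughly half of the eligible
patients in the English hip-replacement survey have no usable outcome — and
the official assessment simply drops incomplete records. `promperf`
implements the alternative: multilevel multiple imputation (MI) of the
ordinal items, indirect standardisation and funnel classification on the
completed data, and a re-weighting sensitivity analysis for missingness
that depends on the unobserved outcome itself (MNAR).

## The analysis model and indirect standardisation

For patient $i$ in provider $j$, with post-operative total $y_{2,ij}$,
pre-operative total $y_{1,ij}$ and case-mix covariates $X_{ij}$ (age band,
sex, ethnicity, comorbidity band, deprivation quintile, symptom duration):

$$y_{2,ij} = \alpha + X_{ij}\beta + y_{1,ij}\gamma + u_j + \varepsilon_{ij},
\qquad u_j \sim N(0, \sigma_u^2),\;
\varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2),$$

fitted by REML (`lme4::lmer`) in `fit_analysis_model()`. Indirect
standardisation (`standardize_providers()`) computes each patient's
case-mix-expected outcome $\hat y_{2,ij}$ from the *fixed part only* and
scales the national mean by the provider's mean observed/expected ratio:

$$\tilde y_{2,j} = \hat\rho_j \,\bar y_2, \qquad
\hat\rho_j = \frac{1}{n_j}\sum_i \frac{y_{2,ij}}{\hat y_{2,ij}}.$$

Excluding $u_j$ from $\hat y_2$ is deliberate: including it would force
every ratio towards 1 and erase the comparison. The within-dataset standard
error of $\tilde y_{2,j}$ is the plug-in
$\bar y_2 \cdot \mathrm{sd}(y_2/\hat y_2)/\sqrt{n_j}$, treating $\bar y_2$
and $\hat y_2$ as fixed; the between-patient SD of the standardised outcome,
$\sigma_{pop} = \bar y_2 \cdot \mathrm{sd}(y_2/\hat y_2)$, feeds the funnel
limits. These are declared choices — the profiling literature does not fix
them uniquely — made so that the same dispersion estimate drives both the
provider SEs and the control limits.

## Scoring and the threshold model

The OHS total is the unweighted sum of 12 items scored 0–4 (total 0 =
worst, 48 = best). A total is only defined when all 12 items are observed:
item non-response is imputed at item level, never pro-rated. Each item is
modelled as a latent standard-normal variable cut at strictly increasing
thresholds; a latent value exactly on a cut-point belongs to the lower
category (`latent_to_category()`).

## The synthetic cohort generator

No real survey data can ship with the package, so `generate_cohort()`
produces cohorts with the statistical structure the analysis assumes:
patients nested in providers, items from the threshold model, outcome
following the analysis model, and missingness from logistic selection
models.

The one non-obvious design element is how an item-level threshold model and
a total-score-level analysis model are made to cohere. For a common latent
shift $\mu$ shared by the 12 items, the expected total is
$F(\mu) = \sum_{k,m}\Phi(\mu - \alpha^k_m)$, a strictly increasing map onto
$(0, 48)$ (`expected_total()`). The generator draws the post-operative
linear predictor $\eta = \alpha + X\beta + y_1\gamma + u_j + \varepsilon$ on
the total-score scale and places the patient's latent item mean at
$F^{-1}(\eta)$, so that $E[\text{total}\mid\eta] = \eta$ *exactly* (up to
clipping of $\eta$ into $(0.1, 47.9)$). The analysis model therefore holds
by construction and generative parameters are recoverable oracles for the
estimators. Two consequences:

* The default configuration (post-operative mean 38, SD 9.5) has ~17% of
  totals at the ceiling of 48, like the real survey; near the ceiling the
  clipping induces the realistic compression of effects, so recovery tests
  use a "midrange" configuration (mean 28) where linearity is essentially
  exact.
* The default item cut-points (`ohs_thresholds()`) are staggered across
  items so the 48 cut-points spread evenly over the latent range, which is
  what makes $F$ near-linear — the classical behaviour of a sum score with
  heterogeneous item difficulties.

Defaults mirror the published descriptive statistics of the 2011–12
hip-replacement cohort: covariate category probabilities; pre-operative
total 17.5 (SD ~8.4); post-operative 38 (SD ~9.5); provider volumes
negative-binomial with mean 200 at desk scale (the real survey's 298
providers with mean 241 is a configuration, not a requirement); length of
stay log-normal (mean ~6 days) loaded on comorbidity and *negatively* on
the post-operative residual (complications lengthen stay and depress
recovery — this is what makes length of stay a useful auxiliary); waiting
time gamma (mean ~88 days); questionnaire-context flags Bernoulli at the
published rates.

Missingness: the Q2 indicator follows
$\mathrm{logit}\,P(R_2{=}1) = \eta_0 + W\eta_1 + Z\eta_2 + \phi_j +
\delta\,(y_2 - c)$ with a provider random intercept $\phi_j$ and $\delta$
the log-odds of response per score unit ($\delta = 0$ is MAR). The model is
printed in the source material as linear with an error term but interpreted
through the logit link (its $\delta = 0.3 \Rightarrow$ odds ratio
$e^{0.3} = 1.35$ statement requires that), so it is implemented as logistic
regression with no residual. The centring constant $c$ only
reparameterises $\eta_0$ so the marginal response rate stays put as
$\delta$ moves. Q1 has its own logistic model with provider-level
predictors and no outcome term by default, and Q2 is only sent to Q1
responders, so $R_1 = 0$ forces $R_2 = 0$. Covariates (ethnicity, symptom
duration) go missing MCAR at 11% and 39%; per-item non-response is
available but off by default (no mechanism for it is documented). Default
intercepts are calibrated so ~62% return Q1 and ~53% both.

What the generator does *not* emulate: linkage failures as a separate
mechanism (folded into Q1 missingness), multi-year cohorts, item-level
differential functioning, and any real-data quirks beyond the published
marginals. Tests passing on these cohorts show the pipeline is correct
under its assumed data-generating process, not that the assumptions hold in
any particular real survey.

## The imputation model

One multivariate latent-normal model per missingness pattern
(`impute_spec()`):

* **Q1 pattern** (fitted on all patients): responses are the 12
  pre-operative items plus the incomplete covariates, ethnicity (binary
  probit) and symptom duration (3-category ordered probit); predictors are
  the complete case-mix covariates, log length of stay, log waiting time,
  and the provider-level private/teaching/volume auxiliaries.
* **Q2 pattern** (fitted on Q1 responders): responses are the 12
  post-operative items; predictors are the completed covariates, the
  completed pre-operative total, and the patient-level auxiliaries
  (length of stay, waiting time, previous surgery, pre-admission flag,
  assistance flag, lives-alone flag).

The latent model is $Z_{ij} = B x_{ij} + u_j + e_{ij}$ with level-1
residual $\Omega_e$ of unit diagonal and a single compound-symmetry
correlation $\rho$ (a full unstructured $\Omega_e$ is out of scope), and
thresholds per component with the first cut-point fixed at 0 for
identification (free intercepts live in $B$).

**Level-2 structure.** The conventional simplification fixes the
cross-item level-2 correlation at zero, i.e. $\Omega_u$ diagonal. We found
— by computing the exact marginal likelihood with $u$ integrated out on
model-generated data — that a diagonal $\Omega_u$ cannot express a provider
effect *shared across items*, which is exactly what the analysis model's
$u_j$ is: raising the independent per-item variances to absorb a shared
shift overdisperses the eleven item-contrast directions, so the likelihood
prefers $\tau_k \approx 0$ and imputation silently erases provider
contrasts (and with them the funnel signal). `promperf` therefore uses a
compound-symmetry $\Omega_u$: $u^k_j = v_j + w^k_j$ with a common provider
factor $v_j \sim N(0, \tau_c^2)$ and item-specific effects
$w^k_j \sim N(0, \tau_k^2)$. With effects that genuinely are item-specific
this reduces to the diagonal model ($\tau_c \to 0$); with shared effects it
recovers them.

**Sampler.** `fit_and_impute()` runs a Metropolis-within-Gibbs cycle
(compiled, RcppArmadillo): truncated-normal draws of each latent value
given its observed category (unconstrained for missing cells); a
matrix-normal conjugate draw of $B$; per-provider conjugate draws of
$w_j$ and $v_j$; inverse-gamma draws of $\tau_k^2$ and $\tau_c^2$
(IG(0.001, 0.001) priors); Cowles-type Metropolis cut-point updates using
the conditional category probabilities given the other components, with an
immediate redraw of the component's latent values on acceptance; and
random-walk Metropolis on $\rho$ (uniform prior on its positive-definite
range). $B$ and the thresholds carry flat priors. Proposal scales adapt
towards ~30% acceptance during burn-in only, so the sampling phase is a
fixed-kernel chain. Providers with no observed patients in a pattern draw
their effects from the prior.

Two further robustness devices, both motivated by the well-known funnel
pathology of centred hierarchical parameterisations: the chain is
initialised at empirical values (latent interval midpoints, OLS $B$,
method-of-moments $u$ and $\tau$), and each iteration proposes a joint
rescaling $u \to s u$, $\tau \to s\tau$ (a generalised-Gibbs scaling move
with the appropriate Jacobian), which lets the chain cross between the
$\tau \approx 0$ and $\tau > 0$ regions that plain Gibbs transitions
between only astronomically slowly.

**Chaining.** Every emitted dataset completes the Q1 responses and
covariates; the Q2 model is then re-fitted per completed dataset (its
predictors differ across completions) as an independent short chain, and
patients whose Q1 was itself imputed receive post-operative items from the
posterior-predictive draw at the emitted parameter state. This makes every
patient complete, which the full-volume MI funnel requires. When stage 1
has nothing to impute, the Q2 model runs as a single thinned chain.
Production-scale settings are M = 100 imputations from 10,000 post-burn-in
iterations thinned every 100th with 1,000 burn-in (burn-in is a declared
default; the source material does not state one). The test suite and the
analysis scripts run M = 10–20 with burn-in 100–200 and thinning 10–20 on
cohorts of 20–50 providers × 100–200 patients — a test-surface choice that
keeps a full run in minutes on one core without changing semantics; the
emitted-state drift heuristic (`check_mixing`) warns if halves of the
emission sequence disagree.

**Invariants.** Observed cells are never altered (the completed matrix
starts from the observed data and only missing cells are filled); imputed
categories are always in range; the whole imputation set is reproducible
from its seed.

## Pooling, the funnel, and the tariff rule

Per completed dataset the analysis model is fitted and providers
standardised; per provider the M estimates are combined by Rubin's rules
(`pool_rubin()`): mean estimate, within variance $V_W$, between variance
$V_B$ (M−1 denominator), total $V_W + (1+1/M)V_B$, with Rubin degrees of
freedom for interval construction. The national mean and $\sigma_{pop}$ are
pooled as means across imputations.

Funnel limits are $\bar y_2 \pm z\,\sigma_{pop}/\sqrt{n}$ at 95%
($z = 1.959964$) and 99.8% ($z = 3.090232$). The profiling convention
"2 and 3 standard deviations" is read as the nominal quantiles; literal
multipliers 2 and 3 are available via `exact_multipliers = TRUE`. No
over-dispersion adjustment is applied. A point exactly on a limit is
inside it (classification uses strict inequalities), and an alarm
supersedes an alert. Under complete-case analysis providers sit at their
complete-case volumes; under MI at their full eligible volumes — the
"volume effect" that narrows the limits around previously shielded
providers. BPT eligibility requires no negative alarm *and* a collection
rate above 50%, where the rate is the share of eligible patients with both
questionnaires fully observed (the denominator is a declared choice; the
rule's source does not pin it down).

## MNAR sensitivity by re-weighting

Under the selection model above with $\delta \ne 0$, the MAR imputations
can be re-weighted rather than re-drawn: imputation $m$ receives
$\tilde w_m = \exp(-\delta S_m)$ with $S_m$ the sum of its imputed
post-operative totals over the missing-outcome patients (pre-operative
imputations never enter), normalised to $w_m$. The sums are in the
thousands, so weights are computed in log space after subtracting the
maximum — a mandatory stabilisation, not an optimisation. For
$\delta > 0$ (better outcomes respond more) the imputations with smaller
imputed totals are up-weighted.

Weighted pooling follows the printed rules exactly: estimate
$\sum w_m \theta_m$, within $\sum w_m \hat\sigma_m^2$, between
$\sum w_m(\theta_m - \hat\theta)^2$, total $V_W + (1+1/M)V_B$. Note the
weighted between variance uses a $1/M$-style denominator, so at
$\delta = 0$ it is a factor $(M-1)/M$ smaller than the classical Rubin
between variance while the pooled estimate coincides exactly; this
discrepancy is implemented as printed, surfaced in the tests, and not
"fixed". Weights are global (shared by all providers), computed once per
$\delta$. `delta_sweep()` re-pools, rebuilds the limits from the weighted
national mean and $\sigma_{pop}$, reclassifies, and reports the effective
sample size $1/\sum w_m^2$ per $\delta$; values near 1 (routine at
$|\delta| \ge 0.3$ with desk-scale M) mean the sweep is effectively
selecting a single imputation and its rows should be read qualitatively.

## Degenerate inputs and numerical choices

Collinear analysis-model designs abort with the offending columns named;
constant imputation-model auxiliaries (e.g. no teaching hospital in a
small cohort) are dropped silently as uninformative. Threshold updates
reject order-violating proposals. Truncated-normal draws fall back to the
nearest boundary when the interval mass underflows. $\hat y_2 \le 0$
aborts standardisation (cannot occur on realistic score scales). A
provider with a single patient gets an undefined (NA) within-dataset SE
but still a point estimate and classification.

## Known limitations

* The delta-method SE and the pooled $\sigma_{pop}$ are plug-in choices;
  a fully Bayesian or bootstrap funnel would propagate more uncertainty.
* The imputation model is compatible with, not identical to, the
  generator (the exact inverse-curve mean map is mildly non-linear), so MI
  coverage is approximately, not exactly, nominal — the acceptance band
  (90–98% for a nominal 95% interval) reflects that.
* Weighted sensitivity analysis with desk-scale M degenerates quickly in
  $|\delta|$; production use should raise M before trusting
  $|\delta| > 0.2$ rows.
* Only compound-symmetry structures are offered at both levels; full
  unstructured covariances are a configurable extension point, not
  implemented.
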