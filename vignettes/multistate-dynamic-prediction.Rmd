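---
title: "Multi-state event-history analysis with deterministic clock transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state event-history analysis with deterministic clock transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmclock)
```

## The model

`msmclock` implements clock-forward Markov multi-state analysis for cohorts
whose treatment schedule forces some state changes at fixed times on the
study clock. The motivating setting is adjuvant chemotherapy (CTx) after
surgery for locally advanced rectal cancer: the disease course is described
by eight states — (1) on CTx for less than 6 months, (2) on CTx between 6
and 12 months, (3) CTx completed, (4) early discontinuation (before 6
months), (5) late discontinuation (6–12 months), (6) local recurrence (LR)
only, (7) distant metastasis (DM) only or both DM and LR, and (8) death,
the absorbing state. All times are in months since the start of CTx
(clock-forward: a single time origin for every transition), with 6 weeks
= 1.5 months and 5 years = 60 months.

Two transitions are *deterministic*: every subject still in state 1 at 6.0
months moves to state 2 at that moment, and every subject still in state 2
at 12.0 months moves to state 3. These transitions carry no hazard — their
purpose is to split the on-treatment period so that covariate effects may
differ before 6 months, between 6 and 12 months, and after completion,
while the model remains Markov. The two discontinuation states exist for
the same reason. The Markov assumption — prognosis depends only on the
state currently occupied, not on the route or the sojourn time — is what
makes the product-integral estimator below valid; it is an assumption, not
a tested property.

Each stochastic transition `q` (arrow `j -> k`) has its own Cox
proportional-hazards model on the study clock,

    alpha_q(t | Z) = alpha_q0(t) * exp(beta_q' Z),

fitted on its own rows of the stacked long-format data (separate baselines,
no shared strata, no cross-transition constraints). Covariates are age (per
10 years, so the hazard ratio is per decade), BMI (per kg/m²), sex
(reference male), UICC stage (reference II), tumor grade (reference 1+2),
CTx arm (reference 5-FU alone) and operation type (reference
abdominoperineal amputation).

## Data preparation

`to_long_format()` converts one row per patient into the stacked
counting-process form: for every at-risk episode, one row per allowed
stochastic transition out of the occupied state, with `status = 1` only on
the realized arrow. Three conventions of the source data are applied by
`derive_state_path()`:

* **Midpoint imputation.** Discontinuation of CTx is reported only as one
  of five periods (0–6 weeks, 6 weeks–3, 3–6, 6–9, 9–12 months);
  `midpoint_impute()` places the event at the period midpoint (0.75, 2.25,
  4.5, 7.5, 10.5 months). Likelihood-based interval-censoring methods are
  deliberately out of scope: midpoint imputation keeps the analysis in the
  standard semi-parametric framework.
* **Direct-transition rule.** When discontinuation is *caused by* LR or DM,
  the subject moves straight from the on-treatment state to state 6 or 7;
  the discontinuation states are never visited. This avoids manufacturing a
  spurious association between discontinuation and the adverse event.
* **Second-event-only recording.** For subjects known to have had both LR
  and DM but with only the later date recorded, the path enters state 7 at
  that recorded time and state 6 is skipped. The unobserved first event is
  ignored; since state 7 already means "DM or both", the approximation only
  affects the timing of entry for these subjects.

Boundary and degenerate cases are resolved as follows, since the
conventions above do not pin them down:

* An event at exactly a deterministic time (6.0 or 12.0) is attributed to
  the *pre-jump* state; the forced jump applies only to subjects without an
  event at that instant.
* A midpoint-imputed discontinuation that lands after a recorded event
  (LR, DM, death) or after censoring is dropped: once the subject has left
  the on-treatment states, the discontinuation states are unreachable, and
  an imputed time cannot override a recorded one.
* Deaths on treatment without any other event are routed 1 -> 8 (before 6
  months) or 2 -> 8 (between 6 and 12 months).
* Zero-length episodes (two events at the same instant) contribute no
  at-risk rows.

## Estimation

Each transition with **more than 20 events** is fitted by
`survival::coxph()` with the Breslow approximation for ties
(Newton–Raphson with step-halving, relative log-likelihood tolerance 1e-9,
at most 50 iterations). Transitions at or below the gate keep a
nonparametric Nelson–Aalen cumulative hazard (increments `d_j / n_j`) and
no covariate effects: with so few events a 10-parameter model is
meaningless. Breslow tie handling (rather than Efron) is chosen for
consistency with the Breslow baseline used in prediction; with
continuous-scale times, ties are rare and the choice is immaterial.

Inference is Wald: `HR = exp(beta)`, 95% CI `exp(beta ± 1.96 se)`,
two-sided normal p-values, no multiplicity adjustment (the per-transition
tests are exploratory). The baseline cumulative hazard is the Breslow
estimator at the zero covariate vector, `dA_q0(t_j) = d_j / sum(exp(beta_q'
Z_i))` over the risk set. Monotone partial likelihoods (a binary covariate
whose events all fall in one group, so the MLE diverges) are detected and
flagged on the fit object rather than raising an error; flagged fits should
not be interpreted.

## Prediction

`aalen_johansen()` builds the matrix of transition probabilities `P(s, t |
Z)` as a finite product over the grid of hazard jump times: at each time
`u` the factor is `I + dA(u | Z)`, where the off-diagonal `(j, k)` entry is
the covariate-scaled increment of arrow `j -> k` and the diagonal is minus
the row sum. At each deterministic time, the factor is post-multiplied by
the forced jump matrix moving all remaining occupancy of the rule's source
state to its target (increments at exactly the rule time act first,
matching the episode convention above). Deterministic transitions as forced
jumps — not estimated hazards — avoid infinite-intensity artifacts. Rows of
every factor sum to one by construction, so `P(s, t)` is row-stochastic
without renormalization, and the Chapman–Kolmogorov identity `P(s, u) =
P(s, t) P(t, u)` holds exactly on shared grids.

If a single scaled increment exceeds one, a diagonal entry of `I + dA`
would be negative and the product is no longer a probability matrix; the
estimator stops with an error naming the offending time. This happens when
a transition is fitted on barely more than 20 events and the covariate
profile of interest is extreme relative to the late, small risk sets — an
overfitting artifact, not a numerical bug. It is rare at a few thousand
subjects and the error message is the honest response; refitting on a
larger cohort (or a less extreme profile) is the remedy.

`fixed_horizon_survival()` gives the dynamic prediction: for a fixed
horizon `T` on the study clock (default 60 months after the start of CTx —
*not* a sliding `s + 60` window) and an observed history, the probability
of being alive at `T` given the state occupied at prediction time `s` is `1
- P[k(s), 8](s, T | Z)`. Counterfactual curves ("what if the DM had not
occurred") are obtained by supplying the alternative history. Standard
errors of predicted probabilities are bootstrap-only
(`bootstrap_se()`: patient-level resampling, full refit per replicate,
reproducible under a seed); analytic Aalen-type variance formulas are out
of scope.

Reference profiles ship as printed in the motivating analysis:
`reference_patient("high_risk")` (UICC IIIc, grade 3+4, 5-FU alone) and
`reference_patient("low_risk")` (UICC II, grade 1+2, 5-FU + folinic acid),
both male, 61 years, BMI 25, anterior resection.

## The synthetic-cohort generator

Because the original trial data are private, `simulate_cohort()` generates
cohorts with known parameters as the test bed. It emulates:

* the published covariate marginals (65.4% male; UICC II/IIIa/IIIb/IIIc at
  34.0/10.2/28.5/27.4%, normalised; grade 3+4 25.9%; arms 35.2/37.2/27.6%;
  anterior resection 65.4%; age and BMI from truncated normals centred at
  the published medians and spanning the published ranges);
* clock-forward Markov dynamics: competing exponential (optionally
  Weibull) clocks on all outgoing arrows, subject rate `baseline *
  exp(beta' Z)`, deterministic rules firing when no stochastic event
  precedes them;
* the data limitations: exact discontinuation times coarsened to the five
  reporting periods, and only the later event time kept (with a flag) when
  both LR and DM occur;
* censoring: administrative at 72 months plus exponential dropout at
  0.008/month, chosen once so that roughly 56% of subjects are censored,
  as in the published cohort.

Covariates are sampled independently — only marginals were published — so
the generator cannot reproduce confounding between, say, stage and
operation type. Baseline hazards are exponential by default; real
recurrence hazards are typically non-monotone. Censoring is
non-informative by construction. Passing tests therefore certify the
estimation and prediction *machinery* under a Markov data-generating
process with the trial's structure, not the clinical estimates themselves,
which would require the original data.

The shipped study-like configuration (`fogt2_sim_config()`) uses baseline
rates chosen once to give an event flow of similar shape to the published
one (about half the cohort with recurrence, eight covariate-modelled
transitions at n = 471); its true log hazard ratios echo the published
significant effects qualitatively (elevated UICC IIIc hazard of entering
state 7 from states 3, 4 and 5; protective anterior resection after late
discontinuation; elevated female mortality after LR), all with |log HR| <=
1.1, without claiming the printed values.

## Problem sizes and numerical choices

* The parameter-recovery experiment in the test suite runs 50 replicates of
  n = 1500 under a data-generating process designed so that eight
  transitions carry several hundred events each while all others stay far
  below the gate; this gives the bias and coverage checks adequate Monte
  Carlo precision (coefficient noise would dominate a bias bound of 0.05 at
  20–40 events per transition).
* Profile-specific prediction demonstrations are fitted on cohorts of
  1500–3000 subjects: at the published cohort size of 471, transitions just
  above the 20-event gate are fitted with 10 covariates and their
  coefficient noise occasionally produces scaled hazard increments above
  one for the extreme reference profiles (see the error contract above).
* Convergence: `coxph.control(eps = 1e-9, iter.max = 50)`. Row-stochasticity
  is asserted to 1e-10 and Chapman–Kolmogorov to 1e-12 in the tests; these
  are numerical, not statistical, tolerances.
* Rank-deficient designs (constant or collinear covariates on a
  transition's rows) raise an error rather than silently dropping terms.

## Limitations

* The Markov assumption is structural; sojourn-time effects beyond the
  state-splitting device are not representable.
* Midpoint imputation biases entry times into the discontinuation states;
  the test suite bounds the induced log-HR bias (< 0.1 under the recovery
  process) but the bias does not vanish.
* No landmark comparison, no non-Markov estimators, no analytic standard
  errors for transition probabilities.
* The generator's independence and exponential-baseline simplifications
  mean agreement with it does not certify behaviour under real-world
  covariate correlation or non-constant hazards.
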