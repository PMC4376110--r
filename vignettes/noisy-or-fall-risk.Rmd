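---
title: "A noisy-OR fall-risk model built from literature odds ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A noisy-OR fall-risk model built from literature odds ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallrisk)
```

## The problem

About a third of community-dwelling adults aged 65 and over fall at least
once a year. Decades of epidemiological work have produced meta-analytic
odds ratios for dozens of fall-risk factors — history of falls, gait
problems, sedative use, and so on — but an odds ratio is not a risk: a
clinician screening a patient wants *"what is this person's probability of
falling in the next year"*, computed from whatever subset of the risk
factors happens to be known. `fallrisk` turns a table of literature odds
ratios and prevalences into exactly that kind of calculator, without any
model fitting on patient data.

## The model

Let $E_1, \dots, E_n$ be binary exposure indicators and let each factor $i$
have a latent *factor-specific fall event* $d_i$ that can only fire when the
subject is exposed, with

$$P(d_i = 1 \mid E_i = 1) = C_i, \qquad P(d_i = 1 \mid E_i = 0) = 0.$$

A distinguished always-present cause $E_0$ with contribution $C_0$ carries
the baseline risk that applies to everyone. The fall event $d$ is the union
of the $d_i$, and the $d_i$ are conditionally independent given the
exposures (a *noisy-OR* / causal-independence structure), so

$$P(d \mid E) \;=\; 1 - (1 - C_0)\prod_{i : E_i = 1} (1 - C_i).$$

### From odds ratios to contributions

The literature reports odds ratios, not contributions. Two assumptions make
the translation unique:

* **(a)** the population odds ratio for factor $i$ is approximated by the
  odds ratio computed on subjects with at most one exposure. For such a
  subject the fall probability is $c_0$ if unexposed and
  $1 - (1 - c_0)(1 - C_i)$ if exposed to factor $i$ alone; equating the
  odds ratio of these two probabilities to the literature $OR_i$ and
  solving gives
  $$C_i = \frac{c_0\,(OR_i - 1)}{1 + c_0\,(OR_i - 1)}.$$
  `contribution_from_or()` implements this; `or_from_contribution()` is its
  exact inverse and the test suite verifies the round-trip to $10^{-12}$
  over $OR \in [1, 100]$, $c_0 \in [0.01, 0.99]$ rather than trusting the
  symbolic form.
* **(b)** $C_0$ is not free: it is solved (by bisection, see below) so that
  the model's expected incidence over a population with independent
  exposures at the stated prevalences equals the reported annual faller
  proportion, 31% by default.

The transform is only defined for $OR \ge 1$: an odds ratio below 1 would
require a negative contribution, which the union-of-events structure cannot
express. Protective factors are therefore rejected at load time (an
explicit `clamp_protective` option maps them to $OR = 1$ with a warning).

### Unknown exposures

Screening data are incomplete by design. When factor $i$'s state is
unknown, the engine replaces its survival multiplier by the
prevalence-weighted expectation $1 - p_i C_i$ — exactly the marginal the
distribution semantics of the generated logic program assigns. The identity
$$P(d \mid E_i = ?) \;=\; p_i\,P(d \mid E_i = 1) + (1 - p_i)\,P(d \mid E_i = 0)$$
holds to machine precision for every factor and is asserted in the tests.

### Scalar and synergy factors

A **scalar** factor with levels $0..m$ behaves like $m$ nested dichotomous
factors: at level $L$ the multipliers $(1 - C_{i,k})$ for all $k \le L$
apply. Meta-analyses usually report a single per-increment odds ratio, so a
scalar factor given one value replicates it across levels; a full
per-level vector is accepted too. An unknown level is marginalized over the
factor's level distribution. The mapping from a raw measurement (age in
years, medication count) to a level is deliberately configuration — an
affine-clamp table in the knowledge base — never hard-coded.

A **synergy** factor over $S$ dichotomous members models the documented
extra risk of co-occurring conditions without breaking causal independence:
with $q$ members present it acts as a scalar factor at level
$\max(q - 1, 0)$, so the penalty starts at the second co-occurring member.

When some members of a synergy set are themselves unknown, the member
count $q$ is random, and the same latent exposure drives both the member's
own risk rule and the synergy level. The engine therefore computes the
*joint* expectation over the $2^u$ exposure patterns of the $u$ unknown
members — not the product of the members' marginal multipliers with the
marginal synergy multiplier, which would be cheaper but wrong under the
program semantics (and would break the marginalization identity above for
synergy members). Synergy sets are small (the packaged comorbidity set has
4 members), so the enumeration is negligible.

### Calibration

`calibrate_c0()` solves `expected_incidence(c0) = target` by bisection on
$(10^{-12}, 1 - 10^{-12})$ with a $10^{-9}$ tolerance on the incidence
residual and a 200-iteration cap. Every contribution is increasing in
$c_0$, so the expected incidence is strictly increasing and the bracket
always converges; the defaults are numerical choices of this package. The
expected incidence itself is closed-form: it equals the risk of the
all-unknown profile, because averaging over independent exposures and
marginalizing unknowns are the same operation. The target defaults to an
annual faller proportion of 0.31; the knowledge base can instead pin
`baseline_c0` directly, which skips calibration (useful for fixtures and
for sensitivity analyses). Note the calibration target is interpreted as
the proportion of people with *at least one* fall, not a fall count — the
model's endpoint is the dichotomous "fell at least once in the span".

## The LPAD export

`generate_lpad()` compiles a model into a Logic Program with Annotated
Disjunctions in cplint-style syntax. The dichotomous template is

```
fall(X) : c0.
e_f(X) : p_f :- u_f(X).
fall(X) : C_f :- e_f(X).
```

where `u_f(X)` asserts that factor f's exposure is undetermined; under the
distribution semantics the probability of `fall(X)` then reproduces the
closed form exactly. Two encodings are this package's own design, since
only the dichotomous template is standard:

* scalar levels use nested atoms `e_f_ge1(X), e_f_ge2(X), ...` with a
  chained conditional-prevalence rule per level
  (`e_f_gek(X) : P(L>=k)/P(L>=k-1) :- e_f_ge(k-1)(X), u_f(X).`), which
  reproduces the full level distribution for an unknown scalar;
* synergy level atoms are derived deterministically (annotation 1) from
  every size-$(l{+}1)$ subset of member exposure atoms, so the coupling
  between unknown members and the synergy level is automatic.

Annotations are rendered with 12 significant digits and the rule list
stores the same rounded values, making `parse_lpad()` an exact inverse and
generation byte-stable. Rules whose annotation would be exactly 0 (odds
ratio 1, prevalence 0) are omitted — they can never affect the query.
The program is an artifact for interoperability and inspection; risk
computation never samples or enumerates it. The equivalence is instead
*tested*: for dozens of randomly generated small models the suite
enumerates every outcome combination of the probabilistic rules, forward
chains each world, and checks the summed world probabilities against the
closed form to $10^{-9}$ for every exposure pattern, unknowns included.

## The cohort simulator

`simulate_cohort()` generates data with precisely the structure the model
assumes: independent exposures at the knowledge-base prevalences, outcomes
drawn by sampling the latent factor-specific events and taking their union
(the generative definition of the fall event, not the closed-form
shortcut), and optional missingness injected completely at random per
factor — mirroring screening data where missingness ranges from 0% (sex,
age) to roughly 17% (vision impairment) per variable. Everything is
seed-deterministic, and the seed is recorded in the cohort's CSV sidecar.

What the simulator does *not* emulate: correlated exposures, repeated
waves per subject, informative missingness, secular trends. Tests passing
on simulated cohorts therefore demonstrate internal consistency of the
pipeline — the model recovering its own inputs — not external validity on
real populations, where exposure correlation and weaker factor-outcome
links compress discrimination well below the simulated AUC.

## The validation battery

`validate_predictions()` bundles the discrimination and calibration
metrics: the tie-aware ROC curve with Mann–Whitney AUC, a DeLong
closed-form AUC confidence interval (stratified or cluster bootstrap as an
alternative), the Brier score, the Hosmer–Lemeshow chi-square, and the
decile calibration table with Wilson intervals.

Two conventions deserve a note:

* **Hosmer–Lemeshow degrees of freedom.** The classical $g - 2$ applies to
  a model fitted on the evaluation data. This engine fits nothing, so under
  the null of perfect calibration the statistic is (slightly conservatively)
  chi-square with $g$ degrees of freedom; with $g - 2$ the test rejects a
  well-calibrated unfitted model roughly 11% of the time at the 5% level.
  Both are available (`hl_df = "g-2"` remains the reporting default for
  comparability with standard usage); the suite's type-I-error check runs
  at `df = "g"`, where the empirical rejection rate on 500 model-generated
  cohorts of n = 2319 sits inside 5% ± 2%, and its power check shows
  rejection at $p < 0.001$ in at least 95% of replicates when risks are
  inflated by a factor 1.3 — the signature of consistent overestimation.
* **Binning.** Quantile bins with ties kept in the lower bin; tied
  prediction values can collapse bins, which is reported by a warning and a
  reduced effective group count rather than silently re-split.

## Packaged knowledge base

`default_knowledge_base()` ships the 27-factor community-dwelling ontology
(24 dichotomous, age and number of medications as scalars, comorbidity as
a synergy over four chronic diseases). The odds-ratio and prevalence
*values* in the packaged file are editable placeholders in realistic
ranges, flagged by `metadata.values_status: placeholder` in the YAML:
transcribe values from a quantitative meta-analytic source before any
substantive use. The factor list, kinds, and all structural invariants are
exact and tested.

## Numerical and testing choices

* Deterministic everywhere: identical inputs give bit-identical outputs;
  all sampling takes an explicit seed and restores the caller's RNG state.
* Closed-form risks use plain products of survival multipliers; no
  log-space tricks are needed because contributions are bounded away
  from 1 by $OR \le 100$-scale inputs.
* Random-model sweeps use up to 6 factors, scalars capped at 2 levels and
  synergies at 3 members, keeping the brute-force world enumeration (at
  most $2^{20}$ worlds, usually far fewer) exact and fast; Monte-Carlo
  cross-checks use $10^6$ draws against a 3-standard-error band, cohort
  statistics use n in the $10^4$–$10^5$ range, and the calibration-test
  size/power simulations use 500 replicates of n = 2319.
* Bin, bisection, precision and df defaults are stated above; none come
  from the underlying literature, and each is overridable at the API.

## Limitations

The model inherits the independence assumptions of its derivation:
exposures independent in the population, factor-specific fall events
conditionally independent, and odds ratios approximated on the
at-most-one-exposure stratum. Synergy factors relax interaction only in
the specific co-occurrence-count form. Confidence intervals on the risk
estimate itself (propagating odds-ratio uncertainty) are out of scope, as
is any learning of contributions from cohort data.
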