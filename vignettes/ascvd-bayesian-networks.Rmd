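---
title: "Modelling ASCVD risk factors with discrete Bayesian networks"
author: "ascvdbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ASCVD risk factors with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Atherosclerotic cardiovascular disease (ASCVD) develops through an
interdependent web of demographic, metabolic and lipid risk factors:
age and sex shape smoking habits, adiposity and blood pressure; adiposity
drives glucose, triglycerides and HDL-C; lipid fractions track one another;
and all of these feed the outcome. A discrete Bayesian network (BN) makes
that web explicit: each variable is a node with a conditional probability
table (CPT) given its parents in a directed acyclic graph (DAG), the joint
distribution factorizes over the graph, and any conditional probability —
"what is the risk of ASCVD for an over-45 smoker with high LDL-C?" — is an
exact inference, not a regression extrapolation.

`ascvdbn` implements this workflow end to end for a cross-sectional cohort
of 491 health-care workers (38 ASCVD cases, prevalence 7.7%): clinical
discretization, baseline descriptive epidemiology, a literature-derived
network structure, score-based structure search, exact inference,
information-criterion and cross-validated model comparison, and a
calibrated synthetic-cohort generator so that the entire pipeline is
reproducible without access to the original (non-deposited) data.

## Data model and discretization

The cohort table has 13 variables: `age`, `sex`, `smoking`, `diabetes`,
`hypertension`, `mets` (metabolic syndrome, ATP-III definition), `ascvd`,
`bmi`, `fbs`, `tg`, `tc`, `hdl`, `ldl`. Continuous measurements are mapped
to guideline categories on load:

| variable | unit  | categories |
|----------|-------|------------|
| age      | years | under45 (< 45), over45 (>= 45) |
| bmi      | kg/m2 | normal (< 25), overweight (25 to < 30), obesity (>= 30) |
| fbs      | mg/dL | normal (< 100), high (>= 100) |
| tg       | mg/dL | normal (< 150), high (>= 150) |
| tc       | mg/dL | normal (< 200), high (>= 200) |
| hdl      | mg/dL | low (< 45), normal (45–55), high (> 55) |
| ldl      | mg/dL | normal (< 130), high (>= 130) |

Three boundary decisions deserve a note, because the guideline bands they
come from do not quite partition the line:

* **LDL-C.** Guidelines name "normal < 130" and "high >= 160", leaving
  [130, 160) unnamed; yet the cohort's two LDL-C categories cover every
  participant. The package places the single boundary at 130 mg/dL
  (configurable via `cohort_schema(ldl_boundary =)`); `strict = TRUE`
  instead raises an error inside the unnamed band.
* **BMI below 18.5.** The cohort uses three BMI classes and reports no
  underweight category. Values below 18.5 kg/m2 map to "normal" with a
  warning (error under `strict = TRUE`).
* **Age 45.** "Over 45" includes age exactly 45 (`age >= 45`), the usual
  epidemiological convention for a 45-year cut.

Missing values are rejected rather than imputed: the analysis is
restricted to completers, matching the source study's 491/500 design.

## Descriptive epidemiology

`table1_report()` reproduces a baseline-characteristics table: per-state
counts and percents by outcome status, a two-sided Fisher exact test per
variable (`stats::fisher.test`; r x 2 tables use its exact network
algorithm), and per-state risk differences against the variable's
reference state. Risk-difference intervals default to Newcombe's
hybrid-score method — square-and-add of Wilson limits — because the cohort
contains a zero cell (no female cases) where a Wald interval collapses;
Wald is available for comparison. Prevalence comes with the exact
Clopper–Pearson interval (`qbeta` closed form). From the published
contingency counts these functions reproduce the study's printed
prevalence (7.7%, 95% CI 5.5–10.5) and all printed risk differences to
one decimal.

One arithmetic caveat is inherited from the source: the published
per-state non-case counts do not sum exactly to the reported group totals.
The package computes risk differences from the per-state counts (as the
study's own results evidently did) and prevalence from the reported totals
(`reference_cohort_size()`), and documents the inconsistency rather than
resolving it.

## The knowledge-based network

`knowledge_dag()` returns the 13-node, 39-arc structure assembled from the
cardiovascular literature: `age` and `sex` are roots; the outcome has nine
parents (age, BMI, T-C, diabetes, FBS, HDL-C, hypertension, LDL-C,
smoking) and no children; metabolic syndrome is a sink determined by its
component factors (BMI, FBS, TG). `is_dseparated()` answers conditional-
independence queries on any DAG via separation in the moralized ancestral
graph (an equivalent formulation of the path-blocking criterion; the test
suite re-verifies it against an independent path-enumeration oracle).

One structural subtlety: conditioning on HDL-C alone does *not* separate
TG from the outcome, because the arc set also routes TG through diabetes
(TG -> diabetes -> ASCVD). Narrative summaries of such networks sometimes
quote the single-path independence; the graph itself is the authority
here, and the d-separation engine reflects it.

## Parametric learning

`fit_bayes_net(structure, data, alpha)` estimates every CPT cell as
(count + alpha) / (config total + alpha * states): maximum likelihood at
`alpha = 0`, Laplace smoothing at the default `alpha = 1`. Parent
configurations never observed get the uniform distribution, with a
message. This fallback is not a corner case: the outcome family has
1,152 parent configurations against ~491 records, so prediction-oriented
fits should always smooth. Fitted objects are standard R models — `print`,
`summary`, `coef`, `logLik`, `AIC`/`BIC`, `predict` (exact posteriors for
new records) and `simulate` (ancestral sampling) all work.

Information criteria follow the "smaller is better" convention,
AIC = -2 log L + 2k and BIC = -2 log L + k log n, with k the free-parameter
count summed over families, computed from maximum-likelihood fits. A
consequence worth stating explicitly: with a 9-parent outcome, k includes
1,151 outcome-family parameters, so at a few thousand records BIC can
prefer the *empty* graph over the true generating structure — the
information in the data cannot outweigh the penalty until roughly
n = 10,000 for this generator (the test suite demonstrates consistency at
n = 20,000). Comparisons between *structures of similar size* (the
knowledge network versus a searched network) are meaningful at cohort
scale; absolute criterion values are not transportable across data sets.

## Structure search

`bayesian_search()` is greedy hill climbing over add/delete/reverse arc
moves on the BDeu score (Bayesian Dirichlet equivalent uniform), with
random restarts. Defaults: equivalent sample size 1, at most 8 parents,
20 restarts (the first from the empty graph, the rest from random DAGs),
deterministic given the seed. Scores are decomposable, so each move
re-scores only the affected family, and family scores are cached across
restarts. On three-node problems the search provably attains the
exhaustive 25-DAG optimum, and with 20,000 records it orients a
strong-effect collider's v-structure — the canonical identifiability
check, since the collider is the only member of its Markov-equivalence
class.

## Exact inference and reports

`bn_query()` computes posteriors by sum-product variable elimination with
a greedy min-degree elimination order. The order affects only running
time, never the answer; the suite checks both claims (agreement with
full-joint enumeration at 1e-10 on networks up to 6 nodes, and invariance
across random orders). Evidence with zero probability raises an error
rather than returning NaN.

`cp_report()` mirrors the study's conditional-probability table: each of
twelve variable pairs is instantiated to its adverse ("risk") state —
over-45, male, past-or-current smoking, "yes" for the binary conditions,
obesity, and the high lipid/glucose levels — and the exact outcome
posterior is reported as percentages. For HDL-C the adverse state is
**low**: low HDL-C carries the higher cardiovascular risk, and the
package follows the clinical direction rather than a mechanical
"highest level" rule.

`strength_of_influence()` quantifies each arc as the mean distance
between the child's conditional distributions across pairs of the
parent's states, averaged over the other parents' configurations —
Euclidean by default, Hellinger and total variation selectable. The
measure is zero exactly when the CPT ignores the parent, and is intended
for *ranking* arcs; its absolute values depend on the metric, so
cross-study numeric comparison is not meaningful.

## Cross-validated evaluation

`loocv_scores()` performs leave-one-out cross-validation with the
structure fixed and CPTs refitted per fold. Because every non-outcome
variable is observed, the held-out posterior factorizes over the families
containing the outcome, and each fold's refit reduces to subtracting the
held-out record's contribution from the full count tables — exactly
equivalent to refitting from scratch (the suite verifies this per fold)
and fast enough to run the full n = 491 cohort in milliseconds.

`roc_auc()` is the rank statistic (ties half-weighted), identical to the
trapezoidal area under the empirical ROC; `diagnostic_indices()` reports
the eight-index panel (AUC, accuracy, sensitivity, specificity, PPV, NPV,
LR+, LR-) at a stated threshold. The study does not report its
classification cut-off, and its printed sensitivity/specificity pair
implies a non-0.5 operating point, so the package makes the threshold
explicit and configurable: the sample prevalence (default — the natural
cut for a rare outcome), the Youden-optimal cut, or any fixed value.
Likelihood ratios are reported on the ratio scale
(LR+ = sens/(1-spec), LR- = (1-sens)/spec); some published tables print
them multiplied by 100.

## The synthetic-cohort generator

The original cohort data are available only on request, so the package
ships a fully specified generating network. Its structure is
`knowledge_dag()` plus one direct `sex -> ascvd` arc. The augmentation is
forced by a published fact: every ASCVD case in the cohort was male.
Under the knowledge DAG, sex reaches the outcome only through smoking,
diabetes, hypertension, HDL-C and TG, and the sex contrast those mediators
can carry (a log-odds gap of roughly 0.5 at the published mediator
prevalences) cannot reconcile a 7.7% overall prevalence with essentially
zero female risk; a direct effect can.

CPTs are built from logistic (multinomial-logit for BMI and HDL-C) parent
effects — round log-odds values encoding standard epidemiology: smoking
strongly male-dominated, age raising blood pressure/glucose/diabetes,
adiposity raising glucose/TG/metabolic syndrome and depressing HDL-C,
LDL-C tracking total cholesterol, and the outcome concentrated in over-45
males with adverse profiles. The intercepts are then *solved*, node by
node in topological order, so that every marginal matches the published
cohort margins exactly (to 1e-12, via exact inference on the partially
built network). Calibration is deterministic, takes ~60 ms, and is
memoized per session. Forward sampling at n = 100,000 lands every margin
within Monte Carlo error of its target, and the generated outcome
reproduces the published gradients: P(ASCVD | female) < 0.5%,
P(ASCVD | over-45) ≈ 19% versus ≈ 1.2% under 45.

`sample_cohort(..., continuous = TRUE)` back-fills raw measurements by
drawing from truncated normal distributions strictly inside each sampled
category's bin (age uses the cohort's reported mean 43.2, SD 7.2), so
discretization recovers the categories with zero mismatches. This
back-fill exists to exercise the discretization code; it makes no claim
about the cohort's real continuous distributions.

**What passing tests do and do not show.** The generator reproduces the
published margins and two published conditional facts, and its dependence
structure comes from the knowledge DAG — but the joint distribution beyond
that is an invention. Pipeline results on synthetic cohorts (AUCs,
criteria, conditional probabilities) validate the *machinery*, not the
study's empirical estimates; quantities that depend on the unpublished
joint (absolute AIC/BIC, fitted CPs, strengths) are expected to differ
from the printed ones.

**A limit of parameter recovery.** Refitting CPTs on a large sample
recovers the generator only where the data can see it: a parent
configuration with joint probability 1e-6 is simply absent from 50,000
records, and its fitted column is the uniform fallback regardless of the
truth. Per-cell recovery of the full 13-node generator to ±0.01 would
need more than 4.6 million records (≈2,000 observations in each of the
outcome's 2,304 configurations). The suite therefore asserts a
sampling-theoretic bound — each observed cell within 0.01 plus four
binomial standard errors at its configuration count — and exact ±0.01
recovery on a five-node network whose families are all well supported.

## The pipeline

`run_pipeline(pipeline_config(...))` chains the seven stages — data,
baseline table, knowledge fit, structure search, criteria, LOOCV
diagnostics, CP/strength reports — writing eight CSV artifacts, two
serialized networks (a quoted-YAML format that round-trips probabilities
bit-exactly), a DOT graph and a JSON manifest. All randomness flows from
the configuration seed, and two runs with the same configuration produce
byte-identical CSVs. Stage failures abort with the stage name and leave a
`FAILED` marker beside any partial outputs.

## Numerical choices and problem sizes

* CPT columns must sum to 1 within 1e-9 (`validate_network()`); exact
  posteriors are normalized once, at the end of elimination.
* Hill-climbing accepts a move only if it improves the score by more than
  1e-9, and scans moves in a fixed order, so ties break deterministically.
* Serialized probabilities are printed with 17 significant digits
  (`%.17g`), which round-trips IEEE doubles exactly.
* Test and acceptance problem sizes are chosen so each property is
  decisively powered at desk scale: 100,000 records for margin
  calibration (Monte Carlo SE ≈ 0.15 pp against a ±2 pp band), 50,000
  for parameter recovery, 20,000 for collider orientation and BIC
  consistency, 491 — the cohort's own size — for the pipeline runs.

## Limitations

The package models categorical variables only (discretization loses
information, as the source study itself notes); structure search explores
a single greedy family (no exact search or MCMC); the generator does not
emulate measurement error, missingness, or realistic continuous
distributions; and confidence intervals for AUC are out of scope, as they
are not part of the reproduced analysis.
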