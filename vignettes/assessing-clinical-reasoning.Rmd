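---
title: "Assessing diagnostic reasoning from virtual-patient traces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing diagnostic reasoning from virtual-patient traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vpdx implements a complete assessment pipeline for staged virtual-patient
(VP) encounters: rubric-driven scoring of learner interaction traces,
rule-based detection of five cognitive-error behaviors, a calibrated
synthetic-cohort simulator, and the longitudinal statistics used to study
clinical-reasoning (CR) growth under deliberate practice. This vignette
explains the models, the defaults, and the reasoning behind the design
choices, in the spirit of a methods appendix.

## The assessment model

A VP case unfolds in four stages - a one-sentence introduction, history,
physical exam, and investigations. At every stage the learner maintains a
differential diagnosis (Ddx) of up to five free-text conditions, flags one
as most probable at each stage transition, assigns clinical data to
diagnoses as increasing or decreasing their likelihood (diagnostic
justification, DxJ), and orders investigations in "get results" rounds.
Completion requires a final most-probable diagnosis with a certainty
rating (recorded, not scored).

The expert scorecard is the unit of assessment logic. It lists the
diagnoses deemed appropriate for the case, labels each (datum, diagnosis)
justification pair as `required_increase`, `required_decrease`, `neutral`
or `wrong`, labels tests as `required`, `neutral` or `inappropriate`, and
links tests to the diagnoses they confirm or rule out. Component scores
follow directly:

* **Ddx** - percent of appropriate diagnoses appearing anywhere in the
  union of the learner's snapshots. The union (rather than the final list)
  is used because the construct is hypothesis *generation*; a diagnosis
  entertained and later discarded was still generated.
* **DxJ** - one point per required pair assigned with the rubric's
  direction, minus `wrong_assignment_deduction` (default 0.5, the
  conventional half-credit penalty) per assignment that is rubric-wrong or
  contradicts a required direction; clamped at zero, normalized by the
  required-entry count.
* **Investigations** - required orders gain a point, inappropriate orders
  lose one, neutral orders do nothing; clamped at zero, normalized by the
  required-test count.
* **Final diagnosis** - full credit for the correct diagnosis, configurable
  second-choice credit (default 0.5) when it is the second-listed entry of
  the final differential.

Percent components are clamped *before* normalization because negative
percents are not interpretable on this rubric; penalties are reported as
separate quantities rather than folded into the investigation score
(a `fold_penalties` switch reverses this). Ordering penalties use a
threshold of twice the cohort mean (rounded up; a count *equal* to the
threshold is not penalized), plus per-test penalties for unused results
and inappropriate orders.

Free-text entries are canonicalized against per-case synonym lexicons
after case-folding, punctuation stripping and whitespace collapsing.
Matching is exact by default; a bounded Levenshtein distance (recommended
at most 2) can be enabled to absorb typos. Exact-match default keeps
scoring reproducible: an edit-distance match can flip when lexicons grow.

## The five error detectors

Each detector is a rule over the canonicalized trace and the rubric, with
configurable thresholds (`error_thresholds()`) and mandatory machine-
readable evidence for every raised flag. Flags are binary per case; the
case-level error count is their sum (0-5).

* **Premature closure** (failure to confirm the chosen diagnosis): the
  final diagnosis has less than `confirm_fraction` (default 0.5) of its
  required supporting data assigned *and* less than that fraction of its
  confirmatory tests ordered.
* **Failure to rule out**: some appropriate competitor the learner
  themselves listed has less than `ruleout_fraction` of its required
  rule-out data assigned and none of its discriminating tests ordered.
  Competitors never listed are the Ddx score's concern, not an error flag.
* **Confirmation bias**: at least `bias_min_count` (default 1) assignments
  read a rubric-contradicting datum (`required_decrease` or `wrong`) as
  *increasing* one of the learner's leading diagnoses.
* **Anchoring**: the same incorrect diagnosis held as most probable over
  at least `anchor_min_stages` (default 2) consecutive transitions while
  at least `anchor_min_contradictions` (default 2) contradicting data had
  already been revealed, and chosen as final.
* **Search satisficing**: fewer than `satisfice_min_ddx` (default 3)
  entries in the post-history differential and under half of the
  appropriate diagnoses ever listed.

Two semantic decisions matter. First, a clause whose denominator is empty
(the rubric defines no confirmatory evidence for a diagnosis) is treated
as vacuous rather than violated: a learner cannot fail to confirm a
diagnosis the rubric gives no means of confirming. Without this rule any
rubric-unsupported final diagnosis would mechanically raise a premature-
closure flag, which both collapses detector separability and couples the
flag to the outcome rather than to the behavior. Second, the detectors
are deterministic and order-independent, so identical traces always
produce identical flags, and three of the five (premature closure, rule
out, confirmation bias) consume only justification assignments, test
orders and rubric labels.

The built-in demonstration rubric links its discriminating tests in both
directions - a CT angiogram *rules out* pulmonary embolism when negative
and *confirms* it when positive - so the premature-closure clause is
assessable for wrong final diagnoses too.

## The synthetic cohort

No real learner data ships with the package; every downstream stage is
exercised on a simulated cohort designed to resemble a multi-site
pre-clerkship study: five schools, 200 students each, up to 20 sequenced
cases.

Each student carries latent skills on the logit scale - differential
building, justification, test ordering, and error proneness - composed of
a population trajectory `a + b log(t)` over case sequence `t`, a school
effect (SD 0.25) drawn once per school, a student effect (SD 0.5), and a
shared AR(1) "form" residual (rho 0.4, SD 0.35) that makes adjacent cases
more similar than distant ones. The log-shaped trajectory reflects growth
that is steep early and slowing but not plateauing. A growing
"verification habit" (the probability of systematically ruling out listed
competitors) carries much of the decline in organic error-detector
firing; error-prone behaviors - contradiction-as-support, anchoring on an
early wrong diagnosis, narrow differentials, inappropriate and duplicate
orders - are injected with probabilities proportional to the error skill.

The final diagnosis is drawn from a logistic link on realized
performance:

```
logit P(correct) = gamma0 + gamma_t log(t)
                   + 0.29 dxj + 0.18 inv + 0.12 ddx - 0.42 errors
```

with component scores on a 0-10 point scale. The slope magnitudes are the
link's design constants; `gamma0` and `gamma_t` are calibrated. The
`gamma_t` term carries practice-driven accuracy growth *not* mediated by
the four scored components (content knowledge accumulating over a
curriculum); without it the two misdiagnosis endpoints cannot both be
reached once the component trajectories are pinned to their own
endpoints.

**Calibration.** The default constants in `vpdx_calibration()` were
solved once by damped Monte-Carlo root-finding on the generator's own
first- and last-case marginals so that the default cohort reproduces its
reference endpoint summaries: Ddx 79 to 90.7 percent, DxJ 27 to 46.5
percent, test ordering 46 to 64.5 percent, cognitive errors 0.87 to 0.43
per student per case, misdiagnosis 27 to 9 percent. With five schools the
school effects are a real part of run-to-run variation, so endpoint
checks use the larger of the school-cluster and iid standard errors; at
1,000 students individual endpoints can still sit one to three points
from their nominal values in any single run (DxJ baseline in particular
tends to run one to three points above 27, because the verification habit
rather than the per-entry assignment rate dominates that marginal).

The M2 (second-year) cohort shares all baseline skills but is less
error-prone at baseline (`m2_a_err_shift = -0.9` on the logit) and by
convention completes 10 cases. The shift size balances two qualitative
requirements: baseline error rates must separate between cohorts while
the 20-case M1 cohort must still finish ahead of the 10-case M2 cohort on
end-of-curriculum error rates.

Seeding is hierarchical: every school, student and (student, case) draw
derives from the study seed, and each student owns a private stream, so
enlarging a cohort never perturbs existing students' traces.

`simulate_cohort_scores()` is a score-level twin of the trace generator:
it draws component scores and error counts from the same latent
trajectories and applies the identical link, skipping event-level
behavior. Because its link is *exactly* logistic in its stored covariates
it is the reference generator for parameter-recovery and power studies.
In the full trace-level pipeline the detected error count is a noisy,
asymmetric proxy of the behavioral error indicators inside the link
(anchoring, for instance, is only detectable when the anchored diagnosis
is actually chosen), so a marginal model fitted to scored traces recovers
the sign pattern reliably but estimates a steeper error coefficient than
the generating constant - ordinary errors-in-variables, documented here
so the two recovery results are read correctly.

**What the generator does not emulate.** All cases share one structural
template; there is no case-difficulty variation, no content-knowledge
dimension, no variation in completion counts (every student finishes all
cases), and navigation behavior is only loosely realistic. Passing tests
therefore demonstrate that the scoring rules, detectors and statistical
machinery behave correctly and that the pipeline reproduces the
endpoint summaries it was calibrated to - not that real learners behave
like the generator.

## The analysis stage

`compare_groups()` contrasts correctly and incorrectly diagnosed cases on
every Table-style variable: group means and SDs, the percent difference
relative to the misdiagnosed group, and a two-group test - a t-test when
a Shapiro-Wilk check (on a subsample capped at 3,000, alpha 0.05) does
not reject normality for either group, a Wilcoxon rank-sum test
otherwise, a two-proportion test for binary variables, and an explicit
skip with a recorded reason for constants.

`fit_gee()` fits the clustered multivariate model: a marginal logistic
regression of per-case correctness on the reasoning components, clusters
at the student level, an AR(1) working correlation over the case sequence
(adjacent cases more alike than distant ones), and school as a fixed
covariate; clustering at the school level is config-selectable.
Component percents enter divided by 10 - a 0-10 point scale chosen so
coefficient magnitudes are comparable with conventionally reported
per-point estimates - time variables are log-transformed, and count
variables with absolute skewness above 2 are dichotomized at zero versus
nonzero; every transformation is recorded in the result. An optional
pruning mode removes predictors above a p-value threshold one at a time
and lists them with the reason "Not significant, removed"; it is off by
default. No multiplicity correction is applied by default (raw p-values
are reported); a Holm option exists at the call-site level via
`stats::p.adjust`.

Because no GEE implementation is available in the package's dependency
envelope, the estimating equations are solved in-package (`gee_logit()`):
Fisher-scoring updates with a moment estimator for the working
correlation, robust sandwich covariance, and the Mancl-DeRouen leverage
correction as the default standard error (the plain Liang-Zeger sandwich
is anti-conservative at moderate cluster counts; the uncorrected version
remains available and is cross-checked in the test suite against
`glm()` plus `sandwich::vcovCL()`, which it reproduces exactly under an
independence working correlation). Non-convergence raises an error
carrying the iteration trace; rank-deficient designs are rejected naming
the collinear columns. A permutation-null property worth knowing:
shuffling outcomes *within* student blocks preserves each student's
outcome mean and with it the between-student covariate-outcome
association, so only a *global* outcome permutation is a genuine null for
marginal associations.

`fit_learning_curves()` fits, per metric, a generalized mixed-effects
model with a random student intercept and a fixed `log(t)` trend -
binomial for correctness, gaussian for percent scores, Poisson for the
error count - and returns the population trend with a delta-method 95%
band. The claim that learning curves "do not plateau" is rendered as:
the fixed trend's slope confidence interval excludes zero over the final
segment, which the log-link trend satisfies whenever the slope itself is
positive. `compare_cohorts()` applies the univariate machinery to the M1
versus M2 contrast at sequence position 1 and at each cohort's final
case, flagging degenerate single-case cohorts.

All analyses are pure functions of (dataset, configuration, seed);
`render_report()` stamps its run manifest with the seed and a
configuration hash, and identical inputs yield byte-identical CSV tables.

## Numerical and testing choices

Auto penalty thresholds round up (`ceiling(2 * mean)`) and ties are not
penalized, matching the "if exceeded" reading. Duplicate justification
assignments are de-duplicated per (datum, diagnosis, direction); a
required pair is credited at most once. Timestamps may be numeric seconds
or ISO-8601 strings. Navigation metrics are reported in minutes.

The test suite exercises the scorers against brute-force oracles
(set-intersection for the differential score, exhaustive enumeration of
all assignment sets over every rubric shape up to 4 data by 3 diagnoses
for the justification score, interval-sum for navigation), the detectors
against archetype traces engineered to trip exactly one flag each (the
5-by-5 confusion matrix is the identity; corrected twins trip nothing),
and the statistics against known-truth simulations: 50-replicate sign
recovery at 200 students by 20 cases, 200-replicate permutation nulls,
and the endpoint round-trip at 1,000 students. These sizes were chosen to
give stable Monte-Carlo assertions at interactive runtimes.

## Known limitations

The rubric template ties detector behavior to rubric completeness: a
scorecard without rule-out labels cannot yield failure-to-rule-out flags.
The error-count scale is calibrated against detector output on one case
template; on richer rubrics the organic firing rates will differ and the
calibration would need re-solving. The trace-level marginal model
overestimates the error coefficient magnitude for the reason given above.
Certainty ratings are recorded but unused. History and physical-exam
information *gathering* is deliberately out of scope: all findings are
revealed to every learner, and only their interpretation is assessed.
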