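---
title: "Auditing the reliability of a network meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the reliability of a network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmaudit)
```

## What this package audits, and why

A network meta-analysis (NMA) combines direct, randomized comparisons of
three or more interventions through shared comparators, so that an effect of
A versus C can be estimated indirectly through A–B and B–C trials. The
validity of that step rests on two linked assumptions. *Transitivity*: the
distribution of effect modifiers (here age, sex, fracture morphology,
comorbidity) is similar across the trial sets that feed different
comparisons. *Coherence*: direct and indirect estimates of the same
comparison agree statistically. Published NMAs of proximal humerus fracture
treatments (nonoperative care, plate fixation, intramedullary nailing,
hemi- and reverse shoulder arthroplasty) often report neither check.
`nmaudit` implements the full audit pipeline — network construction,
frequentist estimation, incoherence testing, quantitative transitivity
assessment, and a six-domain confidence rating — together with a synthetic
trial-network generator so each stage can be calibrated against known truth.

## Estimation model

Every trial is reduced to baseline contrasts: a trial with arms
$b, a_1, \dots, a_{k-1}$ contributes $k-1$ effects $y_i$ (mean differences
in score points or log odds ratios) with covariance equal to the shared
baseline-arm variance off the diagonal. The consistency model stacks these
on the edge-incidence design $X$,

$$\hat\theta = (X^\top W X)^{+} X^\top W y, \qquad W = V^{-1},$$

with $\theta$ the basic parameters (each intervention versus a reference
node) and $V$ block-diagonal per trial. Using the exact multi-arm covariance
block rather than a variance-inflation heuristic keeps the fit identical to
a generalized least-squares solve, which is how the test suite checks it
(against an independent multivariate fit from `metafor`, to $10^{-8}$).

Under the random-effects model each trial's covariance block gains a
compound-symmetry component ($\tau^2$ on the diagonal, $\tau^2/2$ between
contrasts of one trial). A single network $\tau^2$ is estimated by the
multivariate method-of-moments generalization of DerSimonian–Laird,
$\hat\tau^2 = \max\{0, (Q - \mathrm{df})/\operatorname{tr}(MG)\}$, where $Q$
is the common-effects residual statistic, $M$ its residual weight projector,
and $G$ the unit between-trial covariance. The total $Q$ decomposes into a
within-design heterogeneity part (residual of a model with design-specific
effects) and a between-design inconsistency part; the latter, referred to a
$\chi^2$ with df = (independent design contrasts − basic parameters), is the
design-by-treatment interaction test.

## Incoherence

The SIDE (node-splitting) test compares, for one comparison, the pooled
direct evidence with the indirect estimate obtained by *refitting* the
network after removing every trial that contains both interventions
(multi-arm trials containing the pair therefore sit on the direct side;
refitting rather than algebraic subtraction stays exact in multi-loop
networks). The two estimates are compared with a z-test. The decision
threshold is p < 0.10 — deliberately lenient because both tests have low
power, so they can flag incoherence but never certify coherence. The test is
inapplicable for comparisons with only one evidence route; in a network
without any closed loop (a cycle through ≥ 3 interventions — parallel trials
on one comparison do not count) neither SIDE nor the global test applies,
and the audit reports the domain as not assessable rather than unremarkable.

## Quantitative transitivity

Per comparison, the mean ages of its trials are pooled with the
sample-size-weighted combined mean (and, when every trial reports one, the
combined SD built from within- and between-trial components), and the female
proportion is pooled by direct aggregation of counts. Each comparison is
contrasted with a designated reference comparison — hemi-arthroplasty versus
nonoperative care, chosen because every audited network informs it with the
same, demographically similar trials. Flags:

* **age** — absolute pooled difference > 5 years (primary) or 10 years
  (sensitivity). No significance test backs this cutoff: most trials report
  no age SD, so the planned two-sample t-tests are impossible and the
  absolute cutoff is the fallback.
* **gender** — Fisher's exact test on the pooled female/male counts versus
  the reference must be significant at α = 0.05 *and* the absolute
  difference must exceed 20 percentage points (30 in sensitivity). The
  two-sided p-value sums all tables with probability at most that observed.
* **qualitative** — analyst-supplied judgements (fracture morphology,
  surgical indication) are consumed as structured input, never inferred:
  classification and reporting of morphology and comorbidity are too
  heterogeneous to compare computationally.

Each trial then receives an intransitivity level from the count of distinct
flagged modifiers on its comparisons: 0 low, 1 moderate, ≥ 2 high. When a
trial reports only a female percentage, the count is reconstructed by
rounding, and flagged as reconstructed, because the exact test needs counts.

## Confidence ratings

Six domains are rated per comparison (no / some / major concerns):

* *within-study bias* and *intransitivity* use the weighted average rule:
  per-trial levels scored 1/2/3, weighted by the trial's percentage
  contribution, with cut points 1.5 and 2.5 (midpoints; the rule's cut
  points are not standardized, so they sit in configuration).
* *reporting bias* fires on any of the standard indicators (grey literature
  not searched, few positive early findings, industry-dominated evidence,
  documented prior reporting bias), on any unregistered contributing trial,
  or on a registered trial whose reported outcomes deviate from the
  registration. Any trigger maps to some concerns by default.
* *imprecision* and *heterogeneity* compare the 95% confidence interval and
  the prediction interval against the equivalence range ±MCID (5.4
  Constant-score points, 8.1 DASH points; for additional surgery any risk
  increase counts, so the range degenerates to the null). Crossing one
  boundary costs one level, two boundaries two levels; the heterogeneity
  domain charges only the boundaries the prediction interval adds beyond
  the confidence interval. These operational rules are this package's
  codification of practice that published frameworks delegate to a web
  application; they are config-overridable and every judgement carries its
  inputs for audit.
* *incoherence* uses the comparison's SIDE result when applicable (major
  concerns when the direct–indirect disagreement exceeds the MCID),
  otherwise the global test, otherwise not-applicable.

The overall grade starts at high and drops one step per some-concerns domain
and two per major-concerns domain, floored at very low; not-applicable
domains do not downgrade. Because the ladder is a pure function, the test
suite checks all $3^6$ judgement combinations exhaustively.

The contribution matrix behind the weighted rules comes from the hat matrix
of the edge-aggregated consistency model: each comparison's hat row is a
unit evidence flow between the two interventions, decomposed into streams
(shortest paths first, each stream's flow spread equally over its edges) and
allocated to trials by inverse-variance weight within each edge. Any
decomposition satisfying the row-sum and zero-path invariants is admissible;
this one is recorded in the report provenance.

## The synthetic generator

`generate_network()` draws trials with known truth: consistency effects per
intervention, an optional incoherence offset per designated comparison, and
between-trial heterogeneity implemented as independent arm shifts with
variance $\tau^2/2$, which yields exactly $\tau^2$ per contrast and
$\tau^2/2$ shared-arm covariance. Continuous outcomes live on the Constant
score scale (baseline 60, within-arm SD 15, observed means clamped to
0–100; with realistic arm sizes the clamp never binds), binary outcomes on
the logit scale. Trial-level modifiers are drawn from the mixture of the
arms' intervention-specific models — the generator's encoding of the
intransitivity mechanism in which an intervention is preferentially given to
younger patients. Arm SDs can be deleted with a configurable probability to
reproduce the missing-SD situation that breaks continuous networks. One
global seed drives deterministic per-trial substreams, so regeneration is
byte-identical.

What the generator does *not* emulate: real outcome distributions are
skewed and truncated rather than normal; real trials differ in size and
design quality; modifiers correlate within trials; and real missingness is
not at random. Passing calibration on synthetic networks therefore
demonstrates that the machinery is correct under its stated model, not that
the audited clinical conclusions transfer.

### Fixtures shaped like the audited networks

`fixture_like_published()` ships three small networks whose topology, trial
counts, participant totals, pooled ages, and female percentages match the
published transitivity table; outcome values are synthetic. Trial-level
ages are chosen so that the *unrounded* pooled differences reproduce the
printed difference column after half-up rounding (the printed means
themselves are rounded, so subtracting them can be off by 0.1). In each
fixture the plate-versus-hemiarthroplasty trial reports continuous outcomes
without an SD; dropping it removes every closed loop from the sparser
continuous network, reproducing the situation in which coherence cannot be
assessed at all, while SD imputation (the unweighted mean of the outcome's
reported SDs) restores the loop as a sensitivity analysis.

## Numerical and design choices

* Binary effects are log odds ratios; 0.5 is added to all four cells only
  when a zero cell occurs. A risk-ratio switch would be a configuration
  matter, not a structural one.
* Continuous effects are raw mean differences; standardized differences are
  out of scope.
* Estimation uses the Moore–Penrose pseudoinverse throughout, so rank
  deficiencies degrade gracefully; disconnected networks are refused with
  the component list.
* One common $\tau^2$ per network (not per comparison): sparse networks —
  1–3 trials per comparison is typical here — cannot identify more.
* Combining two identical groups' SDs returns slightly *less* than the
  common SD (the pooled sample spends one degree of freedom on its mean);
  the implementation matches the exact-reconstruction oracle rather than
  the intuitive identity.
* Display rounding is half away from zero: one decimal for ages and their
  differences, integers for percentages, two decimals for p-values with
  p < 0.001 printed as such.

## Calibration study sizes

The packaged calibration (analysis/01, and the acceptance script) uses
1000 coherent triangles (one 100-per-arm trial per comparison) for the
type-I error of both incoherence tests, 200 triangles with a 10-SE offset
for power, and 500 four-node networks with $\tau = 0.5$, three trials per
comparison and 200 participants per arm for CI coverage. The coverage
design deliberately uses three trials per comparison rather than the
sparser published shapes: with one or two trials per comparison $\tau^2$ is
essentially unidentifiable and its estimation noise dominates the interval
width, which tests the regime rather than the estimator. Observed values:
type-I ≈ 0.10 for both tests, power 1.0, coverage ≈ 95%.

## Known limitations

* The SIDE z-test treats the direct and indirect sides as independent; with
  multi-arm trials on the split comparison this is the dominant convention,
  not an exact property.
* Imprecision/heterogeneity rules are boundary-crossing codifications;
  other reasonable codifications would shift individual domain percentages
  (not the very-low overall grades, which are driven by bias and reporting
  domains).
* Ranking metrics (SUCRA), Bayesian estimation, and loop-specific
  inconsistency tests are out of scope.
* The audit consumes risk-of-bias levels and qualitative transitivity
  judgements as inputs; it does not derive them.
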