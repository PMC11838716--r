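---
title: "Autovalidation of laboratory results: the rule model, its conventions, and how it is verified"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autovalidation of laboratory results: the rule model, its conventions, and how it is verified}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autovalidr)
```

## The problem

Autovalidation (autoverification) is the computerized release of clinical
laboratory test results without manual review. Every result entering the
post-analytical phase is checked against a configured set of rules; a result
is released automatically only when it satisfies *all* of them, and is
otherwise held for a laboratory professional. `autovalidr` implements this
rule engine together with everything needed to parameterize, verify and
exercise it without access to a real laboratory information system (LIS):
limit-derivation utilities, a two-phase verification harness, and a seeded
synthetic result generator with preanalytical error injection.

## The decision model

A decision for one result is the conjunction of per-rule verdicts. Each rule
returns `PASS`, `HOLD`, or `SKIP` (rule not applicable, e.g. no prior result
for a delta check); the result is `AUTOVALIDATED` if and only if no rule
returns `HOLD`. All rules are equivalent — none outranks another — and all
are always evaluated, with no short-circuiting, so the reviewer of a held
result sees every violated rule at once. The rules are:

* **Demographics.** A result is never released without the patient's age and
  sex; age is computed at the result timestamp (not at evaluation time) so
  that decisions are reproducible. Configured age groups are half-open
  `[min, max)` intervals; ages below 0 or above 120 years are treated as
  implausible and always hold, so an "absurd age" scenario fails even for a
  test with no configured age groups.
* **Analyzer flags.** Flag codes listed as blocking hold the result; all
  other codes are non-blocking but echoed into the decision detail, matching
  the operational distinction between messages that do and do not affect a
  result. An analyzer include-list is enforced here as well (there is no
  separate rule identifier for analyzer admission).
* **HIL indices.** Hemolysis, icterus and lipemia thresholds are per test; a
  configured threshold with an unmeasured index holds the result, since the
  interference status is then unknown.
* **Critical limits.** A result *at or beyond* a critical limit is critical:
  held for immediate manual validation and clinician notification. Critical
  limits dominate the autovalidation range — a critical result inside the
  range is still held.
* **Autovalidation range.** Inclusive at both boundaries: a glucose of
  11.0 mmol/L with a high limit of 11.0 passes. A missing result value holds
  here with its own reason code.
* **Delta check.** See below.
* **Consistency.** Ratio rules between physiologically related tests on one
  sample (AST/ALT within [0.25, 4], conjugated/total bilirubin at most 1,
  albumin/total protein within [0.25, 1] in the shipped example). Bands are
  inclusive; a zero denominator holds; a violation holds *both* participating
  results, since the error could be in either measurement.
* **Internal QC.** Out-of-control status holds all results of the test, and
  a configurable expiry (hours since the last passing QC event) holds
  results once a pass has gone stale.
* **Kill switch.** A configuration-level emergency stop: when set, nothing
  autovalidates, though rule outcomes are still computed and reported. This
  is the mechanism that lets a laboratory stop real-time autovalidation at
  any moment.

### Boundary conventions

The package fixes one convention and applies it everywhere: **inclusive
PASS** at autovalidation-range, HIL and consistency boundaries, **inclusive
HOLD** at critical limits, and **strict exceedance** for the delta limit
(equality with the limit passes). Technical verification requires testing
values *at* each decision point, which is only meaningful when the at-limit
behaviour is fixed and documented; these conventions are asserted by the
boundary test suite and exercised by the Phase I case generator.

## Delta check mathematics

Four difference calculations are supported between the current result and
the most recent eligible prior result of the same patient and test:

| mode | difference | typical use |
|------|------------|-------------|
| `absolute` | $x_2 - x_1$ (units) | electrolytes, tightly regulated analytes |
| `percent` | $100\,(x_2 - x_1)/x_1$ | enzymes, wide dynamic ranges |
| `rate` | $(x_2 - x_1)/\Delta t$ (units/h) | creatinine in AKI, troponin |
| `rcv` | percent difference against a computed reference change value | biological-variation-based limits |

The percent denominator is always the *prior* value: change is expressed
relative to the patient's previous state. The reference change value uses
the classical form
$$\mathrm{RCV} = \sqrt{2}\, z \sqrt{CV_a^2 + CV_i^2},$$
with $z = 1.96$ (two-sided 95%) by default and $z$ configurable; the
log-normal RCV variant is not implemented. A prior of exactly zero makes the
percent forms undefined, and the rule then holds with `delta_undefined`
rather than guessing.

The look-back window is per test. With no eligible prior inside the window
the rule is skipped — a result out of the delta time interval autovalidates
when everything else passes — matching the expectation that a delta check
gates only genuinely consecutive results. Hospital chemistry uses short
windows (the example configuration ships 3–5 days); primary-care
populations would use longer ones.

### Which tests deserve a delta check

The index of individuality $II = CV_i / CV_g$ compares within-subject to
between-subject biological variation. When $II < 0.6$ an individual's
results occupy a narrow band relative to the population, so a consecutive-
result comparison is informative; `select_delta_candidates()` applies this
threshold (strictly) to a biological-variation table and sorts candidates by
$II$. The packaged table covers 21 common chemistry, coagulation and
hematology measurands; 13 of them qualify at the 0.6 threshold, with PSA
($II = 0.16$) the most individual.

## Deriving limits from data

`percentile_limits()` computes an empirical percentile interval (default
5th–95th) of released historical results; `delta_percentile_limits()` does
the same for same-patient consecutive differences within a stated window.
The percentile estimator is fixed once — linear interpolation between order
statistics (`stats::quantile` type 7): for sorted values
$x_{(1)} \le \dots \le x_{(n)}$ and level $p$, with $h = 1 + (n-1)p/100$,
$k = \lfloor h \rfloor$, the estimate is $x_{(k)} + (h-k)(x_{(k+1)} -
x_{(k)})$ — so derived limits are bit-reproducible across runs, and an
independent sort-and-interpolate oracle in the test suite checks the
implementation on random instances. At least 20 finite values are required;
fewer is an error, not a silent wide interval.

Other catalogued approaches (reference interval, reference interval widened
by total allowable error on an explicit percent or absolute scale, midpoint
between the reference-interval median and each critical limit, critical
limits, clinical cutoffs, consensus, literature) are available through
`propose_limits()`. Proposals are deliberately advisory artifacts: they are
written to report files and never applied to a configuration automatically,
because autovalidation criteria must be reviewed and approved by the
laboratory management before use.

## Verification

**Phase I (technical verification).** `generate_phase1_cases()` emits, per
test: absurd age and sex scenarios, a missing result, one case per blocking
flag plus a non-blocking flag, values at / one reporting unit below / one
reporting unit above every bounded decision point (autovalidation range,
critical limits, each HIL threshold, the delta limit), a prior outside the
delta window, in-band and out-of-band consistency ratios, QC failed and
expired scenarios, and a combined multi-rule violation. The step size
("one unit in the last decimal place") comes from the test's configured
reporting precision. Unbounded limits are skipped with a note. Expected
YES/NO labels are produced by `expected_autovalidation()`, a straight-line
restatement of the conventions that shares no code with the engine — so
100% Phase I concordance is a genuine two-route check, and the test suite
additionally verifies that deliberate single-rule mutations of the
configuration (a shifted boundary, a dropped blocking flag, a halved delta
limit, a widened age group) each break concordance. QC state is pinned to a
passing policy in all non-QC cases so the case set does not depend on
wall-clock time.

During any Phase I run the package's only release path,
`release_decisions()`, fails hard, and the run aborts if a release was
attempted; the report records the release counter, which must be zero. No
patient result can leave the system while the algorithm is under
verification.

**Phase II (concordance).** `run_phase2()` compares engine decisions with
manual validation labels record by record. Results autovalidated but
manually rejected are the critical discordances, flagged for review by the
autovalidation team; results held but manually accepted are benign
discordances, reported without a flag. The predetermined percentage of
autovalidated results is a report parameter (`target_percent`) rather than
a built-in constant, since an appropriate target is laboratory-specific and
a lower percentage is expected on first use.

Both phases export the standard verification spreadsheet layouts (the
cross-test sheet and the single-test sheet) with institution / instrument /
verifier header fields, and every CLI run writes a manifest (configuration
digest, input digests, seed, version) for the audit trail.

## The synthetic result generator

`simulate_population()` emulates a stationary population: patient $i$ has a
log-normal homeostatic set-point with between-subject CV $CV_g$, and serial
results vary about it with combined within-subject and analytical CV
$\sqrt{CV_i^2 + CV_a^2}$. CVs are mapped to log-scale standard deviations by
$\sigma = \sqrt{\ln(1 + (CV/100)^2)}$ with a mean-preserving offset, so the
generated moments recover the specified mean and CVs exactly in
expectation (the test suite checks this on $1.2\times10^4$ draws).
Log-normality was chosen because analyte concentrations are positive and
right-skewed; it also gives the percent delta a closed-form null
distribution: for two consecutive results, the two-sided exceedance
probability of a percent limit $r$ is
$$P = \Phi\!\left(-\tfrac{\ln(1+r/100)}{\sigma_w\sqrt{2}}\right) +
      \Phi\!\left(\tfrac{\ln(1-r/100)}{\sigma_w\sqrt{2}}\right),$$
implemented as `delta_nominal_rate()` and used as the reference value for
the clean-data false-alarm test.

Preanalytical errors are injected with known ground truth: sample swaps
(values exchanged between same-test records of different patients — ids and
timestamps stay put), intravenous dilution (values scaled by a factor in
(0, 1)), hemolysis (index raised above a paired threshold) and blocking
flags. Errors are mutually exclusive per record — only still-clean records
are eligible for each injector — so every record carries exactly one label.

The generator's defaults describe a hospital inpatient stream: two to three
draws per patient, 12–72 h apart, adult ages. The simulation *does not*
model disease trajectories, therapy effects, analytical drift, or
correlated panels; passing tests therefore demonstrate the engine's
behaviour under stationary homeostasis plus injected errors, not its
clinical performance on pathological data.

### The detection study

The acceptance suite reproduces, qualitatively, the claim behind the
$II < 0.6$ candidate rule: with RCV-based limits ($z = 1.96$, one matched
analytical CV of 2% across measurands), swap-detection sensitivity pooled
over the low-individuality measurands of the packaged table ($II \le 0.3$:
ALP, creatinine, MCV, PSA) strictly exceeds that over the high-
individuality ones ($II \ge 0.7$: total bilirubin, chloride, potassium,
total protein, sodium). The study uses 300 patients per measurand with all
pairable values swapped (1200 and 1500 affected comparisons per group), and
a separate clean run of 10^4 comparisons checks that the delta-HOLD rate
sits within three standard errors of the model's nominal exceedance rate.
These problem sizes keep the whole suite comfortably reproducible on a
single CPU while leaving Monte Carlo error far smaller than the effects
being demonstrated.

## Numerical and design choices

* **Timestamps** are ISO-8601, handled in UTC throughout; the delimited
  dialect (UTF-8, comma separator, dot decimal) is fixed for cross-locale
  reproducibility of audit artifacts.
* **Unknown sex** is treated as missing, and missing demographics hold the
  result — the engine never autovalidates without age and sex.
* **Manual-trigger versus real-time** operation differ only in invocation;
  the decision logic is identical, which is what lets a laboratory upgrade
  from one to the other without re-deriving rules.
* **One autovalidation range per test:** ranges are not sex- or
  age-stratified (stratification would multiply every boundary case in
  Phase I; it is left as a configuration-schema extension), while age
  *admission* is handled by the age-group rule.
* **Extension point:** repeat testing, reflex testing, patient-based
  real-time QC and diagnosis-dependent rules are not implemented; the
  engine's per-rule structure (every rule returns a `rule_outcome` feeding
  one conjunction) is the seam where such rules would be registered.
* **Degenerate inputs** are explicit errors, never silent: zero prior under
  percent deltas, zero consistency denominators, too-few values for
  percentile limits, dilution factors outside (0, 1), future birth dates.

## Known limitations

The engine evaluates single results in the context of their sample and
patient history; it has no notion of instrument runs, calibration events or
moving averages, so patient-based real-time QC cannot be emulated by
configuration. The consistency rules are pairwise ratios only — joint rules
("both TSH and fT4 below their reference limits") need the extension point.
The synthetic generator's stationarity means Phase II studies built on it
measure rule mechanics, not clinical review behaviour; real Phase II data
must come from a laboratory's own parallel manual validation.
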