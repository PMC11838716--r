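# autovalidr

An autovalidation (autoverification) rule engine for clinical laboratory
results, written for laboratory informaticians and medical biochemists who
want to design, verify and stress-test result-release rules before (or
without) wiring them into a LIS or middleware.

Every analyzer result is evaluated against a conjunctive rule set —
patient demographics, analyzer flags, hemolysis/icterus/lipemia (HIL)
interference indices, the autovalidation range, critical limits, the delta
check, cross-test consistency ratios, and internal QC gating — and is
released automatically only if **every** rule passes:

```
decision = AUTOVALIDATED  ⇔  no rule returns HOLD
```

The delta check supports absolute, percent, rate-of-change and
reference-change-value (RCV) comparisons against the most recent prior
result inside a configurable look-back window, with

```
RCV = √2 · z · √(CVa² + CVi²)      (z = 1.96 by default)
```

and candidate tests chosen by the index of individuality
`II = CVi / CVg < 0.6`. The package also includes percentile-based limit
derivation from historical results, a two-phase verification harness
(generated boundary cases, manual-vs-automatic concordance, and a hard
guarantee that nothing is released during verification), and a seeded
synthetic result generator with preanalytical error injection (sample
swaps, IV dilution, hemolysis) so the whole system is testable with no
real patient data.

## Worked example

Validate a glucose result against the shipped example configuration, with
one prior result for the delta check:

```r
library(autovalidr)
cfg <- load_config(system.file("extdata", "example_config.yaml",
                               package = "autovalidr"))
ts  <- as.POSIXct("2025-03-10 08:00:00", tz = "UTC")
pat <- patient_info("P001", as.Date("1980-05-02"), "female")
r     <- result_record("S100", "GLUC", value = 11.6, unit = "mmol/L",
                       timestamp = ts, patient = pat,
                       hil = hil_indices(20, 5, 10))
prior <- result_record("S099", "GLUC", value = 6.1, unit = "mmol/L",
                       timestamp = ts - 36 * 3600, patient = pat)
validate_record(r, history = list(prior), config = cfg)
#> <HELD> GLUC S100 = 11.6
#> [demographics] PASS: age 44.9 y, sex female
#> [flags] PASS
#> [hil] PASS
#> [critical] PASS
#> [av_range] HOLD (above_av_range): 11.6 > 11
#> [delta] HOLD (delta_increase): |percent delta 90.16| > limit 30 (prior 6.1, 36.0 h ago)
#> [qc] PASS
```

The result is held for two independent reasons — it exceeds the glucose
autovalidation range (high limit 11 mmol/L, boundary inclusive) *and* it
rose 90% from the prior result against a 30% delta limit. All rules are
always evaluated, so the reviewer sees every violation, not just the first.

Pick delta-check candidates from the packaged biological-variation table
(21 measurands) and compute an RCV:

```r
head(select_delta_candidates(read_biovar()), 4)
#>    measurand cvi  cvg        ii
#> 1        PSA 6.8 42.0 0.1619048
#> 2        MCV 0.8  3.9 0.2051282
#> 3 Creatinine 4.4 16.2 0.2716049
#> 4        ALP 6.0 21.0 0.2857143
reference_change_value(2.2, 4.4)   # creatinine, CVa 2.2%, CVi 4.4%
#> [1] 13.63574
```

13 of the 21 measurands fall below the conventional `II < 0.6` threshold;
a creatinine changing by more than ±13.6% between consecutive samples
exceeds combined analytical and within-subject variation at 95% confidence.

Run Phase I technical verification of the glucose rules (boundary cases at,
just below and just above every decision point, generated and labelled
independently of the engine):

```r
cases <- generate_phase1_cases(cfg$tests$GLUC, cfg)
run_phase1(cases, cfg)
#> <verification_report> Phase I: 44 case(s), 44 concordant (100.0%)
#>   autovalidated: 38.6%; released during verification: 0
```

The same operations are available from a shell via
`inst/cli/autovalidr` (`validate`, `verify`, `derive-limits`, `simulate`),
with exit codes 0/1/2/3 for success, usage/config errors, data errors, and
attempted release during verification.

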