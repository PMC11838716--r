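# Example autovalidation rule configuration for a small hospital chemistry
# panel. One canonical schema, versioned; every rule the engine knows is
# parameterized here. Values are illustrative defaults a laboratory would
# replace with its own approved criteria.
schema_version: 1
mode: manual_trigger
kill_switch: false

tests:
  - test_code: GLUC
    name: Glucose
    unit: mmol/L
    decimals: 1
    # autovalidation range anchored at the clinically significant diabetes
    # cutoff (11 mmol/L) on the high side
    av_range: {low: 3.0, high: 11.0}
    critical_limits: {low: 2.5, high: 25.0}
    hil_thresholds: {hemolysis: 100, icterus: 60, lipemia: 200}
    age_groups_included: [[18, 120]]
    flags_blocking: [SAMPLE_CLOT, SAMPLE_SHORT, PROZONE]
    delta:
      mode: percent
      limit: 30
      window_days: 3          # hospital chemistry: short look-back
    biovar: {cvi: 4.6, cvg: 8.1}

  - test_code: K
    name: Potassium
    unit: mmol/L
    decimals: 1
    av_range: {low: 3.0, high: 6.0}
    critical_limits: {low: 2.8, high: 6.2}
    hil_thresholds: {hemolysis: 50}   # potassium is hemolysis-sensitive
    age_groups_included: [[18, 120]]
    flags_blocking: [SAMPLE_CLOT, SAMPLE_SHORT]
    delta:
      mode: absolute          # tight homeostatic control: absolute limits
      limit: 0.8
      window_days: 3
    biovar: {cvi: 3.9, cvg: 5.3}

  - test_code: CREA
    name: Creatinine
    unit: umol/L
    decimals: 0
    av_range: {low: 40, high: 300}
    critical_limits: {low: 10, high: 1000}
    hil_thresholds: {hemolysis: 200, icterus: 100, lipemia: 300}
    age_groups_included: [[18, 120]]
    flags_blocking: [SAMPLE_CLOT, SAMPLE_SHORT]
    delta:
      mode: rcv               # low index of individuality: RCV-based delta
      window_days: 5
      z_value: 1.96
      cv_analytical: 2.2
    biovar: {cvi: 4.4, cvg: 16.2}

  - test_code: AST
    name: Aspartate aminotransferase
    unit: U/L
    decimals: 0
    av_range: {low: 5, high: 200}
    critical_limits: {high: 2000}
    hil_thresholds: {hemolysis: 40}
    age_groups_included: [[18, 120]]
    flags_blocking: [SAMPLE_CLOT]
    delta:
      mode: percent
      limit: 50
      window_days: 3
    biovar: {cvi: 2.5, cvg: 4.1}

  - test_code: ALT
    name: Alanine aminotransferase
    unit: U/L
    decimals: 0
    av_range: {low: 5, high: 250}
    critical_limits: {high: 2000}
    age_groups_included: [[18, 120]]
    flags_blocking: [SAMPLE_CLOT]
    biovar: {cvi: 11.4, cvg: 35.2}

  - test_code: BILT
    name: Bilirubin, total
    unit: umol/L
    decimals: 0
    av_range: {low: 2, high: 100}
    critical_limits: {high: 400}
    age_groups_included: [[18, 120]]
    flags_blocking: [SAMPLE_CLOT]

  - test_code: BILC
    name: Bilirubin, conjugated
    unit: umol/L
    decimals: 0
    av_range: {low: 0.5, high: 80}
    critical_limits: {high: 300}
    age_groups_included: [[18, 120]]
    flags_blocking: [SAMPLE_CLOT]

  - test_code: ALB
    name: Albumin
    unit: g/L
    decimals: 0
    av_range: {low: 20, high: 55}
    critical_limits: {low: 10}
    age_groups_included: [[18, 120]]
    flags_blocking: [SAMPLE_CLOT]

  - test_code: TP
    name: Protein, total
    unit: g/L
    decimals: 0
    av_range: {low: 50, high: 90}
    critical_limits: {low: 30}
    age_groups_included: [[18, 120]]
    flags_blocking: [SAMPLE_CLOT]
    biovar: {cvi: 2.6, cvg: 3.5}

consistency_rules:
  - rule_id: ast_alt
    numerator_test: AST
    denominator_test: ALT
    limits: {low: 0.25, high: 4}
  - rule_id: bilc_bilt
    numerator_test: BILC
    denominator_test: BILT
    limits: {low: 0, high: 1}
  - rule_id: alb_tp
    numerator_test: ALB
    denominator_test: TP
    limits: {low: 0.25, high: 1}

qc_policies:
  - test_code: GLUC
    in_control: true
    last_pass_time: 2025-03-10 06:00:00
    max_age_hours: 24
  - test_code: K
    in_control: true
    last_pass_time: 2025-03-10 06:00:00
    max_age_hours: 24
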