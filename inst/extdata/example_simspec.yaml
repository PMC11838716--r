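# Example simulation spec: a small stationary inpatient population with
# preanalytical errors injected at known rates (ground truth emitted
# alongside the records).
n_patients: 50
draws_per_patient: 2
interval_hours: [12, 48]
seed: 20250
error_rates:
  swap: 0.05
  dilution: 0.02
  hemolysis: 0.02
  flag: 0.02
tests:
  - {test_code: GLUC, mean: 5.5, cvi: 4.6, cvg: 8.1, cva: 2.0, unit: mmol/L}
  - {test_code: K,    mean: 4.2, cvi: 3.9, cvg: 5.3, cva: 1.5, unit: mmol/L}
  - {test_code: CREA, mean: 80,  cvi: 4.4, cvg: 16.2, cva: 2.2, unit: umol/L}
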