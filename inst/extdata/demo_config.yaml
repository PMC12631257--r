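# Demo pipeline configuration: simulate a small FAERS-like database with one
# planted signal and run the full signal-detection flow on it.
mode: simulate
seed: 20260101
simulate:
  n_cohort: 400
  n_background: 8000
  duplicate_rate: 0.05
  planted:
    - pt: Abscess
      rate_ratio: 8
drug: ustekinumab
indication_pts:
  - Crohn's disease
window:
  - 2016Q4
  - 2023Q4
thresholds:
  min_reports: 3
  ror_min: 3
  prr_min: 2
  ic025_min: 0
  ebgm05_min: 2
top: 30
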