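# Default output dialects of the five base pre-miRNA predictors.
# Loaded by read_predictor_specs(); identical to default_predictor_specs().
- name: MiPred
  output_kind: numeric
  na_policy: forbid
  positive_range: [50, 91]
  negative_range: [0]
- name: MIReNA
  output_kind: binary
  positive_token: "Yes"
  negative_tokens: ["No"]
- name: miRPara
  output_kind: numeric
  na_policy: forbid
  positive_range: [0.8, 1]
  negative_range: [0]
- name: ProMiR
  output_kind: numeric
  na_policy: sentinel
  positive_range: [0.017, 3240]
  negative_range: [1.0e-10, 1.0e-2]
  log_uniform: true
  negative_mix: {numeric: 0.5, zero: 0.25, na: 0.25}
- name: TripletSVM
  output_kind: binary
  positive_token: "1"
  negative_tokens: ["NA"]
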