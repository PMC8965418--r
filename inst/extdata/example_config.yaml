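# Example run configuration for the foidecomp pipeline.
seed: 1
mcmc:
  n_chains: 3
  n_iter: 30000
  burn_in: 15000
paths:
  field: results/field_survey.csv
  sentinel: results/sentinel_trials.csv
  contact: results/contact_trials.csv
  transmission: results/transmission.csv
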