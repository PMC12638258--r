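# Smoke-test pipeline configuration: a small synthetic cohort through
# every stage. Run from the repository root:
#   Rscript inst/cli/metaphenome.R all --config inst/extdata/smoke_config.yaml --out scratch/smoke --seed 7
seed: 7
simulate:
  n_participants: 2000
  n_metabolites: 12
scan:
  min_cases: 40
preonset:
  min_cases_per_bin: 5
metrs:
  k: 5
  top_k: 8
  B: 100
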