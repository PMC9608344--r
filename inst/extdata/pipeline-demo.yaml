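# Demo pipeline configuration: 20-patient synthetic cohort at FSAverage
# resolution, full sweep, all pairwise group comparisons, one classification
# experiment. Run with:
#   Rscript inst/scripts/gm-connect.R run --config inst/extdata/pipeline-demo.yaml --out demo-out
seed: 1
cohort:
  n_patients: {CIS: 5, RR: 5, PP: 5, SP: 5}
  n_scans: null
  mean_scans_per_patient: {CIS: 3, RR: 3, PP: 3, SP: 3}
  q: 68
pipeline:
  tau: 0.7
  stat_pairs: all
  experiments: ['RR:PP']
  taus: [0.6, 0.65, 0.7, 0.75, 0.8]
  minimal: true
  k: 5
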