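# Demo configuration: 200-sample SV-dense cohort on a 60-Mb genome with
# three planted recurrent-breakpoint loci, one planted juxtaposition and
# a small method p-value matrix. Drives `svdriverscan run` /
# run_pipeline() end to end.
seed: 11
n_samples: 200
rearr_per_sample: 6
n_rows: 300
n_methods: 4
n_driver_rows: 5
q_threshold: 0.1
srb_spikes:
  - bin: 77
    fold: 5
    regime: dispersed
  - bin: 250
    fold: 5
    regime: clustered
  - bin: 520
    fold: 5
    regime: dispersed
srj_spikes:
  - bin_i: 150
    bin_j: 430
    frequency: 0.04
driver_elements: [1, 2, 3, 4, 5]
driver_frequency: 0.05
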