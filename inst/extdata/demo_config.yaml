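# Desk-scale demonstration run: simulate a study, build kernels, fit GTCBLUP
# with a reduced chain, and evaluate by forward validation on generation 11.
seed: 1
out_dir: omicsblup_demo
model: GTCBLUP
simulate:
  n_individuals: 240
  n_markers: 400
  n_genes: 120
  generation_sizes:
    "4": 24
    "5": 24
    "7": 96
    "11": 96
chain:
  n_iter: 4000
  burn_in: 1000
  thin: 5
split:
  validation_generation: "11"
evaluate:
  n_boot: 2000
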