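# Pipeline configuration for a between-subject design with a skilled
# demonstrator: 3 sessions of five 20-trial blocks (one private block, four
# observational), stable 0.6/0.4 contingencies, 1:1 observational:private
# ratio.
task:
  experiment: exp2        # exp1 | exp2 | exp3
  condition: SD           # demonstrator group for between-subject designs
cohort:
  n_subjects: 20
models: [RW2, DB6, MB9, VS2]
fitting:
  objective: nll          # nll | lpp
  n_restarts: 10
generate:                 # used by the 'simulate' stage
  model: VS2
  params:                 # omit to draw each subject's parameters from the priors
    alpha_p: 0.3
    alpha_i: 0.25
    beta: 5
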