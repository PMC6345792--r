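# Example configuration: dual-reporter bursty expression with lognormal
# interdivision times, decomposed by the age-resolved LNA solver.
preset: bursty
method: lna_numeric
ensembles: [population, lineage]
solver:
  tol: 1.0e-8
  damping: 0.5
  grid_n: 400
simulation:
  mode: constant_N
  n_max: 1000
  t_final: 20
seed: 1
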