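# lineagenoise

Noise decomposition for stochastic gene expression in growing, dividing
cell populations.

## The problem

Gene-expression variability measured across a clonal population mixes two
very different things: *intrinsic* noise from the stochastic firing of
biochemical reactions (and the random partitioning of molecules at
division), and *extrinsic* noise shared by co-expressed reporters. Even
with fixed rate constants, a growing population generates extrinsic noise
on its own: molecule numbers must double over each cell cycle, cells in a
snapshot are caught at different cell-cycle ages, and interdivision times
fluctuate between cells. Worse, the statistics depend on how the cells are
observed — a snapshot of a growing population over-represents fast-dividing
cells, while an isolated lineage tracked through divisions (the
mother-machine setting) does not — so the same circuit shows different
means and noise levels in the two settings.

`lineagenoise` is for quantitative/systems biologists who want to compute,
decompose and cross-validate these statistics for arbitrary intracellular
reaction networks, and to compare mother-machine, time-lapse and
flow-cytometry-style measurements within one framework.

## What it computes

For an interdivision-time law φ(τ_d) the package derives the population
growth rate λ from the Euler–Lotka equation
`1 = 2 ∫ exp(-λ τ_d) φ(τ_d) dτ_d`, the snapshot age distribution
`Π(τ) = 2λ e^{-λτ} S(τ)`, the population interdivision law
`ρ(τ_d) = 2 φ(τ_d) e^{-λ τ_d}` and their lineage counterparts π(τ), φ.
Given a reaction network (mass-action, geometric-burst production and
Hill-repressed transcription are built in), it solves the age-resolved
linear-noise-approximation moment equations

    dE[x|τ]/dτ   = Σ_r ν_r w_r(E[x|τ])
    dΣ_int/dτ    = J Σ_int + Σ_int Jᵀ + D        (biochemical noise)
    dΣ_ext/dτ    = J Σ_ext + Σ_ext Jᵀ            (transported only)

subject to the cell-division boundary conditions (means halve; binomial
partitioning feeds Σ_int, interdivision-time variability feeds Σ_ext) by a
shooting method, and averages over age to obtain the decomposition

    Σ̄ = Σ̄_int + Σ̄_cc + Σ̄_age

into intrinsic, transmitted-cell-cycle and cell-age components — the
latter two being exactly what a dual-reporter experiment reports as
extrinsic covariance. For linear networks an exact algebraic route
(`linear_exact()`) and fully explicit bursty-reporter formulas
(`closed_form_bursty()`, `intrinsic_peak_age()`) are provided, plus
feedback-strength sweeps and minimisers for an autoregulatory circuit.
An exact event-driven agent-based simulator (`simulate_population()`,
`simulate_lineage()`, C++ core) with dual-reporter estimators
(`estimate_decomposition()`) cross-validates every analytic result.

## Worked example

A stable protein produced in geometric bursts (rate k0 = 10, mean burst
size b = 10) in cells with lognormal interdivision times (unit mean,
CV = 1):

```r
library(lineagenoise)
model <- interdivision_model("lognormal", mean = 1, cv = 1)
ps <- population_structure(model)
ps
#> Population structure (lognormal interdivision times, mean 1, cv 1)
#>   growth rate lambda = 0.91517115 (Euler-Lotka residual 0.00e+00)
#>   E_phi[tau_d] = 1         CV2_phi = 1
#>   E_rho[tau_d] = 0.611876  CV2_rho = 0.558904
#>   E_Pi[tau]    = 0.480816  CV2_Pi  = 1.02058
#>   E_pi[tau]    = 1         CV2_pi  = 1.66667

net <- builtin_network("bursty_reporter", k0 = 10, b = 10)
rbind(as.data.frame(linear_exact(net, ps, "population")),
      as.data.frame(linear_exact(net, ps, "lineage")))
#>   species   ensemble       method  mean cv2_int  cv2_cc cv2_age cv2_ext cv2_tot
#> 1 Protein population linear_exact 109.3 0.12386 0.05842  0.1976   0.256  0.3799
#> 2 Protein    lineage linear_exact 200.0 0.07167 0.08333  0.4167   0.500  0.5717
```

The same cell expresses on average 109 proteins when sampled across a
population snapshot but 200 when tracked as an isolated lineage — fast
dividers dominate snapshots and accumulate less protein. Intrinsic noise
(CV² 0.124 vs 0.072) is correspondingly *higher* in snapshots, while the
extrinsic (cell-cycle plus age) component is *lower* (0.256 vs 0.500).

The exact agent-based simulator reproduces this from raw dual-reporter
cells:

```r
snap <- simulate_population(duplicate_reporters(net), model, t_final = 25,
                            mode = "constant_N", n_max = 1e4, seed = 1)
estimate_decomposition(snap, n_boot = 100)$pooled
#>   species  mean sigma_int sigma_ext sigma_tot se_sigma_int se_sigma_ext ...
#> 1 Protein 109.9      1444      3074      4518        29.02        95.04
```

(theory: mean 109.3, Σ_int = 1478, Σ_ext = 3056 — all within two standard
errors). The age of maximal intrinsic noise for b = 10 is
`intrinsic_peak_age(10)` = 0.270 of the mean population interdivision
time, approaching 1/3 for large bursts.

A thin command-line interface over the same functions lives in
`inst/scripts/lineagenoise.R` (commands `growth`, `decompose`, `simulate`,
`validate`, `sweep`, driven by a YAML config; see
`inst/extdata/example_config.yaml`).

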