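# nucleokit

Tools for quantifying the nucleation barriers that make protein-assembly
switches binary — built around DAmFRET-style single-cell flow cytometry,
stochastic nucleation kinetics, fluorescence-image quantification, and
monomer-versus-polymer structural comparison.

## The problem this package addresses

Signalosomes such as the CARD–BCL10–MALT1 (CBM) complex activate NF-κB in
all-or-none fashion: stronger stimulation recruits *more* responding cells
without changing the response level *within* a cell. This behavior arises
when the adaptor protein is constitutively **supersaturated** — expressed
above its solubility limit but held soluble by a kinetic **nucleation
barrier** — so that a single templated nucleation event flips the whole
cellular pool from monomer to polymer. `nucleokit` is aimed at
quantitative cell biologists and biophysicists who need to detect and
measure such barriers.

The central readout is DAmFRET: per-cell AmFRET
(FRET intensity / acceptor intensity) versus expression across ~4 decades,
~5×10⁵ cells per sample. Cells above a negative gate built from a monomeric
control are scored assembled; the assembled fraction in 64 logarithmically
spaced expression bins is fit to a Weibull concentration-response

    F(c) = A · (1 − 2^−(c/EC50)^δ)

so that **EC50** is the median concentration at which nucleation occurs and
**δ** (delta) is a dimensionless proxy for the conformational contribution
to the nucleation barrier (larger δ = nucleation less dependent on
concentration). Profiles are classified *monomer*, *continuous*, or
*discontinuous* (nucleation-limited: a bimodal AmFRET split whose two
populations overlap in expression).

Because no single-cell cytometry or imaging raw data are publicly deposited
for this system, the package ships a first-class synthetic-data module that
generates event tables, kinetic cohorts, and microscopy fields with known
ground truth, against which every estimator is validated.

## Worked example

Simulate one DAmFRET sample of a nucleation-limited polymer (EC50 = 100
a.u., δ = 3) plus a monomer control, build the negative gate, bin, fit and
classify:

```r
library(nucleokit)

params  <- damfret_params(n_cells = 1e5, ec50 = 100, delta = 3, seed = 1)
events  <- simulate_population(params)
control <- simulate_population(
  damfret_params(n_cells = 1e5, archetype = "monomer", seed = 2))

gate  <- build_negative_gate(gate_events(control, acceptor_min = 20))
gated <- gate_events(events, acceptor_min = 20)
bins  <- bin_fraction_assembled(gated, gate)
fit   <- fit_weibull(bins, events = gated, gate = gate,
                     n_boot = 200, seed = 3)
fit
#> <damfret_fit>
#>   EC50: 100.1 a.u.   delta: 2.942   plateau: 1
#>   weighted RSS: 1.686 on 64 bins (67465 events)
#>   95% bootstrap CI: EC50 [99.14, 100.9], delta [2.845, 3.024]

classify_profile(gated, gate, fit)
#> [1] "discontinuous"

tidy(fit)
#> # A tibble: 3 × 4
#>   term    estimate conf.low conf.high
#>   <chr>      <dbl>    <dbl>     <dbl>
#> 1 ec50      100.      99.1     101.
#> 2 delta       2.94     2.84      3.02
#> 3 plateau     1        1         1
```

The fitted EC50 (100.1 a.u.) and δ (2.94) recover the generating values
(100, 3) within the bootstrap intervals, and the profile is called
discontinuous — the supersaturation signature: monomer and polymer
populations coexisting across overlapping expression levels.
`autoplot(fit)` draws the binned fractions with the fitted curve, and
`plot_damfret(events, gate)` the underlying two-dimensional histogram.

The same grammar drives the other modules: `simulate_kinetics()` +
`dose_response_summary()` for hazard-based binary-activation kinetics,
`render_field()` + `quantify_field()` for CV-based puncta calling and
nuclear/cytoplasmic ratios, `structure_rmsd()` for monomer-versus-polymer
Cα RMSD, and `run_pipeline()` to orchestrate simulate → analyze from one
seeded YAML/list configuration.

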