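# mapkrewire

Tools for analyzing synthetic kinase–substrate rewiring circuits in
which a MAP kinase (the yeast mating-pathway MAPK Fus3, or a
constitutively active human ERK2) is redirected — via modular protein
interaction domains and a phosphodegron — to phosphorylate an arbitrary
reporter substrate and send it to SCF/Cdc4-mediated, proteasomal
degradation. The package is aimed at systems/synthetic biologists who
characterize such circuits by flow cytometry: it covers event-level
simulation, the standard cytometry processing steps, steady-state
dose–response modeling and fitting, and a mechanistic kinetic model of
the degradation arm.

## What it computes

**Cytometry processing.** Raw per-event tables (FSC-A, FL1-A, event
time) are corrected per instrument dialect (Accuri: zeros → 1; VYB:
shift by |batch minimum| + 1), optionally gated for transient anomalies
on FSC-A vs. time, and size-normalized by dividing fluorescence by
FSC-A — which removes the strong fluorescence–size correlation and
substantially reduces the population CV. Populations are summarized by
median, interquartile range and CV, and compared as fold changes
(untreated/treated, so degradation gives values > 1).

**Steady-state dose–response models.** Pathway output versus pheromone
dose *x* (µM α-factor) is described by a saturating Hill form

    Y(x) = A + B·xⁿ / (1 + C·xⁿ)

with baseline *A*, induced span *B/C*, and apparent Hill coefficient
*n*. A hybrid incoherent feed-forward loop (the kinase both drives
reporter transcription and degrades the reporter protein) is described
by the band-pass form

    Y(x) = A + [B·xⁿ / (1 + C·xⁿ)] · (1 + E·x) / (1 + D·x)

which reduces exactly to the Hill model when D = E and has an interior
maximum (`bandpass_peak()`) when the degradation arm dominates at high
dose. Fitting (`fit_hill()`, `fit_iffl()`, `fit_hill_joint()`) is
bounded Levenberg–Marquardt least squares on per-dose medians with a
deterministic multistart grid; joint fits can tie any subset of
parameters (typically the saturation coefficient *C*) across
conditions, and `bootstrap_uncertainty()` resamples events within each
dose for percentile intervals.

**Kinetic model.** `simulate_kinetics()` integrates active kinase,
free, complexed and phospho-tagged substrate, with scenario switches
for every control class: dead kinase, broken degron, mismatched
interaction domains, ABA-inducible binding, swapped domain orientation,
constitutively active kinase, pathway-driven (pFUS1) reporter
transcription, and competition for the shared Ste7 or SCF pools.
Phosphorylation scales with degron count up to a saturation count of 3.

**Synthetic data.** Because event-level cytometry data for such
circuits are rarely deposited, `population_spec()` /
`generate_population()` / `generate_dose_series()` /
`generate_timecourse()` produce seeded event tables (log-normal size
and concentration, fluorescence = size × concentration +
autofluorescence, instrument dialects) so the whole pipeline is
testable end to end.

## Worked example

Simulate the fully functional constitutive circuit (10 µM α-factor at
t = 0), generate matching event-level populations, process them, and
measure the fold drop:

```r
library(mapkrewire)

p <- kinetic_params()
traj <- simulate_kinetics(p, scenario(), list(alpha = 10, aba = 0),
                          times = seq(0, 180, by = 60))
round(traj[c("time", "S", "Sp", "Kstar", "total")], 3)
#>   time      S    Sp Kstar  total
#> 1    0 83.333 0.000 0.000 83.333
#> 2   60 24.760 1.767 0.154 26.527
#> 3  120 21.114 1.486 0.154 22.600
#> 4  180 20.904 1.470 0.154 22.374

spec <- population_spec(n_events = 10000, seed = 1)
tc <- generate_timecourse(spec, p, c(0, 180), scen = scenario(),
                          inputs = list(alpha = 10))
summ <- lapply(tc, function(t)
  summarize_population(size_normalize(clean_events(t))))
summ[["0"]]
#> <population_summary> fl1_a_norm: median=0.02065 IQR=[0.01752, 0.02416] CV=0.244 n=10000
summ[["180"]]
#> <population_summary> fl1_a_norm: median=0.006052 IQR=[0.005197, 0.007004] CV=0.227 n=10000

fc <- fold_change(summ[["0"]], summ[["180"]])
fc$fold
#> [1] 3.41
```

The kinetic trajectory shows the reporter pool dropping ~3.7-fold at
the concentration level; the measured median fold through the full
event pipeline is slightly smaller (3.41) because autofluorescence adds
a floor to both medians. The interior maximum of the canonical
band-pass response is analytic:

```r
bandpass_peak(iffl_params(A = 0, B = 1, C = 1, n = 2, D = 1, E = 0))
#> [1] 1.52138   # the real root of x^3 - x - 2 = 0
```

A whole run (simulate → process → fit → classify) is driven from one
YAML config with `run_pipeline()`, or from the shell via the thin
wrapper `inst/cli/mapk-rewire` (`run`, `process`, `fit`, `classify`
subcommands).

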