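---
title: "Methods: modeling retargeted MAPK degradation circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling retargeted MAPK degradation circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkrewire)
```

# The system

A MAP kinase can be redirected to an arbitrary substrate when two
conditions hold: the kinase and substrate carry matching protein
interaction domains (mPDZ/PDZ-ligand, SH3, SYNZIP, or the
ABA-inducible PYL/ABI pair), and the substrate carries a phospho-motif
that, once phosphorylated, recruits a downstream effector. When that
motif is a phosphodegron recognized by the F-box protein Cdc4,
phosphorylation recruits the SCF ubiquitin ligase and the substrate is
degraded by the proteasome. With a fluorescent reporter as substrate,
circuit activity is read out as a drop in per-cell fluorescence by flow
cytometry. This package implements the quantitative side of that
experimental program: event-level simulation, cytometry processing,
steady-state response models with fitting, and a mechanistic kinetic
model with switches for every control strain class.

# Steady-state response models

Pathway output versus pheromone dose $x$ (µM $\alpha$-factor) is
modeled as

$$Y(x) = A + \frac{B x^n}{1 + C x^n},$$

with baseline $A$ (normalized-fluorescence units), induced span $B/C$,
saturation coefficient $C$ (µM$^{-n}$) and apparent Hill coefficient
$n$. The hybrid incoherent feed-forward loop — kinase activity both
drives reporter transcription and degrades the reporter protein — uses
the phenomenological band-pass form

$$Y(x) = A + \frac{B x^n}{1 + C x^n}\cdot\frac{1 + E x}{1 + D x},$$

which reduces exactly to the Hill form when $D = E$ and develops an
interior maximum when the decaying factor ($D > E$) overtakes the
saturating Hill term.

**Equation grouping.** Whether the $(1+Ex)/(1+Dx)$ factor should also
multiply the baseline $A$ is genuinely ambiguous in this model family.
We adopt the grouping in which the factor multiplies only the induced
term, because $A$ represents dose-independent background
(autofluorescence plus leaky expression) that the degradation arm does
not act on; the alternative grouping is available via
`iffl_params(..., baseline_modulated = TRUE)`.

**Derived metrics.** `max_activation()` returns $A + B/C$.
`percent_reduction()` compares two fitted curves as
$100(1 - \mathrm{max_{fb}}/\mathrm{max_{ctrl}})$; by default it uses
the induced span $B/C$ rather than $A + B/C$, since baseline background
should not count as pathway activation — both variants are exposed.
`bandpass_peak()` brackets the interior maximum on a 4000-point
log-spaced grid over $[10^{-6}, 10^{6}]$ µM and refines it with
golden-section search; a plateau or boundary maximum returns `NA`.
`classify_response()` labels a sampled curve band-pass if an interior
point exceeds both endpoints by more than `rel_tol * max(signal)`
(default `rel_tol = 0.05`, chosen so event-sampling noise on ~10⁴-event
medians does not create spurious peaks), amplifier if the final dose
carries the maximum, and flat otherwise.

# Fitting

Fits minimize squared residuals of per-dose medians (the quantity
plotted in dose-response panels) with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`), bounds $A,B \ge 0$, $C > 0$, $0 < n \le 10$ and
$D, E \ge 0$. The upper bound on $n$ prevents runaway cooperativity on
sparse dose grids. The loss is unweighted by default; `inv_iqr`
weighting (1/IQR per dose) is available. Multistart uses a
deterministic grid — $A$ from the minimum median, $C \in \{0.1, 1,
10\}$, $B = \mathrm{span}\cdot C$, $n \in \{1, 2, 4\}$, and $D, E \in
\{0.01, 0.1, 1\}$ for the IFFL model — and reports the best
(lowest-RSS) converged start, so fits are reproducible without a seed.

Degenerate inputs are flagged, not silently fitted: a flat curve
returns `unidentifiable = TRUE` with `converged = FALSE`, and an IFFL
fit whose $\hat D \approx \hat E$ warns that the inhibitory arm is
unidentifiable (the data are effectively Hill). Joint fits
(`fit_hill_joint()`) optimize the concatenated residuals with any
subset of $\{A, B, C, n\}$ tied across conditions; because the tied
model is nested in the free one, its RSS can never be smaller, which
the tests assert on every fixture.

IFFL fits normalize medians to the untreated (zero-dose) condition
first, the convention for band-pass dose-response data; disable with
`normalize = FALSE`.

**Bootstrap.** `bootstrap_uncertainty()` resamples events with
replacement within each dose, recomputes medians, and refits from the
full-data point estimate (a standard and much faster choice than
re-running the multistart, and safe because resampled curves lie close
to the original). Percentile 2.5/97.5 intervals are reported; more than
20% failed refits is an error. The source study reports no fit
uncertainties, so this procedure is the package's own.

# The kinetic model

States: active kinase $K^*$, free substrate $S$, kinase–substrate
complex $C$ (explicit-binding mode only) and phospho-tagged substrate
$S_p$; the observable reporter is $S + C + S_p$.

* Kinase activation: $dK^*/dt = k_{act}\,\theta_\alpha\,(K_{tot} -
  K^*) - k_{inact}K^*$ with receptor occupancy $\theta_\alpha =
  \alpha/(K_\alpha + \alpha)$. A Michaelis form is used because no
  upstream dose-transfer function is measured for this system;
  cooperativity observed in fitted dose responses is carried by the
  phenomenological $n$, not imposed mechanistically.
* Colocalization: by default binding is treated as a quasi-steady-state
  occupancy $\beta = 1/(1 + K_{bind}/K_{tot})$ (scaled by the ABA Hill
  term $aba^{n_{aba}}/(K_{aba}^{n_{aba}} + aba^{n_{aba}})$ in inducible
  mode, by 0.5 for the swapped domain orientation, and 0 for mismatched
  domains). This avoids the stiffness of explicit association kinetics;
  the explicit-complex mode (`binding = "explicit"`, $k_{on} =
  k_{off}/K_{bind}$) exists chiefly so that mass conservation can be
  checked on the full species set.
* Phosphorylation: rate $k_{phos}\min(m, m_{sat})\,\beta\,K^*$ acting
  on $S$, with degron count $m \in \{0..5\}$ and saturation count
  $m_{sat} = 3$ — the simplest form consistent with a degradation rate
  that grows with one to three degrons and plateaus beyond. A smooth
  Michaelis alternative with the same asymptote sits behind
  `smooth_saturation = TRUE`.
* Degradation and turnover: $S_p$ is degraded at $k_{deg}$ (throttled
  by $\mathrm{scf}/(\mathrm{scf} + \sum S_p)$ when the SCF capacity is
  finite), dephosphorylated at $k_{deph}$, and all species dilute at
  $k_{dil}$. Unphosphorylated degron-bearing substrate is additionally
  degraded at $k_{basal}\min(m, 5)$, capturing the lower steady-state
  expression of multi-degron reporters through weak phospho-independent
  engagement of the degradation machinery. Because that basal arm is
  phospho-independent, it remains active in all three negative controls
  (dead kinase, broken degron, mismatched domains), which are therefore
  trajectory-equivalent — a property the tests assert pairwise.
* Pathway-driven reporter (`promoter = "pfus1"`): synthesis becomes
  $k_{syn}\,[\ell + (1-\ell)\,h(K^*/K_{tot})]$ with a transcriptional
  Hill function $h$ (half-activation $K_{tx}$, coefficient $n_{tx}$)
  and leak $\ell$. Transcription saturates at lower pheromone doses
  than the degradation arm (which keeps growing with $K^*$), and a
  band-pass dose response emerges from the mechanism rather than being
  imposed.
* Competition: a second kinase draws on a conserved Ste7 pool
  (activation flux scaled by $P/(P + \sum(K_{tot}-K_i))$); a second
  degron substrate shares the SCF capacity. Infinite pools (the
  default) recover independence exactly.

Integration uses `deSolve::ode` (lsoda, stiff-capable) with `rtol =
1e-8`, `atol = 1e-10`. `steady_state()` solves the fixed point
directly — the kinase balance in closed form (scalar root under finite
Ste7), then the linear substrate subsystem (a scalar root in $S_p$
under finite SCF) — and verifies the residual against the ODE
right-hand side.

## Parameter defaults are calibration choices

No rate constants are measured for this system, so every default in
`kinetic_params()` is a documented calibration, chosen once: dilution
$k_{dil} = 0.01\,\mathrm{min}^{-1}$ (slow log-phase growth), activation
$k_{act} = 0.1$, $k_{inact} = 0.5\,\mathrm{min}^{-1}$ (so the active
fraction rises roughly linearly with receptor occupancy and does not
saturate until several µM pheromone), $K_{bind} = 0.25\,K_{tot}$ (80%
occupancy for constitutive domains), $K_{aba} = 1$ µM with $n_{aba} =
2$ (response emerging around 1 µM ABA), swapped-orientation efficiency
0.5 (fold change roughly half of the original orientation), and
$k_{phos} = 0.32\,\mathrm{min}^{-1}$ — set so that the fully functional
constitutive circuit shows a ~3.7-fold reporter drop three hours after
saturating (10 µM) pheromone, the benchmark magnitude for this circuit
class. The pFUS1 parameters ($K_{tx} = 0.02$, $n_{tx} = 2$, leak 0.05)
place the emergent band-pass peak in the 0.1–1 µM range with a clear
decline toward 10 µM.

# The synthetic-data generator

`generate_population()` draws cell size (FSC-A proxy) and reporter
concentration from log-normal distributions — strictly positive and
right-skewed, as cytometry scatter and expression data are — with the
CV mapped to log-space sigma via $\sigma = \sqrt{\log(1 + cv^2)}$ and
the median to the log-mean, so `response_scale` acts exactly on the
concentration median. Fluorescence is size × concentration +
autofluorescence plus proportional measurement noise (default SD 1% of
signal; no instrument noise model is published, so this is a free
default). The `accuri` dialect floors values at zero; the `vyb`
dialect adds baseline noise (default SD 20 units) and can go negative.
Event times are uniform over a 60 s read, supporting anomaly-gating
tests. Defaults (10⁴ events, size CV 0.35, concentration CV 0.25)
produce the strong fluorescence–size correlation that motivates
normalization; the exact correlation strength in real data is not
printed anywhere, so these are realistic free parameters, not
calibrated constants.

What the generator does *not* emulate — doublets, debris, spectral
spillover, day effects, autofluorescence heterogeneity — bounds what
passing tests show: the pipeline is correct for populations with
independent log-normal size and expression, which is the structure the
processing steps assume, and nothing here validates performance against
instrument artifacts beyond simple transient FSC bursts.

# Cytometry processing choices

* Zero/offset rules: Accuri zeros → 1; VYB values shifted by the
  absolute batch minimum + 1. The batch is the table by default; a
  day-level shared minimum can be passed (`batch_min`) since offsets
  are defined per acquisition day.
* Anomaly gating is off by default (the original procedure was visual
  inspection); when on, it removes events deviating from a centered
  running median of FSC-A (window ≈ 5 s of events) by more than 5
  robust SDs (1.4826 × MAD). Note that heavy log-normal size tails can
  legitimately exceed 5 robust SDs in large clean reads; the gate
  targets transients, and the threshold is configurable.
* Quantiles use linear interpolation (type 7), R's default; no
  quantile rule is published for this procedure.
* CV is sd/mean of the linear-scale normalized signal. Whether
  published CV-reduction figures were computed on linear or
  log-transformed signal is unstated; linear is the package's
  documented default, and the choice matters when comparing magnitudes.
* Fold change is oriented untreated/treated so degradation gives
  values > 1, with `log10_fold` as companion.

# Numerical and testing notes

Tests run on reduced problem sizes chosen to keep the suite fast while
leaving sampling error well below the asserted tolerances: populations
of 2–10 thousand events, Monte-Carlo oracles at 10–20× the tested
sample, 50-replicate recovery studies at 1% noise, and a 100-replicate
bootstrap coverage study (10 doses × 400 events, 200 resamples).
Independent oracles are kept independent: a hand-rolled fixed-step RK4
integrator for trajectories, an eigen-decomposition matrix exponential
for the linear regime, brute-force log-grid argmax for band-pass peaks,
and plain Monte-Carlo for distributional quantities.

# Known limitations

The kinetic model omits nuclear/cytoplasmic compartments, ubiquitin
chain dynamics, scaffold assembly, and stochastic single-cell effects;
upstream cascade feedback is represented only phenomenologically
through the fitted Hill coefficient. The FCS writer emits minimal FCS
3.0 (list mode, float, one dataset) — sufficient for standard parsers,
not a general FCS implementation. Fitted parameters from median-level
least squares are estimators of convenience: the loss, weighting and
optimizer used for any particular published fit are typically
unstated, so numerical agreement with published parameter values
should not be expected even on comparable data.
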