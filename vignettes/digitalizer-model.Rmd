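---
title: "The digitalizer switch: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The digitalizer switch: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digitalizer)
```

## The model

The digitalizer couples an inducible expression device to a post-
transcriptional mutual-inhibition loop. An inducible promoter P1 transcribes
a bicistronic mRNA (`mR`) carrying a transcriptional repressor (`R`,
LacI-like) translationally coupled to the gene of interest; a strong,
R-repressible promoter P2 transcribes a small antisense RNA (`mS`) that pairs
with `mR`, blocks its translation and triggers degradation of both molecules.
`R` shuts P2 down, so the two RNAs are mutually inhibitory: whichever species
dominates eliminates the other.

We model this with four ODEs over concentrations (nM, minutes):

$$\frac{dmR}{dt} = \beta_R + \alpha_R\,\frac{x^{n_{act}}}{K_{TF}^{n_{act}}+x^{n_{act}}}
  - (\delta_{mR}+\mu)\,mR - k_{pair}\,mR\,mS$$
$$\frac{dmS}{dt} = \alpha_S\,\frac{K_R^{n_{rep}}}{K_R^{n_{rep}}+R^{n_{rep}}}
  - (\delta_{mS}+\mu)\,mS - k_{pair}\,mR\,mS$$
$$\frac{dR}{dt} = \lambda_R\,mR - (\delta_R+\mu)\,R,\qquad
  \frac{dG}{dt} = \lambda_G\,mR - (\delta_G+\mu)\,G$$

Assumptions worth making explicit:

* **The input is the active transcription factor.** The dose axis is the
  concentration $x$ of inducer-bound TF; no inducer-binding submodel is
  attached. Doses in chemical units map to $x$ by identity scaling.
* **Pairing is irreversible co-degradation.** One `mR` and one `mS` are lost
  per pairing event, with a single bimolecular rate `k_pair`. Chaperone
  (Hfq-type) kinetics are folded into this constant.
* **Translational coupling is shared transcript usage.** `R` and `G` are
  translated from the same `mR` with their own rates `lambda_R`, `lambda_G`;
  there is no separate coupling efficiency or maturation delay.
* **P2 has no basal leak.** Its only regulation is repression by `R`.
* **Growth is not modelled.** `mu` defaults to zero; for stable proteins the
  decay constants `delta_R`, `delta_G` play the role of effective dilution.
  Growth-phase-dependent promoter activity (the slow basal creep of leaky
  devices in late cultures) is outside the model.

## Baseline parameters and why

```{r}
unlist(digitalizer_params())
```

| parameter | value | meaning |
|---|---|---|
| `alpha_R`, `beta_R` | 10, 0.075 nM/min | induced / basal P1 transcription; a strong promoter with <1% leak |
| `K_TF`, `n_act` | 100 nM, 2 | half-activation and cooperativity of P1 (dimeric activator) |
| `alpha_S` | 5 nM/min | sRNA synthesis rate from the strong P2 |
| `K_R`, `n_rep` | 5000 nM, 2 | half-repression of P2 by R (R binds as an oligomer) |
| `k_pair` | 1 /(nM·min) | pairing/co-degradation, tuned-for-strength antisense |
| `delta_mR`, `delta_mS` | 0.2 /min | ~3.5 min RNA half-lives |
| `delta_R`, `delta_G` | 0.01 /min | stable proteins; effective dilution at ~70 min doubling |
| `lambda_R`, `lambda_G` | 2 /min | translation per transcript |

The load-bearing choice is the **sRNA threshold condition**
$\beta_R \ll \alpha_S < \beta_R + \alpha_R$: uninduced transcription
(0.075 nM/min) is 60-fold below the sRNA supply (5 nM/min), so basal `mR` is
destroyed stoichiometrically and the OFF state is effectively zero; full
induction (10 nM/min) outruns the supply, and the excess `mR` accumulates,
builds `R`, and shuts P2 off entirely. This is the canonical operating point
for sRNA–mRNA co-degradation switches, and it is what makes the device
*digital* rather than merely dimmed.

Three package-level constants were fixed once from this baseline and are used
by the analyses rather than being re-derived per call: the pivot-spread
tolerance (0.25) and RNA-exclusivity threshold (0.1) used to summarise sweep
geometry (the source figures state these properties only qualitatively), and
the hysteresis flag at $10^{-3}$ of the dynamic range.

Parameter sets with a much larger sRNA pool and a much stronger
transcriptional repressor (e.g. `alpha_S = 50`, `K_R = 20`) make the loop a
classic bistable toggle: both branches are stable across most of the dose
axis and the up/down sweeps separate (`hysteresis_scan()` flags this). The
baseline deliberately sits in the monostable regime, consistent with the
de-induction symmetry the device family shows experimentally.

## Dose–response geometry and the sweep

`dose_response()` computes steady states by continuation: each dose is solved
by integrating from the previous dose's state (up-sweep from the uninduced
state, down-sweep from a fully induced one) followed by a damped Newton
refinement, accepted when the residual falls below $10^{-9}(1+\lVert y\rVert)$.
Continuation makes bistable branches discoverable and reproducible; on a
monostable system both directions coincide to solver precision.

`response_metrics()` reports OFF level (dose 0), ON level (top dose), fold
change, EC50 and the 10–90% transition width by monotone linear interpolation
on the **linear** dose axis (a log-axis variant exists but is not used in the
package's own analyses), plus an effective Hill coefficient from a
four-parameter least-squares fit. Degenerate (flat) curves raise an error
rather than returning NaNs. Solver-level wiggles are absorbed with a running
maximum before interpolating; the default dose grid (`default_dose_grid()`)
is dose 0 plus 241 log-spaced points over 0.1–1000 nM.

`repression_sweep()` scales both arms jointly: strength $s$ multiplies
`k_pair` and divides `K_R`. We deliberately do **not** scale `alpha_S` with
$s$: the sRNA supply rate sets the OFF→ON threshold itself, so scaling it
would move the pivot with the colour axis and (for $s\ge 3$) push the supply
above the maximal transcription rate, freezing the switch OFF. With the
chosen scaling the sweep reproduces the expected fan: OFF levels drop
~1/s, fold change rises monotonically (2.8×10³ → 4.9×10⁵ across
$s\in\{0.3..30\}$), and the transition crosses a pivot near 100 nM whose
relative spread over $s\in\{3,10,30\}$ is 0.09.

**A known limitation of the 10–90% width as a sharpness measure.** The width
shrinks strongly while the transition is a smooth crossover (312 → 238 →
198 nM for $s = 0.3, 1, 3$) but saturates once the up-sweep transition
becomes a fold-bifurcation jump ($s \ge 10$): past the jump, the remaining
climb to 90% of the range is the analog tail of the P1 activation Hill
function, which is the same for every strength, while the fold dose itself
still creeps downward. The grid-free widths at $s = 10$ and $s = 30$ are
192.7 and 193.2 nM — equal to within 0.3%, with the *larger* strength very
slightly wider. This is structural, not numerical: making the jump span the
full range would require the sRNA supply to sit at ~90% of the induced
transcription rate, which (given monostability of the baseline, i.e. no
hysteresis) would put the OFF→ON threshold above the reachable production
rate and the switch would never turn on; conversely, de-induction symmetry
requires the ON state to silence P2, which is exactly what creates the fold.
The package therefore treats "sharper with stronger repression" as a
crossover-regime statement; at strong repression the transition is already
maximally sharp (a discontinuous jump) and the metric measures the input
function instead of the switch.

## De-induction

`deinduction()` induces for `t_on` minutes, removes the inducer, and follows
both the digitalized circuit and its non-digitalized parent (`alpha_S = 0`)
with identical solver settings, normalising `G` by its value at removal. At
baseline the post-removal decay curves of the two constructs differ by at
most ~1.3% (sup-norm): after removal the ON-state `R` pool keeps P2 silenced
for about a repressor lifetime, so both constructs' mRNA decays at the same
rate and `G` falls at `delta_G + mu` in both — the model's account of why
induction strength, not circuit memory, governs de-induction. The residual
difference is the non-digitalized basal floor (`beta_R` leak) plus a small
early-time mRNA-tail asymmetry.

## Stochastic layer

The count-level model uses the same nine reaction channels with propensities
equal to the ODE fluxes evaluated at `counts/omega` times `omega`
(`build_reactions()` is the readable specification; the simulator implements
it in C++). Hill propensities are used as-is at the count level — no
elementary operator-binding reactions — which matches the ODE reduction and
is noted as an approximation. Dilution (`mu`) folds into the first-order
decay channels, which has the identical propensity to an explicit dilution
channel.

Sampling is the exact direct method. Per-cell randomness comes from a
counter-based 64-bit hash of `(seed, cell_index)`, so populations are
reproducible and independent of simulation order; protocol breakpoints are
handled by discarding and re-drawing the waiting time (valid by
memorylessness). Correctness anchors in the test suite: a frozen birth–death
subsystem must reproduce the Poisson stationary law (mean = variance within
3 SE at 500 cells), population means must approach the ODE as `omega` grows,
and every recorded event must match a legal stoichiometry change.

`one_hit_survival()` implements colicin-style lethality: a cell dies the
moment its toxin count reaches the threshold (default one molecule); its
state freezes and it stays in the survival denominator. With `omega = 1`
(roughly one molecule per nM in an *E. coli* volume) the baseline gives
complete killing at saturating inducer, ~70% survival uninduced over a 60-min
window, and a monotone dose–kill curve with its midpoint at low-nM doses —
far below the fluorescence EC50, because a single toxin molecule amplifies
leak enormously. A caveat discovered in building the assay: the
*non-digitalized* construct cannot show a meaningful kill curve at all — its
basal leak alone is lethal on any useful time window (the model's version of
the fact that such toxin constructs cannot even be cloned without the
digitalizer) — so comparisons between the two constructs are made on
uninduced survival, not on curve widths.

## Synthetic cytometry and its limits

`generate_flow_experiment()` maps per-cell counts to fluorescence as
`AU = gain * G * exp(eps) + A`, with `eps ~ N(0, sigma_ext)` lognormal
extrinsic noise and lognormal autofluorescence `A`; the promoterless control
is pure `A` and defines the no-fluorescence gate (99.5th percentile per time
point by default). Defaults: `gain = 4` AU/molecule, `sigma_ext = 0.3`,
autofluorescence median 100 AU with sdlog 0.4, floor 1 AU, 25,000 events per
condition. Cells start reporter-free (`init_state = "zero"`), emulating a
freshly diluted outgrowth; uninduced leaky constructs then accumulate basal
signal over the time course, which is how the leaky-parent population drifts
across the gate by 24 h while the digitalized one never leaves it. The
default backend uses the ODE population mean and lets the measurement layer
carry cell-to-cell variability — appropriate for a strong reporter where
extrinsic noise dominates; a full-SSA backend is available per condition.

What the generator does **not** emulate — and hence what passing tests do not
establish about real data:

* **No growth-phase physiology.** The late-culture basal creep is reproduced
  only as relaxation toward steady state, not as density-dependent promoter
  activity.
* **No expression-dependent noise structure.** Extrinsic noise has constant
  log-variance, so the measured CV×100 is essentially flat in expression
  level; the experimental observation that the digitalizer *reduces* CV
  (by removing a low-expressing subpopulation) has no counterpart in a
  unimodal lognormal noise model and is not asserted anywhere in the suite.
  Likewise "faster onset" orderings between constructs depend on population
  structure the generator does not create.
* **No instrument realism.** No scatter channels, doublets or spillover; the
  synthetic events are pre-gated by construction, and the AU scale is a
  package convention, not a calibrated instrument scale.

## Parameter recovery

`fit_parameters()` minimises squared log-median residuals (fluorescence spans
decades) over a log-parameterised bounded search with `n_starts` log-uniform
starts refined by `nlminb`. The model median is
`gain * G_ode(t, dose) + median(A)`, with trajectories started reporter-free
to match the generator. `gain` and `lambda_G` are refused as a joint free
pair (only their product is observable). At the baseline design (six doses
spanning the threshold, four times to 240 min, 500 events per condition,
`sigma_ext = 0.2`), the pair (`k_pair`, `alpha_S`) is recovered within ±25%
in 10/10 seeded replications; identifiability comes from the OFF level
(constraining the product of pairing rate and supply) together with the
threshold dose (constraining the supply alone).

## Problem sizes

The shipped analyses use: 242-point dose grids for sweeps; 50 random
parameter draws for the closed-form oracle; 500 cells for Poisson and
survival checks; 30 cells at `omega = 1000` for the ODE-limit check; 25,000
events per condition for the population digital-OFF readout; and 10 × 10-start
fits for the recovery study. These sizes give sampling errors comfortably
below every margin tested while keeping a full run in the minutes range on a
single CPU.
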