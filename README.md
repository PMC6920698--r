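# digitalizer

Simulation and synthetic benchmarking of an sRNA-based **digitalizer module**:
a post-transcriptional cross-inhibition switch that turns the graded, leaky
output of an inducible bacterial promoter into a clean ON/OFF response.

## The circuit and its model

Inducible bacterial promoters almost never have a true zero OFF state: basal
transcription leaks through, which matters enormously when the payload is
toxic or when circuits must compose predictably. The digitalizer suppresses
this leak by coupling the gene of interest (GOI) to a mutual-inhibition loop
acting on translation:

* An inducible promoter **P1** (activated by an inducer-bound transcription
  factor, TF^a) transcribes a bicistronic mRNA **mR** encoding a
  transcriptional repressor **R** (e.g. LacI) translationally coupled to the
  GOI.
* A strong, R-repressible promoter **P2** transcribes a small RNA **mS** that
  base-pairs with mR, blocking its translation and triggering co-degradation.
* R represses P2 — so **R and mS are mutually inhibitory**: whichever RNA
  species dominates shuts the other down.

The deterministic model is four ODEs in the species (nM) mR, mS, R and G (the
GOI product), with Hill-type promoter activities and a bimolecular
pairing/co-degradation term:

    dmR/dt = beta_R + alpha_R * x^n_act/(K_TF^n_act + x^n_act)
             - (delta_mR + mu) mR - k_pair mR mS
    dmS/dt = alpha_S * K_R^n_rep/(K_R^n_rep + R^n_rep)
             - (delta_mS + mu) mS - k_pair mR mS
    dR/dt  = lambda_R mR - (delta_R + mu) R
    dG/dt  = lambda_G mR - (delta_G + mu) G

with x = TF^a the external input. The baseline parameters place the circuit
in the sRNA threshold regime (`beta_R << alpha_S < beta_R + alpha_R`): the
uninduced transcription rate is far below the sRNA supply, so basal mRNA is
stoichiometrically destroyed (digital OFF), while full induction outruns the
supply and flips the switch ON.

The package provides, all under one roof:

* **Deterministic analyses** — `simulate_ode()`, `steady_state()`,
  `dose_response()` (with up/down continuation), `response_metrics()`
  (EC50, fold change, 10–90% transition width, effective Hill coefficient),
  `repression_sweep()` across joint repression strengths,
  `hysteresis_scan()`, `deinduction()`.
* **Exact stochastic simulation** — a compiled Gillespie direct-method engine
  (`gillespie()`, `simulate_population()`) with reproducible per-cell
  streams, plus `one_hit_survival()` for one-hit toxin (colicin-style)
  killing curves.
* **Synthetic flow cytometry** — `generate_flow_experiment()` turns per-cell
  GOI counts into event tables with lognormal extrinsic noise and
  autofluorescence (the promoterless control defines the no-fluorescence
  gate); `generate_platereader()` produces OD-normalised bulk time courses.
* **Population statistics** — `summarize_cytometry()` with `median_fluorescence()`,
  `cv100()` (CV×100), `gate_threshold()`, `fraction_on()`.
* **Parameter recovery** — `fit_parameters()`, multi-start bounded
  least squares on log-scale medians, with broom-style `tidy()`/`glance()`.
* **An end-to-end pipeline** — `run_pipeline()` (simulate → generate →
  summarise → fit) driven by a TOML configuration, and a thin CLI at
  `inst/scripts/digisim.R`.

## Worked example

```r
library(digitalizer)

p <- digitalizer_params()           # baseline digitalized circuit
dr <- dose_response(p, default_dose_grid(n = 121))
response_metrics(dr)
#> # A tibble: 1 x 7
#>   readout off_level on_level fold_change  ec50 transition_width effective_hill
#>   <chr>       <dbl>    <dbl>       <dbl> <dbl>            <dbl>          <dbl>
#> 1 mR        0.00302     43.8      14485.  157.             238.           4.40
```

The uninduced operon mRNA sits at 0.003 nM — a 14,000-fold dynamic range —
because the sRNA destroys basal transcripts stoichiometrically. Sweeping the
joint strength of both repression arms (multiplying `k_pair`, dividing `K_R`)
reproduces the fan of dose-response curves crossing a near-invariant pivot:

```r
sw <- repression_sweep(p, strengths = c(0.3, 1, 3, 10, 30),
                       doses = default_dose_grid(n = 121))
sw$metrics[, c("strength", "off_level", "fold_change", "ec50")]
#>   strength off_level fold_change  ec50
#> 1      0.3  0.009881        2827 167.2
#> 2      1.0  0.003021       14485 156.9
#> 3      3.0  0.001012       48579 107.5
#> 4     10.0  0.000304      163701  99.9
#> 5     30.0  0.000101      491384  98.4
autoplot(sw)            # Fig-3B-style fan; plot_phase_plane(sw) for mS vs mR
```

Separation (fold change) grows monotonically with repression strength, and
the OFF→ON transition pivots around ~100 nM TF^a at medium-to-strong
repression. A synthetic flow-cytometry experiment shows the digital OFF at
the population level:

```r
ev <- generate_flow_experiment(flow_design(doses = c(0, 1000),
                                           times = c(0, 60, 1440)),
                               n_events = 5000, seed = 1)
summarize_cytometry(ev)[, c("construct", "dose", "time", "median_au", "frac_on")]
#>          construct dose time median_au frac_on
#> 1      digitalized    0 1440     103.5  0.0058   # sits on the control
#> 2  non_digitalized    0 1440     408.9  0.9406   # leaky parent, 94% ON
#> 3     promoterless    0 1440     100.2  0.0044   # autofluorescence gate
#> ...
```

Uninduced, the digitalized construct is indistinguishable from the
promoterless control at every time point (fraction ON ≤ 0.6%, against a gate
at the control's 99.5th percentile), while the non-digitalized parent drifts
almost entirely above the gate by 24 h — yet both reach the same fully
induced level.

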