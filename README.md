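# potaxis

Modeling and analysis of *Escherichia coli* chemotaxis toward potassium.

Electrically signaling biofilms release potassium in periodic waves, and
motile *E. coli* sense potassium as a chemoattractant. This package
implements the computational chain needed to study that attraction, for
researchers in bacterial chemotaxis and biofilm electrophysiology:

- **Signaling model** (`signaling_params`, `kinase_activity`,
  `methylation_step`, `cw_bias`, ...): a Monod–Wyman–Changeux receptor
  cluster, `a = 1/(1 + exp[N(α(m−m0) + ln((1+L/Koff)/(1+L/Kon)))])`, with
  methylation adaptation `dm/dt = kR(1−a) − kB a` (fixed point
  `a* = kR/(kR+kB)`), CheY-P coupling `Yp = 7.86 a` µM, motor CW bias
  `B = Yp^10.3/(Yp^10.3 + 3.1^10.3)` and switching rates `B/0.11` and
  5 s⁻¹. Defaults are the values calibrated for potassium
  (N = 0.85, Koff = 0.17 mM, Kon = 55.17 mM, ...).
- **Potassium field** (`oscillating_field`, `field_concentration`,
  `pde_residual`): the damped thermal wave
  `L(x,t) = L0[1 − cos(2πt/T − kx) e^(−kx)]`, `k = sqrt(π/(DT))`, from an
  oscillating source at `x = 0`, plus static linear gradients.
- **Run-and-tumble simulation** (`run_simulation`, compiled inner loop):
  ensembles of signaling-equipped cells in a 2D arena with reflective /
  periodic boundaries, forward-biased tumble-angle law and rotational
  diffusion.
- **Analyses**: phase delay and lag time of the mean cell position behind
  the oscillating source (`phase_delay`, `replicate_lag`); pH-corrected
  FRET dose–response and adaptation metrics (`ph_correct`, `fit_hill`,
  `fit_mwc`, `adaptation_metrics`); density-profile/drift-velocity and
  CMC statistics and bead-assay motor windowing (`density_profile_fit`,
  `drift_velocity`, `cmc`, `windowed_motor_stats`).
- **Synthetic-data generators** (`gen_fret_trace`, `gen_bead_trace`,
  `gen_positions`, `gen_ph_correction_curves`, `gen_bundle`): seeded
  emulations of every experimental input, with ground truth attached, so
  the full pipeline is testable with no external data.

The `analysis/` directory contains numbered scripts that run the study's
analyses end to end and write tables under `results/`; the
`vignettes/potassium-chemotaxis-methods.Rmd` vignette documents the model,
parameter choices and numerical conventions.

## Worked example

Simulate 1,000 cells for four periods of a 2-hour potassium oscillation
and extract the lag of the population behind the source:

```r
library(potaxis)

params <- signaling_params()
field  <- oscillating_field(L0 = 1, period = 2 * 3600)  # mM, s
cfg    <- sim_config(n_cells = 1000, dt = 0.02, n_periods = 4, rng_seed = 1)

traj <- run_simulation(cfg, field, params)   # ~60 s on one core
lag  <- phase_delay(traj, field)
lag
#> Phase delay: 0.1026 cycle; lag time: 12.32 min (sd 1.96 over 3 periods)
```

The phase delay is the mean offset, as a fraction of the driving cycle,
between the troughs of the displacement toward the source (`1500 − mean x`)
and the troughs of the source itself; the lag time is that fraction times
the period. Averaging three seeds (`replicate_lag`) gives ≈ 12 min for
T = 2 h: the population tracks the potassium wave with a delay of order
ten minutes, comparable to the lags seen in biofilm attraction
experiments, and the phase delay decreases with the driving period while
the lag time stays in a narrow band.

The FRET analysis chain, on synthetic data with known truth:

```r
corr  <- gen_ph_correction_curves()          # no-receptor pH calibration
sched <- dose_schedule(c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100))
trace <- gen_fret_trace(sched, h = 0.88, K05 = 0.33, correction = corr, seed = 1)

fit <- fit_hill(dose_response(ph_correct(trace, corr, extrapolate = TRUE)))
round(c(h = fit$h, K0.5 = fit$K0.5), 3)
#>     h  K0.5
#> 0.815 0.375
```

and the drift velocity implied by an exponential steady-state density
profile with decay constant λ = 0.0085 µm⁻¹ and motility constant
`v_s` = 53.2 µm²/s:

```r
drift_velocity(0.0085, 53.2)
#> [1] 0.4522
```

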