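---
title: "Modeling potassium chemotaxis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling potassium chemotaxis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potaxis)
```

## The scientific problem

Electrically signaling biofilms release potassium in periodic waves, and
swimming *E. coli* are attracted to potassium. `potaxis` implements the
computational chain needed to study that attraction quantitatively:

1. a coarse-grained model of the chemotaxis signaling pathway responding to
   extracellular potassium,
2. the closed-form potassium field around an oscillating source in a
   semi-infinite medium,
3. a stochastic run-and-tumble simulation of a cell ensemble in that field,
4. the analysis procedures used on both simulated and experimental data:
   phase-delay/lag extraction, pH-corrected FRET dose-response and
   adaptation analysis, density-profile/drift-velocity statistics and
   bead-assay motor statistics,
5. seeded synthetic-data generators so every stage is testable without
   external data.

## Signaling model

Receptor clusters are two-state (MWC) allosteric units. Kinase activity is

$$a = \frac{1}{1+\exp[N(f_m + f_L)]}, \qquad
f_L = \ln\frac{1 + L/K_{off}}{1 + L/K_{on}},$$

with $f_m = \alpha(m - m_0)$ the methylation free energy. Methylation
adapts slowly,

$$\frac{dm}{dt} = k_R(1-a) - k_B\,a,$$

so the fixed point of the coupled system is $a^* = k_R/(k_R+k_B) = 1/3$,
independent of the ambient concentration — the mechanism of adaptation.
CheY-P follows activity instantaneously ($Y_p = 7.86\,a$ µM), the motor CW
bias is a steep Hill function $B = Y_p^{10.3}/(Y_p^{10.3}+3.1^{10.3})$, and
motor switching is a two-state process with run-to-tumble rate $B/0.11$ and
tumble-to-run rate $5\,\mathrm{s^{-1}}$.

Defaults (`signaling_params()`): $N=0.85$, $\alpha=-1.7$, $m_0=1.0$,
$K_{off}=0.17$ mM, $K_{on}=55.17$ mM, $k_R=0.005\,\mathrm{s^{-1}}$,
$k_B=0.010\,\mathrm{s^{-1}}$ — the values calibrated against the
pH-corrected potassium dose-response curve, under which the half-drop
concentration of the activity curve is 0.33 mM, matching the Hill-fit
$K_{0.5}$. Every numeric constant (7.86, 10.3, 3.1, 0.11, 5, ...) is a
parameter with these defaults, because sensitivity sweeps (notably over
$k_R$) are first-class use cases.

Two conventions coexist for $f_m$: the dynamic model uses
$\alpha(m - m_0)$; dose-response fitting freezes methylation at its
pre-stimulus level and treats $f_m$ as a single constant
(`fm_override`, default 0.84 in kT units). We interpret the fitted 0.84
as the constant methylation free energy; consistency check: it yields a
baseline activity of $1/(1+e^{0.85\cdot0.84}) \approx 0.33 \approx
k_R/(k_R+k_B)$, i.e. a pre-adapted baseline.

`adapted_methylation()` inverts the fixed-point condition in closed form.
Methylation is clamped to $[0, 4]$ (four methylation sites per receptor
monomer); the adapted level at 100 mM is $\approx 3.66$, so the clamp
never binds in the concentration range studied.

## Potassium field

A source at $x=0$ oscillating as $L_s(t) = L_0[1-\cos(2\pi t/T)]$ drives a
semi-infinite diffusive medium. The bounded solution is the damped thermal
wave

$$L(x,t) = L_0\left[1 - \cos\!\left(\tfrac{2\pi t}{T} - kx\right)
 e^{-kx}\right], \qquad k = \sqrt{\pi/(DT)},$$

with $D = 1333.3$ µm²/s for potassium in water. $k$ is the unique
decay/phase constant for which this expression solves
$\partial_t L = D\,\partial_x^2 L$ with the oscillating boundary condition
and a bounded far field; `pde_residual()` verifies this numerically, and
the tests check that a deliberately wrong $k$ leaves an $O(L_0\omega)$
residual. The field is evaluated analytically everywhere — no PDE solver.
At $T = 1$ h the penetration depth $1/k \approx 1.2$ mm is comparable to
the 1.5 mm arena, which is what makes the spatial phase structure matter.

## Run-and-tumble simulation

Cells are self-propelled particles in a 2D arena (default 1500×1500 µm,
reflective in $x$, periodic in $y$) moving at 25 µm/s during runs with
rotational diffusion $D_r = 0.062$ rad²/s, and stationary during tumbles.
Tumble reorientations follow the forward-biased law
$P(\theta) = \tfrac12(1+\cos\theta)\sin\theta$ on $[0,\pi]$, drawn by
exact inverse CDF ($\theta = \arccos(2\sqrt{u}-1)$; mean $3\pi/8$). Per
timestep (default $dt = 0.01$ s) and cell: read the local concentration,
Euler-update $m$, recompute $a \to Y_p \to B$, draw motor transitions as
Bernoulli events with probability rate·$dt$ (the step() operation rejects
configurations with rate·$dt > 1$), then move.

Design choices on points the model statement leaves open:

- **Dimensionality.** The arena is 2D; the tumble-angle law is applied
  in-plane with a uniform random sign. The reorientation persistence
  $\langle\cos\theta\rangle = 1/3$ is unchanged by this reduction.
- **Rotational diffusion** acts only during runs; tumble reorientation is
  already modeled by the tumble-angle law.
- **Initialization.** Cells start uniformly distributed, running, with
  headings uniform and methylation pre-adapted to the local concentration
  at $t=0$ (`adapted_methylation`). The first period is excluded from lag
  analysis, so initialization transients do not enter reported lags.
- **Boundaries.** Post-move positions are reflected in $x$ (heading
  $x$-component negated) and wrapped in $y$.
- **Sensing continues during tumbles** (receptors keep working while the
  cell reorients), so methylation is updated for all cells every step.

Two engines implement the identical update: a readable vectorised R
reference (`step_cells`) and a compiled loop (`run_simulation`,
`engine = "cpp"`), cross-checked statistically in the tests. The compiled
loop uses 4096-point lookup tables for the smooth one-argument maps (field
envelope/phase factors, ligand free energy, bias-vs-activity), a 4th-order
small-angle rotation for rotational diffusion, and a second-order expansion
of the post-Euler activity update; all interpolation/expansion errors are
below $10^{-6}$ in the respective quantities, orders of magnitude under the
stochastic noise. Both engines draw from R's RNG, so a `rng_seed` fixes a
run exactly.

## Lag analysis

The displacement toward the source, $1500 - \bar{x}(t)$, oscillates with
the driving period and lags the source. The series is smoothed by a
centred moving average (default window $0.05\,T$, configurable — the
ensemble mean retains sampling noise at finite cell number) and troughs
are taken as the local minima that dominate their neighbourhood within a
quarter period on each side. Local-minimum detection, rather than a plain
per-period-window minimum, matters at long driving periods: successive
trough depths differ by ensemble noise, and a window minimum can then lock
onto the window edge while approaching the next, deeper trough. Troughs at
the series boundary samples are discarded, as is the trough of the first
period, which reflects the excluded $t=0$ source trough and the
initialization transient. Each remaining trough is paired with
the latest source trough at or before it ($t = kT$), giving per-period
offsets whose mean is the phase delay $\Delta\phi$ (cycle fraction); the
lag time is $\Delta\phi\cdot T$. Offsets above 0.9 are wrapped so a
near-zero lag is not split across the cycle boundary. Within a run we
average over periods, then across replicate seeds (`replicate_lag`).
Fourier/cross-correlation phase estimation was checked to agree to
within ~0.3 min on simulated traces but is not the primary method.

Problem sizes: the package's analyses use 4 driving periods and ensembles
of 500–10,000 cells; at 1,000 cells the standard error of the ensemble
mean position (~14 µm) is small against oscillation amplitudes of
~100–300 µm. The timestep is 0.01 s, relaxed to 0.02 s for the longer
periods ($T \ge 2$ h), which leaves all per-step switching probabilities
below 0.1 and the Euler methylation update far inside its stability
region (the methylation relaxation time is ~200 s).

The $k_R$ sensitivity analysis sweeps the methylation rate holding
$k_B = 2k_R$, which preserves the adapted activity $a^* = 1/3$ (and hence
the adapted motor behavior) while scaling the adaptation speed — the
quantity the sweep is meant to probe. Sweeping $k_R$ alone would conflate
adaptation speed with a change of the adapted state itself: at fixed
$k_B$, $a^*$ shifts and with it the baseline tumble rate, by orders of
magnitude at the extremes of the swept range.

## FRET pipeline

The FRET signal is the YFP/CFP count ratio normalized to its pre-stimulus
baseline. Because intracellular pH rises with external potassium and
brightens CFP and YFP unequally, raw ratios show an apparent imprecise
adaptation; the correction divides each channel, inside each stimulus
window, by the no-receptor-strain calibration factor $C_{pH}(L)$ (CFP
factor 1.056 at 30 mM). $C_{pH}$ is interpolated monotone
piecewise-linearly in log-concentration between calibrated points, with
$C_{pH}(0)=1$ and linear interpolation toward that anchor below the lowest
calibrated concentration; concentrations above the calibrated range error
unless extrapolation is explicitly enabled.

Relative kinase activity rescales FRET affinely: pre-stimulus 1 maps to
activity 1, the saturated-stimulus value 0.94 maps to 0. The
dose-response value per concentration is the smoothed minimum within a
detection window after addition (default 30 s, 5-point moving average) —
the "immediate response" before adaptation recovers appreciably. Fits:

- **Hill**: $a(L) = 1/(1+(L/K_{0.5})^h)$ with asymptotes fixed at 1 and 0
  by the rescaling; fitted on log-parameters (Levenberg–Marquardt), SEs by
  the delta method.
- **MWC**: the activity expression with frozen $f_m$, normalized by its
  $L=0$ baseline, fitted with bounded least squares
  ($K_{off} \in [10^{-3}, 10]$ mM, $K_{on} \in [1, 10^3]$ mM,
  $N \in (0.05, 20]$, $f_m \in [-5,5]$) from 32 deterministic multi-starts,
  because 4-parameter MWC fits of a single monotone curve are
  ill-conditioned; hitting a bound raises a warning flagging weak
  identifiability. Tests therefore compare the fitted *curve* and its
  half-drop concentration rather than raw parameter tuples.

Adaptation metrics from a step response: $R_L$ is the smoothed
post-addition minimum, $R^*$ the mean over the final fraction (default
20%) of the stimulus window, $P = (R^*-R_L)/(1-R_L)$, and the adaptation
time is the time from the minimum to the first crossing of
$R_L + 0.63\,(R^*-R_L)$. The 63% criterion makes the adaptation time equal
the time constant for a single-exponential recovery; it is configurable
because the original definition is graphical.

## Motility statistics

- **CMC**: per frame, mean of $(x_i - x_c)/194$ with 194 µm the half-width
  of the observed region.
- **Density profile**: histogram along the gradient axis (default 20
  bins), exponential fit $\rho \propto e^{\lambda y}$ by weighted least
  squares on log-density with Poisson count weights (empty bins excluded).
  For log-sensing chemotaxis in a linear gradient, $\lambda = v_d/v_s$, so
  `drift_velocity()` returns $\lambda v_s$; with the measured
  $\lambda = 0.0085\,\mu m^{-1}$ and $v_s = 53.2\,\mu m^2/s$ this gives
  $v_d = 0.452\,\mu m/s$.
- **Bead assay**: signed rotational speed windowed with a 20 s window and
  1 s slide; CW bias is the fraction of CW samples per window (optional
  dead band around zero for noise near reversals, default off), speed the
  mean absolute speed.

## Synthetic-data generators

Each generator emulates the statistical structure one pipeline stage
assumes, retains its ground truth as an attribute, and is deterministic
under a seed:

- `gen_fret_trace()`: two-channel Poisson photon counts at 1 Hz whose true
  activity drops by a Hill response on addition and recovers exponentially
  (time constant per stimulus, a user-supplied table, since the true
  concentration-dependence of recovery kinetics is not parameterized);
  the pH artifact multiplies the channels in-window. Baseline counts
  default to $10^6$ per sample, representative of integrated
  photon-counting PMT signals; at this level count noise contributes
  ~0.1% ratio noise.
- `gen_ph_correction_curves()`: saturating brightness-gain curves per
  channel anchored at CFP 1.056 at 30 mM; channels differ so the
  uncorrected ratio is biased — the artifact the correction must remove.
- `gen_bead_trace()`: two-state CCW/CW Markov motor (stationary CW bias
  $k_1/(k_1+k_2)$) with Gaussian speed jitter and an optional stimulus
  window changing the CCW→CW rate.
- `gen_positions()`: truncated-exponential positions across a 388 µm
  channel (the observed region), uniform transverse coordinate.

What the generators deliberately do *not* emulate: instrument drift,
photobleaching beyond the calibration-ratio mechanism, Tar/Tsr biphasic
responses, tracking/segmentation artifacts in positions, and bead-assay
speed fluctuations from proton-motive-force changes. Parameter-recovery
tests passing on synthetic data therefore validate the analysis chain, not
these aspects of real measurements.

## Numerical and degenerate-input conventions

- Trough detection with tied minima takes the earliest and flags the
  result as ambiguous.
- `density_profile_fit` errors when fewer than three bins are occupied.
- `adaptation_metrics` returns $P=0$ with an undefined (flagged)
  adaptation time when there is no recovery.
- `fit_mwc` rejects flat dose-response data as non-identifiable.
- The simulation rejects timesteps with rate·$dt > 1$.
- Negative concentrations, positions outside the semi-infinite domain and
  malformed stimulus schedules raise errors at the boundary of each
  module.

## Known limitations

- The receptor model is potassium-generic MWC: no Tar/Tsr-specific or
  pH-mechanistic description (none is established), no biphasic Tar
  response, no motor-speed/PMF modeling.
- The 2D reduction of swimming and of the tumble-angle law preserves
  reorientation persistence but is not a literal 3D simulation; simulated
  lag times carry a residual dependence on such unstated discretization
  choices at the 1–2 minute level.
- The oscillating field is 1D in $x$: no finite biofilm geometry,
  consumption, or transverse diffusion.
- Lag estimates at few hundred cells are noisy (period-to-period scatter
  ~1 min); replicate seeds are averaged to compensate.
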