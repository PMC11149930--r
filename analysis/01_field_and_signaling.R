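#!/usr/bin/env Rscript
# Characterizes the two deterministic layers of the study: the oscillating
# potassium field around a biofilm-like source, and the calibrated
# receptor/motor signaling curves. Writes summary tables to results/.

suppressPackageStartupMessages(library(potaxis))
dir.create("results", showWarnings = FALSE)

params <- signaling_params()
field <- oscillating_field(L0 = 1, period = 2 * 3600)

## Field: wavenumber, penetration depth, and verification that the closed
## form solves the diffusion equation
k <- wavenumber(field)
res <- pde_residual(field, seq(50, 2000, length.out = 150),
                    seq(0, field$period, length.out = 500))
cat(sprintf("wavenumber k = %.3e 1/um; penetration depth 1/k = %.0f um\n",
            k, 1 / k))
cat(sprintf("diffusion-equation residual (analytic field): %.2e mM/s\n", res))

profile <- do.call(rbind, lapply(c(0, 0.25, 0.5, 0.75) * field$period,
  function(t) data.frame(t_s = t, x_um = seq(0, 1500, by = 25),
                         conc_mM = field_concentration(field,
                                                       seq(0, 1500, by = 25), t))))
write.csv(profile, "results/field_profiles.csv", row.names = FALSE)

## Signaling: adapted state and dose-response curve of the calibrated model
a_star <- params$kR / (params$kR + params$kB)
Yp <- cheyp_from_activity(a_star, params)
B <- cw_bias(Yp, params)
r <- switching_rates(B, params)
cat(sprintf("adapted state: a* = %.3f, Yp = %.2f uM, CW bias = %.3f\n",
            a_star, Yp, B))
cat(sprintf("switching: run->tumble %.2f /s, tumble->run %.1f /s\n",
            r$run_to_tumble, r$tumble_to_run))

L <- c(0, 10^seq(-2, 2, length.out = 41))
dose <- data.frame(
  conc_mM = L,
  activity = kinase_activity(NULL, L, params, fm_override = params$baseline_fm))
dose$rel_activity <- dose$activity / dose$activity[1]
write.csv(dose, "results/mwc_dose_response.csv", row.names = FALSE)

k05 <- mwc_half_drop(params)
cat(sprintf("half-drop concentration of the calibrated curve: %.3f mM\n", k05))
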