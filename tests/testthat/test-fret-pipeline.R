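test_that("normalized FRET ratio has unit baseline and tracks channel changes", {
  t <- 0:199
  sched <- data.frame(t_add = 100, t_remove = 160, conc_mM = 1)
  tr <- fret_trace(t, cfp = rep(1000, 200), yfp = rep(800, 200), sched)
  fr <- fret_ratio(tr, baseline = c(0, 99))
  expect_equal(fr$fret, rep(1, 200))
  # halving YFP halves the normalized ratio
  yfp <- rep(800, 200); yfp[t >= 100] <- 400
  fr2 <- fret_ratio(fret_trace(t, rep(1000, 200), yfp, sched), c(0, 99))
  expect_equal(fr2$fret[t >= 100], rep(0.5, 100))
  expect_error(fret_trace(t, rep(0, 200), yfp, sched), "positive")
  expect_error(fret_ratio(tr, baseline = c(0, 150)), "precede")
})

test_that("stimulus schedules are validated", {
  t <- 0:99
  bad <- data.frame(t_add = c(10, 30), t_remove = c(40, 60), conc_mM = c(1, 2))
  expect_error(fret_trace(t, rep(1, 100), rep(1, 100), bad), "overlap")
  out <- data.frame(t_add = 50, t_remove = 150, conc_mM = 1)
  expect_error(fret_trace(t, rep(1, 100), rep(1, 100), out), "beyond")
})

test_that("pH correction divides channels inside windows only", {
  t <- 0:199
  sched <- data.frame(t_add = 50, t_remove = 150, conc_mM = 30)
  corr1 <- ph_correction(c(1, 30, 100), rep(1, 3), rep(1, 3))
  tr <- fret_trace(t, rep(1000, 200), rep(900, 200), sched)
  expect_equal(ph_correct(tr, corr1)$cfp, tr$cfp)   # identity when C == 1
  # CFP factor 1.056 at 30 mM
  corr <- ph_correction(c(1, 30, 100), c(1.01, 1.056, 1.06), c(1, 1.03, 1.035))
  out <- ph_correct(tr, corr)
  win <- t >= 50 & t < 150
  expect_equal(out$cfp[win], rep(1000 / 1.056, sum(win)))
  expect_equal(out$cfp[!win], rep(1000, sum(!win)))
  # out-of-calibration concentration errors unless extrapolation enabled
  sched2 <- data.frame(t_add = 50, t_remove = 150, conc_mM = 300)
  tr2 <- fret_trace(t, rep(1000, 200), rep(900, 200), sched2)
  expect_error(ph_correct(tr2, corr), "calibration range")
  expect_silent(ph_correct(tr2, corr, extrapolate = TRUE))
})

test_that("pH correction commutes with ratio normalization", {
  # correcting channels then taking the ratio equals taking the ratio and
  # correcting it window-wise by the factor ratio (baseline has C == 1)
  corr <- gen_ph_correction_curves()
  sched <- data.frame(t_add = 60, t_remove = 120, conc_mM = 10)
  tr <- gen_fret_trace(sched, correction = corr, noise = FALSE, t_end = 200)
  f_corrected <- fret_ratio(ph_correct(tr, corr))$fret
  raw <- fret_ratio(tr)$fret
  win <- tr$t >= 60 & tr$t < 120
  fac <- ph_factor(corr, 10, "yfp") / ph_factor(corr, 10, "cfp")
  raw[win] <- raw[win] / fac
  expect_equal(f_corrected, raw, tolerance = 1e-9)
})

test_that("relative activity is the affine FRET rescaling", {
  expect_equal(relative_activity(1), 1)
  expect_equal(relative_activity(0.94), 0)
  expect_equal(relative_activity(0.97), 0.5)
  expect_error(relative_activity(1, saturated = 1.2))
})

test_that("Hill fit recovers noiseless parameters exactly", {
  L <- 10^seq(-2, 2, length.out = 9)
  y <- 1 / (1 + (L / 0.33)^0.88)
  fit <- fit_hill(data.frame(conc_mM = L, rel_activity = y))
  expect_equal(fit$h, 0.88, tolerance = 1e-5)
  expect_equal(fit$K0.5, 0.33, tolerance = 1e-5)
  # h = 1: K0.5 is the concentration at half activity
  y1 <- 1 / (1 + L / 0.5)
  fit1 <- fit_hill(data.frame(conc_mM = L, rel_activity = y1))
  expect_equal(fit1$K0.5, 0.5, tolerance = 1e-6)
  expect_equal(fit1$h, 1, tolerance = 1e-6)
})

test_that("Hill and MWC fits are concentration-scale consistent", {
  L <- 10^seq(-2, 2, length.out = 12)
  params <- signaling_params()
  y <- kinase_activity(NULL, L, params, fm_override = 0.84) /
    kinase_activity(NULL, 0, params, fm_override = 0.84)
  hf1 <- fit_hill(data.frame(conc_mM = L, rel_activity = y))
  hf2 <- fit_hill(data.frame(conc_mM = 10 * L, rel_activity = y))
  expect_equal(hf2$K0.5, 10 * hf1$K0.5, tolerance = 1e-4)
  expect_equal(hf2$h, hf1$h, tolerance = 1e-4)
  mf1 <- fit_mwc(data.frame(conc_mM = L, rel_activity = y))
  mf2 <- fit_mwc(data.frame(conc_mM = 10 * L, rel_activity = y))
  expect_equal(mf2$Koff, 10 * mf1$Koff, tolerance = 0.05)
  expect_equal(mf2$N, mf1$N, tolerance = 0.05)
})

test_that("MWC fit reproduces the generating receptor-cluster parameters", {
  L <- c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100)
  params <- signaling_params()
  y <- kinase_activity(NULL, L, params, fm_override = 0.84) /
    kinase_activity(NULL, 0, params, fm_override = 0.84)
  fit <- fit_mwc(data.frame(conc_mM = L, rel_activity = y))
  # the fitted curve must match; individual parameters are correlated, so
  # compare the functional prediction and the half-drop concentration
  expect_lt(fit$rss, 1e-8)
  pfit <- signaling_params(N = fit$N, Koff = fit$Koff,
                           Kon = max(fit$Kon, fit$Koff * 1.01),
                           baseline_fm = fit$fm)
  expect_equal(mwc_half_drop(pfit, fit$fm), 0.33, tolerance = 0.02)
  # flat data are rejected as non-identifiable
  expect_error(fit_mwc(data.frame(conc_mM = L, rel_activity = rep(1, 9))),
               "flat")
})

test_that("adaptation metrics implement the recovery definitions", {
  t <- 0:600
  # constructed exponential recovery: drop to 0.8 at t=100, tau = 60 s,
  # adapted plateau 0.96
  R_low <- 0.8; R_star <- 0.96; tau <- 60
  y <- rep(1, length(t))
  win <- t >= 100 & t <= 500
  y[win] <- R_star - (R_star - R_low) * exp(-(t[win] - 100) / tau)
  am <- adaptation_metrics(t, y, c(100, 500))
  expect_equal(am$R_low, R_low, tolerance = 0.01)
  expect_equal(am$R_star, R_star, tolerance = 0.005)
  expect_equal(am$P, (R_star - R_low) / (1 - R_low), tolerance = 0.05)
  # 63% recovery of a single exponential occurs at ~tau
  expect_equal(am$T_adapt, tau, tolerance = 0.1)
  # no recovery: P = 0 and T flagged undefined
  y2 <- rep(1, length(t)); y2[win] <- R_low
  am2 <- adaptation_metrics(t, y2, c(100, 500))
  expect_equal(am2$P, 0)
  expect_true(is.na(am2$T_adapt))
  expect_true(am2$no_recovery)
  # full recovery to baseline: P = 1
  y3 <- rep(1, length(t))
  y3[win] <- 1 - (1 - R_low) * exp(-(t[win] - 100) / 20)
  am3 <- adaptation_metrics(t, y3, c(100, 500))
  expect_equal(am3$P, 1, tolerance = 0.02)
})

test_that("dose-response tables and fit reports round-trip through CSV", {
  L <- c(0.1, 0.3, 1, 3)
  d <- data.frame(conc_mM = L, rel_activity = 1 / (1 + L / 0.3))
  class(d) <- c("dose_response", "data.frame")
  path <- tempfile(fileext = ".csv")
  write_dose_response(d, path)
  d2 <- read_dose_response(path)
  expect_equal(d2$rel_activity, d$rel_activity, tolerance = 1e-12)
})
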