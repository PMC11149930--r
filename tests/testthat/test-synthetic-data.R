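test_that("pH calibration curves anchor at 1 and at the measured CFP ratio", {
  corr <- gen_ph_correction_curves()
  expect_equal(potaxis:::ph_factor(corr, 0, "cfp"), 1)
  expect_equal(potaxis:::ph_factor(corr, 0, "yfp"), 1)
  expect_equal(potaxis:::ph_factor(corr, 30, "cfp"), 1.056, tolerance = 1e-3)
  # channels differ, so the uncorrected ratio is biased in-window
  expect_false(isTRUE(all.equal(corr$cfp_factor, corr$yfp_factor)))
  # monotone in concentration
  expect_true(all(diff(corr$cfp_factor) > 0))
})

test_that("noiseless artifact-free traces reproduce the constructed activity", {
  sched <- dose_schedule(c(0.1, 1, 10))
  tr <- gen_fret_trace(sched, correction = NULL, noise = FALSE)
  truth <- attr(tr, "truth")
  fr <- fret_ratio(tr)
  expect_equal(fr$fret, truth$fret, tolerance = 1e-9)
  act <- relative_activity(fr$fret)
  expect_equal(act, truth$activity, tolerance = 1e-9)
})

test_that("the pH artifact mimics imprecise adaptation and correction removes it", {
  corr <- gen_ph_correction_curves()
  sched <- data.frame(t_add = 60, t_remove = 400, conc_mM = 30)
  tr <- gen_fret_trace(sched, tau = 40, adapt_P = 1, correction = corr,
                       noise = FALSE, t_end = 450)
  truth <- attr(tr, "truth")
  raw <- fret_ratio(tr)$fret
  corrected <- fret_ratio(ph_correct(tr, corr))$fret
  late <- tr$t > 350 & tr$t < 400   # adapted plateau
  # uncorrected trace appears to adapt imprecisely (plateau below truth)
  expect_lt(mean(raw[late]), mean(truth$fret[late]) - 0.005)
  # corrected trace matches the artifact-free ground truth
  expect_equal(corrected[late], truth$fret[late], tolerance = 1e-6)
})

test_that("adaptation metrics recover the generator's time constant", {
  sched <- data.frame(t_add = 60, t_remove = 660, conc_mM = 1)
  tr <- gen_fret_trace(sched, tau = 60, adapt_P = 0.8, correction = NULL,
                       noise = FALSE, t_end = 700)
  fr <- fret_ratio(tr)
  am <- adaptation_metrics(fr$t_s, fr$fret, c(60, 660))
  expect_equal(am$T_adapt, 60, tolerance = 0.15)
  expect_equal(am$P, 0.8, tolerance = 0.05)
})

test_that("generators are deterministic under a fixed seed", {
  sched <- dose_schedule(c(0.1, 1))
  t1 <- gen_fret_trace(sched, seed = 5)
  t2 <- gen_fret_trace(sched, seed = 5)
  expect_identical(t1$cfp, t2$cfp)
  b1 <- gen_bead_trace(duration = 50, seed = 5)
  b2 <- gen_bead_trace(duration = 50, seed = 5)
  expect_identical(b1$speed_hz, b2$speed_hz)
  p1 <- gen_positions(n_cells = 100, seed = 5)
  p2 <- gen_positions(n_cells = 100, seed = 5)
  expect_identical(p1$y_um, p2$y_um)
  p3 <- gen_positions(n_cells = 100, seed = 6)
  expect_false(identical(p1$y_um, p3$y_um))
})

test_that("position generator spans its limits", {
  p0 <- gen_positions(n_cells = 5000, lambda = 0, seed = 9)
  c0 <- cmc(p0, x_center = 194, half_width = 194)  # transverse axis uniform
  expect_lt(abs(c0$cmc), 0.05)
  # strong accumulation pushes the profile toward the source side
  ps <- gen_positions(n_cells = 5000, lambda = 0.1, width = 388, seed = 10)
  expect_gt(mean(ps$y_um), 330)
  expect_error(gen_positions(n_cells = 10, lambda = -1))
})

test_that("the full synthetic bundle writes and re-reads consistently", {
  dir <- tempfile("bundle")
  paths <- gen_bundle(dir, seed = 3)
  expect_true(all(file.exists(unlist(paths))))
  truth <- yaml::read_yaml(paths$truth)
  expect_equal(truth$hill$h, 0.88)
  sched <- utils::read.csv(paths$schedule)
  tr <- read_fret_trace(paths$fret, sched)
  expect_s3_class(tr, "fret_trace")
  cal <- utils::read.csv(paths$calibration)
  corr <- ph_correction(cal$conc_mM, cal$cfp_factor, cal$yfp_factor)
  expect_silent(ph_correct(tr, corr))
  # bundle regenerates identically under the same seed
  dir2 <- tempfile("bundle")
  gen_bundle(dir2, seed = 3)
  expect_identical(readLines(file.path(dir, "fret_trace.csv")),
                   readLines(file.path(dir2, "fret_trace.csv")))
})
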