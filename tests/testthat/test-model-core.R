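params <- signaling_params()

test_that("ligand free energy matches closed form and its limits", {
  expect_equal(ligand_free_energy(0, params), 0)
  # direct arithmetic at 0.33 mM with the calibrated constants
  expect_equal(ligand_free_energy(0.33, params),
               log((1 + 0.33 / 0.17) / (1 + 0.33 / 55.17)), tolerance = 1e-12)
  # saturating value ln(Kon/Koff)
  expect_equal(ligand_free_energy(1e9, params),
               log(55.17 / 0.17), tolerance = 1e-4)
  expect_error(ligand_free_energy(-1, params), "non-negative")
  # monotone increasing
  L <- 10^seq(-3, 3, length.out = 50)
  expect_true(all(diff(ligand_free_energy(L, params)) > 0))
})

test_that("kinase activity follows the two-state MWC form", {
  expect_equal(kinase_activity(params$m0, 0, params), 0.5)
  # frozen methylation free energy, zero ligand
  expect_equal(kinase_activity(NULL, 0, params, fm_override = 0.84),
               1 / (1 + exp(0.85 * 0.84)), tolerance = 1e-12)
  # saturating ligand drives activity to ~0.0036
  a_sat <- 1 / (1 + exp(0.85 * (0.84 + log(55.17 / 0.17))))
  expect_equal(kinase_activity(NULL, 1e9, params, fm_override = 0.84),
               a_sat, tolerance = 1e-4)
  # bounded, decreasing in L, increasing in m (alpha < 0) on a grid
  m <- seq(0, 4, by = 0.25)
  L <- c(0, 10^seq(-3, 3, length.out = 25))
  a_grid <- outer(m, L, function(mm, ll) kinase_activity(mm, ll, params))
  expect_true(all(a_grid > 0 & a_grid < 1))
  expect_true(all(apply(a_grid, 1, diff) <= 0))  # in L
  expect_true(all(apply(a_grid, 2, diff) >= 0))  # in m
})

test_that("methylation dynamics have the adaptation fixed point kR/(kR+kB)", {
  a_star <- params$kR / (params$kR + params$kB)
  expect_equal(a_star, 1 / 3)
  expect_equal(methylation_step(1.2, a_star, 0.01, params), 1.2)
  expect_equal(methylation_step(1, 0, 0.5, params), 1 + params$kR * 0.5)
  expect_equal(methylation_step(1, 1, 0.5, params), 1 - params$kB * 0.5)
  # clamped to the configured range
  expect_equal(methylation_step(4, 0, 100, params), 4)

  # coupled (a, m) dynamics converge to a* from any start, at any L
  for (L in c(0, 0.33, 10)) {
    for (m0 in c(0.1, 2, 3.9)) {
      m <- m0
      for (i in 1:80000) {
        a <- kinase_activity(m, L, params)
        m <- methylation_step(m, a, 0.05, params)
      }
      expect_lt(abs(kinase_activity(m, L, params) - a_star), 1e-4)
    }
  }
})

test_that("CheY-P coupling and motor bias reproduce the calibrated curve", {
  expect_equal(cheyp_from_activity(0, params), 0)
  expect_equal(cheyp_from_activity(1, params), 7.86)
  expect_equal(cheyp_from_activity(1 / 3, params), 2.62)
  expect_equal(cw_bias(3.1, params), 0.5)
  expect_equal(cw_bias(0, params), 0)
  expect_equal(cw_bias(2.62, params), 0.1502, tolerance = 1e-3)
  # monotone composition bias(cheyp(a))
  a <- seq(0, 1, length.out = 101)
  expect_true(all(diff(cw_bias(cheyp_from_activity(a, params), params)) > 0))
})

test_that("switching rates scale bias by the configured constants", {
  r <- switching_rates(0.11, params)
  expect_equal(r$run_to_tumble, 1)
  expect_equal(r$tumble_to_run, 5)
  expect_equal(switching_rates(0, params)$run_to_tumble, 0)
  expect_equal(switching_rates(0.150, params)$run_to_tumble, 0.150 / 0.11)
  # values come from params, not hard-coded
  p2 <- signaling_params(tumble_rate_scale = 0.2, detumble_rate = 3)
  r2 <- switching_rates(0.1, p2)
  expect_equal(r2$run_to_tumble, 0.5)
  expect_equal(r2$tumble_to_run, 3)
})

test_that("adapted methylation solves the fixed-point equation", {
  expect_equal(adapted_methylation(0, params), 0.5203, tolerance = 1e-3)
  expect_equal(adapted_methylation(100, params), 3.664, tolerance = 1e-3)
  for (L in c(0, 0.1, 1, 10, 100)) {
    expect_equal(kinase_activity(adapted_methylation(L, params), L, params),
                 1 / 3, tolerance = 1e-9)
  }
  # out-of-range solution is clamped with a warning
  p_narrow <- signaling_params(m_range = c(0, 1))
  expect_warning(m <- adapted_methylation(100, p_narrow), "clamped")
  expect_equal(m, 1)
})

test_that("half-drop concentration of the calibrated response is ~0.33 mM", {
  expect_equal(mwc_half_drop(params), 0.33, tolerance = 0.01)
})

test_that("parameter validation enforces the model invariants", {
  expect_error(signaling_params(Koff = -1))
  expect_error(signaling_params(Kon = 0.1))   # must exceed Koff
  expect_error(signaling_params(kR = 0))
  expect_error(cheyp_from_activity(1.5, params))
  expect_error(cw_bias(-1, params))
})
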