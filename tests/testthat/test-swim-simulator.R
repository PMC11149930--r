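params <- signaling_params()

test_that("tumble angles follow the forward-biased reorientation law", {
  # CDF endpoints of the inverse transform
  expect_equal(acos(2 * sqrt(1) - 1), 0)
  expect_equal(acos(2 * sqrt(0) - 1), pi)
  set.seed(42)
  th <- sample_tumble_angle(2e5)
  expect_true(all(th >= 0 & th <= pi))
  # analytic mean 3*pi/8; MC standard error ~ sqrt(var/n)
  se <- stats::sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - 3 * pi / 8), 4 * se)
  # empirical CDF against F(theta) = (1 - cos)(3 + cos)/4 (F(pi/2) = 3/4)
  Fth <- function(q) (1 - cos(q)) * (3 + cos(q)) / 4
  expect_equal(Fth(pi / 2), 0.75)
  qs <- seq(0.1, 3, by = 0.2)
  expect_lt(max(abs(vapply(qs, function(q) mean(th <= q), 1) - Fth(qs))), 0.005)
})

test_that("initialization is uniform, running, and pre-adapted to the field", {
  f <- oscillating_field(1, 3600)
  cfg <- sim_config(n_cells = 5000, rng_seed = 7)
  set.seed(cfg$rng_seed)
  ens <- initialize_cells(cfg, f, params, t0 = 0)
  expect_equal(mean(ens$x), 750, tolerance = 0.05)
  expect_equal(mean(ens$y), 750, tolerance = 0.05)
  expect_false(any(ens$tumbling))
  expect_true(all(abs(ens$a - 1 / 3) < 1e-6))
  expect_error(sim_config(n_cells = 0))
})

test_that("single-step micro-rules: reflection, tumbler immobility", {
  lf <- linear_field(0, 0, 0, 1500)   # zero field everywhere
  cfg <- sim_config(n_cells = 3, dt = 0.01, rot_diffusion = 0, speed = 25)
  ens <- structure(list(x = c(0.1, 1499.9, 700), y = c(10, 10, 10),
                        theta = c(pi, 0, 0), m = rep(0.5203, 3),
                        tumbling = c(FALSE, FALSE, TRUE)),
                   class = "cell_ensemble")
  set.seed(1)
  # tumble-to-run exit is stochastic; force no exit via zero detumble draws:
  # with detumble_rate*dt = 0.05 an exit is unlikely in one step, so repeat
  # under a seed where it does not occur
  out <- step_cells(ens, lf, params, cfg, t = 0)
  # cell 1 crossed x = 0 heading left: reflected back with x-heading negated
  expect_equal(out$x[1], abs(0.1 + 25 * 0.01 * cos(pi)), tolerance = 1e-9)
  expect_gt(cos(out$theta[1]), 0)
  # cell 2 crossed x = 1500 heading right: reflected
  expect_equal(out$x[2], 2 * 1500 - (1499.9 + 0.25), tolerance = 1e-9)
  expect_lt(cos(out$theta[2]), 0)
  # cell 3 tumbling: stationary unless it exited the tumble this step
  if (out$tumbling[3]) expect_equal(out$x[3], 700)
})

test_that("with the motor disabled, headings diffuse as pure rotational diffusion", {
  # huge motor_K makes the CW bias (hence tumble rate) essentially zero
  p0 <- signaling_params(motor_K = 1e6)
  lf <- linear_field(0, 0, 0, 1e7)
  cfg <- sim_config(n_cells = 400, dt = 0.01, arena_x = 1e7, arena_y = 1e7,
                    rng_seed = 5)
  set.seed(5)
  ens <- initialize_cells(cfg, lf, p0, 0)
  ens$x <- rep(5e6, 400); ens$y <- rep(5e6, 400)
  th0 <- ens$theta
  nsteps <- 500
  for (s in seq_len(nsteps)) ens <- step_cells(ens, lf, p0, cfg, (s - 1) * 0.01)
  dth2 <- mean((ens$theta - th0)^2)
  expected <- 2 * cfg$rot_diffusion * nsteps * cfg$dt   # = 0.62
  expect_equal(dth2, expected, tolerance = 0.15)
  expect_false(any(ens$tumbling))
})

test_that("uniform field: no drift, and tumble occupancy matches the two-state balance", {
  lf <- linear_field(0.5, 0.5, 0, 1500)  # uniform 0.5 mM
  cfg <- sim_config(n_cells = 2000, dt = 0.01, duration = 100, rng_seed = 11)
  res <- run_simulation(cfg, lf, params, return_ensemble = TRUE)
  s <- res$summary
  se <- 1500 / sqrt(12) / sqrt(cfg$n_cells)
  expect_lt(abs(s$mean_x_um[nrow(s)] - 750), 4 * se)
  expect_lt(abs(s$mean_y_um[nrow(s)] - 750), 4 * se)
  # adapted bias 0.150 -> run->tumble 1.366/s vs tumble->run 5/s
  B_ad <- cw_bias(cheyp_from_activity(1 / 3, params), params)
  r <- switching_rates(B_ad, params)
  expected_frac <- r$run_to_tumble[1] / (r$run_to_tumble[1] + r$tumble_to_run[1])
  frac <- mean(res$ensemble$tumbling)
  expect_equal(frac, expected_frac, tolerance = 0.12)
})

test_that("cells are conserved in-arena and runs are seed-deterministic", {
  f <- oscillating_field(1, 200)
  cfg <- sim_config(n_cells = 300, dt = 0.01, n_periods = 1, rng_seed = 3)
  r1 <- run_simulation(cfg, f, params, return_ensemble = TRUE)
  r2 <- run_simulation(cfg, f, params, return_ensemble = TRUE)
  expect_identical(r1$summary$mean_x_um, r2$summary$mean_x_um)
  expect_identical(r1$ensemble$x, r2$ensemble$x)
  ens <- r1$ensemble
  expect_length(ens$x, 300)
  expect_true(all(ens$x >= 0 & ens$x <= 1500))
  expect_true(all(ens$y >= 0 & ens$y <= 1500))
  expect_true(all(ens$m >= 0 & ens$m <= 4))
  cfg2 <- cfg; cfg2$rng_seed <- 4L
  r3 <- run_simulation(cfg2, f, params)
  expect_false(identical(r1$summary$mean_x_um, r3$mean_x_um))
})

test_that("R and compiled engines agree statistically", {
  f <- oscillating_field(1, 60)
  cfg <- sim_config(n_cells = 400, dt = 0.01, n_periods = 1, rng_seed = 9)
  s_cpp <- run_simulation(cfg, f, params, engine = "cpp")
  s_r <- run_simulation(cfg, f, params, engine = "r")
  # same drift signal up to ensemble noise (SE of mean x ~ 430/sqrt(400) um,
  # but paired over the same initial ensemble, so differences stay small)
  expect_lt(max(abs(s_cpp$mean_x_um - s_r$mean_x_um)), 40)
  expect_equal(mean(s_cpp$mean_x_um), mean(s_r$mean_x_um), tolerance = 0.03)
})

test_that("chemotactic drift climbs a static linear gradient", {
  lf <- linear_field(0, 1, 0, 1500)   # attractant increases with x
  cfg <- sim_config(n_cells = 1500, dt = 0.01, duration = 300, rng_seed = 21)
  s <- run_simulation(cfg, lf, params)
  drift <- s$mean_x_um[nrow(s)] - s$mean_x_um[1]
  se <- 1500 / sqrt(12) / sqrt(cfg$n_cells)
  expect_gt(drift, 3 * se)
})

test_that("a too-coarse timestep is rejected", {
  f <- oscillating_field(1, 60)
  cfg <- sim_config(n_cells = 10, dt = 0.3, n_periods = 1, record_interval = 0.3)
  expect_error(run_simulation(cfg, f, params), "timestep too coarse")
})

test_that("trajectory CSV round-trips with its seed header", {
  f <- oscillating_field(1, 100)
  cfg <- sim_config(n_cells = 50, dt = 0.01, n_periods = 1, rng_seed = 13)
  s <- run_simulation(cfg, f, params)
  path <- tempfile(fileext = ".csv")
  write_trajectory(s, path)
  s2 <- read_trajectory(path)
  expect_equal(attr(s2, "seed"), 13L)
  expect_equal(s2$mean_x_um, s$mean_x_um, tolerance = 1e-9)
  expect_equal(s2$t_s, s$t_s)
})
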