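#' Simulation configuration for the run-and-tumble model
#'
#' Defaults reproduce the study conditions: a 1500 x 1500 um arena with
#' reflective x-boundaries and periodic y-boundaries, 10,000 cells swimming
#' at 25 um/s with rotational diffusion 0.062 rad^2/s, a 0.01 s timestep and
#' at least four source periods.
#'
#' @param arena_x,arena_y Arena dimensions, um.
#' @param n_cells Ensemble size.
#' @param dt Timestep, s.
#' @param speed Run speed, um/s.
#' @param rot_diffusion Rotational diffusion constant, rad^2/s.
#' @param n_periods Number of source periods to simulate (oscillating field).
#' @param duration Simulated time, s (linear field, which has no period).
#' @param record_interval Interval between mean-position records, s.
#' @param signal_interval Interval at which the compiled engine refreshes
#'   each cell's signaling state (ligand read, methylation Euler step, CW
#'   bias), s; motor transitions and motion still advance every `dt`. The
#'   default 0.04 s sits orders of magnitude below the fastest signaling
#'   timescale (~200 s methylation relaxation).
#' @param rng_seed Integer seed; every run is reproducible under it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(arena_x = 1500, arena_y = 1500, n_cells = 10000,
                       dt = 0.01, speed = 25, rot_diffusion = 0.062,
                       n_periods = 4, duration = NULL,
                       record_interval = 1, signal_interval = 0.04,
                       rng_seed = 1) {
  stopifnot(dt > 0, n_cells >= 1, arena_x > 0, arena_y > 0,
            n_periods >= 1, speed >= 0, rot_diffusion >= 0,
            record_interval >= dt, signal_interval > 0)
  structure(list(arena_x = arena_x, arena_y = arena_y, n_cells = n_cells,
                 dt = dt, speed = speed, rot_diffusion = rot_diffusion,
                 n_periods = n_periods, duration = duration,
                 record_interval = record_interval,
                 signal_interval = signal_interval,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Draw tumble angles from the classic reorientation distribution
#'
#' Density \eqn{P(\theta) = 0.5 (1 + \cos\theta)\sin\theta} on \eqn{[0, \pi]},
#' favouring forward-biased reorientations (mean \eqn{3\pi/8}). Sampling is
#' by exact inverse CDF: with \eqn{F(\theta) = (1-\cos\theta)(3+\cos\theta)/4},
#' \eqn{\theta = \arccos(2\sqrt{u} - 1)} for uniform `u`.
#'
#' @param n Number of draws.
#' @return Angles in radians, in \eqn{[0, \pi]}.
#' @export
sample_tumble_angle <- function(n) {
  acos(2 * sqrt(stats::runif(n)) - 1)
}

#' Initialise a cell ensemble adapted to the local field
#'
#' Positions uniform over the arena, headings uniform on \eqn{[0, 2\pi)},
#' all cells running, and methylation set by [adapted_methylation()] at the
#' local concentration at time `t0`, so every cell starts at the adapted
#' activity \eqn{k_R/(k_R + k_B)}.
#'
#' @param config A [sim_config()].
#' @param field A potassium field object.
#' @param params A [signaling_params()].
#' @param t0 Initialisation time, s.
#' @return An object of class `cell_ensemble`: list of vectors
#'   `x`, `y`, `theta`, `m`, `tumbling` plus derived `a`, `Yp`, `B`.
#' @export
initialize_cells <- function(config, field, params = signaling_params(),
                             t0 = 0) {
  n <- config$n_cells
  if (n < 1) stop("n_cells must be at least 1")
  x <- stats::runif(n, 0, config$arena_x)
  y <- stats::runif(n, 0, config$arena_y)
  theta <- stats::runif(n, 0, 2 * pi)
  L <- field_concentration(field, x, t0)
  m <- adapted_methylation(L, params)
  ens <- list(x = x, y = y, theta = theta, m = m,
              tumbling = rep(FALSE, n))
  ens <- refresh_signaling(ens, L, params)
  structure(ens, class = "cell_ensemble")
}

refresh_signaling <- function(ens, L, params) {
  ens$a <- kinase_activity(ens$m, L, params)
  ens$Yp <- cheyp_from_activity(ens$a, params)
  ens$B <- cw_bias(ens$Yp, params)
  ens
}

#' Advance a cell ensemble by one timestep (reference implementation)
#'
#' Vectorised R implementation of the per-step update, kept as the readable
#' reference against which the compiled loop is cross-checked: read local
#' concentration at time `t`, Euler-update methylation, recompute activity /
#' CheY-P / CW bias, draw motor-state transitions with probability
#' `rate * dt`, move runners (constant speed, rotational diffusion with
#' per-step heading variance `2 * rot_diffusion * dt`), reorient cells
#' leaving a tumble by a [sample_tumble_angle()] rotation of random sign,
#' and apply periodic-y / reflective-x boundaries.
#'
#' @param ens A `cell_ensemble`.
#' @param field A potassium field object.
#' @param params A [signaling_params()].
#' @param config A [sim_config()].
#' @param t Time at the start of the step, s.
#' @return The ensemble at `t + dt`.
#' @export
step_cells <- function(ens, field, params, config, t) {
  dt <- config$dt
  L <- field_concentration(field, ens$x, t)
  a_old <- kinase_activity(ens$m, L, params)
  ens$m <- methylation_step(ens$m, a_old, dt, params)
  ens <- refresh_signaling(ens, L, params)
  rates <- switching_rates(ens$B, params)
  if (max(rates$run_to_tumble, rates$tumble_to_run) * dt > 1)
    stop("rate * dt exceeds 1: timestep too coarse for the switching rates")

  u <- stats::runif(length(ens$x))
  was_tumbling <- ens$tumbling
  start_tumble <- !was_tumbling & (u < rates$run_to_tumble * dt)
  exit_tumble <- was_tumbling & (u < rates$tumble_to_run * dt)
  ens$tumbling <- (was_tumbling & !exit_tumble) | start_tumble

  n_exit <- sum(exit_tumble)
  if (n_exit > 0) {
    ang <- sample_tumble_angle(n_exit)
    sgn <- ifelse(stats::runif(n_exit) < 0.5, -1, 1)
    ens$theta[exit_tumble] <- ens$theta[exit_tumble] + sgn * ang
  }

  run <- !ens$tumbling
  n_run <- sum(run)
  if (n_run > 0) {
    ens$theta[run] <- ens$theta[run] +
      stats::rnorm(n_run, 0, sqrt(2 * config$rot_diffusion * dt))
    xn <- ens$x[run] + config$speed * dt * cos(ens$theta[run])
    yn <- ens$y[run] + config$speed * dt * sin(ens$theta[run])
    # reflective x
    refl_lo <- xn < 0
    refl_hi <- xn > config$arena_x
    xn[refl_lo] <- -xn[refl_lo]
    xn[refl_hi] <- 2 * config$arena_x - xn[refl_hi]
    th <- ens$theta[run]
    th[refl_lo | refl_hi] <- pi - th[refl_lo | refl_hi]
    ens$theta[run] <- th
    # periodic y
    yn <- yn %% config$arena_y
    ens$x[run] <- xn
    ens$y[run] <- yn
  }
  ens
}

#' Run the full stochastic swimming simulation
#'
#' Iterates the per-step update for `n_periods` source periods (oscillating
#' field) or `duration` seconds (linear field), recording ensemble mean
#' positions every `record_interval` seconds. The compiled engine and the R
#' reference engine implement the same update; the compiled one is the
#' default and is orders of magnitude faster.
#'
#' @param config A [sim_config()].
#' @param field A potassium field object.
#' @param params A [signaling_params()].
#' @param engine `"cpp"` (default) or `"r"` (reference; small runs only).
#' @param return_ensemble Also return the final cell ensemble?
#' @return A `trajectory_summary`: data.frame with columns `t_s`,
#'   `mean_x_um`, `mean_y_um`; attributes carry the config, field and seed.
#'   With `return_ensemble = TRUE`, a list `(summary, ensemble)`.
#' @export
run_simulation <- function(config, field, params = signaling_params(),
                           engine = c("cpp", "r"),
                           return_ensemble = FALSE) {
  engine <- match.arg(engine)
  if (inherits(field, "oscillating_field")) {
    total_time <- config$n_periods * field$period
  } else {
    if (is.null(config$duration))
      stop("config$duration is required for a non-periodic field")
    total_time <- config$duration
  }
  n_steps <- round(total_time / config$dt)
  record_every <- max(1L, round(config$record_interval / config$dt))

  set.seed(config$rng_seed)
  ens <- initialize_cells(config, field, params, t0 = 0)

  if (engine == "cpp") {
    if (inherits(field, "oscillating_field")) {
      fargs <- list(field_type = 0L, L0 = field$L0, period = field$period,
                    kwave = wavenumber(field), c0 = 0, slope = 0)
    } else {
      slope <- (field$c_high - field$c_low) / (field$y_high - field$y_low)
      fargs <- list(field_type = 1L, L0 = 0, period = 0, kwave = 0,
                    c0 = field$c_low - slope * field$y_low, slope = slope)
    }
    res <- simulate_swim_cpp(
      ens$x, ens$y, ens$theta, ens$m, ens$tumbling,
      fargs$field_type, fargs$L0, fargs$period, fargs$kwave,
      fargs$c0, fargs$slope,
      params$N, params$alpha, params$m0, params$Koff, params$Kon,
      params$kR, params$kB, params$yp_scale,
      params$motor_hill, params$motor_K,
      params$tumble_rate_scale, params$detumble_rate,
      params$m_range[1], params$m_range[2],
      config$arena_x, config$arena_y, config$speed, config$rot_diffusion,
      config$dt, 0, n_steps, record_every,
      max(1L, round((config$signal_interval %||% 0.04) / config$dt)))
    summary <- data.frame(t_s = res$time, mean_x_um = res$mean_x,
                          mean_y_um = res$mean_y)
    final <- structure(list(x = res$x, y = res$y, theta = res$theta,
                            m = res$m, tumbling = res$tumbling),
                       class = "cell_ensemble")
  } else {
    times <- seq(0, n_steps) * config$dt
    rec_idx <- seq(0, n_steps, by = record_every)
    mx <- my <- numeric(length(rec_idx))
    mx[1] <- mean(ens$x); my[1] <- mean(ens$y)
    ir <- 2
    for (s in seq_len(n_steps)) {
      ens <- step_cells(ens, field, params, config, times[s])
      if (s %% record_every == 0) {
        mx[ir] <- mean(ens$x); my[ir] <- mean(ens$y); ir <- ir + 1
      }
    }
    summary <- data.frame(t_s = rec_idx * config$dt, mean_x_um = mx,
                          mean_y_um = my)
    final <- ens
  }

  attr(summary, "config") <- config
  attr(summary, "field") <- field
  attr(summary, "seed") <- config$rng_seed
  class(summary) <- c("trajectory_summary", "data.frame")
  if (return_ensemble) list(summary = summary, ensemble = final)
  else summary
}

#' Write / read a trajectory summary as CSV
#'
#' The CSV carries `t_s, mean_x_um, mean_y_um` with the seed recorded in a
#' `#`-prefixed header comment, and round-trips through [read_trajectory()].
#'
#' @param summary A `trajectory_summary`.
#' @param path Output path.
#' @return `path`, invisibly (writer); the summary (reader).
#' @export
write_trajectory <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(summary, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(as.data.frame(summary), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  seed <- NULL
  if (startsWith(first, "#")) {
    seed <- as.integer(sub(".*seed: *", "", first))
  }
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "seed") <- seed
  class(df) <- c("trajectory_summary", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
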