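#' Synthetic pH-artifact calibration curves
#'
#' Emulates the no-receptor-strain calibration: smooth, monotone per-channel
#' brightness factors rising from \eqn{C(0) = 1} with a saturating shape in
#' concentration, tabulated at the calibration concentrations. By default
#' the CFP curve passes through 1.056 at 30 mM (the measured CFP brightness
#' ratio at that concentration); the YFP curve saturates lower, so the
#' uncorrected YFP/CFP ratio is biased inside stimulus windows — the
#' artifact the correction removes.
#'
#' @param conc_mM Calibration concentrations, mM.
#' @param cfp_sat,yfp_sat Saturating fractional brightness gains.
#' @param K_ph Concentration scale of the brightness response, mM.
#' @return A [ph_correction()] object; ground-truth curve parameters are
#'   attached as attribute `truth`.
#' @export
gen_ph_correction_curves <- function(conc_mM = c(0.01, 0.03, 0.1, 0.3, 1,
                                                 3, 10, 30, 100),
                                     cfp_sat = 0.0616, yfp_sat = 0.030,
                                     K_ph = 3) {
  shape <- function(L, sat) 1 + sat * L / (L + K_ph)
  corr <- ph_correction(conc_mM,
                        cfp_factor = shape(conc_mM, cfp_sat),
                        yfp_factor = shape(conc_mM, yfp_sat))
  attr(corr, "truth") <- list(cfp_sat = cfp_sat, yfp_sat = yfp_sat,
                              K_ph = K_ph, shape = shape)
  corr
}

#' Synthetic two-channel FRET trace with known ground truth
#'
#' Builds a photon-count trace whose underlying relative kinase activity
#' follows: baseline 1; on addition of concentration L, an immediate drop
#' to the Hill response \eqn{1/(1 + (L/K_{0.5})^h)}; exponential recovery
#' with time constant \eqn{\tau(L)} toward the adapted level set by the
#' adaptation percentage; return to baseline on removal. Channels are
#' scaled by the pH-artifact factors inside stimulus windows and Poisson
#' count noise is applied.
#'
#' @param schedule data.frame with `t_add`, `t_remove`, `conc_mM`.
#' @param h,K05 Ground-truth Hill parameters of the immediate response.
#' @param tau Recovery time constant(s), s: scalar or one per stimulus.
#' @param adapt_P Adaptation percentage(s) in \[0, 1\].
#' @param correction A [ph_correction()] whose curves multiply the channels
#'   in-window (`NULL` for no artifact).
#' @param saturated FRET value at zero activity (default 0.94).
#' @param mean_counts Mean baseline counts per sample per channel.
#' @param dt Sampling interval, s (1 Hz default, as for photon-counting
#'   PMTs).
#' @param t_end Trace end time, s.
#' @param noise Apply Poisson noise? (`FALSE` gives noiseless counts.)
#' @param seed Optional integer seed applied via [set.seed()].
#' @return A [fret_trace()]; ground truth (activity series, parameters) is
#'   attached as attribute `truth`.
#' @export
gen_fret_trace <- function(schedule, h = 0.88, K05 = 0.33,
                           tau = 60, adapt_P = 0.8,
                           correction = gen_ph_correction_curves(),
                           saturated = 0.94,
                           mean_counts = 1e6, dt = 1,
                           t_end = max(schedule$t_remove) + 100,
                           noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  schedule <- as.data.frame(schedule)
  n_stim <- nrow(schedule)
  tau <- rep_len(tau, n_stim)
  adapt_P <- rep_len(adapt_P, n_stim)
  t <- seq(0, t_end, by = dt)
  act <- rep(1, length(t))
  for (i in seq_len(n_stim)) {
    L <- schedule$conc_mM[i]
    a_drop <- 1 / (1 + (L / K05)^h)
    a_star <- a_drop + adapt_P[i] * (1 - a_drop)
    win <- t >= schedule$t_add[i] & t < schedule$t_remove[i]
    tw <- t[win] - schedule$t_add[i]
    act[win] <- a_star - (a_star - a_drop) * exp(-tw / tau[i])
    act[t >= schedule$t_remove[i]] <- 1
  }
  fret_true <- saturated + (1 - saturated) * act
  cfp <- rep(mean_counts, length(t))
  yfp <- mean_counts * fret_true            # baseline YFP/CFP ratio = 1
  if (!is.null(correction)) {
    for (i in seq_len(n_stim)) {
      win <- t >= schedule$t_add[i] & t < schedule$t_remove[i]
      L <- schedule$conc_mM[i]
      cfp[win] <- cfp[win] * ph_factor(correction, L, "cfp", extrapolate = TRUE)
      yfp[win] <- yfp[win] * ph_factor(correction, L, "yfp", extrapolate = TRUE)
    }
  }
  if (noise) {
    cfp <- stats::rpois(length(t), cfp)
    yfp <- stats::rpois(length(t), yfp)
    cfp[cfp == 0] <- 1; yfp[yfp == 0] <- 1
  }
  out <- fret_trace(t, cfp, yfp, schedule)
  attr(out, "truth") <- list(h = h, K05 = K05, tau = tau, adapt_P = adapt_P,
                             activity = act, fret = fret_true,
                             saturated = saturated)
  out
}

#' Standard dose-response stimulus schedule
#'
#' Non-overlapping addition/removal windows for a series of concentrations,
#' with a pre-stimulus baseline and inter-stimulus recovery gaps.
#'
#' @param conc_mM Concentrations, mM.
#' @param baseline Baseline duration before the first addition, s.
#' @param on,off Stimulus and recovery durations, s.
#' @return data.frame with `t_add`, `t_remove`, `conc_mM`.
#' @export
dose_schedule <- function(conc_mM = c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100),
                          baseline = 60, on = 60, off = 60) {
  n <- length(conc_mM)
  t_add <- baseline + (seq_len(n) - 1) * (on + off)
  data.frame(t_add = t_add, t_remove = t_add + on, conc_mM = conc_mM)
}

#' Synthetic bead-assay motor trace (two-state Markov motor)
#'
#' Continuous-time two-state (CCW/CW) Markov switching with exponential
#' dwell times, sampled uniformly; signed speed (positive CCW) with
#' Gaussian jitter. Optionally the CCW-to-CW rate changes inside a stimulus
#' window, emulating an attractant response. The long-run CW bias is
#' \eqn{k_1/(k_1 + k_2)} for rates \eqn{k_1} (CCW to CW) and \eqn{k_2}
#' (CW to CCW).
#'
#' @param duration Trace length, s.
#' @param rate_ccw_to_cw,rate_cw_to_ccw Switching rates, 1/s.
#' @param fs Sampling rate, Hz.
#' @param speed_hz Unsigned rotation speed, Hz.
#' @param jitter Gaussian speed jitter SD, Hz.
#' @param stimulus Optional list `(t_on, t_off, rate_ccw_to_cw)` replacing
#'   the CCW-to-CW rate inside the window.
#' @param seed Optional integer seed.
#' @return data.frame with `t_s`, `speed_hz`; ground-truth rates attached
#'   as attribute `truth`.
#' @export
gen_bead_trace <- function(duration = 600, rate_ccw_to_cw = 0.3,
                           rate_cw_to_ccw = 2.7, fs = 10,
                           speed_hz = 50, jitter = 3,
                           stimulus = NULL, seed = NULL) {
  stopifnot(rate_ccw_to_cw > 0, rate_cw_to_ccw > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / fs)
  k1 <- rep(rate_ccw_to_cw, length(t))
  if (!is.null(stimulus))
    k1[t >= stimulus$t_on & t < stimulus$t_off] <- stimulus$rate_ccw_to_cw
  # per-sample transition probabilities (dt << dwell times)
  dtau <- 1 / fs
  cw <- logical(length(t))
  state <- FALSE                     # start CCW
  u <- stats::runif(length(t))
  for (i in seq_along(t)) {
    rate <- if (state) rate_cw_to_ccw else k1[i]
    if (u[i] < rate * dtau) state <- !state
    cw[i] <- state
  }
  sp <- ifelse(cw, -1, 1) * (speed_hz + stats::rnorm(length(t), 0, jitter))
  out <- data.frame(t_s = t, speed_hz = sp)
  attr(out, "truth") <- list(rate_ccw_to_cw = rate_ccw_to_cw,
                             rate_cw_to_ccw = rate_cw_to_ccw,
                             bias = rate_ccw_to_cw /
                               (rate_ccw_to_cw + rate_cw_to_ccw),
                             speed_hz = speed_hz)
  out
}

#' Synthetic steady-state cell positions (exponential profile)
#'
#' Draws positions from a truncated exponential density
#' \eqn{\rho(y) \propto \exp(\lambda y)} over the channel (uniform when
#' \eqn{\lambda = 0}), increasing toward the source side, repeated over
#' frames; the transverse coordinate is uniform.
#'
#' @param n_cells Cells per frame.
#' @param lambda Decay constant, 1/um (>= 0).
#' @param width Channel extent along the gradient axis, um (default 388,
#'   twice the 194 um half-width of the observed region).
#' @param n_frames Number of frames.
#' @param frame_dt Frame interval, s.
#' @param transverse Extent of the transverse axis, um.
#' @param seed Optional integer seed.
#' @return A position table data.frame (`frame`, `t_s`, `cell_id`, `x_um`,
#'   `y_um`) with ground truth attached as attribute `truth`; the gradient
#'   runs along `y_um`.
#' @export
gen_positions <- function(n_cells = 10000, lambda = 0.0085, width = 388,
                          n_frames = 1, frame_dt = 1, transverse = 388,
                          seed = NULL) {
  stopifnot(lambda >= 0, width > 0)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) {
    u <- stats::runif(n)
    if (lambda == 0) u * width
    else log1p(u * expm1(lambda * width)) / lambda   # inverse CDF
  }
  tabs <- lapply(seq_len(n_frames), function(f) {
    data.frame(frame = f, t_s = (f - 1) * frame_dt,
               cell_id = seq_len(n_cells),
               x_um = stats::runif(n_cells, 0, transverse),
               y_um = draw(n_cells))
  })
  out <- do.call(rbind, tabs)
  attr(out, "truth") <- list(lambda = lambda, width = width)
  out
}

#' Generate the full synthetic dataset bundle
#'
#' Writes every synthetic input the analysis pipelines consume — a
#' dose-response FRET trace, pH-calibration table, a bead trace and a
#' position table — as CSVs with a ground-truth sidecar (YAML), all
#' reproducible from one seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the list of file paths written.
#' @export
gen_bundle <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  corr <- gen_ph_correction_curves()
  sched <- dose_schedule()
  trace <- gen_fret_trace(sched, correction = corr)
  bead <- gen_bead_trace()
  pos <- gen_positions(n_cells = 2000)

  paths <- list(
    fret = file.path(dir, "fret_trace.csv"),
    calibration = file.path(dir, "ph_calibration.csv"),
    schedule = file.path(dir, "stimulus_schedule.csv"),
    bead = file.path(dir, "bead_trace.csv"),
    positions = file.path(dir, "positions.csv"),
    truth = file.path(dir, "ground_truth.yaml"))
  write_fret_trace(trace, paths$fret)
  utils::write.csv(data.frame(conc_mM = corr$conc_mM,
                              cfp_factor = corr$cfp_factor,
                              yfp_factor = corr$yfp_factor),
                   paths$calibration, row.names = FALSE)
  utils::write.csv(sched, paths$schedule, row.names = FALSE)
  write_bead_trace(bead, paths$bead)
  write_positions(pos, paths$positions)
  tr <- attr(trace, "truth")
  yaml::write_yaml(list(seed = seed,
                        hill = list(h = tr$h, K05 = tr$K05),
                        tau_s = tr$tau, adapt_P = tr$adapt_P,
                        bead = attr(bead, "truth")[c("rate_ccw_to_cw",
                                                     "rate_cw_to_ccw", "bias")],
                        positions = attr(pos, "truth")),
                   paths$truth)
  invisible(paths)
}
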