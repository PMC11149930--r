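#' Two-channel FRET trace with a stimulus schedule
#'
#' Container for photon-count time series of the CFP (donor) and YFP
#' (acceptor) channels together with the schedule of attractant
#' addition/removal windows.
#'
#' @param t Time, s.
#' @param cfp,yfp Channel counts (> 0).
#' @param schedule data.frame with columns `t_add`, `t_remove`, `conc_mM`
#'   and optionally `label`; intervals must be non-overlapping and within
#'   the time range.
#' @return An object of class `fret_trace`.
#' @export
fret_trace <- function(t, cfp, yfp, schedule) {
  stopifnot(length(t) == length(cfp), length(t) == length(yfp))
  if (any(cfp <= 0) || any(yfp <= 0))
    stop("channel counts must be positive")
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("t_add", "t_remove", "conc_mM") %in% names(schedule)))
  o <- order(schedule$t_add)
  schedule <- schedule[o, , drop = FALSE]
  if (nrow(schedule) > 1 &&
      any(schedule$t_add[-1] < schedule$t_remove[-nrow(schedule)]))
    stop("stimulus windows overlap")
  if (nrow(schedule) > 0 &&
      (min(schedule$t_add) < min(t) || max(schedule$t_remove) > max(t)))
    stop("stimulus schedule extends beyond the trace")
  structure(list(t = t, cfp = cfp, yfp = yfp, schedule = schedule),
            class = "fret_trace")
}

#' Write / read a FRET trace as CSV (columns t_s, cfp_counts, yfp_counts)
#'
#' The stimulus schedule travels in the configuration, not the CSV; supply
#' it to the reader.
#'
#' @param trace A [fret_trace()].
#' @param path File path.
#' @param schedule Stimulus schedule for the reader.
#' @return `path` invisibly (writer); a `fret_trace` (reader).
#' @export
write_fret_trace <- function(trace, path) {
  utils::write.csv(data.frame(t_s = trace$t, cfp_counts = trace$cfp,
                              yfp_counts = trace$yfp),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fret_trace
#' @export
read_fret_trace <- function(path, schedule) {
  df <- utils::read.csv(path)
  fret_trace(df$t_s, df$cfp_counts, df$yfp_counts, schedule)
}

#' Normalized FRET ratio of a trace
#'
#' YFP/CFP ratio divided by its mean over a pre-stimulus baseline window,
#' so the baseline level is 1 by construction.
#'
#' @param trace A [fret_trace()].
#' @param baseline Length-2 window (s) preceding the first stimulus.
#' @return data.frame with `t_s` and `fret` (dimensionless).
#' @export
fret_ratio <- function(trace, baseline = NULL) {
  if (is.null(baseline)) {
    t_first <- if (nrow(trace$schedule)) min(trace$schedule$t_add) else max(trace$t)
    baseline <- c(min(trace$t), t_first)
  }
  if (nrow(trace$schedule) && baseline[2] > min(trace$schedule$t_add) + 1e-9)
    stop("baseline window must precede the first stimulus")
  ratio <- trace$yfp / trace$cfp
  # upper edge exclusive: a sample at the first addition time is stimulated
  in_base <- trace$t >= baseline[1] & trace$t < baseline[2]
  if (!any(in_base)) stop("baseline window contains no samples")
  data.frame(t_s = trace$t, fret = ratio / mean(ratio[in_base]))
}

#' pH-artifact correction curves (no-receptor calibration)
#'
#' Tabulated per-channel correction factors \eqn{C_{pH}(L)}: the ratio of
#' the PMT signal after KCl addition to before, measured in a strain with
#' no chemoreceptors, as a function of KCl concentration. Intracellular pH
#' rises with external potassium and brightens CFP and YFP unequally, which
#' masquerades as imprecise adaptation in the raw ratio; dividing each
#' channel by its factor inside each stimulus window removes the artifact.
#' \eqn{C_{pH}(0) = 1} by definition.
#'
#' @param conc_mM Calibrated concentrations, mM (strictly positive, sorted).
#' @param cfp_factor,yfp_factor Correction factors at those concentrations.
#' @return An object of class `ph_correction` with an interpolator per
#'   channel (monotone piecewise-linear in log-concentration between
#'   calibrated points; linear toward \eqn{C(0)=1} below the lowest point).
#' @export
ph_correction <- function(conc_mM, cfp_factor, yfp_factor) {
  stopifnot(all(conc_mM > 0), !is.unsorted(conc_mM),
            all(cfp_factor > 0), all(yfp_factor > 0),
            length(conc_mM) == length(cfp_factor),
            length(conc_mM) == length(yfp_factor))
  structure(list(conc_mM = conc_mM, cfp_factor = cfp_factor,
                 yfp_factor = yfp_factor),
            class = "ph_correction")
}

#' Evaluate a pH-correction factor at given concentrations
#'
#' Interpolates the calibrated per-channel correction curve: monotone
#' piecewise-linear in log-concentration between calibrated points, linear
#' toward the \eqn{C(0) = 1} anchor below the lowest point; constant beyond
#' the highest point when extrapolation is enabled.
#'
#' @param corr A [ph_correction()].
#' @param L Concentration(s), mM.
#' @param channel `"cfp"` or `"yfp"`.
#' @param extrapolate Allow concentrations above the calibrated range?
#' @return Correction factor(s), dimensionless.
#' @export
ph_factor <- function(corr, L, channel = c("cfp", "yfp"),
                      extrapolate = FALSE) {
  channel <- match.arg(channel)
  fac <- corr[[paste0(channel, "_factor")]]
  cc <- corr$conc_mM
  vapply(L, function(l) {
    if (l == 0) return(1)
    if (l < 0) stop("concentration must be non-negative")
    if (l > max(cc) && !extrapolate)
      stop("concentration ", l, " mM outside calibration range; ",
           "set extrapolate = TRUE to allow")
    if (l >= max(cc)) return(fac[length(fac)])
    if (l <= min(cc)) # linear toward the C(0) = 1 anchor
      return(1 + (fac[1] - 1) * l / cc[1])
    stats::approx(log(cc), fac, xout = log(l))$y
  }, numeric(1))
}

#' Apply the pH correction to a FRET trace
#'
#' Divides both channels by their correction factor at the scheduled
#' concentration, inside each stimulus window only (from addition to
#' removal); samples outside windows are unchanged.
#'
#' @param trace A [fret_trace()].
#' @param correction A [ph_correction()].
#' @param extrapolate Allow concentrations above the calibrated range?
#' @return A corrected [fret_trace()].
#' @export
ph_correct <- function(trace, correction, extrapolate = FALSE) {
  cfp <- trace$cfp; yfp <- trace$yfp
  for (i in seq_len(nrow(trace$schedule))) {
    win <- trace$schedule[i, ]
    idx <- trace$t >= win$t_add & trace$t < win$t_remove
    cfp[idx] <- cfp[idx] / ph_factor(correction, win$conc_mM, "cfp", extrapolate)
    yfp[idx] <- yfp[idx] / ph_factor(correction, win$conc_mM, "yfp", extrapolate)
  }
  fret_trace(trace$t, cfp, yfp, trace$schedule)
}

#' Relative kinase activity from normalized FRET
#'
#' Affine rescaling mapping the pre-stimulus FRET value 1 to activity 1 and
#' the saturated-stimulus value (default 0.94) to activity 0.
#'
#' @param fret Normalized FRET values.
#' @param saturated FRET value at saturating stimulus (< 1).
#' @return Relative kinase activity (same length).
#' @export
relative_activity <- function(fret, saturated = 0.94) {
  stopifnot(saturated < 1)
  (fret - saturated) / (1 - saturated)
}

#' Dose-response extraction: immediate response per stimulus window
#'
#' For each scheduled concentration, the response is the smoothed minimum of
#' the normalized FRET signal within a detection window after addition
#' (default 30 s), converted to relative kinase activity.
#'
#' @param trace A [fret_trace()] (pH-corrected or not).
#' @param detect_window Seconds after addition searched for the response.
#' @param smooth_n Moving-average half-width in samples for the minimum.
#' @param saturated Saturated FRET value passed to [relative_activity()].
#' @return An object of class `dose_response`: data.frame with `conc_mM`
#'   and `rel_activity`, sorted by concentration.
#' @export
dose_response <- function(trace, detect_window = 30, smooth_n = 2,
                          saturated = 0.94) {
  fr <- fret_ratio(trace)
  w <- 2 * smooth_n + 1
  sm <- as.numeric(stats::filter(fr$fret, rep(1 / w, w), sides = 2))
  resp <- vapply(seq_len(nrow(trace$schedule)), function(i) {
    win <- trace$schedule[i, ]
    t_end <- min(win$t_add + detect_window, win$t_remove)
    idx <- which(fr$t_s >= win$t_add & fr$t_s <= t_end & !is.na(sm))
    if (!length(idx)) stop("no samples in detection window ", i)
    min(sm[idx])
  }, numeric(1))
  out <- data.frame(conc_mM = trace$schedule$conc_mM,
                    rel_activity = relative_activity(resp, saturated))
  out <- out[order(out$conc_mM), , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of \eqn{a(L) = 1/(1 + (L/K_{0.5})^h)} to relative
#' kinase activity (asymptotes fixed at 1 and 0 by the relative-activity
#' rescaling). Fitted on log-parameters for positivity; returns estimates
#' with asymptotic standard errors.
#'
#' @param dose A `dose_response` (or data.frame with `conc_mM`,
#'   `rel_activity`); needs at least 3 distinct concentrations.
#' @param start Optional starting values `list(h =, K =)`.
#' @return List with `h`, `K0.5`, `se_h`, `se_K`, `fitted`, and the `nls`
#'   fit object.
#' @export
fit_hill <- function(dose, start = NULL) {
  dose <- as.data.frame(dose)
  stopifnot(length(unique(dose$conc_mM)) >= 3, all(dose$conc_mM > 0))
  if (is.null(start)) {
    below <- dose$conc_mM[dose$rel_activity < 0.5]
    Kg <- if (length(below)) min(below) else stats::median(dose$conc_mM)
    start <- list(h = 1, K = Kg)
  }
  L <- dose$conc_mM; yobs <- dose$rel_activity
  model <- function(p) 1 / (1 + (L / exp(p[2]))^exp(p[1]))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(logh = log(start$h), logK = log(start$K)),
                       fn = function(p) model(p) - yobs,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Hill fit failed to converge: ",
                             conditionMessage(e)))
  if (fit$info < 1 || fit$info > 4)
    stop("Hill fit failed to converge: ", fit$message)
  cf <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  h <- exp(cf[["logh"]]); K <- exp(cf[["logK"]])
  list(h = h, K0.5 = K,
       se_h = h * se[1], se_K = K * se[2],   # delta method on log scale
       fitted = model(cf), fit = fit)
}

#' Fit the MWC receptor-cluster model to a dose-response curve
#'
#' Bounded least-squares fit of
#' \eqn{a(L) = 1/(1 + \exp[N(f_m + f_L(L))])}, normalized by its L = 0
#' baseline so the curve starts at relative activity 1, with parameters
#' \eqn{(N, f_m, K_{off}, K_{on})}. Four-parameter MWC fits to a monotone
#' curve are ill-conditioned, so the fit is multi-started from a coarse
#' grid and the best converged solution returned.
#'
#' @param dose A `dose_response`; needs >= 4 distinct concentrations
#'   spanning below `Koff` and above 1 mM for identifiability.
#' @param n_starts Number of multi-start initialisations.
#' @param bounds List of length-2 ranges for `N`, `fm`, `Koff`, `Kon`.
#' @return List with `N`, `fm`, `Koff`, `Kon`, `rss`, `at_bound` (logical),
#'   and `fitted`.
#' @export
fit_mwc <- function(dose, n_starts = 32,
                    bounds = list(N = c(0.05, 20), fm = c(-5, 5),
                                  Koff = c(1e-3, 10), Kon = c(1, 1e3))) {
  dose <- as.data.frame(dose)
  stopifnot(length(unique(dose$conc_mM)) >= 4)
  if (stats::sd(dose$rel_activity) < 1e-8)
    stop("dose-response data are flat: MWC parameters not identifiable")
  L <- dose$conc_mM; yobs <- dose$rel_activity

  model <- function(p) {
    pr <- signaling_params(N = p[1], Koff = p[3], Kon = max(p[4], p[3] * 1.0001))
    a <- kinase_activity(NULL, L, pr, fm_override = p[2])
    a0 <- kinase_activity(NULL, 0, pr, fm_override = p[2])
    a / a0
  }
  resid_fn <- function(p) model(p) - yobs
  lower <- c(bounds$N[1], bounds$fm[1], bounds$Koff[1], bounds$Kon[1])
  upper <- c(bounds$N[2], bounds$fm[2], bounds$Koff[2], bounds$Kon[2])

  # fixed multi-start grid (deterministic, independent of the caller's RNG)
  u <- function(k, lo, hi) lo + (hi - lo) * ((seq_len(n_starts) * k) %% 97) / 96
  starts <- cbind(u(13, 0.2, 5), u(29, -2, 2),
                  exp(u(41, log(0.01), log(5))),
                  exp(u(59, log(2), log(500))))
  starts[1, ] <- c(1, 1, 0.2, 50)   # always include a domain-informed start

  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) stop("MWC fit failed from every start")
  p <- best$par
  at_bound <- any(abs(p - lower) < 1e-8 * pmax(1, abs(lower))) ||
    any(abs(p - upper) < 1e-8 * pmax(1, abs(upper)))
  if (at_bound)
    warning("MWC fit hit a parameter bound; parameter(s) weakly identified")
  list(N = p[1], fm = p[2], Koff = p[3], Kon = p[4],
       rss = best$rss, at_bound = at_bound, fitted = model(p))
}

#' Half-drop concentration of an MWC dose-response curve
#'
#' The concentration at which activity falls halfway from its L = 0
#' baseline toward zero; root-found on the analytic curve. With the
#' calibrated potassium parameters this reproduces the Hill-fit
#' half-maximal concentration (about 0.33 mM).
#'
#' @param params A [signaling_params()].
#' @param fm Fixed methylation free energy (default the calibrated
#'   `baseline_fm`).
#' @return Concentration, mM.
#' @export
mwc_half_drop <- function(params = signaling_params(),
                          fm = params$baseline_fm) {
  a0 <- kinase_activity(NULL, 0, params, fm_override = fm)
  f <- function(L) kinase_activity(NULL, L, params, fm_override = fm) - a0 / 2
  stats::uniroot(f, c(1e-8, params$Kon * 0.999), tol = 1e-12)$root
}

#' Adaptation metrics of a FRET step response
#'
#' From the normalized FRET response to a stepwise addition: `R_low` is the
#' smoothed post-addition minimum, `R_star` the mean over the final fraction
#' of the stimulus window (the adapted plateau), the adaptation percentage
#' is \eqn{P = (R^* - R_L)/(1 - R_L)}, and the adaptation time is the time
#' from the minimum until the signal first recovers 63% of the way from
#' `R_low` to `R_star`.
#'
#' @param t Time, s.
#' @param fret Normalized FRET series.
#' @param window Length-2 stimulus window `(t_add, t_remove)`, s.
#' @param plateau_frac Final fraction of the window averaged for `R_star`.
#' @param smooth_n Moving-average half-width (samples) for the minimum.
#' @param recovery Recovery fraction defining the adaptation time.
#' @return List with `R_low`, `R_star`, `P`, `T_adapt` (s; `NA` flagged when
#'   there is no recovery), `t_low`.
#' @export
adaptation_metrics <- function(t, fret, window, plateau_frac = 0.2,
                               smooth_n = 2, recovery = 0.63) {
  idx <- which(t >= window[1] & t <= window[2])
  if (length(idx) < 5) stop("stimulus window too short for plateau detection")
  w <- 2 * smooth_n + 1
  sm <- as.numeric(stats::filter(fret, rep(1 / w, w), sides = 2))
  sm_w <- sm[idx]; t_w <- t[idx]
  ok <- !is.na(sm_w)
  i_low <- which.min(replace(sm_w, !ok, Inf))
  R_low <- sm_w[i_low]; t_low <- t_w[i_low]
  # keep the plateau clear of the window end, where the smoother would mix
  # in post-removal samples
  dt_s <- stats::median(diff(t))
  plat <- t_w >= window[2] - plateau_frac * diff(window) &
    t_w <= window[2] - smooth_n * dt_s
  R_star <- mean(sm_w[plat & ok])
  if (!is.finite(R_star) || R_star <= R_low) {
    return(list(R_low = R_low, R_star = max(R_star, R_low), P = 0,
                T_adapt = NA_real_, t_low = t_low, no_recovery = TRUE))
  }
  P <- (R_star - R_low) / (1 - R_low)
  thresh <- R_low + recovery * (R_star - R_low)
  after <- which(t_w > t_low & ok & sm_w >= thresh)
  T_adapt <- if (length(after)) t_w[min(after)] - t_low else NA_real_
  list(R_low = R_low, R_star = R_star, P = P, T_adapt = T_adapt,
       t_low = t_low, no_recovery = FALSE)
}

#' Write / read a dose-response table as CSV (conc_mM, rel_activity)
#'
#' @param dose A `dose_response`.
#' @param path File path.
#' @return `path` invisibly (writer); a `dose_response` (reader).
#' @export
write_dose_response <- function(dose, path) {
  utils::write.csv(as.data.frame(dose), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("dose_response", "data.frame")
  df
}
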