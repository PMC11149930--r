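#' Ligand-dependent free energy of the receptor cluster
#'
#' \eqn{f_L(L) = \ln[(1 + L/K_{off})/(1 + L/K_{on})]}, in kT units.
#' Monotone increasing in `L`, zero at `L = 0`, bounded above by
#' \eqn{\ln(K_{on}/K_{off})}.
#'
#' @param L Ligand (potassium) concentration, mM. Vectorised.
#' @param params A [signaling_params()] object.
#' @return Free energy in kT (same length as `L`).
#' @export
ligand_free_energy <- function(L, params = signaling_params()) {
  if (any(L < 0)) stop("concentration L must be non-negative")
  log1p(L / params$Koff) - log1p(L / params$Kon)
}

#' Receptor-cluster kinase activity (MWC two-state model)
#'
#' \eqn{a = 1/(1 + \exp[N (f_m + f_L(L))])} with
#' \eqn{f_m = \alpha (m - m_0)}, or a fixed constant when `fm_override`
#' is supplied (the convention used when fitting dose-response curves with
#' methylation frozen at its pre-stimulus level).
#'
#' @param m Methylation level (methyl groups). Ignored if `fm_override` given.
#' @param L Ligand concentration, mM.
#' @param params A [signaling_params()] object.
#' @param fm_override Optional fixed methylation free energy (kT).
#' @return Activity in (0, 1). Vectorised over `m` and `L`.
#' @export
kinase_activity <- function(m, L, params = signaling_params(),
                            fm_override = NULL) {
  fm <- if (is.null(fm_override)) params$alpha * (m - params$m0) else fm_override
  fL <- ligand_free_energy(L, params)
  1 / (1 + exp(params$N * (fm + fL)))
}

#' One forward-Euler step of the methylation dynamics
#'
#' \eqn{dm/dt = k_R (1 - a) - k_B a}; the updated level is clamped to
#' `params$m_range`. The fixed point of the coupled (a, m) system is
#' \eqn{a^* = k_R/(k_R + k_B)}, independent of ligand concentration.
#'
#' @param m Current methylation level.
#' @param a Current kinase activity.
#' @param dt Timestep, s (> 0).
#' @param params A [signaling_params()] object.
#' @return Updated methylation level(s).
#' @export
methylation_step <- function(m, a, dt, params = signaling_params()) {
  stopifnot(dt > 0)
  m2 <- m + dt * (params$kR * (1 - a) - params$kB * a)
  pmin(pmax(m2, params$m_range[1]), params$m_range[2])
}

#' CheY-P concentration from kinase activity
#'
#' Linear coupling `Yp = yp_scale * a` (default 7.86 uM at full activity).
#'
#' @param a Kinase activity in \[0, 1\].
#' @param params A [signaling_params()] object.
#' @return CheY-P concentration, uM.
#' @export
cheyp_from_activity <- function(a, params = signaling_params()) {
  stopifnot(all(a >= 0), all(a <= 1))
  params$yp_scale * a
}

#' Motor clockwise bias from CheY-P concentration
#'
#' Hill function \eqn{B = Yp^h / (Yp^h + K^h)} with coefficient
#' `motor_hill` (default 10.3) and half-point `motor_K` (default 3.1 uM).
#'
#' @param Yp CheY-P concentration, uM (>= 0).
#' @param params A [signaling_params()] object.
#' @return CW bias in \[0, 1\].
#' @export
cw_bias <- function(Yp, params = signaling_params()) {
  if (any(Yp < 0)) stop("Yp must be non-negative")
  h <- params$motor_hill
  Yph <- Yp^h
  Yph / (Yph + params$motor_K^h)
}

#' Motor-state switching rates from CW bias
#'
#' The run-to-tumble rate is `B / tumble_rate_scale` (default `B/0.11`)
#' and the tumble-to-run rate is the constant `detumble_rate` (default 5/s).
#'
#' @param B CW bias in \[0, 1\].
#' @param params A [signaling_params()] object.
#' @return A list with `run_to_tumble` and `tumble_to_run` (1/s).
#' @export
switching_rates <- function(B, params = signaling_params()) {
  stopifnot(all(B >= 0), all(B <= 1))
  list(run_to_tumble = B / params$tumble_rate_scale,
       tumble_to_run = rep_len(params$detumble_rate, length(B)))
}

#' Methylation level adapted to a given ligand concentration
#'
#' Solves `kinase_activity(m, L) = kR/(kR+kB)` for `m` in closed form:
#' at the adapted fixed point the total free energy must satisfy
#' \eqn{N(\alpha(m - m_0) + f_L) = \ln(a^{*-1} - 1)}. Used to initialise
#' cells pre-adapted to their local concentration. If the solution falls
#' outside the methylation clamp range it is clamped with a warning.
#'
#' @param L Ligand concentration, mM. Vectorised.
#' @param params A [signaling_params()] object.
#' @return Adapted methylation level(s).
#' @export
adapted_methylation <- function(L, params = signaling_params()) {
  a_star <- params$kR / (params$kR + params$kB)
  target <- log(1 / a_star - 1) / params$N      # required f_m + f_L
  m <- params$m0 + (target - ligand_free_energy(L, params)) / params$alpha
  lo <- params$m_range[1]; hi <- params$m_range[2]
  if (any(m < lo | m > hi)) {
    warning("adapted methylation clamped to [", lo, ", ", hi, "]")
    m <- pmin(pmax(m, lo), hi)
  }
  m
}
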