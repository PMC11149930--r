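#' Signaling parameters for the chemotaxis pathway model
#'
#' Bundles every constant of the coarse-grained receptor/motor model: the
#' MWC receptor-cluster activity, the methylation (adaptation) kinetics, the
#' CheY-P coupling and the motor switching law. Defaults are the values
#' calibrated for the potassium response of wild-type E. coli.
#'
#' The receptor-cluster kinase activity is
#' \deqn{a = \frac{1}{1 + \exp[N(f_m + f_L)]}}
#' with methylation free energy \eqn{f_m = \alpha (m - m_0)} (or a fixed
#' constant when fitting dose-response curves with methylation frozen) and
#' ligand free energy \eqn{f_L = \ln[(1 + L/K_{off})/(1 + L/K_{on})]}.
#' Methylation adapts as \eqn{dm/dt = k_R (1-a) - k_B a}, CheY-P is
#' proportional to activity, the motor CW bias is a Hill function of CheY-P,
#' and the run-to-tumble / tumble-to-run switching rates are `B/tumble_rate_scale`
#' and `detumble_rate`.
#'
#' @param N Receptor-cluster size (dimensionless).
#' @param alpha Free-energy change per added methyl group (kT; negative).
#' @param m0 Methylation offset (methyl groups).
#' @param Koff Dissociation constant of the inactive receptor (mM).
#' @param Kon Dissociation constant of the active receptor (mM); must exceed `Koff`.
#' @param kR Methylation rate (1/s).
#' @param kB Demethylation rate (1/s).
#' @param yp_scale CheY-P concentration per unit kinase activity (uM).
#' @param motor_hill Hill coefficient of the motor CW-bias curve.
#' @param motor_K CheY-P concentration at half-maximal CW bias (uM).
#' @param tumble_rate_scale Divisor converting CW bias to the run-to-tumble
#'   rate (the rate is `B / tumble_rate_scale` in 1/s).
#' @param detumble_rate Tumble-to-run rate (1/s).
#' @param baseline_fm Fixed methylation free energy (kT) used when fitting
#'   dose-response data with methylation held constant.
#' @param m_range Allowed methylation range (clamp), default `c(0, 4)` for
#'   four methylation sites per receptor monomer.
#'
#' @return An object of class `signaling_params` (a validated list).
#' @export
signaling_params <- function(N = 0.85, alpha = -1.7, m0 = 1.0,
                             Koff = 0.17, Kon = 55.17,
                             kR = 0.005, kB = 0.010,
                             yp_scale = 7.86,
                             motor_hill = 10.3, motor_K = 3.1,
                             tumble_rate_scale = 0.11, detumble_rate = 5,
                             baseline_fm = 0.84,
                             m_range = c(0, 4)) {
  p <- list(N = N, alpha = alpha, m0 = m0, Koff = Koff, Kon = Kon,
            kR = kR, kB = kB, yp_scale = yp_scale,
            motor_hill = motor_hill, motor_K = motor_K,
            tumble_rate_scale = tumble_rate_scale,
            detumble_rate = detumble_rate,
            baseline_fm = baseline_fm, m_range = as.numeric(m_range))
  validate_signaling_params(p)
  structure(p, class = "signaling_params")
}

validate_signaling_params <- function(p) {
  stopifnot(
    p$Koff > 0, p$Kon > p$Koff, p$N > 0,
    p$kR > 0, p$kB > 0, p$detumble_rate > 0,
    p$motor_hill > 0, p$motor_K > 0, p$yp_scale > 0,
    p$tumble_rate_scale > 0,
    length(p$m_range) == 2, p$m_range[2] > p$m_range[1]
  )
  invisible(p)
}

#' @export
print.signaling_params <- function(x, ...) {
  cat("Chemotaxis signaling parameters:\n")
  flat <- x[setdiff(names(x), "m_range")]
  for (nm in names(flat)) cat(sprintf("  %-18s %g\n", nm, flat[[nm]]))
  cat(sprintf("  %-18s [%g, %g]\n", "m_range", x$m_range[1], x$m_range[2]))
  invisible(x)
}

#' Read or write model/simulation configuration as YAML
#'
#' All parameter blocks (`signaling_params`, field specs, `sim_config`) are
#' serialized with their field names, so a configuration file round-trips to
#' identical objects.
#'
#' @param path File path.
#' @param config A named list of parameter blocks.
#' @return `read_config` returns the named list; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  # strip classes so the YAML is plain key/value blocks
  plain <- rapply(config, identity, how = "list")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Build parameter objects from a configuration list
#'
#' @param config A list as returned by [read_config()].
#' @return A list with any of `params`, `field`, `sim` populated.
#' @export
config_to_objects <- function(config) {
  out <- list()
  if (!is.null(config$signaling_params))
    out$params <- do.call(signaling_params, config$signaling_params)
  if (!is.null(config$oscillating_field))
    out$field <- do.call(oscillating_field, config$oscillating_field)
  if (!is.null(config$linear_field))
    out$field <- do.call(linear_field, config$linear_field)
  if (!is.null(config$sim_config))
    out$sim <- do.call(sim_config, config$sim_config)
  out
}
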