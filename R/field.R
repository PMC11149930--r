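#' Oscillating potassium field from a periodic source at x = 0
#'
#' A source at the boundary of a semi-infinite 1D medium oscillates as
#' \eqn{L_s(t) = L_0 [1 - \cos(2\pi t/T)]}. Diffusion propagates this as a
#' damped concentration wave
#' \deqn{L(x, t) = L_0 [1 - \cos(2\pi t/T - kx) \exp(-kx)]}
#' with wavenumber \eqn{k = \sqrt{\pi/(D T)}} — the unique decay/phase
#' constant for which this expression solves the diffusion equation
#' \eqn{\partial L/\partial t = D\, \partial^2 L/\partial x^2} with the
#' oscillating boundary condition and a bounded far field (see
#' [pde_residual()], which verifies this numerically).
#'
#' @param L0 Half-maximum source concentration, mM.
#' @param period Source oscillation period T, s.
#' @param D Potassium diffusion constant, um^2/s (default 1333.3).
#' @return An object of class `oscillating_field`.
#' @export
oscillating_field <- function(L0 = 1, period = 3600, D = 1333.3) {
  stopifnot(L0 > 0, period > 0, D > 0)
  structure(list(L0 = L0, period = period, D = D),
            class = c("oscillating_field", "potassium_field"))
}

#' Static linear potassium gradient (microfluidic observation channel)
#'
#' @param c_low,c_high Boundary concentrations, mM (>= 0).
#' @param y_low,y_high Channel coordinates of the two boundaries, um.
#' @return An object of class `linear_field`.
#' @export
linear_field <- function(c_low = 0, c_high = 1, y_low = 0, y_high = 1500) {
  stopifnot(y_high > y_low, c_low >= 0, c_high >= 0)
  structure(list(c_low = c_low, c_high = c_high,
                 y_low = y_low, y_high = y_high),
            class = c("linear_field", "potassium_field"))
}

#' Spatial decay/phase constant of the oscillating field
#'
#' \eqn{k = \sqrt{\pi/(D T)}}, equivalently \eqn{\sqrt{\omega/(2D)}} with
#' \eqn{\omega = 2\pi/T}. Units 1/um.
#'
#' @param field An [oscillating_field()].
#' @return Wavenumber, 1/um.
#' @export
wavenumber <- function(field) {
  stopifnot(inherits(field, "oscillating_field"))
  sqrt(pi / (field$D * field$period))
}

#' Potassium concentration at position(s) and time(s)
#'
#' @param field An [oscillating_field()] or [linear_field()].
#' @param x Position along the gradient axis, um (>= 0 for the oscillating
#'   field; within the channel for the linear field).
#' @param t Time, s (ignored by the linear field).
#' @return Concentration, mM.
#' @export
field_concentration <- function(field, x, t = 0) {
  UseMethod("field_concentration")
}

#' @export
field_concentration.oscillating_field <- function(field, x, t = 0) {
  if (any(x < 0)) stop("x must be non-negative for a semi-infinite field")
  k <- wavenumber(field)
  field$L0 * (1 - cos(2 * pi * t / field$period - k * x) * exp(-k * x))
}

#' @export
field_concentration.linear_field <- function(field, x, t = 0) {
  if (any(x < field$y_low - 1e-9) || any(x > field$y_high + 1e-9))
    stop("position outside the channel [", field$y_low, ", ", field$y_high, "]")
  frac <- (x - field$y_low) / (field$y_high - field$y_low)
  field$c_low + frac * (field$c_high - field$c_low)
}

#' Linear-gradient concentration at channel coordinate y
#'
#' Convenience wrapper for [field_concentration()] on a [linear_field()].
#'
#' @param y Channel coordinate, um.
#' @param field A [linear_field()].
#' @return Concentration, mM.
#' @export
linear_concentration <- function(y, field) {
  field_concentration.linear_field(field, y)
}

#' Diffusion-equation residual of a field on a space-time grid
#'
#' Central-difference estimate of
#' \eqn{\max |\partial L/\partial t - D\, \partial^2 L/\partial x^2|}
#' over an interior grid. For the analytic oscillating field the residual
#' vanishes as the grid refines (it is an exact solution); a field evaluated
#' with a wrong wavenumber leaves a residual of order \eqn{L_0 \omega}.
#'
#' @param field An [oscillating_field()].
#' @param x Strictly increasing positions, um, excluding the x = 0 boundary.
#' @param t Strictly increasing times, s.
#' @param k_override Optional wavenumber replacing the field's own (used to
#'   demonstrate that the analytic `k` is the correct one).
#' @return Maximum absolute residual, mM/s.
#' @export
pde_residual <- function(field, x, t, k_override = NULL) {
  stopifnot(inherits(field, "oscillating_field"),
            length(x) >= 3, length(t) >= 3, all(x > 0))
  k <- if (is.null(k_override)) wavenumber(field) else k_override
  conc <- function(x, t)
    field$L0 * (1 - cos(2 * pi * t / field$period - k * x) * exp(-k * x))
  Lmat <- outer(x, t, conc)                      # rows x, cols t
  dx <- diff(x)[1]; dt_ <- diff(t)[1]
  nx <- length(x); nt <- length(t)
  dLdt <- (Lmat[2:(nx - 1), 3:nt] - Lmat[2:(nx - 1), 1:(nt - 2)]) / (2 * dt_)
  d2Ldx2 <- (Lmat[3:nx, 2:(nt - 1)] - 2 * Lmat[2:(nx - 1), 2:(nt - 1)] +
               Lmat[1:(nx - 2), 2:(nt - 1)]) / dx^2
  max(abs(dLdt - field$D * d2Ldx2))
}
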