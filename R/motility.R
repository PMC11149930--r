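#' Chemotaxis migration coefficient (CMC) time series
#'
#' Per frame, the mean of \eqn{(x_i - x_c)/w} over cells, where `x_c` is the
#' channel centre and `w` the half-width of the observed region (default
#' 194 um). Bounded in \eqn{[-1, 1]}; positive values mean net displacement
#' toward the `+x` side.
#'
#' @param table data.frame with columns `frame`, `t_s`, `cell_id`, `x_um`,
#'   `y_um` (a "position table").
#' @param x_center Channel centre, um.
#' @param half_width Half-width of the observed region, um (default 194).
#' @param frames Frame identifiers to evaluate (default those present in
#'   the table); frames with no cells yield `NA`, flagged in `empty`.
#' @return data.frame with `frame`, `t_s`, `cmc`, `n_cells`, `empty`.
#' @export
cmc <- function(table, x_center, half_width = 194, frames = NULL) {
  stopifnot(all(c("frame", "t_s", "x_um") %in% names(table)))
  if (is.null(frames)) frames <- sort(unique(table$frame))
  out <- do.call(rbind, lapply(frames, function(f) {
    sub <- table[table$frame == f, , drop = FALSE]
    data.frame(frame = f,
               t_s = if (nrow(sub)) sub$t_s[1] else NA_real_,
               cmc = if (nrow(sub)) mean((sub$x_um - x_center) / half_width)
                     else NA_real_,
               n_cells = nrow(sub))
  }))
  out$empty <- out$n_cells == 0
  out
}

#' Exponential fit of a steady-state cell density profile
#'
#' Histograms positions along the gradient axis, normalizes to a discrete
#' density, and fits \eqn{\rho(y) \propto \exp(\lambda y)} (y measured
#' toward the source) by weighted least squares on the log-density with
#' Poisson count weights; empty bins are excluded. For a population
#' performing log-sensing chemotaxis in a linear gradient the steady state
#' is exponential with \eqn{\lambda = v_d / v_s}.
#'
#' @param positions Numeric positions along the gradient axis, um, or a
#'   position table (then `coord` selects the column).
#' @param n_bins Number of histogram bins (default 20).
#' @param range Optional length-2 axis range, um (default data range).
#' @param coord Column used when `positions` is a data.frame.
#' @return An object of class `density_fit`: list with `lambda` (1/um),
#'   `se_lambda`, `bin_centers`, `density` (sums to 1), `log_fit` (the lm).
#' @export
density_profile_fit <- function(positions, n_bins = 20, range = NULL,
                                coord = "y_um") {
  if (is.data.frame(positions)) positions <- positions[[coord]]
  stopifnot(length(positions) >= n_bins)
  if (is.null(range)) range <- base::range(positions)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  h <- graphics::hist(positions, breaks = breaks, plot = FALSE)
  counts <- h$counts
  dens <- counts / sum(counts)
  keep <- counts > 0
  if (sum(keep) < 3) stop("too few occupied bins for an exponential fit")
  df <- data.frame(y = h$mids[keep], logd = log(dens[keep]), wt = counts[keep])
  fit <- stats::lm(logd ~ y, data = df, weights = wt)
  structure(list(lambda = unname(stats::coef(fit)[2]),
                 se_lambda = summary(fit)$coefficients[2, 2],
                 bin_centers = h$mids, density = dens, log_fit = fit),
            class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf("Exponential density fit: lambda = %.5f +/- %.5f 1/um\n",
              x$lambda, x$se_lambda))
  invisible(x)
}

#' Drift velocity from the density decay constant
#'
#' For log-sensing chemotaxis in a linear gradient the exponential decay
#' constant of the steady-state density equals \eqn{v_d / v_s}, so
#' \eqn{v_d = \lambda \, v_s}.
#'
#' @param lambda Decay constant, 1/um (> 0).
#' @param v_s Cell motility constant, um^2/s (> 0; 53.2 for wild-type).
#' @return Drift velocity, um/s.
#' @export
drift_velocity <- function(lambda, v_s = 53.2) {
  stopifnot(lambda >= 0, v_s > 0)
  lambda * v_s
}

#' Sliding-window motor statistics from a bead-assay trace
#'
#' Signed rotational speed (positive = CCW) is windowed (default 20 s
#' window, 1 s slide); per window the CW bias is the fraction of samples
#' rotating CW (negative speed beyond a configurable dead band) and the
#' speed is the mean absolute speed. Results are stamped at window centres.
#'
#' @param t Time, s (uniformly sampled).
#' @param speed_hz Signed rotational speed, Hz.
#' @param window Window length, s (default 20).
#' @param slide Slide, s (default 1).
#' @param dead_band Speeds within +/- this value (Hz) are excluded from the
#'   bias numerator and denominator (noise near reversals); default 0.
#' @return data.frame with `t_center`, `cw_bias`, `speed_hz`.
#' @export
windowed_motor_stats <- function(t, speed_hz, window = 20, slide = 1,
                                 dead_band = 0) {
  stopifnot(length(t) == length(speed_hz))
  total <- max(t) - min(t)
  if (window > total) stop("window longer than the trace")
  starts <- seq(min(t), max(t) - window, by = slide)
  out <- do.call(rbind, lapply(starts, function(s) {
    idx <- t >= s & t < s + window
    sp <- speed_hz[idx]
    informative <- abs(sp) > dead_band
    bias <- if (any(informative)) mean(sp[informative] < 0) else NA_real_
    data.frame(t_center = s + window / 2,
               cw_bias = bias,
               speed_hz = mean(abs(sp)))
  }))
  out
}

#' Write / read a position table as CSV
#' (columns frame, t_s, cell_id, x_um, y_um)
#'
#' @param table Position table data.frame.
#' @param path File path.
#' @return `path` invisibly (writer); the table (reader).
#' @export
write_positions <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  utils::read.csv(path)
}

#' Write / read a bead trace as CSV (columns t_s, speed_hz)
#'
#' @param trace data.frame with `t_s`, `speed_hz`.
#' @param path File path.
#' @return `path` invisibly (writer); the trace (reader).
#' @export
write_bead_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bead_trace
#' @export
read_bead_trace <- function(path) {
  utils::read.csv(path)
}
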