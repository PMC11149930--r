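# centred sliding-window minimum (truncated at the edges), block algorithm
running_min <- function(x, halfwidth) {
  n <- length(x)
  W <- 2L * halfwidth + 1L
  if (W >= n || halfwidth < 1L) return(rep(min(x), n))
  xp <- c(rep(Inf, halfwidth), x, rep(Inf, halfwidth))
  m <- length(xp)
  pad <- (W - m %% W) %% W
  xq <- c(xp, rep(Inf, pad))
  mat <- matrix(xq, nrow = W)
  pre <- apply(mat, 2, cummin)
  suf <- apply(mat[W:1, , drop = FALSE], 2, cummin)[W:1, , drop = FALSE]
  pre <- as.numeric(pre); suf <- as.numeric(suf)
  idx <- seq_len(n)
  pmin(suf[idx], pre[idx + W - 1L])
}

#' Locate the periodic troughs of a noisy oscillating time series
#'
#' Smooths the series with a centred moving average (partial windows at the
#' edges) and takes as troughs the local minima that dominate their
#' neighbourhood within a quarter period on each side — robust against
#' period-to-period depth differences, for which a plain per-window minimum
#' can lock onto a window edge. Troughs at the first or last sample of the
#' series are discarded as boundary artifacts. If a trough is attained at
#' several tied samples, the earliest is taken and the result is flagged;
#' if several local minima fall in one period window, the deepest is kept
#' and the result is flagged.
#'
#' @param t Time grid, s (uniform).
#' @param value Series values.
#' @param period Period T, s; the series must span at least two periods.
#' @param smooth_window Moving-average window, s (default `0.05 * period`).
#' @return A data.frame with `k` (period window index, `t` in
#'   `((k-1)T, kT]`) and `t_trough`, with attribute `ambiguous` (logical
#'   per trough).
#' @export
find_troughs <- function(t, value, period, smooth_window = 0.05 * period) {
  stopifnot(length(t) == length(value), diff(range(t)) >= 2 * period)
  dt <- stats::median(diff(t))
  w <- max(1L, round(smooth_window / dt))
  if (w %% 2 == 0) w <- w + 1L
  sm <- as.numeric(stats::filter(value, rep(1 / w, w), sides = 2))
  hw <- (w - 1L) %/% 2L
  n <- length(value)
  if (hw > 0 && n > w) {
    for (i in seq_len(hw)) {
      sm[i] <- mean(value[1:(i + hw)])
      sm[n - i + 1L] <- mean(value[(n - i + 1L - hw):n])
    }
  }
  dom <- max(1L, round(0.25 * period / dt))
  rmin <- running_min(sm, dom)
  cand <- which(sm <= rmin + 1e-12)
  cand <- cand[cand > 1L & cand < n]       # boundary samples excluded
  if (!length(cand)) {
    out <- data.frame(k = integer(0), t_trough = numeric(0))
    attr(out, "ambiguous") <- logical(0)
    return(out)
  }
  # cluster candidates closer than the dominance radius (ties/flat runs)
  grp <- cumsum(c(1L, diff(cand) > dom))
  troughs <- do.call(rbind, lapply(split(cand, grp), function(ix) {
    data.frame(idx = ix[1], depth = sm[ix[1]], tied = length(ix) > 1)
  }))
  troughs$t <- t[troughs$idx]
  troughs$k <- floor((troughs$t - 1e-9) / period) + 1L
  # one trough per period window: keep the deepest, flag multiplicity
  keep <- do.call(rbind, lapply(split(troughs, troughs$k), function(d) {
    d <- d[order(d$depth), , drop = FALSE]
    out <- d[1, , drop = FALSE]
    out$tied <- out$tied || nrow(d) > 1
    out
  }))
  keep <- keep[order(keep$t), , drop = FALSE]
  out <- data.frame(k = keep$k, t_trough = keep$t)
  attr(out, "ambiguous") <- keep$tied
  out
}

#' Phase delay and lag time of the mean position behind the source
#'
#' Transforms the mean x-position to `arena_x - mean_x` (displacement toward
#' the source at x = 0), finds one trough per period (excluding t = 0), and
#' pairs each with the preceding source trough at `t = k T`. The phase delay
#' is \eqn{\Delta\phi = \langle (t_{trough} - kT)/T \rangle} (cycle
#' fraction) and the lag time is \eqn{\Delta\phi \cdot T}.
#'
#' @param summary A `trajectory_summary` (or data.frame with `t_s`,
#'   `mean_x_um`) spanning at least two full periods.
#' @param field The [oscillating_field()] that drove the simulation
#'   (defaults to the one attached to `summary`).
#' @param arena_x Arena width used for the displacement transform (defaults
#'   to the attached config, else 1500 um).
#' @param smooth_window Smoothing window for trough detection, s.
#' @return An object of class `lag_result`: list with `delta_phi` (cycle
#'   fraction), `lag_s`, `lag_min`, per-period `troughs`, `source_troughs`
#'   and the across-period standard deviation `sd_lag_min`.
#' @export
phase_delay <- function(summary, field = attr(summary, "field"),
                        arena_x = NULL,
                        smooth_window = 0.05 * field$period) {
  if (is.null(field)) stop("an oscillating field specification is required")
  if (is.null(arena_x)) {
    cfg <- attr(summary, "config")
    arena_x <- if (!is.null(cfg)) cfg$arena_x else 1500
  }
  T_ <- field$period
  disp <- arena_x - summary$mean_x_um
  tr <- find_troughs(summary$t_s, disp, T_, smooth_window)
  # the first period's minimum sits at the initialisation transient that
  # follows the source trough at t = 0, which the analysis excludes
  tr <- tr[tr$k > 1 & !is.na(tr$t_trough), , drop = FALSE]
  if (nrow(tr) < 1) stop("no usable trough found after the first period")
  k_src <- floor(tr$t_trough / T_ + 1e-9)
  offs <- tr$t_trough / T_ - k_src
  # near-zero lags can scatter troughs to just before a source trough;
  # wrap those so the average is not split across the cycle boundary
  offs[offs > 0.9] <- offs[offs > 0.9] - 1
  delta_phi <- mean(offs)
  if (delta_phi < 0) delta_phi <- delta_phi + 1
  structure(list(delta_phi = delta_phi,
                 lag_s = delta_phi * T_,
                 lag_min = delta_phi * T_ / 60,
                 troughs = tr$t_trough,
                 source_troughs = k_src * T_,
                 per_period_lag_min = offs * T_ / 60,
                 sd_lag_min = stats::sd(offs * T_ / 60)),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("Phase delay: %.4f cycle; lag time: %.2f min (sd %.2f over %d periods)\n",
              x$delta_phi, x$lag_min,
              ifelse(is.na(x$sd_lag_min), 0, x$sd_lag_min),
              length(x$troughs)))
  invisible(x)
}

#' Write a lag result as structured text (JSON)
#'
#' @param result A `lag_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lag_result <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mean lag over replicate simulations
#'
#' Runs `run_simulation` + `phase_delay` for each seed and averages the
#' within-run lag across replicates.
#'
#' @param config A [sim_config()]; its `rng_seed` is replaced by each seed.
#' @param field An [oscillating_field()].
#' @param params A [signaling_params()].
#' @param seeds Integer vector of seeds.
#' @return A list with `lag_min` (mean across seeds), `per_seed_lag_min`,
#'   `delta_phi` (mean cycle fraction) and `per_seed_delta_phi`.
#' @export
replicate_lag <- function(config, field, params = signaling_params(),
                          seeds = 1:3) {
  per <- vapply(seeds, function(s) {
    config$rng_seed <- as.integer(s)
    res <- run_simulation(config, field, params)
    lr <- phase_delay(res, field)
    c(lr$lag_min, lr$delta_phi)
  }, numeric(2))
  list(lag_min = mean(per[1, ]), per_seed_lag_min = per[1, ],
       delta_phi = mean(per[2, ]), per_seed_delta_phi = per[2, ])
}
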