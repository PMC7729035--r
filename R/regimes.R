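#' Tuning constants for the dynamic-regime classifier
#'
#' The four regimes of the resistant-cell fraction are distinguished by a
#' small set of dimensionless thresholds. The distinction between spike-like
#' and sinusoidal oscillations is visual in origin, so the thresholds are
#' exposed rather than hard-coded.
#'
#' @param transient_frac fraction of the horizon discarded as transient
#'   before measuring the envelope (the damped cases near the bifurcation
#'   decay slowly, hence the generous default of one half).
#' @param osc_tol envelope gap of the ratio series above which the
#'   post-transient dynamics count as oscillatory at this horizon; also the
#'   minimum height by which an overshoot peak must exceed the final value.
#' @param damped_ratio sustained oscillations keep successive peak
#'   amplitudes within this factor; a last-to-first peak-amplitude ratio
#'   below it means the envelope is contracting (damped).
#' @param duty_spike duty cycle (fraction of post-transient time the ratio
#'   spends above its envelope midline) below which a sustained oscillation
#'   counts as spike-like rather than sinusoidal.
#' @return A list of class `regime_control`.
#' @export
regime_control <- function(transient_frac = 0.5, osc_tol = 1e-3,
                           damped_ratio = 0.9, duty_spike = 0.25) {
  stopifnot(transient_frac > 0, transient_frac < 1,
            osc_tol > 0, damped_ratio > 0, damped_ratio < 1,
            duty_spike > 0, duty_spike < 1)
  structure(list(transient_frac = transient_frac, osc_tol = osc_tol,
                 damped_ratio = damped_ratio, duty_spike = duty_spike),
            class = "regime_control")
}

# Indices of strict local maxima of a series.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(diff(sign(diff(x))) == -2) + 1L
}

#' Classify a trajectory into one of four dynamic regimes
#'
#' Labels the long-run behaviour of the resistant-cell fraction R/(R+P) as
#' one of `spike_oscillation`, `sinusoidal_oscillation`, `damped_to_steady`
#' or `monotonic_relaxation`. The decision sequence, applied to the
#' post-transient part of the ratio series:
#'
#' 1. Envelope gap (max - min) at most `osc_tol`: non-oscillatory at this
#'    horizon. The label is `damped_to_steady` if the full trajectory shows
#'    at least one overshoot peak exceeding the final ratio by more than
#'    `osc_tol` (the relics of decayed oscillations), else
#'    `monotonic_relaxation`.
#' 2. Otherwise, oscillatory. With at least two post-transient peaks, the
#'    last-to-first peak-amplitude ratio below `damped_ratio` means the
#'    envelope is still contracting: `damped_to_steady`. With fewer peaks,
#'    the gap of the last quarter of the horizon is compared with the
#'    preceding quarter (contraction below one half means damped).
#' 3. A sustained oscillation is `spike_oscillation` when its duty cycle is
#'    below `duty_spike` (narrow pulses on a low baseline), else
#'    `sinusoidal_oscillation`.
#'
#' @param traj a `biofilm_trajectory` from [simulate_model()].
#' @param control a [regime_control()] list of thresholds.
#' @return A list of class `regime_label` with elements `label` and
#'   `diagnostics` (peak count, envelope, amplitude-decay ratio, duty
#'   cycle).
#' @examples
#' \donttest{
#' traj <- simulate_model(model_parameters(k3 = 10),
#'                        simulation_settings(t_end = 200, dt_out = 0.05))
#' classify_regime(traj)$label   # "damped_to_steady"
#' }
#' @export
classify_regime <- function(traj, control = regime_control()) {
  stopifnot(inherits(control, "regime_control"))
  ratio <- ratio_series(traj)
  t <- traj$time_h
  if (anyNA(ratio)) {
    # An identically undefined ratio (extinct community) relaxes trivially.
    if (all(is.na(ratio))) {
      return(new_regime_label("monotonic_relaxation", npeaks = 0,
                              env = c(NA, NA), decay = NA, duty = NA))
    }
    keep <- !is.na(ratio)
    ratio <- ratio[keep]; t <- t[keep]
  }
  horizon <- t[length(t)] - t[1]
  t_cut <- t[1] + control$transient_frac * horizon
  post <- t >= t_cut
  if (sum(post) < 10 || horizon <= 0) {
    stop("trajectory too short to discard a transient; extend t_end",
         call. = FALSE)
  }
  rp <- ratio[post]
  env <- range(rp)
  gap <- env[2] - env[1]

  if (gap <= control$osc_tol) {
    final <- rp[length(rp)]
    pk_all <- local_maxima(ratio)
    overshoot <- sum(ratio[pk_all] > final + control$osc_tol)
    label <- if (overshoot >= 1) "damped_to_steady" else "monotonic_relaxation"
    return(new_regime_label(label, npeaks = 0, env = env, decay = NA_real_,
                            duty = NA_real_, overshoot_peaks = overshoot))
  }

  mid <- mean(env)
  duty <- mean(rp > mid)
  peak_amps <- function(r, floor_) {
    pk <- local_maxima(r)
    amp <- r[pk] - floor_
    amp[amp > control$osc_tol]
  }
  amp <- peak_amps(rp, env[1])
  if (length(amp) < 2) {
    # Long-period oscillations can leave a single peak in the post-transient
    # window; widen to the last 75% of the horizon for the peak comparison.
    wide <- t >= t[1] + 0.25 * horizon
    amp <- peak_amps(ratio[wide], min(ratio[wide]))
  }
  pk <- seq_along(amp)

  if (length(pk) >= 2) {
    decay <- amp[length(amp)] / amp[1]
    damped <- decay < control$damped_ratio
  } else {
    tp <- t[post]
    q4 <- tp >= tp[1] + 0.75 * (tp[length(tp)] - tp[1])
    q3 <- !q4 & tp >= tp[1] + 0.5 * (tp[length(tp)] - tp[1])
    decay <- diff(range(rp[q4])) / max(diff(range(rp[q3])), .Machine$double.eps)
    damped <- decay < 0.5
  }
  if (damped) {
    return(new_regime_label("damped_to_steady", npeaks = length(pk), env = env,
                            decay = decay, duty = duty))
  }
  label <- if (duty < control$duty_spike) "spike_oscillation" else "sinusoidal_oscillation"
  new_regime_label(label, npeaks = length(pk), env = env, decay = decay,
                   duty = duty)
}

new_regime_label <- function(label, npeaks, env, decay, duty,
                             overshoot_peaks = NA_integer_) {
  structure(list(label = label,
                 diagnostics = list(
                   n_peaks = npeaks,
                   env_min = env[1], env_max = env[2],
                   amplitude = env[2] - env[1],
                   decay_ratio = decay,
                   duty_cycle = duty,
                   overshoot_peaks = overshoot_peaks)),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Regime: %s\n", x$label))
  cat(sprintf("  envelope [%.4g, %.4g] (gap %.4g), peaks %d, decay %.3g, duty %.3g\n",
              d$env_min, d$env_max, d$amplitude, d$n_peaks,
              d$decay_ratio, d$duty_cycle))
  invisible(x)
}

#' Amplitude-envelope bifurcation scan over the public-goods cost
#'
#' For each value of `k3` on a grid, simulates the model well past its
#' transient and records the post-transient maximum and minimum of the
#' resistant-cell fraction. Below the Hopf point the two arms straddle the
#' limit cycle; above it they collapse onto the steady-state ratio
#' `k3 / (k3 + k2)` (for `k1 = k4`; in general `R*/(R*+P*) = k3/(k3+k4)`).
#' The numeric Hopf estimate is the first grid value whose envelope gap
#' falls below `gap_tol`.
#'
#' The default horizon is long (800 h) because the envelope decays only at
#' the slow rate of the eigenvalue pair just above the bifurcation.
#'
#' @inheritParams model_rhs
#' @param k3_grid strictly increasing grid of positive `k3` values (h^-1).
#' @param settings simulation settings applied at every grid point; the
#'   default uses `t_end = 800`, `dt_out = 0.05`, start (1, 1, 1).
#' @param transient_frac fraction of the horizon discarded before measuring
#'   the envelope.
#' @param gap_tol envelope gap below which the dynamics count as steady.
#' @return An object of class `bifurcation_scan`: a data frame with columns
#'   `k3`, `env_min`, `env_max` plus attributes `hopf_estimate` (NA for a
#'   single-point grid or when no crossing occurs) and `gap_tol`.
#' @examples
#' \donttest{
#' sc <- bifurcation_scan(model_parameters(), seq(1.6, 2.4, by = 0.2))
#' attr(sc, "hopf_estimate")
#' }
#' @export
bifurcation_scan <- function(params = model_parameters(), k3_grid,
                             settings = NULL, transient_frac = 0.5,
                             gap_tol = 1e-3) {
  params <- validate_parameters(as_model_parameters(params))
  k3_grid <- as.numeric(k3_grid)
  if (length(k3_grid) < 1 || any(k3_grid <= 0) ||
      (length(k3_grid) > 1 && any(diff(k3_grid) <= 0))) {
    stop("k3_grid must be strictly increasing and positive", call. = FALSE)
  }
  if (is.null(settings)) {
    settings <- simulation_settings(t_end = 800, dt_out = 0.05)
  }
  env <- vapply(k3_grid, function(k3) {
    traj <- tryCatch(
      simulate_model(replace_k3(params, k3), settings),
      error = function(e) stop(sprintf("scan failed at k3 = %g: %s", k3,
                                       conditionMessage(e)), call. = FALSE))
    post <- traj$time_h >= transient_frac * settings$t_end
    r <- traj$ratio[post]
    r <- r[!is.na(r)]
    range(r)
  }, numeric(2))
  out <- data.frame(k3 = k3_grid, env_min = env[1, ], env_max = env[2, ])
  gap <- out$env_max - out$env_min
  hopf <- NA_real_
  if (length(k3_grid) > 1) {
    idx <- which(gap < gap_tol)
    if (length(idx) > 0) hopf <- k3_grid[min(idx)]
  }
  attr(out, "hopf_estimate") <- hopf
  attr(out, "gap_tol") <- gap_tol
  attr(out, "params") <- params
  class(out) <- c("bifurcation_scan", "data.frame")
  out
}

#' Plot the two envelope arms of a bifurcation scan
#'
#' @param x a `bifurcation_scan`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.bifurcation_scan <- function(x, ...) {
  graphics::matplot(x$k3, cbind(x$env_min, x$env_max), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = expression(k[3] ~ (h^-1)),
                    ylab = "R / (R + P) envelope", ...)
  hopf <- attr(x, "hopf_estimate")
  if (!is.na(hopf)) graphics::abline(v = hopf, lty = 2)
  invisible(x)
}
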