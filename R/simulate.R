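#' Time-course settings for the community model
#'
#' Defaults mirror the reference time course: a 25 h horizon reported every
#' 0.025 h (1000 steps) from the state (R, P, M) = (1, 1, 1). Internal
#' stepping is adaptive (lsoda) with tight tolerances; `dt_out` only sets
#' the reporting grid.
#'
#' @param t_end simulation horizon (h).
#' @param dt_out output step (h); `t_end / dt_out` must give at least 10
#'   output points.
#' @param initial_state starting abundances `c(R, P, M)`, non-negative.
#' @param rtol,atol relative / absolute integrator tolerances. The defaults
#'   are tight because both the spike regime and very large `k3` values are
#'   numerically demanding.
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(t_end = 25, dt_out = 0.025,
                                initial_state = c(R = 1, P = 1, M = 1),
                                rtol = 1e-8, atol = 1e-10) {
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (!is.finite(dt_out) || dt_out <= 0) stop("dt_out must be positive", call. = FALSE)
  if (t_end / dt_out < 10) {
    stop("t_end / dt_out must give at least 10 output points", call. = FALSE)
  }
  structure(list(t_end = t_end, dt_out = dt_out,
                 initial_state = as_state(initial_state),
                 rtol = rtol, atol = atol),
            class = "simulation_settings")
}

#' Integrate the community model
#'
#' Runs the three-variable system on a uniform output grid with adaptive
#' error-controlled stepping (lsoda, switching automatically between
#' stiff and non-stiff methods). When the initial resistant abundance is
#' positive the system is integrated in the log-R chart `(log R, P, M)`:
#' in the spike regime R passes through values as small as 1e-35 between
#' spikes, which the linear chart cannot represent stably, while `log R`
#' obeys the smooth equation \eqn{d(\log R)/dt = k_1 N - k_4 - k_2 P}.
#' Starts with `R = 0` lie on an invariant face and use the linear chart,
#' on which the remaining (P, M) subsystem is linear.
#'
#' @inheritParams model_rhs
#' @param settings a [simulation_settings()] object.
#' @return An object of classes `biofilm_trajectory` and `data.frame` with
#'   columns `time_h`, `R`, `P`, `M` and `ratio` = R/(R+P) (`NA` where
#'   R + P < 1e-12). Tiny negative P/M excursions within the integrator's
#'   absolute tolerance are clamped to 0.
#' @examples
#' traj <- simulate_model(model_parameters(), simulation_settings())
#' head(traj)
#' @export
simulate_model <- function(params = model_parameters(),
                           settings = simulation_settings()) {
  params <- validate_parameters(as_model_parameters(params))
  stopifnot(inherits(settings, "simulation_settings"))
  times <- seq(0, settings$t_end, by = settings$dt_out)
  y0 <- settings$initial_state
  p <- as.numeric(unclass(params))

  use_log <- y0[["R"]] > 0
  y <- if (use_log) c(u = log(y0[["R"]]), P = y0[["P"]], M = y0[["M"]]) else y0
  func <- if (use_log) "biofilm_deriv_log" else "biofilm_deriv_lin"

  out <- tryCatch(
    deSolve::lsoda(y, times, func = func, parms = p,
                   dllname = "biofilmgame", initfunc = "biofilm_initmod",
                   rtol = settings$rtol, atol = settings$atol,
                   maxsteps = 100000),
    warning = function(w) {
      stop(sprintf("integration failed for parameters (%s): %s",
                   paste(sprintf("%s=%g", names(unclass(params)),
                                 unclass(params)), collapse = ", "),
                   conditionMessage(w)), call. = FALSE)
    })
  if (nrow(out) < length(times)) {
    stop(sprintf("integration stopped early at t = %g for parameters (%s)",
                 out[nrow(out), 1],
                 paste(sprintf("%s=%g", names(unclass(params)),
                               unclass(params)), collapse = ", ")),
         call. = FALSE)
  }

  R <- if (use_log) exp(out[, 2]) else pmax(out[, 2], 0)
  P <- pmax(out[, 3], 0)
  M <- pmax(out[, 4], 0)
  traj <- data.frame(time_h = out[, 1], R = R, P = P, M = M)
  traj$ratio <- compute_ratio(traj$R, traj$P)
  attr(traj, "params") <- params
  attr(traj, "settings") <- settings
  class(traj) <- c("biofilm_trajectory", "data.frame")
  traj
}

compute_ratio <- function(R, P) {
  tot <- R + P
  ifelse(tot < 1e-12, NA_real_, R / tot)
}

#' Resistant-cell fraction R/(R+P) along a trajectory
#'
#' @param traj a `biofilm_trajectory` (or any data frame with columns `R`
#'   and `P`).
#' @return Numeric vector of R/(R+P); `NA` flags points where R + P is
#'   numerically zero (below 1e-12) and the fraction is undefined.
#' @export
ratio_series <- function(traj) {
  if (NROW(traj) == 0) stop("trajectory is empty", call. = FALSE)
  compute_ratio(traj$R, traj$P)
}

#' @export
print.biofilm_trajectory <- function(x, ...) {
  cat(sprintf("Community trajectory: %d points over %g h\n",
              nrow(x), x$time_h[nrow(x)]))
  NextMethod()
}

#' Plot the resistant-cell fraction of a trajectory
#'
#' @param x a `biofilm_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.biofilm_trajectory <- function(x, ...) {
  graphics::plot(x$time_h, x$ratio, type = "l",
                 xlab = "time (h)", ylab = "R / (R + P)", ylim = c(0, 1), ...)
  invisible(x)
}
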