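#' Write / read a trajectory table
#'
#' CSV with header `time_h,R,P,M,ratio`, time in hours, values at 17
#' significant digits so that a round-trip reproduces the stored series to
#' full double precision.
#'
#' @param traj a `biofilm_trajectory`.
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` a `biofilm_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[, c("time_h", "R", "P", "M", "ratio")]
  for (col in names(df)) df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  stopifnot(all(c("time_h", "R", "P", "M", "ratio") %in% names(df)))
  class(df) <- c("biofilm_trajectory", "data.frame")
  df
}

#' Serialize analysis results to JSON
#'
#' Adds a `schema_version` field and writes with full numeric precision.
#'
#' @param results named list (e.g. with fields `params`, `settings`,
#'   `steady_states`, `eigenvalues`, `hopf_k3`, `regime`, `nash`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  results <- c(list(schema_version = "1.0"), results)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}

#' Full run configuration
#'
#' Bundles model parameters, simulation settings, the bifurcation-scan grid
#' and the game condition into one object that round-trips losslessly
#' through a flat key-value (YAML-subset) config file. The seed only
#' affects fixture generation; the model itself is deterministic.
#'
#' @param params a [model_parameters()] object.
#' @param settings a [simulation_settings()] object.
#' @param scan_k3_min,scan_k3_max,scan_k3_step bifurcation-scan grid.
#' @param game_condition stress tag for [payoff_two_strategy()].
#' @param seed integer seed for [generate_fixtures()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(params = model_parameters(),
                       settings = simulation_settings(),
                       scan_k3_min = 0.2, scan_k3_max = 3, scan_k3_step = 0.1,
                       game_condition = "moderate", seed = 1L) {
  structure(list(params = as_model_parameters(params),
                 settings = settings,
                 scan_k3_min = scan_k3_min, scan_k3_max = scan_k3_max,
                 scan_k3_step = scan_k3_step,
                 game_condition = match.arg(game_condition,
                                            c("no_stress", "moderate", "high")),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @param path config file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  s <- config$settings
  flat <- c(as.list(unclass(config$params)),
            list(t_end = s$t_end, dt_out = s$dt_out,
                 R0 = s$initial_state[["R"]], P0 = s$initial_state[["P"]],
                 M0 = s$initial_state[["M"]],
                 rtol = s$rtol, atol = s$atol,
                 scan_k3_min = config$scan_k3_min,
                 scan_k3_max = config$scan_k3_max,
                 scan_k3_step = config$scan_k3_step,
                 game_condition = config$game_condition,
                 seed = config$seed))
  yaml::write_yaml(flat, path, precision = 17)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    params = as_model_parameters(x),
    settings = simulation_settings(
      t_end = x$t_end, dt_out = x$dt_out,
      initial_state = c(R = x$R0, P = x$P0, M = x$M0),
      rtol = x$rtol, atol = x$atol),
    scan_k3_min = x$scan_k3_min, scan_k3_max = x$scan_k3_max,
    scan_k3_step = x$scan_k3_step,
    game_condition = x$game_condition, seed = x$seed)
}

#' Reproducible fixture families for tests
#'
#' Generates (a) parameter sets stratified across the four dynamic regimes
#' (the reference values `k3` in 0.1, 1, 10, 1000 with defaults, plus
#' jittered variants) and (b) random 2x2 and 3x3 bimatrix games, half of
#' them zero-sum, for Nash-oracle property tests. The same seed yields
#' byte-identical files.
#'
#' @param dir output directory (created if missing); `NULL` skips writing.
#' @param seed integer seed.
#' @param n_games number of random games per shape.
#' @return Invisibly, a list with `params` (data frame: regime label +
#'   parameter columns) and `games` (list of `bimatrix_game`).
#' @export
generate_fixtures <- function(dir = NULL, seed = 0L, n_games = 10L) {
  set.seed(seed)
  ref_k3 <- c(spike_oscillation = 0.1, sinusoidal_oscillation = 1,
              damped_to_steady = 10, monotonic_relaxation = 1000)
  rows <- lapply(names(ref_k3), function(regime) {
    base <- c(k1 = 1, k2 = 1, k3 = unname(ref_k3[regime]), k4 = 1, k5 = 1, N = 4)
    jit <- base
    jit[c("k1", "k2")] <- jit[c("k1", "k2")] * stats::runif(2, 0.9, 1.1)
    rbind(data.frame(regime = regime, t(base)),
          data.frame(regime = regime, t(jit)))
  })
  params <- do.call(rbind, rows)

  rand_game <- function(k, zero_sum) {
    A <- matrix(round(stats::runif(k * k, -3, 3), 3), nrow = k)
    B <- if (zero_sum) -A else matrix(round(stats::runif(k * k, -3, 3), 3), nrow = k)
    bimatrix_game(A, B)
  }
  games <- c(lapply(seq_len(n_games), function(i) rand_game(2, i %% 2 == 0)),
             lapply(seq_len(n_games), function(i) rand_game(3, i %% 2 == 0)))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pfile <- file.path(dir, "regime_parameters.csv")
    pdf <- params
    for (col in setdiff(names(pdf), "regime")) {
      pdf[[col]] <- formatC(pdf[[col]], digits = 17, format = "g")
    }
    utils::write.csv(pdf, pfile, row.names = FALSE, quote = FALSE)
    gfile <- file.path(dir, "random_games.json")
    jsonlite::write_json(
      lapply(games, function(g) list(payoff_p1 = g$payoff_p1,
                                     payoff_p2 = g$payoff_p2,
                                     zero_sum = g$zero_sum)),
      gfile, digits = NA, auto_unbox = TRUE)
  }
  invisible(list(params = params, games = games))
}
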