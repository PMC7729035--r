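# Independent oracles used across the suite.

# Central-difference Jacobian of the model right-hand side.
fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (model_rhs(up, params) - model_rhs(dn, params)) / (2 * h)
  }
  J
}

# Characteristic coefficients read off a matrix directly: negative trace,
# sum of principal 2x2 minors, negative determinant.
char_coefs_from_matrix <- function(J) {
  c(a1 = -sum(diag(J)),
    a2 = det(J[1:2, 1:2]) + det(J[c(1, 3), c(1, 3)]) + det(J[2:3, 2:3]),
    a3 = -det(J))
}

# Closed-form coefficients at the positive steady state.
char_coefs_closed_form <- function(params) {
  k <- unclass(params)
  c(a1 = k[["k3"]] + k[["k5"]],
    a2 = k[["k3"]] * k[["k5"]],
    a3 = k[["k3"]] * k[["k5"]] * (k[["k1"]] * k[["N"]] - k[["k4"]]))
}

# Random point on the k-simplex.
random_simplex <- function(k) {
  x <- -log(runif(k))
  x / sum(x)
}

# Largest payoff gain over random unilateral mixed deviations from (x, y).
# Returns <= 0 (up to tolerance) iff no sampled deviation is profitable.
random_deviation_gain <- function(game, x, y, n_dev = 1e4) {
  m <- length(x); n <- length(y)
  Ay <- drop(game$payoff_p1 %*% y)
  xB <- drop(crossprod(x, game$payoff_p2))
  D1 <- matrix(-log(runif(n_dev * m)), ncol = m)
  D1 <- D1 / rowSums(D1)
  D2 <- matrix(-log(runif(n_dev * n)), ncol = n)
  D2 <- D2 / rowSums(D2)
  # include the pure deviations, the worst case for a mixed profile
  D1 <- rbind(D1, diag(m))
  D2 <- rbind(D2, diag(n))
  max(max(D1 %*% Ay) - sum(x * Ay), max(D2 %*% xB) - sum(xB * y))
}

run_traj <- function(k3, t_end = 200, y0 = c(R = 1, P = 1, M = 1),
                     dt = 0.05, ...) {
  simulate_model(model_parameters(k3 = k3, ...),
                 simulation_settings(t_end = t_end, dt_out = dt,
                                     initial_state = y0))
}

# Random parameter set with a positive steady state (k1*N > k4), optionally
# with a Hopf point (k1*N > k4 + k5 by margin).
random_params <- function(hopf = FALSE) {
  repeat {
    p <- list(k1 = runif(1, 0.5, 2), k2 = runif(1, 0.2, 3),
              k3 = runif(1, 0.2, 3), k4 = runif(1, 0.3, 2),
              k5 = runif(1, 0.3, 2), N = runif(1, 1, 6))
    lhs <- p$k1 * p$N
    if (!hopf && lhs > p$k4 + 0.05) return(do.call(model_parameters, p))
    if (hopf && lhs > p$k4 + p$k5 + 0.5) return(do.call(model_parameters, p))
  }
}
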