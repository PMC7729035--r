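#' Right-hand side of the community model
#'
#' Evaluates the derivative triple (dR/dt, dP/dt, dM/dt) of the
#' three-subpopulation model at a population state. The model is only
#' meaningful on the non-negative orthant, so negative abundances are
#' rejected rather than clipped.
#'
#' @param state numeric vector `c(R, P, M)` of non-negative abundances
#'   (arbitrary units).
#' @param params a [model_parameters()] object.
#' @return Named numeric vector `c(R = dR/dt, P = dP/dt, M = dM/dt)` in h^-1.
#' @examples
#' model_rhs(c(1, 1, 1), model_parameters())  # (2, 0, 0)
#' model_rhs(c(3, 3, 3), model_parameters())  # the positive fixed point
#' @export
model_rhs <- function(state, params = model_parameters()) {
  params <- validate_parameters(as_model_parameters(params))
  state <- as_state(state)
  R <- state[["R"]]; P <- state[["P"]]; M <- state[["M"]]
  k <- unclass(params)
  c(R = k[["k1"]] * k[["N"]] * R - k[["k4"]] * R - k[["k2"]] * R * P,
    P = -k[["k3"]] * P + k[["k5"]] * M,
    M = k[["k4"]] * R - k[["k5"]] * M)
}

as_state <- function(state) {
  state <- as.numeric(state)
  if (length(state) != 3 || any(!is.finite(state))) {
    stop("state must be a finite numeric vector (R, P, M)", call. = FALSE)
  }
  if (any(state < 0)) {
    stop("population state must be non-negative", call. = FALSE)
  }
  names(state) <- c("R", "P", "M")
  state
}

#' Closed-form steady states of the community model
#'
#' The origin is always a fixed point. When `k1 * N > k4` a second, positive
#' fixed point exists at
#' \deqn{P^* = (k_1 N - k_4)/k_2,\quad R^* = k_3 P^*/k_4,\quad M^* = k_4 R^*/k_5.}
#'
#' @inheritParams model_rhs
#' @return A list of named state vectors `c(R, P, M)`; the origin first, the
#'   positive state second when it exists.
#' @examples
#' steady_states(model_parameters())            # (0,0,0) and (3,3,3)
#' steady_states(model_parameters(k3 = 10))     # (0,0,0) and (30,3,30)
#' @export
steady_states <- function(params = model_parameters()) {
  params <- validate_parameters(as_model_parameters(params))
  k <- unclass(params)
  out <- list(c(R = 0, P = 0, M = 0))
  if (k[["k1"]] * k[["N"]] > k[["k4"]]) {
    Pstar <- (k[["k1"]] * k[["N"]] - k[["k4"]]) / k[["k2"]]
    Rstar <- k[["k3"]] * Pstar / k[["k4"]]
    Mstar <- k[["k4"]] * Rstar / k[["k5"]]
    out <- c(out, list(c(R = Rstar, P = Pstar, M = Mstar)))
  }
  out
}

positive_steady_state <- function(params) {
  ss <- steady_states(params)
  if (length(ss) < 2) {
    stop("no positive steady state: requires k1 * N > k4", call. = FALSE)
  }
  ss[[2]]
}

#' Jacobian of the community model at a state
#'
#' @inheritParams model_rhs
#' @return 3x3 numeric matrix of partial derivatives, rows and columns
#'   ordered (R, P, M).
#' @examples
#' jacobian_at(c(0, 0, 0), model_parameters())
#' @export
jacobian_at <- function(state, params = model_parameters()) {
  params <- validate_parameters(as_model_parameters(params))
  state <- as_state(state)
  k <- unclass(params)
  R <- state[["R"]]; P <- state[["P"]]
  J <- matrix(c(
    k[["k1"]] * k[["N"]] - k[["k4"]] - k[["k2"]] * P, -k[["k2"]] * R, 0,
    0, -k[["k3"]], k[["k5"]],
    k[["k4"]], 0, -k[["k5"]]),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("R", "P", "M"), c("R", "P", "M")))
  J
}

#' Characteristic polynomial at the positive steady state
#'
#' Coefficients `(a1, a2, a3)` of the characteristic polynomial
#' \eqn{\lambda^3 + a_1\lambda^2 + a_2\lambda + a_3} of the Jacobian at the
#' positive steady state, computed from the matrix itself (negative trace,
#' sum of principal 2x2 minors, negative determinant). For this model they
#' reduce to `a1 = k3 + k5`, `a2 = k3 k5`, `a3 = k3 k5 (k1 N - k4)`; the
#' test-suite cross-checks the matrix route against those closed forms.
#'
#' @inheritParams model_rhs
#' @return Named numeric vector `c(a1, a2, a3)`.
#' @examples
#' characteristic_coefficients(model_parameters())         # (2, 1, 3)
#' characteristic_coefficients(model_parameters(k3 = 2))   # (3, 2, 6): a1*a2 == a3
#' @export
characteristic_coefficients <- function(params = model_parameters()) {
  params <- validate_parameters(as_model_parameters(params))
  J <- jacobian_at(positive_steady_state(params), params)
  a1 <- -sum(diag(J))
  a2 <- det(J[1:2, 1:2]) + det(J[c(1, 3), c(1, 3)]) + det(J[2:3, 2:3])
  a3 <- -det(J)
  c(a1 = a1, a2 = a2, a3 = a3)
}

#' Critical public-goods cost at the Hopf bifurcation
#'
#' At the positive steady state the Routh-Hurwitz stability conditions for
#' \eqn{\lambda^3 + a_1\lambda^2 + a_2\lambda + a_3} are `a1 > 0`, `a3 > 0`
#' and `a1 * a2 > a3`; equality `a1 * a2 = a3` marks the Hopf point where a
#' pure-imaginary eigenvalue pair crosses the axis. Solving for `k3` gives
#' the closed form \eqn{k_3^{c} = k_1 N - k_4 - k_5}, which notably does not
#' involve `k2`. A positive critical value requires `k1 * N > k4 + k5`.
#'
#' `hopf_k3_numeric()` locates the same point independently, by bisecting on
#' the sign of the real part of the complex eigenvalue pair of the Jacobian
#' as a function of `k3`.
#'
#' @inheritParams model_rhs
#' @param interval search interval for `k3` (defaults to
#'   `(1e-6, k1*N - k4 - 1e-9)`, the range over which the positive steady
#'   state exists).
#' @param tol bisection half-width at termination (h^-1).
#' @return The critical `k3` in h^-1, or `NA_real_` (with a message) when
#'   `k1 * N <= k4 + k5` and no Hopf point exists.
#' @examples
#' hopf_k3_critical(model_parameters())  # 2
#' hopf_k3_numeric(model_parameters())   # 2, via eigenvalue bisection
#' @export
hopf_k3_critical <- function(params = model_parameters()) {
  params <- validate_parameters(as_model_parameters(params))
  k <- unclass(params)
  crit <- k[["k1"]] * k[["N"]] - k[["k4"]] - k[["k5"]]
  if (crit <= 0) {
    message("no Hopf point: requires k1 * N > k4 + k5")
    return(NA_real_)
  }
  crit
}

#' @rdname hopf_k3_critical
#' @export
hopf_k3_numeric <- function(params = model_parameters(), interval = NULL,
                            tol = 1e-8) {
  params <- validate_parameters(as_model_parameters(params))
  k <- unclass(params)
  if (k[["k1"]] * k[["N"]] <= k[["k4"]] + k[["k5"]]) {
    message("no Hopf point: requires k1 * N > k4 + k5")
    return(NA_real_)
  }
  if (is.null(interval)) {
    interval <- c(1e-6, k[["k1"]] * k[["N"]] - k[["k4"]] - 1e-9)
  }
  f <- function(k3) pair_real_part(replace_k3(params, k3))
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo <= 0 || fhi >= 0) {
    stop("bisection interval does not bracket the stability crossing",
         call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

replace_k3 <- function(params, k3) {
  p <- unclass(params)
  p[["k3"]] <- k3
  as_model_parameters(p)
}

# Real part of the complex eigenvalue pair at the positive steady state;
# NA when all eigenvalues are real.
pair_real_part <- function(params) {
  ev <- eigen(jacobian_at(positive_steady_state(params), params),
              only.values = TRUE)$values
  cplx <- ev[abs(Im(ev)) > 1e-10]
  if (length(cplx) < 2) return(NA_real_)
  max(Re(cplx))
}

#' Steady states with eigenvalues and local stability classification
#'
#' Classifies each fixed point of the model from the eigenvalues of its
#' Jacobian. Eigenvalues with `|Re| <` `tol` are treated as marginal and the
#' state is labelled `nonhyperbolic` (this is the situation exactly at the
#' Hopf point). Otherwise, if a complex-conjugate pair is present the label
#' is a focus (`stable_focus` / `unstable_focus`, by the sign of the pair's
#' real part, provided the remaining real eigenvalue agrees in sign with
#' stability; a stable pair with an unstable real direction is a `saddle`).
#' All-real spectra give `stable_node`, `unstable_node` or `saddle`.
#'
#' @inheritParams model_rhs
#' @param tol threshold on `|Re(lambda)|` below which an eigenvalue counts
#'   as marginal.
#' @return An object of class `stability_report`: a list with one entry per
#'   steady state, each holding `state`, `eigenvalues` and `classification`,
#'   plus the Hopf point `hopf_k3` (closed form) as an attribute-style list
#'   element.
#' @examples
#' stability_report(model_parameters())
#' @export
stability_report <- function(params = model_parameters(), tol = 1e-9) {
  params <- validate_parameters(as_model_parameters(params))
  ss <- steady_states(params)
  entries <- lapply(ss, function(s) {
    ev <- eigen(jacobian_at(s, params), only.values = TRUE)$values
    list(state = s,
         eigenvalues = ev,
         classification = classify_eigenvalues(ev, tol))
  })
  structure(list(params = params,
                 steady_states = entries,
                 hopf_k3 = suppressMessages(hopf_k3_critical(params))),
            class = "stability_report")
}

classify_eigenvalues <- function(ev, tol = 1e-9) {
  re <- Re(ev)
  if (any(abs(re) < tol)) return("nonhyperbolic")
  cplx <- abs(Im(ev)) > 1e-10
  if (any(cplx)) {
    pair_re <- max(re[cplx])
    real_re <- re[!cplx]
    if (pair_re > 0) return("unstable_focus")
    if (all(real_re < 0)) return("stable_focus")
    return("saddle")
  }
  if (all(re < 0)) return("stable_node")
  if (all(re > 0)) return("unstable_node")
  "saddle"
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report\n")
  for (e in x$steady_states) {
    cat(sprintf("  state (R, P, M) = (%g, %g, %g): %s\n",
                e$state[["R"]], e$state[["P"]], e$state[["M"]],
                e$classification))
    cat("    eigenvalues:",
        paste(format(e$eigenvalues, digits = 6), collapse = ", "), "\n")
  }
  if (is.na(x$hopf_k3)) {
    cat("  no Hopf point (k1*N <= k4 + k5)\n")
  } else {
    cat(sprintf("  Hopf bifurcation at k3 = %g h^-1 (Routh-Hurwitz a1*a2 = a3)\n",
                x$hopf_k3))
  }
  invisible(x)
}
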