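#' Rate constants and nutrient level of the three-subpopulation model
#'
#' Builds a validated parameter set for the minimal community model with
#' resistant (R), producer (P) and motile (M) subpopulations:
#' \deqn{dR/dt = k_1 N R - k_4 R - k_2 R P}
#' \deqn{dP/dt = -k_3 P + k_5 M}
#' \deqn{dM/dt = k_4 R - k_5 M}
#'
#' All rate constants are in \eqn{h^{-1}}; `N` is the dimensionless nutrient
#' level supplied to the resistant reserve. `k2` is the cost of resistance
#' (the bet-hedging coupling R*P), `k3` the cost of public-goods production,
#' `k4` the R to M transition rate and `k5` the M to P maturation rate.
#'
#' @param k1 proliferation rate of R per unit nutrient (h^-1).
#' @param k2 cost-of-resistance coupling of R and P (h^-1).
#' @param k3 cost of public-goods production / producer decay (h^-1).
#' @param k4 transition rate R -> M (h^-1).
#' @param k5 maturation rate M -> P (h^-1).
#' @param N nutrient level (dimensionless).
#'
#' @return An object of class `model_parameters`: a named numeric vector
#'   with elements `k1, k2, k3, k4, k5, N`.
#' @examples
#' p <- model_parameters()          # k1..k5 = 1 h^-1, N = 4
#' model_parameters(k3 = 10)
#' @export
model_parameters <- function(k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 1, N = 4) {
  p <- c(k1 = as.numeric(k1), k2 = as.numeric(k2), k3 = as.numeric(k3),
         k4 = as.numeric(k4), k5 = as.numeric(k5), N = as.numeric(N))
  validate_parameters(p)
  class(p) <- "model_parameters"
  p
}

validate_parameters <- function(p) {
  nm <- c("k1", "k2", "k3", "k4", "k5", "N")
  if (!all(nm %in% names(p))) {
    stop("parameters must contain ", paste(nm, collapse = ", "), call. = FALSE)
  }
  v <- unclass(p)[nm]
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all model parameters must be strictly positive and finite",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Community model parameters (h^-1 except N):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Coerce a named vector or list to `model_parameters`
#'
#' @param x named vector or list with elements `k1..k5, N`; missing entries
#'   take the defaults of [model_parameters()].
#' @return A `model_parameters` object.
#' @export
as_model_parameters <- function(x) {
  if (inherits(x, "model_parameters")) return(x)
  x <- as.list(x)
  do.call(model_parameters, x[names(x) %in% c("k1", "k2", "k3", "k4", "k5", "N")])
}

#' Read or write a parameter set as a flat key-value config file
#'
#' The config format is a YAML-compatible flat mapping with keys
#' `k1, k2, k3, k4, k5, N`, one per line. [write_parameters()] also accepts
#' `format = "json"`.
#'
#' @param params a `model_parameters` object.
#' @param path file to write to / read from.
#' @param format `"yaml"` (flat key-value) or `"json"`.
#' @return `read_parameters()` returns a `model_parameters` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
write_parameters <- function(params, path, format = c("yaml", "json")) {
  params <- as_model_parameters(params)
  format <- match.arg(format)
  x <- as.list(unclass(params))
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 17)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path, format = c("yaml", "json")) {
  format <- match.arg(format)
  x <- if (format == "json") jsonlite::read_json(path) else yaml::read_yaml(path)
  as_model_parameters(x)
}
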