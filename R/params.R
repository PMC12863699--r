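#' Model parameters
#'
#' Builds and validates the parameter set of the rescaled Caputo system. All
#' rate parameters are expressed in the fractional time unit (per time^alpha),
#' so a single object carries both the ecological rates and the derivative
#' order.
#'
#' @param Lambda constant recruitment rate of susceptible prey
#'   (density/time^alpha).
#' @param k fear level reducing prey recruitment (1/density); `k = 0` switches
#'   the fear effect off.
#' @param mu natural mortality rate of susceptible prey (1/time^alpha).
#' @param beta disease infection rate (1/(density\eqn{\cdot}time^alpha)).
#' @param omega recovery rate of infected prey (1/time^alpha); recovered prey
#'   re-enter the susceptible class.
#' @param delta mortality rate of infected prey (1/time^alpha).
#' @param m predation rate on infected prey (1/time^alpha per predator,
#'   saturated).
#' @param a half-saturation constant of the Holling type-II response
#'   (1/density).
#' @param n conversion (birth) rate of the predator from predation
#'   (1/time^alpha).
#' @param d predator mortality rate (1/time^alpha).
#' @param alpha order of the Caputo derivative, in (0, 1].
#'
#' @return An object of class `"model_params"`: a named list of the eleven
#'   parameters.
#' @examples
#' p <- model_params(Lambda = 10, k = 0.4, mu = 0.5, beta = 1.5, omega = 0.5,
#'                   delta = 0.5, m = 4, a = 1, n = 1, d = 0.5, alpha = 0.95)
#' p
#' @export
model_params <- function(Lambda, k, mu, beta, omega, delta, m, a, n, d, alpha) {
  p <- list(Lambda = Lambda, k = k, mu = mu, beta = beta, omega = omega,
            delta = delta, m = m, a = a, n = n, d = d, alpha = alpha)
  validate_params(p)
  structure(p, class = "model_params")
}

validate_params <- function(p) {
  nm <- c("Lambda", "k", "mu", "beta", "omega", "delta", "m", "a", "n", "d",
          "alpha")
  missing <- setdiff(nm, names(p))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  vals <- unlist(p[nm])
  if (!all(is.finite(vals)))
    stop("all parameters must be finite numbers")
  pos <- c("Lambda", "mu", "beta", "omega", "delta", "m", "a", "n", "d")
  bad <- pos[vals[pos] <= 0]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  if (p$k < 0) stop("fear level k must be non-negative")
  if (p$alpha <= 0 || p$alpha > 1)
    stop("fractional order alpha must lie in (0, 1]")
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-running
#' validation. Convenient for parameter scans.
#'
#' @param params a [model_params()] object.
#' @param ... named replacements, e.g. `beta = 0.06`.
#' @return A `"model_params"` object.
#' @examples
#' p <- table2_params()
#' update_params(p, beta = 0.06)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  repl <- list(...)
  if (length(repl) && (is.null(names(repl)) || any(names(repl) == "")))
    stop("all replacements must be named")
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown))
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  p <- modifyList(unclass(params), repl)
  validate_params(p)
  structure(p, class = "model_params")
}

#' Default parameter set of the numerical experiments
#'
#' The hypothetical parameter set used throughout the bifurcation and phase
#' portrait experiments: Lambda = 10, k = 0.4, mu = 0.5, beta = 1.5,
#' omega = 0.5, delta = 0.5, m = 4, a = 1, n = 1, d = 0.5, alpha = 0.95.
#'
#' @return A `"model_params"` object.
#' @examples
#' basic_reproduction_number(table2_params())
#' @export
table2_params <- function() {
  model_params(Lambda = 10, k = 0.4, mu = 0.5, beta = 1.5, omega = 0.5,
               delta = 0.5, m = 4, a = 1, n = 1, d = 0.5, alpha = 0.95)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Caputo fear-SIS predator-prey parameters\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 7), " = ", format(v)), sep = "\n")
  invisible(x)
}

#' State vector helper
#'
#' @param S,I,P susceptible prey, infected prey and predator densities.
#' @return A named numeric vector `c(S =, I =, P =)`.
#' @examples
#' state_vec(15, 2, 1)
#' @export
state_vec <- function(S, I, P) {
  y <- c(S = as.numeric(S), I = as.numeric(I), P = as.numeric(P))
  if (!all(is.finite(y))) stop("state components must be finite")
  y
}

as_state <- function(y) {
  y <- as.numeric(y)
  if (length(y) != 3L || !all(is.finite(y)))
    stop("state must be 3 finite numbers (S, I, P)")
  names(y) <- c("S", "I", "P")
  y
}
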