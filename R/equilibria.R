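#' Basic reproduction number
#'
#' `R0 = beta * Lambda / ((delta + omega) * mu)`: the expected number of
#' secondary prey infections produced by one infected individual introduced
#' at the disease-and-predator-free state. The disease invades iff `R0 > 1`.
#'
#' @param params a [model_params()] object.
#' @return Scalar `R0`.
#' @examples
#' basic_reproduction_number(update_params(table2_params(), beta = 0.04))  # 0.8
#' @export
basic_reproduction_number <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$beta * params$Lambda / ((params$delta + params$omega) * params$mu)
}

#' Prey-disease-predator-free equilibrium (PDPF)
#'
#' `(Lambda/mu, 0, 0)`: only susceptible prey persist. Always exists.
#'
#' @inheritParams basic_reproduction_number
#' @return Named state vector.
#' @examples
#' eq_pdpf(table2_params())  # (20, 0, 0)
#' @export
eq_pdpf <- function(params) {
  stopifnot(inherits(params, "model_params"))
  state_vec(params$Lambda / params$mu, 0, 0)
}

#' Predator-free equilibrium (PFP)
#'
#' `(Lambda/(mu R0), (R0-1) Lambda/(delta R0), 0)`: susceptible and infected
#' prey coexist while the predator is extinct. Exists only when `R0 > 1`; at
#' `R0 = 1` it coincides with the PDPF and is reported as absent-degenerate.
#'
#' @inheritParams basic_reproduction_number
#' @return Named state vector, or `NULL` when `R0 <= 1` (with attribute
#'   `degenerate = TRUE` on the NULL-marker when `R0 == 1`, see
#'   [equilibrium_report()]).
#' @examples
#' eq_pfp(update_params(table2_params(), beta = 0.052))  # (19.23, 0.77, 0)
#' @export
eq_pfp <- function(params) {
  stopifnot(inherits(params, "model_params"))
  R0 <- basic_reproduction_number(params)
  if (R0 <= 1) return(NULL)
  state_vec(params$Lambda / (params$mu * R0),
            (R0 - 1) * params$Lambda / (params$delta * R0),
            0)
}

#' Coefficients of the interior-equilibrium quadratic
#'
#' At a co-existence point the predator equation pins the infected prey at
#' `sigma = d/(n - a d)` (requires `n > a d`). Solving the infected-prey
#' steady state for `S` gives `S(P) = (delta+omega)/beta + m P/(beta(1+a
#' sigma))`; substituting into the susceptible-prey steady state and
#' multiplying through by `(1+kP)` yields the quadratic
#' `zeta1 P^2 + zeta2 P + zeta3 = 0` with
#' \deqn{\zeta_1 = C_1 k,\quad \zeta_2 = C_1 + C_0 k,\quad
#'       \zeta_3 = C_0 - \Lambda,}
#' where `C0 = (mu + beta sigma)(delta+omega)/beta - omega sigma` and
#' `C1 = (mu + beta sigma) m / (beta (1 + a sigma))`. `zeta1 > 0` (for
#' `k > 0`) and `zeta2 > 0` always; a unique positive root exists iff
#' `zeta3 < 0`, which is equivalent to `Lambda > delta sigma` together with
#' `R0 > Lambda/(Lambda - delta sigma)`.
#'
#' @inheritParams basic_reproduction_number
#' @return List with `zeta1`, `zeta2`, `zeta3`, `sigma`, or `NULL` when
#'   `n <= a d` (no admissible infected-prey level).
#' @export
cep_coefficients <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$n <= params$a * params$d) return(NULL)
  sigma <- params$d / (params$n - params$a * params$d)
  mb <- params$mu + params$beta * sigma
  C0 <- mb * (params$delta + params$omega) / params$beta -
    params$omega * sigma
  C1 <- mb * params$m / (params$beta * (1 + params$a * sigma))
  list(zeta1 = C1 * params$k, zeta2 = C1 + C0 * params$k,
       zeta3 = C0 - params$Lambda, sigma = sigma)
}

#' Co-existence equilibrium (CEP)
#'
#' The unique interior equilibrium `(eta, sigma, kappa)` when it exists:
#' `sigma = d/(n - a d)`, `kappa` the positive root of the quadratic of
#' [cep_coefficients()], and `eta = ((delta+omega)(1+a sigma) + m kappa) /
#' (beta (1 + a sigma))` recovered from the infected-prey steady state.
#' The root is computed in the cancellation-free form
#' `kappa = zeta3 / q`, `q = -(zeta2 + sqrt(zeta2^2 - 4 zeta1 zeta3))/2`
#' (for `k = 0` the quadratic degenerates to a linear equation).
#'
#' @inheritParams basic_reproduction_number
#' @return Named state vector, or `NULL` when the interior point does not
#'   exist.
#' @examples
#' eq_cep(update_params(table2_params(), beta = 0.06))  # (18.39, 1, 0.0517)
#' @export
eq_cep <- function(params) {
  cf <- cep_coefficients(params)
  if (is.null(cf)) return(NULL)
  if (cf$zeta3 >= 0) return(NULL)  # no positive root: predator cannot persist
  kappa <- if (cf$zeta1 == 0) {
    -cf$zeta3 / cf$zeta2
  } else {
    q <- -(cf$zeta2 + sqrt(cf$zeta2^2 - 4 * cf$zeta1 * cf$zeta3)) / 2
    cf$zeta3 / q
  }
  sigma <- cf$sigma
  eta <- ((params$delta + params$omega) * (1 + params$a * sigma) +
            params$m * kappa) / (params$beta * (1 + params$a * sigma))
  state_vec(eta, sigma, kappa)
}

#' Full equilibrium and existence report
#'
#' Computes `R0`, the three candidate equilibria, the interior quadratic
#' coefficients and the existence conditions, and verifies that every
#' reported equilibrium annihilates the vector field (residual below
#' `1e-8 * max(1, |state|)`).
#'
#' @inheritParams basic_reproduction_number
#' @return Object of class `"fearsis_eq_report"`: list with `R0`, `pdpf`,
#'   `pfp`, `cep`, `pfp_exists`, `pfp_degenerate`, `cep_exists`,
#'   `cep_coeffs`, `sigma`, `params`.
#' @examples
#' equilibrium_report(update_params(table2_params(), beta = 0.06))
#' @export
equilibrium_report <- function(params) {
  stopifnot(inherits(params, "model_params"))
  R0 <- basic_reproduction_number(params)
  pdpf <- eq_pdpf(params)
  pfp <- eq_pfp(params)
  cep <- eq_cep(params)
  cf <- cep_coefficients(params)
  for (eq in list(pdpf, pfp, cep)) {
    if (is.null(eq)) next
    res <- max(abs(model_rhs(eq, params)))
    if (res >= 1e-8 * max(1, max(abs(eq))))
      stop("internal error: equilibrium residual ", res)
  }
  structure(list(
    R0 = R0,
    pdpf = pdpf,
    pfp = pfp,
    cep = cep,
    pfp_exists = !is.null(pfp),
    pfp_degenerate = (R0 == 1),
    cep_exists = !is.null(cep),
    cep_coeffs = cf,
    sigma = if (is.null(cf)) NA_real_ else cf$sigma,
    params = params), class = "fearsis_eq_report")
}

#' @export
print.fearsis_eq_report <- function(x, ...) {
  cat(sprintf("R0 = %.6g\n", x$R0))
  fmt <- function(eq) paste(sprintf("%.6g", eq), collapse = ", ")
  cat("PDPF: (", fmt(x$pdpf), ")\n", sep = "")
  cat("PFP : ", if (x$pfp_exists) paste0("(", fmt(x$pfp), ")")
      else if (x$pfp_degenerate) "absent (degenerate at R0 = 1)"
      else "absent (R0 <= 1)", "\n", sep = "")
  cat("CEP : ", if (x$cep_exists) paste0("(", fmt(x$cep), ")")
      else "absent", "\n", sep = "")
  invisible(x)
}
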