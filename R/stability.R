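#' Matignon stability classification of a spectrum
#'
#' For a Caputo system of order `alpha`, an equilibrium is locally
#' asymptotically stable (LAS) iff every Jacobian eigenvalue satisfies
#' `|arg(lambda)| > alpha*pi/2`; eigenvalues inside the cone destabilize. A
#' real eigenvalue inside the cone alongside eigenvalues outside gives a
#' saddle; a complex-conjugate pair inside the cone is reported as
#' `"unstable"` (the spiral instability that feeds a limit cycle), matching
#' how attractors behave in simulation. The stability margin
#' `m(alpha) = alpha*pi/2 - min_j |arg(lambda_j)|` is negative for LAS and
#' crosses zero at a fractional Hopf point. When the spectrum consists of a
#' negative real eigenvalue plus a complex pair `theta +/- i omega` with
#' `theta > 0`, the critical order `alpha_star = (2/pi) atan(omega/theta)` is
#' also reported.
#'
#' @param eigs complex vector of eigenvalues (length 3 for this model).
#' @param alpha fractional order in (0, 1].
#' @param tol classification tolerance: eigenvalues whose argument is within
#'   `tol` radians of the cone boundary (or whose modulus is below 1e-10)
#'   make the verdict `"marginal"`.
#' @return Object of class `"fearsis_stability"`: `eigenvalues`, `min_arg`,
#'   `margin`, `classification` (`"LAS"`, `"saddle"`, `"unstable"`,
#'   `"marginal"`), `alpha_star` (NA unless applicable), `alpha`.
#' @examples
#' classify_matignon(c(-0.5, -0.2, -0.5), alpha = 0.95)
#' @export
classify_matignon <- function(eigs, alpha, tol = 1e-6) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  eigs <- as.complex(eigs)
  args <- abs(Arg(eigs))
  cone <- alpha * pi / 2
  min_arg <- min(args)
  margin <- cone - min_arg
  zero <- Mod(eigs) < 1e-10
  inside <- args < cone - tol
  outside <- args > cone + tol
  classification <-
    if (any(zero) || any(!inside & !outside)) "marginal"
    else if (all(outside)) "LAS"
    else if (all(inside)) "unstable"
    else {
      ins <- eigs[inside]
      # a conjugate pair crossing into the cone is the Hopf-type (spiral)
      # instability; only a real eigenvalue inside, with others outside,
      # gives the saddle's mixed hyperbolic structure
      pair_in <- length(ins) == 2L && all(abs(Im(ins)) > 1e-10) &&
        abs(ins[1] - Conj(ins[2])) < 1e-8 * max(1, Mod(ins[1]))
      if (pair_in) "unstable" else "saddle"
    }
  alpha_star <- NA_real_
  re <- Re(eigs); im <- Im(eigs)
  is_real <- abs(im) < 1e-10
  if (sum(is_real) == 1L && re[is_real] < 0 && all(re[!is_real] > 0)) {
    pair <- eigs[!is_real]
    alpha_star <- (2 / pi) * atan(abs(Im(pair[1])) / Re(pair[1]))
  }
  structure(list(eigenvalues = eigs, min_arg = min_arg, margin = margin,
                 classification = classification, alpha_star = alpha_star,
                 alpha = alpha),
            class = "fearsis_stability")
}

#' @export
print.fearsis_stability <- function(x, ...) {
  cat(sprintf("Matignon classification (alpha = %g): %s\n", x$alpha,
              x$classification))
  cat(sprintf("  margin m(alpha) = %.6g rad (cone half-angle %.6g)\n",
              x$margin, x$alpha * pi / 2))
  if (is.finite(x$alpha_star))
    cat(sprintf("  critical order alpha* = %.6g\n", x$alpha_star))
  invisible(x)
}

#' Characteristic polynomial coefficients of a 3x3 matrix
#'
#' Coefficients of `lambda^3 + c1 lambda^2 + c2 lambda + c3`:
#' `c1 = -trace`, `c2` = sum of the principal 2x2 minors,
#' `c3 = -determinant`.
#'
#' @param J real 3x3 matrix.
#' @return Named numeric `c(c1, c2, c3)`.
#' @export
char_poly_coeffs <- function(J) {
  J <- as.matrix(J)
  stopifnot(is.numeric(J), all(dim(J) == c(3L, 3L)))
  minor <- function(i, j) J[i, i] * J[j, j] - J[i, j] * J[j, i]
  c(c1 = -sum(diag(J)),
    c2 = minor(1, 2) + minor(1, 3) + minor(2, 3),
    c3 = -det(J))
}

#' Fractional Routh-Hurwitz criterion (cubic case)
#'
#' Sufficient conditions for all roots of `lambda^3 + c1 lambda^2 + c2 lambda
#' + c3` to lie outside the cone `|arg(lambda)| <= alpha*pi/2`, in terms of
#' the discriminant `Delta = 18 c1 c2 c3 + (c1 c2)^2 - 4 c3 c1^3 - 4 c2^3 -
#' 27 c3^2`:
#' (i) `Delta > 0, c1 > 0, c3 > 0, c1 c2 > c3` (classical Routh-Hurwitz,
#' any order); (ii) `Delta < 0, c1 >= 0, c2 >= 0, c3 > 0, alpha < 2/3`;
#' (iii) `Delta < 0, c1 > 0, c2 > 0, c1 c2 = c3` (within tolerance).
#' Conversely `Delta < 0, c1 < 0, c2 < 0, alpha > 2/3` forces an eigenvalue
#' inside the cone (instability).
#'
#' @param c1,c2,c3 real polynomial coefficients.
#' @param alpha fractional order in (0, 1].
#' @param tol tolerance for the equality clause (iii) and sign boundaries.
#' @return Object of class `"fearsis_rh"`: `c1,c2,c3`, `Delta`,
#'   `condition_met` (`"i"`, `"ii"`, `"iii"`, `"instability"` or `"none"`),
#'   `stable` (TRUE when a stability clause holds, FALSE for the instability
#'   clause, NA when no clause is decisive).
#' @examples
#' routh_hurwitz_fractional(6, 11, 6, alpha = 0.95)  # (x+1)(x+2)(x+3): stable
#' @export
routh_hurwitz_fractional <- function(c1, c2, c3, alpha, tol = 1e-9) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  Delta <- 18 * c1 * c2 * c3 + (c1 * c2)^2 - 4 * c3 * c1^3 - 4 * c2^3 -
    27 * c3^2
  cond <- if (Delta > 0 && c1 > 0 && c3 > 0 && c1 * c2 > c3) "i"
  else if (Delta < 0 && c1 >= 0 && c2 >= 0 && c3 > 0 && alpha < 2 / 3) "ii"
  else if (Delta < 0 && c1 > 0 && c2 > 0 && abs(c1 * c2 - c3) <=
             tol * max(1, abs(c3))) "iii"
  else if (Delta < 0 && c1 < 0 && c2 < 0 && alpha > 2 / 3) "instability"
  else "none"
  structure(list(c1 = c1, c2 = c2, c3 = c3, Delta = Delta,
                 condition_met = cond,
                 stable = switch(cond, i = TRUE, ii = TRUE, iii = TRUE,
                                 instability = FALSE, NA),
                 alpha = alpha),
            class = "fearsis_rh")
}

#' Local stability of every existing equilibrium
#'
#' Evaluates the analytic Jacobian at each equilibrium the parameter set
#' admits and classifies it with the Matignon condition. For the
#' predator-free point the predator-invasion eigenvalue
#' `lambda_1 = n I2/(1 + a I2) - d` (the decoupled third Jacobian row) is
#' reported separately: its sign decides whether the predator can invade.
#'
#' @inheritParams basic_reproduction_number
#' @param alpha fractional order; defaults to `params$alpha`.
#' @return Named list (entries `pdpf`, `pfp`, `cep` when they exist) of
#'   `"fearsis_stability"` reports; the `pfp` entry carries
#'   `$invasion_eigenvalue`.
#' @examples
#' stability_of_equilibria(update_params(table2_params(), beta = 0.052))
#' @export
stability_of_equilibria <- function(params, alpha = params$alpha) {
  rep <- equilibrium_report(params)
  out <- list()
  out$pdpf <- classify_matignon(
    eigen(model_jacobian(rep$pdpf, params), only.values = TRUE)$values, alpha)
  if (rep$pfp_exists) {
    st <- classify_matignon(
      eigen(model_jacobian(rep$pfp, params), only.values = TRUE)$values, alpha)
    I2 <- rep$pfp[["I"]]
    st$invasion_eigenvalue <- params$n * I2 / (1 + params$a * I2) - params$d
    out$pfp <- st
  }
  if (rep$cep_exists) {
    out$cep <- classify_matignon(
      eigen(model_jacobian(rep$cep, params), only.values = TRUE)$values, alpha)
  }
  out
}

theta_rate <- function(params) min(params$mu, params$delta, params$d)

#' Global stability sufficient condition for the PDPF
#'
#' Lyapunov-derived sufficient condition: with `S~ = Lambda/mu`, the
#' disease-and-predator-free point is globally asymptotically stable if
#' `S~ > omega/beta` and `Lambda k n/(d m) < R0 < (beta S~ - omega)/(beta
#' S~)`. A `FALSE` result is inconclusive (the condition is sufficient
#' only).
#'
#' @inheritParams basic_reproduction_number
#' @return List with `holds`, `S_tilde`, `R0`, `lower`, `upper`.
#' @export
global_pdpf_condition <- function(params) {
  stopifnot(inherits(params, "model_params"))
  S_tilde <- params$Lambda / params$mu
  R0 <- basic_reproduction_number(params)
  lower <- params$Lambda * params$k * params$n / (params$d * params$m)
  upper <- (params$beta * S_tilde - params$omega) / (params$beta * S_tilde)
  list(holds = (S_tilde > params$omega / params$beta) &&
         (lower < R0) && (R0 < upper),
       S_tilde = S_tilde, R0 = R0, lower = lower, upper = upper)
}

#' Global stability sufficient condition for the PFP
#'
#' With `S^ = Lambda/(mu R0)` and `I^ = (R0-1) Lambda/(delta R0)`, the
#' predator-free point is globally asymptotically stable if
#' `d > (n/m) (beta Lambda S^ k/delta + m I^ + m/a)`. Requires `R0 > 1`
#' (otherwise the PFP does not exist and the marker `applicable = FALSE` is
#' returned).
#'
#' @inheritParams basic_reproduction_number
#' @return List with `applicable`, `holds`, `S_hat`, `I_hat`, `rhs`.
#' @export
global_pfp_condition <- function(params) {
  stopifnot(inherits(params, "model_params"))
  pfp <- eq_pfp(params)
  if (is.null(pfp))
    return(list(applicable = FALSE, holds = NA, S_hat = NA_real_,
                I_hat = NA_real_, rhs = NA_real_))
  S_hat <- pfp[["S"]]; I_hat <- pfp[["I"]]
  rhs <- (params$n / params$m) *
    (params$beta * params$Lambda * S_hat * params$k / params$delta +
       params$m * I_hat + params$m / params$a)
  list(applicable = TRUE, holds = params$d > rhs, S_hat = S_hat,
       I_hat = I_hat, rhs = rhs)
}

#' Global stability sufficient condition for the CEP
#'
#' Evaluates the quadratic-Volterra Lyapunov bound for the co-existence point
#' `(eta, sigma, kappa)` over the attracting region `A(t) <= gamma`:
#' \deqn{\gamma_1 = (\omega + \sigma + \beta\gamma - \mu)/2,\quad
#'       \gamma_2 = (\beta\gamma + \sigma + \eta\gamma - 2\delta - \omega)/2,}
#' \deqn{\gamma_3 = (2n + (1+a)\kappa - 2ad)/(2a),}
#' with the offset `gamma_4 = ((mu+beta*gamma)*eta^2 + sigma*(delta+omega)^2 +
#' sigma*omega^2 + beta^2*eta*gamma + kappa*d^2 + n^2*kappa/a)/2 +
#' gamma*Lambda - Lambda*eta/(1+gamma*k)` reported for reference. The CEP is
#' globally asymptotically stable if `gamma1 < 0`, `gamma2 < 0` and
#' `gamma3 < 0`; a `FALSE` result is inconclusive.
#'
#' @inheritParams basic_reproduction_number
#' @param gamma bound on the dissipative region; defaults to
#'   `Lambda/theta + 0.01 * Lambda/theta` with `theta = min(mu, delta, d)`.
#' @return List with `applicable`, `holds`, `gamma`, `theta`,
#'   `gamma1 ... gamma4`.
#' @export
global_cep_condition <- function(params, gamma = NULL) {
  stopifnot(inherits(params, "model_params"))
  cep <- eq_cep(params)
  theta <- theta_rate(params)
  if (is.null(gamma)) gamma <- params$Lambda / theta * 1.01
  if (gamma < params$Lambda / theta)
    stop("gamma must be at least the attractor bound Lambda/theta = ",
         params$Lambda / theta)
  if (is.null(cep))
    return(list(applicable = FALSE, holds = NA, gamma = gamma, theta = theta,
                gamma1 = NA_real_, gamma2 = NA_real_, gamma3 = NA_real_,
                gamma4 = NA_real_))
  eta <- cep[["S"]]; sigma <- cep[["I"]]; kappa <- cep[["P"]]
  g1 <- (params$omega + sigma + params$beta * gamma - params$mu) / 2
  g2 <- (params$beta * gamma + sigma + eta * gamma - 2 * params$delta -
           params$omega) / 2
  g3 <- (2 * params$n + (1 + params$a) * kappa - 2 * params$a * params$d) /
    (2 * params$a)
  g4 <- ((params$mu + params$beta * gamma) * eta^2 +
           sigma * (params$delta + params$omega)^2 + sigma * params$omega^2 +
           params$beta^2 * eta * gamma + kappa * params$d^2 +
           params$n^2 * kappa / params$a) / 2 +
    gamma * params$Lambda - params$Lambda * eta / (1 + gamma * params$k)
  list(applicable = TRUE, holds = (g1 < 0) && (g2 < 0) && (g3 < 0),
       gamma = gamma, theta = theta,
       gamma1 = g1, gamma2 = g2, gamma3 = g3, gamma4 = g4)
}
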