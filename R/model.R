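#' Fear factor
#'
#' Multiplicative reduction of the prey recruitment rate caused by predator
#' presence, `1 / (1 + k P)`. Equals 1 when there is no fear (`k = 0`) or no
#' predators (`P = 0`) and decreases monotonically in `P` otherwise.
#'
#' @param k fear level (1/density), non-negative.
#' @param P predator density, non-negative.
#' @return A scalar in (0, 1].
#' @examples
#' fear_factor(0.4, 2)   # recruitment reduced to 1/1.8
#' fear_factor(0, 7.3)   # no fear: 1
#' @export
fear_factor <- function(k, P) {
  if (!is.finite(k) || !is.finite(P)) stop("k and P must be finite")
  if (k < 0) stop("fear level k must be non-negative")
  if (P < 0) stop("predator density P must be non-negative")
  1 / (1 + k * P)
}

#' Right-hand side of the Caputo fear-SIS predator-prey system
#'
#' Evaluates the vector field (F1, F2, F3) of the rescaled model:
#' \deqn{F_1 = \Lambda/(1+kP) - \mu S - \beta S I + \omega I}
#' \deqn{F_2 = \beta S I - (\delta+\omega) I - m I P/(1+aI)}
#' \deqn{F_3 = n I P/(1+aI) - d P}
#'
#' The same function is the Caputo derivative of the state, so equilibria are
#' exactly its zeros regardless of the order `alpha`.
#'
#' @param state numeric length-3 state `(S, I, P)`.
#' @param params a [model_params()] object.
#' @return Named numeric vector `(S, I, P)` of derivatives.
#' @examples
#' p <- table2_params()
#' model_rhs(c(20, 0, 0), p)  # the disease-and-predator-free point is a zero
#' @export
model_rhs <- function(state, params) {
  y <- as_state(state)
  S <- y[[1]]; I <- y[[2]]; P <- y[[3]]
  hol <- 1 + params$a * I
  c(S = params$Lambda / (1 + params$k * P) - params$mu * S -
        params$beta * S * I + params$omega * I,
    I = params$beta * S * I - (params$delta + params$omega) * I -
        params$m * I * P / hol,
    P = params$n * I * P / hol - params$d * P)
}

#' Analytic Jacobian of the model
#'
#' The exact Jacobian of [model_rhs()] at an arbitrary state; equilibrium
#' Jacobians are obtained by evaluating it at the equilibrium coordinates
#' rather than from per-equilibrium simplified forms.
#'
#' @inheritParams model_rhs
#' @return A 3x3 numeric matrix, rows/columns ordered (S, I, P).
#' @examples
#' p <- table2_params()
#' eigen(model_jacobian(eq_pdpf(p), p))$values
#' @export
model_jacobian <- function(state, params) {
  y <- as_state(state)
  S <- y[[1]]; I <- y[[2]]; P <- y[[3]]
  hol <- 1 + params$a * I
  fearP <- 1 + params$k * P
  matrix(c(
    -params$mu - params$beta * I,
    params$omega - params$beta * S,
    -params$Lambda * params$k / fearP^2,
    params$beta * I,
    params$beta * S - (params$delta + params$omega) - params$m * P / hol^2,
    -params$m * I / hol,
    0,
    params$n * P / hol^2,
    params$n * I / hol - params$d),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("S", "I", "P"), c("S", "I", "P")))
}
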