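#' Solver configuration
#'
#' Bundles the numerical settings of the fractional predictor-corrector.
#' Defaults (`h = 0.05`, `t_end = 2000`, one corrector pass, full memory)
#' resolve the attractors of the fear-SIS model at desk scale; shorter
#' horizons are appropriate for transient studies and tests.
#'
#' @param h step size (time units), > 0.
#' @param t_end final time, > 0; rounded to a whole number of steps.
#' @param corrector_iterations number of corrector passes per step (>= 1).
#' @return An object of class `"solver_config"`.
#' @export
solver_config <- function(h = 0.05, t_end = 2000, corrector_iterations = 1L) {
  if (!is.finite(h) || h <= 0) stop("h must be > 0")
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0")
  corrector_iterations <- as.integer(corrector_iterations)
  if (is.na(corrector_iterations) || corrector_iterations < 1L)
    stop("corrector_iterations must be a positive integer")
  structure(list(h = h, t_end = t_end,
                 corrector_iterations = corrector_iterations,
                 memory = "full"),
            class = "solver_config")
}

#' Integrate a Caputo fractional initial-value problem
#'
#' Full-memory Adams-Bashforth-Moulton (generalized predictor-corrector)
#' scheme for `D^alpha y = f(t, y)`, `y(0) = y0`, on a uniform grid. The
#' scheme reduces to the classical second-order ABM method at `alpha = 1` and
#' has empirical order about `min(2, 1 + alpha)` for smooth problems (see
#' [estimate_convergence_order()]). The whole solution history enters every
#' step (O(N^2) work): no short-memory truncation is applied, since
#' truncation shifts Hopf thresholds.
#'
#' @param f right-hand side, `f(t, y, ...)`, returning a numeric vector the
#'   same length as `y0`.
#' @param y0 numeric initial state.
#' @param alpha Caputo order in (0, 1].
#' @param config a [solver_config()] object (or arguments via `h`, `t_end`,
#'   `corrector_iterations` shortcuts).
#' @param h,t_end,corrector_iterations used when `config` is missing.
#' @param ... further arguments passed to `f`.
#' @return An object of class `"fearsis_traj"`: list with `times` (length
#'   N+1), `states` ((N+1) x d matrix), `alpha` and `config`. If the state
#'   becomes non-finite the function signals an error of class
#'   `"fearsis_integration_error"` whose condition carries the partial
#'   trajectory in `$trajectory`.
#' @examples
#' tr <- fde_solve(function(t, y) -y, 1, alpha = 0.9, h = 0.05, t_end = 2)
#' tail(as.data.frame(tr), 1)
#' @export
fde_solve <- function(f, y0, alpha, config = NULL, h = 0.05, t_end = 10,
                      corrector_iterations = 1L, ...) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (is.null(config)) config <- solver_config(h, t_end, corrector_iterations)
  stopifnot(inherits(config, "solver_config"))
  y0 <- as.numeric(y0)
  if (!all(is.finite(y0))) stop("initial state must be finite")
  N <- max(1L, as.integer(round(config$t_end / config$h)))
  g <- function(t, y) as.numeric(f(t, y, ...))
  res <- abm_solve_cpp(g, y0, alpha, config$h, N, config$corrector_iterations)
  times <- (0:N) * config$h
  states <- res$states
  if (length(y0) == 3L) colnames(states) <- c("S", "I", "P")
  traj <- structure(list(times = times, states = states, alpha = alpha,
                         config = config),
                    class = "fearsis_traj")
  if (!res$ok) {
    kept <- seq_len(res$steps_done + 1L)
    partial <- traj
    partial$times <- times[kept]
    partial$states <- states[kept, , drop = FALSE]
    stop(errorCondition(
      sprintf("state became non-finite at t = %.6g; partial trajectory attached",
              times[res$steps_done + 2L]),
      trajectory = partial,
      class = c("fearsis_integration_error", "error", "condition")))
  }
  traj
}

#' Simulate the fear-SIS predator-prey model
#'
#' Convenience wrapper around [fde_solve()] with [model_rhs()] as the vector
#' field and the order taken from `params$alpha`.
#'
#' @param params a [model_params()] object.
#' @param y0 initial state `(S, I, P)`; defaults to the most interior
#'   existing equilibrium (CEP, else PFP, else PDPF) perturbed by +5% per
#'   component, which suppresses long transients in attractor
#'   classification.
#' @param config a [solver_config()]; see defaults there.
#' @inheritParams fde_solve
#' @return A `"fearsis_traj"` with the parameter set attached as `$params`.
#' @examples
#' p <- update_params(table2_params(), beta = 0.04)
#' tr <- simulate_model(p, y0 = c(15, 2, 1), t_end = 100)
#' tail(as.data.frame(tr), 1)  # approaches (20, 0, 0)
#' @export
simulate_model <- function(params, y0 = NULL, config = NULL, h = 0.05,
                           t_end = 2000, corrector_iterations = 1L) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(y0)) y0 <- default_initial_state(params)
  traj <- fde_solve(function(t, y) model_rhs(y, params), as_state(y0),
                    alpha = params$alpha, config = config, h = h,
                    t_end = t_end, corrector_iterations = corrector_iterations)
  traj$params <- params
  traj
}

default_initial_state <- function(params) {
  eq <- eq_cep(params)
  if (is.null(eq)) eq <- eq_pfp(params)
  if (is.null(eq)) eq <- eq_pdpf(params)
  eq * 1.05
}

#' @export
print.fearsis_traj <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Caputo trajectory: %d steps, h = %g, t in [0, %g], alpha = %g\n",
              n - 1L, x$config$h, x$times[n], x$alpha))
  cat("final state:", paste(sprintf("%.6g", x$states[n, ]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.fearsis_traj <- function(x, ...) {
  df <- as.data.frame(x$states)
  if (is.null(names(df)) || !length(names(df)))
    names(df) <- paste0("y", seq_len(ncol(x$states)))
  cbind(time = x$times, df)
}

#' Empirical convergence order of the fractional integrator
#'
#' Solves the same problem on a sequence of step sizes, measures the endpoint
#' error against the finest solution in the list, and returns the slope of
#' log(error) against log(h). For smooth problems the scheme's order is about
#' `min(2, 1 + alpha)`.
#'
#' @inheritParams fde_solve
#' @param h_list at least 3 step sizes, each an integer divisor of `t_end`;
#'   geometric sequences (e.g. `0.1 * 2^-(0:4)`) work best.
#' @param t_end common final time.
#' @return Scalar slope estimate.
#' @examples
#' estimate_convergence_order(function(t, y) -y, 1, alpha = 0.8,
#'                            h_list = 0.2 / 2^(0:3), t_end = 1)
#' @export
estimate_convergence_order <- function(f, y0, alpha, h_list, t_end, ...) {
  h_list <- sort(as.numeric(h_list), decreasing = TRUE)
  if (length(h_list) < 3L)
    stop("h_list must contain at least 3 step sizes")
  sols <- lapply(h_list, function(h) fde_solve(f, y0, alpha, h = h,
                                               t_end = t_end, ...))
  fine <- sols[[length(sols)]]
  h_fine <- h_list[length(h_list)]
  hs <- h_list[-length(h_list)]
  # max-norm error on each coarse grid, against the finest solution at the
  # same times (the global error, dominated by the t^alpha layer at t = 0,
  # carries the min(2, 1+alpha) order; the endpoint alone superconverges)
  errs <- vapply(seq_along(hs), function(i) {
    idx <- round(sols[[i]]$times / h_fine) + 1L
    if (max(abs(sols[[i]]$times - fine$times[idx])) > 1e-9 * max(1, t_end))
      stop("h_list entries must share grid points with the finest step")
    max(abs(sols[[i]]$states - fine$states[idx, , drop = FALSE]))
  }, numeric(1))
  keep <- errs > 0
  if (sum(keep) < 2L) stop("errors vanished; use coarser steps")
  unname(coef(lm(log(errs[keep]) ~ log(hs[keep])))[2L])
}

#' Trajectory non-negativity check
#'
#' Biologically admissible solutions stay in the non-negative octant; the
#' discretized trajectory is allowed a small numerical undershoot.
#'
#' @param traj a `"fearsis_traj"`.
#' @param tol permitted undershoot (default 1e-6).
#' @return `TRUE`/`FALSE`, with attribute `min_value`.
#' @export
check_nonnegativity <- function(traj, tol = 1e-6) {
  mn <- min(traj$states)
  structure(mn >= -tol, min_value = mn)
}

#' Trajectory dissipativity (boundedness) check
#'
#' The weighted total population `A(t) = S + I + (m/n) P` satisfies
#' `D^alpha A <= Lambda - theta A` with `theta = min(mu, delta, d)`, hence
#' `A(t) <= max(A(0), Lambda/theta)` up to transient overshoot. The check
#' allows 5% of `Lambda/theta` slack for discretization error.
#'
#' @param traj a `"fearsis_traj"` produced by [simulate_model()].
#' @param params parameters; defaults to `traj$params`.
#' @return `TRUE`/`FALSE`, with attributes `bound` and `max_A`.
#' @export
check_boundedness <- function(traj, params = traj$params) {
  stopifnot(inherits(params, "model_params"))
  A <- traj$states[, 1] + traj$states[, 2] +
    params$m / params$n * traj$states[, 3]
  theta <- min(params$mu, params$delta, params$d)
  bound <- max(A[1], params$Lambda / theta) + 0.05 * params$Lambda / theta
  structure(max(A) <= bound, bound = bound, max_A = max(A))
}

#' Write / read a trajectory as CSV
#'
#' Writes `time,S,I,P` rows at full double precision (17 significant digits,
#' so the grid round-trips bit-exactly) plus a JSON sidecar
#' (`<file>.json`) holding the parameters and solver settings.
#'
#' @param traj a `"fearsis_traj"`.
#' @param file CSV path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file, sidecar = TRUE) {
  stopifnot(inherits(traj, "fearsis_traj"))
  cn <- colnames(traj$states)
  if (is.null(cn)) cn <- paste0("y", seq_len(ncol(traj$states)))
  header <- paste(c("time", cn), collapse = ",")
  body <- apply(cbind(traj$times, traj$states), 1L,
                function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(header, body), file)
  if (sidecar) {
    meta <- list(alpha = traj$alpha, config = unclass(traj$config))
    if (!is.null(traj$params)) meta$params <- unclass(traj$params)
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = I(17))
  }
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  df <- read.csv(file, colClasses = "numeric")
  states <- as.matrix(df[, -1, drop = FALSE])
  meta_file <- paste0(file, ".json")
  alpha <- NA_real_; config <- NULL; params <- NULL
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    alpha <- meta$alpha
    if (!is.null(meta$config))
      config <- structure(meta$config, class = "solver_config")
    if (!is.null(meta$params))
      params <- structure(as.list(meta$params), class = "model_params")
  }
  structure(list(times = df$time, states = states, alpha = alpha,
                 config = config, params = params),
            class = "fearsis_traj")
}
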