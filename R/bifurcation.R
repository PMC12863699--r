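#' Forward-bifurcation threshold in the infection rate
#'
#' The disease-and-predator-free point exchanges stability with the
#' predator-free branch at `R0 = 1`, i.e. at
#' `beta = (delta + omega) mu / Lambda`.
#'
#' @inheritParams basic_reproduction_number
#' @return Scalar threshold (the current `beta` in `params` is ignored).
#' @examples
#' forward_threshold_beta(table2_params())  # 0.05
#' @export
forward_threshold_beta <- function(params) {
  stopifnot(inherits(params, "model_params"))
  (params$delta + params$omega) * params$mu / params$Lambda
}

#' Predator-invasion threshold in the infection rate
#'
#' The predator-free point loses stability when its invasion eigenvalue
#' `n I2/(1 + a I2) - d` crosses zero, i.e. when the infected-prey level
#' reaches `sigma = d/(n - a d)`. In closed form
#' `beta = (delta + omega) mu / (Lambda - delta sigma)`, equivalently the
#' boundary `R0 = Lambda/(Lambda - delta sigma)` of interior-equilibrium
#' existence.
#'
#' @inheritParams basic_reproduction_number
#' @return Scalar threshold, or `NA` (with a message attribute) when
#'   `Lambda <= delta sigma` so the predator can never invade.
#' @examples
#' predator_invasion_threshold_beta(table2_params())  # 1/19 = 0.052632
#' @export
predator_invasion_threshold_beta <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$n <= params$a * params$d)
    stop("requires n > a*d (otherwise the predator equation has no ",
         "admissible infected-prey level)")
  sigma <- params$d / (params$n - params$a * params$d)
  if (params$Lambda <= params$delta * sigma)
    return(structure(NA_real_,
                     message = "Lambda <= delta*sigma: predator cannot invade"))
  (params$delta + params$omega) * params$mu /
    (params$Lambda - params$delta * sigma)
}

#' Matignon margin at an equilibrium
#'
#' `m(alpha) = alpha*pi/2 - min_j |arg(lambda_j)|` for the Jacobian spectrum
#' at the named equilibrium. Negative values mean every eigenvalue lies
#' outside the stability cone (LAS); a zero crossing marks a fractional Hopf
#' point.
#'
#' @inheritParams basic_reproduction_number
#' @param which `"cep"`, `"pfp"` or `"pdpf"`.
#' @param alpha order; defaults to `params$alpha`.
#' @return Scalar margin (radians).
#' @export
matignon_margin <- function(params, which = c("cep", "pfp", "pdpf"),
                            alpha = params$alpha) {
  which <- match.arg(which)
  eq <- switch(which, cep = eq_cep(params), pfp = eq_pfp(params),
               pdpf = eq_pdpf(params))
  if (is.null(eq))
    stop("equilibrium '", which, "' does not exist for these parameters")
  eigs <- eigen(model_jacobian(eq, params), only.values = TRUE)$values
  alpha * pi / 2 - min(abs(Arg(eigs)))
}

#' Locate a fractional Hopf threshold by margin bisection
#'
#' Bisects the Matignon margin of the co-existence equilibrium as a function
#' of one parameter (`"alpha"`, `"beta"`, `"k"`, ...) over a bracket with a
#' sign change. At the root the Jacobian spectrum is verified to have the
#' Hopf structure (one negative real eigenvalue plus a complex pair), and
#' the transversality of the margin is checked numerically. When the swept
#' parameter is `alpha` itself the closed form
#' `alpha* = (2/pi) atan(omega/theta)` of the eigenpair `theta +/- i omega`
#' is attached for cross-checking.
#'
#' @inheritParams basic_reproduction_number
#' @param parameter name of the parameter to vary.
#' @param bracket length-2 numeric bracket with opposite margin signs.
#' @param which equilibrium to track (default `"cep"`).
#' @param tol bisection tolerance in the parameter (default 1e-6).
#' @return Object of class `"fearsis_threshold"`: `parameter`, `bracket`,
#'   `root`, `method`, `margin_at_root`, `eigenvalues`, `hopf_structure`,
#'   `margin_slope_sign`, `alpha_star_closed_form` (NA unless
#'   `parameter == "alpha"`).
#' @examples
#' p <- table2_params()
#' find_hopf_threshold(p, "beta", c(0.055, 0.08))  # about 0.0653
#' @export
find_hopf_threshold <- function(params, parameter, bracket,
                                which = "cep", tol = 1e-6) {
  stopifnot(inherits(params, "model_params"), length(bracket) == 2L)
  bracket <- sort(as.numeric(bracket))
  marg <- function(v) {
    p <- do.call(update_params, c(list(params), setNames(list(v), parameter)))
    eq <- switch(which, cep = eq_cep(p), pfp = eq_pfp(p), pdpf = eq_pdpf(p))
    if (is.null(eq))
      stop("equilibrium '", which, "' loses existence inside the bracket at ",
           parameter, " = ", v,
           if (which == "cep")
             paste0(" (existence boundary R0 = Lambda/(Lambda - delta*sigma))")
           else "")
    alpha <- if (parameter == "alpha") v else p$alpha
    eigs <- eigen(model_jacobian(eq, p), only.values = TRUE)$values
    list(m = alpha * pi / 2 - min(abs(Arg(eigs))), eigs = eigs)
  }
  lo <- bracket[1]; hi <- bracket[2]
  mlo <- marg(lo)$m; mhi <- marg(hi)$m
  if (sign(mlo) == sign(mhi))
    stop("margin has the same sign at both bracket ends (", signif(mlo, 6),
         ", ", signif(mhi, 6), "): no Hopf crossing bracketed")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    mm <- marg(mid)$m
    if (sign(mm) == sign(mlo)) { lo <- mid; mlo <- mm } else hi <- mid
  }
  root <- (lo + hi) / 2
  at_root <- marg(root)
  eigs <- at_root$eigs
  re <- Re(eigs); im <- Im(eigs)
  is_real <- abs(im) < 1e-8 * pmax(1, Mod(eigs))
  hopf_structure <- sum(is_real) == 1L && re[is_real][1] < 0 &&
    sum(!is_real) == 2L
  dstep <- max(tol, 1e-7 * max(1, abs(root)))
  slope <- (marg(root + dstep)$m - marg(root - dstep)$m) / (2 * dstep)
  alpha_star <- NA_real_
  if (parameter == "alpha" && hopf_structure) {
    pair <- eigs[!is_real][1]
    if (Re(pair) > 0) alpha_star <- (2 / pi) * atan(abs(Im(pair)) / Re(pair))
  }
  structure(list(parameter = parameter, bracket = bracket, root = root,
                 method = "margin-bisection", margin_at_root = at_root$m,
                 eigenvalues = eigs, hopf_structure = hopf_structure,
                 margin_slope_sign = sign(slope),
                 alpha_star_closed_form = alpha_star),
            class = "fearsis_threshold")
}

#' @export
print.fearsis_threshold <- function(x, ...) {
  cat(sprintf("Hopf threshold in '%s': %.6g (method %s)\n", x$parameter,
              x$root, x$method))
  cat(sprintf("  margin at root = %.3g; Hopf eigenvalue structure: %s\n",
              x$margin_at_root, x$hopf_structure))
  invisible(x)
}

#' Limit-cycle detection on a computed trajectory
#'
#' Discards the leading `transient_fraction` of the trajectory and measures
#' the per-component relative amplitude `(max - min)/max(1, |mean|)` over
#' the tail. Any component exceeding `amplitude_tol` classifies the attractor
#' as a cycle; otherwise the trajectory is taken to sit on an equilibrium.
#'
#' @param traj a `"fearsis_traj"`.
#' @param transient_fraction fraction of the trajectory discarded (default
#'   0.5).
#' @param amplitude_tol relative-amplitude threshold (default 1e-2).
#' @return List with `class` (`"cycle"` or `"equilibrium"`), `amplitude`
#'   (per component), `tail_mean`, `tail_min`, `tail_max`.
#' @export
detect_limit_cycle <- function(traj, transient_fraction = 0.5,
                               amplitude_tol = 1e-2) {
  stopifnot(inherits(traj, "fearsis_traj"))
  n <- nrow(traj$states)
  start <- floor(n * transient_fraction) + 1L
  if (n - start + 1L < 100L)
    stop("trajectory tail too short (need at least 100 points after the ",
         "transient)")
  tail_states <- traj$states[start:n, , drop = FALSE]
  mins <- apply(tail_states, 2L, min)
  maxs <- apply(tail_states, 2L, max)
  means <- colMeans(tail_states)
  amp <- (maxs - mins) / pmax(1, abs(means))
  list(class = if (any(amp > amplitude_tol)) "cycle" else "equilibrium",
       amplitude = amp, tail_mean = means, tail_min = mins, tail_max = maxs)
}

#' Parameter sweep with attractor classification
#'
#' Integrates the model along a monotone parameter grid, warm-starting each
#' run from the previous run's final state (continuation), and classifies
#' each attractor with [detect_limit_cycle()]. This is the empirical
#' (simulation) route to the bifurcation diagram; [find_hopf_threshold()] is
#' the deterministic eigenvalue route.
#'
#' @inheritParams basic_reproduction_number
#' @param parameter name of the swept parameter.
#' @param grid strictly monotone numeric grid.
#' @param y0 initial state for the first grid point; defaults to the
#'   equilibrium of interest perturbed by +5% per component.
#' @param h,t_end solver settings per grid point.
#' @param transient_fraction,amplitude_tol passed to [detect_limit_cycle()].
#' @return Object of class `"fearsis_sweep"`: a data frame with columns
#'   `value`, `class` (`"equilibrium"`, `"cycle"` or `"divergent"`),
#'   `S_min, S_max, I_min, I_max, P_min, P_max` and the final state, plus
#'   attributes `parameter` and `settings`.
#' @examples
#' \donttest{
#' sw <- sweep_parameter(table2_params(), "beta", c(0.04, 0.06, 0.6),
#'                       t_end = 300)
#' sw$class
#' }
#' @export
sweep_parameter <- function(params, parameter, grid, y0 = NULL, h = 0.05,
                            t_end = 400, transient_fraction = 0.5,
                            amplitude_tol = 1e-2) {
  stopifnot(inherits(params, "model_params"))
  grid <- as.numeric(grid)
  if (length(grid) < 1L ||
      (length(grid) > 1L && !(all(diff(grid) > 0) || all(diff(grid) < 0))))
    stop("grid must be strictly monotone")
  p0 <- do.call(update_params,
                c(list(params), setNames(list(grid[1]), parameter)))
  if (is.null(y0)) y0 <- default_initial_state(p0)
  rows <- vector("list", length(grid))
  current <- as_state(y0)
  for (i in seq_along(grid)) {
    p <- do.call(update_params,
                 c(list(params), setNames(list(grid[i]), parameter)))
    res <- tryCatch({
      traj <- simulate_model(p, y0 = current, h = h, t_end = t_end)
      cyc <- detect_limit_cycle(traj, transient_fraction, amplitude_tol)
      fin <- traj$states[nrow(traj$states), ]
      # continuation floor: S = I = P = 0 are invariant planes, so a state
      # that has decayed onto one could never show invasion as the parameter
      # grows; re-seeding at 1e-3 keeps every compartment invasible
      current <- pmax(fin, 1e-3)
      data.frame(value = grid[i], class = cyc$class,
                 S_min = cyc$tail_min[["S"]], S_max = cyc$tail_max[["S"]],
                 I_min = cyc$tail_min[["I"]], I_max = cyc$tail_max[["I"]],
                 P_min = cyc$tail_min[["P"]], P_max = cyc$tail_max[["P"]],
                 S_end = fin[["S"]], I_end = fin[["I"]], P_end = fin[["P"]])
    }, fearsis_integration_error = function(e) {
      data.frame(value = grid[i], class = "divergent",
                 S_min = NA_real_, S_max = NA_real_, I_min = NA_real_,
                 I_max = NA_real_, P_min = NA_real_, P_max = NA_real_,
                 S_end = NA_real_, I_end = NA_real_, P_end = NA_real_)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "settings") <- list(h = h, t_end = t_end,
                                transient_fraction = transient_fraction,
                                amplitude_tol = amplitude_tol)
  class(out) <- c("fearsis_sweep", "data.frame")
  out
}
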