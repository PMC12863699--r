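test_that("forward threshold sits exactly at R0 = 1", {
  b1 <- forward_threshold_beta(p_default)
  expect_equal(b1, 0.05, tolerance = 1e-14)
  expect_equal(basic_reproduction_number(p_beta(b1)), 1, tolerance = 1e-14)
  p2 <- update_params(p_default, Lambda = 20)
  expect_equal(forward_threshold_beta(p2), b1 / 2, tolerance = 1e-14)
})

test_that("predator-invasion threshold matches its closed form", {
  b2 <- predator_invasion_threshold_beta(p_default)
  expect_equal(b2, 1 / 19, tolerance = 1e-14)
  expect_equal(round(b2, 4), 0.0526)
  expect_equal(basic_reproduction_number(p_beta(b2)), 20 / 19,
               tolerance = 1e-12)
  # vanishing half-saturation limit
  p0 <- update_params(p_default, a = 1e-9)
  expect_equal(predator_invasion_threshold_beta(p0), 0.5 / 9.75,
               tolerance = 1e-6)
  # predator never invades when Lambda <= delta*sigma
  p_weak <- update_params(p_default, n = 0.52, Lambda = 5)  # sigma = 25
  expect_true(is.na(predator_invasion_threshold_beta(p_weak)))
  expect_error(predator_invasion_threshold_beta(
    update_params(p_default, n = 0.4)), "n > a\\*d")
})

test_that("Matignon margin has the expected signs across the beta scan", {
  expect_lt(matignon_margin(p_beta(0.06), "cep"), 0)
  expect_gt(matignon_margin(p_beta(0.6), "cep"), 0)
  # all-real-negative spectrum: margin = alpha*pi/2 - pi < 0 for alpha <= 1
  expect_equal(matignon_margin(p_beta(0.04), "pdpf"),
               0.95 * pi / 2 - pi, tolerance = 1e-12)
  expect_error(matignon_margin(p_beta(0.04), "cep"), "does not exist")
})

test_that("margin bisection locates the infection-rate Hopf point", {
  th <- find_hopf_threshold(p_default, "beta", c(0.06, 0.1))
  expect_equal(th$root, 0.0651, tolerance = 0.005)
  expect_lt(abs(th$margin_at_root), 1e-5)
  expect_true(th$hopf_structure)
  expect_gt(th$margin_slope_sign, 0)
  # independent bracket converges to the same root
  th2 <- find_hopf_threshold(p_default, "beta", c(0.055, 0.08))
  expect_equal(th$root, th2$root, tolerance = 1e-5)
})

test_that("order-driven Hopf point equals the closed form (2/pi) atan(omega/theta)", {
  th <- find_hopf_threshold(p_default, "alpha", c(0.62, 0.999))
  expect_true(th$hopf_structure)
  expect_equal(th$root, th$alpha_star_closed_form, tolerance = 1e-5)
  pair <- th$eigenvalues[Im(th$eigenvalues) > 0]
  expect_equal(th$root, (2 / pi) * atan(Im(pair) / Re(pair)),
               tolerance = 1e-5)
  # the margin is strictly increasing in alpha, so the root is unique
  ms <- vapply(seq(0.65, 1, by = 0.05), function(a)
    matignon_margin(p_default, "cep", alpha = a), numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("bisection errors are informative", {
  expect_error(find_hopf_threshold(p_default, "beta", c(0.07, 0.08)),
               "same sign")
  expect_error(find_hopf_threshold(p_default, "beta", c(0.04, 0.08)),
               "loses existence")
})

test_that("limit-cycle detector measures amplitudes correctly", {
  fake_traj <- function(states) {
    structure(list(times = seq_len(nrow(states)) - 1, states = states,
                   alpha = 1, config = solver_config(h = 1, t_end = nrow(states))),
              class = "fearsis_traj")
  }
  const <- fake_traj(matrix(5, nrow = 400, ncol = 3,
                            dimnames = list(NULL, c("S", "I", "P"))))
  dc <- detect_limit_cycle(const)
  expect_identical(dc$class, "equilibrium")
  expect_equal(unname(dc$amplitude), c(0, 0, 0))
  # sinusoid of amplitude A about mean 5: relative amplitude 2A/5
  t <- seq(0, 200, by = 0.1)
  A <- 1.3
  sin_states <- cbind(S = 5 + A * sin(t), I = 5 + A * sin(t), P = 5 + A * sin(t))
  ds <- detect_limit_cycle(fake_traj(sin_states))
  expect_identical(ds$class, "cycle")
  expect_equal(unname(ds$amplitude[1]), 2 * A / 5, tolerance = 0.05)
  expect_error(detect_limit_cycle(fake_traj(sin_states[1:50, ])), "too short")
})

test_that("default configuration sustains a limit cycle around the interior point", {
  tr <- simulate_model(p_default, t_end = 400)
  expect_identical(detect_limit_cycle(tr)$class, "cycle")
})

test_that("beta sweep classifies the attractor sequence of the infection scan", {
  sw <- sweep_parameter(p_default, "beta", c(0.04, 0.052, 0.06, 0.6),
                        t_end = 2000)
  expect_identical(sw$class,
                   c("equilibrium", "equilibrium", "equilibrium", "cycle"))
  expect_equal(sw$S_end[1], 20, tolerance = 1e-2)
  expect_gt(sw$I_max[4] - sw$I_min[4], 1)
})

test_that("sweep transition brackets the bisected Hopf point and cycle amplitudes shrink toward it", {
  root <- find_hopf_threshold(p_default, "beta", c(0.055, 0.08))$root
  grid <- seq(0.055, 0.085, by = 0.005)
  sw <- sweep_parameter(p_default, "beta", grid, t_end = 2000)
  first_cycle <- grid[match("cycle", sw$class)]
  expect_lt(abs(first_cycle - root), 0.005 + 1e-12)
  # supercritical scaling: amplitude grows with distance above threshold
  amps <- (sw$I_max - sw$I_min)[sw$class == "cycle"]
  expect_true(all(diff(amps) > 0))
  # below the threshold the amplitude is below tolerance
  expect_lt(sw$I_max[1] - sw$I_min[1], 1e-2)
})

test_that("sweep validates its grid", {
  expect_error(sweep_parameter(p_default, "beta", c(0.1, 0.05, 0.2)),
               "monotone")
})

test_that("sweep started at a stable equilibrium stays there with zero amplitude", {
  p <- p_beta(0.06)
  sw <- sweep_parameter(p, "beta", 0.06, y0 = eq_cep(p), t_end = 100)
  expect_identical(sw$class, "equilibrium")
  expect_lt(sw$I_max - sw$I_min, 1e-6)
})
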