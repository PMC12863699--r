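test_that("Matignon classification covers the cone geometry", {
  st <- classify_matignon(c(-0.5, -0.2, -0.5), alpha = 0.95)
  expect_identical(st$classification, "LAS")
  expect_equal(st$min_arg, pi)
  # complex pair with positive real part: stable below alpha*, unstable above
  eigs <- c(-1, complex(real = 0.3, imaginary = 2),
            complex(real = 0.3, imaginary = -2))
  a_star <- (2 / pi) * atan(2 / 0.3)
  expect_identical(classify_matignon(eigs, a_star - 0.05)$classification, "LAS")
  st_hi <- classify_matignon(eigs, min(1, a_star + 0.05))
  # the pair spirals into the cone: Hopf-type instability
  expect_identical(st_hi$classification, "unstable")
  expect_equal(st_hi$alpha_star, a_star, tolerance = 1e-12)
  # mixed-sign real spectrum is a saddle at any order
  expect_identical(classify_matignon(c(-1, 2, -3), 0.7)$classification,
                   "saddle")
  # an eigenvalue at the origin is marginal
  expect_identical(classify_matignon(c(0, -1, -2), 0.9)$classification,
                   "marginal")
})

test_that("alpha_star is reported exactly for the Hopf eigenvalue structure", {
  expect_true(is.na(classify_matignon(c(-1, -2, -3), 0.9)$alpha_star))
  expect_true(is.na(classify_matignon(c(1, complex(real = 0.3, imaginary = 1),
                                        complex(real = 0.3, imaginary = -1)),
                                      0.9)$alpha_star))
  st <- classify_matignon(c(-1, complex(real = 0.5, imaginary = 1),
                            complex(real = 0.5, imaginary = -1)), 0.9)
  expect_equal(st$alpha_star, (2 / pi) * atan(2), tolerance = 1e-12)
})

test_that("characteristic coefficients reproduce the spectrum of random matrices", {
  expect_equal(char_poly_coeffs(diag(3)), c(c1 = -3, c2 = 3, c3 = -1))
  expect_equal(char_poly_coeffs(matrix(0, 3, 3)), c(c1 = 0, c2 = 0, c3 = 0))
  set.seed(41)
  for (i in 1:50) {
    M <- matrix(rnorm(9), 3, 3)
    cc <- char_poly_coeffs(M)
    roots <- polyroot(c(cc[3], cc[2], cc[1], 1))
    ev <- eigen(M, only.values = TRUE)$values
    expect_lt(max(abs(sort(Re(roots)) - sort(Re(ev)))) +
                max(abs(sort(Im(roots)) - sort(Im(ev)))), 1e-8)
  }
})

test_that("fractional Routh-Hurwitz clauses behave as stated", {
  # (x+1)(x+2)(x+3): Delta > 0, c1 c2 = 66 > 6
  rh <- routh_hurwitz_fractional(6, 11, 6, alpha = 0.95)
  expect_identical(rh$condition_met, "i")
  expect_true(rh$stable)
  # discriminant identity re-evaluated independently
  with(rh, expect_equal(Delta,
                        18 * c1 * c2 * c3 + (c1 * c2)^2 - 4 * c3 * c1^3 -
                          4 * c2^3 - 27 * c3^2))
  # c3 < 0 means a positive real root: no stability clause can hold
  rh2 <- routh_hurwitz_fractional(1, 1, -2, alpha = 0.9)
  expect_false(isTRUE(rh2$stable))
  # clause (ii): complex pair, low order
  cc <- char_poly_coeffs(matrix(c(0, -2, 0, 2, 0, 0, 0, 0, -1), 3, 3,
                                byrow = TRUE))  # eigs +-2i, -1
  rh3 <- routh_hurwitz_fractional(cc[1], cc[2], cc[3], alpha = 0.5)
  expect_identical(rh3$condition_met, "ii")
})

test_that("stability survey matches the infection-rate narrative", {
  s04 <- stability_of_equilibria(p_beta(0.04))
  expect_identical(s04$pdpf$classification, "LAS")
  s52 <- stability_of_equilibria(p_beta(0.052))
  expect_identical(s52$pdpf$classification, "saddle")
  expect_identical(s52$pfp$classification, "LAS")
  s06 <- stability_of_equilibria(p_beta(0.06))
  expect_identical(s06$cep$classification, "LAS")
  s60 <- stability_of_equilibria(p_beta(0.6))
  expect_identical(s60$cep$classification, "unstable")
})

test_that("predator-invasion eigenvalue equals its closed form", {
  for (b in c(0.052, 0.055, 0.06)) {
    p <- p_beta(b)
    R0 <- basic_reproduction_number(p)
    st <- stability_of_equilibria(p)
    xi2 <- (R0 - 1) * p$Lambda / (p$delta * R0 + (R0 - 1) * p$Lambda * p$a)
    expect_equal(st$pfp$invasion_eigenvalue, xi2 * p$n - p$d,
                 tolerance = 1e-12)
    # it is an actual Jacobian eigenvalue
    expect_lt(min(abs(st$pfp$eigenvalues - st$pfp$invasion_eigenvalue)), 1e-10)
  }
})

test_that("Routh-Hurwitz and direct Matignon verdicts agree when both are decisive", {
  n_checked <- 0
  for (p in draw_params(500, seed = 51)) {
    cep <- eq_cep(p)
    if (is.null(cep)) next
    J <- model_jacobian(cep, p)
    st <- classify_matignon(eigen(J, only.values = TRUE)$values, p$alpha)
    cc <- char_poly_coeffs(J)
    rh <- routh_hurwitz_fractional(cc[1], cc[2], cc[3], p$alpha)
    if (is.na(rh$stable) || abs(st$margin) < 1e-6) next
    n_checked <- n_checked + 1
    if (rh$stable) expect_identical(st$classification, "LAS")
    else expect_identical(st$classification, "unstable")
  }
  expect_gt(n_checked, 30)
})

test_that("global PDPF sufficient condition evaluates its stated bounds", {
  p <- update_params(p_beta(0.04), k = 0)
  g <- global_pdpf_condition(p)
  expect_equal(g$S_tilde, 20)
  expect_equal(g$lower, 0)
  expect_equal(g$upper, (0.04 * 20 - 0.5) / (0.04 * 20), tolerance = 1e-12)
  # sufficient condition is not satisfied here (upper bound 0.375 < R0)
  expect_false(g$holds)
  # R0 >= 1 can never satisfy it: the upper bound is < 1
  expect_lt(global_pdpf_condition(p_beta(0.06))$upper, 1)
  expect_false(global_pdpf_condition(p_beta(0.06))$holds)
  # large fear level violates the lower bound
  p_k <- update_params(p_beta(0.04), k = 50)
  expect_gt(global_pdpf_condition(p_k)$lower,
            basic_reproduction_number(p_k))
  expect_false(global_pdpf_condition(p_k)$holds)
})

test_that("a satisfied PDPF condition predicts global convergence", {
  # low recovery, subcritical disease: condition holds
  p <- model_params(Lambda = 10, k = 0, mu = 0.5, beta = 0.025, omega = 0.1,
                    delta = 0.9, m = 4, a = 1, n = 1, d = 0.5, alpha = 0.95)
  g <- global_pdpf_condition(p)
  expect_true(g$holds)
  set.seed(61)
  for (i in 1:10) {
    tr <- simulate_model(p, y0 = runif(3, 0.1, 8), h = 0.01, t_end = 150)
    expect_lt(max(abs(tr$states[nrow(tr$states), ] - eq_pdpf(p))), 0.05)
  }
})

test_that("global PFP condition matches direct arithmetic and is monotone in k", {
  p <- update_params(p_beta(0.052), k = 0)
  g <- global_pfp_condition(p)
  expect_true(g$applicable)
  expect_equal(g$rhs, (1 / 4) * (4 * g$I_hat + 4), tolerance = 1e-6)
  expect_false(g$holds)  # 1.769 > d = 0.5
  # vanishing conversion rate: right-hand side collapses below d
  p_n <- update_params(p, n = 1e-6)
  expect_true(global_pfp_condition(p_n)$holds)
  # increasing fear only raises the right-hand side
  rhs_k <- vapply(c(0, 0.5, 1, 2), function(k)
    global_pfp_condition(update_params(p_beta(0.052), k = k))$rhs, numeric(1))
  expect_true(all(diff(rhs_k) > 0))
  expect_false(global_pfp_condition(p_beta(0.04))$applicable)
})

test_that("global CEP condition computes the Lyapunov gamma terms", {
  g <- global_cep_condition(p_default, gamma = 20)
  expect_true(g$applicable)
  expect_equal(g$gamma1, (0.5 + 1 + 1.5 * 20 - 0.5) / 2)  # 15.5 > 0
  kappa <- eq_cep(p_default)[["P"]]
  expect_equal(g$gamma3, (2 + 2 * kappa - 1) / 2, tolerance = 1e-9)
  expect_false(g$holds)
  # gamma1 is increasing in the region bound gamma
  g2 <- global_cep_condition(p_default, gamma = 40)
  expect_gt(g2$gamma1, g$gamma1)
  expect_error(global_cep_condition(p_default, gamma = 1), "at least")
  expect_false(global_cep_condition(p_beta(0.04))$applicable)
})
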