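test_that("next-generation decomposition: closed forms agree with numeric algebra", {
  set.seed(41)
  for (k in 1:500) {
    p <- random_params()
    S0 <- runif(1, 0, 100)
    ngm <- next_generation(p, S0)
    expect_lte(max(abs(ngm$K %*% ngm$K_inv - diag(3))), 1e-10)
    expect_equal(ngm$K_inv, ngm$K_inv_numeric, tolerance = 1e-10)
    tr <- sum(diag(ngm$F %*% ngm$K_inv_numeric))
    expect_equal(ngm$R0, tr, tolerance = 1e-12)
    expect_equal(ngm$R0, ngm$H, tolerance = 1e-12)
  }
})

test_that("R0 vanishes without relapse or susceptibles, and fig7 value is reproduced", {
  p <- fig7_params()
  p0 <- sitr_params(alpha = 0.3, gamma = 0.5, beta = 0, lam = 0.47,
                    b = 0.34, eta = 0.47, zeta = 0.16, mu1 = 0.9,
                    mu2 = 0.92, u1 = 0.04, u2 = 0.29)
  expect_identical(next_generation(p0, 15)$R0, 0)
  expect_identical(max(abs(next_generation(p0, 15)$F)), 0)
  expect_identical(next_generation(p, 0)$R0, 0)
  # frozen from exact-fraction evaluation of H (fig7, beta = 0.05, S0 = 15)
  expect_equal(next_generation(p, 15)$R0, 0.11528533638492655,
               tolerance = 1e-12)
  expect_equal(next_generation(p, 15)$G, 0.36456967213114755,
               tolerance = 1e-12)
  expect_error(next_generation(
    sitr_params(alpha = 0, gamma = 0.5, beta = 0.05, lam = 0, b = 0.34,
                eta = 0.47, zeta = 0.16, mu1 = 0.9, mu2 = 0.92, u1 = 0.04,
                u2 = 0.29), 15), "singular")
})

test_that("analytic Jacobian matches finite differences and the published entries", {
  set.seed(43)
  for (k in 1:25) {
    p <- random_params()
    st <- random_state(50)
    J <- sitr_jacobian(st, p)
    Jfd <- fd_jacobian(st, p)
    expect_equal(J, Jfd, tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(sum(diag(J)), sitr_divergence(st, p))
  }
  p <- fig7_params()
  J0 <- sitr_jacobian(free_equilibrium(15), p)
  expect_equal(J0["S", "T1"], -p$beta * p$eta * 15)
  expect_equal(J0["S", "N"], p$gamma)
  expect_equal(J0["N", "N"], p$gamma - p$alpha)
})

test_that("cubic coefficients match the characteristic polynomial of the infected block", {
  p <- fig7_params()
  co <- cubic_coefficients(p, 15)
  expect_identical(co[["a0"]], 1)
  expect_equal(co[["a1"]], 3 * p$alpha + p$lam + p$mu1 + p$mu2)
  # frozen exact-fraction values (fig7, S0 = 15)
  expect_equal(unname(co), c(1, 3.19, 3.2338465, 0.997321146),
               tolerance = 1e-12)
  # numeric oracle: eigenvalues of the (I, T1, T2) block at Q0
  set.seed(47)
  for (k in 1:50) {
    q <- random_params()
    S0 <- runif(1, 0, 30)
    coq <- cubic_coefficients(q, S0)
    ev <- eigen(sitr_jacobian(free_equilibrium(S0), q)[2:4, 2:4],
                only.values = TRUE)$values
    # elementary symmetric functions of the eigenvalues
    expect_equal(coq[["a1"]], -Re(sum(ev)), tolerance = 1e-8)
    expect_equal(coq[["a2"]],
                 Re(ev[1] * ev[2] + ev[1] * ev[3] + ev[2] * ev[3]),
                 tolerance = 1e-8)
    expect_equal(coq[["a3"]], -Re(prod(ev)), tolerance = 1e-8)
  }
  # beta = 0 closed form
  p0 <- sitr_params(alpha = 0.3, gamma = 0.5, beta = 0, lam = 0.47,
                    b = 0.34, eta = 0.47, zeta = 0.16, mu1 = 0.9,
                    mu2 = 0.92, u1 = 0.04, u2 = 0.29)
  co0 <- cubic_coefficients(p0, 15)
  al <- p0$alpha
  expect_equal(co0[["a2"]],
               (al + p0$lam) * (al + p0$mu1) +
                 (al + p0$mu2) * (p0$lam + al) +
                 (al + p0$mu1) * (al + p0$mu2))
  expect_equal(co0[["a3"]],
               (al + p0$mu1) * (al + p0$mu2) * (al + p0$lam))
})

test_that("Routh-Hurwitz boolean is equivalent to numeric root signs", {
  expect_true(routh_hurwitz(c(1, 3, 3, 1))$stable)
  expect_false(routh_hurwitz(c(1, 1, 1, 3))$stable)
  expect_error(routh_hurwitz(c(-1, 1, 1, 1)), "positive")
  rh <- routh_hurwitz(c(1, 2, 3, 4))
  expect_equal(rh$delta3, 4 * rh$delta2)
  set.seed(53)
  for (k in 1:1000) {
    co <- if (k %% 2) stable_cubic_coeffs() else
      c(1, runif(3, -3, 3))
    roots <- polyroot(rev(co))
    verdict <- routh_hurwitz(co)$stable
    expect_identical(verdict, all(Re(roots) < 0),
                     label = paste("cubic", paste(co, collapse = ",")))
  }
})

test_that("disease-free classification follows the sign of gamma - alpha under R0 < 1", {
  # fig7: gamma - alpha = 0.2 > 0, R0(S0=15) < 1
  st <- classify_free_equilibrium(fig7_params(), 15)
  expect_lt(st$R0, 1)
  expect_identical(st$classification, "STABLE_NOT_ASYMPTOTIC")
  # numeric eigenvalues include -alpha and gamma - alpha
  expect_lte(min(abs(st$eigenvalues - (-0.3))), 1e-8)
  expect_lte(min(abs(st$eigenvalues - 0.2)), 1e-8)
  # Delta identities
  co <- st$cubic_coeffs
  expect_equal(st$delta2, co[["a1"]] * co[["a2"]] - co[["a0"]] * co[["a3"]])
  expect_equal(st$delta3, co[["a3"]] * st$delta2)

  base <- list(alpha = 0.3, gamma = 0.3, beta = 0.05,
                              lam = 0.47, b = 0.34, eta = 0.47,
                              zeta = 0.16, mu1 = 0.9, mu2 = 0.92,
                              u1 = 0.04, u2 = 0.29)
  expect_identical(
    classify_free_equilibrium(do.call(sitr_params, base), 15)$classification,
    "UNSTABLE")
  base$gamma <- 0.1
  stc <- classify_free_equilibrium(do.call(sitr_params, base), 15)
  expect_identical(stc$classification, "ASYMPTOTICALLY_STABLE")
  expect_true(all(Re(stc$eigenvalues) <= 0))
  # R0 >= 1 gate: crank beta until R0 > 1
  base$gamma <- 0.5; base$beta <- 1
  big <- do.call(sitr_params, base)
  expect_gt(next_generation(big, 100)$R0, 1)
  expect_identical(classify_free_equilibrium(big, 100)$classification,
                   "NOT_APPLICABLE")
})

test_that("published sign claims a2, a3, Delta2 > 0 hold whenever R0 < 1", {
  set.seed(59)
  violations <- 0L
  for (k in 1:300) {
    p <- random_params()
    S0 <- runif(1, 0, 50)
    if (next_generation(p, S0)$R0 >= 1) next
    co <- cubic_coefficients(p, S0)
    if (!(co[["a2"]] > 0 && co[["a3"]] > 0 &&
          co[["a1"]] * co[["a2"]] - co[["a3"]] > 0))
      violations <- violations + 1L
  }
  expect_identical(violations, 0L)
})
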