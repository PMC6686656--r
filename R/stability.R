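#' Next-generation decomposition and basic reproduction number
#'
#' Linearizes the infected subsystem (I, T1, T2) at the disease-free
#' population (S = N = S0) and splits it into the "returning" matrix F,
#' which carries the relapse terms, and the "affected" matrix K, which
#' carries the transitions:
#' \deqn{F = \begin{pmatrix} 0 & \beta\eta S_0 & \beta\zeta S_0 \\
#'   0&0&0 \\ 0&0&0 \end{pmatrix}, \quad
#'   K = \begin{pmatrix} \alpha+\lambda & 0 & 0 \\
#'   -b\lambda & \alpha+\mu_1 & 0 \\
#'   -(1-b)\lambda & -(1-u_1)\mu_1 & \alpha+\mu_2 \end{pmatrix}.}
#' The basic reproduction number is \eqn{R_0 = \mathrm{Trace}(F K^{-1})},
#' which equals the closed-form scalar H.  Both the closed-form inverse of
#' the lower-triangular K and its numeric inverse are retained, so the
#' algebra is continuously cross-checked.
#'
#' @param params A [sitr_params()] object.
#' @param S0 Disease-free susceptible/total count (nonnegative).
#' @return An object of class `"sitr_ngm"`: list with `F`, `K`, `K_inv`
#'   (closed form), `K_inv_numeric`, `H`, `G`, `R0`.
#' @examples
#' ngm <- next_generation(scenario_preset("fig7")$params, S0 = 15)
#' ngm$R0
#' @export
next_generation <- function(params, S0) {
  stopifnot(inherits(params, "sitr_params"))
  if (!is.numeric(S0) || length(S0) != 1L || !is.finite(S0) || S0 < 0)
    stop("S0 must be a single nonnegative number", call. = FALSE)
  al <- params$alpha; be <- params$beta; lam <- params$lam; b <- params$b
  eta <- params$eta; ze <- params$zeta; mu1 <- params$mu1; mu2 <- params$mu2
  u1 <- params$u1

  d <- c(al + lam, al + mu1, al + mu2)
  if (any(d == 0))
    stop("affected matrix K is singular: ",
         paste(c("alpha+lambda", "alpha+mu1", "alpha+mu2")[d == 0],
               collapse = ", "), " = 0", call. = FALSE)

  Fm <- matrix(0, 3, 3, dimnames = rep(list(c("I", "T1", "T2")), 2))
  Fm[1, 2] <- be * eta * S0
  Fm[1, 3] <- be * ze * S0
  K <- matrix(c(al + lam, 0, 0,
                -b * lam, al + mu1, 0,
                -(1 - b) * lam, -(1 - u1) * mu1, al + mu2),
              3, 3, byrow = TRUE, dimnames = dimnames(Fm))
  # closed-form inverse of the lower-triangular K, as displayed
  Kinv <- matrix(0, 3, 3, dimnames = dimnames(Fm))
  Kinv[1, 1] <- 1 / (al + lam)
  Kinv[2, 1] <- b * lam / ((al + lam) * (al + mu1))
  Kinv[2, 2] <- 1 / (al + mu1)
  Kinv[3, 1] <- (b * lam * (1 - u1) * mu1 + (al + mu1) * lam * (1 - b)) /
    ((al + lam) * (al + mu1) * (al + mu2))
  Kinv[3, 2] <- (1 - u1) * mu1 / ((al + mu2) * (al + mu1))
  Kinv[3, 3] <- 1 / (al + mu2)

  H <- be * eta * S0 * b * lam / ((al + lam) * (al + mu1)) +
    be * ze * S0 * (b * lam * mu1 * (1 - u1) + (al + mu1) * lam * (1 - b)) /
    ((al + lam) * (al + mu1) * (al + mu2))
  G <- be * eta * S0 / (al + mu1) +
    be * ze * S0 * (1 - u1) * mu1 / ((al + mu1) * (al + mu2))

  structure(list(F = Fm, K = K, K_inv = Kinv, K_inv_numeric = solve(K),
                 H = H, G = G, R0 = H),
            class = "sitr_ngm")
}

#' @export
print.sitr_ngm <- function(x, ...) {
  cat(sprintf("Next-generation decomposition: R0 = %.6g (H = %.6g, G = %.6g)\n",
              x$R0, x$H, x$G))
  cat(sprintf("  check: trace(F K^-1) = %.6g\n",
              sum(diag(x$F %*% x$K_inv_numeric))))
  invisible(x)
}

#' Analytic Jacobian of the SIT1T2R field
#'
#' Partial derivatives of [sitr_rhs()] in the fixed row/column order
#' (S, I, T1, T2, N, R).  At the disease-free point this reproduces the
#' published linearization; at the endemic point it reproduces the
#' published community matrix A with \eqn{P^* = I^*} (rows/columns 1-5).
#'
#' @inheritParams sitr_rhs
#' @return A 6x6 numeric matrix with dimnames.
#' @examples
#' p <- scenario_preset("fig7")
#' sitr_jacobian(free_equilibrium(15), p$params)
#' @export
sitr_jacobian <- function(state, params) {
  state <- check_state(state)
  stopifnot(inherits(params, "sitr_params"))
  al <- params$alpha; ga <- params$gamma; be <- params$beta
  lam <- params$lam; b <- params$b; eta <- params$eta; ze <- params$zeta
  mu1 <- params$mu1; mu2 <- params$mu2; u1 <- params$u1; u2 <- params$u2
  S <- state[["S"]]; T1 <- state[["T1"]]; T2 <- state[["T2"]]
  force_S <- be * (eta * T1 + ze * T2)   # d(force)/dS
  J <- matrix(0, 6, 6, dimnames = rep(list(sitr_compartments), 2))
  J["S", ]  <- c(-al - force_S, 0, -be * eta * S, -be * ze * S, ga, 0)
  J["I", ]  <- c(force_S, -(lam + al), be * eta * S, be * ze * S, 0, 0)
  J["T1", ] <- c(0, lam * b, -(mu1 + al), 0, 0, 0)
  J["T2", ] <- c(0, (1 - b) * lam, (1 - u1) * mu1, -(mu2 + al), 0, 0)
  J["N", ]  <- c(0, 0, 0, -(1 - u2) * mu2, ga - al, 0)
  J["R", ]  <- c(0, 0, u1 * mu1, u2 * mu2, 0, -al)
  J
}

#' Characteristic-cubic coefficients at the disease-free point
#'
#' After factoring out the explicit eigenvalues \eqn{-\alpha} and
#' \eqn{\gamma-\alpha}, the remaining spectrum of the disease-free
#' linearization is governed by the cubic
#' \eqn{a_0\lambda^3 + a_1\lambda^2 + a_2\lambda + a_3 = 0} with
#' \eqn{a_0 = 1}, \eqn{a_1 = 3\alpha + \lambda + \mu_1 + \mu_2}, and the
#' published closed forms for \eqn{a_2} and \eqn{a_3}.  The cubic is also
#' the characteristic polynomial of the (I, T1, T2) block of
#' [sitr_jacobian()] at the free equilibrium, which serves as the numeric
#' cross-check in the tests.
#'
#' @inheritParams next_generation
#' @return Named numeric vector `c(a0, a1, a2, a3)`.
#' @export
cubic_coefficients <- function(params, S0) {
  stopifnot(inherits(params, "sitr_params"))
  al <- params$alpha; be <- params$beta; lam <- params$lam; b <- params$b
  eta <- params$eta; ze <- params$zeta; mu1 <- params$mu1; mu2 <- params$mu2
  u1 <- params$u1
  a1 <- (3 * al + mu2) + lam + mu1
  a2 <- -b * lam * be * eta * S0 + (al + lam) * (al + mu1) +
    (al + mu2) * (lam + al) + (al + mu1) * (al + mu2) -
    be * ze * S0 * (1 - b) * lam
  a3 <- -b * lam * be * eta * S0 * (al + mu2) -
    b * lam * be * S0 * ze * mu1 * (1 - u1) +
    (al + mu1) * (al + mu2) * (al + lam) -
    (al + mu1) * be * ze * S0 * (1 - b) * lam
  c(a0 = 1, a1 = a1, a2 = a2, a3 = a3)
}

#' Routh-Hurwitz test for a cubic
#'
#' For \eqn{a_0\lambda^3 + a_1\lambda^2 + a_2\lambda + a_3} with
#' \eqn{a_0 > 0}, computes the Hurwitz minors
#' \eqn{\Delta_2 = a_1 a_2 - a_0 a_3} and
#' \eqn{\Delta_3 = a_3 \Delta_2}, and declares all roots to have negative
#' real part iff \eqn{a_1 > 0}, \eqn{\Delta_2 > 0} and \eqn{\Delta_3 > 0}.
#'
#' @param coeffs Numeric vector `(a0, a1, a2, a3)`; `a0` must be positive.
#' @return List with `delta2`, `delta3`, `stable` (logical).
#' @examples
#' routh_hurwitz(c(1, 3, 3, 1))  # (x+1)^3: stable
#' @export
routh_hurwitz <- function(coeffs) {
  if (!is.numeric(coeffs) || length(coeffs) != 4L || any(!is.finite(coeffs)))
    stop("coeffs must be four finite numbers (a0, a1, a2, a3)", call. = FALSE)
  a0 <- coeffs[[1]]; a1 <- coeffs[[2]]; a2 <- coeffs[[3]]; a3 <- coeffs[[4]]
  if (a0 <= 0) stop("a0 must be positive", call. = FALSE)
  delta2 <- a1 * a2 - a0 * a3
  delta3 <- a3 * delta2
  list(delta2 = delta2, delta3 = delta3,
       stable = a1 > 0 && delta2 > 0 && delta3 > 0)
}

#' Classify the disease-free equilibrium
#'
#' Under the hypothesis \eqn{R_0 < 1} the three non-explicit eigenvalues
#' (roots of the cubic) all have negative real part by the Routh-Hurwitz
#' criterion, and the verdict is driven entirely by the sign of the
#' explicit eigenvalue \eqn{\gamma - \alpha}:
#' * \eqn{\gamma - \alpha > 0}: locally stable but not asymptotically
#'   stable (`"STABLE_NOT_ASYMPTOTIC"`) — arrivals outpace drop-outs;
#' * \eqn{\gamma - \alpha = 0}: unstable (`"UNSTABLE"`);
#' * \eqn{\gamma - \alpha < 0}: locally asymptotically stable
#'   (`"ASYMPTOTICALLY_STABLE"`).
#'
#' When \eqn{R_0 \ge 1} the rule does not apply and the classification is
#' `"NOT_APPLICABLE"`.  The sign comparison is exact (no epsilon):
#' parameters are user-specified literals.  Numeric eigenvalues of the
#' full 6x6 Jacobian are reported alongside so callers can audit the rule,
#' but they never override it.
#'
#' @inheritParams next_generation
#' @return An object of class `"sitr_stability"`: list with
#'   `classification`, `R0`, `jacobian`, `factored_roots` (the explicit
#'   eigenvalues \eqn{-\alpha} and \eqn{\gamma-\alpha}), `cubic_coeffs`,
#'   `delta2`, `delta3`, `eigenvalues` (6 complex values, ordered by
#'   decreasing real part, ties by imaginary part).
#' @examples
#' classify_free_equilibrium(scenario_preset("fig7")$params, S0 = 15)
#' @export
classify_free_equilibrium <- function(params, S0) {
  ngm <- next_generation(params, S0)
  co <- cubic_coefficients(params, S0)
  rh <- routh_hurwitz(co)
  J <- sitr_jacobian(free_equilibrium(S0), params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev), Im(ev))]
  d <- params$gamma - params$alpha
  cls <- if (ngm$R0 >= 1) "NOT_APPLICABLE"
  else if (d > 0) "STABLE_NOT_ASYMPTOTIC"
  else if (d == 0) "UNSTABLE"
  else "ASYMPTOTICALLY_STABLE"
  structure(list(classification = cls, R0 = ngm$R0, jacobian = J,
                 factored_roots = c(-params$alpha, d),
                 cubic_coeffs = co, delta2 = rh$delta2, delta3 = rh$delta3,
                 cubic_stable = rh$stable, eigenvalues = ev),
            class = "sitr_stability")
}

#' @export
print.sitr_stability <- function(x, ...) {
  cat("Disease-free equilibrium classification:", x$classification, "\n")
  cat(sprintf("  R0 = %.6g; explicit eigenvalues -alpha = %.4g, gamma-alpha = %.4g\n",
              x$R0, x$factored_roots[1], x$factored_roots[2]))
  cat(sprintf("  cubic a = (%s); Delta2 = %.6g, Delta3 = %.6g (Hurwitz: %s)\n",
              paste(signif(x$cubic_coeffs, 6), collapse = ", "),
              x$delta2, x$delta3, x$cubic_stable))
  cat("  numeric eigenvalues (Re):",
      paste(signif(Re(x$eigenvalues), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.sitr_stability <- function(x, ...) {
  data.frame(classification = x$classification, R0 = x$R0,
             root_minus_alpha = x$factored_roots[1],
             root_gamma_minus_alpha = x$factored_roots[2],
             a0 = x$cubic_coeffs[["a0"]], a1 = x$cubic_coeffs[["a1"]],
             a2 = x$cubic_coeffs[["a2"]], a3 = x$cubic_coeffs[["a3"]],
             delta2 = x$delta2, delta3 = x$delta3,
             cubic_stable = x$cubic_stable)
}
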