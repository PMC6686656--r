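#' Disease-free equilibrium
#'
#' The free equilibrium is the 5-tuple (S0, 0, 0, 0, S0) mapped into the
#' six-compartment state as S = N = S0 with I = T1 = T2 = R = 0 (the
#' recovered class is set to zero; the published 5-tuple's last entry is
#' read as N).  It is an exact fixed point of the field only when
#' \eqn{\gamma = \alpha}: otherwise `sitr_rhs()` leaves the residual
#' \eqn{(\gamma-\alpha) S_0} in the S and N components, which callers can
#' inspect directly.
#'
#' @param S0 Nonnegative susceptible/total count at the disease-free state.
#' @return A state vector (see [sitr_state()]).
#' @examples
#' free_equilibrium(15)
#' @export
free_equilibrium <- function(S0) {
  if (!is.numeric(S0) || length(S0) != 1L || !is.finite(S0) || S0 < 0)
    stop("S0 must be a single nonnegative number", call. = FALSE)
  sitr_state(S = S0, I = 0, T1 = 0, T2 = 0, N = S0, R = 0)
}

#' Closed-form endemic equilibrium
#'
#' Evaluates the published closed forms for the interior fixed point
#' \eqn{Q^* = (S^*, I^*, T_1^*, T_2^*, N^*)} literally:
#' \deqn{S^* = E\,T_1^*, \quad I^* = \frac{\alpha+\mu_1}{b\lambda} T_1^*,
#'   \quad T_2^* = L\,T_1^*,}
#' \deqn{T_1^* = \frac{(\alpha+\lambda)(\alpha+\mu_1)}
#'   {\lambda b\,\beta E(\eta + L\zeta)},}
#' with the intermediate scalars E and L as displayed (E's denominator
#' contains \eqn{\gamma-\alpha}, while N* divides by \eqn{\lambda-\alpha};
#' the tension between the two is deliberate — see Details).  The
#' recovered class, for which no closed form is published, is
#' reconstructed from \eqn{R' = 0} as
#' \eqn{R^* = (u_1\mu_1 T_1^* + u_2\mu_2 T_2^*)/\alpha}.
#'
#' @details The chain of published formulas is transcribed verbatim, typos
#' and all; no attempt is made to guess authorial intent.  Instead the
#' max-norm of [sitr_rhs()] at the reconstructed point is returned as
#' `residual_norm`, so any internal inconsistency of the closed forms is
#' measured rather than hidden.  (For the bundled scenarios the I, T1, T2
#' and R equations are satisfied exactly; nonzero residual concentrates in
#' the S and N equations.)  Use [solve_equilibrium()] as an independent
#' numeric root finder.
#'
#' Feasibility (the point lying in the open positive orthant) is the
#' verbatim pair of published conditions: \eqn{\lambda > \alpha} together
#' with
#' \eqn{\gamma\lambda(1-u_2)\mu_2(1-u_1)\mu_1 + (1-u_2)\mu_2(1-b)(\mu_1+\alpha)
#'  > (\lambda+\alpha)(\mu_1+\alpha)(\gamma-\alpha)(\mu_2+\alpha)}.
#'
#' @param params A [sitr_params()] object.
#' @return An object of class `"sitr_endemic"`: a list with elements
#'   `S_star`, `I_star`, `T1_star`, `T2_star`, `N_star`, `R_star`, `E`,
#'   `L`, `feasible`, `residual_norm`, and `state` (the 6-vector with N
#'   from the closed form).
#' @examples
#' eq <- endemic_equilibrium(scenario_preset("fig7")$params)
#' eq$residual_norm   # how far the printed formulas are from a true root
#' @export
endemic_equilibrium <- function(params) {
  stopifnot(inherits(params, "sitr_params"))
  al <- params$alpha; ga <- params$gamma; be <- params$beta
  lam <- params$lam; b <- params$b; eta <- params$eta; ze <- params$zeta
  mu1 <- params$mu1; mu2 <- params$mu2; u1 <- params$u1; u2 <- params$u2

  dens <- c("b" = b, "alpha+mu2" = al + mu2, "gamma-alpha" = ga - al,
            "lambda-alpha" = lam - al, "alpha" = al)
  bad <- names(dens)[dens == 0]
  if (length(bad))
    stop("endemic closed forms undefined: denominator(s) ",
         paste(bad, collapse = ", "), " vanish", call. = FALSE)

  L <- (b * (1 - u1) * mu1 + (1 - b) * (mu1 + al)) / (b * (mu2 + al))
  E <- (ga * lam * (1 - u2) * mu2 * (1 - u1) * mu1 +
          (1 - u2) * mu2 * (1 - b) * (mu1 + al) -
          (lam + al) * (mu1 + al) * (ga - al) * (mu2 + al)) /
    (lam * b * (ga - al) * (mu2 + al))
  denomT1 <- lam * b * (be * eta * E + be * E * L * ze)
  if (denomT1 == 0)
    stop("endemic closed forms undefined: denominator(s) ",
         "lambda*b*beta*E*(eta + L*zeta) vanish", call. = FALSE)

  T1s <- (al + lam) * (al + mu1) / denomT1
  Ss  <- E * T1s
  Is  <- (al + mu1) / (b * lam) * T1s
  T2s <- L * T1s
  Ns  <- (1 - u2) * mu2 * (b * (1 - u1) * mu1 + (1 - b) * (mu1 + al)) /
    ((lam - al) * b * (mu2 + al)) * T1s
  Rs  <- (u1 * mu1 * T1s + u2 * mu2 * T2s) / al

  feas <- (lam > al) &&
    (ga * lam * (1 - u2) * mu2 * (1 - u1) * mu1 +
       (1 - u2) * mu2 * (1 - b) * (mu1 + al) >
       (lam + al) * (mu1 + al) * (ga - al) * (mu2 + al))

  st <- c(S = Ss, I = Is, T1 = T1s, T2 = T2s, N = Ns, R = Rs)
  res <- max(abs(sitr_rhs(st, params)))
  structure(list(S_star = Ss, I_star = Is, T1_star = T1s, T2_star = T2s,
                 N_star = Ns, R_star = Rs, E = E, L = L,
                 feasible = feas, residual_norm = res, state = st),
            class = "sitr_endemic")
}

#' @export
print.sitr_endemic <- function(x, ...) {
  cat("Endemic equilibrium (closed form, as published):\n")
  print(round(x$state, 6))
  cat(sprintf("E = %.6g, L = %.6g\n", x$E, x$L))
  cat(sprintf("feasible: %s   max |rhs| residual: %.6g\n",
              x$feasible, x$residual_norm))
  invisible(x)
}

#' @export
as.data.frame.sitr_endemic <- function(x, ...) {
  data.frame(S_star = x$S_star, I_star = x$I_star, T1_star = x$T1_star,
             T2_star = x$T2_star, N_star = x$N_star, R_star = x$R_star,
             E = x$E, L = x$L, feasible = x$feasible,
             residual_norm = x$residual_norm)
}

#' Numeric equilibrium by damped Newton iteration
#'
#' Independent audit for the closed-form equilibria: finds a root of
#' [sitr_rhs()] from a supplied guess with Newton's method using the
#' analytic Jacobian, damping each step by successive halving (at most 50
#' halvings) until the residual norm does not increase.
#'
#' @param params A [sitr_params()] object.
#' @param guess Finite starting state (6-vector).
#' @param tol Relative convergence tolerance on the max-norm residual
#'   (scaled by `max(1, max |state|)`).
#' @param max_iter Maximum Newton iterations.
#' @return A list with `root` (state), `residual` (max-norm of the field
#'   there), `converged`, `iterations`.  A singular Jacobian or
#'   non-convergence is reported in the result (with the final iterate),
#'   not raised as an error.
#' @examples
#' p <- scenario_preset("fig7")
#' solve_equilibrium(p$params, guess = p$initial)
#' @export
solve_equilibrium <- function(params, guess, tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(params, "sitr_params"))
  x <- check_state(guess)
  fx <- sitr_rhs(x, params)
  singular <- FALSE
  it <- 0L
  scale <- function(x) max(1, max(abs(x)))
  while (it < max_iter && max(abs(fx)) > tol * scale(x)) {
    it <- it + 1L
    J <- sitr_jacobian(x, params)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) { singular <- TRUE; break }
    lam <- 1
    for (k in 0:50) {
      xn <- x + lam * step
      fn <- sitr_rhs(xn, params)
      if (all(is.finite(fn)) && max(abs(fn)) <= max(abs(fx))) break
      lam <- lam / 2
    }
    x <- xn; fx <- fn
  }
  converged <- !singular && max(abs(fx)) <= tol * scale(x)
  list(root = x, residual = max(abs(fx)), converged = converged,
       iterations = it, singular_jacobian = singular)
}
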