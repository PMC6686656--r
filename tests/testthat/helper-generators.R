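# Random-input generators and independent numeric oracles shared across
# the suite.  All property tests seed the RNG explicitly.

random_params <- function() {
  sitr_params(alpha = runif(1, 0.01, 1), gamma = runif(1, 0.01, 1),
              beta = runif(1, 0, 0.2), lam = runif(1, 0.01, 1),
              b = runif(1), eta = runif(1, 0.01, 1),
              zeta = runif(1, 0.01, 1), mu1 = runif(1, 0.01, 1),
              mu2 = runif(1, 0.01, 1), u1 = runif(1), u2 = runif(1))
}

# A state on the consistent manifold N = S + I + T1 + T2 + R, where the
# bookkeeping identity (and hence the conservation residual) is exact.
random_consistent_state <- function(scale = 100) {
  v <- runif(5, 0, scale)
  sitr_state(S = v[1], I = v[2], T1 = v[3], T2 = v[4], N = sum(v), R = v[5])
}

random_state <- function(scale = 100) {
  v <- runif(6, 0, scale)
  sitr_state(S = v[1], I = v[2], T1 = v[3], T2 = v[4], N = v[5], R = v[6])
}

# Central finite-difference Jacobian of the vector field.
fd_jacobian <- function(state, params, rel_step = 1e-6) {
  J <- matrix(0, 6, 6)
  for (j in 1:6) {
    h <- rel_step * max(1, abs(state[j]))
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (sitr_rhs(up, params) - sitr_rhs(dn, params)) / (2 * h)
  }
  J
}

# Monic cubic with prescribed roots: one real, one complex pair, all with
# negative real part -> Hurwitz-stable by construction.
stable_cubic_coeffs <- function() {
  r1 <- -runif(1, 0.05, 5)
  re <- -runif(1, 0.05, 5); im <- runif(1, 0, 5)
  # (x - r1)(x^2 - 2 re x + re^2 + im^2)
  c(1, -r1 - 2 * re, re^2 + im^2 + 2 * re * r1, -r1 * (re^2 + im^2))
}

# The published 5x5 qualitative pattern of the endemic community matrix,
# rebuilt here entry by entry so tests do not lean on the package copy.
pattern_B <- function() {
  matrix(c(-1,  0, -1, -1,  1,
            0, -1,  1,  1,  0,
            0,  1, -1,  0,  0,
            0,  1,  1, -1,  0,
            0,  0,  0, -1,  1), 5, 5, byrow = TRUE)
}

fig7_params <- function() scenario_preset("fig7")$params
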