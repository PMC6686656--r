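#' Model parameters for the SIT1T2R system
#'
#' Constructs and validates the eleven rate/fraction parameters of the
#' SIT1T2R compartmental model of infertility treatment under polycystic
#' ovary syndrome.  All rates are per unit time; `b`, `u1`, `u2` are
#' dimensionless fractions in \[0, 1\].
#'
#' @param alpha Drop-out ("death") rate: patients leaving the clinic
#'   without a result.
#' @param gamma Arrival ("birth") rate: new patients entering the clinic.
#' @param beta Relapse rate: return-to-treatment after abortion or ovarian
#'   hyperstimulation.
#' @param lam Treatment-assignment rate of diagnosed patients (the model's
#'   \eqn{\lambda}; spelled `lam` to avoid masking base R).
#' @param b Fraction of assigned patients routed to the drug arm
#'   (clomiphene citrate + gonadotropin); the remainder go to IVF.
#' @param eta Treatment speed of the drug arm (\eqn{\eta}).
#' @param zeta Treatment speed of the IVF arm (\eqn{\zeta}).
#' @param mu1 Recovery/progression rate of the drug arm (\eqn{\mu_1}).
#' @param mu2 Recovery rate of the IVF arm (\eqn{\mu_2}).
#' @param u1 Cure fraction of the drug arm; the complement progresses to IVF.
#' @param u2 Cure fraction of the IVF arm.
#'
#' @return An object of class `"sitr_params"`: a named list of the eleven
#'   validated parameters.
#' @examples
#' p <- sitr_params(alpha = 0.3, gamma = 0.5, beta = 0.05, lam = 0.47,
#'                  b = 0.34, eta = 0.47, zeta = 0.16, mu1 = 0.9,
#'                  mu2 = 0.92, u1 = 0.04, u2 = 0.29)
#' p
#' @seealso [sitr_state()], [sitr_rhs()], [scenario_preset()]
#' @export
sitr_params <- function(alpha, gamma, beta, lam, b, eta, zeta, mu1, mu2,
                        u1, u2) {
  p <- list(alpha = alpha, gamma = gamma, beta = beta, lam = lam, b = b,
            eta = eta, zeta = zeta, mu1 = mu1, mu2 = mu2, u1 = u1, u2 = u2)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be nonnegative (got ", v, ")",
           call. = FALSE)
  }
  for (nm in c("b", "u1", "u2"))
    if (p[[nm]] > 1)
      stop("fraction '", nm, "' must lie in [0, 1] (got ", p[[nm]], ")",
           call. = FALSE)
  structure(lapply(p, as.numeric), class = "sitr_params")
}

#' @export
print.sitr_params <- function(x, ...) {
  cat("SIT1T2R model parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
as.double.sitr_params <- function(x, ...) unlist(x)

# Fixed compartment ordering used throughout the package.
sitr_compartments <- c("S", "I", "T1", "T2", "N", "R")

#' A point in SIT1T2R compartment space
#'
#' Builds a named state vector in the fixed compartment order
#' (S, I, T1, T2, N, R).  Counts are treated as continuous; components must
#' be finite but may be negative (integration is never clipped, so states
#' produced by the solver can legitimately cross zero and are reported
#' as-is).
#'
#' @param S,I,T1,T2,N,R Compartment values: susceptible, patients,
#'   drug-treatment arm, IVF arm, total population, recovered.
#' @return A named numeric vector of length 6.
#' @examples
#' sitr_state(S = 15, I = 30, T1 = 27, T2 = 12, N = 104, R = 20)
#' @export
sitr_state <- function(S, I, T1, T2, N, R) {
  x <- c(S = S, I = I, T1 = T1, T2 = T2, N = N, R = R)
  check_state(x)
  x
}

check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 6L)
    stop("state must be a numeric vector of length 6 (S, I, T1, T2, N, R)",
         call. = FALSE)
  if (any(!is.finite(state)))
    stop("state has non-finite component(s): ",
         paste(sitr_compartments[!is.finite(state)], collapse = ", "),
         call. = FALSE)
  if (is.null(names(state))) names(state) <- sitr_compartments
  state
}

#' Check the bookkeeping identity N = S + I + T1 + T2 + R
#'
#' The total population N carries its own rate equation in the SIT1T2R
#' system even though it is defined as the sum of the five classes.  A
#' state is called consistent when \eqn{|N - (S+I+T1+T2+R)|} is at most
#' `tol`.  The identity is exact analytically, so the default tolerance
#' only allows for floating-point drift.
#'
#' @param state A state vector as from [sitr_state()].
#' @param tol Absolute tolerance; defaults to `1e-8 * max(1, N)`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' state_consistent(sitr_state(15, 30, 27, 12, 104, 20))  # 15+30+27+12+20 = 104
#' @export
state_consistent <- function(state, tol = NULL) {
  state <- check_state(state)
  if (is.null(tol)) tol <- 1e-8 * max(1, abs(state[["N"]]))
  abs(state[["N"]] - sum(state[c("S", "I", "T1", "T2", "R")])) <= tol
}
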