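#' SIT1T2R model object
#'
#' Bundles a parameter set, an initial state and a time grid into a single
#' model object, the package's central interface.  The object knows how to
#' print itself, report its coefficients ([coef()]), produce a full
#' analytic summary ([summary()]: reproduction number, disease-free
#' classification, endemic equilibrium and its residual, divergence),
#' integrate itself ([simulate()]) and plot the resulting trajectory
#' ([plot()]).
#'
#' @param params A [sitr_params()] object.
#' @param initial Initial state; defaults to the published initial
#'   compartments (15, 30, 27, 12, 104, 20).
#' @param grid A [time_grid()]; defaults to \[0, 25\] with M = 50.
#' @return An object of class `"sitr_model"`.
#' @examples
#' m <- sitr_model(scenario_preset("fig7")$params)
#' m
#' coef(m)
#' head(simulate(m))
#' summary(m)
#' @export
sitr_model <- function(params, initial = NULL, grid = NULL) {
  stopifnot(inherits(params, "sitr_params"))
  if (is.null(initial)) initial <- shared_initial()
  if (is.null(grid)) grid <- default_grid()
  stopifnot(inherits(grid, "time_grid"))
  structure(list(params = params, initial = check_state(initial),
                 grid = grid),
            class = "sitr_model")
}

#' @export
print.sitr_model <- function(x, ...) {
  cat("SIT1T2R compartmental model\n")
  cat("  parameters:", sprintf("%s=%g", names(x$params), unlist(x$params)),
      "\n")
  cat("  initial:   ", sprintf("%s=%g", names(x$initial), x$initial), "\n")
  cat(sprintf("  grid:       [%g, %g], M = %d\n",
              x$grid$t_start, x$grid$t_end, x$grid$M))
  ngm <- next_generation(x$params, S0 = x$initial[["S"]])
  cat(sprintf("  R0 (at S0 = %g): %.6g\n", x$initial[["S"]], ngm$R0))
  invisible(x)
}

#' @export
coef.sitr_model <- function(object, ...) unlist(object$params)

#' Simulate an SIT1T2R model
#'
#' Integrates the model on its grid with the fixed-step RK4 scheme.  The
#' system is deterministic, so `nsim` and `seed` are accepted for generic
#' compatibility but do not alter the result (`nsim > 1` returns a list
#' of identical trajectories).
#'
#' @param object An [sitr_model()].
#' @param nsim Number of trajectories.
#' @param seed Ignored (deterministic model); present for the generic.
#' @param ... Unused.
#' @return A trajectory data.frame (columns t, S, I, T1, T2, N, R), or a
#'   list of them when `nsim > 1`.
#' @export
simulate.sitr_model <- function(object, nsim = 1, seed = NULL, ...) {
  one <- function()
    as.data.frame(suppressWarnings(
      rk4_integrate(object$initial, object$grid, object$params)))
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @export
summary.sitr_model <- function(object, ...) {
  S0 <- object$initial[["S"]]
  structure(list(model = object,
                 ngm = next_generation(object$params, S0),
                 stability = classify_free_equilibrium(object$params, S0),
                 endemic = endemic_equilibrium(object$params),
                 divergence = sitr_divergence(object$initial,
                                              object$params),
                 trajectory_summary = summarize_trajectory(
                   suppressWarnings(rk4_integrate(object$initial,
                                                  object$grid,
                                                  object$params)))),
            class = "summary.sitr_model")
}

#' @export
print.summary.sitr_model <- function(x, ...) {
  print(x$model)
  cat("\n"); print(x$stability)
  cat("\n"); print(x$endemic)
  cat(sprintf("\nDivergence at the initial state: %.6g\n", x$divergence))
  cat("\nTrajectory summary:\n")
  print(x$trajectory_summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sitr_model <- function(x, ...) {
  plot(suppressWarnings(rk4_integrate(x$initial, x$grid, x$params)), ...)
  invisible(x)
}
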