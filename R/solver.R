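#' Uniform time grid
#'
#' @param t_start,t_end Interval endpoints (`t_end > t_start`).  Named to
#'   avoid any collision with the treatment fraction `b`.
#' @param M Number of steps (positive integer); the step is
#'   `h = (t_end - t_start) / M` and the grid has `M + 1` nodes.
#' @return An object of class `"time_grid"`: list with `t_start`, `t_end`,
#'   `M`, `h`, `times`.
#' @examples
#' time_grid(0, 25, 50)$h
#' @export
time_grid <- function(t_start = 0, t_end = 25, M = 50) {
  if (!is.numeric(t_start) || !is.numeric(t_end) || !is.finite(t_start) ||
      !is.finite(t_end) || t_end <= t_start)
    stop("need finite t_end > t_start", call. = FALSE)
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M))
    stop("M must be a positive integer", call. = FALSE)
  M <- as.integer(M)
  h <- (t_end - t_start) / M
  structure(list(t_start = t_start, t_end = t_end, M = M, h = h,
                 times = t_start + h * (0:M)),
            class = "time_grid")
}

#' One classical Runge-Kutta step
#'
#' Advances the full six-component state by one step of the classical
#' fourth-order scheme: stages
#' \eqn{K_1 = h f(t, w)}, \eqn{K_2 = h f(t + h/2, w + K_1/2)},
#' \eqn{K_3 = h f(t + h/2, w + K_2/2)}, \eqn{K_4 = h f(t + h, w + K_3)},
#' update \eqn{w + (K_1 + 2K_2 + 2K_3 + K_4)/6}.  All components advance
#' simultaneously (no per-component splitting); the field is autonomous so
#' `t` only documents position on the grid.
#'
#' @param state Current state.
#' @param t Current time.
#' @param h Step size (> 0).
#' @param params A [sitr_params()] object.
#' @return The state after one step.
#' @export
rk4_step <- function(state, t, h, params) {
  if (!is.numeric(h) || h <= 0) stop("h must be positive", call. = FALSE)
  w <- check_state(state)
  k1 <- h * sitr_rhs(w, params)
  if (any(!is.finite(k1))) stop("non-finite RK4 stage K1", call. = FALSE)
  k2 <- h * sitr_rhs(w + k1 / 2, params)
  if (any(!is.finite(k2))) stop("non-finite RK4 stage K2", call. = FALSE)
  k3 <- h * sitr_rhs(w + k2 / 2, params)
  if (any(!is.finite(k3))) stop("non-finite RK4 stage K3", call. = FALSE)
  k4 <- h * sitr_rhs(w + k3, params)
  if (any(!is.finite(k4))) stop("non-finite RK4 stage K4", call. = FALSE)
  w + (k1 + 2 * k2 + 2 * k3 + k4) / 6
}

#' Integrate the SIT1T2R system on a fixed grid
#'
#' Applies `M` sequential [rk4_step()]s.  Compartments crossing zero are
#' never clipped: the trajectory is returned as computed, and a warning
#' lists the first grid time at which each affected compartment turns
#' negative (silent projection would mask parameter or step-size
#' pathologies).  If a step produces a non-finite state the partial
#' trajectory up to the last finite node is returned with attribute
#' `error_index` and a warning.
#'
#' @param initial Initial state (finite 6-vector).
#' @param grid A [time_grid()].
#' @param params A [sitr_params()] object.
#' @return An object of class `"sitr_trajectory"`: list with `grid`,
#'   `params`, and `states`, an (M+1) x 6 matrix in time order whose first
#'   row is the initial state.
#' @examples
#' sc <- scenario_preset("fig7")
#' traj <- rk4_integrate(sc$initial, sc$grid, sc$params)
#' summary(traj)
#' @export
rk4_integrate <- function(initial, grid, params) {
  stopifnot(inherits(grid, "time_grid"))
  w <- check_state(initial)
  states <- matrix(NA_real_, grid$M + 1L, 6L,
                   dimnames = list(NULL, sitr_compartments))
  states[1L, ] <- w
  error_index <- NULL
  for (j in seq_len(grid$M)) {
    w <- tryCatch(rk4_step(w, grid$times[j], grid$h, params),
                  error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w))) { error_index <- j; break }
    states[j + 1L, ] <- w
  }
  if (!is.null(error_index)) {
    states <- states[seq_len(error_index), , drop = FALSE]
    warning("integration failed at step ", error_index,
            "; partial trajectory returned", call. = FALSE)
  }
  neg <- apply(states < 0, 2L, function(col) match(TRUE, col))
  if (any(!is.na(neg))) {
    hit <- which(!is.na(neg))
    warning("compartment(s) crossed zero: ",
            paste(sprintf("%s at t=%g", sitr_compartments[hit],
                          grid$times[neg[hit]]), collapse = ", "),
            call. = FALSE)
  }
  structure(list(grid = grid, params = params, states = states,
                 error_index = error_index),
            class = "sitr_trajectory")
}

#' @export
as.data.frame.sitr_trajectory <- function(x, ...) {
  data.frame(t = x$grid$times[seq_len(nrow(x$states))], x$states)
}

#' @export
print.sitr_trajectory <- function(x, ...) {
  cat(sprintf("SIT1T2R trajectory: %d nodes on [%g, %g], h = %g\n",
              nrow(x$states), x$grid$t_start, x$grid$t_end, x$grid$h))
  df <- as.data.frame(x)
  print(utils::head(df, 3))
  cat("  ...\n")
  print(utils::tail(df, 2))
  invisible(x)
}

#' Per-compartment trajectory summary
#'
#' For each compartment: the minimum value along the trajectory, the time
#' at which it is first attained (ties broken by first attainment), the
#' final value, and whether the compartment is rising over the trailing
#' 10% of the grid (strictly increasing across every node in that window
#' — the "incremental mode at the end of the cycle").
#'
#' @param traj A [sitr_trajectory][rk4_integrate()].
#' @return A data.frame with one row per compartment: `compartment`,
#'   `min`, `t_min`, `final`, `trailing_increase`.
#' @export
summarize_trajectory <- function(traj) {
  stopifnot(inherits(traj, "sitr_trajectory"))
  st <- traj$states
  times <- traj$grid$times[seq_len(nrow(st))]
  tail_from <- max(1L, nrow(st) - ceiling(0.1 * (nrow(st) - 1L)))
  out <- lapply(sitr_compartments, function(cn) {
    v <- st[, cn]
    j <- which.min(v)
    tail_v <- v[tail_from:length(v)]
    data.frame(compartment = cn, min = v[j], t_min = times[j],
               final = v[length(v)],
               trailing_increase = length(tail_v) >= 2 &&
                 all(diff(tail_v) > 0))
  })
  do.call(rbind, out)
}

#' @export
summary.sitr_trajectory <- function(object, ...) summarize_trajectory(object)

#' Plot a trajectory, one line per compartment
#'
#' Base-graphics line plot of all six compartments against time, the
#' layout used by the model's published figures.
#'
#' @param x A trajectory from [rk4_integrate()].
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sitr_trajectory <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::matplot(df$t, df[sitr_compartments], type = "l", lty = 1,
                    col = seq_len(6), xlab = "time", ylab = "count", ...)
  graphics::legend("topleft", legend = sitr_compartments, col = seq_len(6),
                   lty = 1, bty = "n")
  invisible(x)
}
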