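# Scenario presets and flat-YAML configuration handling.
#
# The three presets carry the parameter values of the model's published
# figure captions and the shared initial state (15, 30, 27, 12, 104, 20).
# Two quantities the captions never state are fixed package-wide and
# documented in the methods vignette: the relapse rate beta = 0.05 and
# the integration horizon [0, 25] with M = 50 steps.

scenario_schema_keys <- c("alpha", "gamma", "beta", "lam", "b", "eta",
                          "zeta", "mu1", "mu2", "u1", "u2",
                          "S0", "I0", "T1_0", "T2_0", "N0", "R0_init",
                          "t_start", "t_end", "M")

default_beta <- 0.05
default_grid <- function() time_grid(0, 25, 50)
shared_initial <- function()
  sitr_state(S = 15, I = 30, T1 = 27, T2 = 12, N = 104, R = 20)

preset_param_table <- list(
  fig7 = list(alpha = 0.3, gamma = 0.5, beta = default_beta, lam = 0.47,
              b = 0.34, eta = 0.47, zeta = 0.16, mu1 = 0.9, mu2 = 0.92,
              u1 = 0.04, u2 = 0.29),
  fig8 = list(alpha = 0.16, gamma = 0.23, beta = default_beta, lam = 0.47,
              b = 0.34, eta = 0.47, zeta = 0.16, mu1 = 0.9, mu2 = 0.92,
              u1 = 0.04, u2 = 0.29),
  fig9 = list(alpha = 0.16, gamma = 0.23, beta = default_beta, lam = 0.47,
              b = 0.34, eta = 0.47, zeta = 0.08, mu1 = 0.9, mu2 = 0.96,
              u1 = 0.04, u2 = 0.19))

preset_descriptions <- c(
  fig7 = "ages 20-25, ovarian reserve > 3.5",
  fig8 = "ages 25-30, ovarian reserve > 3.5 (alpha, gamma reduced)",
  fig9 = "ovarian reserve < 3.5 (IVF arm slower, lower cure fraction)")

#' Assemble a validated scenario
#'
#' A scenario bundles a parameter set, an initial state and a time grid.
#' The initial state must pass the bookkeeping consistency check
#' `N = S + I + T1 + T2 + R` (see [state_consistent()]) and be
#' componentwise nonnegative.
#'
#' @param name Identifier.
#' @param params A [sitr_params()] object.
#' @param initial Initial state (6-vector).
#' @param grid A [time_grid()].
#' @param description Free text.
#' @return An object of class `"sitr_scenario"`.
#' @export
scenario <- function(name, params, initial, grid = default_grid(),
                     description = "") {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(params, "sitr_params"), inherits(grid, "time_grid"))
  initial <- check_state(initial)
  if (any(initial < 0))
    stop("initial state must be nonnegative", call. = FALSE)
  if (!state_consistent(initial))
    stop("initial state inconsistent: N0 = ", initial[["N"]],
         " but S0+I0+T1_0+T2_0+R0 = ",
         sum(initial[c("S", "I", "T1", "T2", "R")]), call. = FALSE)
  structure(list(name = name, params = params, initial = initial,
                 grid = grid, description = description),
            class = "sitr_scenario")
}

#' @export
print.sitr_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s)\n", x$name, x$description))
  cat("  params: "); cat(sprintf("%s=%g", names(x$params), unlist(x$params)),
                         sep = " ")
  cat("\n  initial:", sprintf("%s=%g", names(x$initial), x$initial), "\n")
  cat(sprintf("  grid: [%g, %g], M = %d (h = %g)\n",
              x$grid$t_start, x$grid$t_end, x$grid$M, x$grid$h))
  invisible(x)
}

#' Built-in scenario presets
#'
#' Returns one of the three bundled scenarios, whose parameters reproduce
#' the published figure captions (`fig7`: alpha = 0.3, gamma = 0.5;
#' `fig8`: alpha = 0.16, gamma = 0.23; `fig9`: additionally zeta = 0.08,
#' mu2 = 0.96, u2 = 0.19), with the shared initial state
#' (15, 30, 27, 12, 104, 20) and the default grid \[0, 25\], M = 50.  The
#' relapse rate `beta = 0.05` is a package default: the captions omit it
#' (choice documented in the methods vignette).
#'
#' @param name One of `"fig7"`, `"fig8"`, `"fig9"`.
#' @return An `"sitr_scenario"`.
#' @examples
#' scenario_preset("fig8")
#' @export
scenario_preset <- function(name = c("fig7", "fig8", "fig9")) {
  name <- match.arg(name)
  scenario(name, do.call(sitr_params, preset_param_table[[name]]),
           shared_initial(), default_grid(),
           description = preset_descriptions[[name]])
}

#' Load a scenario from a preset name or a YAML config file
#'
#' A config file is a flat YAML document with exactly the keys
#' `alpha, gamma, beta, lam, b, eta, zeta, mu1, mu2, u1, u2` (parameters),
#' `S0, I0, T1_0, T2_0, N0, R0_init` (initial compartments; `R0_init`
#' names the initial recovered count, distinct from the reproduction
#' number), and `t_start, t_end, M` (grid), plus optional `name` and
#' `description`.  Missing or unknown keys, malformed values, out-of-range
#' fractions, or an inconsistent initial state are all rejected with the
#' offending key names.
#'
#' @param source A preset name (`"fig7"`, `"fig8"`, `"fig9"`) or a path to
#'   a config file.
#' @return An `"sitr_scenario"`.
#' @seealso [write_scenario()] for the inverse; round-tripping a preset
#'   through a file reproduces it exactly.
#' @export
load_scenario <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (source %in% names(preset_param_table)) return(scenario_preset(source))
  if (!file.exists(source))
    stop("'", source, "' is neither a preset name (",
         paste(names(preset_param_table), collapse = ", "),
         ") nor an existing config file", call. = FALSE)
  cfg <- yaml::read_yaml(source)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  extra <- setdiff(names(cfg), c(scenario_schema_keys, "name", "description"))
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(scenario_schema_keys, names(cfg))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- Filter(function(k) !is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L ||
                  !is.finite(cfg[[k]]), scenario_schema_keys)
  if (length(bad))
    stop("non-numeric config value(s) for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  params <- do.call(sitr_params, cfg[scenario_schema_keys[1:11]])
  initial <- sitr_state(S = cfg$S0, I = cfg$I0, T1 = cfg$T1_0,
                        T2 = cfg$T2_0, N = cfg$N0, R = cfg$R0_init)
  grid <- time_grid(cfg$t_start, cfg$t_end, cfg$M)
  scenario(if (is.null(cfg$name)) basename(source) else cfg$name,
           params, initial, grid,
           description = if (is.null(cfg$description)) "" else
             cfg$description)
}

#' Serialize a scenario to a YAML config file
#'
#' @param sc An `"sitr_scenario"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "sitr_scenario"))
  cfg <- c(list(name = sc$name, description = sc$description),
           lapply(unclass(sc$params), identity),
           list(S0 = sc$initial[["S"]], I0 = sc$initial[["I"]],
                T1_0 = sc$initial[["T1"]], T2_0 = sc$initial[["T2"]],
                N0 = sc$initial[["N"]], R0_init = sc$initial[["R"]],
                t_start = sc$grid$t_start, t_end = sc$grid$t_end,
                M = sc$grid$M))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 12, format = "g")

write_flat_kv <- function(x, path) {
  writeLines(sprintf("%s: %s", names(x),
                     vapply(x, function(v) paste(format(v), collapse = " "),
                            character(1))), path)
}

#' Run a full scenario report
#'
#' Produces, in one fresh directory: the RK4 trajectory
#' (`trajectory.csv`, 12 significant digits), its per-compartment summary
#' (`summary.csv`), the next-generation record (`r0.csv`, using S0 = the
#' scenario's initial S), the disease-free stability report
#' (`stability.csv` + `jacobian_q0.csv`), the sign-stability verdict of
#' the endemic community matrix (`signstab.csv`; evaluated at the numeric
#' equilibrium when the damped Newton audit converges to an interior
#' point, else at the closed-form equilibrium), and a flat key-value
#' `manifest.txt` embedding the full scenario, package version and
#' horizon.  A failing stage is recorded in the manifest and the
#' remaining stages are still attempted.  Outputs are deterministic:
#' two runs give byte-identical CSVs.
#'
#' @param sc An `"sitr_scenario"`.
#' @param out_dir Output directory; must not exist or be empty.
#' @param plot If `TRUE`, additionally writes `trajectory.pdf` (one line
#'   per compartment).
#' @return Invisibly, a list with the in-memory results and `errors`, a
#'   named character vector of stage failures (empty on full success).
#' @export
run_report <- function(sc, out_dir, plot = FALSE) {
  stopifnot(inherits(sc, "sitr_scenario"))
  if (dir.exists(out_dir) && length(list.files(out_dir, all.files = TRUE,
                                               no.. = TRUE)))
    stop("output directory '", out_dir, "' exists and is not empty",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- character(0)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  res$trajectory <- stage("trajectory", {
    traj <- suppressWarnings(rk4_integrate(sc$initial, sc$grid, sc$params))
    df <- as.data.frame(traj)
    df[] <- lapply(df, format_num)
    utils::write.csv(df, file.path(out_dir, "trajectory.csv"),
                     row.names = FALSE, quote = FALSE)
    traj
  })
  res$summary <- stage("summary", {
    sm <- summarize_trajectory(res$trajectory)
    sm$min <- format_num(sm$min); sm$final <- format_num(sm$final)
    utils::write.csv(sm, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    sm
  })
  res$ngm <- stage("r0", {
    ngm <- next_generation(sc$params, S0 = sc$initial[["S"]])
    utils::write.csv(data.frame(R0 = ngm$R0, H = ngm$H, G = ngm$G,
                                S0 = sc$initial[["S"]]),
                     file.path(out_dir, "r0.csv"), row.names = FALSE,
                     quote = FALSE)
    ngm
  })
  res$stability <- stage("stability", {
    st <- classify_free_equilibrium(sc$params, S0 = sc$initial[["S"]])
    utils::write.csv(as.data.frame(st), file.path(out_dir, "stability.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(st$jacobian),
                     file.path(out_dir, "jacobian_q0.csv"),
                     row.names = FALSE, quote = FALSE)
    st
  })
  res$signstab <- stage("signstab", {
    eq <- endemic_equilibrium(sc$params)
    nsol <- solve_equilibrium(sc$params, eq$state)
    at <- if (nsol$converged && all(nsol$root > 0)) nsol$root else eq$state
    J5 <- sitr_jacobian(at, sc$params)[1:5, 1:5]
    verdict <- is_sign_stable(J5, zero_tol = 1e-12 * max(abs(J5)))
    utils::write.csv(as.data.frame(verdict),
                     file.path(out_dir, "signstab.csv"),
                     row.names = FALSE)
    verdict
  })
  if (plot) stage("plot", {
    grDevices::pdf(file.path(out_dir, "trajectory.pdf"), width = 7,
                   height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(res$trajectory, main = sc$name)
  })

  manifest <- c(list(scenario = sc$name, description = sc$description),
                unclass(sc$params),
                as.list(stats::setNames(sc$initial,
                                        paste0("init_",
                                               names(sc$initial)))),
                list(t_start = sc$grid$t_start, t_end = sc$grid$t_end,
                     M = sc$grid$M,
                     package_version =
                       as.character(utils::packageVersion("pcosdyn")),
                     stages_failed = if (length(errors))
                       paste(names(errors), collapse = ",") else "none"))
  write_flat_kv(manifest, file.path(out_dir, "manifest.txt"))
  res$errors <- errors
  invisible(res)
}

#' Compare two scenarios
#'
#' Integrates both scenarios and reports, per compartment, the ratio of
#' trajectory minima (b over a) and of times-of-minimum, together with a
#' parameter-difference table.  If the grids differ, both scenarios are
#' re-integrated on the coarser grid (larger step) with a warning.
#'
#' @param a,b `"sitr_scenario"` objects.
#' @return A list with `minima` (data.frame: compartment, min_a, min_b,
#'   min_ratio, t_min_a, t_min_b, t_min_ratio) and `param_diff`
#'   (data.frame: param, a, b, ratio).
#' @examples
#' cmp <- compare_scenarios(scenario_preset("fig7"), scenario_preset("fig8"))
#' cmp$minima
#' @export
compare_scenarios <- function(a, b) {
  stopifnot(inherits(a, "sitr_scenario"), inherits(b, "sitr_scenario"))
  ga <- a$grid; gb <- b$grid
  if (!identical(unclass(ga)[c("t_start", "t_end", "M")],
                 unclass(gb)[c("t_start", "t_end", "M")])) {
    g <- if (ga$h >= gb$h) ga else gb
    warning("scenario grids differ; both rebinned to the coarser grid [",
            g$t_start, ", ", g$t_end, "], M = ", g$M, call. = FALSE)
    ga <- gb <- g
  }
  sa <- summarize_trajectory(
    suppressWarnings(rk4_integrate(a$initial, ga, a$params)))
  sb <- summarize_trajectory(
    suppressWarnings(rk4_integrate(b$initial, gb, b$params)))
  minima <- data.frame(compartment = sa$compartment,
                       min_a = sa$min, min_b = sb$min,
                       min_ratio = sb$min / sa$min,
                       t_min_a = sa$t_min, t_min_b = sb$t_min,
                       t_min_ratio = sb$t_min / sa$t_min)
  pa <- unlist(a$params); pb <- unlist(b$params)
  param_diff <- data.frame(param = names(pa), a = pa, b = pb,
                           ratio = pb / pa, row.names = NULL)
  list(minima = minima, param_diff = param_diff)
}
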