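test_that("presets carry the published caption values and initial state", {
  f7 <- scenario_preset("fig7")
  expect_equal(unlist(f7$params)[c("alpha", "gamma", "lam", "b", "eta",
                                   "zeta", "mu1", "mu2", "u1", "u2")],
               c(alpha = 0.3, gamma = 0.5, lam = 0.47, b = 0.34,
                 eta = 0.47, zeta = 0.16, mu1 = 0.9, mu2 = 0.92,
                 u1 = 0.04, u2 = 0.29))
  expect_equal(unname(f7$initial), c(15, 30, 27, 12, 104, 20))
  expect_equal(f7$grid$M, 50L)
  f8 <- scenario_preset("fig8")
  expect_equal(f8$params$alpha, 0.16)
  expect_equal(f8$params$gamma, 0.23)
  expect_equal(unlist(f8$params)[c("lam", "b", "eta", "zeta", "mu1",
                                   "mu2", "u1", "u2")],
               unlist(f7$params)[c("lam", "b", "eta", "zeta", "mu1",
                                   "mu2", "u1", "u2")])
  f9 <- scenario_preset("fig9")
  expect_equal(f9$params$zeta, 0.08)
  expect_equal(f9$params$mu2, 0.96)
  expect_equal(f9$params$u2, 0.19)
  expect_equal(f9$params$alpha, 0.16)
  # the three presets share the relapse rate default
  expect_equal(f7$params$beta, f9$params$beta)
  expect_true(state_consistent(f7$initial))
})

test_that("scenario config files round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".yml")
  sc <- scenario_preset("fig9")
  write_scenario(sc, path)
  back <- load_scenario(path)
  expect_equal(back$params, sc$params)
  expect_equal(back$initial, sc$initial)
  expect_equal(back$grid$times, sc$grid$times)
  expect_identical(back$name, sc$name)
})

test_that("malformed configs are rejected with offending keys", {
  dir <- withr::local_tempdir()
  n_cfg <- 0L
  write_cfg <- function(lines) {
    n_cfg <<- n_cfg + 1L
    path <- file.path(dir, sprintf("cfg%d.yml", n_cfg))
    writeLines(lines, path)
    path
  }
  base <- c("alpha: 0.3", "gamma: 0.5", "beta: 0.05", "lam: 0.47",
            "b: 0.34", "eta: 0.47", "zeta: 0.16", "mu1: 0.9", "mu2: 0.92",
            "u1: 0.04", "u2: 0.29", "S0: 15", "I0: 30", "T1_0: 27",
            "T2_0: 12", "N0: 104", "R0_init: 20", "t_start: 0",
            "t_end: 25", "M: 50")
  expect_s3_class(load_scenario(write_cfg(base)), "sitr_scenario")
  expect_error(load_scenario(write_cfg(c(base, "bogus_key: 1"))),
               "bogus_key")
  expect_error(load_scenario(write_cfg(base[-1])), "alpha")
  b_bad <- base; b_bad[5] <- "b: 1.3"
  expect_error(load_scenario(write_cfg(b_bad)), "\\[0, 1\\]")
  n_bad <- base; n_bad[16] <- "N0: 999"
  expect_error(load_scenario(write_cfg(n_bad)), "inconsistent")
  expect_error(load_scenario("no_such_preset"), "preset")
})

test_that("report bundles are complete, deterministic, and refuse dirty directories", {
  dir <- withr::local_tempdir()
  out1 <- file.path(dir, "a"); out2 <- file.path(dir, "b")
  res <- run_report(scenario_preset("fig8"), out1)
  expect_identical(res$errors, character(0))
  files <- c("trajectory.csv", "summary.csv", "r0.csv", "stability.csv",
             "jacobian_q0.csv", "signstab.csv", "manifest.txt")
  expect_true(all(file.exists(file.path(out1, files))))
  # fig8 has gamma > alpha: endemic community matrix not sign stable,
  # diagonal witness
  ss <- utils::read.csv(file.path(out1, "signstab.csv"))
  expect_false(ss$overall)
  expect_match(ss$witness, "\\(5,5\\)")
  # byte-identical rerun
  run_report(scenario_preset("fig8"), out2)
  for (f in files)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  # refuse non-empty target, leaving it untouched
  before <- list.files(out1)
  expect_error(run_report(scenario_preset("fig7"), out1), "not empty")
  expect_identical(list.files(out1), before)
  # manifest embeds the scenario
  mf <- readLines(file.path(out1, "manifest.txt"))
  expect_true(any(grepl("^alpha: 0.16$", mf)))
  expect_true(any(grepl("^t_end: 25$", mf)))
  expect_true(any(grepl("^stages_failed: none$", mf)))
})

test_that("comparing a scenario with itself gives unit ratios", {
  cmp <- compare_scenarios(scenario_preset("fig7"), scenario_preset("fig7"))
  expect_equal(cmp$minima$min_ratio, rep(1, 6))
  expect_equal(cmp$param_diff$ratio, rep(1, 11))
})

test_that("fig7 vs fig8 differ only in alpha and gamma", {
  cmp <- compare_scenarios(scenario_preset("fig7"), scenario_preset("fig8"))
  pd <- cmp$param_diff
  changed <- pd$param[pd$a != pd$b]
  expect_setequal(changed, c("alpha", "gamma"))
  expect_equal(pd$ratio[pd$param == "alpha"], 0.16 / 0.3)
  expect_equal(pd$ratio[pd$param == "gamma"], 0.23 / 0.5)
})

test_that("mismatched grids are rebinned to the coarser grid with a warning", {
  a <- scenario_preset("fig7")
  fine <- scenario("fig8fine", scenario_preset("fig8")$params,
                   scenario_preset("fig8")$initial, time_grid(0, 25, 200))
  expect_warning(cmp <- compare_scenarios(a, fine), "coarser")
  ref <- compare_scenarios(a, scenario_preset("fig8"))
  expect_equal(cmp$minima$min_ratio, ref$minima$min_ratio)
})

test_that("model object methods are coherent", {
  m <- sitr_model(fig7_params())
  expect_equal(coef(m), unlist(fig7_params()))
  traj <- simulate(m)
  expect_s3_class(traj, "data.frame")
  expect_equal(dim(traj), c(51L, 7L))
  expect_equal(traj$t[51], 25)
  sm <- summary(m)
  expect_s3_class(sm, "summary.sitr_model")
  expect_equal(sm$ngm$R0,
               next_generation(fig7_params(), 15)$R0)
  expect_identical(sm$stability$classification, "STABLE_NOT_ASYMPTOTIC")
  expect_output(print(m), "R0")
})
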