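test_that("run_study writes the full result bundle with the expected shapes", {
  out_dir <- withr::local_tempdir()
  res <- run_study(out_dir, grid = default_grid(), n_reps = 200L, seed = 5,
                   engine = "simulation")
  power <- readr::read_csv(file.path(out_dir, "power.csv"),
                           show_col_types = FALSE)
  expect_equal(nrow(power), 240L)
  tax <- readr::read_csv(file.path(out_dir, "taxonomy.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(tax), 60L)
  expect_true(all(c("relative_gain_pct", "category", "borderline") %in%
                    names(tax)))
  figs <- list.files(out_dir, pattern = "^power_curves_.*\\.png$")
  expect_equal(length(figs), 3L)
  log <- readLines(file.path(out_dir, "run_log.txt"))
  expect_true(any(grepl("seed: 5", log)))
  expect_true(any(grepl("design: fresh", log)))
  expect_true(any(grepl("n_reps: 200", log)))
})

test_that("the analytic engine fills the same schema without Monte Carlo
           columns", {
  out_dir <- withr::local_tempdir()
  grid <- scenario_grid(ns = c(50, 300), beta3s = c(0.14, 0.39),
                        pair_kinds = "cont_cont")
  res <- run_study(out_dir, grid = grid, engine = "analytic",
                   figures = FALSE)
  expect_true(all(is.na(res$power$mc_se)))
  expect_true(all(is.na(res$power$n_reject)))
  expect_equal(nrow(res$power), nrow(grid))
  expect_equal(nrow(res$taxonomy), 4L)
})

test_that("engine = both reports per-cell simulation/analytic differences", {
  out_dir <- withr::local_tempdir()
  grid <- scenario_grid(alphas = c(0.05, 0.20), ns = 300, beta3s = 0.39,
                        pair_kinds = "cont_cont")
  res <- run_study(out_dir, grid = grid, n_reps = 2000L, seed = 6,
                   engine = "both", figures = FALSE)
  expect_true("abs_diff_vs_analytic" %in% names(res$power))
  sim_rows <- res$power[res$power$engine == "simulation", ]
  # at n = 300 the simulated and analytic power agree within 4 mc_se
  expect_true(all(sim_rows$abs_diff_vs_analytic <
                    4 * pmax(sim_rows$mc_se, 1e-3)))
})

test_that("identical configurations give byte-identical tables", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  grid <- scenario_grid(alphas = c(0.05, 0.20), ns = 50, beta3s = 0.39)
  run_study(dir_a, grid = grid, n_reps = 300L, seed = 9, figures = FALSE)
  run_study(dir_b, grid = grid, n_reps = 300L, seed = 9, figures = FALSE)
  for (f in c("power.csv", "taxonomy.csv")) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)))
  }
})

test_that("power tables round-trip through CSV at full precision", {
  out_dir <- withr::local_tempdir()
  grid <- scenario_grid(alphas = c(0.05, 0.20), ns = 50, beta3s = 0.14,
                        pair_kinds = "dich_dich")
  res <- run_study(out_dir, grid = grid, n_reps = 700L, seed = 10,
                   figures = FALSE, engine = "simulation")
  back <- readr::read_csv(file.path(out_dir, "power.csv"),
                          show_col_types = FALSE)
  expect_equal(back$power, res$power$power, tolerance = 1e-12)
  expect_equal(back$mc_se, res$power$mc_se, tolerance = 1e-12)
})

test_that("power-curve plots are ggplot objects and validate their input", {
  pw <- analytic_power(default_grid())
  p <- plot_power_curves(pw, pair_kind = "cont_cont")
  expect_s3_class(p, "ggplot")
  expect_error(plot_power_curves(pw, pair_kind = "no_such_kind"), "no rows")
  expect_error(plot_power_curves(pw[, c("pair_kind", "n")]),
               "missing column")
  sim <- simulate_power(scenario_grid(alphas = c(0.05, 0.20), ns = 50,
                                      beta3s = 0.39), n_reps = 200, seed = 3)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(classify_gain(sim)), "ggplot")
})

test_that("the command-line front end runs against the installed package", {
  cli <- system.file("cli", "interpower", package = "interpower")
  expect_true(nzchar(cli))
  out <- suppressWarnings(system2(
    "Rscript",
    c(cli, "analytic", "--pair", "cd", "--n", "200", "--beta3", "0.39",
      "--alpha", "0.05"),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(out, "status")
  if (is.null(status)) status <- 0L
  expect_equal(status, 0L)
  csv <- readr::read_csv(I(paste(out, collapse = "\n")),
                         show_col_types = FALSE)
  expect_equal(csv$power, 0.7835, tolerance = 1e-3)
})
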