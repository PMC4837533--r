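test_that("selection-proportion grids are exact multiples of the step", {
  g <- tsp_grid()
  expect_length(g, 19L)
  expect_equal(g[c(1, 19)], c(0.05, 0.95))
  expect_true(all(abs(g * 400 - round(g * 400)) < 1e-9))
  expect_equal(spm_grid(0.9), c(0.9, 0.95, 1))
  expect_length(spm_grid(0.1), 19L)
  expect_true(all(spm_grid(0.35) >= 0.35))
  expect_error(spm_grid(0.12), "grid")
  expect_error(tsp_grid(0.03), "divide")
})

test_that("run_cell is deterministic in its root seed and degenerates sanely", {
  sc <- scenario(6)
  a <- run_cell(sc, "phenotype", tsp = 0.5, reps = 50, seed = 9)
  b <- run_cell(sc, "phenotype", tsp = 0.5, reps = 50, seed = 9)
  expect_identical(a$mean_gain, b$mean_gain)
  c <- run_cell(sc, "phenotype", tsp = 0.5, reps = 50, seed = 10)
  expect_false(identical(a$mean_gain, c$mean_gain))

  one <- run_cell(sc, "marker", tsp = 0.25, reps = 1, seed = 3)
  expect_equal(one$sd_gain, 0)
  expect_equal(one$ci_low, one$mean_gain)
  expect_equal(one$ci_high, one$mean_gain)

  zero <- run_cell(scenario(16), "marker", tsp = 0.25, reps = 5, seed = 3)
  expect_equal(zero$mean_gain, 20)
  expect_equal(zero$sd_gain, 0)
})

test_that("gain curves over a TSP grid equal isolated single-cell runs", {
  sc <- scenario(2)
  curve <- gains_over_tsp(sc, "marker", tsp = c(0.25, 0.5, 0.75),
                          dominance = "partial", reps = 40, seed = 21)
  for (p in c(0.25, 0.5, 0.75)) {
    single <- gains_over_tsp(sc, "marker", tsp = p, dominance = "partial",
                             reps = 40, seed = 21)
    expect_equal(curve$mean_gain[curve$tsp == p], single$mean_gain)
  }
  scan <- two_stage_scan(sc, 0.2, spm = c(0.25, 0.6), dominance = "partial",
                         reps = 40, seed = 21)
  single <- two_stage_scan(sc, 0.2, spm = 0.6, dominance = "partial",
                           reps = 40, seed = 21)
  expect_equal(scan$mean_gain[scan$spm == 0.6], single$mean_gain)
})

test_that("simulated means track the analytic predictions", {
  sc <- scenario(6)
  est <- run_cell(sc, "phenotype", tsp = 0.5, reps = 400, seed = 13)
  pred <- gain_phenotype_only(sc$H, sc$Vp, 0.5)
  expect_lt(abs(est$mean_gain - pred), 4 * est$sd_gain / sqrt(est$reps))

  mt <- marker_table(sc, "three", "none")
  estm <- run_cell(sc, "marker", tsp = 0.4, reps = 400, seed = 13)
  expect_lt(abs(estm$mean_gain - gain_marker_only(mt, 0.4)),
            4 * estm$sd_gain / sqrt(estm$reps))
})

test_that("derived-vs-simulated correlation behaves at its edge cases", {
  expect_equal(correlate_derived_simulated(1:5, 1:5), 1)
  expect_warning(r <- correlate_derived_simulated(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r))
  expect_error(correlate_derived_simulated(1:2, 1:2), "length")
  expect_error(correlate_derived_simulated(1:4, 1:5), "length")
})

test_that("the full experiment assembles consistent tables deterministically", {
  cfg <- seedgain_config(H_levels = c(0.2, 0.8), P_levels = 0.5, reps = 25,
                         populations = "three", dominance = "partial",
                         tsp_step = 0.25, spm_step = 0.25, seed = 31)
  ex <- full_experiment(cfg)
  expect_s3_class(ex, "seedgain_experiment")
  # 2 scenarios x (3 single strategies x 3 TSP + two-stage scans of 4+3+2 cells)
  expect_equal(nrow(ex$gains_simulated), 2 * (9 + 9))
  expect_equal(nrow(ex$gains_derived), 2 * 4 * 3)
  expect_equal(nrow(ex$two_stage_optima), 2 * 3)
  expect_equal(nrow(ex$correlations), 2 * 4)
  expect_true(all(ex$two_stage_optima$spm_sim >= ex$two_stage_optima$tsp))
  expect_true(all(!is.na(ex$two_stage_optima$gain_derived)))

  ex2 <- full_experiment(cfg)
  expect_identical(ex$gains_simulated, ex2$gains_simulated)

  dir <- withr::local_tempdir()
  write_experiment(ex, dir)
  expect_setequal(list.files(dir),
                  c("scenario_effects.csv", "gains_simulated.csv",
                    "gains_derived.csv", "two_stage_optima.csv",
                    "correlations.csv"))
  back <- readr::read_csv(file.path(dir, "gains_simulated.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(ex$gains_simulated))
  expect_equal(back$mean_gain, ex$gains_simulated$mean_gain)

  g <- glance(ex)
  expect_equal(g$n_cells, nrow(ex$gains_simulated))
  expect_equal(nrow(tidy(ex)), nrow(ex$gains_simulated))
})
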