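test_that("selection intensity matches the truncated-normal integral", {
  p <- c(0.05, 0.1, 0.25, 0.5, 0.9, 1)
  expect_equal(selection_intensity(p), selection_intensity_oracle(p),
               tolerance = 1e-8)
  expect_equal(selection_intensity(1), 0)
  expect_true(all(diff(selection_intensity(tsp_grid())) < 0))
  expect_error(selection_intensity(0), "p")
})

test_that("phenotype-only prediction composes H, intensity and sd(P)", {
  expect_equal(gain_phenotype_only(0.5, 200, 1), 0)
  expect_equal(gain_phenotype_only(0.5, 200, 0.5),
               0.5 * selection_intensity_oracle(0.5) * sqrt(200))
  expect_equal(gain_phenotype_only(1, 200, 0.05),
               selection_intensity_oracle(0.05) * sqrt(200),
               tolerance = 1e-8) # ~29.2
})

test_that("exact marker-only gain enumerates fractional class truncation", {
  mt <- three_genotype_table(4, "none")
  expect_equal(gain_marker_only(mt, 0.25), 4)
  expect_equal(gain_marker_only(mt, 0.75), 4 / 3) # (.25*4 + .5*0)/.75
  expect_equal(gain_marker_only(mt, 1), 0)
  # flat while the boundary stays inside the top class
  expect_equal(gain_marker_only(mt, c(0.05, 0.1, 0.2, 0.25)), rep(4, 4))
})

test_that("the normal approximation improves with more marker classes", {
  Vm <- 50
  mt3 <- three_genotype_table(derive_a3(Vm, 0), "none")
  mt9 <- nine_genotype_table(derive_a9(Vm))
  approx <- gain_marker_only_normal(Vm, 0.5)
  expect_lt(abs(gain_marker_only(mt9, 0.5) - approx),
            abs(gain_marker_only(mt3, 0.5) - approx))
  expect_equal(gain_marker_only_normal(Vm, 1), 0)
})

test_that("marker-distribution truncation renormalises and tracks moments", {
  mt <- three_genotype_table(4, "none")
  t25 <- attr(truncate_marker_table(mt, 0.25), "truncation")
  expect_equal(t25$mean, 4)
  expect_equal(t25$variance, 0)
  tr <- truncate_marker_table(mt, 0.75)
  expect_equal(sum(tr$freq), 1)
  t75 <- attr(tr, "truncation")
  expect_equal(t75$mean, 4 / 3)
  expect_equal(t75$variance, 2 * 16 / 9) # two-class enumeration
  t1 <- attr(truncate_marker_table(mt, 1), "truncation")
  expect_equal(t1$mean, marker_table_moments(mt)$mean)
  expect_equal(t1$variance, marker_table_moments(mt)$variance)
})

test_that("two-stage prediction hits its documented endpoints", {
  sc <- scenario(6)
  mt <- marker_table(sc, "three", "partial")
  expect_equal(gain_two_stage(mt, sc$Vb, sc$Ve, 0.2, 1),
               gain_phenotype_only(sc$H, sc$Vp, 0.2))
  expect_equal(gain_two_stage(mt, sc$Vb, sc$Ve, 0.2, 0.2),
               gain_marker_only(mt, 0.2))
  expect_error(gain_two_stage(mt, sc$Vb, sc$Ve, 0.5, 0.25), "spm")
})

test_that("the derived two-stage optimum for scenario 2 at TSP 0.1 is SP_M 0.25", {
  sc <- scenario(2)
  mt <- marker_table(sc, "three", "partial")
  opt <- optimal_two_stage(mt, sc$Vb, sc$Ve, 0.1)
  expect_equal(opt$spm_opt, 0.25)
})

test_that("two-stage optimum ties resolve to the largest SP_M", {
  # zero marker variance: every SP_M gives the phenotype-only gain
  mt <- three_genotype_table(0, "none")
  opt <- optimal_two_stage(mt, 50, 50, 0.2)
  expect_equal(opt$spm_opt, 1)
  expect_equal(opt$gain, gain_phenotype_only(0.5, 100, 0.2))
})

test_that("index prediction reduces to its limiting strategies", {
  expect_equal(gain_index(0.5, 0, 200, 0.2), gain_phenotype_only(0.5, 200, 0.2))
  expect_equal(gain_index(0.5, 1, 200, 0.2),
               gain_marker_only_normal(0.5 * 200, 0.2))
  expect_equal(gain_index(1, 1, 200, 0.2),
               selection_intensity(0.2) * sqrt(200))
  # composed value at H = 0.5, P = 0.8, TSP = 0.05
  br <- 0.8 / 0.5 + (1 - 0.8)^2 / (1 - 0.5 * 0.8)
  expect_equal(gain_index(0.5, 0.8, 200, 0.05),
               0.5 * selection_intensity_oracle(0.05) * sqrt(200) * sqrt(br),
               tolerance = 1e-8)
})

test_that("derived gains respect the dominance orderings of the theory", {
  grid <- tidyr::expand_grid(H = c(0.2, 0.5, 0.8, 1), P = c(0.2, 0.5, 0.8, 1),
                             tsp = c(0.05, 0.25, 0.5, 0.9))
  for (r in seq_len(nrow(grid))) {
    H <- grid$H[r]; P <- grid$P[r]; tsp <- grid$tsp[r]
    gi <- gain_index(H, P, 200, tsp)
    expect_gte(gi + 1e-9, gain_phenotype_only(H, 200, tsp))
    expect_gte(gi + 1e-9, gain_marker_only_normal(P * H * 200, tsp))
  }
  # all derived gains non-increasing in TSP
  sc <- scenario(7)
  der <- derived_gains(sc, "three", "partial")
  for (st in unique(der$strategy)) {
    expect_true(all(diff(der$gain[der$strategy == st]) <= 1e-9))
  }
  # the grid optimum dominates both endpoint strategies
  mt <- marker_table(sc, "three", "partial")
  for (tsp in c(0.1, 0.25, 0.5)) {
    opt <- optimal_two_stage(mt, sc$Vb, sc$Ve, tsp)
    expect_gte(opt$gain + 1e-9, gain_phenotype_only(sc$H, sc$Vp, tsp))
    expect_gte(opt$gain + 1e-9, gain_marker_only(mt, tsp))
  }
})
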