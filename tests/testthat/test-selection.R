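make_pop <- function(i, population = "three", dominance = "none", seed = 5) {
  sc <- scenario(i)
  simulate_population(marker_table(sc, population, dominance), sc,
                      n = 400, seed = seed)
}

test_that("selecting everything yields zero gain for every strategy", {
  pop <- make_pop(6)
  expect_equal(attr(select_phenotype(pop, 1), "selection")$delta_g, 0)
  expect_equal(attr(select_marker(pop, 1), "selection")$delta_g, 0)
  expect_equal(attr(select_two_stage(pop, 1, 1), "selection")$delta_g, 0)
  expect_equal(attr(select_index(pop, 1), "selection")$delta_g, 0)
})

test_that("retained counts follow round(tsp * n), including stage one", {
  pop <- make_pop(6)
  expect_equal(nrow(select_phenotype(pop, 0.25)), 100L)
  expect_equal(nrow(select_marker(pop, 0.3)), 120L)
  res <- select_two_stage(pop, 0.1, 0.5)
  expect_equal(nrow(res), 40L)
  expect_error(select_phenotype(pop, 0), "proportion")
  expect_error(select_phenotype(pop, 1.2), "proportion")
  expect_error(select_two_stage(pop, 0.5, 0.25), "spm")
})

test_that("zero-noise selection recovers the best marker class exactly", {
  pop <- make_pop(16) # Vb = Ve = 0, a3 = 20, class means 45/25/5
  for (res in list(select_phenotype(pop, 0.25), select_marker(pop, 0.25),
                   select_two_stage(pop, 0.25, 0.5),
                   select_index(pop, 0.25))) {
    expect_equal(sort(unique(res$genotype)), "MM")
    expect_equal(attr(res, "selection")$delta_g, 20)
  }
})

test_that("realized gain matches its definition", {
  pop <- make_pop(6)
  expect_equal(realized_gain(pop, pop$id), 0)
  best <- pop$id[which.max(pop$g)]
  expect_equal(realized_gain(pop, best), max(pop$g) - mean(pop$g))
  sel <- select_marker(pop, 0.25)
  expect_equal(realized_gain(pop, sel), attr(sel, "selection")$delta_g)
  expect_error(realized_gain(pop, integer(0)), "empty")
  expect_error(realized_gain(pop, 9999L), "ids")
})

test_that("index weights follow (1/H - 1)/(1 - P) with documented limits", {
  expect_equal(index_weights(0.2, 0.5)$b_m, 8)
  expect_equal(index_weights(1, 0.3)$b_m, 0)
  expect_equal(index_weights(0.5, 1)$b_m, Inf)
  expect_error(index_weights(0, 0.5), "H")
})

test_that("marker-only selection thins only the boundary class at random", {
  pop <- make_pop(2, dominance = "partial") # MM best, boundary inside MM at tsp 0.1
  set.seed(1)
  res <- select_marker(pop, 0.1)
  expect_equal(unique(res$genotype), "MM")
  # at tsp = 0.5 all MM survive and Mm is thinned
  set.seed(1)
  res2 <- select_marker(pop, 0.5)
  expect_equal(sum(res2$genotype == "MM"), 100L)
  expect_equal(sum(res2$genotype == "Mm"), 100L)
})

test_that("degenerate strategy settings collapse to their simpler strategy", {
  pop <- make_pop(6, dominance = "partial")
  # SP_M = 1 makes stage one vacuous: same retained set as phenotype-only
  ph <- select_phenotype(pop, 0.2)
  ts <- select_two_stage(pop, 0.2, 1)
  expect_setequal(ts$id, ph$id)
  # SP_M = TSP makes stage two vacuous: marker-only in distribution; here we
  # check the retained class composition, which thinning cannot change
  set.seed(2)
  mk <- select_marker(pop, 0.25)
  set.seed(2)
  ts2 <- select_two_stage(pop, 0.25, 0.25)
  expect_equal(table(ts2$genotype), table(mk$genotype))
  # H = 1 index reduces to phenotype-only
  ix <- select_index(pop, 0.2, H = 1, P = 0.5)
  expect_setequal(ix$id, ph$id)
  # P = 1 index ranks by marker class first
  ix2 <- select_index(pop, 0.25, H = 0.5, P = 1)
  expect_equal(unique(ix2$genotype), "MM")
})

test_that("tidy() summarises a selection in one row", {
  pop <- make_pop(6)
  out <- tidy(select_two_stage(pop, 0.1, 0.5))
  expect_equal(out$strategy, "two_stage")
  expect_equal(out$tsp, 0.1)
  expect_equal(out$spm, 0.5)
  expect_equal(out$n_selected, 40L)
})
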