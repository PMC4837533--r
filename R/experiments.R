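# Replication engine: repeated simulation of selection cells, confidence
# intervals, TSP/SP_M grids, and derived-vs-simulated comparisons.
#
# Seeding: a cell run with root seed s draws one replicate seed per
# replicate from a stream seeded with s. Replicate seeds depend only on
# (s, replicate), never on the cell's scenario, strategy or grid position,
# so runs sharing a root seed share simulated populations replicate by
# replicate (common random numbers). Paired comparisons between strategies,
# scenarios or grid points are therefore differences on the same
# populations, which is also how curves over TSP or SP_M are computed:
# within a replicate, one population and one selection ranking serve every
# grid point (nested truncation). Each cell's marginal distribution is
# identical to an isolated run with the same root seed.

#' Total-selection-proportion grid
#'
#' The 19 proportions 0.05, 0.10, ..., 0.95, generated as integer
#' multiples of the step to avoid floating-point drift.
#'
#' @param step Grid step; must divide 1 evenly.
#' @return A numeric vector of proportions (the default has length 19).
#' @export
tsp_grid <- function(step = 0.05) {
  m <- check_grid_step(step)
  (seq_len(m - 1L)) * step
}

#' First-stage-proportion grid for two-stage selection
#'
#' All proportions from `tsp` to 1 in steps of `step`; `tsp` must itself
#' lie on the grid.
#'
#' @param tsp Total selection proportion, on the `step` grid.
#' @inheritParams tsp_grid
#' @return A numeric vector from `tsp` to 1.
#' @export
spm_grid <- function(tsp, step = 0.05) {
  m <- check_grid_step(step)
  i <- round(tsp / step)
  if (abs(tsp - i * step) > 1e-9 || i < 1 || i > m) {
    abort(sprintf("`tsp` = %s is not on the %s grid.", format(tsp), format(step)))
  }
  (i:m) * step
}

check_grid_step <- function(step) {
  m <- round(1 / step)
  if (!is.numeric(step) || length(step) != 1L || step <= 0 ||
      abs(1 - m * step) > 1e-9) {
    abort("`step` must divide 1 evenly (e.g. 0.05).")
  }
  as.integer(m)
}

#' Replicated simulation of one selection cell
#'
#' Simulates `reps` independent populations for one scenario, applies one
#' selection strategy at one (`tsp`, `spm`) setting, and summarises the
#' realized genetic gains: mean, s.d., and the 95% confidence interval
#' `mean +/- 1.96 s/sqrt(reps)`.
#'
#' @param scenario A one-row scenario tibble (see [trait_scenarios()]).
#' @param strategy One of `"phenotype"`, `"marker"`, `"two_stage"`,
#'   `"index"`.
#' @param tsp Total selection proportion, in (0, 1].
#' @param spm First-stage proportion (two-stage only), in \[`tsp`, 1\].
#' @param population,dominance Passed to [marker_table()].
#' @param n Population size (default 400).
#' @param reps Number of replicates (default 1000).
#' @param seed Root seed for the cell.
#'
#' @return A one-row `gain_estimate` tibble: scenario identifiers, cell
#'   settings, `mean_gain`, `sd_gain`, `ci_low`, `ci_high`, `reps`, `seed`.
#' @examples
#' sc <- trait_scenarios()[6, ]
#' run_cell(sc, "phenotype", tsp = 0.5, reps = 100, seed = 1)
#' @export
run_cell <- function(scenario, strategy = c("phenotype", "marker", "two_stage", "index"),
                     tsp, spm = NULL,
                     population = c("three", "nine"), dominance = "none",
                     n = 400, reps = 1000, seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "two_stage") {
    if (is.null(spm)) abort("`spm` is required for two-stage selection.")
    rows <- two_stage_scan(scenario, tsp, spm = spm, population = population,
                           dominance = dominance, n = n, reps = reps, seed = seed)
    return(rows)
  }
  gains_over_tsp(scenario, strategy, tsp = tsp, population = population,
                 dominance = dominance, n = n, reps = reps, seed = seed)
}

#' Simulated gain curves over a TSP grid
#'
#' Runs `reps` replicates for one scenario and single-stage strategy and
#' evaluates every total selection proportion in `tsp` on the same
#' replicate populations (nested truncation along one selection ranking
#' per replicate).
#'
#' @inheritParams run_cell
#' @param tsp Vector of total selection proportions, each in (0, 1].
#'
#' @return A `gain_estimate` tibble with one row per `tsp` value.
#' @examples
#' sc <- trait_scenarios()[1, ]
#' gains_over_tsp(sc, "marker", tsp = c(0.25, 0.5), reps = 100, seed = 1)
#' @export
gains_over_tsp <- function(scenario, strategy = c("phenotype", "marker", "index"),
                           tsp = tsp_grid(),
                           population = c("three", "nine"), dominance = "none",
                           n = 400, reps = 1000, seed = 1L) {
  strategy <- match.arg(strategy)
  scenario <- scenario_row(scenario)
  population <- match.arg(population)
  mt <- marker_table(scenario, population, dominance)
  ks <- vapply(tsp, retained_count, integer(1), n = n)
  b_m <- if (strategy == "index") index_weights(scenario$H, scenario$P)$b_m else 0
  gains <- sim_gain_curves(mt, scenario, strategy, ks, b_m, n, reps, seed)
  cell_summary(scenario, population, dominance, strategy,
               tsp, NA_real_, gains, n, reps, seed)
}

#' Simulated two-stage gains over an SP_M grid
#'
#' Runs `reps` replicates for one scenario at a fixed total selection
#' proportion and evaluates every first-stage proportion in `spm` on the
#' same replicate populations (one marker ranking per replicate; the
#' first-stage survivor sets are nested across the grid).
#'
#' @inheritParams run_cell
#' @param spm Vector of first-stage proportions, each in \[`tsp`, 1\].
#'
#' @return A `gain_estimate` tibble with one row per `spm` value.
#' @export
two_stage_scan <- function(scenario, tsp, spm = spm_grid(tsp),
                           population = c("three", "nine"), dominance = "none",
                           n = 400, reps = 1000, seed = 1L) {
  scenario <- scenario_row(scenario)
  population <- match.arg(population)
  mt <- marker_table(scenario, population, dominance)
  k <- retained_count(tsp, n)
  for (s in spm) check_spm(s, tsp)
  k1s <- pmax(vapply(spm, retained_count, integer(1), n = n, name = "spm"), k)
  gains <- sim_two_stage_curves(mt, scenario, k, k1s, n, reps, seed)
  cell_summary(scenario, population, dominance, "two_stage",
               tsp, spm, gains, n, reps, seed)
}

#' Pearson correlation between derived and simulated gain curves
#'
#' Quantifies the closeness of closed-form predictions and simulated mean
#' gains over a common TSP grid. For two-stage selection the paired inputs
#' should be the per-TSP optimal gains.
#'
#' @param derived,simulated Paired numeric vectors of equal length (at
#'   least 3).
#'
#' @return The Pearson product-moment correlation, or `NA` (with a
#'   warning) if either vector has zero variance.
#' @export
correlate_derived_simulated <- function(derived, simulated) {
  if (length(derived) != length(simulated) || length(derived) < 3L) {
    abort("`derived` and `simulated` must be paired vectors of length >= 3.")
  }
  if (sd(derived) == 0 || sd(simulated) == 0) {
    warning("correlation undefined: a gain vector has zero variance",
            call. = FALSE)
    return(NA_real_)
  }
  cor(derived, simulated)
}

# ---- internal simulation core -------------------------------------------

replicate_seeds <- function(seed, reps) {
  set.seed(seed)
  sample.int(2147483646L, reps)
}

# simulate gains for a single-stage strategy at several retained counts ks,
# sharing one population and one ranking per replicate; returns reps x
# length(ks) matrix of realized gains
sim_gain_curves <- function(mt, scenario, strategy, ks, b_m, n, reps, seed) {
  counts <- class_counts(mt, n)
  gm <- rep(mt$value, counts)
  sB <- sqrt(scenario$Vb)
  sE <- sqrt(scenario$Ve)
  need_z <- strategy != "marker"
  seeds <- replicate_seeds(seed, reps)
  out <- matrix(0, nrow = reps, ncol = length(ks))
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    g <- gm + rnorm(n, 0, sB)
    z <- if (need_z) g + rnorm(n, 0, sE) else NULL
    ord <- rank_candidates(strategy, gm, z, b_m = b_m)
    cg <- cumsum(g[ord])
    out[r, ] <- cg[ks] / ks - mean(g)
  }
  out
}

# two-stage gains at several first-stage counts k1s with final count k,
# sharing one population and one marker ranking per replicate
sim_two_stage_curves <- function(mt, scenario, k, k1s, n, reps, seed) {
  counts <- class_counts(mt, n)
  gm <- rep(mt$value, counts)
  sB <- sqrt(scenario$Vb)
  sE <- sqrt(scenario$Ve)
  seeds <- replicate_seeds(seed, reps)
  out <- matrix(0, nrow = reps, ncol = length(k1s))
  ksq <- seq_len(k)
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    g <- gm + rnorm(n, 0, sB)
    z <- g + rnorm(n, 0, sE)
    mrank <- order(gm, runif(n), decreasing = TRUE)
    gbar <- mean(g)
    for (j in seq_along(k1s)) {
      s1 <- mrank[seq_len(k1s[j])]
      sel <- s1[rank_values(z[s1])[ksq]]
      out[r, j] <- mean(g[sel]) - gbar
    }
  }
  out
}

# summarise a reps x cells gain matrix into gain_estimate rows
cell_summary <- function(scenario, population, dominance, strategy,
                         tsp, spm, gains, n, reps, seed) {
  mean_gain <- colMeans(gains)
  sd_gain <- if (reps > 1) apply(gains, 2, sd) else rep(0, ncol(gains))
  half <- 1.96 * sd_gain / sqrt(reps)
  scenario_id <- if ("scenario" %in% names(scenario)) scenario$scenario else NA_integer_
  H <- scenario$H
  P <- scenario$P
  out <- tibble(
    scenario = scenario_id,
    H = H, P = P,
    population = population,
    dominance = if (population == "three") dominance else NA_character_,
    strategy = strategy,
    tsp = if (length(tsp) == ncol(gains)) tsp else rep(tsp, ncol(gains)),
    spm = if (length(spm) == ncol(gains)) spm else rep(spm, ncol(gains)),
    mean_gain = mean_gain, sd_gain = sd_gain,
    ci_low = mean_gain - half, ci_high = mean_gain + half,
    n = n, reps = reps, seed = seed
  )
  structure(out, class = c("gain_estimate", class(out)))
}

#' @method tidy gain_estimate
#' @export
tidy.gain_estimate <- function(x, ...) as_tibble(unclass_tbl(x))
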