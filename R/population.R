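#' Simulate a seedling population
#'
#' Builds a population of `n` single-clone seedlings for one trait-test
#' scenario. Genotype classes are assigned as exact fixed counts
#' (`n * freq` per class, e.g. 100/200/100 at `n = 400` for the
#' three-genotype population), not multinomial draws; only the background
#' genotypic effect `g_b ~ N(0, Vb)` and the environmental effect
#' `e ~ N(0, Ve)` are stochastic. Per seedling,
#' `g = g_m + g_b` and `z = g + e` hold exactly, with the marker effect
#' `g_m` equal to the zero point (25) plus the class mean.
#'
#' @param table A `marker_table` (see [marker_table()]).
#' @param scenario A one-row scenario tibble supplying `Vb` and `Ve`.
#' @param n Population size; `n * freq` must be an integer for every class.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A `seedling_population`: tibble with columns `id`, `genotype`,
#'   `g_m`, `g_b`, `e`, `g`, `z` and attributes `scenario`, `marker_table`,
#'   `n`, `seed`.
#' @examples
#' sc <- trait_scenarios()[6, ]
#' pop <- simulate_population(marker_table(sc, "three"), sc, n = 400, seed = 1)
#' population_moments(pop)
#' @export
simulate_population <- function(table, scenario, n = 400, seed = NULL) {
  scenario <- scenario_row(scenario)
  counts <- class_counts(table, n)
  if (!is.null(seed)) set.seed(seed)
  g_m <- attr(table, "zero_point") %||% ZERO_POINT
  g_m <- g_m + rep(table$value, counts)
  g_b <- rnorm(n, 0, sqrt(scenario$Vb))
  e <- rnorm(n, 0, sqrt(scenario$Ve))
  g <- g_m + g_b
  pop <- tibble(
    id = seq_len(n),
    genotype = rep(table$genotype, counts),
    g_m = g_m, g_b = g_b, e = e, g = g, z = g + e
  )
  structure(pop,
    scenario = scenario, marker_table = table, n = n, seed = seed,
    class = c("seedling_population", class(pop))
  )
}

# exact per-class counts; errors on the first non-integral class
class_counts <- function(table, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a single positive population size.")
  }
  raw <- table$freq * n
  counts <- round(raw)
  bad <- which(abs(raw - counts) > 1e-9)
  if (length(bad)) {
    abort(sprintf(
      "Population size %s gives a non-integer count for genotype class %s (%s x %s = %s).",
      format(n), table$genotype[bad[1]], format(n),
      format(table$freq[bad[1]]), format(raw[bad[1]])
    ))
  }
  as.integer(counts)
}

#' Moments of a seedling population
#'
#' Arithmetic means and variances of the genotypic (`g`) and phenotypic
#' (`z`) values. Variances use the population convention (divide by `n`),
#' so that enumerated zero-noise populations match their marker-table
#' variance exactly.
#'
#' @param pop A `seedling_population` (or any data frame with `g` and `z`).
#'
#' @return A one-row tibble: `mean_g`, `var_g`, `mean_z`, `var_z`.
#' @export
population_moments <- function(pop) {
  if (!is.data.frame(pop) || nrow(pop) == 0L) {
    abort("`pop` must be a non-empty population data frame.")
  }
  pvar <- function(x) mean((x - mean(x))^2)
  tibble(
    mean_g = mean(pop$g), var_g = pvar(pop$g),
    mean_z = mean(pop$z), var_z = pvar(pop$z)
  )
}

#' @method glance seedling_population
#' @export
glance.seedling_population <- function(x, ...) {
  sc <- attr(x, "scenario")
  bind_cols(
    tibble(n = nrow(x), H = sc$H, P = sc$P),
    population_moments(x)
  )
}

#' @export
print.seedling_population <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf(
    "Seedling population: n = %d, H = %.2g, P = %.2g, Vp = %.4g\n",
    nrow(x), sc$H, sc$P, sc$Vp
  ))
  print(as_tibble(unclass_tbl(x)), ...)
  invisible(x)
}
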