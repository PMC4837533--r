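# Discrete marker-genotype distributions.
#
# A marker table is a tibble (genotype, freq, value) where `value` is the
# class mean genotypic value on the adjusted scale, i.e. after subtracting
# the zero point (25). The zero point cancels in every gain computation and
# is added back only when phenotypes are materialised.

ZERO_POINT <- 25

# nine-genotype population: two unlinked loci, M (major: 2a, a, -2a) and
# T (minor: a, 0, -a), with epistatic overrides for MMTt (3a instead of 2a)
# and mmTT (-2.5a instead of -a).
NINE_LABELS <- c("MMTT", "MMTt", "MMtt", "MmTT", "MmTt", "Mmtt",
                 "mmTT", "mmTt", "mmtt")
NINE_FREQ <- c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16
NINE_UNIT <- c(3, 3, 1, 2, 1, 0, -2.5, -2, -3)

# weighted variance of the nine class means at a9 = 1
nine_unit_variance <- function() {
  sum(NINE_FREQ * NINE_UNIT^2) - sum(NINE_FREQ * NINE_UNIT)^2
}

dominance_ratio <- function(dominance) {
  switch(match.arg(dominance, c("none", "partial", "complete")),
    none = 0, partial = 0.5, complete = 1
  )
}

#' Allele-effect scalar for the three-genotype population
#'
#' Solves for the additive effect `a3` such that a single biallelic locus with
#' genotype frequencies 1/4 (MM), 1/2 (Mm), 1/4 (mm) and class means `a3`,
#' `d3`, `-a3` has weighted variance equal to the marker variance `Vm`:
#' \deqn{a_3 = \sqrt{4 V_M / (2 + (d_3/a_3)^2)}.}
#'
#' @param Vm Marker-explained genotypic variance, non-negative. Vectorised.
#' @param ratio Dominance ratio `d3/a3`: 0 (no dominance), 0.5 (partial) or
#'   1 (complete). Any non-negative value is accepted.
#'
#' @return `a3` in trait units.
#' @examples
#' derive_a3(8, 0)     # 4
#' derive_a3(200, 1)   # 16.33
#' @export
derive_a3 <- function(Vm, ratio = 0) {
  check_variance(Vm, "Vm")
  if (!is.numeric(ratio) || any(ratio < 0)) {
    abort("`ratio` (d3/a3) must be non-negative.")
  }
  sqrt(4 * Vm / (2 + ratio^2))
}

#' Allele-effect scalar for the nine-genotype population
#'
#' The nine-genotype class means are fixed multiples of a single scalar `a9`
#' (see [nine_genotype_table()]), so their weighted variance is `c * a9^2`
#' with `c` the enumerated weighted variance of the unit means
#' (`c = 3.6708984375`). `a9` is defined as the positive scalar matching the
#' marker variance: `a9 = sqrt(Vm / c)`.
#'
#' @param Vm Marker-explained genotypic variance, non-negative. Vectorised.
#'
#' @return `a9` in trait units.
#' @examples
#' derive_a9(8)    # 1.48
#' derive_a9(200)  # 7.38
#' @export
derive_a9 <- function(Vm) {
  check_variance(Vm, "Vm")
  sqrt(Vm / nine_unit_variance())
}

check_variance <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be a non-negative, finite variance.", name))
  }
  invisible(x)
}

new_marker_table <- function(df, population, dominance, effect) {
  structure(
    as_tibble(df),
    population = population,
    dominance = dominance,
    effect_scalar = effect,
    zero_point = ZERO_POINT,
    class = c("marker_table", class(as_tibble(df)))
  )
}

#' Three-genotype marker table
#'
#' One biallelic trait locus completely linked to its marker. Genotypes MM,
#' Mm, mm segregate 1:2:1 with class means `a3`, `d3`, `-a3` on the adjusted
#' scale, where `d3` is 0, `a3/2` or `a3` for no, partial, or complete
#' dominance. The table mean is `d3/2` (population mean `25 + d3/2` on the
#' observed scale).
#'
#' @param a3 Additive effect, non-negative (trait units).
#' @param dominance `"none"`, `"partial"` or `"complete"`.
#'
#' @return A `marker_table`: tibble with columns `genotype`, `freq`, `value`
#'   and attributes `population`, `dominance`, `effect_scalar`, `zero_point`.
#' @examples
#' three_genotype_table(4, "none")
#' @export
three_genotype_table <- function(a3, dominance = c("none", "partial", "complete")) {
  dominance <- match.arg(dominance)
  if (!is.numeric(a3) || length(a3) != 1L || !is.finite(a3) || a3 < 0) {
    abort("`a3` must be a single non-negative effect.")
  }
  d3 <- dominance_ratio(dominance) * a3
  new_marker_table(
    tibble(
      genotype = c("MM", "Mm", "mm"),
      freq = c(0.25, 0.5, 0.25),
      value = c(a3, d3, -a3)
    ),
    population = "three", dominance = dominance, effect = a3
  )
}

#' Nine-genotype (epistatic) marker table
#'
#' Two unlinked trait loci, each completely linked to a marker: locus M with
#' major effect (2, 1, -2 times `a9` for MM, Mm, mm) and locus T with minor
#' effect (1, 0, -1 times `a9`), with epistatic overrides for MMTt (3`a9`)
#' and mmTT (-2.5`a9`). Frequencies follow independent 1:2:1 segregation at
#' the two loci. The table mean is `17 a9 / 32`.
#'
#' @param a9 Effect scalar, non-negative (trait units).
#'
#' @return A `marker_table` with nine classes.
#' @examples
#' nine_genotype_table(1)
#' @export
nine_genotype_table <- function(a9) {
  if (!is.numeric(a9) || length(a9) != 1L || !is.finite(a9) || a9 < 0) {
    abort("`a9` must be a single non-negative effect.")
  }
  new_marker_table(
    tibble(genotype = NINE_LABELS, freq = NINE_FREQ, value = NINE_UNIT * a9),
    population = "nine", dominance = NA_character_, effect = a9
  )
}

#' Marker table for a trait-test scenario
#'
#' Derives the allele-effect scalar from the scenario's marker variance and
#' builds the corresponding genotype table, so that the table's weighted
#' variance equals the scenario's `Vm` exactly.
#'
#' @param scenario A one-row scenario tibble (see [trait_scenarios()]).
#' @param population `"three"` (single locus, with dominance) or `"nine"`
#'   (two epistatic loci).
#' @param dominance Dominance case for the three-genotype population; ignored
#'   for `"nine"`.
#'
#' @return A `marker_table`.
#' @examples
#' sc <- trait_scenarios()[6, ]
#' marker_table(sc, "three", "partial")
#' @export
marker_table <- function(scenario, population = c("three", "nine"),
                         dominance = c("none", "partial", "complete")) {
  scenario <- scenario_row(scenario)
  population <- match.arg(population)
  if (population == "three") {
    dominance <- match.arg(dominance)
    three_genotype_table(derive_a3(scenario$Vm, dominance_ratio(dominance)),
                         dominance)
  } else {
    nine_genotype_table(derive_a9(scenario$Vm))
  }
}

#' Weighted moments of a marker table
#'
#' Frequency-weighted mean and variance of the class means on the adjusted
#' scale. For a table built from a scenario, the variance equals the
#' scenario's `Vm` and the mean equals `d3/2` (three-genotype) or `17 a9/32`
#' (nine-genotype).
#'
#' @param table A `marker_table` (any tibble with `freq` and `value` columns).
#'
#' @return A one-row tibble with columns `mean` and `variance`.
#' @examples
#' marker_table_moments(three_genotype_table(4))
#' @export
marker_table_moments <- function(table) {
  f <- table$freq
  v <- table$value
  m <- sum(f * v)
  tibble(mean = m, variance = sum(f * v^2) - m^2)
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf(
    "Marker-genotype table (%s-genotype%s), effect scalar %.4g, zero point %d\n",
    attr(x, "population"),
    if (!is.na(attr(x, "dominance"))) paste0(", dominance: ", attr(x, "dominance")) else "",
    attr(x, "effect_scalar"), attr(x, "zero_point")
  ))
  print(as_tibble(unclass_tbl(x)), ...)
  invisible(x)
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("marker_table", "seedling_population",
                                  "selection_result", "gain_estimate"))
  x
}
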