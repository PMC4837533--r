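# Closed-form genetic-gain predictions. Truncation selection on a standard
# normal underlies the phenotype-based formulas; marker-based formulas use
# exact enumeration over the discrete marker-class distribution, with
# fractional thinning of the boundary class (unbiased, since thinning a
# class uniformly at random leaves its mean unchanged). All predictions are
# infinite-population expectations; the finite-n simulation discretises the
# boundary class to whole seedlings.

#' Truncation selection intensity
#'
#' Mean deviation, in standard-deviation units, of the retained upper tail
#' of a standard normal distribution when a proportion `p` is retained:
#' `i(p) = phi(Phi^-1(1 - p)) / p`. Decreasing in `p`, with `i(1) = 0`.
#'
#' @param p Selection proportion(s), each in (0, 1].
#'
#' @return Selection intensity (unitless), vectorised over `p`.
#' @examples
#' selection_intensity(c(0.05, 0.5, 1))
#' @export
selection_intensity <- function(p) {
  check_proportion(p, "p")
  ifelse(p == 1, 0, dnorm(qnorm(1 - p)) / p)
}

#' Predicted gain from phenotype-only selection
#'
#' Truncated-normal prediction `delta_g = H * i(tsp) * sqrt(Vp)`, valid to
#' the extent that the phenotype is approximately normal (for strongly
#' marker-structured scenarios the phenotype is a mixture and the
#' prediction degrades; see the package vignette).
#'
#' @param H Broad-sense heritability, in (0, 1].
#' @param Vp Phenotypic variance.
#' @param tsp Total selection proportion(s), each in (0, 1].
#'
#' @return Predicted gain (trait units), vectorised over `tsp`.
#' @examples
#' gain_phenotype_only(0.5, 200, 0.5)
#' @export
gain_phenotype_only <- function(H, Vp, tsp) {
  check_proportion(H, "H")
  check_variance(Vp, "Vp")
  H * selection_intensity(tsp) * sqrt(Vp)
}

#' Exact predicted gain from marker-only selection
#'
#' Enumerates truncation of the discrete marker-class distribution: classes
#' are taken from the best mean downward and the boundary class is thinned
#' fractionally to retain exactly `tsp` of the population. Returns
#' `M' - M`, the post- minus pre-selection mean marker effect.
#'
#' @param table A `marker_table`.
#' @param tsp Total selection proportion(s), each in (0, 1].
#'
#' @return Predicted gain (trait units), vectorised over `tsp`.
#' @examples
#' gain_marker_only(three_genotype_table(4), c(0.25, 0.75))
#' @export
gain_marker_only <- function(table, tsp) {
  check_proportion(tsp, "tsp")
  M <- marker_table_moments(table)$mean
  vapply(tsp, function(p) {
    w <- truncation_weights(table, p)
    sum(w * table$value) / p - M
  }, numeric(1))
}

#' Normal-approximation gain from marker-only selection
#'
#' `delta_g = i(tsp) * sqrt(Vm)`, treating the marker-class distribution as
#' normal. A useful approximation when many classes segregate; the exact
#' enumeration ([gain_marker_only()]) is preferred for few classes.
#'
#' @param Vm Marker-explained variance.
#' @inheritParams gain_phenotype_only
#'
#' @return Predicted gain (trait units), vectorised over `tsp`.
#' @export
gain_marker_only_normal <- function(Vm, tsp) {
  check_variance(Vm, "Vm")
  selection_intensity(tsp) * sqrt(Vm)
}

#' Truncate a marker-class distribution
#'
#' Retains the top `spm` of the distribution by class mean, thinning the
#' boundary class fractionally, and renormalises the surviving frequencies.
#' The result carries the post-selection mean (`M'`) and variance (`Vm'`)
#' of the marker effects, the inputs to the second-stage gain prediction.
#'
#' @param table A `marker_table`.
#' @param spm First-stage selection proportion, in (0, 1].
#'
#' @return A `marker_table` of the surviving classes (renormalised
#'   frequencies) with attribute `truncation`, a list holding `spm`,
#'   `mean` (`M'`) and `variance` (`Vm'`).
#' @examples
#' tr <- truncate_marker_table(three_genotype_table(4), 0.75)
#' attr(tr, "truncation")
#' @export
truncate_marker_table <- function(table, spm) {
  check_proportion(spm, "spm")
  if (length(spm) != 1L) abort("`spm` must be a single proportion.")
  w <- truncation_weights(table, spm)
  keep <- w > 0
  out <- tibble(
    genotype = table$genotype[keep],
    freq = w[keep] / spm,
    value = table$value[keep]
  )
  m <- sum(out$freq * out$value)
  v <- max(sum(out$freq * out$value^2) - m^2, 0)
  new_marker_table(out, attr(table, "population"), attr(table, "dominance"),
                   attr(table, "effect_scalar")) |>
    structure(truncation = list(spm = spm, mean = m, variance = v))
}

# retained (unnormalised) frequency mass per class when the top `p` of the
# distribution is kept, classes ordered by descending mean
truncation_weights <- function(table, p) {
  ord <- order(table$value, decreasing = TRUE)
  f <- table$freq[ord]
  taken_before <- c(0, cumsum(f)[-length(f)])
  w <- pmin(f, pmax(p - taken_before, 0))
  w[order(ord)]
}

#' Predicted gain from two-stage selection
#'
#' Stage 1 truncates the marker-class distribution at `spm`, contributing
#' `delta_g1 = M' - M`. Stage 2 applies phenotypic truncation at
#' `SP_P = tsp/spm` to the survivors, predicted as
#' `delta_g2 = H' * i(tsp/spm) * sqrt(Vp')` with post-stage-1 heritability
#' `H' = (Vm' + Vb)/(Vm' + Vb + Ve)` and phenotypic variance
#' `Vp' = Vm' + Vb + Ve`. The total is `delta_g1 + delta_g2`.
#'
#' @param table A `marker_table`.
#' @param Vb Background genotypic variance.
#' @param Ve Environmental variance.
#' @param tsp Total selection proportion, in (0, 1].
#' @param spm First-stage proportion(s), each in \[`tsp`, 1\].
#'
#' @return Predicted gain (trait units), vectorised over `spm`.
#' @examples
#' sc <- trait_scenarios()[2, ]
#' mt <- marker_table(sc, "three", "partial")
#' gain_two_stage(mt, sc$Vb, sc$Ve, tsp = 0.1, spm = c(0.25, 1))
#' @export
gain_two_stage <- function(table, Vb, Ve, tsp, spm) {
  check_variance(Vb, "Vb")
  check_variance(Ve, "Ve")
  check_proportion(tsp, "tsp")
  if (any(spm < tsp - 1e-9)) abort("`spm` must be at least `tsp`.")
  check_proportion(spm, "spm")
  vapply(spm, function(s) {
    tr <- attr(truncate_marker_table(table, s), "truncation")
    delta1 <- tr$mean - marker_table_moments(table)$mean
    Vp2 <- tr$variance + Vb + Ve
    H2 <- if (Vp2 > 0) (tr$variance + Vb) / Vp2 else 0
    delta1 + H2 * selection_intensity(min(tsp / s, 1)) * sqrt(Vp2)
  }, numeric(1))
}

#' Optimal first-stage proportion for two-stage selection
#'
#' Evaluates the two-stage prediction over a grid of first-stage
#' proportions and returns the argmax. Ties go to the largest `spm` (the
#' least marker-based culling).
#'
#' @inheritParams gain_two_stage
#' @param spm Grid of first-stage proportions; defaults to
#'   [spm_grid()]`(tsp)`.
#'
#' @return A one-row tibble: `tsp`, `spm_opt`, `gain`.
#' @export
optimal_two_stage <- function(table, Vb, Ve, tsp, spm = spm_grid(tsp)) {
  if (length(spm) == 0L) abort("`spm` grid must be non-empty.")
  gains <- gain_two_stage(table, Vb, Ve, tsp, spm)
  best <- max(gains)
  opt <- max(spm[gains >= best - 1e-12])
  tibble(tsp = tsp, spm_opt = opt, gain = best)
}

#' Predicted gain from index selection
#'
#' Truncated-normal prediction for the weighted index of phenotype and
#' marker score (after Lande & Thompson 1990, with broad-sense
#' heritability):
#' \deqn{\Delta g = H\, i(tsp) \sqrt{V_P} \sqrt{P/H + (1-P)^2/(1-HP)}.}
#' At `P = 0` this reduces to the phenotype-only prediction; at `P = 1` to
#' the normal-approximation marker-only prediction with `Vm = H Vp`; at
#' `H = P = 1` the bracket limit is 1.
#'
#' @param H Broad-sense heritability, in (0, 1].
#' @param P DNA-test predictiveness, in \[0, 1\].
#' @inheritParams gain_phenotype_only
#'
#' @return Predicted gain (trait units), vectorised over `tsp`.
#' @examples
#' gain_index(0.5, 0.8, 200, 0.05)
#' @export
gain_index <- function(H, P, Vp, tsp) {
  check_proportion(H, "H")
  check_proportion(P, "P", min_open = FALSE)
  check_variance(Vp, "Vp")
  bracket <- if (H * P >= 1) 1 else P / H + (1 - P)^2 / (1 - H * P)
  H * selection_intensity(tsp) * sqrt(Vp) * sqrt(bracket)
}

#' Predicted gain curves for all strategies over a TSP grid
#'
#' Convenience wrapper assembling the closed-form predictions for one
#' scenario and population into a long tibble. Two-stage rows report the
#' per-TSP optimum over the `spm` grid (column `spm` holds the optimal
#' first-stage proportion).
#'
#' @param scenario A one-row scenario tibble.
#' @param population,dominance Passed to [marker_table()].
#' @param tsp TSP grid (defaults to [tsp_grid()]).
#'
#' @return A tibble: `strategy`, `tsp`, `spm`, `gain`.
#' @export
derived_gains <- function(scenario, population = c("three", "nine"),
                          dominance = "none", tsp = tsp_grid()) {
  scenario <- scenario_row(scenario)
  mt <- marker_table(scenario, population, dominance)
  two <- map_dfr(tsp, function(p) {
    optimal_two_stage(mt, scenario$Vb, scenario$Ve, p)
  })
  bind_rows(
    tibble(strategy = "phenotype", tsp = tsp, spm = NA_real_,
           gain = gain_phenotype_only(scenario$H, scenario$Vp, tsp)),
    tibble(strategy = "marker", tsp = tsp, spm = NA_real_,
           gain = gain_marker_only(mt, tsp)),
    tibble(strategy = "two_stage", tsp = tsp, spm = two$spm_opt,
           gain = two$gain),
    tibble(strategy = "index", tsp = tsp, spm = NA_real_,
           gain = gain_index(scenario$H, scenario$P, scenario$Vp, tsp))
  )
}
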