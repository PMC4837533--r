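#' Partition phenotypic variance into genetic, marker and background components
#'
#' For a single trait in a clonally propagated seedling population, the
#' phenotypic variance `Vp` is split by the broad-sense heritability `H`
#' (proportion of `Vp` that is genotypic, relevant under clonal propagation
#' because dominance and epistatic effects are captured along with additive
#' ones) and the DNA-test predictiveness `P` (proportion of the genotypic
#' variance explained by the marker loci in the test):
#'
#' \deqn{V_G = H V_P,\quad V_E = V_P - V_G,\quad V_M = P V_G,\quad V_B = V_G - V_M}
#'
#' so that `Vp = Vg + Ve` and `Vg = Vm + Vb` hold exactly.
#'
#' @param Vp Phenotypic variance (trait units squared), positive.
#' @param H Broad-sense heritability, in (0, 1]. Vectorised.
#' @param P DNA-test predictiveness, in (0, 1]. Vectorised.
#'
#' @return A tibble with one row per (`H`, `P`) pair and columns
#'   `H`, `P`, `Vp`, `Vg`, `Ve`, `Vm`, `Vb`.
#'
#' @examples
#' partition_variance(200, 0.5, 0.5)
#' @export
partition_variance <- function(Vp, H, P) {
  if (!is.numeric(Vp) || any(!is.finite(Vp)) || any(Vp <= 0)) {
    abort("`Vp` must be a positive, finite phenotypic variance.")
  }
  check_proportion(H, "H")
  check_proportion(P, "P")
  Vg <- H * Vp
  Vm <- P * Vg
  tibble(
    H = H, P = P, Vp = Vp,
    Vg = Vg, Ve = Vp - Vg, Vm = Vm, Vb = Vg - Vm
  )
}

#' Grid of trait-test scenarios
#'
#' Builds the scenario grid crossing heritability and predictiveness levels at
#' a common phenotypic variance. The default levels (0.2, 0.5, 0.8, 1.0 for
#' both, `Vp = 200`) give the 16 standard scenarios, ordered with `H` as the
#' outer factor and `P` as the inner one.
#'
#' @param H_levels,P_levels Heritability and predictiveness levels, each in
#'   (0, 1].
#' @param Vp Phenotypic variance shared by all scenarios.
#'
#' @return A tibble with columns `scenario`, `H`, `P`, `Vp`, `Vg`, `Ve`, `Vm`,
#'   `Vb`, one row per scenario.
#'
#' @examples
#' trait_scenarios()
#' @export
trait_scenarios <- function(H_levels = c(0.2, 0.5, 0.8, 1),
                            P_levels = c(0.2, 0.5, 0.8, 1),
                            Vp = 200) {
  grid <- tidyr::expand_grid(H = H_levels, P = P_levels)
  out <- partition_variance(Vp, grid$H, grid$P)
  bind_cols(tibble(scenario = seq_len(nrow(out))), out)
}

#' Scenario grid with derived allele-effect scalars
#'
#' Extends [trait_scenarios()] with the allele-effect scalars that make each
#' marker-genotype distribution reproduce the scenario's marker variance
#' `Vm`: `a3` for the three-genotype population under no, partial
#' (`d3 = a3/2`) and complete (`d3 = a3`) dominance, and `a9` for the
#' nine-genotype epistatic population.
#'
#' @inheritParams trait_scenarios
#' @param digits Optional number of decimals to round the effect columns to
#'   (e.g. `1` for a display table); `NULL` keeps full precision.
#'
#' @return A tibble with the [trait_scenarios()] columns plus
#'   `a3_d0`, `a3_dhalf`, `a3_dfull` and `a9`.
#'
#' @examples
#' scenario_effects(digits = 1)
#' @export
scenario_effects <- function(H_levels = c(0.2, 0.5, 0.8, 1),
                             P_levels = c(0.2, 0.5, 0.8, 1),
                             Vp = 200, digits = NULL) {
  out <- trait_scenarios(H_levels, P_levels, Vp)
  out <- mutate(out,
    a3_d0    = derive_a3(.data$Vm, 0),
    a3_dhalf = derive_a3(.data$Vm, 0.5),
    a3_dfull = derive_a3(.data$Vm, 1),
    a9       = derive_a9(.data$Vm)
  )
  if (!is.null(digits)) {
    out <- mutate(out, dplyr::across(
      dplyr::all_of(c("a3_d0", "a3_dhalf", "a3_dfull", "a9")),
      ~ round(.x, digits)
    ))
  }
  out
}

check_proportion <- function(x, name, min_open = TRUE) {
  ok <- is.numeric(x) & is.finite(x) & x <= 1 & (if (min_open) x > 0 else x >= 0)
  if (!is.numeric(x) || !all(ok)) {
    abort(sprintf(
      "`%s` must be %s and at most 1 (got %s).",
      name, if (min_open) "greater than 0" else "at least 0",
      paste(utils::head(format(x[!ok]), 3), collapse = ", ")
    ))
  }
  invisible(x)
}

# pick one scenario row (tibble) by id from a scenario grid
scenario_row <- function(scenario) {
  if (!is.data.frame(scenario) || nrow(scenario) != 1L) {
    abort("`scenario` must be a single scenario row (a one-row data frame).")
  }
  need <- c("H", "P", "Vp", "Vg", "Ve", "Vm", "Vb")
  missing <- setdiff(need, names(scenario))
  if (length(missing)) {
    abort(paste0("`scenario` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  scenario
}
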