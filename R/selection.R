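# Seedling-selection strategies. All strategies retain k = round(TSP * n)
# seedlings; ties (always present among marker-class scores, and present in
# phenotypes only under zero noise) are broken uniformly at random so that
# "retained individuals were randomly selected" holds within a boundary
# class.

#' Index weights for combined phenotype-plus-marker selection
#'
#' Weights of the linear selection index `I = b_z z + b_m m`, where `z` is
#' the phenotype and `m` the marker score (the seedling's class mean). With
#' `b_z = 1`, the weight ratio is `b_m = (1/H - 1)/(1 - P)` (after Lande &
#' Thompson 1990, with broad-sense heritability in place of narrow-sense).
#' Degenerate cases: `H = 1` gives `b_m = 0` (pure phenotypic ranking);
#' `P = 1` with `H < 1` gives `b_m = Inf`, realised as ranking by marker
#' class first, phenotype second.
#'
#' @param H Broad-sense heritability, in (0, 1].
#' @param P DNA-test predictiveness, in \[0, 1\].
#'
#' @return A one-row tibble with columns `b_z` and `b_m`.
#' @examples
#' index_weights(0.2, 0.5)  # b_m = 8
#' @export
index_weights <- function(H, P) {
  check_proportion(H, "H")
  check_proportion(P, "P", min_open = FALSE)
  b_m <- if (H == 1) 0 else if (P == 1) Inf else (1 / H - 1) / (1 - P)
  tibble(b_z = 1, b_m = b_m)
}

#' Realized genetic gain of a selected set
#'
#' The increase in mean genotypic value of the selected seedlings over the
#' whole pre-selection population: `delta_g = mean(g[selected]) - mean(g)`.
#'
#' @param pop A `seedling_population`.
#' @param selected A `selection_result`, or an integer vector of seedling
#'   ids; must be a non-empty subset of `pop$id`.
#'
#' @return The realized gain (trait units).
#' @export
realized_gain <- function(pop, selected) {
  if (inherits(selected, "selection_result")) selected <- selected$id
  if (length(selected) == 0L) abort("`selected` must not be empty.")
  if (!all(selected %in% pop$id)) {
    abort("`selected` contains ids not present in `pop`.")
  }
  mean(pop$g[match(selected, pop$id)]) - mean(pop$g)
}

#' Phenotype-only seedling selection
#'
#' Retains the `round(tsp * n)` seedlings with the highest phenotypic
#' values `z`; phenotypic ties are broken uniformly at random.
#'
#' @param pop A `seedling_population`.
#' @param tsp Total selection proportion, in (0, 1].
#'
#' @return A `selection_result`: the retained rows of `pop`, with
#'   attributes `strategy`, `tsp`, `spm` and `delta_g`. Use [tidy()] for a
#'   one-row summary.
#' @examples
#' sc <- trait_scenarios()[6, ]
#' pop <- simulate_population(marker_table(sc, "three"), sc, seed = 1)
#' tidy(select_phenotype(pop, 0.25))
#' @export
select_phenotype <- function(pop, tsp) {
  k <- retained_count(tsp, nrow(pop))
  ids <- rank_candidates("phenotype", pop$g_m, pop$z)[seq_len(k)]
  selection_result(pop, ids, "phenotype", tsp)
}

#' Marker-only seedling selection
#'
#' Retains seedlings by descending marker-class mean; the boundary class is
#' thinned uniformly at random to reach `round(tsp * n)` retained seedlings.
#'
#' @inheritParams select_phenotype
#' @return A `selection_result`.
#' @export
select_marker <- function(pop, tsp) {
  k <- retained_count(tsp, nrow(pop))
  ids <- rank_candidates("marker", pop$g_m, pop$z)[seq_len(k)]
  selection_result(pop, ids, "marker", tsp)
}

#' Two-stage seedling selection
#'
#' Stage 1 retains `round(spm * n)` seedlings by marker class (with random
#' thinning of the boundary class); stage 2 retains the final
#' `round(tsp * n)` among the survivors by phenotype (second-stage
#' proportion `SP_P = tsp/spm`).
#'
#' @inheritParams select_phenotype
#' @param spm First-stage (marker) selection proportion, in \[`tsp`, 1\].
#' @return A `selection_result`.
#' @export
select_two_stage <- function(pop, tsp, spm) {
  n <- nrow(pop)
  k <- retained_count(tsp, n)
  check_spm(spm, tsp)
  k1 <- max(retained_count(spm, n), k)
  s1 <- rank_candidates("marker", pop$g_m, pop$z)[seq_len(k1)]
  z1 <- pop$z[s1]
  ids <- s1[rank_values(z1)[seq_len(k)]]
  selection_result(pop, pop$id[ids], "two_stage", tsp, spm)
}

#' Index seedling selection
#'
#' Retains the top `round(tsp * n)` seedlings by the selection index
#' `I = z + b_m m` (see [index_weights()]). When `b_m` is infinite
#' (`P = 1`, `H < 1`) seedlings are ranked by marker class first and
#' phenotype second.
#'
#' @inheritParams select_phenotype
#' @param H,P Heritability and predictiveness used for the weights; default
#'   to the scenario the population was simulated from.
#' @return A `selection_result`.
#' @export
select_index <- function(pop, tsp, H = NULL, P = NULL) {
  sc <- attr(pop, "scenario")
  H <- H %||% sc$H
  P <- P %||% sc$P
  if (is.null(H) || is.null(P)) {
    abort("Supply `H` and `P`, or use a population carrying its scenario.")
  }
  b_m <- index_weights(H, P)$b_m
  k <- retained_count(tsp, nrow(pop))
  ids <- rank_candidates("index", pop$g_m, pop$z, b_m = b_m)[seq_len(k)]
  selection_result(pop, ids, "index", tsp)
}

#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  sel <- attr(x, "selection")
  tibble(
    strategy = sel$strategy,
    tsp = sel$tsp,
    spm = sel$spm,
    n_selected = nrow(x),
    delta_g = sel$delta_g
  )
}

#' @export
print.selection_result <- function(x, ...) {
  sel <- attr(x, "selection")
  cat(sprintf(
    "Selection result: %s, TSP = %.3g%s, %d retained, delta_g = %.4g\n",
    sel$strategy, sel$tsp,
    if (!is.na(sel$spm)) sprintf(", SP_M = %.3g", sel$spm) else "",
    nrow(x), sel$delta_g
  ))
  print(as_tibble(unclass_tbl(x)), ...)
  invisible(x)
}

# ---- internal ranking machinery (shared with the replication engine) ----

# full ranking (best first) of candidate indices for a single-stage strategy
rank_candidates <- function(strategy, g_m, z, b_m = 0) {
  n <- length(g_m)
  switch(strategy,
    phenotype = rank_values(z),
    marker = order(g_m, runif(n), decreasing = TRUE),
    index = {
      if (is.infinite(b_m)) {
        order(g_m, z, runif(n), decreasing = TRUE)
      } else {
        rank_values(z + b_m * g_m)
      }
    },
    abort(sprintf("Unknown strategy '%s'.", strategy))
  )
}

# descending order with random tie-break only when ties exist
rank_values <- function(x) {
  if (anyDuplicated(x)) {
    order(x, runif(length(x)), decreasing = TRUE)
  } else {
    order(x, decreasing = TRUE)
  }
}

retained_count <- function(tsp, n, name = "tsp") {
  if (!is.numeric(tsp) || length(tsp) != 1L || !is.finite(tsp) ||
      tsp <= 0 || tsp > 1) {
    abort(sprintf("`%s` must be a single proportion in (0, 1].", name))
  }
  k <- as.integer(round(tsp * n))
  if (k < 1L) {
    abort(sprintf("`%s` = %s retains no seedlings at n = %d.", name, format(tsp), n))
  }
  k
}

check_spm <- function(spm, tsp) {
  if (!is.numeric(spm) || length(spm) != 1L || !is.finite(spm) ||
      spm > 1 || spm < tsp - 1e-9) {
    abort("`spm` must lie in [tsp, 1]: the first stage cannot retain fewer seedlings than the final count.")
  }
  invisible(spm)
}

selection_result <- function(pop, ids, strategy, tsp, spm = NA_real_) {
  res <- as_tibble(unclass_tbl(pop[match(ids, pop$id), , drop = FALSE]))
  # one list attribute: "tsp" alone is R's reserved time-series attribute
  attr(res, "selection") <- list(
    strategy = strategy, tsp = tsp, spm = spm,
    delta_g = mean(res$g) - mean(pop$g)
  )
  class(res) <- c("selection_result", class(res))
  res
}
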