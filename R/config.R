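#' Experiment configuration
#'
#' Assembles and validates the settings of a full replication experiment.
#' Defaults are the standard study conditions: `Vp = 200`, heritability and
#' predictiveness levels 0.2/0.5/0.8/1.0, populations of 400 single-clone
#' seedlings, 1000 replicates per cell, and 0.05 grids for both selection
#' proportions.
#'
#' @param Vp Phenotypic variance.
#' @param H_levels,P_levels Heritability / predictiveness levels, in (0, 1].
#' @param n Population size; must give integral class counts for every
#'   requested population (divisible by 4 for `"three"`, by 16 for
#'   `"nine"`).
#' @param reps Replicates per cell.
#' @param populations Character subset of `c("three", "nine")`.
#' @param dominance Dominance cases for the three-genotype population,
#'   subset of `c("none", "partial", "complete")`.
#' @param tsp_step,spm_step Grid steps; each must divide 1 evenly.
#' @param seed Root seed.
#'
#' @return A validated list of class `seedgain_config`.
#' @examples
#' seedgain_config(reps = 50, populations = "three", dominance = "partial")
#' @export
seedgain_config <- function(Vp = 200,
                            H_levels = c(0.2, 0.5, 0.8, 1),
                            P_levels = c(0.2, 0.5, 0.8, 1),
                            n = 400, reps = 1000,
                            populations = c("three", "nine"),
                            dominance = c("none", "partial", "complete"),
                            tsp_step = 0.05, spm_step = 0.05,
                            seed = 1L) {
  check_variance(Vp, "Vp")
  check_proportion(H_levels, "H_levels")
  check_proportion(P_levels, "P_levels")
  populations <- match.arg(populations, several.ok = TRUE)
  dominance <- match.arg(dominance, several.ok = TRUE)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1) {
    abort("`reps` must be a positive replicate count.")
  }
  check_grid_step(tsp_step)
  check_grid_step(spm_step)
  for (pop in populations) {
    div <- if (pop == "three") 4L else 16L
    if (!is.numeric(n) || length(n) != 1L || n < div || abs(n / div - round(n / div)) > 1e-9) {
      abort(sprintf(
        "`n` = %s gives non-integer genotype-class counts for the %s-genotype population (needs a multiple of %d).",
        format(n), pop, div
      ))
    }
  }
  structure(
    list(Vp = Vp, H_levels = H_levels, P_levels = P_levels,
         n = as.integer(n), reps = as.integer(reps),
         populations = populations, dominance = dominance,
         tsp_step = tsp_step, spm_step = spm_step, seed = as.integer(seed)),
    class = "seedgain_config"
  )
}

#' Load an experiment configuration from a YAML file
#'
#' Reads a YAML file whose top-level keys are [seedgain_config()] arguments;
#' missing keys take the defaults, an empty file yields the full default
#' configuration, and unknown keys or out-of-domain values are rejected
#' with the offending field named.
#'
#' @param path Path to a YAML file.
#' @return A `seedgain_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' not found.", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) abort("Config file must contain a YAML mapping.")
  # YAML 1.1 resolves a bare key `n` (or `N`) to a boolean; map it back to
  # the population-size field, the only schema key affected
  names(vals)[names(vals) %in% c("FALSE", "no")] <- "n"
  unknown <- setdiff(names(vals), names(formals(seedgain_config)))
  if (length(unknown)) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(seedgain_config, vals)
}

#' Write a result table as CSV
#'
#' Deterministic RFC-4180 CSV output (fixed column order, full-precision
#' numbers) for any of the package's result tibbles.
#'
#' @param records A data frame.
#' @param path Output file path.
#' @return `records`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  readr::write_csv(as_tibble(unclass_tbl(records)), path, progress = FALSE)
  invisible(records)
}

#' @export
print.seedgain_config <- function(x, ...) {
  cat("Seedling-selection experiment configuration\n")
  cat(sprintf("  Vp = %g; H levels: %s; P levels: %s\n", x$Vp,
              paste(x$H_levels, collapse = ", "),
              paste(x$P_levels, collapse = ", ")))
  cat(sprintf("  n = %d, reps = %d, seed = %d\n", x$n, x$reps, x$seed))
  cat(sprintf("  populations: %s; dominance: %s\n",
              paste(x$populations, collapse = ", "),
              paste(x$dominance, collapse = ", ")))
  cat(sprintf("  TSP step %g, SP_M step %g\n", x$tsp_step, x$spm_step))
  invisible(x)
}
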