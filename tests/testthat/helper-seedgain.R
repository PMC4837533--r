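# shared fixtures, built in code

SCENARIOS <- trait_scenarios()

scenario <- function(i) SCENARIOS[i, ]

# independent enumeration of the nine-genotype class layout, written out
# literally so it does not depend on the package's own constants
NINE_ORACLE <- list(
  freq = c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16,
  unit = c(3, 3, 1, 2, 1, 0, -2.5, -2, -3)
)

# weighted variance of the nine class means at unit effect, by enumeration
nine_unit_var_oracle <- function() {
  f <- NINE_ORACLE$freq
  v <- NINE_ORACLE$unit
  sum(f * v^2) - sum(f * v)^2
}

# truncated-normal mean of the retained upper tail, by numerical integration
selection_intensity_oracle <- function(p) {
  vapply(p, function(pp) {
    if (pp == 1) return(0)
    stats::integrate(function(x) x * stats::dnorm(x),
                     stats::qnorm(1 - pp), Inf, rel.tol = 1e-10)$value / pp
  }, numeric(1))
}

ci_half_width <- function(est) (est$ci_high - est$ci_low) / 2
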