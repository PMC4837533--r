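---
title: "Modeling genetic gain from marker-assisted seedling selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling genetic gain from marker-assisted seedling selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedgain)
```

## The problem

In clonally propagated crops (apple, potato, grape, strawberry, many forest
trees), a selected seedling is multiplied asexually, so *all* of its genotypic
value — additive, dominance and epistatic — is carried into the cultivar.
Seedling selection, the first and most drastic culling step after crossing,
can therefore be driven by the **broad-sense** heritability of the trait,
not the narrow-sense quantity that governs response in seed-propagated crops.
When a DNA test tags part of that genotypic variance, breeders can select
seedlings on marker genotypes (cheap and early), phenotypes (complete but
noisy and late), or a combination. `seedgain` predicts and simulates the
genetic gain of four such strategies so the choice can be made quantitatively.

## Genetic model

Each seedling's phenotype is

$$z = g + e, \qquad g = g_M + g_B,$$

where $g_M$ is the mean genotypic value of the seedling's marker-genotype
class (its *marker effect*), $g_B \sim N(0, V_B)$ is the background genotypic
effect of untagged loci, and $e \sim N(0, V_E)$ is environmental noise.
Two ratios index a trait-test scenario:

* $H = V_G / V_P$, the broad-sense heritability, and
* $P = V_M / V_G$, the *predictiveness* of the DNA test,

giving the exact partition $V_G = H V_P$, $V_E = V_P - V_G$, $V_M = P V_G$,
$V_B = V_G - V_M$ (`partition_variance()`). The default grid crosses
$H, P \in \{0.2, 0.5, 0.8, 1.0\}$ at $V_P = 200$, yielding 16 scenarios
(`trait_scenarios()`); these defaults are the study conditions of the whole
package, not tuning knobs.

Interactions between the tagged loci and the background genome are assumed
absent, markers are assumed completely linked to their trait loci, and all
parameters ($H$, $P$, marker effects) are treated as known without error.
These assumptions are what the derived-versus-simulated comparisons below
measure *given*; relaxing them (estimation error, recombination) is out of
scope.

## Segregating populations

Two marker-class distributions are built, both on an adjusted scale whose
zero point (25) is added back only when phenotypes are materialised — it
cancels in every gain.

**Three genotypes** (`three_genotype_table()`): one biallelic locus, MM/Mm/mm
segregating 1:2:1 with class means $a_3$, $d_3$, $-a_3$ and dominance cases
$d_3 \in \{0, a_3/2, a_3\}$. Matching the class variance to $V_M$ gives
$a_3 = \sqrt{4 V_M / (2 + (d_3/a_3)^2)}$.

**Nine genotypes with epistasis** (`nine_genotype_table()`): two unlinked
loci, a major locus M ($2a_9, a_9, -2a_9$) and a minor locus T
($a_9, 0, -a_9$), with epistatic overrides MMTt $\to 3a_9$ and
mmTT $\to -2.5a_9$. The scalar $a_9$ is *defined* by the variance-matching
condition: the frequency-weighted variance of the nine class means equals
$c\,a_9^2$ with $c = 3.6708984375$ by enumeration, so
$a_9 = \sqrt{V_M / c}$. We adopt this enumeration definition as the single
source of truth because it is the only self-consistent closed form: the
resulting effects reproduce all sixteen tabulated scenario values at
1-decimal precision.

A note on reference values: two tabulated three-genotype cells
(scenarios 7/10, no dominance) print 12.7 where the closed form gives
$\sqrt{160} = 12.649$, and two (scenarios 8/14, complete dominance) print
11.6 against $\sqrt{400/3} = 11.547$ — both consistent with the reference
values having been rounded twice (to 2 decimals, then to 1). The package
keeps full precision internally and compares display values at half a
printed unit plus this double-rounding allowance (0.055).

## Selection strategies

All strategies retain $k = \mathrm{round}(TSP \times n)$ seedlings (R's
round-half-to-even; every default grid point at $n = 400$ is exact, so the
convention only matters for off-grid user input).

* **Phenotype-only** — top $k$ by $z$.
* **Marker-only** — classes in descending class mean; the boundary class is
  thinned uniformly at random.
* **Two-stage** — marker truncation at $SP_M$, then phenotypic truncation at
  $SP_P = TSP/SP_M$ among survivors. The final count takes precedence: stage
  two always returns exactly $k$ seedlings.
* **Index** — top $k$ by $I = z + b_m g_M$ with
  $b_m = (1/H - 1)/(1 - P)$ (Lande & Thompson 1990, with $H$ replacing
  $h^2$ because clonal propagation captures total genotypic value). The
  marker score enters as the class mean; any affine shift of it reorders
  nothing, so the adjusted and observed scales give identical selections.

Realized gain is $\Delta g = \bar g_{\text{selected}} - \bar g_{\text{all}}$,
the lift in mean genotypic value over the pre-selection population.

Degenerate settings are resolved as limits, not errors: $H = 1$ makes the
index purely phenotypic ($b_m = 0$); $P = 1$ with $H < 1$ makes $b_m$
infinite, implemented as lexicographic ranking (marker class, then
phenotype); phenotypic ties — probability zero under noise, certain when
$V_B = V_E = 0$ — are broken uniformly at random, so zero-noise scenarios
degrade gracefully to marker-only behaviour.

## Closed-form predictions

With $i(p) = \phi(\Phi^{-1}(1-p))/p$ the truncated-normal selection
intensity (`selection_intensity()`):

* phenotype-only: $\Delta g = H\, i(TSP) \sqrt{V_P}$;
* marker-only: $\Delta g = M' - M$ by exact enumeration with fractional
  thinning of the boundary class (`gain_marker_only()`), or
  $i(TSP)\sqrt{V_M}$ as a normal approximation that improves with the
  number of segregating classes;
* two-stage: $\Delta g_1 = M' - M$ from truncating the class distribution at
  $SP_M$, plus $\Delta g_2 = H'\, i(TSP/SP_M) \sqrt{V_P'}$ with
  $V_P' = V_M' + V_B + V_E$ and $H' = (V_M' + V_B)/V_P'$;
* index: $\Delta g = H\, i(TSP) \sqrt{V_P} \sqrt{P/H + (1-P)^2/(1-HP)}$,
  with the bracket taken as 1 in the $H = P = 1$ limit.

Each formula is written as intensity × standard deviation ($i\sigma$), the
dimensionally consistent form of the classical breeder's equation. The
stage-one enumeration uses *fractional* boundary thinning — an
infinite-population expectation — whereas the simulation culls whole
seedlings; with $n = 400$ this discreteness is negligible at grid
proportions. The stage-two prediction treats the survivor mixture as
normal; this is precisely the approximation whose quality the
derived-versus-simulated correlations quantify. Predictions degrade
visibly where the phenotype is strongly multimodal (high $H \times P$),
and that degradation is part of the expected output, not a defect.

## Simulation design and seeding

`simulate_population()` assigns genotype classes as **exact fixed counts**
($n \times$ frequency, e.g. 100/200/100 at $n = 400$), not multinomial
draws; only $g_B$ and $e$ are stochastic. Non-integral counts are rejected
naming the offending class. Moments use the divide-by-$n$ convention so
zero-noise populations match their enumerated tables exactly.

The replication engine (`run_cell()`, `gains_over_tsp()`,
`two_stage_scan()`) derives one replicate seed per replicate from the root
seed only — never from the cell's scenario, strategy or grid position. Two
consequences, both deliberate:

1. **Common random numbers.** Cells sharing a root seed see identical
   replicate populations, so strategy orderings, scenario contrasts and
   $SP_M$ argmaxes are paired comparisons with much lower variance than
   independent runs — the right design for the comparative questions this
   package answers.
2. **Nested truncation.** Within a replicate, one population and one
   selection ranking serve every $TSP$ (via cumulative means along the
   ranking) and every $SP_M$ (via nested survivor sets). Each cell's
   marginal distribution is identical to an isolated run with the same
   root seed — an exact-equality property covered by the test suite — and a
   19-point gain curve costs little more than a single cell.

Summaries report the mean gain over replicates, its standard deviation and
the 95% confidence interval $\bar x \pm 1.96\, s/\sqrt{n_{\text{reps}}}$;
with a single replicate the s.d. is defined as 0 and the interval collapses
to the point estimate.

## Reference experimental conditions and test sizes

The full design is 16 scenarios × 4 population cases (three-genotype with
three dominance cases, plus the nine-genotype population) × 4 strategies ×
a 19-point $TSP$ grid, with an $SP_M$ scan per $TSP$ for two-stage, at 1000
replicates of $n = 400$ — about 17,000 cells, roughly a quarter of an hour
on one core via `full_experiment(seedgain_config())`. The test suite exercises the same
machinery at full replicate counts where a quantitative claim depends on it
(marker-only CI coverage on scenarios 1/6/11/16; the $SP_M = 0.25$ optimum
of scenario 2 at $TSP = 0.1$; strategy orderings across all 16 scenarios at
$TSP = 0.25$ on the nine-genotype population, the top-class boundary where
marker information is used without random culling) and at reduced sizes
(tens of replicates, coarse grids) where only plumbing is under test.

What passing these simulations shows — and does not show — about real data:
the generator realises exactly the stated model (known effects, complete
linkage, normal background and environment, exact class counts). Agreement
between derivation and simulation validates the formulas *under those
assumptions*; it says nothing about estimation error in $H$, $P$ or marker
effects, marker–trait recombination, genotype-by-environment interaction,
or non-normal environments, all of which real programs face.

## Design choices made where the design was open

* **Tie-breaking the derived $SP_M$ optimum:** ties go to the largest
  $SP_M$, i.e. the least marker-based culling — the conservative choice
  when gains are indistinguishable (relevant in the $H = P = 1$ row, where
  simulated gain is flat in $SP_M$).
* **Index marker score:** the weight formula's marker score is taken to be
  the class-mean genotypic value, the only reading under which the
  published weight ratio has its index-theory meaning.
* **Stage-two ranking:** survivors are re-ranked by raw $z$; no
  re-standardisation, since truncation selection is invariant to monotone
  transforms.
* **Orientation of the two-stage first-stage gain:** written $M' - M$
  (non-negative under truncation from above) so the two endpoint identities
  hold: $SP_M = 1$ reproduces phenotype-only and $SP_M = TSP$ reproduces
  marker-only.
* **Grid arithmetic:** proportion grids are integer multiples of the step,
  avoiding floating-point drift across the 0.05 lattice.

## Known limitations

* The phenotype-only and index predictions assume approximate normality;
  in high-$HP$ scenarios the phenotype is an explicit mixture and the
  predictions are biased (the simulation is the reference there).
* Index selection weakly dominates the two-stage optimum in the
  simulations: both use the same information, but the index uses it
  simultaneously while two-stage can discard top genotypic values in its
  marker stage. The difference is small (≤ ~5% of the gain at 1000
  replicates) yet larger than the very tight Monte-Carlo confidence
  intervals, so "equal within CI" is *not* an invariant of the model —
  only "similar, with index at least as good".
* Single trait, single population structure per run, no cost/time
  efficiency weighting, no multi-environment replication, no pedigree.
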