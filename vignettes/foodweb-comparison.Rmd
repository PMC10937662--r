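---
title: "Comparing mass-balanced food webs: fluxes, footprints, and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing mass-balanced food webs: fluxes, footprints, and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicflux)
```

# The model

`trophicflux` compares two static, steady-state descriptions of the same
ecosystem — for instance one parameterized before and one after a multi-year
marine heatwave — each expressed as an Ecopath-style mass-balanced food web.
A model is an ordered set of functional groups (living groups, nutrient
pools, detritus pools, fishing fleets), each living group carrying a biomass
density $B$, a production-to-biomass ratio $P/B$, a consumption-to-biomass
ratio $Q/B$ and an assimilation efficiency $AE$, together with a
diet-composition matrix $DC$ whose column $j$ gives the fraction of consumer
$j$'s intake taken from each prey, and a landings matrix $Y$ for the fleets.

Mass balance is bookkept through the ecotrophic efficiency, from the master
equation at steady state with no imports, exports, or biomass accumulation:

$$B_i \left(\tfrac{P}{B}\right)_i EE_i \;=\; \sum_j B_j
\left(\tfrac{Q}{B}\right)_j DC_{ij} \;+\; \sum_f Y_{if}.$$

$EE_i$ is the fraction of group $i$'s production removed by predators and
fisheries; a model is balanced when every $EE \le 1$. The package only
*detects* imbalance (`computeEE`, `isBalanced`); it never rebalances a model
automatically, because balancing published models is a judgment-laden manual
process that should not be hidden inside an analysis pipeline.

Producers are treated as "consumers" of the nutrient pools (their $Q/B$ acts
on a nutrient diet column), so a single production-fate machinery covers
every living group: total consumption $Q = B \cdot Q/B$ splits into
non-assimilated egestion $(1 - AE)$ to detritus, metabolic costs
$AE - \frac{P/B}{Q/B}$ to nutrient pools, production consumed by each
predator or fleet $q_{g \to j}/Q$, and senescence
$\frac{P/B}{Q/B}(1 - EE)$ to detritus. These fractions sum to one for every
group — consumption is conserved — and `buildProductionFate` computes
senescence as the residual so the identity holds to machine precision. The
paper trail for energy flow itself is the consumption-flux network
(`consumptionFlux`): $q_{i \to j} = B_j (Q/B)_j\, DC_{ij}$, with fleet edges
carrying the landings.

Units are declared model-level tags (`mt km^-2` with `yr^-1` by default) and
never converted: every statistic here is a ratio, a fraction, or a
difference within one currency, so the analysis is unit-covariant.

# Network metrics

Trophic levels solve the standard diet-weighted recursion
$TL_j = 1 + \sum_i DC_{ij} TL_i$ as the linear system
$(I - DC^\top)\,TL = \mathbf{1}$, which handles cannibalism and mutual
predation exactly; an isolated consumer loop with no path to a basal node is
singular and reported as such. The analyzed node set excludes nutrient pools
and includes detritus and fleets by default — the published node counts
(86 nodes from 80 living groups, 5 detritus pools and fleets) are not
exactly derivable from the group-type arithmetic, so the node-set rule is a
configuration choice (`analyzedNodes`), not a constant. Fleets have no diet
column; their trophic level is taken as one plus the landings-share-weighted
mean trophic level of what they catch, which is this package's own
convention.

Connectance is realized links over $N^2$: self-links are possible, which is
forced by the published possible-link count ($86 \times 86 = 7396$), and
link density is identically connectance $\times N$. Links are counted on
the diet/landings *support* (any $DC > 0$ or $Y > 0$), not on a thresholded
flux. Uncertainty on both metrics comes from a node bootstrap
(`bootstrapMetrics`): each replicate resamples which nodes to use, with
replacement, keeping duplicate rows and columns of the induced matrix; the
induced-network construction is otherwise unspecified in the source
material, and index-resampling is the choice made here because it preserves
the self-link convention.

# Footprint and reach

The two headline metrics trace energy through *all* direct and indirect
living pathways. With $\phi_{gk}$ the fraction of $g$'s production consumed
by $k$ and $\psi_{kc} = DC_{kc}$ the fraction of $c$'s consumption taken
from $k$:

$$D_f(g) = \phi_{g,f} + \sum_{k \notin E,\, k \ne f} \phi_{gk} D_f(k),
\qquad
P_f(c) = \psi_{f,c} + \sum_{k \notin E,\, k \ne f} \psi_{kc} P_f(k),$$

with $D_f(f) = P_f(f) = 1$. $D_f(g)$ is the fraction of $g$'s production
destined for the focal group $f$; $P_f(c)$ the fraction of $c$'s production
that originated with or passed through $f$. Both are solved as linear
systems, valid under cycles because leakage to detritus, metabolism and
senescence keeps the spectral radius below one. The exclusion set $E$
always contains the nutrient and detritus pools: energy entering a detrital
pool is treated as leaving the traced web and does not re-enter a footprint
through detritivory. **Footprint** is the production-weighted mean of $D_f$
over living groups other than the focal; **reach** is the
production-weighted mean of $P_f$ over living consumer groups, counting the
focal's own production. Three conventions the source description leaves
open are fixed here and flagged for sensitivity analysis: the focal is
excluded from both sides of the footprint ratio, the focal's production is
included in reach, and the footprint denominator does not exclude
detritus-fueled production. Focal *sets* (e.g., all gelatinous zooplankton)
are handled by merging the members at the recursion boundary. Fleets are
terminal consumers in $\phi$ but contribute no production to either
denominator.

# Uncertainty and comparison tests

Pedigree CVs express data quality per parameter and per diet cell; the
conventional classes 0.1 / 0.5 / 0.8 map from well-sampled to poorly
sampled diets. `drawEnsemble` resamples every CV-flagged quantity from
$\mathcal{N}(\text{base},\ (cv \cdot |\text{base}|)^2)$, truncates negatives
to zero, renormalizes diet columns, and recomputes everything downstream per
draw. Sampling is applied at the *parameter* level (biomass, $P/B$, $Q/B$,
$AE$, diet cells) rather than directly to production-fate elements: fate
fractions are derived quantities, and perturbing them directly would not
yield a re-derivable model. A lognormal option (`sampling = "lognormal"`,
matched in mean and CV) avoids the truncation bias entirely for workflows
that prefer it. Assimilation efficiency is clipped to $[0,1]$ and $P/B$
capped at $AE \cdot Q/B$ where a joint draw would break thermodynamics;
both events are rare at the CV magnitudes above. Note that an individual
draw may legitimately be unbalanced ($EE > 1$) — that is the uncertainty
being propagated — so fate matrices are only defined for balanced draws.

Defaults follow the study design: 1000 draws for footprint/reach
distributions, 100 for network-metric comparisons. Differences between two
ensembles are tested per metric with Welch's unequal-variance $t$
(the fractional degrees of freedom in the published comparison tables
identify the Welch form), corrected with a conservative Bonferroni factor
equal to the family size — all focal groups $\times$ both metrics when
comparing footprint/reach tables. A summary-statistics Welch form
(`welchTTestStats`) recomputes published table rows from printed
mean/SD/$N$.

# Harmonization, pruning, and the difference network

Comparing two independently built models requires a common group list:
`harmonizeModels` aggregates groups under an explicit mapping — diets
combined as biomass-weighted means of member columns, prey rows summed,
biomasses summed, rates biomass-weighted — then inserts any group present
in only one model into the other at a trace biomass of $10^{-5}$, small
enough to leave mass balance untouched while keeping node sets identical.
When a later model inherits the earlier model's trophic connections,
`pruneCarryoverLinks` removes every diet cell not present in the
period-specific evidence and renormalizes the affected columns (leaving
them unnormalized would break mass balance), reporting exactly what was cut.

The difference network (`differenceNetwork`) reports per-node biomass
multiplication factors — second state over first, so a factor above one is
an increase — and per-edge signed flux deltas (second minus first), on the
shared node ordering. Both the ratio and its log are emitted, since either
may be wanted for scaling node glyphs; the trace biomass doubles as the
floor preventing division by zero for inserted groups.

# Temperature scalings

Two closed forms summarize how warming reshapes turnover and costs. From
the empirical turnover relationship
$P/B = 1.06\, e^{0.018 T} K^{0.75}$, holding the von Bertalanffy parameter
$K$ fixed, the conversion factor between thermal states is
$e^{0.018\,\Delta T}$ — 1.037 for a 2 °C warming, i.e. biomass turns over
3.7 % faster. Metabolic costs scale as $Q_{10}^{\Delta T / 10}$; with the
common general $Q_{10} = 2$, the same warming raises costs by the factor
1.149. `applyTemperatureScenario` applies the first factor to every living
group's $P/B$, recomputes $EE$, and reports — without clipping — the groups
whose assimilation margin cannot absorb the implied metabolic increase.
These are interpretive scalars on a static model, not a dynamic simulation;
factors are printed to three decimals to match conventional reporting while
full precision is kept internally.

# The synthetic generator

`generateWeb` builds balanced models for testing, power analysis, and
pipeline validation. Its defaults mirror the study system's structure:
80 living groups, 3 nutrient pools, 5 detritus pools, 2 fleets; guild
proportions (15 % producers, 30 % herbivores, 30 % omnivores, 25 %
carnivores) chosen to give the familiar bottom-heavy web; log-normal
biomasses declining up the trophic hierarchy; guild-specific $P/B$ ranges
spanning phytoplankton-like (50–150 yr⁻¹) down to top-predator-like
(0.2–2 yr⁻¹) turnover; diet CV classes 0.1 / 0.5 / 0.8 assigned per
consumer column and a conservative 0.1 on group parameters. Guilds feed
strictly downward (producers on nutrient pools only), so generated webs are
acyclic and trophic levels finite — which also makes them ideal substrates
for the path-enumeration oracles in the test suite. Balance is
constructive, not iterative: guild by guild from the bottom up, each prey's
remaining production headroom defines a scale factor
$s_i = \min(1,\ ee_{cap} \cdot \mathrm{Prod}_i / \mathrm{demand}_i)$, and
each consumer's $Q/B$ is multiplied by the minimum $s_i$ over its living
prey, after which every $EE$ is provably below the cap (0.9 by default).
Landings are then drawn inside the residual headroom. A `chain` topology
(each group eating only its predecessor) provides webs with exactly known
trophic levels.

`generateModelPair` applies a recorded perturbation — biomass multipliers,
diet-link removals or additions, an invader inserted the way a bloom-forming
newcomer enters a system — and re-caps $Q/B$ where the edit overdraws a
prey, returning the ground truth so that recovery by the difference network
and the pruning report can be asserted exactly.

What generated webs do *not* emulate: empirically realistic diet-breadth
distributions, cannibalism and mutual-predation loops (exercised instead by
hand-built cyclic fixtures), ontogenetic stanzas, import/export terms, and
any resemblance to a specific region's taxa or parameter values. Passing
tests on synthetic webs therefore demonstrate algorithmic correctness and
invariant preservation, not ecological fidelity of any particular
parameterization.

# Numerical choices

* Normalization invariants (diet columns, fate rows) are enforced at an
  absolute tolerance of $10^{-9}$; drift up to $10^{-6}$ is renormalized
  with a warning, larger drift is an error — except in operations (pruning,
  trace insertion) whose purpose is a large renormalization.
* All linear systems are solved densely (`solve`); the webs in scope are
  below ~100 nodes, where sparse machinery would add dependency weight for
  no gain. Singular systems are reported with the offending groups named.
* Tiny negative round-off in trace solutions is clipped to $[0, 1]$.
* One top-level seed expands to per-stage seeds as
  `seed * 100 + offset` (bootstrap A/B = 1/2, Monte Carlo A/B = 3/4), so any
  stage can be reproduced in isolation.
* Tests run the property suites at 4–20 living groups — large enough to
  exercise every guild interaction, small enough that the brute-force
  oracles (path enumeration, power series) remain exact and fast — with the
  default 80-group structure checked separately for balance and structure.

# A worked comparison

```{r example, eval = FALSE}
sp <- syntheticWebSpec(nLiving = 20, seed = 1)
pair <- generateModelPair(
  sp, list(invader = list(name = "pyrosome", biomass = 2,
                          pb = 10, qb = 30, ae = 0.7,
                          diet = setNames(1, 1))), seed = 1)

res <- runPipeline(
  list(seed = 1, monteCarloN = 200, bootstrapN = 100,
       focals = list(pyrosome = "pyrosome"),
       temperature = list(tBefore = 10, tAfter = 12, q10 = 2),
       outDir = "comparison-out"),
  modelA = pair$before, modelB = pair$after)

res$metrics                  # Table-style network metrics per model
res$tests                    # Welch/Bonferroni footprint-reach comparisons
head(res$difference$nodes)   # biomass factors (invader tops the ranking)
res$temperature$pbFactor     # 1.0367; metabolicFactor 1.1487
```

# Limitations

Static steady-state snapshots cannot resolve transient dynamics between the
two states; the temperature factors are interpretive, not mechanistic
forcing; harmonization quality is bounded by the user-supplied group
mapping; and the Monte Carlo treats parameters as independent
normals/lognormals, ignoring covariance among diet cells beyond the
renormalization constraint. The fate of energy routed through detritus is
deliberately outside footprint/reach — analyses of detrital recycling need
a different tracer.
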