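# trophicflux

Energy-flux comparison of mass-balanced food-web models across two
ecosystem states.

Ecosystem modellers often hold two static, steady-state snapshots of the
same system — for example one parameterized before and one after a
multi-year marine heatwave — and need to say, quantitatively, what changed:
which groups now move more or less energy, whether the web's structure
(trophic levels, connectance, link density) shifted, and whether those
shifts survive the parameter uncertainty inherited from surveys and diet
databases. `trophicflux` is for researchers doing exactly that with
Ecopath-style models: it provides the containers, the flux accounting, the
network and trophic-tracing metrics, the Monte Carlo uncertainty machinery
and the comparison statistics as one tested pipeline.

## What it computes

A model holds functional groups (living, nutrient pools, detritus pools,
fleets) with biomass $B$, production $P/B$, consumption $Q/B$, assimilation
efficiency $AE$, a diet matrix $DC$ (columns sum to 1) and landings $Y$.
The core quantities:

* **Ecotrophic efficiency** from the mass-balance master equation
  $B_i (P/B)_i\, EE_i = \sum_j B_j (Q/B)_j DC_{ij} + \sum_f Y_{if}$;
  balanced means all $EE \le 1$.
* **Consumption-flux network** $q_{i \to j} = B_j (Q/B)_j DC_{ij}$ (fleet
  edges carry landings) and the **production-fate matrix** splitting each
  group's consumption into egestion, metabolism, predation and senescence —
  rows sum to 1 exactly.
* **Network metrics**: diet-weighted trophic levels solved as
  $(I - DC^\top) TL = \mathbf{1}$ (cycles handled), connectance
  $= \text{links}/N^2$ and link density $= \text{links}/N$ over a
  nutrient-free node set, with node-bootstrap uncertainty.
* **Footprint and reach**: the fraction of every group's production
  destined for a focal group, and the fraction of every consumer's
  production that passed through it, via all direct and indirect living
  pathways (detritus excluded), aggregated production-weighted into two
  numbers in [0, 1].
* **Monte Carlo pedigree uncertainty**: every CV-flagged parameter and diet
  cell resampled per draw (normal truncated at 0, or lognormal), diet
  columns renormalized, metrics recomputed; ensembles compared metric-wise
  with Welch *t*-tests and Bonferroni correction.
* **Model comparison**: harmonization onto a common group set (aggregation
  by biomass-weighted diets, trace insertion at 1e-5), pruning of
  carried-over diet links not present in period evidence, and the
  difference network of node biomass factors and signed edge-flux deltas.
* **Temperature scalings**: $P/B$ factor $e^{0.018\,\Delta T}$ (1.037 for
  +2 °C) and metabolic factor $Q_{10}^{\Delta T/10}$ (1.149 for
  $Q_{10} = 2$, +2 °C).

A seeded synthetic-web generator (`generateWeb`, `generateModelPair`)
produces balanced webs with the study system's structure (80 living groups,
3 nutrient pools, 5 detritus pools, 2 fleets; pedigree CV classes
0.1/0.5/0.8) and before/after pairs with recorded ground-truth edits for
end-to-end validation.

## Worked example

A 20-group web is perturbed by inserting an invading gelatinous grazer
("pyrosome") at biomass 2 eating the first producer, and the full pipeline
compares the pair:

```r
library(trophicflux)
sp <- syntheticWebSpec(nLiving = 20, seed = 1)
pair <- generateModelPair(
  sp, list(invader = list(name = "pyrosome", biomass = 2, pb = 10,
                          qb = 30, ae = 0.7, diet = setNames(1, 1))),
  seed = 1)
res <- runPipeline(
  list(seed = 1, monteCarloN = 200, bootstrapN = 100,
       focals = list(pyrosome = "pyrosome"),
       temperature = list(tBefore = 10, tAfter = 12, q10 = 2)),
  modelA = pair$before, modelB = pair$after)
```

`res$metrics` — structural metrics per state (28 analyzed nodes: 21 living
+ 5 detritus + 2 fleets; the invader is trace-inserted into the "before"
model during harmonization, so counts match):

```
  model n_nodes n_links mean_tl biomass_weighted_tl connectance link_density
1     A      28      88   2.171               1.396      0.1122        3.143
2     B      28      88   2.171               1.412      0.1122        3.143
```

`res$tests` — the invader's footprint rises from effectively zero (trace)
to 2.6 % of system production, its reach to 6.6 % of consumer production,
both overwhelmingly significant across 200 Monte Carlo draws per state:

```
              metric    meanA  meanB    t  df p_adjusted significant
1 pyrosome.footprint 1.32e-07 0.0264 -192 199  1.52e-227        TRUE
2     pyrosome.reach 3.53e-07 0.0658 -222 199  4.13e-240        TRUE
```

`res$difference$nodes` ranked by biomass factor — the injected invader
tops the ranking at exactly biomass / trace = 2 / 1e-5:

```
   id        name factor logFactor
31 31    pyrosome  2e+05     12.21
1   1 producer_01  1e+00      0.00
```

`res$temperature` reports the two closed-form factors for the +2 °C
scenario: `pbFactor` 1.0367 (biomass turnover +3.7 %) and
`metabolicFactor` 1.1487 (metabolic costs +14.9 %).

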