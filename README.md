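# latticepop

Discrete-generation metapopulation simulation on a resource-limited cell
lattice.

`latticepop` is for ecologists and modellers who want to ask how *dispersal
strategies* — uniform, locally random, globally aggregated, gregarious —
shape the fate of interacting populations: the efficiency of habitat use,
the stability of predator–prey and brood-parasite systems, and the
coexistence of many competitors on one resource (the paradox of the
plankton).

## The model

A habitat is a ring of `m` cells, each renewing `R` discrete resource units
per generation.  Species are defined by an initial population, a
Hamilton-style fecundity pair — `DirectOffspring` `f` (offspring when
unassociated) and `IndirectOffspring` `g` (the fecundity effect conferred
on an associated partner) — a dispersal strategy, and a per-organism
resource need.  Every generation, in each cell:

1. occupants compete for resources in a uniformly random order (with unit
   needs: `min(occupants, R)` survivors, drawn hypergeometrically);
2. interaction rules pair survivors one-to-one (`min` matching, rules in
   order);
3. an unpaired organism leaves `f` offspring, a paired one
   `max(0, f + g_partner)` — so a brood parasite `(0, −2)` in a host's
   `(2, 2)` nest fledges 2 while the host fledges 0;
4. offspring disperse by their species' strategy (`<prefix><kind>`):
   * `n` — one by one into a window of radius `round(prefix/100·m)` around
     the natal cell (`0n` stay home, `100n` uniform over the lattice);
   * `r` — the global pool splits into an even share (weight
     `1 − prefix/100`) plus an aggregated share allocated as random-sized
     groups (spacings of sorted uniforms) on random cells, giving the
     positively skewed, negative-binomial-like profile of aggregated
     counts;
   * `h` — gregarious: `prefix`% of cells are left empty and the rest get
     the fully aggregated allocation.

The package also provides the one-sided Chebyshev ceiling on exclusion
probability, `q·σ²/(μ−κ)²`, quantifying why aggregation is inefficient:
variance sends organisms past the per-cell capacity `κ`.

## A worked example

The classic efficiency contrast: one self-replicating prey (`f = 3`,
conferring 2 on an associated predator) and one specialist predator
(`(0, −3)`: hunted prey leave nothing) on 100 cells × 120 resources —
a carrying capacity of 12,000 organisms.

```r
library(latticepop)

cfg <- scenario_config(
  habitat = habitat_spec(100, 120, default_dispersal = "100n"),
  species = list(species_spec("prey", 1000, 3, 2),
                 species_spec("predator", 100, 0, -3)),
  interactions = list(interaction_rule("predator", "prey")),
  generations = 300, seed = 1)

res <- run_simulation(cfg)
res
#> <sim_result> 2 species, 300 generations
#>   final totals: prey=12000, predator=0
#>   final richness: 1
tail_mean(res, "prey")
#> [1] 12000
```

Under uniform dispersal (`100n`) the predator starves out and the prey
fills the habitat exactly to capacity: 12,000.  Switch both species to
aggregated dispersal:

```r
cfg_r <- scenario_config(
  habitat = habitat_spec(100, 120, default_dispersal = "100r"),
  species = list(species_spec("prey", 1000, 3, 2),
                 species_spec("predator", 100, 0, -3)),
  interactions = cfg$interactions,
  generations = 300, seed = 1)
res_r <- run_simulation(cfg_r)
round(c(prey = tail_mean(res_r, "prey"),
        predator = tail_mean(res_r, "predator")))
#>     prey predator 
#>     8259     1871
```

Same capacity, but spatial variance now wastes part of every generation —
the standing prey population settles near 8,300 — and the predator
persists, because aggregation leaves predator-free patches where prey
recover.  Inefficiency and stabilisation are two faces of the same
variance.

Ready-made reconstructions of classic experiments (predator–prey
efficiency, cuckoo/warbler brood parasitism, multi-species fecundity
ladders, habitat fragmentation, competitive-exclusion rescue, specialist
predators) are available through `scenario_fixture()`; see
`list_fixtures()` and the methods vignette
(`vignettes/lattice-population-dynamics.Rmd`).

A small CLI wraps the same functions:

```sh
Rscript inst/cli/latticepop run --fixture 1Para.sim3 --seed 7 --out out/
Rscript inst/cli/latticepop sweep --fixture 1Plank4.sim3 \
    --parameter prefix --values 1,20,40,60,80,100 --out sweep.csv
```

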