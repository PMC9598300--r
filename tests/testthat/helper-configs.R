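# shared helpers: tiny configs and summary statistics

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
}

# one self-replicating species, ample or tight resources
mono_config <- function(direct = 2, dispersal = "100n", cells = 20,
                        resources = 30, n0 = 100, generations = 10,
                        seed = 1) {
  scenario_config(
    habitat = habitat_spec(cells, resources, dispersal),
    species = list(species_spec("sp", n0, direct, 0)),
    generations = generations, seed = seed)
}

# cuckoo/warbler pair with the classic fecundities
parasite_config <- function(dispersal_cuckoo = "100r",
                            dispersal_warbler = "100r",
                            cells = 100, resources = 25,
                            generations = 50, seed = 1) {
  scenario_config(
    habitat = habitat_spec(cells, resources),
    species = list(
      species_spec("warbler", 200, 2, 2, dispersal = dispersal_warbler),
      species_spec("cuckoo", 20, 0, -2, dispersal = dispersal_cuckoo)),
    interactions = list(interaction_rule("cuckoo", "warbler")),
    generations = generations, seed = seed)
}
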