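test_that("competition caps survivors at the cell's resources", {
  set.seed(1)
  res <- compete(c(a = 40L), 25)
  expect_identical(unname(res$survivors), 25L)
  expect_identical(unname(res$deaths), 15L)

  under <- compete(c(a = 10L, b = 5L), 25)
  expect_identical(sum(under$deaths), 0L)
  expect_identical(under$resources_left, 10L)

  # multi-species survivors are multivariate-hypergeometric: check the
  # marginal mean and variance for one species against theory
  draws <- replicate(2000, compete(c(a = 30L, b = 10L), 20)$survivors[["a"]])
  N <- 40; K <- 30; k <- 20
  expect_equal(mean(draws), k * K / N, tolerance = 0.02)
  v_theory <- k * (K / N) * (1 - K / N) * (N - k) / (N - 1)
  expect_equal(var(draws), v_theory, tolerance = 0.1)
})

test_that("unequal needs produce the small-portion effect", {
  # needs 5 and 1 with 7 resources: both survive in either processing order
  set.seed(2)
  for (rep in 1:20) {
    res <- compete(c(big = 1L, small = 1L), 7, needs = c(5L, 1L))
    expect_identical(unname(res$survivors), c(1L, 1L))
  }
  # needs 5 and 5 with 7 resources: exactly one survives, order decides which
  who <- replicate(200, {
    s <- compete(c(big = 1L, other = 1L), 7, needs = c(5L, 5L))$survivors
    expect_identical(sum(s), 1L)
    which(s == 1L)
  })
  expect_gt(mean(who == 1), 0.35)  # both orders occur
  expect_lt(mean(who == 1), 0.65)
  # leftovers below the big species' need still feed the small species
  set.seed(3)
  res <- compete(c(big = 2L, small = 3L), 13, needs = c(5L, 1L))
  expect_identical(sum(res$survivors * c(5L, 1L)) <= 13, TRUE)
  expect_gte(res$survivors[["small"]], 1L)
})

test_that("pair formation follows min-matching with sequential depletion", {
  rules <- list(interaction_rule("cuckoo", "warbler"))
  pr <- form_pairs(c(cuckoo = 3L, warbler = 5L), rules)
  expect_identical(pr$pairs, 3L)
  expect_identical(pr$unpaired, c(cuckoo = 0L, warbler = 2L))

  pr0 <- form_pairs(c(pred = 0L, prey = 7L),
                    list(interaction_rule("pred", "prey")))
  expect_identical(pr0$pairs, 0L)
  expect_identical(pr0$unpaired[["prey"]], 7L)

  # chain A-B then B-C with counts (2, 3, 4): 2 pairs, then min(1, 4) = 1
  chain <- list(interaction_rule("A", "B"), interaction_rule("B", "C"))
  pr2 <- form_pairs(c(A = 2L, B = 3L, C = 4L), chain)
  expect_identical(pr2$pairs, c(2L, 1L))
  expect_identical(pr2$unpaired, c(A = 0L, B = 0L, C = 3L))
})

test_that("realized offspring reproduces the brood-parasite worked example", {
  warbler <- species_spec("warbler", 10, 2, 2)
  cuckoo <- species_spec("cuckoo", 10, 0, -2)
  expect_identical(realized_offspring(warbler), 2L)            # unparasitised
  expect_identical(realized_offspring(cuckoo, warbler), 2L)    # 0 + 2
  expect_identical(realized_offspring(warbler, cuckoo), 0L)    # 2 - 2
  neutral <- species_spec("n", 1, 0, 0)
  expect_identical(realized_offspring(warbler, neutral), 2L)
  expect_identical(realized_offspring(neutral, cuckoo), 0L)    # clamped at 0
  obligate <- species_spec("o", 1, 3, 0, requires_partner = TRUE)
  expect_identical(realized_offspring(obligate), 0L)
  expect_identical(realized_offspring(obligate, warbler), 5L)
  # rule-level override beats the partner's species-level indirect
  expect_identical(realized_offspring(warbler, warbler, effect = -1L), 1L)
})

test_that("the generation step has absorbing zero and replacement equilibria", {
  cfg <- mono_config(direct = 1, dispersal = "100n", generations = 5)
  st0 <- population_state(matrix(0L, 20, 1, dimnames = list(NULL, "sp")))
  out <- step(st0, cfg)
  expect_identical(sum(out$state$counts), 0L)

  # replacement reproduction with ample capacity: totals constant
  set.seed(4)
  r <- run_simulation(cfg)
  expect_true(all(r$totals == 100L))
})

test_that("uniform dispersal fills the habitat to carrying capacity", {
  cfg <- mono_config(direct = 3, dispersal = "100n", cells = 100,
                     resources = 120, n0 = 1000, generations = 15, seed = 1)
  r <- run_simulation(cfg)
  expect_identical(unname(r$totals[16, "sp"]), 12000L)
  expect_true(all(r$totals[8:16, "sp"] == 12000L))
})

test_that("predator-prey pairing semantics match the hunt rule", {
  # one cell, no movement (0n), ample resources: deterministic offspring
  cfg <- scenario_config(
    habitat = habitat_spec(1, 1000, "0n"),
    species = list(species_spec("prey", 3, 2, 2, dispersal = "0n"),
                   species_spec("pred", 2, 0, -2, dispersal = "0n")),
    interactions = list(interaction_rule("pred", "prey")),
    generations = 1)
  st <- initial_state(cfg)
  out <- step(st, cfg)
  # 2 pairs: hunted prey leave nothing, predators gain 2 each,
  # the single unpaired prey leaves 2
  expect_identical(unname(out$record$pairs), 2L)
  expect_identical(unname(out$record$offspring), c(2L, 4L))
  expect_identical(unname(out$state$counts[1, ]), c(2L, 4L))
})

test_that("simulations are bit-identical under a fixed seed", {
  cfg <- parasite_config(generations = 30)
  r1 <- run_simulation(cfg, seed = 99)
  r2 <- run_simulation(cfg, seed = 99)
  expect_identical(r1$totals, r2$totals)
  expect_identical(r1$extinctions, r2$extinctions)
})

test_that("the count-based engine matches the individual-based oracle", {
  # deterministic instance: 0n dispersal, under-capacity, pairing saturated
  cfg <- scenario_config(
    habitat = habitat_spec(4, 100, "0n"),
    species = list(species_spec("host", 8, 2, 1, dispersal = "0n"),
                   species_spec("guest", 4, 1, -1, dispersal = "0n")),
    interactions = list(interaction_rule("guest", "host")),
    generations = 1)
  counts <- matrix(c(3L, 3L, 1L, 1L, 2L, 0L, 1L, 1L), nrow = 4,
                   dimnames = list(NULL, c("host", "guest")))
  eng_out <- step(population_state(counts), cfg)
  set.seed(1)
  ref_out <- step_reference(counts, cfg)
  expect_identical(unclass(eng_out$state$counts), unclass(ref_out$counts))

  # stochastic instance: compare survivor distributions over replicates
  cfg2 <- scenario_config(
    habitat = habitat_spec(3, 4, "0n"),
    species = list(species_spec("a", 6, 1, 0, dispersal = "0n"),
                   species_spec("b", 6, 1, 0, dispersal = "0n")),
    generations = 1)
  counts2 <- matrix(c(3L, 2L, 1L, 2L, 3L, 1L), nrow = 3,
                    dimnames = list(NULL, c("a", "b")))
  set.seed(5)
  eng_draws <- replicate(800, step(population_state(counts2),
                                   cfg2)$record$survivors["a"])
  ref_draws <- replicate(800, step_reference(counts2, cfg2)$survivors[1])
  expect_equal(mean(eng_draws), mean(ref_draws), tolerance = 0.03)
  tab <- rbind(tabulate(eng_draws + 1L, 7), tabulate(ref_draws + 1L, 7))
  keep <- colSums(tab) > 0
  tst <- suppressWarnings(stats::chisq.test(tab[, keep]))
  expect_gt(tst$p.value, 0.01)
})

test_that("within a generation deaths + survivors equal occupants", {
  cfg <- parasite_config(cells = 10, generations = 1, seed = 8)
  set.seed(8)
  st <- initial_state(cfg)
  out <- step(st, cfg)
  occupants <- colSums(st$counts)
  storage.mode(occupants) <- "integer"
  expect_identical(out$record$survivors + out$record$deaths, occupants)
  # resource law: survivors never exceed total resources
  expect_lte(sum(out$record$survivors), 10 * 25)
})
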