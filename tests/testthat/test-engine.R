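test_that("run_simulation honours the horizon and records provenance", {
  cfg <- mono_config(generations = 1, seed = 3)
  r <- run_simulation(cfg)
  expect_identical(nrow(r$totals), 2L)
  expect_identical(r$seed, 3L)
  expect_match(r$config_digest, "^[0-9a-f]{32}$")

  # extinction bookkeeping: a species at zero stays at zero
  cfg2 <- scenario_config(
    habitat = habitat_spec(10, 5, "100n"),
    species = list(species_spec("doomed", 10, 0, 0)),
    generations = 10, seed = 1)
  r2 <- run_simulation(cfg2)
  # generation 1 still has (capacity-limited) adults; generation 2 is empty
  expect_identical(unname(r2$extinctions["doomed"]), 2L)
  expect_true(all(r2$totals[-(1:2), "doomed"] == 0L))
  expect_identical(r2$richness[nrow(r2$totals)], 0L)
})

test_that("cell statistics are recorded when requested", {
  cfg <- mono_config(generations = 3, seed = 2)
  cfg$record_cell_stats <- TRUE
  r <- run_simulation(cfg)
  cs <- r$cell_stats
  expect_s3_class(cs, "data.frame")
  expect_setequal(names(cs), c("generation", "species", "sigma",
                               "max_density", "empty_cells", "deaths"))
  expect_identical(nrow(cs), 3L)
})

test_that("the Chebyshev exclusion ceiling follows the closed form", {
  expect_identical(chebyshev_bound(mu = 10, sigma2 = 0, kappa = 5), 0)
  expect_equal(chebyshev_bound(mu = 20, sigma2 = 4, kappa = 16, q = 1 / 2),
               0.125)
  # symmetric case: q = 1/2 is half the two-sided ceiling
  expect_equal(chebyshev_bound(10, 9, 7, q = 1 / 2),
               chebyshev_bound(10, 9, 7, q = 1) / 2)
  expect_error(chebyshev_bound(5, 1, 5), "undefined")
  expect_equal(chebyshev_bound(4, 100, 2, q = 1, clip = TRUE), 1)
})

test_that("estimate_q is a tail share in [0, 1] and 1/2 for symmetry", {
  set.seed(6)
  x <- rep(c(0, 10, 20), times = c(5, 20, 5))  # symmetric around 10
  expect_equal(estimate_q(x, kappa = 5), 0.5)
  agg <- disperse_r(5000, 200, 100)
  q <- estimate_q(agg, kappa = 10)
  expect_gte(q, 0)
  expect_lte(q, 1)
  expect_error(estimate_q(rep(5, 3), kappa = 5), "undefined")
})

test_that("exclusion frequency matches an enumeration oracle", {
  # uniform under capacity: nothing dies
  expect_identical(
    exclusion_frequency(function() disperse_r(100, 10, 0), 25, 10L), 0)

  # enumeration: feed every composition of 6 organisms into 3 cells once;
  # the function's average must equal the hand-computed mean overflow
  comps <- list()
  for (a in 0:6) for (b in 0:(6 - a)) comps[[length(comps) + 1]] <-
    c(a, b, 6 - a - b)
  i <- 0
  sampler <- function() { i <<- i + 1; comps[[i]] }
  freq <- exclusion_frequency(sampler, capacity = 2,
                              replicates = length(comps))
  oracle <- mean(vapply(comps, function(x) sum(pmax(0, x - 2)) / 6, 0))
  expect_equal(freq, oracle)

  # aggregation is less efficient than uniformity at matched capacity
  set.seed(10)
  f_unif <- exclusion_frequency(function() disperse_r(2000, 100, 0), 25, 50L)
  f_agg <- exclusion_frequency(function() disperse_r(2000, 100, 100), 25, 50L)
  expect_gt(f_agg, f_unif)
})

test_that("empirical exclusion never exceeds the Chebyshev ceiling", {
  set.seed(12)
  total <- 2000; m <- 100; cap <- 25
  samplers <- list(
    r0   = function() disperse_r(total, m, 0),
    r50  = function() disperse_r(total, m, 50),
    r100 = function() disperse_r(total, m, 100),
    n100 = function() disperse_n(rep.int(total %/% m, m), 100),
    h40  = function() disperse_h(total, m, 40))
  for (nm in names(samplers)) {
    pool <- do.call(cbind, replicate(200, samplers[[nm]](), simplify = FALSE))
    freq <- sum(pmax(0, pool - cap)) / sum(pool)
    mu <- mean(pool); s2 <- stats::var(as.vector(pool))
    if (mu == cap || s2 == 0) {
      expect_identical(freq, 0, label = nm)
    } else {
      q <- estimate_q(as.vector(pool), cap)
      bound <- chebyshev_bound(mu, s2, cap, q = max(q, 1e-3))
      expect_lte(freq, bound + 1e-9, label = nm)
    }
  }
})

test_that("uniform dispersal sustains a larger equilibrium than aggregated", {
  tails <- vapply(1:20, function(s) {
    cfg_n <- mono_config(direct = 2, dispersal = "100n", cells = 50,
                         resources = 40, n0 = 500, generations = 60, seed = s)
    cfg_r <- mono_config(direct = 2, dispersal = "100r", cells = 50,
                         resources = 40, n0 = 500, generations = 60, seed = s)
    c(tail_mean(run_simulation(cfg_n), "sp"),
      tail_mean(run_simulation(cfg_r), "sp"))
  }, c(n = 0, r = 0))
  expect_true(all(tails["n", ] >= tails["r", ]))
})

test_that("summaries and CSV writers emit the documented schemas", {
  cfg <- parasite_config(generations = 10, seed = 4)
  r <- run_simulation(cfg)
  s <- summarize_result(r)
  expect_setequal(names(s$totals), c("generation", "species", "count"))
  expect_identical(nrow(s$totals), 2L * nrow(r$totals))
  expect_setequal(names(s$extinctions), c("species", "extinct_generation"))
  expect_identical(s$richness$richness, r$richness)

  dir <- withr::local_tempdir()
  write_result(r, dir)
  expect_true(all(file.exists(file.path(dir,
    c("totals.csv", "richness.csv", "extinctions.csv", "manifest.json")))))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_identical(man$config_digest, r$config_digest)
  back <- utils::read.csv(file.path(dir, "totals.csv"))
  expect_identical(nrow(back), nrow(s$totals))
})
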