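test_that("all dispersal operators conserve the total exactly", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(2:200, 1)
    total <- sample(0:50000, 1)
    p <- sample(0:100, 1)
    expect_identical(sum(disperse_r(total, m, p)), as.integer(total))
    counts <- disperse_r(total, m, 100)
    expect_identical(sum(disperse_n(counts, p)), as.integer(total))
    if (p < 100)
      expect_identical(sum(disperse_h(total, m, p)), as.integer(total))
    cc <- runif(1, 0.05, 1)
    expect_identical(sum(disperse_r(total, m, p, clump_cells = cc)),
                     as.integer(total))
  }
})

test_that("neighbourhood dispersal respects the window radius", {
  # prefix 0: offspring stay in their natal cell
  x <- c(0L, 7L, 0L, 0L, 3L)
  expect_identical(disperse_n(x, 0), x)

  # 6% of 50 cells -> radius 3: a point source spreads over 7 cells at most
  set.seed(1)
  for (rep in 1:10) {
    y <- integer(50); y[26] <- 500L
    out <- disperse_n(y, 6)
    expect_true(all(which(out > 0) %in% 23:29))
  }

  # non-wrapping lattice truncates the window at the edges
  set.seed(2)
  z <- integer(10); z[1] <- 100L
  out <- disperse_n(z, 20, wrap = FALSE)   # radius 2
  expect_true(all(which(out > 0) %in% 1:3))
})

test_that("full-window neighbourhood dispersal matches a uniform multinomial", {
  set.seed(7)
  m <- 50
  N <- 1e5
  out <- disperse_n(rep.int(N %/% m, m), 100)
  # oracle: a direct uniform multinomial sample, same N and m
  oracle <- as.integer(stats::rmultinom(1, N, rep(1 / m, m)))
  tst <- suppressWarnings(stats::chisq.test(rbind(out, oracle)))
  expect_gt(tst$p.value, 0.01)
  # and against the theoretical uniform directly
  gof <- stats::chisq.test(out, p = rep(1 / m, m))
  expect_gt(gof$p.value, 0.01)
})

test_that("aggregated dispersal at prefix 0 spreads the average exactly", {
  expect_identical(disperse_r(1000, 50, 0), rep.int(20L, 50))
})

test_that("per-cell skewness of the dense aggregated kernel is exponential-like", {
  set.seed(11)
  sk <- replicate(100, sample_skewness(disperse_r(5e6, 2000, 100)))
  expect_gte(mean(sk >= 1.6 & sk <= 2.4), 0.95)
  expect_gt(mean(sk), 1.8)
  expect_lt(mean(sk), 2.2)
})

test_that("aggregation (sigma) increases monotonically with the r prefix", {
  set.seed(5)
  sigmas <- vapply(c(0, 25, 50, 75, 100), function(p)
    mean(replicate(200, stats::sd(disperse_r(20000, 100, p)))), 0)
  expect_true(all(diff(sigmas) > 0))
})

test_that("repeated neighbourhood dispersal smooths towards uniformity", {
  set.seed(9)
  sig <- replicate(30, {
    x <- integer(50); x[seq(5, 50, 10)] <- 200L   # five equidistant towers
    vapply(1:8, function(g) { x <<- disperse_n(x, 6); stats::sd(x) }, 0)
  })
  avg <- rowMeans(sig)
  # strong early smoothing, and no later re-clumping beyond noise
  expect_true(all(diff(avg[1:4]) < 0))
  expect_lt(avg[8], 0.5 * avg[1])
  expect_true(all(diff(avg) < 1))
})

test_that("gregarious dispersal empties exactly the prefixed share of cells", {
  set.seed(3)
  empties <- replicate(100, sum(disperse_h(5e5, 50, 40) == 0))
  expect_true(all(empties >= 20))
  expect_gte(mean(empties == 20), 0.95)
  expect_error(disperse_h(10, 50, 100), "no cell available")
  expect_identical(disperse_h(0, 50, 100), integer(50))
})

test_that("gregarious dispersal at prefix 0 matches fully aggregated r", {
  set.seed(13)
  a <- as.vector(replicate(40, disperse_h(5000, 40, 0)))
  b <- as.vector(replicate(40, disperse_r(5000, 40, 100)))
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(a), mean(b), tolerance = 0.05)
})

test_that("allocation_stats matches brute-force diagnostics", {
  counts <- c(40L, 10L, 0L, 25L, 3L)
  st <- allocation_stats(counts, 25)
  expect_identical(st$to_die, 15L)         # one cell of 40 over capacity 25
  expect_identical(st$empty_cells, 1L)
  expect_identical(st$max_density, 40L)
  expect_equal(st$sigma, stats::sd(counts))

  set.seed(21)
  for (rep in 1:10) {
    x <- disperse_r(5000, 30, 100)
    cap <- sample(10:300, 30, replace = TRUE)
    brute <- sum(vapply(seq_along(x), function(i) max(0L, x[i] - cap[i]), 0L))
    expect_identical(allocation_stats(x, cap)$to_die, brute)
  }

  uni <- allocation_stats(rep.int(10L, 6), 12)
  expect_identical(uni$sigma, 0)
  expect_identical(uni$to_die, 0L)
  expect_identical(uni$empty_cells, 0L)
})

test_that("organisms excluded (to_die) increase with sigma across strategies", {
  set.seed(17)
  total <- 2000; m <- 100; cap <- 25
  stats_for <- function(f) {
    reps <- replicate(200, {
      x <- f()
      c(stats::sd(x), sum(pmax(0, x - cap)))
    })
    rowMeans(reps)
  }
  uniform <- stats_for(function() disperse_r(total, m, 0))
  local_u <- stats_for(function() disperse_n(rep.int(total %/% m, m), 100))
  agg     <- stats_for(function() disperse_r(total, m, 100))
  greg    <- stats_for(function() disperse_h(total, m, 40))
  ord <- order(c(uniform[1], local_u[1], agg[1], greg[1]))
  deaths <- c(uniform[2], local_u[2], agg[2], greg[2])
  expect_true(all(diff(deaths[ord]) >= 0))
})
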