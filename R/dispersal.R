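#' Dispersal operators
#'
#' The three offspring-dispersal strategies, each an allocation operator over
#' the cell lattice that conserves the total count exactly.
#'
#' `disperse_n()` is the local strategy: each organism in cell `i` moves to a
#' uniformly random cell within the window of radius
#' `rho = round(prefix/100 * number_of_cells)` centred on `i` (origin cell
#' included).  With `prefix = 0` offspring stay in their natal cell; with
#' `prefix = 100` the window covers the lattice and the allocation is a
#' single uniform multinomial.  Iterating the operator smooths any initial
#' clumping towards uniformity.
#'
#' `disperse_r()` is the global aggregated strategy: the pool is reallocated
#' in groups of random size without regard to cell of origin.  A share
#' `prefix/100` of the pool is aggregated, the rest is spread evenly (so `0r`
#' places the average in every cell and the variance grows with the prefix).
#' The aggregated share is split into `n_g = round(clump_cells * m)` groups
#' whose sizes are the spacings of `n_g` sorted uniforms (the first element
#' plus successive differences, normalised and integerised by
#' largest-remainder rounding); the groups are placed on `n_g` distinct,
#' uniformly random cells.  With the default `clump_cells = 1` every cell
#' receives one spacing-sized group, which yields the near-exponential,
#' positively skewed per-cell profile of classic aggregated counts (the
#' negative-binomial-like shape).  `clump_cells < 1` models colonial or
#' swarm-forming communities whose clumps occupy only that fraction of
#' patches and vacate the rest; because the group count is fixed, clump
#' sizes scale with the species' own abundance, which self-limits dense
#' species and shelters sparse ones.
#'
#' `disperse_h()` is the gregarious strategy, a subtype of `r` at maximum
#' aggregation: a uniformly random set of `floor(prefix/100 * m)` cells is
#' forced empty and the `100r` allocation is applied over the remaining
#' cells, emulating organisms that seek out conspecifics and vacate ground.
#' `0h` coincides with `100r` by construction.
#'
#' All operators draw from R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param counts integer vector of per-cell counts (source allocation).
#' @param prefix integer percentage in `[0, 100]` (see [dispersal_spec()]).
#' @param wrap logical; ring topology (the default) or truncated windows.
#' @param total total number of organisms to allocate.
#' @param number_of_cells number of lattice cells.
#' @param clump_cells fraction in `(0, 1]` of cells that the aggregated
#'   share occupies (habitat trait; 1 = one group per cell).
#' @return an integer vector of per-cell counts summing to the input total.
#' @examples
#' set.seed(1)
#' x <- disperse_r(1000, number_of_cells = 50, prefix = 0)   # 20 everywhere
#' y <- disperse_r(1000, number_of_cells = 50, prefix = 100) # clumped
#' sd(x); sd(y)
#' @name dispersal-operators
NULL

#' @rdname dispersal-operators
#' @export
disperse_n <- function(counts, prefix, wrap = TRUE) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  .check_prefix(prefix)
  m <- length(counts)
  rho <- as.integer(round(prefix / 100 * m))
  cpp_disperse_n(counts, rho, isTRUE(wrap))
}

#' @rdname dispersal-operators
#' @export
disperse_r <- function(total, number_of_cells, prefix, clump_cells = 1) {
  .check_prefix(prefix)
  if (total < 0) stop("total must be >= 0", call. = FALSE)
  if (length(clump_cells) != 1L || is.na(clump_cells) ||
      clump_cells <= 0 || clump_cells > 1)
    stop("clump_cells must be a fraction in (0, 1]", call. = FALSE)
  m <- as.integer(number_of_cells)
  if (m < 1L) stop("number_of_cells must be >= 1", call. = FALSE)
  total <- round(total)
  t_agg <- round(prefix / 100 * total)
  t_unif <- total - t_agg
  out <- rep.int(as.integer(t_unif %/% m), m)
  extra <- as.integer(t_unif %% m)
  if (extra > 0L) {
    idx <- sample.int(m, extra)
    out[idx] <- out[idx] + 1L
  }
  if (t_agg > 0) {
    n_g <- min(m, max(1L, as.integer(round(clump_cells * m))))
    sizes <- cpp_spacing_alloc(as.numeric(t_agg), n_g, 1)
    idx <- if (n_g == m) sample.int(m) else sample.int(m, n_g)
    out[idx] <- out[idx] + sizes
  }
  out
}

#' @rdname dispersal-operators
#' @export
disperse_h <- function(total, number_of_cells, prefix) {
  .check_prefix(prefix)
  if (total < 0) stop("total must be >= 0", call. = FALSE)
  m <- as.integer(number_of_cells)
  n_empty <- as.integer(floor(prefix / 100 * m))
  occupied <- m - n_empty
  if (occupied < 1L) {
    if (total > 0) stop("gregarious dispersal with prefix ", prefix,
                        " leaves no cell available", call. = FALSE)
    return(integer(m))
  }
  alloc <- disperse_r(total, occupied, 100)
  out <- integer(m)
  out[sample.int(m, occupied)] <- alloc
  out
}

.check_prefix <- function(prefix) {
  if (length(prefix) != 1L || is.na(prefix) || prefix < 0 || prefix > 100)
    stop("prefix must be a single percentage in [0, 100]", call. = FALSE)
}

#' Dispatch a dispersal step for one species
#'
#' The `n` strategy operates cell by cell on the source allocation; `r` and
#' `h` reallocate the species' global pool.
#'
#' @param counts per-cell offspring counts before dispersal.
#' @param spec a [dispersal_spec()].
#' @param wrap ring topology flag (from the habitat).
#' @param clump_cells habitat clump-occupancy fraction for the `r` strategy.
#' @return dispersed per-cell counts (same total).
#' @export
disperse <- function(counts, spec, wrap = TRUE, clump_cells = 1) {
  stopifnot(inherits(spec, "dispersal_spec"))
  switch(spec$kind,
         n = disperse_n(counts, spec$prefix, wrap = wrap),
         r = disperse_r(sum(counts), length(counts), spec$prefix, clump_cells),
         h = disperse_h(sum(counts), length(counts), spec$prefix))
}

#' Spatial summary of a cell allocation
#'
#' Reports the diagnostics used throughout to compare strategies: the
#' standard deviation of per-cell counts (aggregation), the maximum cell
#' density, the number of empty cells, and `to_die`, the number of organisms
#' exceeding the per-cell capacity (at unit resource need), i.e.
#' `sum(pmax(0, counts - capacity))`.
#'
#' @param counts integer vector of per-cell counts.
#' @param capacity_per_cell scalar or per-cell vector of capacities.
#' @return a list with elements `sigma`, `max_density`, `empty_cells`,
#'   `to_die`.
#' @export
allocation_stats <- function(counts, capacity_per_cell) {
  capacity <- as.integer(rep_len(capacity_per_cell, length(counts)))
  list(sigma = stats::sd(counts),
       max_density = max(counts),
       empty_cells = sum(counts == 0L),
       to_die = as.integer(sum(pmax(0L, as.integer(counts) - capacity))))
}
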