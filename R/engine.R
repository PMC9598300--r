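#' Run a whole simulation
#'
#' Applies the generation cycle for `generations` steps (or until every
#' species is extinct), recording per-generation population totals and,
#' optionally, per-cell spatial diagnostics.
#'
#' The recorded total for generation `g >= 1` is the number of organisms of
#' that generation that secured resources (the post-competition standing
#' population); row 1 holds the founding populations.  A species is extinct
#' at the first generation with total 0; an extinct species never reappears.
#'
#' @param config a [scenario_config()].
#' @param seed RNG seed; defaults to the seed stored in the config.  `NULL`
#'   leaves the RNG state untouched.
#' @param generations override of the config's horizon.
#' @return an object of class `"sim_result"`: a list with
#'   * `totals`: matrix (generation, species) of population totals, row 1
#'     the founding populations;
#'   * `richness`: integer vector, species with total > 0 per row of `totals`;
#'   * `extinctions`: named integer vector, generation of extinction (`NA` if
#'     the species is alive at the horizon);
#'   * `cell_stats`: per-generation, per-species spatial diagnostics (a long
#'     data.frame), or `NULL` unless `record_cell_stats` was set;
#'   * `seed`, `config`, `config_digest` for provenance.
#' @examples
#' cfg <- scenario_config(
#'   habitat = habitat_spec(20, 30, "100n"),
#'   species = list(species_spec("moss", 100, 2, 0)),
#'   generations = 10, seed = 1)
#' res <- run_simulation(cfg)
#' res$totals[11, ]   # capacity-limited equilibrium: 20 * 30 = 600
#' @export
run_simulation <- function(config, seed = config$seed,
                           generations = config$generations) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  eng <- .engine(config)
  S <- length(eng$ids)
  state <- initial_state(config)
  counts <- state$counts
  totals <- matrix(NA_integer_, nrow = generations + 1L, ncol = S,
                   dimnames = list(NULL, eng$ids))
  totals[1L, ] <- as.integer(colSums(counts))
  cell_stats <- if (config$record_cell_stats)
    vector("list", generations) else NULL
  g_done <- 0L
  for (g in seq_len(generations)) {
    if (all(totals[g, ] == 0L)) break
    res <- .step_engine(counts, eng)
    counts <- res$counts
    totals[g + 1L, ] <- res$survivors
    g_done <- g
    if (config$record_cell_stats) {
      st <- lapply(seq_len(S), function(j) {
        a <- allocation_stats(res$surv_matrix[, j], eng$resources)
        data.frame(generation = g, species = eng$ids[j],
                   sigma = a$sigma, max_density = a$max_density,
                   empty_cells = a$empty_cells, deaths = res$deaths[j])
      })
      cell_stats[[g]] <- do.call(rbind, st)
    }
  }
  totals <- totals[seq_len(g_done + 1L), , drop = FALSE]
  ext <- apply(totals, 2L, function(x) {
    i <- which(x == 0L)
    if (length(i)) i[1L] - 1L else NA_integer_
  })
  structure(list(
    totals = totals,
    richness = as.integer(rowSums(totals > 0L)),
    extinctions = ext,
    cell_stats = if (!is.null(cell_stats)) do.call(rbind, cell_stats),
    seed = if (!is.null(seed)) as.integer(seed),
    config = config,
    config_digest = config_digest(config)),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  G <- nrow(x$totals) - 1L
  cat("<sim_result> ", ncol(x$totals), " species, ", G, " generations\n",
      sep = "")
  cat("  final totals: ",
      paste0(colnames(x$totals), "=", x$totals[G + 1L, ], collapse = ", "),
      "\n  final richness: ", x$richness[G + 1L], "\n", sep = "")
  invisible(x)
}

#' MD5 digest of a configuration's canonical JSON
#' @param config a [scenario_config()].
#' @return a character MD5 string.
#' @export
config_digest <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Tail mean of a species' population total
#'
#' Equilibrium populations are read as the mean total over the last
#' `tail_fraction` of the recorded generations (after the burn-in implied by
#' the rest of the run).
#'
#' @param result a `sim_result`.
#' @param species species id.
#' @param tail_fraction fraction of the series to average over (default the
#'   final third).
#' @export
tail_mean <- function(result, species, tail_fraction = 1 / 3) {
  x <- result$totals[, species]
  n <- length(x)
  from <- max(1L, n - as.integer(ceiling(tail_fraction * n)) + 1L)
  mean(x[from:n])
}

# ---- Chebyshev exclusion bound ---------------------------------------------

#' Chebyshev ceiling on the exclusion probability
#'
#' For a spatial distribution of per-cell density with mean `mu` and variance
#' `sigma2`, and a per-cell carrying capacity `kappa`, the one-sided
#' Chebyshev bound with skewness-dependent tail-share factor `q` is
#' `q * sigma2 / (mu - kappa)^2` — the maximum probability that an organism
#' is excluded from reproduction because its cell exceeds the carrying
#' capacity.  The value is a ceiling, not a probability: it may exceed 1
#' (use `clip = TRUE` for a reporting-friendly value).
#'
#' @param mu mean per-cell density.
#' @param sigma2 per-cell density variance (>= 0).
#' @param kappa average per-cell carrying capacity; must differ from `mu`.
#' @param q tail-share factor in `[0, 1]`; 1/2 for a symmetric distribution,
#'   estimable from data with [estimate_q()].
#' @param clip clip the ceiling at 1?
#' @return a non-negative number.
#' @examples
#' chebyshev_bound(mu = 20, sigma2 = 4, kappa = 16, q = 1 / 2)  # 0.125
#' @export
chebyshev_bound <- function(mu, sigma2, kappa, q = 1 / 2, clip = FALSE) {
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (q < 0) stop("q must be >= 0", call. = FALSE)
  if (mu == kappa)
    stop("bound undefined for mu == kappa", call. = FALSE)
  b <- q * sigma2 / (mu - kappa)^2
  if (clip) min(b, 1) else b
}

#' Estimate the tail-share factor q from an allocation
#'
#' `q` is the share of the two-sided Chebyshev tail mass that sits on the
#' capacity side of the mean, estimated from the empirical per-cell counts
#' at distance `|mu - kappa|`: the realized proportion
#' `P(tail on the kappa side) / P(both tails)`.  This is an estimate; a
#' perfectly symmetric allocation gives 1/2.
#'
#' @param counts per-cell counts (one allocation, or pooled replicates).
#' @param kappa per-cell carrying capacity.
#' @return a number in `[0, 1]` (0 when no mass lies in either tail).
#' @export
estimate_q <- function(counts, kappa) {
  mu <- mean(counts)
  if (mu == kappa)
    stop("q undefined for mu == kappa", call. = FALSE)
  alpha <- abs(mu - kappa)
  lo <- mean(counts <= mu - alpha)
  hi <- mean(counts >= mu + alpha)
  if (lo + hi == 0) return(0)
  if (kappa < mu) lo / (lo + hi) else hi / (lo + hi)
}

#' Monte-Carlo exclusion frequency of a dispersal strategy
#'
#' Estimates the fraction of organisms that land in cells beyond the carrying
#' capacity (deaths / total, at unit resource need), averaged over
#' replicate allocations.
#'
#' @param alloc_sampler a function of no arguments returning a per-cell
#'   allocation (e.g. `function() disperse_r(2000, 100, 100)`).
#' @param capacity per-cell carrying capacity (scalar or vector).
#' @param replicates number of replicate allocations (>= 1).
#' @return the mean exclusion frequency in `[0, 1]`.
#' @export
exclusion_frequency <- function(alloc_sampler, capacity, replicates = 100L) {
  stopifnot(replicates >= 1L)
  freqs <- vapply(seq_len(replicates), function(i) {
    counts <- alloc_sampler()
    tot <- sum(counts)
    if (tot == 0) return(0)
    sum(pmax(0, counts - rep_len(capacity, length(counts)))) / tot
  }, 0)
  mean(freqs)
}

# ---- tidy summaries --------------------------------------------------------

#' Tidy tables from a simulation result
#'
#' @param result a `sim_result`.
#' @return a list of data.frames:
#'   * `totals`: long table (generation, species, count);
#'   * `extinctions`: (species, extinct_generation), `NA` when alive;
#'   * `richness`: (generation, richness);
#'   * `cell_stats`: the recorded spatial diagnostics, or `NULL`.
#' @export
summarize_result <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  G <- nrow(result$totals)
  sp <- colnames(result$totals)
  list(
    totals = data.frame(
      generation = rep(seq_len(G) - 1L, times = length(sp)),
      species = rep(sp, each = G),
      count = as.vector(result$totals)),
    extinctions = data.frame(species = sp,
                             extinct_generation = unname(result$extinctions)),
    richness = data.frame(generation = seq_len(G) - 1L,
                          richness = result$richness),
    cell_stats = result$cell_stats)
}

#' Write the result tables of a run to CSV
#'
#' Writes `totals.csv`, `richness.csv`, `extinctions.csv`, optionally
#' `cellstats.csv`, plus `manifest.json` with the seed and config digest.
#'
#' @param result a `sim_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- summarize_result(result)
  utils::write.csv(s$totals, file.path(dir, "totals.csv"),
                   row.names = FALSE)
  utils::write.csv(s$richness, file.path(dir, "richness.csv"),
                   row.names = FALSE)
  utils::write.csv(s$extinctions, file.path(dir, "extinctions.csv"),
                   row.names = FALSE)
  if (!is.null(s$cell_stats))
    utils::write.csv(s$cell_stats, file.path(dir, "cellstats.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = result$seed, config_digest = result$config_digest,
         generations = nrow(result$totals) - 1L,
         species = colnames(result$totals)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
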