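#' Population state
#'
#' Organism counts per (cell, species) at one generation.  Generations are
#' non-overlapping: the state holds the recruits of the current generation,
#' adults having died after reproducing.
#'
#' @param counts integer matrix, `number_of_cells` rows, one named column per
#'   species.
#' @param generation integer >= 0.
#' @return an object of class `"population_state"`.
#' @export
population_state <- function(counts, generation = 0L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("population counts must be >= 0", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, generation = as.integer(generation)),
            class = "population_state")
}

#' Founding population state for a scenario
#'
#' Species with a global strategy (`r`, `h`) are placed by one application of
#' their own dispersal operator to the initial pool; species with the local
#' `n` strategy are spread evenly across cells (largest-remainder even
#' split), which is the natural "resident" starting point for a local
#' disperser.
#'
#' @param config a [scenario_config()].
#' @return a [population_state()] at generation 0.
#' @export
initial_state <- function(config) {
  m <- config$habitat$number_of_cells
  cc <- config$habitat$clump_cells
  counts <- vapply(config$species, function(s) {
    d <- s$dispersal
    if (d$kind == "n") {
      base <- s$number_of_items %/% m
      extra <- s$number_of_items %% m
      out <- rep.int(base, m)
      if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
      as.integer(out)
    } else {
      switch(d$kind,
             r = disperse_r(s$number_of_items, m, d$prefix,
                            s$clump_cells %||% cc),
             h = disperse_h(s$number_of_items, m, d$prefix))
    }
  }, integer(m))
  counts <- matrix(counts, nrow = m,
                   dimnames = list(NULL, names(config$species)))
  population_state(counts, 0L)
}

# ---- per-cell operations (exported contracts) ------------------------------

#' Within-cell resource competition
#'
#' All occupants of a cell, pooled across species, are processed in a
#' uniformly random order; each consumes its species' `resource_need` if
#' enough resources remain, otherwise it is excluded (dies).  With unit needs
#' this reduces to drawing `min(total, resources)` survivors uniformly at
#' random without replacement (multivariate hypergeometric across species).
#' Leftover resources smaller than a species' need are unusable by it but
#' remain available to lower-need species processed later in the order — the
#' small-portion effect.
#'
#' @param occupants named integer vector of per-species occupant counts.
#' @param resources non-negative integer resource units in the cell.
#' @param needs per-species resource needs (recycled; default unit need).
#' @return a list with `survivors`, `deaths` (named integer vectors) and
#'   `resources_left`.
#' @export
compete <- function(occupants, resources, needs = 1L) {
  nms <- names(occupants)
  occupants <- as.integer(occupants)
  names(occupants) <- nms
  needs <- rep_len(as.integer(needs), length(occupants))
  if (resources < 0) stop("resources must be >= 0", call. = FALSE)
  if (all(needs == 1L)) {
    total <- sum(occupants)
    k <- min(total, as.integer(resources))
    surv <- .mvhyper(occupants, k)
    left <- as.integer(resources - sum(surv))
  } else {
    surv <- cpp_compete_order(occupants, as.numeric(resources), needs)
    left <- as.integer(resources - sum(surv * needs))
  }
  names(surv) <- names(occupants)
  list(survivors = surv, deaths = occupants - surv, resources_left = left)
}

# multivariate hypergeometric draw via sequential conditioning
.mvhyper <- function(occupants, k) {
  S <- length(occupants)
  surv <- integer(S)
  rem_tot <- sum(occupants)
  rem_k <- k
  for (j in seq_len(S)) {
    if (rem_k <= 0L) break
    white <- occupants[j]
    black <- rem_tot - white
    d <- stats::rhyper(1L, white, black, rem_k)
    surv[j] <- d
    rem_k <- rem_k - d
    rem_tot <- black
  }
  surv
}

#' Within-cell pair formation
#'
#' Rules are applied in order; each forms `min(available_a, available_b)`
#' one-to-one pairs and depletes both pools, so a species engaged by an
#' earlier rule is unavailable to later ones.
#'
#' @param survivors named integer vector of per-species survivor counts.
#' @param rules list of [interaction_rule()].
#' @return a list with `pairs` (integer vector, one entry per rule) and
#'   `unpaired` (named integer vector).
#' @export
form_pairs <- function(survivors, rules) {
  avail <- as.integer(survivors)
  names(avail) <- names(survivors)
  pairs <- integer(length(rules))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    p <- min(avail[[r$species_a]], avail[[r$species_b]])
    pairs[i] <- p
    avail[[r$species_a]] <- avail[[r$species_a]] - p
    avail[[r$species_b]] <- avail[[r$species_b]] - p
  }
  list(pairs = pairs, unpaired = avail)
}

#' Realized per-organism fecundity
#'
#' An unassociated organism produces its species' `direct_offspring` (zero
#' for an obligate associate).  An associated organism produces
#' `max(0, direct_offspring + effect conferred by the partner)`, the
#' conferred effect defaulting to the partner species' `indirect_offspring`.
#' So a brood parasite with (direct 0, indirect -2) paired with a host of
#' (direct 2, indirect 2) produces 0 + 2 = 2 offspring while the host in
#' that pair produces 2 - 2 = 0.
#'
#' @param species a [species_spec()].
#' @param partner a [species_spec()] or `NULL` if unassociated.
#' @param effect optional integer overriding the partner's
#'   `indirect_offspring` (from an [interaction_rule()]).
#' @return integer >= 0.
#' @export
realized_offspring <- function(species, partner = NULL, effect = NULL) {
  if (is.null(partner)) {
    if (species$requires_partner) return(0L)
    return(species$direct_offspring)
  }
  eff <- if (!is.null(effect)) as.integer(effect)
         else partner$indirect_offspring
  max(0L, species$direct_offspring + eff)
}

# ---- compiled engine and the vectorised generation step --------------------

# Flatten a scenario_config into indexed vectors for the hot loop.
.engine <- function(config) {
  sp <- config$species
  ids <- names(sp)
  rules <- lapply(config$interactions, function(r) {
    ai <- match(r$species_a, ids)
    bi <- match(r$species_b, ids)
    list(ai = ai, bi = bi,
         fec_a = max(0L, sp[[ai]]$direct_offspring +
                       (r$effect_on_a %||% sp[[bi]]$indirect_offspring)),
         fec_b = max(0L, sp[[bi]]$direct_offspring +
                       (r$effect_on_b %||% sp[[ai]]$indirect_offspring)))
  })
  m <- config$habitat$number_of_cells
  list(m = m,
       resources = rep_len(config$habitat$resources_per_cell, m),
       clump_cells = vapply(sp, function(s)
         s$clump_cells %||% config$habitat$clump_cells, 0),
       wrap = config$habitat$wrap,
       ids = ids,
       direct = vapply(sp, function(s)
         if (s$requires_partner) 0L else s$direct_offspring, 0L),
       needs = vapply(sp, function(s) s$resource_need, 0L),
       unit_needs = all(vapply(sp, function(s) s$resource_need, 0L) == 1L),
       dispersal = lapply(sp, function(s) s$dispersal),
       rules = rules)
}

# Vectorised competition over all cells.  Unit needs: per-species sequential
# conditional hypergeometric draws, vectorised across the over-capacity
# cells.  Unequal needs: random-order processing per over-subscribed cell.
.compete_matrix <- function(counts, eng) {
  surv <- counts
  total <- rowSums(counts)
  if (eng$unit_needs) {
    over <- which(total > eng$resources)
    if (length(over)) {
      rem_tot <- total[over]
      rem_k <- pmin(eng$resources[over], rem_tot)
      S <- ncol(counts)
      for (j in seq_len(S)) {
        cj <- counts[over, j]
        nz <- which(cj > 0L)
        if (length(nz)) {
          white <- cj[nz]
          black <- rem_tot[nz] - white
          d <- stats::rhyper(length(nz), white, black, rem_k[nz])
          surv[over[nz], j] <- d
          rem_k[nz] <- rem_k[nz] - d
          rem_tot[nz] <- black
        }
      }
    }
  } else {
    needs <- eng$needs
    load <- as.vector(counts %*% needs)
    over <- which(load > eng$resources)
    for (i in over)
      surv[i, ] <- cpp_compete_order(counts[i, ], eng$resources[i], needs)
  }
  surv
}

.pairs_matrix <- function(surv, eng) {
  R <- length(eng$rules)
  pairs <- matrix(0L, nrow = eng$m, ncol = R)
  avail <- surv
  for (r in seq_len(R)) {
    ru <- eng$rules[[r]]
    p <- pmin(avail[, ru$ai], avail[, ru$bi])
    pairs[, r] <- p
    avail[, ru$ai] <- avail[, ru$ai] - p
    avail[, ru$bi] <- avail[, ru$bi] - p
  }
  list(pairs = pairs, avail = avail)
}

.offspring_matrix <- function(avail, pairs, eng) {
  off <- sweep(avail, 2L, eng$direct, `*`)
  for (r in seq_along(eng$rules)) {
    ru <- eng$rules[[r]]
    off[, ru$ai] <- off[, ru$ai] + pairs[, r] * ru$fec_a
    off[, ru$bi] <- off[, ru$bi] + pairs[, r] * ru$fec_b
  }
  storage.mode(off) <- "integer"
  off
}

.step_engine <- function(counts, eng) {
  surv <- .compete_matrix(counts, eng)
  pr <- .pairs_matrix(surv, eng)
  off <- .offspring_matrix(pr$avail, pr$pairs, eng)
  newc <- counts
  for (j in seq_along(eng$ids)) {
    d <- eng$dispersal[[j]]
    newc[, j] <- switch(d$kind,
      n = cpp_disperse_n(off[, j],
                         as.integer(round(d$prefix / 100 * eng$m)),
                         eng$wrap),
      r = disperse_r(sum(off[, j]), eng$m, d$prefix, eng$clump_cells[j]),
      h = disperse_h(sum(off[, j]), eng$m, d$prefix))
  }
  int_sums <- function(x) {
    out <- colSums(x)
    storage.mode(out) <- "integer"
    out
  }
  list(counts = newc,
       survivors = int_sums(surv),
       deaths = int_sums(counts - surv),
       pairs = int_sums(pr$pairs),
       offspring = int_sums(off),
       surv_matrix = surv)
}

#' Advance one generation
#'
#' Executes the generation cycle in every cell — resource competition, pair
#' formation among the survivors, offspring computation from the
#' direct/indirect fecundity parameters — and then disperses each species'
#' offspring by its own strategy (`n` cell by cell, `r`/`h` on the species'
#' global pool).  Adults do not persist.
#'
#' @param state a [population_state()] consistent with `config`.
#' @param config a [scenario_config()].
#' @return a list with `state` (the next [population_state()]) and `record`
#'   (named totals: `survivors`, `deaths`, `pairs`, `offspring`, `dispersed`
#'   for this generation).
#' @export
step <- function(state, config) {
  stopifnot(inherits(state, "population_state"))
  eng <- .engine(config)
  if (!identical(dim(state$counts), c(eng$m, length(eng$ids))))
    stop("state shape does not match config", call. = FALSE)
  res <- .step_engine(state$counts, eng)
  dispersed <- colSums(res$counts)
  storage.mode(dispersed) <- "integer"
  list(state = population_state(res$counts, state$generation + 1L),
       record = list(survivors = res$survivors, deaths = res$deaths,
                     pairs = res$pairs, offspring = res$offspring,
                     dispersed = dispersed))
}
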