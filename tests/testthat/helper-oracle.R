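# Individual-based reference implementation of one generation, used as an
# independent oracle for the vectorised count-based engine on tiny lattices.
# Every organism is an explicit record; competition processes organisms one
# by one in a random order, pairing matches individuals one by one, and
# dispersal moves each offspring individually.

step_reference <- function(counts, config) {
  m <- config$habitat$number_of_cells
  resources <- rep_len(config$habitat$resources_per_cell, m)
  sp <- config$species
  ids <- names(sp)
  S <- length(ids)

  # explicit organisms: data.frame(cell, species)
  orgs <- do.call(rbind, lapply(seq_len(m), function(i) {
    do.call(rbind, lapply(seq_len(S), function(j) {
      n <- counts[i, j]
      if (n == 0) NULL else data.frame(cell = rep(i, n), species = rep(j, n))
    }))
  }))

  survivors <- NULL
  if (!is.null(orgs) && nrow(orgs)) {
    keep <- logical(nrow(orgs))
    for (i in seq_len(m)) {
      idx <- which(orgs$cell == i)
      if (!length(idx)) next
      ord <- sample(idx)
      left <- resources[i]
      for (k in ord) {
        need <- sp[[orgs$species[k]]]$resource_need
        if (need <= left) {
          left <- left - need
          keep[k] <- TRUE
        }
      }
    }
    survivors <- orgs[keep, , drop = FALSE]
  }

  # pairing: per cell, per rule in order, match individuals one by one
  offspring <- matrix(0L, nrow = m, ncol = S)
  if (!is.null(survivors) && nrow(survivors)) {
    survivors$paired_with <- NA_integer_   # rule index
    for (i in seq_len(m)) {
      for (r in seq_along(config$interactions)) {
        ru <- config$interactions[[r]]
        ja <- match(ru$species_a, ids); jb <- match(ru$species_b, ids)
        free_a <- which(survivors$cell == i & survivors$species == ja &
                          is.na(survivors$paired_with))
        free_b <- which(survivors$cell == i & survivors$species == jb &
                          is.na(survivors$paired_with))
        k <- min(length(free_a), length(free_b))
        if (k > 0) {
          survivors$paired_with[free_a[seq_len(k)]] <- r
          survivors$paired_with[free_b[seq_len(k)]] <- r
        }
      }
    }
    for (k in seq_len(nrow(survivors))) {
      j <- survivors$species[k]
      r <- survivors$paired_with[k]
      fec <- if (is.na(r)) {
        if (sp[[j]]$requires_partner) 0L else sp[[j]]$direct_offspring
      } else {
        ru <- config$interactions[[r]]
        ja <- match(ru$species_a, ids)
        eff <- if (j == ja) {
          if (!is.null(ru$effect_on_a)) ru$effect_on_a
          else sp[[match(ru$species_b, ids)]]$indirect_offspring
        } else {
          if (!is.null(ru$effect_on_b)) ru$effect_on_b
          else sp[[ja]]$indirect_offspring
        }
        max(0L, sp[[j]]$direct_offspring + eff)
      }
      offspring[survivors$cell[k], j] <- offspring[survivors$cell[k], j] + fec
    }
  }

  # dispersal, organism by organism
  new_counts <- matrix(0L, nrow = m, ncol = S, dimnames = list(NULL, ids))
  for (j in seq_len(S)) {
    d <- sp[[j]]$dispersal
    if (d$kind == "n") {
      rho <- as.integer(round(d$prefix / 100 * m))
      for (i in seq_len(m)) {
        n <- offspring[i, j]
        if (n == 0) next
        if (rho == 0) {
          new_counts[i, j] <- new_counts[i, j] + n
        } else if (2 * rho + 1 >= m) {
          dest <- sample.int(m, n, replace = TRUE)
          for (dd in dest) new_counts[dd, j] <- new_counts[dd, j] + 1L
        } else {
          for (k in seq_len(n)) {
            dest <- ((i - 1 + sample(-rho:rho, 1)) %% m) + 1L
            new_counts[dest, j] <- new_counts[dest, j] + 1L
          }
        }
      }
    } else {
      pool <- sum(offspring[, j])
      cc <- if (is.null(sp[[j]]$clump_cells)) config$habitat$clump_cells
            else sp[[j]]$clump_cells
      new_counts[, j] <- disperse_r(pool, m, d$prefix, cc)
    }
  }
  list(counts = new_counts,
       survivors = if (is.null(survivors) || !nrow(survivors)) integer(S)
                   else tabulate(survivors$species, nbins = S))
}
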