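#' Habitat specification
#'
#' The habitat is a one-dimensional lattice of cells, each holding a discrete
#' number of resource units per generation.  By default the lattice wraps
#' around (a ring), so local dispersal has no edge effects; set `wrap = FALSE`
#' for a bounded transect whose neighbourhood windows are truncated at the
#' edges.
#'
#' @param number_of_cells positive integer, number of lattice cells.
#' @param resources_per_cell non-negative integer: either a scalar applied to
#'   every cell or a vector of length `number_of_cells`.
#' @param default_dispersal dispersal used by any species that does not
#'   declare its own (a [dispersal_spec()] or a string such as `"100r"`).
#' @param wrap logical; ring topology for the `n` strategy.
#' @param clump_cells fraction in `(0, 1]` of cells that an aggregated
#'   (`r`) species' clumps occupy; 1 (the default) places one random-sized
#'   group in every cell, smaller values model colonial communities whose
#'   swarms settle only part of the habitat and vacate the rest (see
#'   [disperse_r()]).
#' @return an object of class `"habitat_spec"`.
#' @export
habitat_spec <- function(number_of_cells, resources_per_cell,
                         default_dispersal = "100r", wrap = TRUE,
                         clump_cells = 1) {
  if (length(number_of_cells) != 1L || number_of_cells < 1)
    stop("number_of_cells must be a single integer >= 1", call. = FALSE)
  number_of_cells <- as.integer(number_of_cells)
  if (!length(resources_per_cell) %in% c(1L, number_of_cells))
    stop("resources_per_cell must be scalar or length number_of_cells",
         call. = FALSE)
  if (any(resources_per_cell < 0))
    stop("resources_per_cell entries must be >= 0", call. = FALSE)
  if (length(clump_cells) != 1L || is.na(clump_cells) ||
      clump_cells <= 0 || clump_cells > 1)
    stop("clump_cells must be a fraction in (0, 1]", call. = FALSE)
  structure(list(number_of_cells  = number_of_cells,
                 resources_per_cell = as.integer(resources_per_cell),
                 default_dispersal  = parse_dispersal(default_dispersal),
                 wrap = isTRUE(wrap),
                 clump_cells = as.numeric(clump_cells)),
            class = "habitat_spec")
}

#' Species specification
#'
#' Each digital species is described by its initial population and by the two
#' Hamilton-style fecundity components: `direct_offspring`, the number of
#' offspring an organism produces when it is not associated with a partner,
#' and `indirect_offspring`, the fecundity effect (possibly negative) that it
#' confers on an organism of another species it pairs with.
#'
#' @param id unique species name.
#' @param number_of_items non-negative integer initial population size.
#' @param direct_offspring integer >= 0.
#' @param indirect_offspring integer, may be negative.
#' @param dispersal a [dispersal_spec()]/string, or `NULL` to inherit the
#'   habitat default.
#' @param resource_need positive integer: resource units one organism must
#'   capture in its cell to survive and reproduce.  The default of 1 makes a
#'   cell with `k` resources support exactly `k` organisms.  Unequal needs
#'   enable the small-portion effect: leftovers below a species' need are
#'   unusable by it but still feed lower-need species.
#' @param requires_partner logical; if `TRUE` the species is an obligate
#'   associate (e.g. a consumer that only feeds through an interaction): an
#'   unpaired organism produces no offspring regardless of
#'   `direct_offspring`.
#' @param clump_cells optional override of the habitat's clump-occupancy
#'   fraction for this species' aggregated (`r`) dispersal; `NULL` inherits
#'   the habitat value (see [habitat_spec()]).
#' @return an object of class `"species_spec"`.
#' @export
species_spec <- function(id, number_of_items, direct_offspring,
                         indirect_offspring, dispersal = NULL,
                         resource_need = 1L, requires_partner = FALSE,
                         clump_cells = NULL) {
  if (length(id) != 1L || !is.character(id) || !nzchar(id))
    stop("species id must be a non-empty string", call. = FALSE)
  if (number_of_items < 0)
    stop("number_of_items must be >= 0 for species '", id, "'", call. = FALSE)
  if (direct_offspring < 0)
    stop("direct_offspring must be >= 0 for species '", id, "'",
         call. = FALSE)
  if (resource_need < 1)
    stop("resource_need must be >= 1 for species '", id, "'", call. = FALSE)
  if (!is.null(clump_cells) &&
      (length(clump_cells) != 1L || is.na(clump_cells) ||
       clump_cells <= 0 || clump_cells > 1))
    stop("clump_cells must be in (0, 1] for species '", id, "'",
         call. = FALSE)
  structure(list(id = id,
                 number_of_items    = as.integer(number_of_items),
                 direct_offspring   = as.integer(direct_offspring),
                 indirect_offspring = as.integer(indirect_offspring),
                 dispersal = if (!is.null(dispersal)) parse_dispersal(dispersal),
                 resource_need      = as.integer(resource_need),
                 requires_partner   = isTRUE(requires_partner),
                 clump_cells = if (!is.null(clump_cells))
                   as.numeric(clump_cells)),
            class = "species_spec")
}

#' Pairwise interaction rule
#'
#' Within every cell, rules are applied in the order given: each rule forms
#' `min(available_a, available_b)` one-to-one pairs between the two species;
#' paired organisms are unavailable to later rules.  A paired organism's
#' fecundity becomes `max(0, own direct_offspring + effect conferred by the
#' partner)`; by default the conferred effect is the partner species'
#' `indirect_offspring`, but a rule may override it on either side, which is
#' needed when one species takes part in interactions of different kinds
#' (e.g. a prey that feeds its specialist predator but inhibits a competitor).
#'
#' @param species_a,species_b species ids; must differ.
#' @param effect_on_a effect conferred on a paired `species_a` organism;
#'   `NULL` means "use `species_b`'s `indirect_offspring`".
#' @param effect_on_b ditto, conferred on `species_b` by `species_a`.
#' @return an object of class `"interaction_rule"`.
#' @export
interaction_rule <- function(species_a, species_b,
                             effect_on_a = NULL, effect_on_b = NULL) {
  if (identical(species_a, species_b))
    stop("interaction requires two distinct species, got '", species_a, "'",
         call. = FALSE)
  structure(list(species_a = species_a, species_b = species_b,
                 effect_on_a = if (!is.null(effect_on_a)) as.integer(effect_on_a),
                 effect_on_b = if (!is.null(effect_on_b)) as.integer(effect_on_b)),
            class = "interaction_rule")
}

#' Scenario configuration
#'
#' Bundles the habitat, the species list, the interaction rules and the run
#' control into the single object that [run_simulation()] consumes.  Species
#' without their own dispersal inherit the habitat default at construction
#' time, so a validated config is fully resolved.
#'
#' @param habitat a [habitat_spec()].
#' @param species list of [species_spec()].
#' @param interactions list of [interaction_rule()] (may be empty).
#' @param generations positive integer number of generations to simulate.
#' @param seed integer RNG seed, or `NULL` to leave the RNG state untouched.
#' @param record_cell_stats logical; record per-generation spatial diagnostics
#'   (per-cell standard deviation, maximum density, empty cells, deaths).
#' @return an object of class `"scenario_config"`.
#' @seealso [load_config()], [save_config()], [run_simulation()]
#' @export
scenario_config <- function(habitat, species, interactions = list(),
                            generations, seed = NULL,
                            record_cell_stats = FALSE) {
  stopifnot(inherits(habitat, "habitat_spec"))
  if (!length(species)) stop("at least one species is required", call. = FALSE)
  ids <- vapply(species, function(s) s$id, "")
  if (anyDuplicated(ids))
    stop("duplicate species id: '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  species <- lapply(species, function(s) {
    if (is.null(s$dispersal)) s$dispersal <- habitat$default_dispersal
    s
  })
  names(species) <- ids
  for (r in interactions) {
    stopifnot(inherits(r, "interaction_rule"))
    for (side in c("species_a", "species_b"))
      if (!r[[side]] %in% ids)
        stop("interaction references unknown species '", r[[side]], "'",
             call. = FALSE)
  }
  if (length(generations) != 1L || generations < 1)
    stop("generations must be a single integer >= 1", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(habitat = habitat, species = species,
                 interactions = interactions,
                 generations = as.integer(generations), seed = seed,
                 record_cell_stats = isTRUE(record_cell_stats)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  habitat: ", x$habitat$number_of_cells, " cells x ",
      if (length(unique(x$habitat$resources_per_cell)) == 1L)
        x$habitat$resources_per_cell[1L] else "variable",
      " resources, default dispersal ",
      format(x$habitat$default_dispersal), "\n", sep = "")
  for (s in x$species)
    cat("  species ", s$id, ": n0=", s$number_of_items,
        " direct=", s$direct_offspring, " indirect=", s$indirect_offspring,
        " dispersal=", format(s$dispersal),
        if (s$resource_need != 1L) paste0(" need=", s$resource_need),
        if (s$requires_partner) " (obligate associate)", "\n", sep = "")
  for (r in x$interactions)
    cat("  interaction ", r$species_a, " -- ", r$species_b, "\n", sep = "")
  cat("  generations: ", x$generations,
      if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  invisible(x)
}

# ---- JSON (de)serialisation ------------------------------------------------

# Aliases keep the field's traditional variable names greppable in configs.
.habitat_aliases <- c(NumberOfCells = "number_of_cells",
                      NumberOfRsrcsInEachCell = "resources_per_cell",
                      Distribution = "default_dispersal")
.species_aliases <- c(NumberOfItems = "number_of_items",
                      DirectOffspring = "direct_offspring",
                      IndirectOffspring = "indirect_offspring",
                      Distribution = "dispersal")

.apply_aliases <- function(x, aliases) {
  for (a in names(aliases)) {
    if (a %in% names(x)) {
      canon <- aliases[[a]]
      if (canon %in% names(x))
        stop("field '", a, "' duplicates '", canon, "'", call. = FALSE)
      names(x)[names(x) == a] <- canon
    }
  }
  x
}

.known_or_stop <- function(x, known, where) {
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown field '", bad[1L], "' in ", where, call. = FALSE)
  x
}

#' Read a scenario configuration from JSON
#'
#' Accepts the canonical snake_case schema written by [save_config()] and, as
#' aliases, the traditional CamelCase variable names (`NumberOfCells`,
#' `NumberOfRsrcsInEachCell`, `Distribution`, `NumberOfItems`,
#' `DirectOffspring`, `IndirectOffspring`).  Validation errors name the
#' offending field.
#'
#' @param path path to a JSON file.
#' @return a validated [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  config_from_list(raw)
}

#' @rdname load_config
#' @param raw a nested list with the same structure as the JSON document.
#' @export
config_from_list <- function(raw) {
  raw <- .known_or_stop(raw, c("habitat", "species", "interactions",
                               "generations", "seed", "record_cell_stats"),
                        "config")
  if (is.null(raw$habitat)) stop("config is missing 'habitat'", call. = FALSE)
  if (is.null(raw$species)) stop("config is missing 'species'", call. = FALSE)
  h <- .apply_aliases(raw$habitat, .habitat_aliases)
  h <- .known_or_stop(h, c("number_of_cells", "resources_per_cell",
                           "default_dispersal", "wrap", "clump_cells"),
                      "habitat")
  habitat <- habitat_spec(
    number_of_cells    = h$number_of_cells,
    resources_per_cell = unlist(h$resources_per_cell),
    default_dispersal  = if (is.null(h$default_dispersal)) "100r"
                         else h$default_dispersal,
    wrap = if (is.null(h$wrap)) TRUE else h$wrap,
    clump_cells = h$clump_cells %||% 1)
  species <- lapply(raw$species, function(s) {
    s <- .apply_aliases(s, .species_aliases)
    s <- .known_or_stop(s, c("id", "number_of_items", "direct_offspring",
                             "indirect_offspring", "dispersal",
                             "resource_need", "requires_partner",
                             "clump_cells"),
                        paste0("species '", s$id %||% "?", "'"))
    species_spec(id = s$id,
                 number_of_items    = s$number_of_items %||% 0L,
                 direct_offspring   = s$direct_offspring %||% 0L,
                 indirect_offspring = s$indirect_offspring %||% 0L,
                 dispersal          = s$dispersal,
                 resource_need      = s$resource_need %||% 1L,
                 requires_partner   = s$requires_partner %||% FALSE,
                 clump_cells        = s$clump_cells)
  })
  interactions <- lapply(raw$interactions %||% list(), function(r) {
    r <- .known_or_stop(r, c("species_a", "species_b",
                             "effect_on_a", "effect_on_b"), "interaction")
    interaction_rule(r$species_a, r$species_b, r$effect_on_a, r$effect_on_b)
  })
  scenario_config(habitat = habitat, species = species,
                  interactions = interactions,
                  generations = raw$generations %||% 1L,
                  seed = raw$seed,
                  record_cell_stats = raw$record_cell_stats %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration to JSON
#'
#' The file uses canonical snake_case keys in a fixed order, so saving is
#' byte-stable and `load_config(save_config(x))` reproduces `x`
#' field-for-field.
#'
#' @param config a [scenario_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  jsonlite::write_json(config_to_list(config), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
config_to_list <- function(config) {
  h <- config$habitat
  drop_null <- function(x) x[!vapply(x, is.null, TRUE)]
  out <- list(
    habitat = list(
      number_of_cells = h$number_of_cells,
      resources_per_cell =
        if (length(h$resources_per_cell) == 1L) h$resources_per_cell
        else I(h$resources_per_cell),
      default_dispersal = format(h$default_dispersal),
      wrap = h$wrap,
      clump_cells = h$clump_cells),
    species = lapply(unname(config$species), function(s) drop_null(list(
      id = s$id,
      number_of_items    = s$number_of_items,
      direct_offspring   = s$direct_offspring,
      indirect_offspring = s$indirect_offspring,
      dispersal          = format(s$dispersal),
      resource_need      = if (s$resource_need != 1L) s$resource_need,
      requires_partner   = if (s$requires_partner) TRUE,
      clump_cells        = s$clump_cells))),
    interactions = lapply(config$interactions, function(r) drop_null(list(
      species_a = r$species_a, species_b = r$species_b,
      effect_on_a = r$effect_on_a, effect_on_b = r$effect_on_b))),
    generations = config$generations,
    record_cell_stats = config$record_cell_stats)
  if (!is.null(config$seed)) out$seed <- config$seed
  out
}
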