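#' Dispersal strategy specification
#'
#' A dispersal strategy is written as an integer percentage prefix followed by
#' a strategy letter, e.g. `"100r"`, `"6n"`, `"40h"`:
#'
#' * `n` — local neighbourhood dispersal: each offspring moves, one by one, to
#'   a uniformly random cell within a window centred on its cell of origin.
#'   The prefix sets the window radius as a percentage of the lattice
#'   (`0n` keeps offspring in their natal cell, `100n` reaches every cell).
#' * `r` — global aggregated dispersal: the species' whole offspring pool is
#'   reallocated over the lattice using spacings of sorted uniforms, which
#'   produces a positively skewed, clumped distribution.  The prefix is the
#'   weight of the clumped component; `0r` spreads the average into every
#'   cell, `100r` is maximally aggregated.
#' * `h` — gregarious dispersal: a subtype of `r` at maximum aggregation in
#'   which the prefix fixes the percentage of cells that are left empty,
#'   emulating animals that actively seek conspecifics.
#'
#' @param prefix integer percentage in `[0, 100]`.
#' @param kind one of `"n"`, `"r"`, `"h"`.
#' @return an object of class `"dispersal_spec"`.
#' @examples
#' dispersal_spec(100, "r")
#' parse_dispersal("6n")
#' @export
dispersal_spec <- function(prefix, kind) {
  if (length(prefix) != 1L || is.na(prefix) || !is.numeric(prefix))
    stop("dispersal prefix must be a single number", call. = FALSE)
  if (prefix < 0 || prefix > 100)
    stop("dispersal prefix must lie in [0, 100], got ", prefix, call. = FALSE)
  if (abs(prefix - round(prefix)) > 1e-8)
    stop("dispersal prefix must be an integer percentage, got ", prefix,
         call. = FALSE)
  if (length(kind) != 1L || !kind %in% c("n", "r", "h"))
    stop("dispersal kind must be one of 'n', 'r', 'h'", call. = FALSE)
  structure(list(prefix = as.integer(round(prefix)), kind = kind),
            class = "dispersal_spec")
}

#' @rdname dispersal_spec
#' @param x a strategy string such as `"100r"`, or a `dispersal_spec`.
#' @export
parse_dispersal <- function(x) {
  if (inherits(x, "dispersal_spec")) return(x)
  if (length(x) != 1L || !is.character(x) || !grepl("^[0-9]+[nrh]$", x))
    stop("cannot parse dispersal strategy ", deparse(x),
         " (expected e.g. '100r', '6n', '40h')", call. = FALSE)
  n <- nchar(x)
  dispersal_spec(as.integer(substr(x, 1L, n - 1L)), substr(x, n, n))
}

#' @export
format.dispersal_spec <- function(x, ...) paste0(x$prefix, x$kind)

#' @export
print.dispersal_spec <- function(x, ...) {
  cat("<dispersal ", format(x), ">\n", sep = "")
  invisible(x)
}

#' @export
as.character.dispersal_spec <- function(x, ...) format(x)
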