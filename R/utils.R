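#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded package functions do not disturb
#' the user's random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Default trait vocabulary
#'
#' The six focal traits plus the two low-availability extras. Names are the
#' canonical identifiers used across the package: `plant_height` (m),
#' `seed_mass` (mg), `leaf_area` (mm^2), `SLA` (mm^2/mg), `LDMC` (g/g),
#' `leaf_N` (% dry mass), `stem_density` (g/cm^3), `leaf_lifespan` (months).
#'
#' @return Character vector of canonical trait names.
#' @export
trait_vocabulary <- function() {
  c("plant_height", "seed_mass", "leaf_area", "SLA", "LDMC", "leaf_N",
    "stem_density", "leaf_lifespan")
}

#' Economic and size trait sets
#'
#' The two major axes of plant form and function: resource-economic leaf
#' traits versus plant size traits.
#'
#' @return Named list with elements `economic` and `size`.
#' @export
trait_axes <- function() {
  list(economic = c("SLA", "LDMC", "leaf_N"),
       size = c("plant_height", "seed_mass", "leaf_area"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
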