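# shared helpers

#' Taxonomic ranks used throughout the package
#'
#' Lineages are handled at six fixed ranks, in this order.
#'
#' @format Character vector of length six.
#' @export
TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

.MOLECULES <- c("rDNA", "rRNA")
.LAYERS <- c("surface", "middle", "bottom")
.BIOMES <- c("FL", "PA")

#' Round half up
#'
#' Presentation rounding used for reported percentages: exact halves round
#' away from zero-towards-larger values (so 92.575 -> 92.58), unlike base
#' [round()] which rounds half to even. Internal computation always keeps
#' full precision; this is applied only when a value is formatted for a
#' report column.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' roundHalfUp(14.778, 0)   # 15
#' roundHalfUp(92.5795, 2)  # 92.58
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. Every stochastic operation in the package takes an
# explicit seed and routes through here: no hidden global state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# integral within floating tolerance
.isWholeNumber <- function(x, tol = 1e-8) {
  all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
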