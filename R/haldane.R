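#' Haldane map function
#'
#' Converts a genetic map distance in centiMorgans into a recombination
#' fraction under the Haldane (no crossover interference) model,
#' r = (1 - exp(-2d)) / 2 with d in Morgans.
#'
#' @param distance_cM non-negative map distance(s) in centiMorgans.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane(10)      # ~0.0906
#' haldane_inverse(haldane(10))
#' @export
haldane <- function(distance_cM) {
  if (any(distance_cM < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * distance_cM / 100)) / 2
}

#' Inverse Haldane map function
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return map distance(s) in centiMorgans.
#' @export
haldane_inverse <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination fraction must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}
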