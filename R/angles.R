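#' Wrap angles to (-180, 180]
#'
#' All angular arithmetic in the package is circular; angles are in degrees,
#' counter-clockwise positive.
#'
#' @param theta numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(190, -190, 360, 180))
wrap_angle <- function(theta) {
  w <- (theta + 180) %% 360 - 180
  # %% maps 180 -> -180; keep the convention (-180, 180]
  w[w == -180] <- 180
  w
}

#' Circular difference a - b wrapped to (-180, 180]
#' @param a,b angles in degrees.
#' @return wrapped differences.
#' @export
circ_diff <- function(a, b) wrap_angle(a - b)
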