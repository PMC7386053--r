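#' Wrap phase values to (-pi, pi]
#'
#' Maps arbitrary finite phase values onto the principal interval by adding
#' the unique integer multiple of \code{2*pi} that lands each value in
#' \code{(-pi, pi]}. The interval is half-open at the lower end, so
#' \code{wrap_phase(-pi)} returns \code{pi}.
#'
#' @param x numeric vector, matrix or array of phase values in radians.
#' @return object of the same shape as \code{x}, with all values in
#'   \code{(-pi, pi]}.
#' @examples
#' wrap_phase(3 * pi / 2)   # -pi/2
#' wrap_phase(c(-pi, pi))   # pi, pi
#' @export
wrap_phase <- function(x) {
  if (any(!is.finite(x))) stop("wrap_phase: non-finite input")
  # wrap to [-pi, pi) then flip the -pi endpoint to +pi
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  w[w <= -pi] <- pi
  w
}

# Wrapped difference b - a, in (-pi, pi]. Internal helper.
phase_diff <- function(b, a) wrap_phase(b - a)
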