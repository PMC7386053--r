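#' Convolution kernels for topological-charge estimation
#'
#' The four kernel pairs used by the convolutional charge detector. Each
#' element is a list with x- and y-direction weight matrices \code{gx} and
#' \code{gy} and a \code{gain}: the signed response of the kernel pair to an
#' ideal unit vortex, by which the raw convolution sum is divided so that
#' every kernel reports topological charge on the same scale (n_t = +/-1 at
#' an ideal core) and with one sign convention (+1 = phase increasing along a
#' loop traversed clockwise as seen from outside the surface). The weights
#' are kept exactly as published; the published Sobel pairs carry the
#' opposite internal orientation to the nabla pair, which the sign of
#' \code{gain} absorbs.
#'
#' \itemize{
#'   \item \code{sobel3}: 3x3 Sobel-type pair with half weights on the corner
#'     rows, the classic choice for the discrete line integral.
#'   \item \code{sobel5}: standard 5x5 Sobel pair (smoothing (1,4,6,4,1),
#'     derivative (-1,-2,0,2,1)), a longer integration path.
#'   \item \code{nabla2}: 2x2 forward-difference pair; with one-step wrapped
#'     phase gradients this reproduces the 2x2-plaquette winding number
#'     exactly (a 4-step closed path).
#'   \item \code{nabla3}: 3x3 unsmoothed difference pair assembling the
#'     8-step closed circulation around the 3x3 neighborhood ring, the
#'     longer-path analogue of \code{nabla2}.
#' }
#'
#' The y kernels point "up" (positive weights at smaller row index) so that
#' the combination \code{gx * ky + gy * kx} computes the curl of the spatial
#' phase gradient.
#'
#' @format a named list of lists with elements \code{gx}, \code{gy},
#'   \code{gain}.
#' @export
ps_kernels <- list(
  sobel3 = list(
    gx = matrix(c(-1/2, 0, 1/2,
                  -1,   0, 1,
                  -1/2, 0, 1/2), 3, 3, byrow = TRUE),
    gy = matrix(c( 1/2, 1,  1/2,
                   0,   0,  0,
                  -1/2, -1, -1/2), 3, 3, byrow = TRUE),
    gain = -1),
  sobel5 = list(
    gx = outer(c(1, 4, 6, 4, 1), c(-1, -2, 0, 2, 1)),
    gy = outer(c(1, 2, 0, -2, -1), c(1, 4, 6, 4, 1)),
    gain = -18),
  nabla2 = list(
    gx = matrix(c(1, -1,
                  0,  0), 2, 2, byrow = TRUE),
    gy = matrix(c(-1, 0,
                   1, 0), 2, 2, byrow = TRUE),
    gain = 1),
  nabla3 = list(
    gx = matrix(c( 1, 0, -1,
                   1, 0, -1,
                   0, 0,  0), 3, 3, byrow = TRUE),
    gy = matrix(c(-1, -1, 0,
                   0,  0, 0,
                   1,  1, 0), 3, 3, byrow = TRUE),
    gain = 1)
)
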