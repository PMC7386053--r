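#' Cylindrical grid projection
#'
#' Bijective mapping between mesh nodes and the cells of a regular 2D grid,
#' as produced by the point-by-point cylindrical projection of a mapping
#' system's shell (by default 32 latitude rows by 64 longitude columns). The
#' column axis is periodic (cylinder seam); rows are clamped at top/bottom.
#'
#' @param rows,cols grid dimensions (defaults 32 and 64).
#' @param node_of optional rows x cols integer matrix giving the node index of
#'   each cell; defaults to row-major numbering.
#' @return an object of class \code{grid_projection}: list with \code{rows},
#'   \code{cols}, \code{node_of} (rows x cols matrix) and \code{cell_of}
#'   (n x 2 matrix of row, col per node).
#' @export
grid_projection <- function(rows = 32L, cols = 64L, node_of = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.null(node_of))
    node_of <- matrix(seq_len(rows * cols), rows, cols, byrow = TRUE)
  node_of <- as.matrix(node_of)
  storage.mode(node_of) <- "integer"
  if (!identical(dim(node_of), c(rows, cols)))
    stop("grid_projection: node_of must be rows x cols")
  if (!setequal(node_of, seq_len(rows * cols)))
    stop("grid_projection: node_of must be a bijection onto 1..rows*cols")
  cell_of <- matrix(0L, rows * cols, 2)
  idx <- cbind(as.vector(row(node_of)), as.vector(col(node_of)))
  cell_of[as.vector(node_of), ] <- idx
  colnames(cell_of) <- c("row", "col")
  structure(list(rows = rows, cols = cols, node_of = node_of,
                 cell_of = cell_of),
            class = "grid_projection")
}

#' @export
print.grid_projection <- function(x, ...) {
  cat(sprintf("grid_projection: %d rows x %d cols (columns periodic)\n",
              x$rows, x$cols))
  invisible(x)
}

# Clockwise "diamond" ring of Manhattan radius N around (row, col), with
# periodic wrap on columns and clamping on rows.  Returns an integer matrix
# of (row, col) pairs, or NULL when the ring would leave the grid through the
# top or bottom (no closed ring; the node is skipped).  Order starts at
# (row - N, col) and proceeds through decreasing columns, which is clockwise
# when the grid is viewed from outside the cylinder (rows = height, columns =
# azimuth), matching the mesh ring orientation.
diamond_ring_cells <- function(row, col, N, rows, cols) {
  if (row - N < 1L || row + N > rows) return(NULL)
  k <- seq_len(N) - 1L
  dr <- c(-N + k, k, N - k, -k)
  dc <- -c(k, N - k, -k, -N + k)
  r <- row + dr
  cc <- ((col - 1L + dc) %% cols) + 1L
  cbind(row = r, col = cc)
}

# Precompute clockwise diamond rings (as node indices) for every grid cell.
# Cells too close to the top/bottom rows get NULL.
grid_rings <- function(projection, N) {
  rows <- projection$rows; cols <- projection$cols
  out <- vector("list", rows * cols)
  for (r in seq_len(rows)) {
    if (r - N < 1L || r + N > rows) next
    for (cc in seq_len(cols)) {
      cells <- diamond_ring_cells(r, cc, N, rows, cols)
      out[[projection$node_of[r, cc]]] <-
        projection$node_of[cbind(cells[, 1], cells[, 2])]
    }
  }
  out
}
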