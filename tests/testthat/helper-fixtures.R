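# shared fixtures, built in code

# small cylinder used by most unit tests (fast); full-size shells are built
# inside the tests that need them
small_cylinder <- function(rows = 12L, cols = 16L, ...) {
  make_cylinder_mesh(rows = rows, cols = cols, ...)
}

# independent brute-force winding number of the plaquette anchored at each
# cell, clockwise as seen from outside (rows of height, periodic columns);
# rows 1..(nrow-1) are defined
brute_winding <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  W <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr - 1)) for (cc in seq_len(nc)) {
    c2 <- if (cc == nc) 1L else cc + 1L
    W[r, cc] <- (wrap_phase(M[r + 1, cc] - M[r, cc]) +
                 wrap_phase(M[r + 1, c2] - M[r + 1, cc]) +
                 wrap_phase(M[r, c2] - M[r + 1, c2]) +
                 wrap_phase(M[r, cc] - M[r, c2])) / (2 * pi)
  }
  W
}

# frame vector -> rows x cols matrix via the projection
frame_matrix <- function(phase_seq, f, projection = phase_seq$projection) {
  M <- matrix(NA_real_, projection$rows, projection$cols)
  n <- projection$rows * projection$cols
  M[cbind(projection$cell_of[, 1], projection$cell_of[, 2])] <-
    phase_seq$phase[f, seq_len(n)]
  M
}

# independent BFS graph distances from a source node
bfs_distances <- function(adj, source, maxd) {
  dist <- rep(NA_integer_, length(adj))
  dist[source] <- 0L
  frontier <- source
  for (d in seq_len(maxd)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), which(!is.na(dist)))
    if (!length(frontier)) break
    dist[frontier] <- d
  }
  dist
}
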