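test_that("wrap_phase maps onto (-pi, pi] and only shifts by 2*pi multiples", {
  expect_equal(wrap_phase(3 * pi / 2), -pi / 2)
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-pi), pi)
  set.seed(11)
  x <- stats::runif(1e4, -40, 40)
  w <- wrap_phase(x)
  expect_true(all(w > -pi & w <= pi))
  # brute-force search for the shift multiple
  k <- sapply(seq_along(x), function(i) {
    ks <- -10:10
    ks[which(abs(x[i] + 2 * pi * ks - w[i]) < 1e-9)]
  })
  expect_equal(x + 2 * pi * unlist(k), w, tolerance = 1e-9)
  expect_error(wrap_phase(NaN), "non-finite")
})

test_that("mesh construction enforces the structural invariants", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_silent(tri_mesh(v, rbind(c(1, 2, 3), c(3, 2, 4))))
  # inconsistent winding: shared edge traversed twice in the same direction
  expect_error(tri_mesh(v, rbind(c(1, 2, 3), c(2, 3, 4))),
               "orientation")
  expect_error(tri_mesh(v, rbind(c(1, 2, 2))), "repeated")
  expect_error(tri_mesh(v, rbind(c(1, 2, 5))), "out of range")
  vdeg <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(tri_mesh(vdeg, rbind(c(1, 2, 3))), "degenerate")
  # non-manifold: three faces on one edge
  v5 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  expect_error(tri_mesh(v5, rbind(c(1, 2, 3), c(2, 1, 4), c(1, 2, 5))),
               "orientation|non-manifold")
})

test_that("neighbor index matches edge sharing, including brute force", {
  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  rbind(c(1, 2, 3)))
  adj <- build_neighbor_index(tri)
  expect_equal(adj, list(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
               ignore_attr = TRUE)

  cyl <- make_cylinder_mesh(rows = 5, cols = 20)   # 100 nodes
  set.seed(3)
  v <- cyl$mesh$vertices + matrix(stats::rnorm(300, 0, 0.2), ncol = 3)
  mesh <- tri_mesh(v, cyl$mesh$faces)
  adj <- build_neighbor_index(mesh)
  # oracle: O(faces) enumeration of all face edge pairs
  ref <- vector("list", mesh$node_count)
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    for (p in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- f[p[1]]; b <- f[p[2]]
      ref[[a]] <- union(ref[[a]], b)
      ref[[b]] <- union(ref[[b]], a)
    }
  }
  expect_equal(adj, lapply(ref, sort), ignore_attr = TRUE)
  # symmetric, and interior vertices of a triangulated quad grid have degree 6
  for (i in seq_along(adj))
    for (j in adj[[i]]) expect_true(i %in% adj[[j]])
  interior <- setdiff(seq_len(100), boundary_nodes(mesh))
  expect_true(all(lengths(adj[interior]) == 6))
})

test_that("node_distance is the Euclidean metric in mm", {
  mesh <- tri_mesh(rbind(c(0, 0, 0), c(3, 4, 0), c(0, 1, 0)),
                   rbind(c(1, 2, 3)))
  expect_equal(node_distance(mesh, 1, 1), 0)
  expect_equal(node_distance(mesh, 1, 2), 5)
  cyl <- small_cylinder()
  set.seed(4)
  i <- sample(cyl$mesh$node_count, 25, replace = TRUE)
  j <- sample(cyl$mesh$node_count, 25, replace = TRUE)
  expect_equal(node_distance(cyl$mesh, i, j), node_distance(cyl$mesh, j, i))
})

test_that("grid diamond rings have the right members and wrap the seam", {
  proj <- grid_projection(12, 16)
  r1 <- diamond_ring_cells(6, 8, 1, 12, 16)
  expect_equal(nrow(r1), 4)
  expect_setequal(paste(r1[, 1], r1[, 2]), c("5 8", "6 9", "7 8", "6 7"))
  r2 <- diamond_ring_cells(6, 8, 2, 12, 16)
  expect_equal(nrow(r2), 8)
  expect_true(all(abs(r2[, 1] - 6) + pmin(abs(r2[, 2] - 8), 16 - abs(r2[, 2] - 8)) == 2))
  # seam wrap: ring at column 1 reaches the last column
  rs <- diamond_ring_cells(6, 1, 2, 12, 16)
  expect_true(any(rs[, 2] == 15) && any(rs[, 2] == 16))
  # clamped at the top: no ring
  expect_null(diamond_ring_cells(2, 8, 3, 12, 16))
})

test_that("mesh rings are closed loops of the exact graph distance, consistently oriented", {
  cyl <- small_cylinder()
  adj <- build_neighbor_index(cyl$mesh)
  normals <- vertex_normals(cyl$mesh)
  boundary <- boundary_nodes(cyl$mesh)
  interior_cell <- cyl$projection$node_of[6, 5]
  sweeps <- c()
  for (N in 1:3) {
    for (center in c(interior_cell, cyl$projection$node_of[7, 1])) {
      ring <- neighbor_ring_sorted(cyl$mesh, center, N, adj = adj,
                                   normals = normals, boundary = boundary)
      expect_true(ring$closed)
      # members at graph distance exactly N (independent BFS oracle)
      dist <- bfs_distances(adj, center, N + 1)
      expect_true(all(dist[ring$members] == N))
      expect_setequal(ring$members, which(dist == N))
      # consecutive members share an edge, including the closing pair
      nxt <- c(ring$members[-1], ring$members[1])
      expect_true(all(mapply(function(a, b) b %in% adj[[a]],
                             ring$members, nxt)))
      expect_equal(ring$members[1], min(ring$members))
      # signed angular sweep around the center has one global sign
      n <- normals[center, ]
      ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * n) * n; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
              n[1] * e1[2] - n[2] * e1[1])
      d <- cyl$mesh$vertices[ring$members, , drop = FALSE] -
        matrix(cyl$mesh$vertices[center, ], length(ring$members), 3,
               byrow = TRUE)
      ang <- atan2(d %*% e2, d %*% e1)
      sweeps <- c(sweeps, sum(wrap_phase(diff(c(ang, ang[1])))))
    }
  }
  expect_true(all(sweeps < 0))  # clockwise viewed from outside
  # ring size at radius 1 equals the vertex degree
  r1 <- neighbor_ring_sorted(cyl$mesh, interior_cell, 1, adj = adj,
                             normals = normals, boundary = boundary)
  expect_equal(length(r1$members), length(adj[[interior_cell]]))
  # boundary nodes are flagged by returning NULL
  expect_null(neighbor_ring_sorted(cyl$mesh, cyl$projection$node_of[1, 4], 1,
                                   adj = adj, normals = normals,
                                   boundary = boundary))
})

test_that("grid projection round-trips across the periodic seam", {
  proj <- grid_projection(8, 10)
  for (r in seq_len(8)) for (cc in c(1, 5, 10)) {
    node <- proj$node_of[r, cc]
    expect_equal(proj$cell_of[node, ], c(row = r, col = cc))
  }
  expect_setequal(as.vector(proj$node_of), seq_len(80))
})
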