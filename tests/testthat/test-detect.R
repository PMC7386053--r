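test_that("loop statistics classify monotonic rings, constants and reversals", {
  # ideal ring: phases are the member angles around a core
  m <- 12
  ang <- wrap_phase(seq(0, 2 * pi, length.out = m + 1)[-(m + 1)])
  st <- loop_monotonic_stats(ang)
  expect_true(st$monotonic)
  expect_equal(st$direction, 1L)
  expect_equal(st$gradient, 2 * pi * (m - 1) / m, tolerance = 1e-9)
  rev_st <- loop_monotonic_stats(rev(ang))
  expect_true(rev_st$monotonic)
  expect_equal(rev_st$direction, -1L)

  cst <- loop_monotonic_stats(rep(0.3, 6))
  expect_false(cst$monotonic)
  expect_equal(cst$gradient, 0)

  expect_false(loop_monotonic_stats(c(0, 1, 0.5, 2))$monotonic)
  expect_error(loop_monotonic_stats(c(0, 1)), "3 loop members")
})

test_that("topological charge matches the plaquette winding oracle exactly (nabla2)", {
  set.seed(21)
  for (rep in 1:10) {
    M <- matrix(stats::runif(16 * 24, -pi, pi), 16, 24)
    ch <- topological_charge_2d(M, "nabla2")$charge
    W <- brute_winding(M)
    keep <- !is.na(W)
    expect_true(all(abs(ch[keep] - W[keep]) < 1e-9))
    expect_true(all(sign(round(ch[keep])) == sign(round(W[keep]))))
  }
})

test_that("charge fields localize ideal cores and respect symmetries", {
  cyl <- small_cylinder(16, 24)
  sim <- synth_phase_sequence(scenario("spiral", core = c(8.5, 12.5),
                                       frames = 1L),
                              cyl$projection)
  M <- frame_matrix(sim$phase, 1)
  for (kn in names(ps_kernels)) {
    ch <- topological_charge_2d(M, kn)$charge
    i <- which(abs(ch) == max(abs(ch)), arr.ind = TRUE)[1, ]
    expect_equal(ch[i[1], i[2]], 1, tolerance = 0.05)
    expect_lt(max(abs(i - c(8, 12))), 2)
    # cells more than 3 cells from the core carry almost no charge
    far <- abs(row(ch) - 8.5) > 3 & pmin(abs(col(ch) - 12.5),
                                         24 - abs(col(ch) - 12.5)) > 3
    far[nrow(ch), ] <- FALSE  # clamped last row is undefined
    expect_lt(max(abs(ch[far])), 0.1)
    # mirror flips the sign exactly
    chm <- topological_charge_2d(M[nrow(M):1, ], kn)$charge
    expect_equal(max(chm), -min(ch), tolerance = 1e-9)
  }
  # uniform field carries no charge
  expect_true(all(topological_charge_2d(matrix(0.7, 16, 24), "sobel3")$charge == 0))
  expect_error(topological_charge_2d(matrix(0, 2, 2), "sobel3"), "smaller")
  expect_error(topological_charge_2d(M, "sobel7"), "unknown kernel")
})

test_that("all four detectors find an ideal core, with the right chirality", {
  cyl <- small_cylinder(16, 24)
  for (chir in c(1L, -1L)) {
    sim <- synth_phase_sequence(scenario("spiral", core = c(8.5, 12.5),
                                         chirality = chir, frames = 3L), cyl)
    truth_node <- sim$truth$node[1]
    for (alg in 1:4) {
      det <- detect_ps(sim$phase, alg)
      expect_gt(nrow(det), 0)
      for (f in 1:3) {
        d <- det[det$frame == f, ]
        dd <- node_distance(cyl$mesh, d$node, rep(truth_node, nrow(d)))
        expect_lt(min(dd), 5)
        expect_equal(d$chirality[which.min(dd)], chir)
      }
    }
  }
})

test_that("planar traveling waves produce no detections", {
  cyl <- small_cylinder(16, 24)
  sim <- synth_phase_sequence(scenario("planar", frames = 4L), cyl)
  for (alg in 1:4)
    expect_equal(nrow(detect_ps(sim$phase, alg)), 0)
})

test_that("counter-rotating pairs give two detections of opposite chirality", {
  cyl <- small_cylinder(20, 32)
  sim <- synth_phase_sequence(scenario("spiral_pair", frames = 2L), cyl)
  for (alg in c(3L, 4L)) {
    det <- detect_ps(sim$phase, alg,
                     detector_params(alg, refine = "dbscan"))
    for (f in 1:2) {
      d <- det[det$frame == f, ]
      expect_equal(nrow(d), 2)
      expect_equal(sort(d$chirality), c(-1L, 1L))
    }
  }
})

test_that("discrete rings cannot reach a full 2*pi gradient", {
  cyl <- small_cylinder(16, 24)
  sim <- synth_phase_sequence(scenario("spiral", core = c(8.5, 12.5),
                                       frames = 1L), cyl)
  det <- detect_ps(sim$phase, 2, detector_params(2, threshold = 2 * pi,
                                                 refine = "none"))
  expect_equal(nrow(det), 0)
  expect_equal(nrow(detect_ps(phase_sequence(
    matrix(0.2, 2, 16 * 24), 512, projection = cyl$projection,
    mesh = cyl$mesh), 2)), 0)
})

test_that("reflection flips every detection's chirality (all four algorithms)", {
  cyl <- small_cylinder(16, 24)
  proj <- cyl$projection
  sim <- synth_phase_sequence(scenario("spiral", core = c(8.5, 12.5),
                                       noise_sd = 0.05, frames = 1L,
                                       seed = 5), cyl)
  M <- frame_matrix(sim$phase, 1)
  Mr <- M[nrow(M):1, ]   # reflect across the equator
  p_ref <- Mr[cbind(proj$cell_of[, 1], proj$cell_of[, 2])]
  ps_ref <- phase_sequence(matrix(p_ref, 1), 512, projection = proj,
                           mesh = cyl$mesh)
  ps_orig <- phase_sequence(matrix(
    M[cbind(proj$cell_of[, 1], proj$cell_of[, 2])], 1), 512,
    projection = proj, mesh = cyl$mesh)
  for (alg in 1:4) {
    d1 <- detect_ps(ps_orig, alg)
    d2 <- detect_ps(ps_ref, alg)
    expect_equal(nrow(d1), nrow(d2))
    if (nrow(d1)) {
      expect_equal(sort(table(d1$chirality)),
                   sort(table(-d2$chirality)), ignore_attr = TRUE)
      expect_equal(sum(d1$chirality), -sum(d2$chirality))
    }
  }
})

test_that("cluster refinement merges by adjacency/5mm, keeps max gradient, is idempotent", {
  cyl <- small_cylinder()
  adjn <- build_neighbor_index(cyl$mesh)
  n1 <- cyl$projection$node_of[6, 5]
  n2 <- adjn[[n1]][1]
  n3 <- adjn[[n1]][2]
  det <- data.frame(frame = 1L, node = c(n1, n2, n3),
                    row = NA, col = NA, chirality = 1L,
                    loop_gradient = c(5, 6.2, 4.8))
  ref <- dbscan_refine(det, cyl$mesh)
  expect_equal(nrow(ref), 1)
  expect_equal(ref$node, n2)          # greatest gradient wins
  expect_equal(nrow(dbscan_refine(ref, cyl$mesh)), 1)  # idempotent

  far <- data.frame(frame = 1L, node = c(cyl$projection$node_of[3, 2],
                                         cyl$projection$node_of[10, 10]),
                    row = NA, col = NA, chirality = 1L,
                    loop_gradient = c(5, 5))
  expect_gt(node_distance(cyl$mesh, far$node[1], far$node[2]), 20)
  expect_equal(nrow(dbscan_refine(far, cyl$mesh)), 2)

  empty <- dbscan_refine(det[0, ], cyl$mesh)
  expect_equal(nrow(empty), 0)

  # tie on gradient -> lowest node index
  tie <- data.frame(frame = 1L, node = c(n2, n1), row = NA, col = NA,
                    chirality = 1L, loop_gradient = c(5, 5))
  expect_equal(dbscan_refine(tie, cyl$mesh)$node, min(n1, n2))

  # never increases the count (random detection sets)
  set.seed(8)
  for (i in 1:5) {
    nodes <- sample(cyl$mesh$node_count, 30)
    d <- data.frame(frame = rep(1:3, each = 10), node = nodes,
                    row = NA, col = NA, chirality = 1L,
                    loop_gradient = stats::runif(30))
    expect_lte(nrow(dbscan_refine(d, cyl$mesh)), nrow(d))
  }
})

test_that("sparse refinement neighborhoods agree with direct distances", {
  cyl <- small_cylinder()
  nbrs <- refine_neighbors(cyl$mesh, 5)
  adj <- build_neighbor_index(cyl$mesh)
  set.seed(13)
  for (i in sample(cyl$mesh$node_count, 12)) {
    d <- node_distance(cyl$mesh, rep(i, cyl$mesh$node_count),
                       seq_len(cyl$mesh$node_count))
    ref <- sort(union(which(d <= 5 & seq_along(d) != i), adj[[i]]))
    expect_equal(nbrs[[i]], ref)
  }
})

test_that("detector parameter validation enforces the documented ranges", {
  expect_equal(detector_params(1)$threshold, 1.5 * pi)
  expect_equal(detector_params(2)$refine, "dbscan")
  expect_equal(detector_params(3)$kernel, "sobel3")
  expect_equal(detector_params(4)$threshold, 3.5)
  expect_equal(detector_params(4)$radius, 1L)
  expect_error(detector_params(1, radius = 1), "radius")
  expect_error(detector_params(2, threshold = 0), "threshold")
  expect_error(detector_params(2, threshold = 7), "threshold")
  expect_error(detector_params(3, kernel = "box"), "kernel")
  expect_error(detector_params(5), "algorithm")
})

test_that("the 2D detectors accept a bare frame matrix", {
  cyl <- small_cylinder(16, 24)
  sim <- synth_phase_sequence(scenario("spiral", core = c(8.5, 12.5),
                                       frames = 1L), cyl)
  M <- frame_matrix(sim$phase, 1)
  d3 <- detect_ps(M, 3)
  expect_equal(nrow(d3), 1)
  expect_lt(max(abs(c(d3$row, d3$col) - c(8, 12))), 2)
  d1 <- detect_ps(M, 1)
  expect_equal(nrow(d1), 1)
  expect_error(detect_ps(M, 2), "algorithm")
})
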