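test_that("density maps count visits and normalize by the maximum", {
  proj <- grid_projection(8, 10)
  empty <- psd_map(data.frame(node = integer(0)), proj, 10)
  expect_true(all(empty$counts == 0) && all(empty$normalized == 0))

  one <- psd_map(data.frame(node = rep(proj$node_of[3, 4], 10)), proj, 10)
  expect_equal(one$counts[3, 4], 10)
  expect_equal(one$normalized[3, 4], 1)
  expect_equal(sum(one$counts), 10)

  set.seed(2)
  nodes <- sample(80, 37, replace = TRUE)
  rnd <- psd_map(data.frame(node = nodes), proj, 37)
  expect_equal(sum(rnd$counts), 37)    # conservation
})

test_that("SSIM identities: self-similarity, constants, symmetry, scale sensitivity", {
  set.seed(14)
  A <- matrix(stats::runif(64 * 32), 32, 64)
  B <- matrix(stats::runif(64 * 32), 32, 64)
  expect_equal(map_ssim(A, A), 1)
  # constant maps 0 vs 1 with L = 1: plugging zero variances into the merged
  # form gives c1/(1+c1)
  c1 <- 0.01^2
  expect_equal(map_ssim(matrix(0, 4, 4), matrix(1, 4, 4)), c1 / (1 + c1),
               tolerance = 1e-12)
  expect_equal(map_ssim(A, B), map_ssim(B, A))
  expect_lt(map_ssim(A, 2 * A), 1)     # scale-sensitive
  expect_error(map_ssim(A, matrix(0, 3, 3)), "shape")
})

test_that("map correlation matches a two-pass elementwise evaluation", {
  set.seed(15)
  A <- matrix(stats::runif(64 * 32), 32, 64)
  B <- matrix(stats::runif(64 * 32), 32, 64)
  expect_equal(map_corr(A, A), 1)
  expect_equal(map_corr(A, 0.7 - A), -1)
  expect_equal(map_corr(A, 2 * A), 1)   # scale-invariant
  two_pass <- function(A, B) {
    Am <- A - mean(A); Bm <- B - mean(B)
    sum(Am * Bm) / sqrt(sum(Am^2) * sum(Bm^2))
  }
  expect_equal(map_corr(A, B), two_pass(A, B), tolerance = 1e-12)
  expect_error(map_corr(A, matrix(1, 32, 64)), "zero-variance")
})

test_that("tolerance matching implements the TP/FP/FN/TN accounting", {
  cyl <- small_cylinder()
  node <- cyl$projection$node_of[6, 5]
  ann <- data.frame(frame = 1L, node = node)

  exact <- match_detections(data.frame(frame = 1L, node = node), ann,
                            cyl$mesh, 5, n_frames = 1)
  expect_equal(c(exact$TP, exact$FP, exact$FN), c(1L, 0L, 0L))
  expect_equal(exact$TN, cyl$mesh$node_count - 1)

  # a detection two nodes away (6.9 mm) is both a false positive and leaves
  # the annotation unmatched
  far_node <- cyl$projection$node_of[6, 7]
  expect_gt(node_distance(cyl$mesh, node, far_node), 5)
  far <- match_detections(data.frame(frame = 1L, node = far_node), ann,
                          cyl$mesh, 5, n_frames = 1)
  expect_equal(c(far$TP, far$FP, far$FN), c(0L, 1L, 1L))

  # duplicate detections near one annotation: one TP, extras are FPs
  nb <- build_neighbor_index(cyl$mesh)[[node]][1]
  dup <- match_detections(data.frame(frame = 1L, node = c(node, nb)), ann,
                          cyl$mesh, 5, n_frames = 1)
  expect_equal(c(dup$TP, dup$FP, dup$FN), c(1L, 1L, 0L))

  # conservation: TP + FN = number of annotations, on random sets
  set.seed(16)
  for (i in 1:5) {
    det <- data.frame(frame = rep(1:4, each = 5),
                      node = sample(cyl$mesh$node_count, 20, replace = TRUE))
    anns <- data.frame(frame = rep(1:4, each = 2),
                       node = sample(cyl$mesh$node_count, 8, replace = TRUE))
    cm <- match_detections(det, anns, cyl$mesh, 5, n_frames = 4)
    expect_equal(cm$TP + cm$FN, nrow(anns))
    expect_equal(cm$TP + cm$FP, nrow(det))
    expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, cyl$mesh$node_count * 4)
  }
})

test_that("F-beta reproduces the closed-form values and degenerate rules", {
  # fixed point: precision = recall = p gives score p for any beta
  for (beta in c(0.5, 1, 2, 3)) {
    fb <- f_beta(list(TP = 3, FP = 7, FN = 7), beta)
    expect_equal(fb$precision, fb$recall)
    expect_equal(fb$score, fb$precision)
  }
  fb <- f_beta(list(TP = 1, FP = 1, FN = 0), beta = 2)
  expect_equal(fb$precision, 0.5)
  expect_equal(fb$recall, 1)
  expect_equal(fb$score, 5 * 0.5 * 1 / (4 * 0.5 + 1))  # 0.8333...
  expect_warning(z <- f_beta(list(TP = 0, FP = 0, FN = 3)), "degenerate")
  expect_equal(z$score, 0)
  # recall weighting: with precision < recall, larger beta raises the score
  lo <- f_beta(list(TP = 4, FP = 6, FN = 1), 1)$score
  hi <- f_beta(list(TP = 4, FP = 6, FN = 1), 2)$score
  expect_gt(hi, lo)
})

test_that("a single-cell grid sweep returns that cell as the argmax", {
  cyl <- small_cylinder(16, 24)
  sim <- synth_phase_sequence(scenario("spiral", core = c(8.5, 12.5),
                                       frames = 4L), cyl)
  grid <- list(thresholds = 3.5, radii = 1L)
  sw <- parameter_sweep(list(sim), 4L, grid, refine = "dbscan")
  expect_equal(nrow(sw$surface), 1)
  expect_equal(sw$best, 1L)
  expect_gt(sw$surface$score[1], 0.9)
})

test_that("sweeps agree with direct detector runs at matching settings", {
  cyl <- small_cylinder(16, 24)
  sim <- synth_phase_sequence(scenario("spiral", core = c(8.5, 12.5),
                                       noise_sd = 0.05, frames = 4L,
                                       seed = 6), cyl)
  grid <- list(thresholds = c(1.0 * pi, 1.5 * pi), radii = c(1L, 2L))
  for (alg in c(2L, 4L)) {
    sw <- parameter_sweep(list(sim), alg, grid, refine = "none")
    for (s in seq_len(nrow(sw$surface))) {
      params <- detector_params(alg, threshold = sw$surface$threshold[s],
                                radius = sw$surface$radius[s],
                                refine = "none")
      det <- detect_ps(sim$phase, alg, params)
      cm <- match_detections(det, sim$truth, cyl$mesh, 5, n_frames = 4)
      fb <- suppressWarnings(f_beta(cm, 2))
      expect_equal(sw$surface$score[s], fb$score, tolerance = 1e-12)
    }
  }
  # algorithm 3 path: kernels instead of radii
  sw3 <- parameter_sweep(list(sim), 3L,
                         list(thresholds = 1.9 * pi,
                              kernels = c("sobel3", "nabla2")),
                         refine = "none")
  det3 <- detect_ps(sim$phase, 3, detector_params(3, refine = "none"))
  cm3 <- match_detections(det3, sim$truth, cyl$mesh, 5, n_frames = 4)
  expect_equal(sw3$surface$score[1],
               suppressWarnings(f_beta(cm3, 2))$score, tolerance = 1e-12)
})

test_that("cross-validation: exchangeable folds and the k=2 edge case", {
  cyl <- small_cylinder(16, 24)
  base <- synth_phase_sequence(scenario("spiral", core = c(8.5, 12.5),
                                        frames = 3L), cyl)
  episodes <- rep(list(base), 4)
  grid <- list(thresholds = c(2.5, 3.5), radii = 1L)
  cv <- cross_validate(episodes, 4L, grid, k = 4, seed = 3, refine = "dbscan")
  # identical episodes: every fold picks the same setting; test == train
  expect_equal(length(unique(cv$folds$threshold)), 1)
  expect_equal(cv$folds$test_score, cv$folds$train_score, tolerance = 1e-12)

  cv2 <- cross_validate(episodes[1:2], 4L, grid, k = 2, seed = 3,
                        refine = "dbscan")
  expect_equal(nrow(cv2$folds), 2)
  expect_error(cross_validate(episodes[1:2], 4L, grid, k = 10), "fewer")
})
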