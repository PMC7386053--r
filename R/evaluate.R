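#' Phase-singularity density map
#'
#' Accumulates detections on the 2D projection: each cell counts the number
#' of times a singularity visited it across the frames of an episode. The
#' normalized map scales counts to [0, 1] by the maximum (all zeros when
#' empty).
#'
#' @param detections detection data frame (needs \code{node} or
#'   \code{row}/\code{col} columns).
#' @param projection a \code{\link{grid_projection}}.
#' @param frames number of frames in the episode (metadata).
#' @return object of class \code{psd_map}: list with \code{counts},
#'   \code{normalized} (rows x cols matrices) and \code{frames}.
#' @export
psd_map <- function(detections, projection, frames) {
  counts <- matrix(0L, projection$rows, projection$cols)
  if (nrow(detections) > 0) {
    nodes <- detections$node
    nodes <- nodes[nodes <= nrow(projection$cell_of)]
    cells <- projection$cell_of[nodes, , drop = FALSE]
    for (i in seq_len(nrow(cells)))
      counts[cells[i, 1], cells[i, 2]] <- counts[cells[i, 1], cells[i, 2]] + 1L
  }
  normalized <- if (max(counts) > 0) counts / max(counts) else counts * 0
  structure(list(counts = counts, normalized = normalized, frames = frames),
            class = "psd_map")
}

as_map_matrix <- function(x) {
  if (inherits(x, "psd_map")) x$normalized else as.matrix(x)
}

#' Structural similarity of two density maps
#'
#' Global (single-window) SSIM in the merged two-factor form
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'                   {(\mu_x^2+\mu_y^2+c_1)(\sigma_x^2+\sigma_y^2+c_2)}}
#' with \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2}. Defaults
#' \eqn{k_1 = 0.01}, \eqn{k_2 = 0.03}, and dynamic range \eqn{L = 1} for
#' normalized density maps. Statistics are map-level (population variances).
#' A sliding-window mean SSIM is available with \code{window}; the global
#' form is the default.
#'
#' @param a,b \code{\link{psd_map}} objects (normalized maps are compared) or
#'   plain matrices of identical shape.
#' @param k1,k2,L SSIM constants.
#' @param window optional odd window size for a sliding-window mean SSIM
#'   (default \code{NULL}: single global window).
#' @return similarity in [-1, 1]; 1 for identical maps.
#' @export
map_ssim <- function(a, b, k1 = 0.01, k2 = 0.03, L = 1, window = NULL) {
  A <- as_map_matrix(a); B <- as_map_matrix(b)
  if (!identical(dim(A), dim(B))) stop("map_ssim: shape mismatch")
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  ssim_block <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    (2 * mx * my + c1) * (2 * cxy + c2) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  if (is.null(window)) return(ssim_block(A, B))
  if (window %% 2 != 1) stop("map_ssim: window must be odd")
  h <- (window - 1) / 2
  vals <- c()
  for (r in seq(1 + h, nrow(A) - h)) for (cc in seq(1 + h, ncol(A) - h)) {
    ri <- (r - h):(r + h); ci <- (cc - h):(cc + h)
    vals <- c(vals, ssim_block(A[ri, ci], B[ri, ci]))
  }
  mean(vals)
}

#' Pearson correlation of two density maps
#'
#' 2D Pearson correlation coefficient
#' \deqn{CORR = \frac{\sum_i\sum_j (A_{ij}-\bar A)(B_{ij}-\bar B)}
#'  {\sqrt{\sum_i\sum_j (A_{ij}-\bar A)^2 \sum_i\sum_j (B_{ij}-\bar B)^2}}}
#'
#' @inheritParams map_ssim
#' @return correlation in [-1, 1].
#' @export
map_corr <- function(a, b) {
  A <- as_map_matrix(a); B <- as_map_matrix(b)
  if (!identical(dim(A), dim(B))) stop("map_corr: shape mismatch")
  if (stats::var(as.vector(A)) == 0 || stats::var(as.vector(B)) == 0)
    stop("map_corr: undefined correlation (zero-variance map)")
  stats::cor(as.vector(A), as.vector(B))
}

#' Tolerance-based confusion counts for detections vs annotations
#'
#' Per frame, detections are matched to annotated singularities one-to-one by
#' a nearest-first greedy assignment among pairs within \code{tolerance} mm.
#' Every matched annotation contributes one true positive; every unmatched
#' detection is a false positive (whether it duplicates an already-matched
#' annotation or sits far from all of them); every unmatched annotation is a
#' false negative; all remaining node-frame combinations are true negatives.
#'
#' @param detections,annotations data frames with \code{frame} and \code{node}
#'   columns.
#' @param mesh a \code{\link{tri_mesh}} supplying node coordinates.
#' @param tolerance matching tolerance in mm (default 5, roughly one node
#'   spacing and below the size of an ablation lesion).
#' @param n_frames total frames in the episode (default: largest frame index
#'   seen).
#' @return object of class \code{confusion_counts}: list with \code{TP},
#'   \code{FP}, \code{FN}, \code{TN}, \code{tolerance}.
#' @export
match_detections <- function(detections, annotations, mesh, tolerance = 5,
                             n_frames = NULL) {
  if (is.null(n_frames))
    n_frames <- max(c(detections$frame, annotations$frame, 1L))
  TP <- 0L; FP <- 0L; FN <- 0L
  for (f in seq_len(n_frames)) {
    dn <- detections$node[detections$frame == f]
    an <- annotations$node[annotations$frame == f]
    if (length(dn) == 0L && length(an) == 0L) next
    matched <- 0L
    if (length(dn) > 0L && length(an) > 0L) {
      dmat <- matrix(node_distance(mesh,
                                   rep(dn, times = length(an)),
                                   rep(an, each = length(dn))),
                     length(dn), length(an))
      pairs <- which(dmat <= tolerance, arr.ind = TRUE)
      if (nrow(pairs) > 0L) {
        ord <- order(dmat[pairs])
        used_d <- logical(length(dn)); used_a <- logical(length(an))
        for (i in ord) {
          di <- pairs[i, 1]; ai <- pairs[i, 2]
          if (!used_d[di] && !used_a[ai]) {
            used_d[di] <- TRUE; used_a[ai] <- TRUE
            matched <- matched + 1L
          }
        }
      }
    }
    TP <- TP + matched
    FP <- FP + (length(dn) - matched)
    FN <- FN + (length(an) - matched)
  }
  TN <- as.numeric(mesh$node_count) * n_frames - TP - FP - FN
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN, tolerance = tolerance),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts (tolerance %.1f mm): TP=%d FP=%d FN=%d TN=%.0f\n",
              x$tolerance, x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Precision, recall and F-beta score
#'
#' \code{precision = TP/(TP+FP)}, \code{recall = TP/(TP+FN)} and
#' \deqn{F_\beta = (1+\beta^2)\,\frac{precision \cdot recall}
#'   {\beta^2 \cdot precision + recall}.}
#' \code{beta = 2} weighs recall above precision, appropriate when missed
#' singularities are costlier than over-detections. Degenerate zero
#' denominators yield 0 with a warning.
#'
#' @param counts a \code{confusion_counts} (or list with TP, FP, FN).
#' @param beta recall weighting (default 2).
#' @return list with \code{precision}, \code{recall}, \code{score}.
#' @export
f_beta <- function(counts, beta = 2) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  if ((TP + FP) == 0 || (TP + FN) == 0) {
    warning("f_beta: degenerate counts; score set to 0")
    pr <- if (TP + FP > 0) TP / (TP + FP) else 0
    rc <- if (TP + FN > 0) TP / (TP + FN) else 0
    return(list(precision = pr, recall = rc, score = 0))
  }
  pr <- TP / (TP + FP)
  rc <- TP / (TP + FN)
  sc <- if (pr == 0 && rc == 0) 0 else
    (1 + beta^2) * pr * rc / (beta^2 * pr + rc)
  list(precision = pr, recall = rc, score = sc)
}

#' Default parameter grid for the sweep
#'
#' Thresholds 0.1*pi to 2*pi in 0.1*pi steps; search radii 1--8 (2--8 for
#' algorithm 1); the four kernels for algorithm 3.
#'
#' @param algorithm integer 1--4.
#' @return list with \code{thresholds} and \code{radii} or \code{kernels}.
#' @export
default_grid <- function(algorithm) {
  thresholds <- seq(0.1, 2, by = 0.1) * pi
  if (algorithm == 3L) list(thresholds = thresholds,
                            kernels = names(ps_kernels))
  else list(thresholds = thresholds,
            radii = if (algorithm == 1L) 2:8 else 1:8)
}

# enumerate grid settings as a data frame
grid_settings <- function(algorithm, grid) {
  if (algorithm == 3L)
    expand.grid(threshold = grid$thresholds, kernel = grid$kernels,
                stringsAsFactors = FALSE)
  else
    expand.grid(threshold = grid$thresholds, radius = grid$radii)
}

# nearest-first greedy one-to-one matching for one frame; returns TP/FP/FN
match_frame <- function(det_nodes, ann_nodes, verts, tolerance) {
  nd <- length(det_nodes); na <- length(ann_nodes)
  if (nd == 0L || na == 0L) return(c(tp = 0L, fp = nd, fn = na))
  dv <- verts[det_nodes, , drop = FALSE]
  matched_d <- logical(nd); matched <- 0L
  for (ai in order(ann_nodes)) {
    av <- verts[ann_nodes[ai], ]
    dd <- sqrt((dv[, 1] - av[1])^2 + (dv[, 2] - av[2])^2 +
                 (dv[, 3] - av[3])^2)
    dd[matched_d] <- Inf
    j <- which.min(dd)
    if (dd[j] <= tolerance) {
      matched_d[j] <- TRUE
      matched <- matched + 1L
    }
  }
  c(tp = matched, fp = nd - matched, fn = na - matched)
}

# assemble per-setting confusion_counts from accumulated tp/fp/fn matrices
assemble_counts <- function(tp, fp, fn, n_nodes, n_frames, tolerance) {
  lapply(seq_along(tp), function(s)
    structure(list(TP = tp[s], FP = fp[s], FN = fn[s],
                   TN = as.numeric(n_nodes) * n_frames - tp[s] - fp[s] - fn[s],
                   tolerance = tolerance),
              class = "confusion_counts"))
}

# confusion counts for one episode under every grid setting (list of counts,
# in grid_settings order: threshold varying fastest).  Ring differences /
# charge fields are computed once per frame and shared across thresholds;
# refinement uses the precomputed sparse neighborhoods.
episode_sweep_counts <- function(episode, algorithm, grid, settings, refine,
                                 tolerance, mesh, projection,
                                 rings_by_radius = NULL, nbrs = NULL) {
  phase <- episode$phase
  truth <- episode$truth
  n_frames <- nrow(phase$phase)
  verts <- mesh$vertices
  nT <- length(grid$thresholds)
  nS <- nrow(settings)
  tp <- integer(nS); fp <- integer(nS); fn <- integer(nS)
  ann_by_frame <- split(truth$node, factor(truth$frame, levels = seq_len(n_frames)))
  do_refine <- refine == "dbscan"
  if (do_refine && is.null(nbrs)) nbrs <- refine_neighbors(mesh)

  tally <- function(s, nodes, grads, f) {
    if (do_refine && length(nodes) > 1L) {
      keep <- refine_components(nodes, grads, nbrs)
      nodes <- nodes[keep]
    }
    m <- match_frame(nodes, ann_by_frame[[f]], verts, tolerance)
    tp[s] <<- tp[s] + m[1]; fp[s] <<- fp[s] + m[2]; fn[s] <<- fn[s] + m[3]
  }

  if (algorithm %in% c(2L, 4L)) {
    for (ri in seq_along(grid$radii)) {
      groups <- ring_groups(rings_by_radius[[as.character(grid$radii[ri])]])
      for (f in seq_len(n_frames)) {
        p <- phase$phase[f, ]
        gv <- lapply(groups, function(g) {
          V <- matrix(p[g$members], nrow(g$members), g$L)
          list(D = V[, c(2:g$L, 1L), drop = FALSE] - V, grad = row_range(V),
               centers = g$centers)
        })
        if (algorithm == 2L) {
          jit <- 0.25
          mono <- lapply(gv, function(x) {
            nwd <- rowSums(x$D <= -pi); nwu <- rowSums(x$D >= pi)
            up <- nwd == 1L & nwu == 0L & rowSums(x$D < -jit & x$D > -pi) == 0L
            down <- !up & nwu == 1L & nwd == 0L &
              rowSums(x$D > jit & x$D < pi) == 0L
            up | down
          })
          for (ti in seq_len(nT)) {
            thr <- grid$thresholds[ti]
            nodes <- integer(0); grads <- numeric(0)
            for (gi in seq_along(gv)) {
              keep <- mono[[gi]] & gv[[gi]]$grad >= thr
              nodes <- c(nodes, gv[[gi]]$centers[keep])
              grads <- c(grads, gv[[gi]]$grad[keep])
            }
            tally((ri - 1L) * nT + ti, nodes, grads, f)
          }
        } else {
          for (ti in seq_len(nT)) {
            thr <- grid$thresholds[ti]
            nodes <- integer(0); grads <- numeric(0)
            for (gi in seq_along(gv)) {
              s <- rowSums(gv[[gi]]$D < -thr) - rowSums(gv[[gi]]$D > thr)
              keep <- (abs(s) %% 2L) == 1L
              nodes <- c(nodes, gv[[gi]]$centers[keep])
              grads <- c(grads, gv[[gi]]$grad[keep])
            }
            tally((ri - 1L) * nT + ti, nodes, grads, f)
          }
        }
      }
    }
  } else if (algorithm == 3L) {
    cellr <- projection$cell_of[, 1]; cellc <- projection$cell_of[, 2]
    for (ki in seq_along(grid$kernels)) {
      for (f in seq_len(n_frames)) {
        M <- matrix(NA_real_, projection$rows, projection$cols)
        M[cbind(cellr, cellc)] <- phase$phase[f, seq_len(projection$rows *
                                                           projection$cols)]
        val <- 2 * pi * topological_charge_2d(M, grid$kernels[ki])$charge
        aval <- abs(val)
        for (ti in seq_len(nT)) {
          sel <- which(aval >= grid$thresholds[ti])
          tally((ki - 1L) * nT + ti, projection$node_of[sel], aval[sel], f)
        }
      }
    }
  } else {  # algorithm 1: centroid clustering is integral to the detector
    for (ri in seq_along(grid$radii)) {
      N <- grid$radii[ri]
      rings <- rings_by_radius[[as.character(N)]]
      cellr <- projection$cell_of[, 1]; cellc <- projection$cell_of[, 2]
      for (f in seq_len(n_frames)) {
        M <- matrix(NA_real_, projection$rows, projection$cols)
        M[cbind(cellr, cellc)] <- phase$phase[f, seq_len(projection$rows *
                                                           projection$cols)]
        E <- canny_phase_edges(M)
        cand <- if (any(E)) which(E & neighbor_count4(E) <= 1L, arr.ind = TRUE)
                else matrix(0L, 0, 2)
        stats <- vector("list", nrow(cand))
        for (i in seq_len(nrow(cand))) {
          ring <- rings[[projection$node_of[cand[i, 1], cand[i, 2]]]]
          if (is.null(ring)) next
          stats[[i]] <- loop_monotonic_stats(
            M[cbind(cellr[ring], cellc[ring])])
        }
        ok <- vapply(stats, function(x) !is.null(x) && x$monotonic, FALSE)
        grads <- vapply(stats[ok], `[[`, 0, "gradient")
        cells <- cand[ok, , drop = FALSE]
        for (ti in seq_len(nT)) {
          keep <- grads >= grid$thresholds[ti]
          nodes <- integer(0)
          if (any(keep)) {
            kc <- cells[keep, , drop = FALSE]
            lab <- label_components8(kc, projection$cols)
            nodes <- vapply(unique(lab), function(l) {
              sel <- lab == l
              r_mean <- mean(kc[sel, 1])
              a <- 2 * pi * (kc[sel, 2] - 1) / projection$cols
              c_mean <- atan2(mean(sin(a)), mean(cos(a))) *
                projection$cols / (2 * pi) + 1
              r0 <- min(max(snap_low(r_mean), 1L), projection$rows)
              c0 <- ((snap_low(c_mean) - 1L) %% projection$cols) + 1L
              projection$node_of[r0, c0]
            }, 0L)
          }
          m <- match_frame(nodes, ann_by_frame[[f]], verts, tolerance)
          s <- (ri - 1L) * nT + ti
          tp[s] <- tp[s] + m[1]; fp[s] <- fp[s] + m[2]; fn[s] <- fn[s] + m[3]
        }
      }
    }
  }
  assemble_counts(tp, fp, fn, mesh$node_count, n_frames, tolerance)
}

pool_counts <- function(counts_list) {
  structure(list(TP = sum(vapply(counts_list, `[[`, 0, "TP")),
                 FP = sum(vapply(counts_list, `[[`, 0, "FP")),
                 FN = sum(vapply(counts_list, `[[`, 0, "FN")),
                 TN = sum(vapply(counts_list, `[[`, 0, "TN")),
                 tolerance = counts_list[[1]]$tolerance),
            class = "confusion_counts")
}

# argmax with the declared tie rule: larger threshold first, then smaller
# radius (kernels tie-break by grid order)
best_setting <- function(scores, settings) {
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  if (length(cand) > 1L) {
    ord <- order(-settings$threshold[cand],
                 if (!is.null(settings$radius)) settings$radius[cand]
                 else seq_along(cand))
    cand <- cand[ord]
  }
  cand[1L]
}

#' F-beta parameter sweep over thresholds and radii (or kernels)
#'
#' Runs the detector on every episode for every grid setting, pools
#' (micro-averages) the confusion counts across episodes, and computes the
#' F-beta surface. The argmax ties break toward the larger threshold, then
#' the smaller radius (stricter and cheaper).
#'
#' @param episodes list of episodes, each a list with \code{phase} (a
#'   \code{\link{phase_sequence}}) and \code{truth} (annotation data frame).
#' @param algorithm integer 1--4.
#' @param grid parameter grid as from \code{\link{default_grid}}.
#' @param refine refinement applied during the sweep (default: the
#'   algorithm's default).
#' @param tolerance matching tolerance in mm.
#' @param beta F-beta weight (default 2).
#' @param mesh,projection geometry (defaults: attached to the first episode).
#' @return object of class \code{sweep_result}: data frame \code{surface}
#'   (setting columns plus precision, recall, score), \code{best} (row index
#'   of the argmax), \code{beta}.
#' @export
parameter_sweep <- function(episodes, algorithm, grid = default_grid(algorithm),
                            refine = NULL, tolerance = 5, beta = 2,
                            mesh = NULL, projection = NULL) {
  settings <- grid_settings(algorithm, grid)
  if (nrow(settings) == 0L) stop("parameter_sweep: empty grid")
  if (is.null(mesh)) mesh <- episodes[[1]]$phase$mesh
  if (is.null(projection)) projection <- episodes[[1]]$phase$projection
  if (is.null(refine)) refine <- detector_params(algorithm)$refine
  rings_by_radius <- NULL
  if (algorithm %in% c(2L, 4L)) {
    adj <- build_neighbor_index(mesh)
    rings_by_radius <- lapply(stats::setNames(as.list(grid$radii),
                                              grid$radii),
                              function(N) mesh_rings(mesh, N, adj = adj))
  } else if (algorithm == 1L) {
    rings_by_radius <- lapply(stats::setNames(as.list(grid$radii),
                                              grid$radii),
                              function(N) grid_rings(projection, N))
  }
  nbrs <- if (refine == "dbscan") refine_neighbors(mesh) else NULL
  per_episode <- lapply(episodes, episode_sweep_counts, algorithm = algorithm,
                        grid = grid, settings = settings, refine = refine,
                        tolerance = tolerance, mesh = mesh,
                        projection = projection,
                        rings_by_radius = rings_by_radius, nbrs = nbrs)
  surface <- settings
  scores <- numeric(nrow(settings))
  for (s in seq_len(nrow(settings))) {
    pooled <- pool_counts(lapply(per_episode, `[[`, s))
    fb <- suppressWarnings(f_beta(pooled, beta))
    surface$precision[s] <- fb$precision
    surface$recall[s] <- fb$recall
    surface$score[s] <- fb$score
    scores[s] <- fb$score
  }
  structure(list(surface = surface, best = best_setting(scores, settings),
                 beta = beta, per_episode = per_episode,
                 settings = settings, algorithm = algorithm,
                 refine = refine),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  b <- x$surface[x$best, ]
  cat(sprintf("sweep_result: algorithm %d, %d settings, best F_%g = %.3f at\n",
              x$algorithm, nrow(x$surface), x$beta, b$score))
  print(b, row.names = FALSE)
  invisible(x)
}

#' k-fold cross-validated parameter optimization
#'
#' Episodes are partitioned into \code{k} folds deterministically from
#' \code{seed} (one episode per fold when counts match). For each fold, the
#' parameter setting maximizing the pooled F-beta score on the training
#' episodes is selected and evaluated on the held-out episodes; the per-fold
#' optima and test scores and their means are returned.
#'
#' @inheritParams parameter_sweep
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return object of class \code{cv_result}: data frame \code{folds} (per-fold
#'   best setting, train and test score), \code{mean_test}, \code{mean_train}.
#' @export
cross_validate <- function(episodes, algorithm, grid = default_grid(algorithm),
                           k = 10, seed = 1, refine = NULL, tolerance = 5,
                           beta = 2, mesh = NULL, projection = NULL) {
  n <- length(episodes)
  if (n < k) stop("cross_validate: fewer episodes than folds")
  sw <- parameter_sweep(episodes, algorithm, grid, refine = refine,
                        tolerance = tolerance, beta = beta, mesh = mesh,
                        projection = projection)
  settings <- sw$settings
  fold_of <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  folds <- list()
  for (fd in seq_len(k)) {
    train <- which(fold_of != fd); test <- which(fold_of == fd)
    scores <- vapply(seq_len(nrow(settings)), function(s) {
      suppressWarnings(
        f_beta(pool_counts(lapply(sw$per_episode[train], `[[`, s)),
               beta)$score)
    }, 0)
    bi <- best_setting(scores, settings)
    test_fb <- suppressWarnings(
      f_beta(pool_counts(lapply(sw$per_episode[test], `[[`, bi)), beta))
    folds[[fd]] <- cbind(fold = fd, settings[bi, , drop = FALSE],
                         train_score = scores[bi],
                         test_score = test_fb$score)
  }
  folds <- do.call(rbind, folds)
  rownames(folds) <- NULL
  structure(list(folds = folds, mean_test = mean(folds$test_score),
                 mean_train = mean(folds$train_score), sweep = sw,
                 algorithm = algorithm, k = k, beta = beta),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: algorithm %d, %d folds, mean test F_%g = %.3f (train %.3f)\n",
              x$algorithm, x$k, x$beta, x$mean_test, x$mean_train))
  invisible(x)
}
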