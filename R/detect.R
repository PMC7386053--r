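# --- small 2D helpers: periodic columns (cylinder seam), clamped/padded rows ---

# out[r,c] = A[r+dr, c+dc]; columns wrap, rows replicate the edge row
shift_clamp <- function(A, dr, dc) {
  nr <- nrow(A); nc <- ncol(A)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- ((seq_len(nc) + dc - 1L) %% nc) + 1L
  A[ri, ci, drop = FALSE]
}

# out[r,c] = A[r+dr, c+dc]; columns wrap, out-of-range rows read as `pad`
shift_pad <- function(A, dr, dc, pad = 0) {
  nr <- nrow(A); nc <- ncol(A)
  out <- matrix(pad, nr, nc)
  rs <- seq_len(nr) + dr
  ok <- rs >= 1L & rs <= nr
  ci <- ((seq_len(nc) + dc - 1L) %% nc) + 1L
  out[ok, ] <- A[rs[ok], ci, drop = FALSE]
  out
}

# correlation of A with kernel K; odd kernels are centered, even kernels are
# anchored at the top-left of their window
corr2_pc <- function(A, K) {
  kr <- nrow(K); kc <- ncol(K)
  cr <- if (kr %% 2 == 1) (kr + 1L) %/% 2L else 1L
  cc <- if (kc %% 2 == 1) (kc + 1L) %/% 2L else 1L
  out <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    if (K[i, j] != 0)
      out <- out + K[i, j] * shift_clamp(A, i - cr, j - cc)
  }
  out
}

# one-step wrapped phase differences along columns (x) and rows (y);
# the x axis is periodic (seam), the last row of ky is zero (clamped)
phase_gradients <- function(M) {
  kx <- wrap_phase(shift_clamp(M, 0L, 1L) - M)
  down <- shift_clamp(M, 1L, 0L)
  ky <- wrap_phase(down - M)
  ky[nrow(M), ] <- 0
  list(kx = kx, ky = ky)
}

# --- monotonic loop statistics -------------------------------------------------

#' Monotonic progression statistics of a closed phase loop
#'
#' Given the phases of a closed loop of neighboring nodes (in traversal
#' order), reports the loop phase gradient \code{max(phi) - min(phi)}, whether
#' the phases progress monotonically around the loop with exactly one wrap
#' crossing (a full rotation), and the direction of progression. A loop that
#' ascends around the ring with exactly one wrap-scale descent (a raw step at
#' or below \code{-pi}) is monotonic with direction +1; the mirror case gives
#' -1. Descents smaller than \code{jitter} are treated as discrete-sampling
#' jitter rather than reversals: on finite rings even an ideal rotor produces
#' sub-tenth-radian counter-steps, so exact monotonicity would reject every
#' loop. Constant loops are degenerate and reported non-monotonic.
#'
#' @param loop_phases numeric vector of at least 3 wrapped phases in traversal
#'   order.
#' @param jitter tolerated counter-step magnitude in radians (default 0.25).
#' @return list with \code{gradient} (radians), \code{monotonic} (logical) and
#'   \code{direction} (+1, -1, or 0 when non-monotonic).
#' @export
loop_monotonic_stats <- function(loop_phases, jitter = 0.25) {
  L <- length(loop_phases)
  if (L < 3L) stop("loop_monotonic_stats: need at least 3 loop members")
  d <- c(loop_phases[-1L], loop_phases[1L]) - loop_phases
  up <- sum(d <= -pi) == 1L && !any(d >= pi) && !any(d < -jitter & d > -pi)
  down <- !up && sum(d >= pi) == 1L && !any(d <= -pi) &&
    !any(d > jitter & d < pi)
  list(gradient = max(loop_phases) - min(loop_phases),
       monotonic = up || down,
       direction = if (up) 1L else if (down) -1L else 0L)
}

# --- detector parameters -------------------------------------------------------

#' Detector parameter set
#'
#' Builds a validated parameter object for one of the four detectors, filled
#' with the published defaults: algorithm 1 uses a 1.5*pi loop-gradient
#' threshold, search radius 3 and centroid clustering; algorithm 2 the same
#' threshold and radius with DBSCAN-style refinement; algorithm 3 a 1.9*pi
#' charge threshold with the 3x3 Sobel kernel and no refinement; algorithm 4 a
#' 3.5 rad jump threshold (about 1.1*pi), radius 1, no refinement.
#'
#' @param algorithm integer 1--4.
#' @param threshold phase-gradient / charge / jump threshold in radians, in
#'   (0, 2*pi].
#' @param radius integer search radius in nodal distances, 1--8 (algorithm 1:
#'   2--8). Ignored by algorithm 3.
#' @param kernel kernel name for algorithm 3: one of
#'   \code{names(\link{ps_kernels})}.
#' @param refine one of "none", "centroid", "dbscan".
#' @param dbscan_distance refinement distance threshold in mm (default 5).
#' @return object of class \code{detector_params}.
#' @export
detector_params <- function(algorithm, threshold = NULL, radius = NULL,
                            kernel = NULL, refine = NULL, dbscan_distance = 5) {
  algorithm <- as.integer(algorithm)
  if (!algorithm %in% 1:4) stop("detector_params: algorithm must be 1..4")
  defaults <- switch(algorithm,
    list(threshold = 1.5 * pi, radius = 3L, kernel = NA, refine = "centroid"),
    list(threshold = 1.5 * pi, radius = 3L, kernel = NA, refine = "dbscan"),
    list(threshold = 1.9 * pi, radius = NA, kernel = "sobel3", refine = "none"),
    list(threshold = 3.5,      radius = 1L, kernel = NA, refine = "none"))
  if (is.null(threshold)) threshold <- defaults$threshold
  if (is.null(radius)) radius <- defaults$radius
  if (is.null(kernel)) kernel <- defaults$kernel
  if (is.null(refine)) refine <- defaults$refine
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 2 * pi)
    stop("detector_params: threshold must be in (0, 2*pi]")
  if (algorithm != 3L) {
    radius <- as.integer(radius)
    lo <- if (algorithm == 1L) 2L else 1L
    if (radius < lo || radius > 8L)
      stop(sprintf("detector_params: radius must be in %d..8 for algorithm %d",
                   lo, algorithm))
  }
  if (algorithm == 3L && !kernel %in% names(ps_kernels))
    stop("detector_params: unknown kernel ", kernel)
  refine <- match.arg(refine, c("none", "centroid", "dbscan"))
  structure(list(algorithm = algorithm, threshold = threshold, radius = radius,
                 kernel = kernel, refine = refine,
                 dbscan_distance = dbscan_distance),
            class = "detector_params")
}

# --- topological charge --------------------------------------------------------

#' Topological charge field of a 2D phase frame
#'
#' Estimates the topological charge n_t = (1/2*pi) * circulation of the phase
#' gradient per grid cell, as the curl of the wrapped one-step phase
#' differences computed by a pair of convolution kernels
#' (\code{\link{ps_kernels}}). The column axis is treated as periodic (seam);
#' rows are clamped. With the \code{nabla2} kernel the result is exactly the
#' winding number of the 2x2 plaquette anchored at each cell.
#'
#' A +1 charge marks a core around which phase increases along the plaquette
#' loop traversed clockwise as seen from outside the cylinder, matching the
#' ring-based detectors' chirality convention.
#'
#' @param frame numeric matrix of wrapped phases (rows x cols).
#' @param kernel_name one of \code{names(\link{ps_kernels})}.
#' @return list of class \code{charge_field}: \code{charge} (n_t per cell),
#'   \code{kx}, \code{ky} (wrapped gradients), \code{kernel}.
#' @export
topological_charge_2d <- function(frame, kernel_name = "sobel3") {
  if (!kernel_name %in% names(ps_kernels))
    stop("topological_charge_2d: unknown kernel ", kernel_name)
  K <- ps_kernels[[kernel_name]]
  if (nrow(frame) < nrow(K$gx) || ncol(frame) < ncol(K$gx))
    stop("topological_charge_2d: frame smaller than kernel")
  g <- phase_gradients(frame)
  raw <- corr2_pc(g$ky, K$gx) + corr2_pc(g$kx, K$gy)
  charge <- raw / (2 * pi * K$gain)
  structure(list(charge = charge, kx = g$kx, ky = g$ky, kernel = kernel_name),
            class = "charge_field")
}

# --- Canny edge detection on the wrapped phase gradient ------------------------

# Edge map of a phase frame: non-maximum suppression and hysteresis applied to
# the magnitude of the wrapped one-step phase gradient (not to raw phase: raw
# phase would mark the wrap line itself everywhere). Thresholds in radians per
# unit grid step.
canny_phase_edges <- function(M, low = 0.3 * pi, high = 0.6 * pi) {
  g <- phase_gradients(M)
  G <- sqrt(g$kx^2 + g$ky^2)
  ang <- atan2(g$ky, g$kx)
  sector <- (round(ang / (pi / 4)) %% 4)
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nms <- matrix(0, nrow(M), ncol(M))
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    nb1 <- shift_pad(G, o[1], o[2], pad = 0)
    nb2 <- shift_pad(G, -o[1], -o[2], pad = 0)
    keep <- (G > nb1 & G >= nb2) & (sector == s)
    nms[keep] <- G[keep]
  }
  strong <- nms >= high
  weak <- nms >= low
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_pad(strong, dr, dc, pad = FALSE)
    }
    new_edges <- weak & grown
    if (all(new_edges == strong)) break
    if (!any(new_edges & !strong)) break
    strong <- strong | new_edges
  }
  strong
}

# count of 8-connected edge neighbors per pixel (periodic columns)
neighbor_count8 <- function(E) {
  cnt <- matrix(0L, nrow(E), ncol(E))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    cnt <- cnt + shift_pad(E, dr, dc, pad = FALSE)
  }
  cnt
}

# count of 4-connected edge neighbors per pixel (periodic columns)
neighbor_count4 <- function(E) {
  shift_pad(E, 1L, 0L, pad = FALSE) + shift_pad(E, -1L, 0L, pad = FALSE) +
    shift_pad(E, 0L, 1L, pad = FALSE) + shift_pad(E, 0L, -1L, pad = FALSE)
}

# label 8-connected components among pixel set given as (row, col) matrix;
# columns periodic. Returns integer component labels.
label_components8 <- function(cells, cols) {
  n <- nrow(cells)
  if (n == 0L) return(integer(0))
  lab <- integer(n)
  key <- paste(cells[, 1], cells[, 2])
  idx_of <- seq_len(n); names(idx_of) <- key
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- cells[p, 1] + dr
        c2 <- ((cells[p, 2] + dc - 1L) %% cols) + 1L
        j <- idx_of[paste(r2, c2)]
        if (!is.na(j) && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# --- per-frame detector cores --------------------------------------------------

empty_detections <- function() {
  data.frame(frame = integer(0), node = integer(0), row = integer(0),
             col = integer(0), chirality = integer(0),
             loop_gradient = numeric(0))
}

# snap with ties toward the lower value
snap_low <- function(x) floor(x + 0.5 - 1e-9)

alg1_frame <- function(M, projection, params, rings,
                       canny_low = 0.3 * pi, canny_high = 0.6 * pi) {
  E <- canny_phase_edges(M, canny_low, canny_high)
  if (!any(E)) return(empty_detections())
  # candidates: ends of edge lines = edge pixels with at most one 4-connected
  # edge neighbor (covers isolated pixels and diagonal line ends; spurious
  # candidates are removed by the monotonic-loop confirmation below)
  cnt <- neighbor_count4(E)
  endpoints <- which(E & cnt <= 1L, arr.ind = TRUE)
  if (nrow(endpoints) == 0L) return(empty_detections())
  keep <- matrix(0L, 0, 2)
  chir <- integer(0); grad <- numeric(0)
  for (i in seq_len(nrow(endpoints))) {
    r <- endpoints[i, 1]; cc <- endpoints[i, 2]
    ring <- rings[[projection$node_of[r, cc]]]
    if (is.null(ring)) next
    st <- loop_monotonic_stats(M[cbind(projection$cell_of[ring, 1],
                                       projection$cell_of[ring, 2])])
    if (st$monotonic && st$gradient >= params$threshold) {
      keep <- rbind(keep, c(r, cc))
      chir <- c(chir, st$direction)
      grad <- c(grad, st$gradient)
    }
  }
  if (nrow(keep) == 0L) return(empty_detections())
  if (params$refine == "none")
    return(data.frame(frame = NA_integer_,
                      node = projection$node_of[keep],
                      row = keep[, 1], col = keep[, 2],
                      chirality = chir, loop_gradient = grad))
  # centroid clustering: replace each 8-connected group by its center of
  # gravity snapped to the nearest cell (circular mean along the seam axis)
  lab <- label_components8(keep, projection$cols)
  out <- lapply(unique(lab), function(l) {
    sel <- lab == l
    r_mean <- mean(keep[sel, 1])
    a <- 2 * pi * (keep[sel, 2] - 1) / projection$cols
    c_mean <- atan2(mean(sin(a)), mean(cos(a))) * projection$cols / (2 * pi) + 1
    r0 <- min(max(snap_low(r_mean), 1L), projection$rows)
    c0 <- ((snap_low(c_mean) - 1L) %% projection$cols) + 1L
    g <- max(grad[sel])
    ch <- chir[sel][which.max(grad[sel])]
    data.frame(frame = NA_integer_, node = projection$node_of[r0, c0],
               row = r0, col = c0, chirality = ch, loop_gradient = g)
  })
  do.call(rbind, out)
}

alg3_frame <- function(M, projection, params) {
  cf <- topological_charge_2d(M, params$kernel)
  val <- 2 * pi * cf$charge
  sel <- which(abs(val) >= params$threshold, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(empty_detections())
  data.frame(frame = NA_integer_,
             node = projection$node_of[sel],
             row = sel[, 1], col = sel[, 2],
             chirality = as.integer(sign(val[sel])),
             loop_gradient = abs(val[sel]))
}

# group precomputed rings by loop length for vectorized ring evaluation
ring_groups <- function(rings) {
  lens <- vapply(rings, function(r) if (is.null(r)) 0L else length(r), 0L)
  out <- list()
  for (L in sort(unique(lens[lens >= 3L]))) {
    centers <- which(lens == L)
    out[[as.character(L)]] <- list(
      L = L, centers = centers,
      members = matrix(unlist(rings[centers]), length(centers), L, byrow = TRUE))
  }
  out
}

row_range <- function(V) {
  n <- nrow(V)
  vmax <- V[cbind(seq_len(n), max.col(V, ties.method = "first"))]
  vmin <- V[cbind(seq_len(n), max.col(-V, ties.method = "first"))]
  vmax - vmin
}

alg2_frame_groups <- function(p, groups, threshold) {
  out <- list()
  for (g in groups) {
    V <- matrix(p[g$members], nrow(g$members), g$L)
    D <- V[, c(2:g$L, 1L), drop = FALSE] - V
    jit <- 0.25
    nwrap_dn <- rowSums(D <= -pi); nwrap_up <- rowSums(D >= pi)
    up <- nwrap_dn == 1L & nwrap_up == 0L &
      rowSums(D < -jit & D > -pi) == 0L
    down <- !up & nwrap_up == 1L & nwrap_dn == 0L &
      rowSums(D > jit & D < pi) == 0L
    grad <- row_range(V)
    keep <- (up | down) & grad >= threshold
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        frame = NA_integer_, node = g$centers[keep],
        row = NA_integer_, col = NA_integer_,
        chirality = ifelse(up[keep], 1L, -1L),
        loop_gradient = grad[keep])
  }
  if (length(out) == 0L) return(empty_detections())
  do.call(rbind, out)
}

alg4_frame_groups <- function(p, groups, threshold) {
  out <- list()
  for (g in groups) {
    V <- matrix(p[g$members], nrow(g$members), g$L)
    D <- V[, c(2:g$L, 1L), drop = FALSE] - V
    s <- rowSums(D < -threshold) - rowSums(D > threshold)
    keep <- (abs(s) %% 2L) == 1L
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        frame = NA_integer_, node = g$centers[keep],
        row = NA_integer_, col = NA_integer_,
        chirality = as.integer(sign(s[keep])),
        loop_gradient = row_range(V)[keep])
  }
  if (length(out) == 0L) return(empty_detections())
  do.call(rbind, out)
}

# --- cluster refinement --------------------------------------------------------

#' Refinement neighborhoods: mesh adjacency plus a metric cut-off
#'
#' Precomputes, for every node, the set of nodes that the cluster refinement
#' treats as neighbors: direct triangulation neighbors plus all nodes within
#' \code{distance} mm (found with a voxel hash, so the cost is linear in the
#' node count). Passing the result to \code{\link{dbscan_refine}} makes
#' per-frame refinement linear in the number of detections, which matters in
#' low-threshold parameter sweeps.
#'
#' @param mesh a \code{\link{tri_mesh}}.
#' @param distance metric cut-off in mm (default 5).
#' @param adj optional precomputed \code{\link{build_neighbor_index}} result.
#' @return list of integer vectors (neighbors per node, self excluded).
#' @export
refine_neighbors <- function(mesh, distance = 5, adj = NULL) {
  if (is.null(adj)) adj <- build_neighbor_index(mesh)
  v <- mesh$vertices
  n <- nrow(v)
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3])
  vox <- floor(v / distance)
  bins <- split(seq_len(n), key(vox))
  out <- vector("list", n)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      b <- bins[[paste(vox[i, 1] + offs[o, 1], vox[i, 2] + offs[o, 2],
                       vox[i, 3] + offs[o, 3])]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    d2 <- (v[cand, 1] - v[i, 1])^2 + (v[cand, 2] - v[i, 2])^2 +
      (v[cand, 3] - v[i, 3])^2
    out[[i]] <- sort(unique(c(cand[d2 <= distance^2], adj[[i]])))
  }
  out
}

# connected components of a detection node set under the refinement
# neighborhoods; returns indices (into `nodes`) of cluster representatives
# (greatest gradient, ties to lowest node index)
refine_components <- function(nodes, grads, nbrs) {
  n <- length(nodes)
  pos <- integer(max(nodes))
  pos[nodes] <- seq_len(n)
  lab <- integer(n)
  cur <- 0L
  reps <- integer(0)
  for (i in seq_len(n)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    comp <- i
    lab[i] <- cur
    queue <- i
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      nb <- nbrs[[nodes[p]]]
      nb <- nb[nb <= length(pos)]
      nbi <- pos[nb]
      nbi <- nbi[nbi > 0L]
      nbi <- nbi[lab[nbi] == 0L]
      if (length(nbi)) {
        lab[nbi] <- cur
        comp <- c(comp, nbi)
        queue <- c(queue, nbi)
      }
    }
    reps <- c(reps, comp[order(-grads[comp], nodes[comp])][1L])
  }
  sort(reps)
}

#' DBSCAN-style cluster refinement of per-frame detections
#'
#' Duplicate detections referring to the same singularity are merged: within
#' each frame, detections that are direct mesh neighbors or within
#' \code{distance} mm of each other are connected, and every connected cluster
#' is replaced by its member with the greatest loop gradient (ties break to
#' the lowest node index). This is a density-based spatial clustering in which
#' the neighbor-searching radius is replaced by triangulation adjacency plus a
#' metric cut-off.
#'
#' @param detections detection data frame (columns \code{frame}, \code{node},
#'   \code{chirality}, \code{loop_gradient}, ...).
#' @param mesh a \code{\link{tri_mesh}} supplying coordinates and adjacency.
#' @param distance distance threshold in mm (default 5).
#' @param nbrs optional precomputed \code{\link{refine_neighbors}} result; it
#'   is computed on the fly otherwise.
#' @return refined detection data frame (one row per cluster); idempotent.
#' @export
dbscan_refine <- function(detections, mesh, distance = 5, nbrs = NULL) {
  if (nrow(detections) == 0L) return(detections)
  if (is.null(nbrs)) nbrs <- refine_neighbors(mesh, distance)
  pieces <- split(detections, detections$frame)
  out <- lapply(pieces, function(d) {
    if (nrow(d) == 1L) return(d)
    d[refine_components(d$node, d$loop_gradient, nbrs), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# --- top-level detection -------------------------------------------------------

#' Detect phase singularities in every frame of a phase sequence
#'
#' Runs one of the four single-frame detectors over all frames:
#' \describe{
#'   \item{1}{2D image-processing detector: Canny edges of the wrapped phase
#'     gradient, edge-line endpoints as candidates, monotonic diamond-loop
#'     confirmation, centroid clustering.}
#'   \item{2}{mesh neighbor-ring detector: every node with a closed sorted
#'     ring at the search radius is tested for monotonic phase progression
#'     exceeding the loop-gradient threshold; DBSCAN-style refinement.}
#'   \item{3}{convolutional topological charge on the 2D projection; cells
#'     with |2*pi*n_t| at or above the threshold are detections.}
#'   \item{4}{ring phase-jump counting on the mesh: an odd signed count of
#'     sudden jumps (raw consecutive differences beyond the threshold) marks a
#'     singularity, the sign giving the chirality.}
#' }
#'
#' @param phase a \code{\link{phase_sequence}} (or a single frame matrix for
#'   the 2D detectors 1 and 3).
#' @param algorithm integer 1--4.
#' @param params a \code{\link{detector_params}}; defaults to the published
#'   defaults for the algorithm.
#' @param mesh,projection geometry; default to those attached to \code{phase}.
#' @param rings optional precomputed rings (\code{\link{mesh_rings}} for
#'   algorithms 2 and 4, \code{\link{grid_rings}} for 1) to amortize across
#'   calls.
#' @param frames optional integer vector of frame indices to process.
#' @return data frame with columns \code{frame}, \code{node}, \code{row},
#'   \code{col}, \code{chirality}, \code{loop_gradient}.
#' @export
detect_ps <- function(phase, algorithm, params = detector_params(algorithm),
                      mesh = NULL, projection = NULL, rings = NULL,
                      frames = NULL) {
  if (is.matrix(phase)) {
    stopifnot(algorithm %in% c(1L, 3L))
    if (is.null(projection))
      projection <- grid_projection(nrow(phase), ncol(phase))
    p <- phase[cbind(projection$cell_of[, 1], projection$cell_of[, 2])]
    phase <- phase_sequence(matrix(p, 1), frame_rate = 1,
                            projection = projection)
  }
  stopifnot(inherits(phase, "phase_sequence"))
  if (params$algorithm != algorithm)
    params <- detector_params(algorithm, threshold = params$threshold,
                              radius = params$radius, kernel = params$kernel,
                              refine = params$refine,
                              dbscan_distance = params$dbscan_distance)
  if (is.null(mesh)) mesh <- phase$mesh
  if (is.null(projection)) projection <- phase$projection
  if (is.null(frames)) frames <- seq_len(nrow(phase$phase))

  if (algorithm %in% c(1L, 3L)) {
    if (is.null(projection))
      stop("detect_ps: algorithms 1 and 3 need a grid projection")
    cellr <- projection$cell_of[, 1]; cellc <- projection$cell_of[, 2]
    if (algorithm == 1L && is.null(rings))
      rings <- grid_rings(projection, params$radius)
    res <- lapply(frames, function(f) {
      M <- matrix(NA_real_, projection$rows, projection$cols)
      M[cbind(cellr, cellc)] <- phase$phase[f, ]
      d <- if (algorithm == 1L) alg1_frame(M, projection, params, rings)
           else alg3_frame(M, projection, params)
      if (nrow(d)) d$frame <- f
      d
    })
  } else {
    if (is.null(mesh)) stop("detect_ps: algorithms 2 and 4 need a mesh")
    if (is.null(rings)) rings <- mesh_rings(mesh, params$radius)
    groups <- ring_groups(rings)
    res <- lapply(frames, function(f) {
      p <- phase$phase[f, ]
      d <- if (algorithm == 2L) alg2_frame_groups(p, groups, params$threshold)
           else alg4_frame_groups(p, groups, params$threshold)
      if (nrow(d)) {
        d$frame <- f
        if (!is.null(projection)) {
          ok <- d$node <= nrow(projection$cell_of)
          d$row[ok] <- projection$cell_of[d$node[ok], 1]
          d$col[ok] <- projection$cell_of[d$node[ok], 2]
        }
      }
      d
    })
  }
  det <- do.call(rbind, res)
  if (is.null(det) || nrow(det) == 0L) return(empty_detections())
  rownames(det) <- NULL
  if (params$refine == "dbscan") {
    if (is.null(mesh))
      stop("detect_ps: DBSCAN refinement needs a mesh")
    det <- dbscan_refine(det, mesh, params$dbscan_distance)
  }
  det
}
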