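#' Triangulated surface mesh
#'
#' Constructs a triangulated 3D surface mesh from vertex coordinates (in mm)
#' and faces with consistent winding, as exported by clinical mapping systems.
#' Validation enforces the structural invariants every downstream detector
#' relies on: all face indices in range, no degenerate (zero-area) faces, no
#' non-manifold edges (an edge shared by more than two faces), and consistent
#' orientation (each interior edge traversed in opposite directions by its two
#' incident faces).
#'
#' @param vertices numeric matrix, one row per vertex, three columns (x, y, z
#'   in mm).
#' @param faces integer matrix, one row per triangle, three columns of 1-based
#'   vertex indices with consistent winding.
#' @param validate logical; run the invariant checks (default \code{TRUE}).
#' @return an object of class \code{tri_mesh}: a list with elements
#'   \code{vertices}, \code{faces} and \code{node_count}.
#' @export
tri_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("tri_mesh: vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("tri_mesh: faces must have 3 columns")
  n <- nrow(vertices)
  mesh <- structure(list(vertices = vertices, faces = faces, node_count = n),
                    class = "tri_mesh")
  if (validate) validate_tri_mesh(mesh)
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              x$node_count, nrow(x$faces)))
  invisible(x)
}

validate_tri_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (any(f < 1L) || any(f > mesh$node_count))
    stop("tri_mesh: face index out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("tri_mesh: face with repeated vertex")
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr^2))
  if (any(area2 <= 1e-12))
    stop("tri_mesh: degenerate (zero-area) face")
  # directed half-edges; an oriented manifold has each directed edge at most
  # once and each undirected edge at most twice
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key_dir))
    stop("tri_mesh: inconsistent face orientation (duplicated directed edge)")
  lo <- pmin(he[, 1], he[, 2]); hi <- pmax(he[, 1], he[, 2])
  key_und <- paste(lo, hi)
  cnt <- table(key_und)
  if (any(cnt > 2))
    stop("tri_mesh: non-manifold edge (more than 2 incident faces)")
  invisible(TRUE)
}

#' Direct neighbor index from triangulation
#'
#' Returns, for every node, the set of vertices sharing an edge with it.
#' This is the adjacency structure the mesh-based detectors iterate over.
#'
#' @param mesh a \code{\link{tri_mesh}}.
#' @return list of length \code{node_count}; element \code{i} is a sorted
#'   integer vector of the direct neighbors of node \code{i}.
#' @export
build_neighbor_index <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  bad <- table(und)
  if (any(bad > 2)) {
    culprit <- names(bad)[which(bad > 2)[1]]
    stop("build_neighbor_index: non-manifold edge (", culprit,
         ") with more than 2 incident faces")
  }
  # symmetrize
  src <- c(he[, 1], he[, 2])
  dst <- c(he[, 2], he[, 1])
  adj <- split(dst, factor(src, levels = seq_len(mesh$node_count)))
  lapply(adj, function(x) sort(unique(x)))
}

# Vertices incident to an edge belonging to exactly one face.
boundary_nodes <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(he[, 1], he[, 2]); hi <- pmax(he[, 1], he[, 2])
  key <- paste(lo, hi)
  once <- !(key %in% key[duplicated(key)])
  sort(unique(c(he[once, 1], he[once, 2])))
}

# Angle-weighted average of incident face normals, unit length.
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- matrix(0, nrow(v), 3)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e12 <- p2 - p1; e23 <- p3 - p2; e31 <- p1 - p3
  fn <- cbind(e12[, 2] * (-e31)[, 3] - e12[, 3] * (-e31)[, 2],
              e12[, 3] * (-e31)[, 1] - e12[, 1] * (-e31)[, 3],
              e12[, 1] * (-e31)[, 2] - e12[, 2] * (-e31)[, 1])
  fn <- fn / sqrt(rowSums(fn^2))
  ang <- function(u, w) {
    cu <- sqrt(rowSums(u^2)); cw <- sqrt(rowSums(w^2))
    acos(pmin(1, pmax(-1, rowSums(u * w) / (cu * cw))))
  }
  a1 <- ang(e12, -e31); a2 <- ang(e23, -e12); a3 <- ang(e31, -e23)
  for (k in 1:3) {
    w <- switch(k, a1, a2, a3)
    idx <- f[, k]
    for (d in 1:3) {
      acc <- rowsum(fn[, d] * w, idx)
      nrm[as.integer(rownames(acc)), d] <- nrm[as.integer(rownames(acc)), d] + acc
    }
  }
  nrm / sqrt(rowSums(nrm^2))
}

#' Euclidean distance between two mesh nodes
#'
#' Straight-line 3D distance in mm (not geodesic): the 5 mm scales used for
#' cluster refinement and detection matching are small relative to atrial
#' curvature, so the chord is an adequate metric.
#'
#' @param mesh a \code{\link{tri_mesh}}.
#' @param i,j node indices (vectors allowed, recycled).
#' @return numeric vector of distances in mm.
#' @export
node_distance <- function(mesh, i, j) {
  d <- mesh$vertices[i, , drop = FALSE] - mesh$vertices[j, , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Sorted neighbor ring at a given nodal radius
#'
#' Extracts the set of nodes at graph distance exactly \code{radius} from
#' \code{center} (an annulus shell, not the filled disc) and orders them
#' clockwise when viewed from outside the surface, i.e. by decreasing angle of
#' their projection onto the tangent plane at \code{center} (the plane
#' orthogonal to the angle-weighted vertex normal). The starting member is the
#' lowest node index; ties in angle break by node index. Nodes whose
#' \code{radius}-hop neighborhood touches an open mesh boundary have no closed
#' ring and return \code{NULL}; callers skip them.
#'
#' @param mesh a \code{\link{tri_mesh}}.
#' @param center node index.
#' @param radius integer nodal (graph) distance, >= 1.
#' @param adj optional precomputed \code{\link{build_neighbor_index}} result.
#' @param normals optional precomputed vertex normal matrix.
#' @param boundary optional precomputed boundary node vector.
#' @return a list with elements \code{center}, \code{radius}, \code{members}
#'   (ordered integer vector) and \code{closed} (are consecutive members
#'   mesh-adjacent, including the closing pair), or \code{NULL}.
#' @export
neighbor_ring_sorted <- function(mesh, center, radius, adj = NULL,
                                 normals = NULL, boundary = NULL) {
  stopifnot(radius >= 1)
  if (is.null(adj)) adj <- build_neighbor_index(mesh)
  if (is.null(boundary)) boundary <- boundary_nodes(mesh)
  dist <- integer(0)
  seen <- center
  frontier <- center
  for (d in seq_len(radius)) {
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    if (length(frontier) == 0L) return(NULL)
    seen <- c(seen, frontier)
  }
  if (any(seen %in% boundary)) return(NULL)  # ring cannot close near a boundary
  members <- frontier
  if (length(members) < 3L) return(NULL)
  if (is.null(normals)) normals <- vertex_normals(mesh)
  n <- normals[center, ]
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  dvec <- mesh$vertices[members, , drop = FALSE] -
    matrix(mesh$vertices[center, ], length(members), 3, byrow = TRUE)
  ang <- atan2(dvec %*% e2, dvec %*% e1)
  ord <- order(-ang, members)   # decreasing angle = clockwise from outside
  members <- members[ord]
  start <- which.min(members)
  if (start > 1L)
    members <- c(members[start:length(members)], members[seq_len(start - 1L)])
  nxt <- c(members[-1L], members[1L])
  closed <- all(mapply(function(a, b) b %in% adj[[a]], members, nxt))
  list(center = center, radius = radius, members = members, closed = closed)
}

#' Neighbor rings for every node of a mesh
#'
#' Precomputes \code{\link{neighbor_ring_sorted}} for all nodes at one radius.
#' Nodes without a closed ring (open boundary within \code{radius} hops) get
#' \code{NULL}; the number skipped is attached as attribute \code{n_skipped}.
#'
#' @inheritParams neighbor_ring_sorted
#' @return list of length \code{node_count} of ordered member vectors (or
#'   \code{NULL}).
#' @export
mesh_rings <- function(mesh, radius, adj = NULL) {
  if (is.null(adj)) adj <- build_neighbor_index(mesh)
  normals <- vertex_normals(mesh)
  boundary <- boundary_nodes(mesh)
  out <- vector("list", mesh$node_count)
  skipped <- 0L
  for (i in seq_len(mesh$node_count)) {
    r <- neighbor_ring_sorted(mesh, i, radius, adj = adj, normals = normals,
                              boundary = boundary)
    if (is.null(r)) skipped <- skipped + 1L else out[[i]] <- r$members
  }
  attr(out, "n_skipped") <- skipped
  out
}
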