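# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cylinder mesh with exact grid projection
#'
#' Builds a triangulated cylinder of \code{rows x cols} vertices emulating the
#' mapping system's shell: 64 longitude columns (periodic) by 32 latitude
#' rows, with the point-by-point cylindrical projection attached. Radius and
#' height default so that neighboring nodes are \code{spacing} mm apart
#' (3.45 mm, the mean inter-node distance of 2048-node clinical shells).
#' With \code{close_caps = TRUE} two apex vertices close the tube into a
#' boundary-free surface (the apexes have no grid cell).
#'
#' @param rows,cols grid size (defaults 32, 64; rows >= 4, cols >= 8).
#' @param spacing target node spacing in mm (default 3.45).
#' @param radius,height cylinder dimensions in mm; default derived from
#'   \code{spacing}.
#' @param close_caps close top and bottom with apex vertices (default FALSE).
#' @return list with elements \code{mesh} (a \code{\link{tri_mesh}} with
#'   outward-oriented faces) and \code{projection} (a
#'   \code{\link{grid_projection}}).
#' @export
make_cylinder_mesh <- function(rows = 32L, cols = 64L, spacing = 3.45,
                               radius = NULL, height = NULL,
                               close_caps = FALSE) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 4L || cols < 8L) stop("make_cylinder_mesh: need rows >= 4, cols >= 8")
  if (is.null(radius)) radius <- spacing / (2 * sin(pi / cols))
  if (is.null(height)) height <- spacing * (rows - 1)
  proj <- grid_projection(rows, cols)
  alpha <- 2 * pi * (proj$cell_of[, 2] - 1) / cols
  z <- (proj$cell_of[, 1] - 1) * height / (rows - 1)
  v <- cbind(radius * cos(alpha), radius * sin(alpha), z)
  faces <- matrix(0L, 0, 3)
  idx <- proj$node_of
  for (r in seq_len(rows - 1L)) {
    cc <- seq_len(cols)
    cn <- c(2:cols, 1L)
    A <- idx[r, cc]; B <- idx[r, cn]; C <- idx[r + 1L, cn]; D <- idx[r + 1L, cc]
    faces <- rbind(faces, cbind(A, B, C), cbind(A, C, D))
  }
  if (close_caps) {
    apex_b <- rows * cols + 1L
    apex_t <- rows * cols + 2L
    v <- rbind(v, c(0, 0, -spacing), c(0, 0, height + spacing))
    cc <- seq_len(cols); cn <- c(2:cols, 1L)
    faces <- rbind(faces,
                   cbind(rep(apex_b, cols), idx[1L, cn], idx[1L, cc]),
                   cbind(rep(apex_t, cols), idx[rows, cc], idx[rows, cn]))
  }
  dimnames(faces) <- NULL
  list(mesh = tri_mesh(v, faces), projection = proj)
}

#' Synthetic rotor scenario
#'
#' Describes a synthetic phase-field episode with known ground truth. Defaults
#' mirror the clinical study conditions: 205 frames at 512 Hz (about 0.4 s),
#' one rotor at 6.4 Hz on a 32 x 64 cylinder, spatial wavenumber 0.35 rad per
#' cell (wavelength about 62 mm at 3.45 mm spacing).
#'
#' @param kind one of "planar", "spiral", "spiral_pair", "meander".
#' @param core numeric (row, col) of the rotor core in fractional grid cells;
#'   default domain center offset by half a cell so the core never sits on a
#'   node. For "spiral_pair", a 2 x 2 matrix of the two cores.
#' @param chirality +1 or -1 (for pairs, the first core's sign; the second is
#'   opposite).
#' @param freq_hz rotor rotation frequency in Hz (default 6.4).
#' @param frame_rate frames per second (default 512).
#' @param wavenumber radial spatial wavenumber in rad per grid cell (default
#'   0.35).
#' @param noise_sd phase-additive Gaussian noise SD in radians (default 0).
#' @param frames number of frames (default 205).
#' @param meander_radius circular drift radius in cells for "meander"
#'   (default 3).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return object of class \code{ps_scenario}.
#' @export
scenario <- function(kind = c("spiral", "planar", "spiral_pair", "meander"),
                     core = NULL, chirality = 1L, freq_hz = 6.4,
                     frame_rate = 512, wavenumber = 0.35, noise_sd = 0,
                     frames = 205L, meander_radius = 3, seed = 1L) {
  kind <- match.arg(kind)
  if (noise_sd < 0) stop("scenario: noise_sd must be >= 0")
  if (!chirality %in% c(-1L, 1L)) stop("scenario: chirality must be +/-1")
  structure(list(kind = kind, core = core, chirality = as.integer(chirality),
                 freq_hz = freq_hz, frame_rate = frame_rate,
                 wavenumber = wavenumber, noise_sd = noise_sd,
                 frames = as.integer(frames), meander_radius = meander_radius,
                 seed = as.integer(seed)),
            class = "ps_scenario")
}

# periodic-aware angular field of a single vortex on a cylinder strip:
# Arg(exp(2i*pi*(z - z0)/L) - 1) has one +1 winding at z0 per period and is
# single-valued across the seam; the compensating charge escapes through the
# bottom boundary (or sits at the bottom apex of a capped mesh).
vortex_angle <- function(col, row, core_col, core_row, L) {
  u <- 2 * pi * (complex(real = col - core_col, imaginary = row - core_row)) / L
  Arg(exp(1i * u) - 1)
}

# shortest periodic distance in cell units
periodic_dist <- function(col, row, core_col, core_row, L) {
  dc <- (col - core_col) %% L
  dc <- pmin(dc, L - dc)
  sqrt(dc^2 + (row - core_row)^2)
}

# chirality +1 means phase increasing along clockwise-from-outside loops
# (the detectors' convention), which is the negative of the mathematical
# counterclockwise angle in (col, row) coordinates
spiral_phase <- function(col, row, core, chir, k, L) {
  th <- vortex_angle(col, row, core[2], core[1], L)
  d <- periodic_dist(col, row, core[2], core[1], L)
  -chir * th - k * d
}

pair_phase <- function(col, row, core1, core2, chir, k, L) {
  u1 <- pi * (complex(real = col - core1[2], imaginary = row - core1[1])) / L
  u2 <- pi * (complex(real = col - core2[2], imaginary = row - core2[1])) / L
  th <- Arg(sin(u1) / sin(u2))
  d <- pmin(periodic_dist(col, row, core1[2], core1[1], L),
            periodic_dist(col, row, core2[2], core2[1], L))
  -chir * th - k * d
}

#' Generate a synthetic phase sequence with ground truth
#'
#' Paints the scenario's analytic phase field on a grid or mesh domain, frame
#' by frame, and returns the exact core annotations. Spirals are Archimedean:
#' \code{phi = wrap(chirality * theta - k * r + omega * t + noise)}, with the
#' angular field constructed to be single-valued across the cylinder seam.
#' On a capped (closed) mesh a single spiral's compensating opposite charge
#' sits at the bottom apex and is recorded in the annotations, so total
#' chirality is zero on boundary-free surfaces. Planar waves travel along the
#' row axis and have no singularity (empty annotation table).
#'
#' @param scen a \code{\link{scenario}}.
#' @param domain a list with \code{mesh} and/or \code{projection} (e.g. the
#'   result of \code{\link{make_cylinder_mesh}}), or a
#'   \code{\link{grid_projection}} alone.
#' @return list with \code{phase} (a \code{\link{phase_sequence}}) and
#'   \code{truth} (data frame \code{frame}, \code{node}, \code{row},
#'   \code{col}, \code{chirality}).
#' @export
synth_phase_sequence <- function(scen, domain) {
  if (inherits(domain, "grid_projection")) domain <- list(projection = domain)
  proj <- domain$projection
  mesh <- domain$mesh
  if (is.null(proj)) stop("synth_phase_sequence: domain needs a projection")
  rows <- proj$rows; cols <- proj$cols
  n_grid <- rows * cols
  n_nodes <- if (!is.null(mesh)) mesh$node_count else n_grid
  capped <- n_nodes == n_grid + 2L
  rr <- proj$cell_of[, 1]; cc <- proj$cell_of[, 2]

  core <- scen$core
  if (is.null(core)) {
    core <- switch(scen$kind,
      spiral = , meander = c(rows / 2 + 0.5, cols / 2 + 0.5),
      spiral_pair = rbind(c(rows / 2 + 0.5, cols / 4 + 0.5),
                          c(rows / 2 + 0.5, 3 * cols / 4 + 0.5)),
      planar = NULL)
  }
  # a core sitting exactly on a node is perturbed half a cell (recorded)
  perturb <- function(co) {
    if (max(abs(co - round(co))) < 1e-9) co + c(0.5, 0.5) else co
  }
  if (!is.null(core)) {
    if (is.matrix(core)) core <- t(apply(core, 1, perturb)) else core <- perturb(core)
  }

  omega <- 2 * pi * scen$freq_hz / scen$frame_rate
  k <- scen$wavenumber
  chir <- scen$chirality
  tt <- seq_len(scen$frames)

  static <- switch(scen$kind,
    planar = k * rr,
    spiral = spiral_phase(cc, rr, core, chir, k, cols),
    spiral_pair = pair_phase(cc, rr, core[1, ], core[2, ], chir, k, cols),
    meander = NULL)

  phase <- matrix(NA_real_, scen$frames, n_nodes)
  truth <- list()
  core_t <- core
  for (f in tt) {
    if (scen$kind == "meander") {
      a <- 2 * pi * (f - 1) / scen$frames
      core_t <- core + scen$meander_radius * c(sin(a), 1 - cos(a))
      base <- spiral_phase(cc, rr, core_t, chir, k, cols)
    } else base <- static
    phase[f, seq_len(n_grid)] <- base + omega * (f - 1)
    if (scen$kind %in% c("spiral", "meander")) {
      r0 <- min(max(round(core_t[1]), 1L), rows)
      c0 <- ((round(core_t[2]) - 1L) %% cols) + 1L
      truth[[f]] <- data.frame(frame = f, node = proj$node_of[r0, c0],
                               row = r0, col = c0, chirality = chir)
      if (capped)   # compensating far-side charge at the bottom apex
        truth[[f]] <- rbind(truth[[f]],
          data.frame(frame = f, node = n_grid + 1L, row = NA_integer_,
                     col = NA_integer_, chirality = -chir))
    } else if (scen$kind == "spiral_pair") {
      snap <- function(co, ch) {
        r0 <- min(max(round(co[1]), 1L), rows)
        c0 <- ((round(co[2]) - 1L) %% cols) + 1L
        data.frame(frame = f, node = proj$node_of[r0, c0], row = r0, col = c0,
                   chirality = ch)
      }
      truth[[f]] <- rbind(snap(core[1, ], chir), snap(core[2, ], -chir))
    }
  }
  if (capped) {
    # apex phases: circular mean of the adjacent boundary row, per frame
    bot <- phase[, proj$node_of[1, ], drop = FALSE]
    top <- phase[, proj$node_of[rows, ], drop = FALSE]
    cmean <- function(M) atan2(rowMeans(sin(M)), rowMeans(cos(M)))
    phase[, n_grid + 1L] <- cmean(bot)
    phase[, n_grid + 2L] <- cmean(top)
  }
  if (scen$noise_sd > 0) {
    noise <- with_seed(scen$seed,
      matrix(stats::rnorm(length(phase), 0, scen$noise_sd), nrow(phase)))
    phase <- phase + noise
  }
  phase <- wrap_phase(phase)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(0), node = integer(0), row = integer(0),
               col = integer(0), chirality = integer(0))
  list(phase = phase_sequence(phase, scen$frame_rate, projection = proj,
                              mesh = mesh),
       truth = truth)
}

#' Synthesize electrograms from a phase sequence
#'
#' Generates one channel per node: \code{a_node * sin(phi(node, t)) + noise},
#' with per-node amplitudes jittered around 1. The quadrature convention
#' (sine, with phase advancing in time) is chosen so that the
#' recomposition-plus-Hilbert pipeline (\code{\link{phase_field}}) recovers
#' the generating phase with no constant offset, keeping the round trip
#' directly comparable.
#'
#' @param phase a \code{\link{phase_sequence}}.
#' @param fs output sampling rate in Hz (default: the phase frame rate).
#' @param amplitude_jitter half-width of the uniform per-node amplitude jitter
#'   (default 0).
#' @param noise_sd additive white noise SD in amplitude units (default 0).
#' @param seed RNG seed.
#' @return an \code{\link{egm_set}} (channels x time, channel i = node i).
#' @export
synth_egm_from_phase <- function(phase, fs = phase$frame_rate,
                                 amplitude_jitter = 0, noise_sd = 0,
                                 seed = 1L) {
  stopifnot(inherits(phase, "phase_sequence"))
  if (fs != phase$frame_rate)
    stop("synth_egm_from_phase: fs must equal the phase frame rate")
  n_nodes <- ncol(phase$phase)
  nt <- nrow(phase$phase)
  sig <- with_seed(seed, {
    a <- 1 + amplitude_jitter * stats::runif(n_nodes, -1, 1)
    s <- t(sin(phase$phase)) * a
    if (noise_sd > 0) s <- s + matrix(stats::rnorm(length(s), 0, noise_sd),
                                      n_nodes, nt)
    s
  })
  egm_set(sig, fs)
}
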