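# On-disk conventions: node, row, col and frame indices are 0-based in every
# text interface (PLY faces are 0-based by format; OBJ faces 1-based by
# format); in memory everything is 1-based R indexing.

#' Read and write triangle meshes (ASCII PLY and OBJ)
#'
#' Minimal readers/writers for the two ASCII formats the package exchanges
#' meshes in. Coordinates are in mm.
#'
#' @param mesh a \code{\link{tri_mesh}}.
#' @param path file path; format chosen by extension (.ply or .obj).
#' @return \code{read_mesh} returns a \code{\link{tri_mesh}};
#'   \code{write_mesh} returns \code{path} invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(format(v, trim = TRUE, digits = 10), 1, paste,
                     collapse = " "), con)
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("v", v[, 1], v[, 2], v[, 3]), con)
    writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
  } else stop("write_mesh: unsupported extension ", ext)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    lines <- readLines(path)
    endh <- which(lines == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)[1]))
    vl <- lines[(endh + 1):(endh + nv)]
    fl <- lines[(endh + nv + 1):(endh + nv + nf)]
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(x) as.numeric(x[1:3])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"),
                               function(x) as.integer(x[2:4]) + 1L))
    tri_mesh(v, f)
  } else if (ext == "obj") {
    lines <- readLines(path)
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(x) as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
    tri_mesh(v, f)
  } else stop("read_mesh: unsupported extension ", ext)
}

#' Read and write a grid projection as CSV
#'
#' Columns \code{node,row,col}, all 0-based on disk.
#'
#' @param projection a \code{\link{grid_projection}}.
#' @param path file path.
#' @export
write_projection_csv <- function(projection, path) {
  df <- data.frame(node = seq_len(nrow(projection$cell_of)) - 1L,
                   row = projection$cell_of[, 1] - 1L,
                   col = projection$cell_of[, 2] - 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_projection_csv
#' @export
read_projection_csv <- function(path) {
  df <- utils::read.csv(path)
  rows <- max(df$row) + 1L; cols <- max(df$col) + 1L
  node_of <- matrix(0L, rows, cols)
  node_of[cbind(df$row + 1L, df$col + 1L)] <- df$node + 1L
  grid_projection(rows, cols, node_of)
}

#' Read and write detection tables as CSV
#'
#' Columns \code{frame,node,row,col,chirality,loop_gradient}; frame, node,
#' row and col are 0-based on disk. Ground-truth annotation tables use the
#' same schema (without \code{loop_gradient}).
#'
#' @param detections detection data frame.
#' @param path file path.
#' @export
write_detections_csv <- function(detections, path) {
  df <- detections
  for (cn in intersect(c("frame", "node", "row", "col"), names(df)))
    df[[cn]] <- df[[cn]] - 1L
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path)
  for (cn in intersect(c("frame", "node", "row", "col"), names(df)))
    df[[cn]] <- df[[cn]] + 1L
  df
}

#' Read and write electrogram sets as delimited text
#'
#' One column per channel with a header row of 0-based node ids; a leading
#' comment line \code{# fs <Hz>} records the sampling rate. Rows are time
#' samples.
#'
#' @param egm an \code{\link{egm_set}}.
#' @param path file path.
#' @export
write_egm_csv <- function(egm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs %.10g", egm$fs), con)
  writeLines(paste(egm$node_map - 1L, collapse = ","), con)
  utils::write.table(t(egm$samples), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_egm_csv
#' @export
read_egm_csv <- function(path) {
  first <- readLines(path, n = 2L)
  if (!grepl("^# fs ", first[1]))
    stop("read_egm_csv: missing '# fs' header line")
  fs <- as.numeric(sub("^# fs ", "", first[1]))
  node_map <- as.integer(strsplit(first[2], ",")[[1]]) + 1L
  m <- as.matrix(utils::read.table(path, sep = ",", skip = 2L))
  dimnames(m) <- NULL
  egm_set(t(m), fs, node_map)
}

#' Read and write phase sequences as delimited text
#'
#' One column per node (header of 0-based node ids), one row per frame; a
#' leading comment line \code{# frame_rate <Hz>}.
#'
#' @param phase a \code{\link{phase_sequence}}.
#' @param path file path.
#' @export
write_phase_csv <- function(phase, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate %.10g", phase$frame_rate), con)
  writeLines(paste(seq_len(ncol(phase$phase)) - 1L, collapse = ","), con)
  utils::write.table(phase$phase, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_csv
#' @export
read_phase_csv <- function(path, projection = NULL, mesh = NULL) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# frame_rate ", first))
    stop("read_phase_csv: missing '# frame_rate' header line")
  fr <- as.numeric(sub("^# frame_rate ", "", first))
  m <- as.matrix(utils::read.table(path, sep = ",", skip = 2L))
  dimnames(m) <- NULL
  phase_sequence(m, fr, projection = projection, mesh = mesh)
}

#' Read and write detector parameters as JSON
#'
#' JSON keys mirror the \code{\link{detector_params}} fields.
#'
#' @param params a \code{\link{detector_params}}.
#' @param path file path.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  detector_params(p$algorithm, threshold = p$threshold,
                  radius = if (is.null(p$radius) || is.na(p$radius)) NULL
                           else p$radius,
                  kernel = if (is.null(p$kernel) || is.na(p$kernel)) NULL
                           else p$kernel,
                  refine = p$refine,
                  dbscan_distance = p$dbscan_distance %||% 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
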