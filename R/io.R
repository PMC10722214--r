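# Portable file formats: plain-text grid files with a metadata header,
# CSV tables, binary state checkpoints and legacy-VTK snapshot export.

#' Write a numeric grid to a plain-text file
#'
#' Format: a header (`fibronet-grid 1`, `nx`, `ny`, `dx`, `field`, `dtype`
#' lines, plus any extra metadata) followed by the body, one line per y-row
#' with nx whitespace-separated values.
#'
#' @param mat numeric or logical nx by ny matrix.
#' @param path output path.
#' @param field field name recorded in the header.
#' @param dx inter-nodal spacing (mm).
#' @param meta named list of extra header entries.
#' @export
write_grid <- function(mat, path, field = "field", dx = 0.3125,
                       meta = list()) {
  stopifnot(is.matrix(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("fibronet-grid 1",
               paste("nx", nrow(mat)), paste("ny", ncol(mat)),
               paste("dx", format(dx, digits = 15)),
               paste("field", field),
               paste("dtype", if (is.logical(mat)) "logical" else "double"),
               vapply(names(meta),
                      function(n) paste(n, format(meta[[n]], digits = 15)),
                      character(1)),
               "body"), con)
  utils::write.table(t(mat * 1), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a grid file written by [write_grid()]
#'
#' @param path file path.
#' @return the matrix, with the header entries attached as attributes
#'   (`field`, `dx`, and any extra metadata).
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "fibronet-grid"))
    stop("not a fibronet grid file: ", path)
  body_at <- match("body", lines)
  hdr <- strsplit(lines[2:(body_at - 1)], " ", fixed = TRUE)
  keys <- vapply(hdr, `[`, character(1), 1)
  vals <- vapply(hdr, function(x) paste(x[-1], collapse = " "), character(1))
  nx <- as.integer(vals[keys == "nx"])
  ny <- as.integer(vals[keys == "ny"])
  body <- scan(text = lines[(body_at + 1):length(lines)], quiet = TRUE)
  m <- matrix(body, nx, ny)
  if (vals[keys == "dtype"] == "logical") m <- m != 0
  attr(m, "field") <- vals[keys == "field"]
  attr(m, "dx") <- as.numeric(vals[keys == "dx"])
  extra <- setdiff(keys, c("nx", "ny", "dx", "field", "dtype"))
  for (k in extra) attr(m, k) <- vals[keys == k]
  m
}

#' Save / load a tissue state checkpoint
#'
#' Checkpoints are RDS containers with a format-version attribute; a reload
#' reproduces continued simulation bitwise.
#'
#' @param state a `tissue_state`.
#' @param path checkpoint path.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "tissue_state"))
  attr(state, "fibronet_checkpoint_version") <- 1L
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  if (is.null(attr(state, "fibronet_checkpoint_version")))
    stop("not a fibronet checkpoint: ", path)
  state
}

#' Export voltage snapshots as a legacy-VTK structured-points series
#'
#' Writes one ASCII `.vtk` file per snapshot column, suitable for movie
#' rendering in ParaView-compatible viewers.
#'
#' @param snapshots matrix of node-by-time voltage snapshots (as returned in
#'   `tissue_result$snapshots`).
#' @param times snapshot times (ms).
#' @param nx,ny grid dimensions.
#' @param dx spacing (mm).
#' @param prefix output path prefix; files are `<prefix>_<index>.vtk`.
#' @export
write_vtk_series <- function(snapshots, times, nx, ny, dx = 0.3125,
                             prefix = "snapshot") {
  stopifnot(nrow(snapshots) == nx * ny)
  paths <- character(ncol(snapshots))
  for (i in seq_len(ncol(snapshots))) {
    path <- sprintf("%s_%04d.vtk", prefix, i)
    con <- file(path, "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("fibronet voltage t=%.3f ms", times[i]),
                 "ASCII", "DATASET STRUCTURED_POINTS",
                 sprintf("DIMENSIONS %d %d 1", nx, ny),
                 sprintf("SPACING %g %g 1", dx, dx),
                 "ORIGIN 0 0 0",
                 sprintf("POINT_DATA %d", nx * ny),
                 "SCALARS voltage double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(snapshots[, i], digits = 8), con)
    close(con)
    paths[i] <- path
  }
  invisible(paths)
}

#' Write a P(TA) result table to CSV
#'
#' @param result a `pta_result`.
#' @param path output path.
#' @param condition named list of condition metadata columns prepended to
#'   every row.
#' @export
write_pta_csv <- function(result, path, condition = list()) {
  stopifnot(inherits(result, "pta_result"))
  row <- c(condition, list(n = result$n, k_focal = result$k_focal,
                           p_ta = result$p_ta))
  write.csv(as.data.frame(row), path, row.names = FALSE)
  invisible(path)
}
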