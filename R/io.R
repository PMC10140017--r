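# Standard-format I/O: NIfTI velocity volumes, STL/PLY surfaces,
# CSV centerlines and waveforms, JSON metadata.

#' Write a velocity field to NIfTI
#'
#' One `.nii.gz` file per velocity component with the cardiac phase as the
#' 4th dimension, plus a JSON sidecar holding VENC, timing and grid
#' metadata. Two dialects: `"velocity"` stores m/s directly;
#' `"phase"` stores the encoded phase `pi * v / VENC` in radians.
#'
#' @param field a [velocity_field].
#' @param prefix output path prefix; files `<prefix>_v{x,y,z}.nii.gz` and
#'   `<prefix>_meta.json` are written.
#' @param dialect `"velocity"` (default) or `"phase"`.
#' @return invisibly, the vector of file paths written.
#' @export
write_velocity_nifti <- function(field, prefix, dialect = c("velocity", "phase")) {
  dialect <- match.arg(dialect)
  comp <- c("vx", "vy", "vz")
  paths <- character(0)
  for (c3 in 1:3) {
    a <- field$v[, , , c3, , drop = TRUE]
    if (field$n_phases == 1) a <- array(a, c(field$dim, 1))
    if (dialect == "phase") a <- pi * a / field$venc
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- c(field$spacing, field$dt / 1000)
    p <- sprintf("%s_%s.nii.gz", prefix, comp[c3])
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  meta <- list(venc_ms = field$venc, dt_ms = field$dt,
               n_phases = field$n_phases, origin_mm = field$origin,
               spacing_mm = field$spacing, dialect = dialect)
  mp <- sprintf("%s_meta.json", prefix)
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read a velocity field from NIfTI component files
#'
#' @param paths character length 3: the x, y, z component files.
#' @param venc m/s; taken from the sidecar if `NULL`.
#' @param dt ms; taken from the sidecar if `NULL`.
#' @param meta path to the JSON sidecar written by
#'   [write_velocity_nifti]; by default derived from `paths[1]`.
#' @return a [velocity_field] (mask all-TRUE; apply [mask_lumen]).
#' @export
read_velocity_nifti <- function(paths, venc = NULL, dt = NULL, meta = NULL) {
  stopifnot(length(paths) == 3)
  if (is.null(meta)) meta <- sub("_v[xyz]\\.nii(\\.gz)?$", "_meta.json", paths[1])
  md <- if (file.exists(meta)) jsonlite::read_json(meta, simplifyVector = TRUE) else list()
  if (is.null(venc)) venc <- md$venc_ms
  if (is.null(dt)) dt <- md$dt_ms
  if (is.null(venc)) stop("VENC not given and no metadata sidecar found", call. = FALSE)
  arrs <- lapply(paths, function(p) {
    a <- as.array(RNifti::readNifti(p))
    if (length(dim(a)) == 3) a <- array(a, c(dim(a), 1))
    a
  })
  if (length(unique(lapply(arrs, dim))) != 1) {
    stop("velocity component volumes have mismatched shapes", call. = FALSE)
  }
  d <- dim(arrs[[1]])
  v <- array(0, c(d[1:3], 3, d[4]))
  for (c3 in 1:3) v[, , , c3, ] <- arrs[[c3]]
  if (identical(md$dialect, "phase")) v <- venc * v / pi
  origin <- if (!is.null(md$origin_mm)) md$origin_mm else c(0, 0, 0)
  spacing <- if (!is.null(md$spacing_mm)) md$spacing_mm else
    RNifti::pixdim(RNifti::readNifti(paths[1]))[1:3]
  velocity_field(v, origin, spacing, dt = if (is.null(dt)) 49 else dt,
                 venc = venc)
}

#' Write a surface to ASCII STL
#' @param surface a [vessel_surface].
#' @param path output file.
#' @export
write_surface_stl <- function(surface, path) {
  nrm <- triangle_cross(surface)
  len <- pmax(rownorms(nrm), 1e-30)
  nrm <- nrm / len
  v <- surface$vertices; tr <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  blocks <- vapply(seq_len(nrow(tr)), function(i) {
    p <- v[tr[i, ], , drop = FALSE]
    paste0(sprintf(" facet normal %g %g %g\n  outer loop\n", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
           paste(sprintf("   vertex %g %g %g", p[, 1], p[, 2], p[, 3]), collapse = "\n"),
           "\n  endloop\n endfacet")
  }, character(1))
  writeLines(blocks, con)
  writeLines("endsolid surface", con)
  invisible(path)
}

#' Read an ASCII STL surface
#'
#' Vertices are merged exactly (identical coordinate triples).
#' @param path STL file.
#' @return a [vessel_surface].
#' @export
read_surface_stl <- function(path) {
  ln <- readLines(path)
  vx <- grep("^\\s*vertex", ln, value = TRUE)
  m <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  key <- paste(m[, 1], m[, 2], m[, 3])
  uk <- unique(key)
  idx <- match(key, uk)
  verts <- m[match(uk, key), , drop = FALSE]
  vessel_surface(verts, matrix(idx, ncol = 3, byrow = TRUE))
}

#' Write a surface to ASCII PLY
#' @param surface a [vessel_surface].
#' @param path output file.
#' @export
write_surface_ply <- function(surface, path) {
  v <- surface$vertices; tr <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1, tr[, 2] - 1, tr[, 3] - 1), con)
  invisible(path)
}

#' Read an ASCII PLY surface
#' @param path PLY file.
#' @return a [vessel_surface].
#' @export
read_surface_ply <- function(path) {
  ln <- readLines(path)
  hd_end <- which(ln == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", ln, value = TRUE)[1]))
  vl <- ln[hd_end + seq_len(nv)]
  fl <- ln[hd_end + nv + seq_len(nf)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[1:3])))
  tris <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) as.integer(x[2:4]) + 1L))
  vessel_surface(verts, tris)
}

#' Write a centerline to CSV (columns s, x_mm, y_mm, z_mm, d_mm)
#' @param cl a [centerline].
#' @param path output file.
#' @export
write_centerline_csv <- function(cl, path) {
  utils::write.csv(data.frame(s = cl$arclength, x_mm = cl$points[, 1],
                              y_mm = cl$points[, 2], z_mm = cl$points[, 3],
                              d_mm = cl$d_vessel),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a centerline from CSV
#' @param path CSV with columns s, x_mm, y_mm, z_mm, d_mm.
#' @return a [centerline].
#' @export
read_centerline_csv <- function(path) {
  d <- utils::read.csv(path)
  centerline(cbind(d$x_mm, d$y_mm, d$z_mm), d$d_mm)
}

#' Write a flow waveform to CSV (columns t_s, q_ml_s)
#' @param waveform a [flow_waveform].
#' @param path output file.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(data.frame(t_s = waveform$times, q_ml_s = waveform$q),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a flow waveform from CSV
#' @param path CSV with columns t_s, q_ml_s.
#' @param f0 fundamental frequency, Hz (default `1 / period`).
#' @return a [flow_waveform].
#' @export
read_waveform_csv <- function(path, f0 = NULL) {
  d <- utils::read.csv(path)
  flow_waveform(d$t_s, d$q_ml_s, f0 = f0)
}
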