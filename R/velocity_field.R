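#' Time-resolved 3-component velocity field on a regular voxel grid
#'
#' The container consumed by every pipeline stage. Coordinates are physical
#' millimetres on a cell-centred, right-handed grid: the centre of voxel
#' `(1,1,1)` is at `origin` and voxel centres are spaced by `spacing`.
#' Velocities are stored in m/s as a 5-D array with axis order
#' (x, y, z, component, cardiac phase).
#'
#' @param v 5-D numeric array `[nx, ny, nz, 3, n_phases]`, m/s.
#' @param origin numeric length 3, mm.
#' @param spacing numeric length 3, mm (default 0.5 mm isotropic).
#' @param dt temporal resolution, ms (default 49).
#' @param venc velocity-encoding limit, m/s.
#' @param mask logical array `[nx, ny, nz]`; voxels belonging to the lumen.
#'   All statistics are taken over masked voxels only.
#' @param ground_truth optional list of analytic reference quantities
#'   attached by the synthetic generators.
#' @return Object of class `velocity_field`.
#' @export
velocity_field <- function(v, origin, spacing = c(0.5, 0.5, 0.5), dt = 49,
                           venc = 1.1, mask = NULL, ground_truth = NULL) {
  stopifnot(length(dim(v)) == 5, dim(v)[4] == 3)
  spacing <- rep_len(spacing, 3)
  stopifnot_positive(spacing, dt, venc)
  if (is.null(mask)) mask <- array(TRUE, dim(v)[1:3])
  stopifnot(identical(dim(mask), dim(v)[1:3]))
  structure(list(v = v, origin = as.numeric(origin), spacing = spacing,
                 dim = dim(v)[1:3], n_phases = dim(v)[5], dt = dt,
                 venc = venc, mask = mask, ground_truth = ground_truth),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "Velocity field: %d x %d x %d voxels (%.2g mm), %d phases at %g ms, VENC %g m/s\n",
    x$dim[1], x$dim[2], x$dim[3], x$spacing[1], x$n_phases, x$dt, x$venc))
  cat(sprintf("  lumen mask: %d voxels; peak speed %.3f m/s\n",
              sum(x$mask), max(field_speed(x))))
  invisible(x)
}

#' Voxel-centre coordinates of a field's grid
#' @param field a [velocity_field].
#' @return list of axis coordinate vectors `x`, `y`, `z` (mm).
#' @export
grid_axes <- function(field) {
  list(x = field$origin[1] + (seq_len(field$dim[1]) - 1) * field$spacing[1],
       y = field$origin[2] + (seq_len(field$dim[2]) - 1) * field$spacing[2],
       z = field$origin[3] + (seq_len(field$dim[3]) - 1) * field$spacing[3])
}

# n_voxel x 3 matrix of all voxel centres (x fastest), mm
grid_points <- function(field) {
  ax <- grid_axes(field)
  as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z, KEEP.OUT.ATTRS = FALSE))
}

# speed magnitude array [nx,ny,nz,n_phases]
field_speed <- function(field) {
  sqrt(field$v[, , , 1, , drop = FALSE]^2 +
         field$v[, , , 2, , drop = FALSE]^2 +
         field$v[, , , 3, , drop = FALSE]^2)[, , , 1, , drop = TRUE]
}

# spatial mean speed inside the mask, one value per phase
masked_mean_speed <- function(field) {
  sp <- field_speed(field)
  if (field$n_phases == 1) sp <- array(sp, c(field$dim, 1))
  apply(sp, 4, function(s) mean(s[field$mask]))
}

#' Grid specification helper for the synthetic generators
#'
#' Builds a grid that encloses a tube of given radius and length aligned
#' with the z axis and centred on x = y = 0, with one voxel of margin.
#'
#' @param radius tube radius, mm.
#' @param length tube length, mm.
#' @param spacing voxel size, mm (isotropic).
#' @return list with `origin`, `spacing`, `dim`.
#' @export
tube_grid <- function(radius, length, spacing = 0.5) {
  stopifnot_positive(radius, length, spacing)
  nxy <- 2 * ceiling(radius / spacing) + 3
  nz <- ceiling(length / spacing) + 3
  half <- (nxy - 1) / 2
  list(origin = c(-half * spacing, -half * spacing, -spacing),
       spacing = rep(spacing, 3), dim = c(nxy, nxy, nz))
}
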