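# Velocity preprocessing: temporal phase-unwrap, normalized-median outlier
# repair, lumen masking.

#' Temporal phase-wrap correction of a velocity field
#'
#' Velocity aliasing in a phase-contrast acquisition adds +/- 2 VENC jumps
#' between consecutive cardiac phases (phase steps beyond +/- pi). Starting
#' from the diastolic baseline (the cardiac phase with minimum spatial-mean
#' speed inside the mask) and walking forward cyclically in time, whenever
#' the step of a voxel's component between consecutive phases exceeds
#' +VENC, 2 VENC is subtracted from all subsequent samples, and added for
#' steps below -VENC. The corrected output may legitimately exceed VENC.
#'
#' Residual steps still larger than VENC after correction (unresolvable
#' multiple wraps within one step) are reported in the `"unresolved"`
#' attribute.
#'
#' @param field a [velocity_field].
#' @param venc velocity-encoding limit, m/s.
#' @return corrected [velocity_field].
#' @export
unwrap_temporal <- function(field, venc = field$venc) {
  stopifnot_positive(venc)
  if (field$n_phases < 2) stop("need at least 2 cardiac phases", call. = FALSE)
  base <- which.min(masked_mean_speed(field))
  n <- field$n_phases
  ord <- ((base - 1 + 0:(n - 1)) %% n) + 1
  nvox <- prod(field$dim) * 3
  v <- matrix(field$v[, , , , ord], nrow = nvox)   # voxels*components x phases
  d <- v[, -1, drop = FALSE] - v[, -n, drop = FALSE]
  k <- (d > venc) - (d < -venc)
  kcum <- t(apply(k, 1, cumsum))
  v[, -1] <- v[, -1] - 2 * venc * kcum
  # verify: any residual super-VENC step is an unresolved multiple wrap
  d2 <- v[, -1, drop = FALSE] - v[, -n, drop = FALSE]
  unresolved <- which(rowSums(abs(d2) > venc + 1e-12) > 0)
  out <- field
  out$v[, , , , ord] <- array(v, c(field$dim, 3, n))
  attr(out, "unresolved") <- unresolved
  out
}

#' Normalized-median outlier detection and repair
#'
#' Spurious velocity vectors near the wall are detected with a normalized
#' median test using the 8 in-plane neighbour vectors and a detection
#' threshold of 1: per voxel, phase and component, with `m` the median of
#' the valid neighbours and `r_med` the median absolute neighbour residual,
#' a voxel is flagged when the maximum over components of
#' `|v - m| / (r_med + epsilon)` exceeds `threshold`. Flagged voxels are
#' replaced by the component-wise neighbourhood median. Voxels with fewer
#' than 3 valid (in-mask) neighbours are left untouched and listed
#' separately.
#'
#' @param field a [velocity_field], masked to the lumen.
#' @param threshold detection threshold (default 1).
#' @param epsilon noise floor, m/s (default `0.05 * venc`).
#' @param slice_axis axis orthogonal to the 8-neighbour plane; `NULL`
#'   (default) picks the dominant flow axis (largest mean absolute
#'   component inside the mask).
#' @return list with `field` (repaired) and `report` (data frame: voxel
#'   index triple, phase, residual ratio, replacement values) plus a
#'   `skipped` attribute listing voxels with too few neighbours.
#' @export
median_filter_outliers <- function(field, threshold = 1,
                                   epsilon = 0.05 * field$venc,
                                   slice_axis = NULL) {
  stopifnot_positive(epsilon, threshold)
  if (is.null(slice_axis)) {
    mm <- sapply(1:3, function(c3) {
      mean(abs(field$v[, , , c3, ])[array(field$mask, c(field$dim, field$n_phases))])
    })
    slice_axis <- which.max(mm)
  }
  dims <- field$dim
  mask <- field$mask
  # in-plane neighbour offsets in the two axes != slice_axis
  ax <- setdiff(1:3, slice_axis)
  offs <- expand.grid(a = -1:1, b = -1:1)
  offs <- offs[!(offs$a == 0 & offs$b == 0), ]
  idx_all <- which(mask, arr.ind = TRUE)
  n_m <- nrow(idx_all)
  # neighbour linear indices (n_m x 8), NA when off-grid or out of mask
  nb_idx <- matrix(NA_integer_, n_m, 8)
  for (o in seq_len(8)) {
    sh <- idx_all
    sh[, ax[1]] <- sh[, ax[1]] + offs$a[o]
    sh[, ax[2]] <- sh[, ax[2]] + offs$b[o]
    ok <- sh[, 1] >= 1 & sh[, 1] <= dims[1] & sh[, 2] >= 1 & sh[, 2] <= dims[2] &
      sh[, 3] >= 1 & sh[, 3] <= dims[3]
    lin <- rep(NA_integer_, n_m)
    lin[ok] <- sh[ok, 1] + dims[1] * (sh[ok, 2] - 1) + dims[1] * dims[2] * (sh[ok, 3] - 1)
    valid <- !is.na(lin)
    valid[valid] <- mask[lin[valid]]
    lin[!valid] <- NA_integer_
    nb_idx[, o] <- lin
  }
  n_valid <- rowSums(!is.na(nb_idx))
  eligible <- n_valid >= 3
  out <- field
  rows <- list()
  for (p in seq_len(field$n_phases)) {
    ratio_max <- rep(0, n_m)
    med_all <- matrix(NA_real_, n_m, 3)
    for (c3 in 1:3) {
      vol <- field$v[, , , c3, p]
      nb_v <- matrix(vol[nb_idx], n_m, 8)
      m <- apply(nb_v, 1, stats::median, na.rm = TRUE)
      r_med <- apply(abs(nb_v - m), 1, stats::median, na.rm = TRUE)
      vi <- vol[idx_all]
      ratio <- abs(vi - m) / (r_med + epsilon)
      ratio_max <- pmax(ratio_max, ifelse(is.na(ratio), 0, ratio))
      med_all[, c3] <- m
    }
    flag <- eligible & ratio_max > threshold
    if (any(flag)) {
      for (c3 in 1:3) {
        vol <- out$v[, , , c3, p]
        vol[idx_all[flag, , drop = FALSE]] <- med_all[flag, c3]
        out$v[, , , c3, p] <- vol
      }
      rows[[p]] <- data.frame(i = idx_all[flag, 1], j = idx_all[flag, 2],
                              k = idx_all[flag, 3], phase = p,
                              ratio = ratio_max[flag],
                              vx = med_all[flag, 1], vy = med_all[flag, 2],
                              vz = med_all[flag, 3])
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               phase = integer(0), ratio = numeric(0),
               vx = numeric(0), vy = numeric(0), vz = numeric(0))
  attr(report, "skipped") <- idx_all[!eligible, , drop = FALSE]
  attr(report, "slice_axis") <- slice_axis
  list(field = out, report = report)
}

#' Mask a velocity field to the lumen of a registered surface
#'
#' Sets the lumen mask to the voxels whose centre lies inside the (rigidly
#' transformed) closed surface; velocities outside are zeroed and excluded
#' from all downstream statistics.
#'
#' @param field a [velocity_field].
#' @param surface a watertight [vessel_surface].
#' @param transform optional [rigid_transform] mapping surface coordinates
#'   into image coordinates (default identity).
#' @return masked [velocity_field].
#' @export
mask_lumen <- function(field, surface, transform = NULL) {
  if (!is_watertight(surface)) {
    stop("surface is not watertight", call. = FALSE)
  }
  if (!is.null(transform)) surface <- apply_transform(surface, transform)
  pts <- grid_points(field)
  inside <- points_in_surface(surface, pts, check_watertight = FALSE)
  if (!any(inside)) stop("transformed surface contains no voxel centres",
                         call. = FALSE)
  mask <- array(inside, field$dim)
  out <- field
  out$mask <- mask
  keep <- array(rep(mask, 3 * field$n_phases), dim(field$v))
  out$v[!keep] <- 0
  out
}
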