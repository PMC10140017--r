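# Wall shear stress on the sac wall, time-averaged WSS and the
# oscillatory shear index.
#
# The WSS vector is the tangential projection of the viscous traction:
# in the local basis B = {t1, t2, n} at a wall point,
#   WSS = mu * (d v_t1 / d xi3, d v_t2 / d xi3, 0)_B
# with xi3 the inward-normal coordinate; the pressure part of the Cauchy
# stress drops out of the tangential projection and the tangential
# derivatives of the normal component vanish by no-slip.

#' Inward wall normals by local principal component analysis
#'
#' Per wall point, the normal is the smallest-variance principal axis of
#' its `k` nearest neighbours; the sign is chosen so a probe point
#' displaced by `delta` along the normal lies inside the lumen. Tangents
#' `t1`, `t2` complete a right-handed orthonormal basis.
#'
#' @param points n x 3 matrix of wall points, mm.
#' @param k number of nearest neighbours (default 20).
#' @param inside_test function mapping an m x 3 point matrix to a logical
#'   vector (TRUE inside the lumen): e.g. built from the lumen mask or a
#'   closed surface.
#' @param delta probe displacement, mm (default 0.1).
#' @return list with `normals`, `t1`, `t2` (n x 3 matrices) and `flagged`
#'   (logical: orientation ambiguous or neighbourhood degenerate; excluded
#'   downstream).
#' @export
pca_normals <- function(points, k = 20, inside_test, delta = 0.1) {
  points <- matrix(points, ncol = 3)
  n <- nrow(points)
  if (n < k + 1) stop(sprintf("need at least k+1 = %d points", k + 1), call. = FALSE)
  d2 <- outer(rowSums(points^2), rowSums(points^2), "+") - 2 * tcrossprod(points)
  normals <- matrix(0, n, 3)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k + 1)]   # includes the point itself
    x <- sweep(points[nb, , drop = FALSE], 2, colMeans(points[nb, , drop = FALSE]))
    sv <- svd(x, nu = 0)
    if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-30)) { flagged[i] <- TRUE; next }
    normals[i, ] <- sv$v[, 3]
  }
  probe_in <- inside_test(points + delta * normals)
  probe_out <- inside_test(points - delta * normals)
  flip <- !probe_in & probe_out
  normals[flip, ] <- -normals[flip, ]
  flagged <- flagged | (!probe_in & !probe_out)
  t1 <- matrix(0, n, 3); t2 <- matrix(0, n, 3)
  for (i in which(!flagged)) {
    tb <- tangent_basis(normals[i, ])
    t1[i, ] <- tb$t1; t2[i, ] <- tb$t2
  }
  list(normals = normals, t1 = t1, t2 = t2, flagged = flagged)
}

# one-sided cubic-interpolant derivative at 0 for samples at xi = h*(0:3),
# with the wall sample forced to zero: f'(0) = (18 f1 - 9 f2 + 2 f3)/(6 h)
cubic_wall_derivative <- function(f1, f2, f3, h) {
  (18 * f1 - 9 * f2 + 2 * f3) / (6 * h)
}

#' Wall shear stress vector at a single wall point
#'
#' Velocities are sampled at `n_samples` points spaced along the inward
#' normal over `normal_length` (the wall sample forced to the no-slip
#' zero); each tangential velocity component is fitted by the cubic
#' polynomial interpolant through the samples and the WSS is `mu` times
#' its derivative at the wall, expressed back in world coordinates. The
#' estimate is exact for velocity profiles up to cubic in the normal
#' coordinate.
#'
#' @param field a [velocity_field], or a sampler `function(pts, phase)`
#'   returning an m x 3 velocity matrix (m/s) for exact analytic sampling.
#' @param vertex wall point, mm.
#' @param basis list with unit `normal` (inward), `t1`, `t2`.
#' @param mu dynamic viscosity, Pa s.
#' @param phase cardiac phase index.
#' @param n_samples points along the normal including the wall (default 4).
#' @param normal_length length of the sampling segment, mm (default 1.5).
#' @return WSS vector (Pa, world coordinates; tangent to the wall), or
#'   `NULL` if any sample falls outside the field grid.
#' @export
wss_at_vertex <- function(field, vertex, basis, mu, phase = 1,
                          n_samples = 4, normal_length = 1.5) {
  h <- normal_length / (n_samples - 1)
  xi <- h * seq_len(n_samples - 1)           # off-wall sample offsets, mm
  pts <- matrix(vertex, n_samples - 1, 3, byrow = TRUE) + outer(xi, basis$normal)
  vel <- if (is.function(field)) field(pts, phase) else
    interp_velocity(field, pts, phase)
  if (any(is.na(vel))) return(NULL)
  vt1 <- as.vector(vel %*% basis$t1)
  vt2 <- as.vector(vel %*% basis$t2)
  # derivative in 1/mm -> *1e3 for SI; WSS = mu * dv/dn
  g1 <- cubic_wall_derivative(vt1[1], vt1[2], vt1[3], h) * 1e3
  g2 <- cubic_wall_derivative(vt2[1], vt2[2], vt2[3], h) * 1e3
  mu * (g1 * basis$t1 + g2 * basis$t2)
}

#' Time-resolved WSS record on a sac wall
#'
#' Applies [wss_at_vertex] to every wall vertex and cardiac phase. Normals
#' are estimated by [pca_normals] from the sac vertices, oriented into the
#' lumen via the field mask. Vertices whose normals are ambiguous or whose
#' sample segments leave the grid are flagged and excluded from the
#' summary statistics; more than `max_flagged_frac` flagged vertices is an
#' error (geometry or registration is then suspect).
#'
#' @param field a [velocity_field] (preprocessed, masked).
#' @param sac a [vessel_surface] (wall vertices are used), or an n x 3
#'   point matrix.
#' @param mu dynamic viscosity, Pa s.
#' @param k neighbours for the normal estimate.
#' @param n_samples,normal_length see [wss_at_vertex].
#' @param sampler optional analytic sampler forwarded to [wss_at_vertex].
#' @param max_flagged_frac error threshold on flagged vertices
#'   (default 0.2).
#' @param eval_subset optional integer/logical index of wall points at
#'   which to evaluate the WSS; normals are always estimated from the full
#'   point cloud (subsampling the cloud itself would degrade them).
#' @return Object of class `wss_record`: `wss` array
#'   `[n_vertex, 3, n_phases]` (Pa), `vertices`, `normals`, `flagged`,
#'   `dt` (ms), per-phase spatial `max_mag` and `mean_mag` over unflagged
#'   vertices.
#' @export
wss_field <- function(field, sac, mu = fluid_properties()$dynamic_viscosity,
                      k = 20, n_samples = 4, normal_length = 1.5,
                      sampler = NULL, max_flagged_frac = 0.2,
                      eval_subset = NULL) {
  pts <- if (inherits(sac, "vessel_surface")) sac$vertices else matrix(sac, ncol = 3)
  inside_test <- function(p) {
    val <- interp_trilinear(field$mask * 1, field$origin, field$spacing, p)
    !is.na(val) & val > 0.5
  }
  # probe deep enough that the interpolated mask is decisive at this voxel size
  delta <- max(0.1, 0.75 * max(field$spacing))
  nb <- pca_normals(pts, k = k, inside_test = inside_test, delta = delta)
  if (!is.null(eval_subset)) {
    sel <- if (is.logical(eval_subset)) which(eval_subset) else eval_subset
    pts <- pts[sel, , drop = FALSE]
    nb$normals <- nb$normals[sel, , drop = FALSE]
    nb$t1 <- nb$t1[sel, , drop = FALSE]
    nb$t2 <- nb$t2[sel, , drop = FALSE]
    nb$flagged <- nb$flagged[sel]
  }
  n_v <- nrow(pts)
  wss <- array(NA_real_, c(n_v, 3, field$n_phases))
  flagged <- nb$flagged
  src <- if (is.null(sampler)) field else sampler
  for (i in seq_len(n_v)) {
    if (flagged[i]) next
    basis <- list(normal = nb$normals[i, ], t1 = nb$t1[i, ], t2 = nb$t2[i, ])
    for (p in seq_len(field$n_phases)) {
      w <- wss_at_vertex(src, pts[i, ], basis, mu, phase = p,
                         n_samples = n_samples, normal_length = normal_length)
      if (is.null(w)) { flagged[i] <- TRUE; break }
      wss[i, , p] <- w
    }
  }
  if (mean(flagged) > max_flagged_frac) {
    stop(sprintf("%.0f%% of wall vertices flagged; geometry/registration suspect",
                 100 * mean(flagged)), call. = FALSE)
  }
  mags <- sqrt(apply(wss^2, c(1, 3), sum))
  ok <- !flagged
  structure(list(wss = wss, vertices = pts, normals = nb$normals,
                 flagged = flagged, dt = field$dt,
                 max_mag = apply(mags[ok, , drop = FALSE], 2, max),
                 mean_mag = apply(mags[ok, , drop = FALSE], 2, mean)),
            class = "wss_record")
}

#' @export
print.wss_record <- function(x, ...) {
  cat(sprintf(
    "WSS record: %d vertices x %d phases (%d flagged); peak |WSS| %.2f Pa\n",
    nrow(x$vertices), dim(x$wss)[3], sum(x$flagged), max(x$max_mag)))
  invisible(x)
}

#' Time-averaged WSS vector and magnitude
#'
#' Vector rectangle-rule average over the uniformly sampled periodic
#' cardiac cycle.
#'
#' @param record a `wss_record` (or an `[n_vertex, 3, n_phases]` array).
#' @return list with `vector` (n x 3, Pa) and `magnitude` (n, Pa).
#' @export
tawss <- function(record) {
  w <- if (inherits(record, "wss_record")) record$wss else record
  if (any(is.na(w)) && all(is.na(w))) stop("no WSS samples", call. = FALSE)
  vec <- apply(w, c(1, 2), mean)
  list(vector = vec, magnitude = rownorms(vec))
}

#' Oscillatory shear index
#'
#' `OSI = (1 - ||int WSS dt|| / int ||WSS|| dt) / 2`, in `[0, 0.5]`:
#' 0 for unidirectional shear, 0.5 for fully reversing shear. The same
#' rectangle-rule quadrature as [tawss] is used; vertices with zero
#' denominator (dead flow for the whole cycle) are reported as `NA`
#' rather than 0 or 0.5.
#'
#' @param record a `wss_record` (or an `[n_vertex, 3, n_phases]` array).
#' @return numeric vector of per-vertex OSI.
#' @export
osi <- function(record) {
  w <- if (inherits(record, "wss_record")) record$wss else record
  num <- rownorms(apply(w, c(1, 2), mean))
  den <- rowMeans(sqrt(apply(w^2, c(1, 3), sum)))
  out <- 0.5 * (1 - num / den)
  out[!is.na(den) & den == 0] <- NA_real_
  # clamp quadrature round-off
  pmin(pmax(out, 0), 0.5)
}
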