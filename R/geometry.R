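# Vessel and aneurysm geometry: rigid transforms, centerline extraction,
# co-registration, sac isolation, neck-plane fit, morphometrics,
# measurement planes.

#' Rigid-body transform
#'
#' Rotation parametrised by extrinsic x-y-z Euler angles (degrees) plus a
#' translation (mm). The rotation matrix is proper orthonormal.
#'
#' @param angles numeric length 3, degrees.
#' @param translation numeric length 3, mm.
#' @return Object of class `rigid_transform` with `angles`, `translation`
#'   and the 3 x 3 rotation matrix `r`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  a <- angles * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  structure(list(angles = angles, translation = translation, r = rz %*% ry %*% rx),
            class = "rigid_transform")
}

#' Apply a rigid transform to points, a surface or a centerline
#' @param x n x 3 matrix, [vessel_surface] or [centerline].
#' @param transform a [rigid_transform].
#' @return transformed object of the same type.
#' @export
apply_transform <- function(x, transform) {
  tf_pts <- function(p) {
    t(transform$r %*% t(p)) +
      matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  }
  if (inherits(x, "vessel_surface")) {
    vessel_surface(tf_pts(x$vertices), x$triangles)
  } else if (inherits(x, "centerline")) {
    centerline(tf_pts(x$points), x$d_vessel)
  } else {
    tf_pts(matrix(x, ncol = 3))
  }
}

# nearest-centerline-point lookup: for each query row return index and
# distance to the closest centerline point
nearest_centerline_point <- function(cl, pts) {
  pts <- matrix(pts, ncol = 3)
  cp <- cl$points
  n <- nrow(pts)
  idx <- integer(n); dist <- numeric(n)
  block <- 4096L
  for (s in seq(1, n, by = block)) {
    e <- min(n, s + block - 1)
    d2 <- outer(rowSums(pts[s:e, , drop = FALSE]^2), rowSums(cp^2), "+") -
      2 * pts[s:e, , drop = FALSE] %*% t(cp)
    idx[s:e] <- max.col(-d2, ties.method = "first")
    dist[s:e] <- sqrt(pmax(0, d2[cbind(seq_len(e - s + 1), idx[s:e])]))
  }
  list(index = idx, distance = dist)
}

#' Extract a vessel centerline from a closed surface
#'
#' The lumen is voxelised, each interior voxel scored by its distance to
#' the wall, and the medial path found as the shortest path between the
#' voxels nearest the two endpoints under edge cost
#' `length / (distance + eps)` on the 26-connected interior graph — the
#' path therefore hugs the maximal-inscribed-sphere ridge. The raw voxel
#' path is spline-smoothed, and `D_vessel` is twice the wall distance
#' sampled along it.
#'
#' @param surface watertight [vessel_surface].
#' @param source,target endpoints near the lumen openings, mm.
#' @param voxel voxelisation pitch, mm (default 0.4).
#' @param spar smoothing parameter passed to [stats::smooth.spline]
#'   (default 0.6).
#' @param check_watertight require a closed surface (default TRUE); set
#'   FALSE for unstitched phantom unions whose ray parity is still
#'   well defined.
#' @return a [centerline].
#' @export
compute_centerline <- function(surface, source, target, voxel = 0.4,
                               spar = 0.6, check_watertight = TRUE) {
  bb_lo <- apply(surface$vertices, 2, min) - voxel
  bb_hi <- apply(surface$vertices, 2, max) + voxel
  ax <- lapply(1:3, function(k) seq(bb_lo[k], bb_hi[k], by = voxel))
  dims <- sapply(ax, length)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  inside <- points_in_surface(surface, pts, check_watertight = check_watertight)
  if (!any(inside)) stop("no interior voxels found", call. = FALSE)
  in_pts <- pts[inside, , drop = FALSE]
  # wall distance: nearest surface vertex (dense mesh assumption)
  sv <- surface$vertices
  wall_d <- numeric(nrow(in_pts))
  block <- 2048L
  for (s in seq(1, nrow(in_pts), by = block)) {
    e <- min(nrow(in_pts), s + block - 1)
    d2 <- outer(rowSums(in_pts[s:e, , drop = FALSE]^2), rowSums(sv^2), "+") -
      2 * in_pts[s:e, , drop = FALSE] %*% t(sv)
    wall_d[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  # endpoints: interior voxels nearest to the requested source/target
  near <- function(p) {
    d2 <- rowSums((in_pts - matrix(p, nrow(in_pts), 3, byrow = TRUE))^2)
    which.min(d2)
  }
  s_idx <- near(source); t_idx <- near(target)
  if (sqrt(sum((in_pts[s_idx, ] - source)^2)) > 5 * voxel ||
      sqrt(sum((in_pts[t_idx, ] - target)^2)) > 5 * voxel) {
    stop("endpoints are not inside the lumen", call. = FALSE)
  }
  # 26-connectivity graph over interior voxels
  lin_of <- array(0L, dims)
  ii <- which(inside)
  lin_of[ii] <- seq_along(ii)
  arr <- which(array(inside, dims), arr.ind = TRUE)
  eps <- 0.05
  edges <- list(); wts <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  for (o in seq_len(nrow(offs))) {
    sh <- arr + matrix(offs[o, ], nrow(arr), 3, byrow = TRUE)
    ok <- sh[, 1] >= 1 & sh[, 1] <= dims[1] & sh[, 2] >= 1 & sh[, 2] <= dims[2] &
      sh[, 3] >= 1 & sh[, 3] <= dims[3]
    lin <- lin_of[sh[ok, , drop = FALSE]]
    from <- seq_len(nrow(arr))[ok][lin > 0]
    to <- lin[lin > 0]
    if (!length(from)) next
    len <- voxel * sqrt(sum(offs[o, ]^2))
    w <- len / (0.5 * (wall_d[from] + wall_d[to]) + eps)
    edges[[length(edges) + 1]] <- rbind(from, to)
    wts[[length(wts) + 1]] <- w
  }
  g <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                          n = nrow(in_pts), directed = FALSE)
  path <- igraph::shortest_paths(g, from = s_idx, to = t_idx,
                                 weights = unlist(wts))$vpath[[1]]
  path <- as.integer(path)
  if (length(path) < 2) stop("no interior path between endpoints", call. = FALSE)
  raw <- in_pts[path, , drop = FALSE]
  # spline-smooth against cumulative arclength
  s_arc <- c(0, cumsum(rownorms(diff(raw))))
  sm <- sapply(1:3, function(k) {
    if (length(path) >= 8) {
      stats::predict(stats::smooth.spline(s_arc, raw[, k], spar = spar), s_arc)$y
    } else raw[, k]
  })
  keep <- c(TRUE, rownorms(diff(sm)) > 1e-9)
  sm <- sm[keep, , drop = FALSE]
  # de-quantise: snap each point to the local maximal-inscribed-sphere
  # centre by maximising wall distance in the plane orthogonal to the
  # local tangent (offsets bounded by one voxel)
  wall_dist <- function(p) {
    d2 <- colSums((t(sv) - p)^2)
    sqrt(min(d2))
  }
  n_s <- nrow(sm)
  for (i in seq_len(n_s)) {
    i0 <- max(1, i - 1); i1 <- min(n_s, i + 1)
    tang <- sm[i1, ] - sm[i0, ]
    tang <- tang / max(vnorm(tang), 1e-12)
    tb <- tangent_basis(tang)
    obj <- function(ab) {
      if (max(abs(ab)) > voxel) return(1e6)
      -wall_dist(sm[i, ] + ab[1] * tb$t1 + ab[2] * tb$t2)
    }
    opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 60, reltol = 1e-6))
    sm[i, ] <- sm[i, ] + opt$par[1] * tb$t1 + opt$par[2] * tb$t2
  }
  # light re-smooth after refinement, then final wall distances
  s_arc2 <- c(0, cumsum(rownorms(diff(sm))))
  if (n_s >= 8) {
    sm <- sapply(1:3, function(k) {
      stats::predict(stats::smooth.spline(s_arc2, sm[, k], spar = spar),
                     s_arc2)$y
    })
  }
  keep <- c(TRUE, rownorms(diff(sm)) > 1e-9)
  sm <- sm[keep, , drop = FALSE]
  d_sm <- apply(sm, 1, wall_dist)
  centerline(sm, 2 * d_sm)
}

#' Rigid co-registration of a surface to a reference speed image
#'
#' Optimises rotation and translation so that the mean reference-image
#' intensity sampled at points inside the transformed surface is maximal,
#' using a quasi-Newton (BFGS) local optimiser with numeric gradients.
#' The reference image is typically the systolic speed volume; the initial
#' alignment must be within a few mm / degrees.
#'
#' @param surface a [vessel_surface].
#' @param reference 3-D array of reference intensities (e.g. systolic
#'   speed), on the grid described by `origin`/`spacing`.
#' @param origin,spacing grid geometry of `reference`, mm.
#' @param sample_pitch spacing of interior sample points, mm (default 0.3).
#' @param maxit maximum BFGS iterations (default 200).
#' @return a [rigid_transform], with attributes `objective` (final mean
#'   intensity), `trace` (objective per evaluation) and `converged`.
#' @export
register_rigid <- function(surface, reference, origin, spacing,
                           sample_pitch = 0.3, maxit = 200) {
  bb_lo <- apply(surface$vertices, 2, min)
  bb_hi <- apply(surface$vertices, 2, max)
  ax <- lapply(1:3, function(k) seq(bb_lo[k], bb_hi[k], by = sample_pitch))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  inside <- points_in_surface(surface, pts)
  spts <- pts[inside, , drop = FALSE]
  if (nrow(spts) < 10) stop("too few interior sample points", call. = FALSE)
  trace_env <- new.env(); trace_env$vals <- numeric(0)
  objective <- function(par) {
    tf <- rigid_transform(par[1:3], par[4:6])
    q <- apply_transform(spts, tf)
    vals <- interp_trilinear(reference, origin, spacing, q)
    vals[is.na(vals)] <- 0
    m <- mean(vals)
    trace_env$vals <- c(trace_env$vals, m)
    -m
  }
  fit <- stats::optim(rep(0, 6), objective, method = "BFGS",
                      control = list(maxit = maxit,
                                     parscale = c(rep(2, 3), rep(0.5, 3)),
                                     reltol = 1e-10))
  out <- rigid_transform(fit$par[1:3], fit$par[4:6])
  attr(out, "objective") <- -fit$value
  attr(out, "trace") <- trace_env$vals
  converged <- fit$convergence == 0
  rng <- diff(range(trace_env$vals))
  if (rng < 1e-12 * max(abs(trace_env$vals), 1)) {
    warning("flat registration objective (featureless reference image)")
    converged <- FALSE
  } else if (!converged) {
    warning("registration did not converge; returning best transform found")
  }
  attr(out, "converged") <- converged
  out
}

#' Isolate the aneurysm sac from a vessel surface
#'
#' Removes every triangle whose centroid lies within a radius of
#' `(D_vessel + margin) / 2` of its nearest centerline point, with
#' `D_vessel` the local vessel diameter there; what remains of the wall is
#' split into connected components and the largest (by area) is returned
#' as the sac, together with its ordered neck boundary loop.
#'
#' @param surface a [vessel_surface].
#' @param cl a [centerline] spanning the parent vessel.
#' @param margin added to the local diameter before halving, mm
#'   (default 1).
#' @param rank which component to return, by decreasing area (default 1,
#'   the largest).
#' @return list with `sac` (a [vessel_surface] or `NULL`), `neck_loop`
#'   (ordered point matrix), `status` (`"ok"` or `"empty"`) and
#'   `removed` (logical per original triangle).
#' @export
isolate_sac <- function(surface, cl, margin = 1, rank = 1) {
  cen <- triangle_centroids(surface)
  near <- nearest_centerline_point(cl, cen)
  r_remove <- (cl$d_vessel[near$index] + margin) / 2
  removed <- near$distance <= r_remove
  if (all(removed)) {
    return(list(sac = NULL, neck_loop = NULL, status = "empty",
                removed = removed))
  }
  keep_surface <- submesh(surface, !removed)
  memb <- triangle_components(keep_surface)
  areas <- triangle_areas(keep_surface)
  comp_area <- tapply(areas, memb, sum)
  ord <- order(comp_area, decreasing = TRUE)
  if (rank > length(ord)) {
    return(list(sac = NULL, neck_loop = NULL, status = "empty",
                removed = removed))
  }
  sac <- submesh(keep_surface, memb == as.integer(names(comp_area)[ord[rank]]))
  loop_idx <- order_boundary_loop(boundary_edges(sac))
  list(sac = sac,
       neck_loop = sac$vertices[loop_idx, , drop = FALSE],
       status = "ok", removed = removed)
}

#' Fit the aneurysm neck plane to the neck boundary points
#'
#' Total-least-squares plane through the neck loop: the plane through the
#' centroid whose normal is the smallest-variance principal axis of the
#' points, which minimises the sum of squared orthogonal distances.
#'
#' @param points n x 3 matrix of neck points, mm (n >= 3, non-collinear).
#' @return Object of class `neck_plane` with unit `normal`, `point`
#'   (centroid) and `residual` (RMS orthogonal distance, mm).
#' @export
fit_neck_plane <- function(points) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30)) {
    stop("neck points are collinear", call. = FALSE)
  }
  normal <- sv$v[, 3]
  res <- sqrt(mean((x %*% normal)^2))
  structure(list(normal = normal, point = ctr, residual = res),
            class = "neck_plane")
}

#' @export
print.neck_plane <- function(x, ...) {
  cat(sprintf("Neck plane: normal (%.3f, %.3f, %.3f), residual %.3g mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$residual))
  invisible(x)
}

# signed area of a planar polygon given 2D coordinates
polygon_area <- function(uv) {
  n <- nrow(uv)
  j <- c(2:n, 1)
  abs(sum(uv[, 1] * uv[j, 2] - uv[j, 1] * uv[, 2])) / 2
}

#' Morphometric indices of an isolated aneurysm sac
#'
#' Conventions: perpendicular height is the maximum distance of sac
#' vertices from the neck plane on the sac side; maximum height is the
#' maximum distance from the neck-loop centroid to any sac vertex; maximum
#' width is the largest pairwise distance among sac vertices projected onto
#' the neck plane; the neck diameter is the area-equivalent diameter
#' `2 sqrt(A/pi)` of the projected neck loop; the volume closes the sac
#' with the planar neck cap and applies the divergence theorem; the aspect
#' ratio is perpendicular height over neck diameter.
#'
#' @param sac a [vessel_surface] (the isolated sac, open at the neck).
#' @param neck_plane a [neck_plane].
#' @param neck_loop ordered neck boundary points, mm.
#' @param parent_diameter optional inlet parent-artery diameter to carry
#'   through, mm.
#' @return Object of class `sac_morphometrics`: list with `max_height`,
#'   `perpendicular_height`, `max_width`, `volume`, `surface`,
#'   `neck_diameter`, `aspect_ratio`, `inlet_parent_diameter` (mm / mm^3 /
#'   mm^2 / dimensionless).
#' @export
sac_morphometrics <- function(sac, neck_plane, neck_loop,
                              parent_diameter = NA_real_) {
  stopifnot(inherits(sac, "vessel_surface"), inherits(neck_plane, "neck_plane"))
  v <- sac$vertices
  d_signed <- as.vector(
    (v - matrix(neck_plane$point, nrow(v), 3, byrow = TRUE)) %*% neck_plane$normal)
  # orient so the sac side is positive
  if (abs(min(d_signed)) > abs(max(d_signed))) d_signed <- -d_signed
  perp_h <- max(d_signed)
  loop_ctr <- colMeans(neck_loop)
  max_h <- max(rownorms(v - matrix(loop_ctr, nrow(v), 3, byrow = TRUE)))
  # in-plane frame for projections
  tb <- tangent_basis(neck_plane$normal)
  proj <- cbind((v - matrix(neck_plane$point, nrow(v), 3, byrow = TRUE)) %*% tb$t1,
                (v - matrix(neck_plane$point, nrow(v), 3, byrow = TRUE)) %*% tb$t2)
  max_w <- max_pairwise_distance(proj)
  uv <- cbind((neck_loop - matrix(neck_plane$point, nrow(neck_loop), 3, byrow = TRUE)) %*% tb$t1,
              (neck_loop - matrix(neck_plane$point, nrow(neck_loop), 3, byrow = TRUE)) %*% tb$t2)
  a_neck <- polygon_area(uv)
  neck_d <- 2 * sqrt(a_neck / pi)
  # close the sac with a fan over the neck loop and integrate the volume
  closed <- close_with_cap(sac)
  vol <- abs(enclosed_volume(closed))
  surf <- surface_area(sac)
  structure(list(max_height = max_h, perpendicular_height = perp_h,
                 max_width = max_w, volume = vol, surface = surf,
                 neck_diameter = neck_d,
                 aspect_ratio = aspect_ratio(perp_h, neck_d),
                 inlet_parent_diameter = parent_diameter),
            class = "sac_morphometrics")
}

#' Aspect ratio of an aneurysm sac
#'
#' Perpendicular height of the dome over the neck diameter, the common
#' rupture-risk morphometric.
#'
#' @param perpendicular_height mm.
#' @param neck_diameter mm.
#' @return dimensionless ratio.
#' @examples
#' aspect_ratio(8.31, 6.72)  # 1.24
#' @export
aspect_ratio <- function(perpendicular_height, neck_diameter) {
  stopifnot_positive(neck_diameter)
  perpendicular_height / neck_diameter
}

#' @export
print.sac_morphometrics <- function(x, ...) {
  cat("Sac morphometrics:\n")
  cat(sprintf("  max height            %.2f mm\n", x$max_height))
  cat(sprintf("  perpendicular height  %.2f mm\n", x$perpendicular_height))
  cat(sprintf("  max width             %.2f mm\n", x$max_width))
  cat(sprintf("  volume                %.0f mm^3\n", x$volume))
  cat(sprintf("  surface               %.0f mm^2\n", x$surface))
  cat(sprintf("  neck diameter         %.2f mm\n", x$neck_diameter))
  cat(sprintf("  aspect ratio          %.2f\n", x$aspect_ratio))
  if (is.finite(x$inlet_parent_diameter))
    cat(sprintf("  inlet parent diameter %.2f mm\n", x$inlet_parent_diameter))
  invisible(x)
}

max_pairwise_distance <- function(m) {
  # diameter of a 2D point set; hull-free O(n^2) in blocks is fine at mesh size
  n <- nrow(m)
  if (n > 2000) m <- m[round(seq(1, n, length.out = 2000)), , drop = FALSE]
  max(stats::dist(m))
}

# close an open sac mesh with a triangle fan over its boundary loop,
# wound so the cap faces away from the sac body (consistent outward
# orientation for the divergence-theorem volume)
close_with_cap <- function(sac) {
  be <- boundary_edges(sac)
  loop <- order_boundary_loop(be)
  if (length(loop) < 3) return(sac)
  ctr <- colMeans(sac$vertices[loop, , drop = FALSE])
  side <- colMeans(sac$vertices) - ctr        # towards the sac body
  fan <- cbind(nrow(sac$vertices) + 1L, loop, c(loop[-1], loop[1]))
  cap <- vessel_surface(rbind(sac$vertices, ctr), fan)
  if (sum(triangle_cross(cap) %*% side) > 0) {
    fan <- fan[, c(1, 3, 2)]
  }
  vessel_surface(rbind(sac$vertices, ctr), rbind(sac$triangles, fan))
}

#' Centerline-orthogonal measurement planes
#'
#' Equally spaced arclength stations along a (spline-smoothed) centerline;
#' at each station a plane through the centerline point with normal equal
#' to the local tangent (central finite differences), carrying an in-plane
#' orthonormal 2-D frame.
#'
#' @param cl a [centerline].
#' @param spacing station spacing, mm.
#' @param half_width half-extent of the in-plane raster, mm (default the
#'   local vessel radius plus 2 mm).
#' @return list of plane frames: each has `point`, `normal`, `e1`, `e2`,
#'   `arclength`, `half_width`, `d_vessel`.
#' @export
orthogonal_planes <- function(cl, spacing, half_width = NULL) {
  stopifnot_positive(spacing)
  total <- max(cl$arclength)
  if (spacing > total) stop("spacing exceeds centerline length", call. = FALSE)
  stations <- seq(0, total, by = spacing)
  # dense resample of the centerline by arclength for stable tangents
  s_dense <- seq(0, total, length.out = max(200, 4 * nrow(cl$points)))
  dense <- sapply(1:3, function(k) {
    stats::spline(cl$arclength, cl$points[, k], xout = s_dense)$y
  })
  d_dense <- stats::approx(cl$arclength, cl$d_vessel, xout = s_dense)$y
  lapply(stations, function(s0) {
    i <- which.min(abs(s_dense - s0))
    i0 <- max(1, i - 2); i1 <- min(length(s_dense), i + 2)
    tangent <- dense[i1, ] - dense[i0, ]
    tangent <- tangent / vnorm(tangent)
    tb <- tangent_basis(tangent)
    hw <- if (is.null(half_width)) d_dense[i] / 2 + 2 else half_width
    list(point = dense[i, ], normal = tangent, e1 = tb$t1, e2 = tb$t2,
         arclength = s0, half_width = hw, d_vessel = d_dense[i])
  })
}
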