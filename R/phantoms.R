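# Vessel phantoms with known ground truth.

#' Vessel centerline
#'
#' @param points n x 3 matrix of ordered points, mm.
#' @param d_vessel local vessel diameter at each point, mm (twice the
#'   distance to the wall).
#' @return Object of class `centerline` with `points`, `arclength`
#'   (cumulative, mm, strictly increasing) and `d_vessel`.
#' @export
centerline <- function(points, d_vessel) {
  points <- matrix(points, ncol = 3)
  stopifnot(nrow(points) >= 2, length(d_vessel) == nrow(points))
  if (any(d_vessel <= 0)) stop("vessel diameter must be positive", call. = FALSE)
  seg <- rownorms(diff(points))
  if (any(seg <= 0)) stop("centerline points must be distinct", call. = FALSE)
  structure(list(points = points, arclength = c(0, cumsum(seg)),
                 d_vessel = d_vessel),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("Centerline: %d points, length %.2f mm, D_vessel %.2f-%.2f mm\n",
              nrow(x$points), max(x$arclength), min(x$d_vessel),
              max(x$d_vessel)))
  invisible(x)
}

# triangulated open cylinder wall along z in [0, length], plus end caps
cylinder_mesh <- function(radius, length, mesh_pitch) {
  n_c <- max(12, ceiling(2 * pi * radius / mesh_pitch))
  n_z <- max(2, ceiling(length / mesh_pitch) + 1)
  theta <- 2 * pi * (seq_len(n_c) - 1) / n_c
  z <- seq(0, length, length.out = n_z)
  ring <- cbind(radius * cos(theta), radius * sin(theta))
  vertices <- do.call(rbind, lapply(z, function(zz) cbind(ring, zz)))
  tris <- list()
  for (k in seq_len(n_z - 1)) {
    b0 <- (k - 1) * n_c
    for (i in seq_len(n_c)) {
      i2 <- if (i == n_c) 1L else i + 1L
      # outward winding (CCW viewed from outside)
      tris[[length(tris) + 1]] <- c(b0 + i, b0 + i2, b0 + n_c + i)
      tris[[length(tris) + 1]] <- c(b0 + i2, b0 + n_c + i2, b0 + n_c + i)
    }
  }
  # end caps: fans around centre points
  c_bot <- nrow(vertices) + 1L
  c_top <- nrow(vertices) + 2L
  vertices <- rbind(vertices, c(0, 0, 0), c(0, 0, length))
  for (i in seq_len(n_c)) {
    i2 <- if (i == n_c) 1L else i + 1L
    tris[[length(tris) + 1]] <- c(c_bot, i2, i)                        # z=0, outward -z
    b0 <- (n_z - 1) * n_c
    tris[[length(tris) + 1]] <- c(c_top, b0 + i, b0 + i2)              # z=L, outward +z
  }
  vessel_surface(vertices, do.call(rbind, tris))
}

#' Straight-tube phantom
#'
#' Watertight triangulated cylinder of given radius along the z axis from
#' z = 0 to z = `length`, with its axis polyline as centerline and local
#' diameter `2 * radius` everywhere.
#'
#' @param radius mm.
#' @param length mm.
#' @param mesh_pitch target triangle edge length, mm (default 0.4).
#' @return list with `surface` (a [vessel_surface]) and `centerline`
#'   (a [centerline]).
#' @examples
#' ph <- make_tube_phantom(1.675, 20)
#' surface_area(ph$surface)  # ~ 2*pi*1.675*20 + caps
#' @export
make_tube_phantom <- function(radius, length, mesh_pitch = 0.4) {
  stopifnot_positive(radius, length, mesh_pitch)
  surface <- cylinder_mesh(radius, length, mesh_pitch)
  n_pts <- max(2, ceiling(length / mesh_pitch) + 1)
  pts <- cbind(0, 0, seq(0, length, length.out = n_pts))
  list(surface = surface,
       centerline = centerline(pts, rep(2 * radius, n_pts)))
}

# unit sphere mesh (icosphere-like via lat/long grid), radius a at centre
sphere_mesh <- function(a, centre, mesh_pitch) {
  n_lat <- max(8, ceiling(pi * a / mesh_pitch))
  n_lon <- max(12, ceiling(2 * pi * a / mesh_pitch))
  phi <- seq(0, pi, length.out = n_lat + 1)[-c(1, n_lat + 1)]
  theta <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  vertices <- do.call(rbind, lapply(phi, function(p) {
    cbind(a * sin(p) * cos(theta), a * sin(p) * sin(theta), a * cos(p))
  }))
  north <- nrow(vertices) + 1L
  south <- nrow(vertices) + 2L
  vertices <- rbind(vertices, c(0, 0, a), c(0, 0, -a))
  tris <- list()
  n_band <- length(phi)
  for (i in seq_len(n_lon)) {
    i2 <- if (i == n_lon) 1L else i + 1L
    tris[[length(tris) + 1]] <- c(north, i, i2)
    b0 <- (n_band - 1) * n_lon
    tris[[length(tris) + 1]] <- c(south, b0 + i2, b0 + i)
  }
  for (k in seq_len(n_band - 1)) {
    b0 <- (k - 1) * n_lon
    for (i in seq_len(n_lon)) {
      i2 <- if (i == n_lon) 1L else i + 1L
      tris[[length(tris) + 1]] <- c(b0 + i, b0 + n_lon + i, b0 + i2)
      tris[[length(tris) + 1]] <- c(b0 + i2, b0 + n_lon + i, b0 + n_lon + i2)
    }
  }
  vertices <- vertices + matrix(centre, nrow(vertices), 3, byrow = TRUE)
  vessel_surface(vertices, do.call(rbind, tris))
}

#' Sphere-on-tube aneurysm phantom
#'
#' A straight tube carrying a spherical sac fused at a circular neck. The
#' sac is the spherical cap of radius `sac_radius` cut by the neck plane
#' (tangent to the tube wall at mid-length, normal +x); the neck circle has
#' radius `neck_radius`. Ground-truth neck geometry and closed-form cap
#' area/volume are returned alongside. With `sac_radius = 0` the plain tube
#' phantom is returned.
#'
#' @param tube_radius mm.
#' @param sac_radius mm (0 for no sac).
#' @param neck_radius mm, `0 < neck_radius <= sac_radius`.
#' @param length tube length, mm.
#' @param mesh_pitch mm.
#' @return list with `surface` (tube plus sac cap, unstitched union),
#'   `centerline`, and `sac_truth` (list: `neck_center`, `neck_normal`,
#'   `neck_radius`, `sphere_center`, `sac_area`, `sac_volume`,
#'   `cap` the sac-only mesh with boundary at the neck circle).
#' @export
make_sphere_on_tube <- function(tube_radius, sac_radius, neck_radius,
                                length = 20, mesh_pitch = 0.4) {
  stopifnot_positive(tube_radius, length, mesh_pitch)
  if (sac_radius == 0) return(make_tube_phantom(tube_radius, length, mesh_pitch))
  stopifnot_positive(sac_radius, neck_radius)
  if (neck_radius > sac_radius + 1e-12) {
    stop("neck radius cannot exceed sac radius", call. = FALSE)
  }
  neck_radius <- min(neck_radius, sac_radius)
  tube <- make_tube_phantom(tube_radius, length, mesh_pitch)
  d <- sqrt(max(0, sac_radius^2 - neck_radius^2))
  centre <- c(tube_radius + d, 0, length / 2)
  sph <- sphere_mesh(sac_radius, centre, mesh_pitch)
  # keep sphere triangles on the sac side of the neck plane x = tube_radius
  cen <- triangle_centroids(sph)
  keep <- cen[, 1] > tube_radius
  cap <- submesh(sph, keep)
  h <- sac_radius + d                         # cap height above neck plane
  truth <- list(neck_center = c(tube_radius, 0, length / 2),
                neck_normal = c(1, 0, 0),
                neck_radius = neck_radius,
                sphere_center = centre,
                sac_area = 2 * pi * sac_radius * h,
                sac_volume = pi / 3 * h^2 * (3 * sac_radius - h),
                cap = cap)
  combined <- vessel_surface(
    rbind(tube$surface$vertices, cap$vertices),
    rbind(tube$surface$triangles,
          cap$triangles + nrow(tube$surface$vertices)))
  list(surface = combined, centerline = tube$centerline, sac_truth = truth)
}

#' Torus-segment bent-tube phantom
#'
#' Tube of radius `tube_radius` bent along a circular arc of given major
#' radius and angle, lying in the x-z plane; used to exercise centerline
#' extraction and orthogonal-plane generation on curved vessels.
#'
#' @param major_radius arc radius, mm.
#' @param tube_radius mm.
#' @param angle arc angle, radians (default `pi/2`).
#' @param mesh_pitch mm.
#' @return list with `surface`, `centerline` (analytic arc) and
#'   `arc_length` (analytic, mm).
#' @export
make_torus_tube <- function(major_radius, tube_radius, angle = pi / 2,
                            mesh_pitch = 0.4) {
  stopifnot_positive(major_radius, tube_radius, angle, mesh_pitch)
  n_s <- max(8, ceiling(major_radius * angle / mesh_pitch) + 1)
  n_c <- max(12, ceiling(2 * pi * tube_radius / mesh_pitch))
  s <- seq(0, angle, length.out = n_s)
  th <- 2 * pi * (seq_len(n_c) - 1) / n_c
  verts <- list()
  for (k in seq_len(n_s)) {
    # arc point and Frenet frame: centre of arc at origin, arc in x-z plane
    cpt <- c(major_radius * cos(s[k]), 0, major_radius * sin(s[k]))
    e_r <- c(cos(s[k]), 0, sin(s[k]))   # radial (in-plane normal)
    e_y <- c(0, 1, 0)
    ring <- t(sapply(th, function(t_) {
      cpt + tube_radius * (cos(t_) * e_r + sin(t_) * e_y)
    }))
    verts[[k]] <- ring
  }
  vertices <- do.call(rbind, verts)
  tris <- list()
  for (k in seq_len(n_s - 1)) {
    b0 <- (k - 1) * n_c
    for (i in seq_len(n_c)) {
      i2 <- if (i == n_c) 1L else i + 1L
      tris[[length(tris) + 1]] <- c(b0 + i, b0 + i2, b0 + n_c + i)
      tris[[length(tris) + 1]] <- c(b0 + i2, b0 + n_c + i2, b0 + n_c + i)
    }
  }
  # caps
  c0 <- nrow(vertices) + 1L; c1 <- nrow(vertices) + 2L
  vertices <- rbind(vertices,
                    c(major_radius, 0, 0),
                    c(major_radius * cos(angle), 0, major_radius * sin(angle)))
  for (i in seq_len(n_c)) {
    i2 <- if (i == n_c) 1L else i + 1L
    tris[[length(tris) + 1]] <- c(c0, i2, i)
    b0 <- (n_s - 1) * n_c
    tris[[length(tris) + 1]] <- c(c1, b0 + i, b0 + i2)
  }
  surface <- vessel_surface(vertices, do.call(rbind, tris))
  cl_pts <- cbind(major_radius * cos(s), 0, major_radius * sin(s))
  list(surface = surface,
       centerline = centerline(cl_pts, rep(2 * tube_radius, n_s)),
       arc_length = major_radius * angle)
}
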