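# Surface fairing, centerline, registration, sac isolation, neck plane,
# morphometrics, measurement planes.

test_that("Taubin smoothing removes noise without shrinking", {
  sph <- anewall:::sphere_mesh(4, c(0, 0, 0), 0.25)
  set.seed(5)
  noisy <- vessel_surface(
    sph$vertices * (1 + stats::rnorm(nrow(sph$vertices), sd = 0.02)),
    sph$triangles)
  sm <- taubin_smooth(noisy, 30)
  rms <- function(s) sqrt(mean((sqrt(rowSums(s$vertices^2)) - 4)^2))
  expect_gte(rms(noisy) / rms(sm), 3)
  expect_lt(abs(mean(sqrt(rowSums(sm$vertices^2))) / 4 - 1), 0.01)
  # shrink-free relative to a pure Laplacian: volume change < 2%
  expect_lt(abs(enclosed_volume(sm) / enclosed_volume(noisy) - 1), 0.02)
  expect_identical(taubin_smooth(noisy, 0), noisy)
  expect_identical(dim(sm$triangles), dim(noisy$triangles))
})

test_that("centerline of a straight tube is the axis with the true diameter", {
  ph <- fix("tube20", make_tube_phantom(std_radius, 20, mesh_pitch = 0.3))
  cl <- fix("tube20_cl",
            compute_centerline(ph$surface, c(0, 0, 1), c(0, 0, 19)))
  interior <- cl$points[, 3] > 3 & cl$points[, 3] < 17
  expect_lt(max(sqrt(cl$points[interior, 1]^2 + cl$points[interior, 2]^2)), 0.2)
  expect_lt(max(abs(cl$d_vessel[interior] / (2 * std_radius) - 1)), 0.05)
  expect_true(all(diff(cl$arclength) > 0))
  expect_error(compute_centerline(ph$surface, c(20, 20, 0), c(0, 0, 19)),
               "not inside")
})

test_that("centerline of a torus bend has the analytic arc length", {
  tor <- fix("torus", make_torus_tube(10, 1.5))
  cl <- compute_centerline(tor$surface, tor$centerline$points[1, ],
                           tor$centerline$points[nrow(tor$centerline$points), ])
  expect_rel(max(cl$arclength), tor$arc_length, 0.05)
})

test_that("centerline avoids an attached sac", {
  sot <- fix("sot", make_sphere_on_tube(1.7, 5, 3, length = 20, mesh_pitch = 0.4))
  cl <- compute_centerline(sot$surface, c(0, 0, 1), c(0, 0, 19),
                           check_watertight = FALSE)
  # the medial path stays in the tube: never nearer the sac centre than
  # the neck, and close to the tube axis throughout
  d_sac <- rownorms(cl$points - matrix(sot$sac_truth$sphere_center,
                                       nrow(cl$points), 3, byrow = TRUE))
  expect_true(all(d_sac > 5))
  expect_lt(max(sqrt(cl$points[, 1]^2 + cl$points[, 2]^2)), 0.6)
})

test_that("rigid registration recovers known perturbations", {
  f <- pois_field(0.5)
  ph <- tube8()
  ref <- field_speed(f)
  # already aligned: transform within 0.05 mm / 0.1 deg of identity
  reg0 <- register_rigid(ph$surface, ref, f$origin, f$spacing)
  expect_lt(max(abs(reg0$translation)), 0.05)
  expect_lt(max(abs(reg0$angles)), 0.1)
  # known 2 mm / 5 deg perturbation: composite surface error < 0.1 mm
  truth <- rigid_transform(c(5, 0, 0), c(2, 0, 0))
  pert <- apply_transform(ph$surface, truth)
  reg <- register_rigid(pert, ref, f$origin, f$spacing)
  rec <- apply_transform(pert, reg)
  expect_lt(max(rownorms(rec$vertices - ph$surface$vertices)), 0.1)
  expect_true(attr(reg, "converged"))
  # featureless reference: flat objective warning
  expect_warning(
    register_rigid(ph$surface, array(1, f$dim), f$origin, f$spacing,
                   maxit = 5),
    "flat")
})

test_that("sac isolation recovers the spherical cap and handles edge cases", {
  sot <- fix("sot", make_sphere_on_tube(1.7, 5, 3, length = 20, mesh_pitch = 0.4))
  iso <- isolate_sac(sot$surface, sot$centerline)
  expect_equal(iso$status, "ok")
  expect_rel(surface_area(iso$sac), sot$sac_truth$sac_area, 0.10)
  expect_gte(nrow(iso$neck_loop), 8)
  # removed + kept partition the original triangle set
  expect_equal(sum(iso$removed) + sum(!iso$removed), nrow(sot$surface$triangles))
  # a plain tube has no sac
  tb <- tube8()
  expect_equal(isolate_sac(tb$surface, tb$centerline)$status, "empty")
  # two sacs: largest returned first, the other by rank
  s1 <- make_sphere_on_tube(1.7, 5, 3, length = 30, mesh_pitch = 0.4)
  s2 <- make_sphere_on_tube(1.7, 3, 2, length = 30, mesh_pitch = 0.4)
  shift <- s2$sac_truth$cap
  shift <- vessel_surface(shift$vertices + matrix(c(0, 0, 8), nrow(shift$vertices),
                                                 3, byrow = TRUE),
                          shift$triangles)
  both <- vessel_surface(rbind(s1$surface$vertices, shift$vertices),
                         rbind(s1$surface$triangles,
                               shift$triangles + nrow(s1$surface$vertices)))
  big <- isolate_sac(both, s1$centerline, rank = 1)
  small <- isolate_sac(both, s1$centerline, rank = 2)
  expect_gt(surface_area(big$sac), surface_area(small$sac))
  expect_rel(surface_area(small$sac), surface_area(s2$sac_truth$cap), 0.15)
})

test_that("neck-plane fit is total least squares and matches a brute-force search", {
  # coplanar ring: exact plane, zero residual
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  ring <- cbind(3 * cos(th), 3 * sin(th), 0 * th)
  tf <- rigid_transform(c(25, 40, -10), c(1, 2, 3))
  ring_t <- apply_transform(ring, tf)
  np <- fit_neck_plane(ring_t)
  expect_lt(np$residual, 1e-10)
  n_true <- tf$r %*% c(0, 0, 1)
  expect_gt(abs(sum(np$normal * n_true)), 1 - 1e-10)
  # jittered ring: normal within 2 degrees
  set.seed(8)
  jit <- ring_t + outer(stats::rnorm(nrow(ring), sd = 0.1), as.vector(n_true))
  npj <- fit_neck_plane(jit)
  expect_lt(acos(min(1, abs(sum(npj$normal * n_true)))) * 180 / pi, 2)
  # saddle loop: agrees with a dense orientation-grid search oracle
  saddle <- cbind(3 * cos(th), 3 * sin(th), 0.8 * cos(2 * th))
  nps <- fit_neck_plane(saddle)
  golden <- pi * (3 - sqrt(5))
  k <- 0:3999
  dirs <- cbind(sqrt(1 - ((2 * k + 1) / 4000 - 1)^2) * cos(golden * k),
                sqrt(1 - ((2 * k + 1) / 4000 - 1)^2) * sin(golden * k),
                (2 * k + 1) / 4000 - 1)
  ctr <- colMeans(saddle)
  sse <- colSums((t(saddle) - ctr)^2) # not used; oracle below
  obj <- apply(dirs, 1, function(nrm) {
    sum((sweep(saddle, 2, ctr) %*% nrm)^2)
  })
  best <- dirs[which.min(obj), ]
  expect_lt(acos(min(1, abs(sum(nps$normal * best)))) * 180 / pi, 2)
  expect_error(fit_neck_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
})

test_that("sac morphometrics reproduce hemisphere closed forms", {
  a <- 4
  hemi <- make_sphere_on_tube(1.7, a, a, length = 20)
  cap <- hemi$sac_truth$cap
  loop <- cap$vertices[anewall:::order_boundary_loop(
    anewall:::boundary_edges(cap)), ]
  np <- fit_neck_plane(loop)
  m <- sac_morphometrics(cap, np, loop, parent_diameter = 3.4)
  expect_rel(m$perpendicular_height, a, 0.02)
  expect_rel(m$neck_diameter, 2 * a, 0.01)
  expect_rel(m$aspect_ratio, 0.5, 0.03)
  expect_rel(m$volume, 2 * pi * a^3 / 3, 0.03)
  expect_rel(m$surface, 2 * pi * a^2, 0.02)
  expect_rel(m$max_width, 2 * a, 0.02)
  expect_gte(m$max_height, m$perpendicular_height - 1e-9)
  expect_equal(m$inlet_parent_diameter, 3.4)
})

test_that("morphometrics are invariant under rigid motion", {
  hemi <- make_sphere_on_tube(1.7, 3, 2.2, length = 20)
  cap <- hemi$sac_truth$cap
  loop <- cap$vertices[anewall:::order_boundary_loop(
    anewall:::boundary_edges(cap)), ]
  m0 <- sac_morphometrics(cap, fit_neck_plane(loop), loop)
  set.seed(13)
  for (rep in 1:3) {
    tf <- rigid_transform(stats::runif(3, -180, 180), stats::runif(3, -10, 10))
    cap_t <- apply_transform(cap, tf)
    loop_t <- apply_transform(loop, tf)
    m1 <- sac_morphometrics(cap_t, fit_neck_plane(loop_t), loop_t)
    expect_equal(unlist(m1[1:7]), unlist(m0[1:7]), tolerance = 1e-6)
  }
  # degenerate flat sac: near-zero height and aspect ratio
  th <- seq(0, 2 * pi, length.out = 30)[-30]
  disc <- rbind(c(0, 0, 1e-4), cbind(2 * cos(th), 2 * sin(th), 0))
  tris <- cbind(1, 1 + seq_len(29), 1 + c(seq_len(28) + 1, 1))
  flat <- vessel_surface(disc, tris)
  loop_f <- disc[-1, ][anewall:::order_boundary_loop(
    anewall:::boundary_edges(flat)) - 1, ]
  mf <- sac_morphometrics(flat, fit_neck_plane(loop_f), loop_f)
  expect_lt(mf$perpendicular_height, 1e-3)
  expect_lt(mf$aspect_ratio, 1e-3)
})

test_that("orthogonal planes follow the centerline tangent", {
  tb <- make_tube_phantom(std_radius, 20)
  pls <- orthogonal_planes(tb$centerline, 1.25)
  expect_length(pls, floor(20 / 1.25) + 1)
  devs <- sapply(pls, function(p) acos(min(1, abs(p$normal[3]))) * 180 / pi)
  expect_lt(max(devs), 0.5)
  # in-plane frames are orthonormal
  p1 <- pls[[3]]
  expect_equal(c(sum(p1$e1 * p1$e2), sum(p1$e1 * p1$normal), vnorm(p1$e1)),
               c(0, 0, 1), tolerance = 1e-12)
  # torus: normals tangent to the analytic circle within 2 degrees
  tor <- fix("torus", make_torus_tube(10, 1.5))
  plt <- orthogonal_planes(tor$centerline, 2)
  errs <- sapply(plt, function(p) {
    s <- p$arclength / 10
    acos(min(1, abs(sum(p$normal * c(-sin(s), 0, cos(s)))))) * 180 / pi
  })
  expect_lt(max(errs), 2)
  expect_error(orthogonal_planes(tb$centerline, 50), "exceeds")
})
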