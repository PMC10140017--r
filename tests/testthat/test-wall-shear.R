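# WSS from normal-line velocity profiles; TAWSS; OSI.

test_that("PCA normals recover plane and sphere orientations", {
  # points on z = 0 bounding the half-space lumen z > 0
  set.seed(21)
  pl <- cbind(stats::runif(200, -5, 5), stats::runif(200, -5, 5), 0)
  nb <- pca_normals(pl, k = 20, inside_test = function(p) p[, 3] > 0)
  expect_false(any(nb$flagged))
  expect_equal(nb$normals, matrix(rep(c(0, 0, 1), each = 200), ncol = 3),
               tolerance = 1e-12)
  # basis is right-handed and orthonormal
  i <- 5
  expect_equal(sum(nb$t1[i, ] * nb$t2[i, ]), 0, tolerance = 1e-12)
  cr <- c(nb$t1[i, 2] * nb$t2[i, 3] - nb$t1[i, 3] * nb$t2[i, 2],
          nb$t1[i, 3] * nb$t2[i, 1] - nb$t1[i, 1] * nb$t2[i, 3],
          nb$t1[i, 1] * nb$t2[i, 2] - nb$t1[i, 2] * nb$t2[i, 1])
  expect_equal(cr, nb$normals[i, ], tolerance = 1e-12)
  # sphere sampled at ~2000 points: normals within 2 degrees of radial
  golden <- pi * (3 - sqrt(5))
  k <- 0:1999
  z <- (2 * k + 1) / 2000 - 1
  sph <- 4 * cbind(sqrt(1 - z^2) * cos(golden * k),
                   sqrt(1 - z^2) * sin(golden * k), z)
  nbs <- pca_normals(sph, k = 20,
                     inside_test = function(p) rowSums(p^2) < 16)
  ang <- acos(pmin(1, abs(rowSums(nbs$normals * (-sph / 4))))) * 180 / pi
  expect_lt(max(ang[!nbs$flagged]), 2)
  # degenerate collinear neighbourhood is flagged
  line <- cbind(seq(0, 1, length.out = 6), 0, 0)
  nbl <- pca_normals(line, k = 3, inside_test = function(p) rep(TRUE, nrow(p)))
  expect_true(any(nbl$flagged))
})

test_that("vertex WSS is exact for analytic profiles and tangent to the wall", {
  mu <- std_fluid()$dynamic_viscosity
  u0 <- 2 * 4.38e-6 / (pi * (std_radius * 1e-3)^2)
  sampler <- function(pts, phase) {
    cbind(0, 0, pmax(0, u0 * (1 - (pts[, 1]^2 + pts[, 2]^2) / std_radius^2)))
  }
  basis <- list(normal = c(-1, 0, 0), t1 = c(0, 0, 1), t2 = c(0, -1, 0))
  w <- wss_at_vertex(sampler, c(std_radius, 0, 4), basis, mu)
  expect_equal(vnorm(w), gt_wss, tolerance = 5e-4)   # 6.33 Pa to 3 s.f.
  expect_equal(sum(w * basis$normal), 0)              # exact tangency
  # zero field gives the zero vector
  w0 <- wss_at_vertex(function(p, ph) matrix(0, nrow(p), 3),
                      c(std_radius, 0, 4), basis, mu)
  expect_equal(w0, c(0, 0, 0))
  # samples leaving the grid flag the vertex (NULL)
  f <- pois_field(0.5)
  out <- wss_at_vertex(f, c(std_radius, 0, 4), list(normal = c(1, 0, 0),
                       t1 = c(0, 0, 1), t2 = c(0, 1, 0)), mu)
  expect_null(out)
})

test_that("tube-wall WSS is uniform and converges to the Poiseuille value", {
  wall <- tube8_wall()
  means <- numeric(0)
  for (h in c(0.5, 0.25, 0.1)) {
    rec <- wss_field(pois_field(h), wall$cloud,
                     mu = std_fluid()$dynamic_viscosity,
                     eval_subset = wall$eval)
    means <- c(means, rec$mean_mag[1])
    # tangency at every vertex
    dots <- sapply(seq_len(nrow(rec$vertices)), function(i) {
      if (rec$flagged[i]) return(0)
      abs(sum(rec$wss[i, , 1] * rec$normals[i, ]))
    })
    expect_lt(max(dots), 1e-10 * max(rec$max_mag))
    # axisymmetric flow: spatial coefficient of variation < 3%
    mags <- sqrt(rowSums(rec$wss[!rec$flagged, , 1]^2))
    expect_lt(stats::sd(mags) / mean(mags), 0.03)
    expect_equal(rec$max_mag[1], max(mags))
  }
  # biased low on the acquisition grid, monotone improvement on refinement
  expect_true(all(diff(means) > 0))
  expect_lt(means[1], gt_wss)
  expect_rel(means[3], gt_wss, 0.02)
})

test_that("pulsatile wall shear tracks the closed-form Womersley series", {
  wall <- tube8_wall()
  f <- wom_field(0.1, length = 8)
  ev <- wall$eval[seq(1, length(wall$eval), by = 2)]
  rec <- wss_field(f, wall$cloud, mu = std_fluid()$dynamic_viscosity,
                   eval_subset = ev)
  gt <- abs(f$ground_truth$wss_t)
  expect_lt(sqrt(mean((rec$mean_mag - gt)^2)) / sqrt(mean(gt^2)), 0.05)
  # a single-vertex time series also stays within 5% RMS
  i <- which(!rec$flagged)[1]
  ser <- sqrt(colSums(rec$wss[i, , ]^2))
  expect_lt(sqrt(mean((ser - gt)^2)) / sqrt(mean(gt^2)), 0.05)
})

test_that("TAWSS is the vector time average", {
  w <- array(0, c(2, 3, 4))
  w[1, , ] <- c(1, 2, 3)                      # constant vector over the cycle
  w[2, , ] <- outer(c(1, 0, 0), c(1, -1, 1, -1))   # alternating
  ta <- tawss(w)
  expect_equal(ta$vector[1, ], c(1, 2, 3))
  expect_equal(ta$vector[2, ], c(0, 0, 0))
  expect_equal(ta$magnitude, c(vnorm(c(1, 2, 3)), 0))
  # sinusoid with DC offset: TAWSS magnitude = offset (exact on the
  # uniform periodic grid, quadrature error below 0.5%)
  t21 <- 2 * pi * (0:20) / 21
  w2 <- array(0, c(1, 3, 21))
  w2[1, 1, ] <- 2.5 + 1.7 * sin(t21)
  expect_equal(tawss(w2)$magnitude, 2.5, tolerance = 0.005)
})

test_that("OSI spans 0 for unidirectional to 0.5 for reversing shear", {
  t21 <- 2 * pi * (0:20) / 21
  w <- array(0, c(4, 3, 21))
  w[1, 1, ] <- 1 + 0.5 * sin(t21)       # fixed direction, positive magnitude
  w[2, 1, ] <- rep(c(1, -1), length.out = 21)  # unused amplitude pattern
  w[2, , ] <- outer(c(0.7, 0, 0.7), sin(t21))  # pure sinusoid, zero mean
  w[3, 2, ] <- -2                       # constant reversed direction
  w[4, , ] <- 0                         # dead flow: undefined
  o <- osi(w)
  expect_equal(o[1], 0)
  expect_equal(o[2], 0.5, tolerance = 1e-6)
  expect_equal(o[3], 0)
  expect_true(is.na(o[4]))
  # two-phase series {+w, -w}
  w2 <- array(0, c(1, 3, 2))
  w2[1, , 1] <- c(1, 0, 0); w2[1, , 2] <- c(-1, 0, 0)
  expect_equal(osi(w2)[1], 0.5)
  expect_true(all(stats::na.omit(c(o)) >= 0 & stats::na.omit(c(o)) <= 0.5))
})

test_that("high OSI co-locates with low TAWSS on a recirculating wall field", {
  # synthetic sac wall: vertices indexed by a latitude-like coordinate s;
  # steady component dies towards the dome tip while the oscillation from
  # the moving vortex persists, as in a recirculating sac
  set.seed(31)
  n_v <- 200
  s <- stats::runif(n_v)                       # 0 = dome tip, 1 = neck
  # vortex-core tip: weak mean shear fully dominated by the oscillation;
  # elsewhere the mean flow keeps the shear unidirectional
  steady <- ifelse(s < 0.05, 0.1, 1.2 + 2 * s)  # Pa
  osc <- 0.8                                    # Pa oscillation amplitude
  t21 <- 2 * pi * (0:20) / 21
  w <- array(0, c(n_v, 3, 21))
  for (i in seq_len(n_v)) {
    w[i, 1, ] <- steady[i] + osc * sin(t21 + 2 * pi * s[i])
  }
  ta <- tawss(w)$magnitude
  o <- osi(w)
  high_osi <- which(o > 0.2)
  low_decile <- which(ta <= stats::quantile(ta, 0.1))
  expect_gt(length(high_osi), 0)
  expect_true(all(high_osi %in% low_decile))
})

test_that("wss_field rejects geometries with too many unusable vertices", {
  f <- pois_field(0.5)
  # a wall cloud floating outside the grid: every vertex flagged
  far <- tube8_wall()$cloud + 100
  expect_error(wss_field(f, far, mu = 1), "flagged")
})
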