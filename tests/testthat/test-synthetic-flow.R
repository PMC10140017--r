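# Synthetic flows, phantom geometry and the phase-contrast signal model.

test_that("fluid properties couple density and viscosities consistently", {
  fl <- fluid_properties()
  expect_equal(fl$dynamic_viscosity, fl$density * fl$kinematic_viscosity)
  expect_equal(fl$dynamic_viscosity, 5.33314e-3, tolerance = 1e-6)
  expect_error(fluid_properties(density = -1), "positive")
})

test_that("tube phantom matches closed-form cylinder geometry", {
  ph <- make_tube_phantom(1.675, 20)
  a_true <- 2 * pi * 1.675 * 20 + 2 * pi * 1.675^2   # wall + two caps
  expect_rel(surface_area(ph$surface), a_true, 0.01)
  expect_true(is_watertight(ph$surface))
  expect_rel(abs(enclosed_volume(ph$surface)), pi * 1.675^2 * 20, 0.01)
  expect_true(all(ph$centerline$d_vessel == 2 * 1.675))
  expect_error(make_tube_phantom(1.675, 0), "positive")
})

test_that("sphere-on-tube phantom carries exact cap ground truth", {
  a <- 4
  hemi <- make_sphere_on_tube(1.7, a, a, length = 20)
  expect_equal(hemi$sac_truth$sac_area, 2 * pi * a^2)
  expect_equal(hemi$sac_truth$sac_volume, 2 * pi * a^3 / 3)
  # meshed cap area approaches the closed form
  expect_rel(surface_area(hemi$sac_truth$cap), 2 * pi * a^2, 0.02)
  # narrow neck: cap approaches the full sphere
  narrow <- make_sphere_on_tube(1.7, a, 0.2, length = 20)
  expect_rel(narrow$sac_truth$sac_area, 4 * pi * a^2, 0.01)
  # no sac degenerates to the plain tube
  plain <- make_sphere_on_tube(1.7, 0, 0.5)
  expect_null(plain$sac_truth)
  expect_error(make_sphere_on_tube(1.7, 2, 3), "neck")
})

test_that("carotid waveform has the prescribed mean, period and shape", {
  wf <- make_ica_waveform(4.38, f0 = 1, n_phases = 21)
  expect_equal(mean(wf$q), 4.38, tolerance = 1e-9)
  expect_equal(wf$q_bar, mean(wf$q))
  # 21 phases at 49 ms cover one ~1 s cycle as acquired
  expect_equal(21 * 0.049, 1.029)
  expect_equal(wf$period, 1)
  # exactly one systolic maximum per period
  qq <- c(wf$q, wf$q[1])
  n_max <- sum(diff(sign(diff(c(qq, wf$q[2])))) < 0)
  expect_equal(n_max, 1)
  ratio <- max(wf$q) / wf$q_bar
  expect_gt(ratio, 1.4); expect_lt(ratio, 2.0)
})

test_that("Poiseuille sampler reproduces the analytic parabola and wall shear", {
  f <- pois_field(0.5)
  expect_equal(f$ground_truth$wss_pa, gt_wss, tolerance = 1e-4)
  # centreline velocity = 2 Q / (pi R^2)
  ic <- which(grid_axes(f)$x == 0)
  u_max <- 2 * 4.38e-6 / (pi * (1.675e-3)^2)
  expect_equal(f$v[ic, ic, 3, 3, 1], u_max, tolerance = 1e-12)
  # zero flow gives the null field
  f0 <- sample_poiseuille(tube_grid(1.675, 4), 0, 1.675)
  expect_true(all(f0$v == 0))
  # grid must cover the lumen
  expect_error(sample_poiseuille(tube_grid(0.5, 4), 1, 1.675), "lumen")
})

test_that("complex Bessel evaluation agrees with base R on both axes", {
  z <- c(0.3, 2, 8, 13.5, 16, 24)
  expect_equal(Re(anewall:::besselJ_complex(z, 0)), besselJ(z, 0), tolerance = 1e-10)
  expect_equal(Re(anewall:::besselJ_complex(z, 1)), besselJ(z, 1), tolerance = 1e-10)
  zi <- complex(imaginary = c(0.7, 6, 15))
  # J0(ix) = I0(x), J1(ix) = i I1(x)
  expect_equal(anewall:::besselJ_complex(zi, 0), complex(real = besselI(Im(zi), 0)),
               tolerance = 1e-9)
  expect_equal(anewall:::besselJ_complex(zi, 1),
               complex(imaginary = besselI(Im(zi), 1)), tolerance = 1e-9)
})

test_that("Womersley sampler reproduces the requested flow waveform", {
  f <- wom_field(0.1, length = 2)
  mid <- ceiling(f$dim[3] / 2)
  q_num <- vapply(seq_len(f$n_phases), function(p) {
    sum(f$v[, , mid, 3, p]) * 0.1^2
  }, numeric(1))
  expect_lt(max(abs(q_num - f$ground_truth$q_t)) / max(abs(f$ground_truth$q_t)),
            0.01)
})

test_that("Womersley solution reduces to quasi-steady Poiseuille at low alpha", {
  # alpha ~ 0.06 via an artificially high viscosity
  fl <- fluid_properties(1142, 4.67e-3)
  g <- tube_grid(1.675, 2, 0.1)
  harm <- list(f0 = 1, q0 = 4.38, coef = complex(real = 1.5))
  fw <- sample_womersley(g, harm, 1.675, fluid = fl, n_phases = 8, dt = 125)
  mid <- ceiling(fw$dim[3] / 2)
  m <- fw$mask[, , mid]
  for (p in c(1, 4, 7)) {
    fp <- sample_poiseuille(g, fw$ground_truth$q_t[p], 1.675, fluid = fl)
    err <- max(abs(fw$v[, , mid, 3, p][m] - fp$v[, , mid, 3, 1][m]))
    expect_lt(err / max(abs(fp$v)), 0.01)
  }
  # zero-amplitude harmonics give steady Poiseuille exactly
  h0 <- list(f0 = 1, q0 = 4.38, coef = complex(real = 0))
  fs <- sample_womersley(g, h0, 1.675, n_phases = 4, dt = 250)
  fp <- sample_poiseuille(g, 4.38, 1.675, n_phases = 4, dt = 250)
  expect_equal(fs$v, fp$v, tolerance = 1e-12)
})

test_that("synthetic fields are divergence-free inside the lumen", {
  for (f in list(pois_field(0.5), wom_field(0.5))) {
    h <- f$spacing[1]
    d <- f$dim
    p <- 1
    div <- (f$v[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1), 1, p] -
              f$v[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1), 1, p] +
            f$v[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1), 2, p] -
              f$v[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1), 2, p] +
            f$v[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3], 3, p] -
              f$v[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2), 3, p]) / (2 * h)
    # strictly interior: erode the mask by one voxel in every direction
    m <- f$mask
    er <- m[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] &
      m[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)] & m[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)] &
      m[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)] & m[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)] &
      m[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)] & m[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]]
    grad_scale <- max(abs(f$v)) / f$ground_truth$radius_mm
    expect_lt(max(abs(div[er])), 1e-3 * grad_scale)
  }
})

test_that("phase-contrast synthesis wraps, decodes and reproduces target SNR", {
  f <- pois_field(0.5)
  # noiseless: decode is the identity below VENC
  acq0 <- make_pc_series(f, venc = 1.1, target_snr = Inf, seed = 1)
  expect_equal(acq0$field$v, f$v, tolerance = 1e-12)
  # single wrap: 1.3 VENC acquires as -0.7 VENC
  f2 <- f; f2$v[6, 6, 3, 3, 1] <- 1.3 * 1.1
  acq2 <- make_pc_series(f2, venc = 1.1, target_snr = Inf, seed = 1)
  expect_equal(acq2$field$v[6, 6, 3, 3, 1], -0.7 * 1.1, tolerance = 1e-9)
  # deterministic under a fixed seed
  a <- make_pc_series(f, target_snr = 120, seed = 42)
  b <- make_pc_series(f, target_snr = 120, seed = 42)
  expect_identical(a$field$v, b$field$v)
  expect_identical(a$magnitude$s, b$magnitude$s)
  # recovered SNR near the target (difference method on >= 1e4 ROI voxels)
  big <- velocity_field(array(0.2, c(25, 25, 25, 3, 2)), c(0, 0, 0), venc = 1.1)
  acq <- make_pc_series(big, target_snr = 100, seed = 3)
  est <- snr_difference(acq$magnitude, c(1, 2))
  expect_rel(as.numeric(est), 100, 0.05)
})
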