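# Analytic pipe flows and phase-contrast-like synthetic acquisitions.
# All flows are axial (along +z) in a straight tube of radius R centred on
# x = y = 0; ground truth (imposed waveform, analytic wall shear) travels
# with the field so downstream estimators can be validated.

poiseuille_wss <- function(q_mls, radius_mm, mu) {
  # 4 mu Q / (pi R^3), SI units in, Pa out
  4 * mu * (q_mls * 1e-6) / (pi * (radius_mm * 1e-3)^3)
}

#' Sample a steady Poiseuille flow onto a voxel grid
#'
#' Axial velocity `u(r) = (2Q / pi R^2) (1 - r^2/R^2)` with zero transverse
#' components, identical at all cardiac phases. The analytic wall shear
#' stress `4 mu Q / (pi R^3)` is attached as ground truth.
#'
#' @param grid grid specification from [tube_grid] (fields `origin`,
#'   `spacing`, `dim`).
#' @param q volumetric flow rate, ml/s.
#' @param radius tube radius, mm.
#' @param fluid a [fluid_properties].
#' @param n_phases number of cardiac phases to replicate.
#' @param dt temporal resolution, ms.
#' @param venc velocity-encoding limit, m/s.
#' @return A [velocity_field] with `ground_truth$wss_pa`,
#'   `ground_truth$q_mls`, `ground_truth$radius_mm`.
#' @examples
#' f <- sample_poiseuille(tube_grid(1.675, 10), q = 4.38, radius = 1.675)
#' f$ground_truth$wss_pa  # 6.33 Pa
#' @export
sample_poiseuille <- function(grid, q, radius, fluid = fluid_properties(),
                              n_phases = 1, dt = 49, venc = 1.1) {
  stopifnot_positive(radius)
  stopifnot(q >= 0)
  ax <- list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1],
             y = grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2])
  if (min(ax$x) > -radius || max(ax$x) < radius ||
      min(ax$y) > -radius || max(ax$y) < radius) {
    stop("grid does not cover the lumen cross-section", call. = FALSE)
  }
  r2 <- outer(ax$x^2, ax$y^2, "+")                       # nx x ny
  u_max <- 2 * (q * 1e-6) / (pi * (radius * 1e-3)^2)     # m/s
  u_xy <- u_max * pmax(0, 1 - r2 / radius^2)             # m/s
  inside <- r2 < radius^2
  u_xy[!inside] <- 0
  nz <- grid$dim[3]
  v <- array(0, c(grid$dim, 3, n_phases))
  v[, , , 3, ] <- array(rep(u_xy, nz * n_phases), c(grid$dim, n_phases))
  mask <- array(rep(inside, nz), grid$dim)
  gt <- list(kind = "poiseuille", q_mls = q, radius_mm = radius,
             wss_pa = poiseuille_wss(q, radius, fluid$dynamic_viscosity),
             fluid = fluid)
  velocity_field(v, grid$origin, grid$spacing, dt = dt, venc = venc,
                 mask = mask, ground_truth = gt)
}

# Complex radial profile factor and wall-shear factor for one harmonic.
# beta = i^{3/2} alpha_n. Returns u(r)/A and the flow-normalisation so that
# u_n(r) = Qn / (pi R^2 L(beta)) * [1 - J0(beta r/R)/J0(beta)],
#   L(beta) = 1 - 2 J1(beta) / (beta J0(beta))
# du/dr at wall = (beta/R) J1(beta)/J0(beta) / L(beta) * Qn/(pi R^2).
womersley_profile <- function(r_over_R, alpha_n) {
  if (alpha_n < 1e-3) {
    # quasi-steady limit: parabola
    return(list(shape = 2 * (1 - r_over_R^2), dshape_wall = -4))
  }
  beta <- complex(modulus = alpha_n, argument = 3 * pi / 4)  # i^{3/2} alpha
  J0b <- besselJ_complex(beta, 0)
  J1b <- besselJ_complex(beta, 1)
  L <- 1 - 2 * J1b / (beta * J0b)
  shape <- (1 - besselJ_complex(beta * r_over_R, 0) / J0b) / L
  dshape_wall <- (beta * J1b / J0b) / L  # d(shape)/d(r/R) at r/R = 1
  list(shape = shape, dshape_wall = dshape_wall)
}

#' Sample a Womersley pulsatile pipe flow onto a voxel grid
#'
#' Closed-form oscillatory pipe-flow solution: per flow harmonic the radial
#' profile is a Bessel-function profile, superposed with the steady
#' Poiseuille term; the per-phase cross-section flow equals the requested
#' `Q(t)` by construction. The analytic wall shear time series and the
#' closed-form `Q(t)` are attached as ground truth.
#'
#' @param grid grid specification ([tube_grid]).
#' @param harmonics list with `f0` (Hz), `q0` (ml/s) and complex `coef`
#'   (ml/s), as from [waveform_harmonics].
#' @param radius tube radius, mm.
#' @param fluid a [fluid_properties].
#' @param n_phases number of cardiac phases over one period of `f0`.
#' @param dt temporal resolution, ms; `n_phases * dt` should equal the
#'   period `1/f0` (checked to 1%).
#' @param venc velocity-encoding limit, m/s.
#' @return A [velocity_field] with `ground_truth$q_t` (ml/s per phase) and
#'   `ground_truth$wss_t` (signed axial wall shear, Pa, per phase).
#' @export
sample_womersley <- function(grid, harmonics, radius,
                             fluid = fluid_properties(), n_phases = 21,
                             dt = 49, venc = 1.1) {
  stopifnot_positive(radius, n_phases, dt)
  R_m <- radius * 1e-3
  w0 <- 2 * pi * harmonics$f0
  alpha <- R_m * sqrt(w0 / fluid$kinematic_viscosity)
  n_h <- length(harmonics$coef)
  if (alpha * sqrt(n_h) > 20) {
    warning(sprintf("Womersley number %.1f (highest harmonic) above validated range",
                    alpha * sqrt(n_h)))
  }
  # the acquisition grid may overcover the cycle slightly (21 x 49 ms ~ 1 s)
  if (abs(n_phases * dt / 1000 - 1 / harmonics$f0) > 0.05 / harmonics$f0) {
    warning("n_phases * dt does not span one period of f0")
  }
  ax <- list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1],
             y = grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2])
  r_xy <- sqrt(outer(ax$x^2, ax$y^2, "+"))
  inside <- r_xy < radius
  rr <- r_xy[inside] / radius
  times <- (seq_len(n_phases) - 1) * dt / 1000
  area <- pi * R_m^2

  # steady part
  u_in <- 2 * (harmonics$q0 * 1e-6) / area * (1 - rr^2)   # m/s
  u_phase <- matrix(rep(u_in, n_phases), ncol = n_phases)
  tau_t <- rep(poiseuille_wss(harmonics$q0, radius, fluid$dynamic_viscosity),
               n_phases)
  q_t <- rep(harmonics$q0, n_phases)

  mu <- fluid$dynamic_viscosity
  for (k in seq_len(n_h)) {
    alpha_k <- alpha * sqrt(k)
    prof <- womersley_profile(rr, alpha_k)
    qk <- harmonics$coef[k] * 1e-6                         # m^3/s complex amp
    e_t <- exp(1i * k * w0 * times)
    u_phase <- u_phase + Re(outer(prof$shape * qk / area, e_t))
    # signed wall shear in +z: tau = -mu du/dr|wall ; d/dr = (1/R) d/d(r/R)
    tau_t <- tau_t + Re(-mu * (prof$dshape_wall / R_m) * qk / area * e_t)
    q_t <- q_t + Re(qk * e_t) * 1e6
  }

  nz <- grid$dim[3]
  v <- array(0, c(grid$dim, 3, n_phases))
  uz <- array(0, c(grid$dim[1], grid$dim[2], n_phases))
  for (p in seq_len(n_phases)) {
    sl <- matrix(0, grid$dim[1], grid$dim[2])
    sl[inside] <- u_phase[, p]
    uz[, , p] <- sl
  }
  for (p in seq_len(n_phases)) {
    v[, , , 3, p] <- array(rep(uz[, , p], nz), grid$dim)
  }
  mask <- array(rep(inside, nz), grid$dim)
  gt <- list(kind = "womersley", alpha = alpha, radius_mm = radius,
             q_t = q_t, wss_t = tau_t,
             times = times, harmonics = harmonics, fluid = fluid)
  velocity_field(v, grid$origin, grid$spacing, dt = dt, venc = venc,
                 mask = mask, ground_truth = gt)
}

#' Synthesize a phase-contrast acquisition from a ground-truth field
#'
#' Emulates the image-space signal model of a phase-contrast sequence:
#' the magnitude image is a piecewise-constant lumen signal `a` (background
#' `a/10`) plus zero-mean Gaussian noise of standard deviation
#' `a/target_snr`; each velocity component is encoded as phase
#' `pi * v / venc`, perturbed by matched phase noise
#' (`sigma_v = sqrt(2)/pi * venc / target_snr` on the decoded velocity) and
#' wrapped into `(-pi, pi]`. The returned velocity field is the wrapped,
#' noisy decode `venc * phase / pi`, so true speeds above `venc` alias.
#'
#' @param field ground-truth [velocity_field].
#' @param venc velocity-encoding limit, m/s (defaults to the field's).
#' @param target_snr magnitude signal-to-noise ratio (`Inf` for noiseless).
#' @param seed integer RNG seed; the output is reproducible under it.
#' @param a lumen magnitude signal, arbitrary units.
#' @return list with `magnitude` (a `magnitude_series`) and `field`
#'   (the acquired [velocity_field]).
#' @export
make_pc_series <- function(field, venc = field$venc, target_snr = 120,
                           seed = 1, a = 100) {
  stopifnot_positive(venc)
  if (is.na(target_snr) || target_snr <= 0) {
    stop("'target_snr' must be positive (Inf for noiseless)", call. = FALSE)
  }
  dims <- field$dim
  n_ph <- field$n_phases
  sigma_s <- a / target_snr
  sigma_v <- sqrt(2) / pi * venc / target_snr
  out <- with_seed(seed, {
    s <- array(a / 10, c(dims, n_ph))
    s <- s + ifelse(array(field$mask, c(dims, n_ph)), a - a / 10, 0)
    if (is.finite(target_snr)) {
      s <- s + array(stats::rnorm(prod(dims) * n_ph, sd = sigma_s), c(dims, n_ph))
      s <- pmax(s, 0)  # magnitude images are non-negative
    }
    ph <- pi * field$v / venc
    if (is.finite(target_snr)) {
      ph <- ph + array(stats::rnorm(length(ph), sd = pi * sigma_v / venc), dim(ph))
    }
    # wrap into (-pi, pi]
    ph <- ph - 2 * pi * ceiling((ph - pi) / (2 * pi))
    list(s = s, ph = ph)
  })
  mag <- magnitude_series(out$s, roi_vessel = field$mask)
  acq <- velocity_field(venc * out$ph / pi, field$origin, field$spacing,
                        dt = field$dt, venc = venc, mask = field$mask,
                        ground_truth = field$ground_truth)
  list(magnitude = mag, field = acq)
}

#' Phase-contrast magnitude image series
#'
#' @param s non-negative 4-D array `[nx, ny, nz, n_phases]`, arbitrary
#'   signal units.
#' @param roi_vessel logical array `[nx, ny, nz]`: the high-signal region
#'   of interest (the vascular lumen).
#' @param slice_axis grid axis enumerating acquisition slices (default 3).
#' @return Object of class `magnitude_series`.
#' @export
magnitude_series <- function(s, roi_vessel, slice_axis = 3) {
  stopifnot(length(dim(s)) == 4, identical(dim(s)[1:3], dim(roi_vessel)))
  if (min(s) < 0) stop("magnitude signal must be non-negative", call. = FALSE)
  structure(list(s = s, roi_vessel = roi_vessel, slice_axis = slice_axis,
                 n_slices = dim(s)[slice_axis], n_phases = dim(s)[4]),
            class = "magnitude_series")
}
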