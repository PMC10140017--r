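# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

fix <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(build)
  .fix[[name]]
}

std_fluid <- function() fluid_properties()          # 1142 kg/m^3, 4.67e-6 m^2/s
std_radius <- 1.675                                 # IA1 parent radius, mm
gt_wss <- 6.3288                                    # 4 mu Q / (pi R^3), Pa, frozen

# straight tube phantom, 8 mm, dense mesh
tube8 <- function() fix("tube8", make_tube_phantom(std_radius, 8, mesh_pitch = 0.3))

# steady Poiseuille fields at several voxel sizes
pois_field <- function(h) {
  key <- sprintf("pois%g", h)
  fix(key, sample_poiseuille(tube_grid(std_radius, 8, h), 4.38, std_radius,
                             std_fluid()))
}

# pulsatile Womersley field from the built-in carotid waveform
wom_field <- function(h, length = 6) {
  key <- sprintf("wom%g_%g", h, length)
  fix(key, {
    wf <- make_ica_waveform(4.38)
    sample_womersley(tube_grid(std_radius, length, h), waveform_harmonics(wf),
                     std_radius, std_fluid())
  })
}

# dense wall point cloud of the 8 mm tube (side wall only) and an interior
# evaluation subset away from the openings
tube8_wall <- function() {
  fix("tube8_wall", {
    pts <- tube8()$surface$vertices
    side <- (pts[, 1]^2 + pts[, 2]^2) > (0.9 * std_radius)^2
    cloud <- pts[side, , drop = FALSE]
    ev <- which(cloud[, 3] > 1.5 & cloud[, 3] < 6.5)
    list(cloud = cloud, eval = ev[seq(1, length(ev), by = 3)])
  })
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
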