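# End-to-end orchestration: configuration, stage sequencing, report.

#' Build or validate a case configuration
#'
#' A case is either synthetic (`case = "tube"` or `"sac"`, generated by
#' the phantom and flow modules) or file-based (NIfTI velocity volumes
#' plus surface/centerline/waveform files). Defaults mirror the emulated
#' acquisition: 0.5 mm isotropic voxels, 21 phases at 49 ms, VENC 1.1 m/s,
#' 1 Hz pulse, glycerine/water blood analogue.
#'
#' @param x a named list, or path to a YAML/JSON document.
#' @return validated config list of class `case_config`.
#' @export
case_config <- function(x = list()) {
  if (is.character(x)) {
    x <- if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  }
  def <- list(
    case = "tube",
    seed = 1,
    venc = 1.1,
    target_snr = 120,
    density = 1142,
    kinematic_viscosity = 4.67e-6,
    q_bar = 4.38,
    f0 = 1,
    n_phases = 21,
    dt = 49,
    voxel = 0.5,
    tube_radius = 1.675,
    tube_length = 20,
    sac_radius = 3,
    neck_radius = 2,
    plane_spacing = 1.25,
    flow_resolution = 0.1,
    paths = NULL,
    stages = list(preprocess = TRUE, register = TRUE, flow = TRUE,
                  sac = TRUE, wss = TRUE, quality = TRUE)
  )
  cfg <- utils::modifyList(def, x)
  if (!cfg$case %in% c("tube", "sac", "files")) {
    stop("config error: case must be tube, sac or files", call. = FALSE)
  }
  ok <- tryCatch({
    stopifnot_positive(cfg$venc, cfg$density, cfg$kinematic_viscosity,
                       cfg$q_bar, cfg$f0, cfg$n_phases, cfg$dt, cfg$voxel,
                       cfg$tube_radius, cfg$tube_length)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("config error: ", conditionMessage(ok), call. = FALSE)
  if (cfg$case == "files") {
    needed <- unlist(cfg$paths[c("vx", "vy", "vz", "surface")])
    if (length(needed) < 4 || !all(file.exists(needed))) {
      stop("config error: missing input files", call. = FALSE)
    }
  }
  structure(cfg, class = "case_config")
}

run_stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %-12s %6.1f s", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run a full case end-to-end
#'
#' Executes the processing chain — simulate/load, temporal unwrap,
#' normalized-median outlier repair, rigid registration, lumen masking,
#' per-plane flow rates with mass-conservation statistics and waveform
#' comparison, sac isolation with neck-plane fit and morphometrics, WSS /
#' TAWSS / OSI on the sac wall, SNR / VNR — and writes a JSON report plus
#' CSV side outputs. Deterministic for a fixed config seed (stage timings
#' go to the log only, never the report).
#'
#' @param config a [case_config] (or list / file path coerced by it).
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return the report, invisibly; written to `<out_dir>/report.json`.
#' @export
run_case <- function(config, out_dir, quiet = FALSE) {
  cfg <- if (inherits(config, "case_config")) config else case_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log <- function(msg) {
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  fluid <- fluid_properties(cfg$density, cfg$kinematic_viscosity)
  report <- list(case = cfg$case, seed = cfg$seed)

  # --- inputs -------------------------------------------------------------
  sim <- run_stage("inputs", log, {
    if (cfg$case == "files") {
      field <- read_velocity_nifti(unlist(cfg$paths[c("vx", "vy", "vz")]),
                                   venc = cfg$venc, dt = cfg$dt)
      surface <- if (grepl("\\.ply$", cfg$paths$surface))
        read_surface_ply(cfg$paths$surface) else read_surface_stl(cfg$paths$surface)
      cl <- if (!is.null(cfg$paths$centerline))
        read_centerline_csv(cfg$paths$centerline) else NULL
      wf <- if (!is.null(cfg$paths$waveform))
        read_waveform_csv(cfg$paths$waveform) else NULL
      list(field = field, surface = surface, centerline = cl,
           waveform = wf, magnitude = NULL, truth = NULL)
    } else {
      wf <- make_ica_waveform(cfg$q_bar, cfg$f0, cfg$n_phases)
      harm <- waveform_harmonics(wf)
      grid <- tube_grid(cfg$tube_radius, cfg$tube_length, cfg$voxel)
      if (cfg$case == "sac") {
        # widen the grid so the sac (sphere tangent to the wall at +x,
        # mid-length) and a margin around it are imaged too
        h <- cfg$voxel
        d_neck <- sqrt(max(0, cfg$sac_radius^2 - cfg$neck_radius^2))
        x_hi <- cfg$tube_radius + d_neck + cfg$sac_radius + 2 * h
        y_hi <- max(cfg$tube_radius, cfg$sac_radius) + 2 * h
        grid$origin[1:2] <- c(-(cfg$tube_radius + 2 * h), -y_hi)
        grid$dim[1] <- ceiling((x_hi - grid$origin[1]) / h) + 1
        grid$dim[2] <- 2 * ceiling(y_hi / h) + 1
      }
      truth_field <- sample_womersley(grid, harm, cfg$tube_radius, fluid,
                                      n_phases = cfg$n_phases, dt = cfg$dt,
                                      venc = cfg$venc)
      ph <- if (cfg$case == "sac") {
        make_sphere_on_tube(cfg$tube_radius, cfg$sac_radius, cfg$neck_radius,
                            length = cfg$tube_length)
      } else {
        make_tube_phantom(cfg$tube_radius, cfg$tube_length)
      }
      if (cfg$case == "sac") {
        # dead-flow sac: extend the sampling mask into the sac interior
        gp <- grid_points(truth_field)
        ctr <- ph$sac_truth$sphere_center
        in_sac <- rowSums((gp - matrix(ctr, nrow(gp), 3, byrow = TRUE))^2) <
          cfg$sac_radius^2
        truth_field$mask <- truth_field$mask | array(in_sac, truth_field$dim)
      }
      acq <- make_pc_series(truth_field, venc = cfg$venc,
                            target_snr = cfg$target_snr, seed = cfg$seed)
      list(field = acq$field, surface = ph$surface,
           centerline = ph$centerline, waveform = wf,
           magnitude = acq$magnitude, truth = truth_field,
           phantom = ph)
    }
  })
  field <- sim$field

  # --- preprocessing ------------------------------------------------------
  if (isTRUE(cfg$stages$preprocess)) {
    field <- run_stage("unwrap", log, unwrap_temporal(field))
    mf <- run_stage("outliers", log, median_filter_outliers(field))
    field <- mf$field
    report$preprocess <- list(n_outliers = nrow(mf$report),
                              unresolved_wraps = length(attr(field, "unresolved")))
  }

  # --- registration + masking --------------------------------------------
  reg <- NULL
  if (isTRUE(cfg$stages$register) && cfg$case != "sac") {
    sp <- field_speed(field)
    if (field$n_phases > 1) {
      syst <- which.max(masked_mean_speed(field))
      sp <- sp[, , , syst]
    }
    reg <- run_stage("register", log, {
      register_rigid(sim$surface, sp, field$origin, field$spacing)
    })
    report$registration <- list(angles_deg = reg$angles,
                                translation_mm = reg$translation,
                                objective = attr(reg, "objective"))
    field <- run_stage("mask", log, mask_lumen(field, sim$surface, reg))
  }

  # --- flow rates ---------------------------------------------------------
  flow_stats <- NULL
  if (isTRUE(cfg$stages$flow) && !is.null(sim$centerline)) {
    flow_stats <- run_stage("flow", log, {
      planes <- orthogonal_planes(sim$centerline, cfg$plane_spacing)
      # skip stations within a diameter of the openings
      smax <- max(sim$centerline$arclength)
      planes <- Filter(function(pl) {
        pl$arclength > pl$d_vessel & pl$arclength < smax - pl$d_vessel
      }, planes)
      qs <- lapply(planes, function(pl) {
        plane_flow_rate(field, pl, sim$surface, resolution = cfg$flow_resolution)
      })
      st <- interplane_stats(qs)
      utils::write.csv(
        data.frame(t_s = (seq_len(field$n_phases) - 1) * field$dt / 1000,
                   q_mean = st$mean, q_sd = st$sd),
        file.path(out_dir, "flow_planes.csv"), row.names = FALSE)
      st
    })
    d_in <- sim$centerline$d_vessel[1]
    report$flow <- list(
      q_bar_mls = mean(flow_stats$q_bar),
      systolic_index = flow_stats$systolic_index,
      interplane_sd_over_mean_pct =
        100 * max(flow_stats$sd / pmax(abs(flow_stats$mean), 1e-12)),
      reynolds = reynolds_number(mean(flow_stats$q_bar), d_in,
                                 fluid$kinematic_viscosity),
      womersley = womersley_number(d_in, cfg$f0, fluid$kinematic_viscosity))
    if (!is.null(sim$waveform)) {
      meas <- flow_waveform((seq_len(field$n_phases) - 1) * field$dt / 1000,
                            flow_stats$mean, f0 = cfg$f0)
      cmpw <- compare_waveforms(meas, sim$waveform)
      report$flow$time_averaged_difference_pct <- cmpw$time_averaged_difference
      report$flow$systolic_difference_pct <- cmpw$systolic_difference
      write_waveform_csv(meas, file.path(out_dir, "waveform_measured.csv"))
      write_waveform_csv(sim$waveform, file.path(out_dir, "waveform_reference.csv"))
    }
  }

  # --- sac geometry -------------------------------------------------------
  sac_out <- NULL
  if (isTRUE(cfg$stages$sac) && !is.null(sim$centerline)) {
    sac_out <- run_stage("sac", log, isolate_sac(sim$surface, sim$centerline))
    if (sac_out$status == "ok" && nrow(sac_out$neck_loop) >= 3) {
      np <- fit_neck_plane(sac_out$neck_loop)
      morpho <- sac_morphometrics(sac_out$sac, np, sac_out$neck_loop,
                                  parent_diameter = sim$centerline$d_vessel[1])
      report$sac <- morpho[c("max_height", "perpendicular_height",
                             "max_width", "volume", "surface",
                             "neck_diameter", "aspect_ratio",
                             "inlet_parent_diameter")]
      tab <- data.frame(
        quantity = c("max_height_mm", "perpendicular_height_mm",
                     "max_width_mm", "volume_mm3", "surface_mm2",
                     "inlet_parent_diameter_mm", "neck_diameter_mm",
                     "aspect_ratio"),
        value = unlist(report$sac)[c(1:3, 4, 5, 8, 6, 7)])
      utils::write.csv(tab, file.path(out_dir, "morphometrics.csv"),
                       row.names = FALSE)
      write_surface_ply(sac_out$sac, file.path(out_dir, "sac.ply"))
      utils::write.csv(as.data.frame(sac_out$neck_loop),
                       file.path(out_dir, "neck_loop.csv"), row.names = FALSE)
    } else {
      report$sac <- list(status = "empty")
    }
  }

  # --- wall shear ---------------------------------------------------------
  if (isTRUE(cfg$stages$wss)) {
    wall <- if (!is.null(sac_out) && sac_out$status == "ok") sac_out$sac
    else sim$surface
    rec <- run_stage("wss", log, {
      pts <- wall$vertices
      # interior wall band only: drop points near the tube openings
      zr <- range(field$origin[3] + (field$dim[3] - 1) * field$spacing[3],
                  field$origin[3])
      keep <- pts[, 3] > min(zr) + 1.5 & pts[, 3] < max(zr) - 1.5
      pts <- pts[keep, , drop = FALSE]
      if (nrow(pts) > 400) pts <- pts[round(seq(1, nrow(pts), length.out = 400)), ]
      wss_field(field, pts, mu = fluid$dynamic_viscosity)
    })
    ta <- tawss(rec)
    os <- osi(rec)
    syst <- if (!is.null(flow_stats)) flow_stats$systolic_index else
      which.max(rec$mean_mag)
    ok <- !rec$flagged
    report$wss <- list(
      systolic_index = syst,
      max_wss_syst_pa = rec$max_mag[syst],
      mean_wss_syst_pa = rec$mean_mag[syst],
      mean_tawss_pa = mean(ta$magnitude[ok]),
      max_osi = if (all(is.na(os[ok]))) NA else max(os[ok], na.rm = TRUE),
      n_vertices = sum(ok), n_flagged = sum(rec$flagged))
    utils::write.csv(
      data.frame(x_mm = rec$vertices[, 1], y_mm = rec$vertices[, 2],
                 z_mm = rec$vertices[, 3], tawss_pa = ta$magnitude,
                 osi = os),
      file.path(out_dir, "wss_vertices.csv"), row.names = FALSE)
  }

  # --- quality ------------------------------------------------------------
  if (isTRUE(cfg$stages$quality) && !is.null(sim$magnitude)) {
    qm <- run_stage("quality", log, quality_metrics(field, sim$magnitude))
    report$quality <- list(snr = qm$snr, vnr = qm$vnr, pair = qm$pair,
                           mean_speed_ms = qm$mean_speed, venc_ms = qm$venc)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  log("done")
  invisible(report)
}
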