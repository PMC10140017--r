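# Image quality metrics: SNR by the two-image difference method, and the
# velocity-to-noise ratio.

#' Select the cardiac phase pair for the SNR difference method
#'
#' Among consecutive phase pairs whose masked mean speeds differ by at
#' most `max_rel_diff` (default 1%), returns the pair with the highest
#' difference-method SNR (several pairs typically qualify around
#' diastole). If no pair qualifies the minimum-difference pair is
#' returned with a warning flag. Ties resolve to the lowest index.
#'
#' @param field a [velocity_field] (>= 2 phases).
#' @param series optional [magnitude_series]; needed to rank qualifying
#'   pairs by SNR (otherwise the lowest-index qualifying pair is
#'   returned).
#' @param max_rel_diff relative mean-speed difference threshold
#'   (default 0.01).
#' @return list with `pair` (c(i, i+1)), `fallback` (TRUE when no pair
#'   met the threshold) and `rel_diff`.
#' @export
select_phase_pair <- function(field, series = NULL, max_rel_diff = 0.01) {
  if (field$n_phases < 2) stop("need at least 2 phases", call. = FALSE)
  ms <- masked_mean_speed(field)
  n <- field$n_phases
  i <- seq_len(n - 1)
  rel <- abs(ms[i + 1] - ms[i]) / pmax(pmax(ms[i], ms[i + 1]), 1e-300)
  qual <- which(rel <= max_rel_diff)
  fallback <- length(qual) == 0
  if (fallback) {
    best <- which.min(rel)
    warning("no consecutive phase pair within the mean-speed tolerance; ",
            "using the minimum-difference pair")
  } else if (!is.null(series)) {
    snrs <- vapply(qual, function(k) {
      snr_difference(series, c(k, k + 1))
    }, numeric(1))
    best <- qual[which.max(snrs)]
  } else {
    best <- qual[1]
  }
  list(pair = c(best, best + 1L), fallback = fallback, rel_diff = rel[best])
}

#' SNR by the two-image difference method
#'
#' Per acquisition slice, the signal is the region-of-interest mean of the
#' sum of two near-identical magnitude images and the noise is the ROI
#' standard deviation of their difference:
#' `SNR_k = mean(S_i + S_{i+1}) / (sqrt(2) sd(S_i - S_{i+1}))`,
#' averaged over slices. Estimating noise from a difference image works in
#' the presence of signal; the method is invariant under joint intensity
#' scaling.
#'
#' @param series a [magnitude_series].
#' @param pair integer pair of consecutive phase indices.
#' @param roi_vessel optional logical ROI array overriding the one stored
#'   in `series`.
#' @return scalar SNR, with attribute `per_slice`.
#' @export
snr_difference <- function(series, pair, roi_vessel = NULL) {
  stopifnot(inherits(series, "magnitude_series"), length(pair) == 2)
  roi <- if (is.null(roi_vessel)) series$roi_vessel else roi_vessel
  ax <- series$slice_axis
  n_sl <- dim(series$s)[ax]
  per_slice <- rep(NA_real_, n_sl)
  for (k in seq_len(n_sl)) {
    idx <- lapply(dim(roi), seq_len)
    idx[[ax]] <- k
    roi_k <- do.call(`[`, c(list(roi), idx, list(drop = FALSE)))
    if (!any(roi_k)) next
    s_i <- do.call(`[`, c(list(series$s), idx, list(pair[1]), list(drop = FALSE)))
    s_j <- do.call(`[`, c(list(series$s), idx, list(pair[2]), list(drop = FALSE)))
    sum_m <- mean((s_i + s_j)[roi_k])
    sd_d <- stats::sd((s_i - s_j)[roi_k])
    if (sd_d == 0) {
      stop(sprintf("zero difference standard deviation on slice %d", k),
           call. = FALSE)
    }
    per_slice[k] <- sum_m / (sqrt(2) * sd_d)
  }
  if (all(is.na(per_slice))) stop("ROI is empty on every slice", call. = FALSE)
  out <- mean(per_slice, na.rm = TRUE)
  attr(out, "per_slice") <- per_slice
  out
}

#' Velocity-to-noise ratio
#'
#' `VNR = (pi / sqrt(2)) * (mean_speed / VENC) * SNR`, where `mean_speed`
#' is the spatial mean over the fluid volume of the magnitude of the
#' time-averaged velocity field.
#'
#' @param snr scalar SNR (difference method).
#' @param mean_speed m/s.
#' @param venc m/s.
#' @return scalar VNR.
#' @examples
#' vnr(100, 0.2, 1.0)  # 44.43
#' @export
vnr <- function(snr, mean_speed, venc) {
  stopifnot_positive(snr, venc)
  stopifnot(mean_speed >= 0)
  pi / sqrt(2) * (mean_speed / venc) * as.numeric(snr)
}

#' Mean speed of the time-averaged velocity field over the lumen
#'
#' The velocity signal entering the VNR: per voxel the velocity is first
#' averaged over the cardiac cycle, then its magnitude is averaged over
#' the masked fluid volume.
#'
#' @param field a [velocity_field].
#' @return scalar mean speed, m/s.
#' @export
mean_timeaveraged_speed <- function(field) {
  vbar <- apply(field$v, 1:4, mean)       # time average per voxel/component
  sp <- sqrt(vbar[, , , 1]^2 + vbar[, , , 2]^2 + vbar[, , , 3]^2)
  mean(sp[field$mask])
}

#' Quality metrics of an acquisition
#'
#' Convenience wrapper running phase-pair selection, the SNR difference
#' method and the VNR on one dataset.
#'
#' @param field a [velocity_field].
#' @param series a [magnitude_series].
#' @return Object of class `quality_metrics`: `snr`, `vnr`, `pair`,
#'   `per_slice_snr`, `mean_speed`, `venc`.
#' @export
quality_metrics <- function(field, series) {
  sel <- select_phase_pair(field, series)
  s <- snr_difference(series, sel$pair)
  msp <- mean_timeaveraged_speed(field)
  structure(list(snr = as.numeric(s), vnr = vnr(s, msp, field$venc),
                 pair = sel$pair, per_slice_snr = attr(s, "per_slice"),
                 mean_speed = msp, venc = field$venc),
            class = "quality_metrics")
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf("Quality: SNR %.2f (phases %d/%d), mean speed %.3f m/s, VNR %.2f\n",
              x$snr, x$pair[1], x$pair[2], x$mean_speed, x$vnr))
  invisible(x)
}
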