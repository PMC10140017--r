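#' Fluid properties of a blood analogue
#'
#' Bundles density and viscosity of the working fluid. The defaults are a
#' glycerine/water blood analogue at 37 degrees C (density 1142 kg/m^3,
#' kinematic viscosity 4.67e-6 m^2/s), whose dynamic viscosity matches human
#' blood at high shear rate.
#'
#' @param density kg/m^3.
#' @param kinematic_viscosity m^2/s.
#' @return Object of class `fluid_properties` with fields `density`,
#'   `kinematic_viscosity` and `dynamic_viscosity` (Pa s), the latter equal
#'   to their product.
#' @examples
#' fl <- fluid_properties()
#' fl$dynamic_viscosity  # ~5.33e-3 Pa s
#' @export
fluid_properties <- function(density = 1142, kinematic_viscosity = 4.67e-6) {
  stopifnot_positive(density, kinematic_viscosity)
  structure(list(density = density,
                 kinematic_viscosity = kinematic_viscosity,
                 dynamic_viscosity = density * kinematic_viscosity),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: rho = %g kg/m^3, nu = %g m^2/s, mu = %g Pa s\n",
              x$density, x$kinematic_viscosity, x$dynamic_viscosity))
  invisible(x)
}

#' Volumetric flow waveform over one cardiac cycle
#'
#' @param times seconds; uniform grid spanning exactly one period starting
#'   at 0 (the closing sample at `T` is not repeated).
#' @param q ml/s, one value per time sample.
#' @param f0 fundamental frequency, Hz. Defaults to `1 / period`.
#' @return Object of class `flow_waveform` with `times`, `q`, `q_bar`
#'   (rectangle-rule time average, exact on the uniform periodic grid),
#'   `f0`, `period` and `systolic_index` (index of maximum flow).
#' @export
flow_waveform <- function(times, q, f0 = NULL) {
  stopifnot(length(times) == length(q), length(q) >= 2)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("'times' must be a uniform grid", call. = FALSE)
  }
  period <- length(times) * dt[1]
  if (is.null(f0)) f0 <- 1 / period
  structure(list(times = times, q = q, q_bar = mean(q), f0 = f0,
                 period = period, systolic_index = which.max(q)),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "Flow waveform: %d samples over %.3f s, Q_bar = %.3f ml/s, peak %.3f ml/s at phase %d\n",
    length(x$q), x$period, x$q_bar, max(x$q), x$systolic_index))
  invisible(x)
}

# Fixed harmonic table of a generic internal-carotid-artery pulse shape,
# relative to unit mean flow: Q(t)/Qbar = 1 + sum a_n cos(n w t + phi_n).
# Digitised once from a generic single-peak ICA pulse; amplitudes decay so
# the waveform has one systolic maximum and peak/mean ~ 1.6.
.ica_harmonics <- data.frame(
  n   = 1:8,
  a   = c(0.400, 0.220, 0.120, 0.060, 0.030, 0.016, 0.008, 0.004),
  phi = c(-0.60, -1.60, -2.60, -3.60, -4.60, -5.60, -6.60, -7.60)
)

#' Generate a physiological internal-carotid-artery flow waveform
#'
#' A fixed built-in harmonic shape (8 harmonics, single systolic peak,
#' peak-to-mean ratio about 1.6) is rescaled so that its rectangle-rule time
#' average equals `q_bar`. With the default 21 phases at 49 ms the sampled
#' cycle spans 1.029 s, emulating a 1 Hz cardiac trigger.
#'
#' @param q_bar target time-averaged flow, ml/s.
#' @param f0 fundamental frequency, Hz.
#' @param n_phases number of cardiac phases sampling one period.
#' @return A [flow_waveform].
#' @examples
#' wf <- make_ica_waveform(4.38)
#' wf$q_bar          # 4.38
#' max(wf$q) / wf$q_bar  # systolic peak ratio ~1.6
#' @export
make_ica_waveform <- function(q_bar, f0 = 1, n_phases = 21) {
  stopifnot_positive(q_bar, f0, n_phases)
  times <- (seq_len(n_phases) - 1) / (n_phases * f0)
  h <- .ica_harmonics
  shape <- rep(1, n_phases)
  for (i in seq_len(nrow(h))) {
    shape <- shape + h$a[i] * cos(2 * pi * h$n[i] * f0 * times + h$phi[i])
  }
  # the harmonic sum has zero mean on the periodic grid only in the limit;
  # rescale exactly so the sampled mean is q_bar
  q <- shape / mean(shape) * q_bar
  flow_waveform(times, q, f0 = f0)
}

#' Complex Fourier harmonics of a sampled periodic waveform
#'
#' Decomposes a [flow_waveform] into its mean and the first `n_harmonics`
#' complex Fourier coefficients so that
#' `Q(t) = q0 + Re(sum_k coef[k] * exp(1i * k * w0 * t))`.
#'
#' @param waveform a [flow_waveform].
#' @param n_harmonics number of harmonics to keep (at most
#'   `floor((n-1)/2)`).
#' @return list with `f0`, `q0` (ml/s) and complex vector `coef` (ml/s).
#' @export
waveform_harmonics <- function(waveform, n_harmonics = 8) {
  q <- waveform$q
  n <- length(q)
  n_harmonics <- min(n_harmonics, floor((n - 1) / 2))
  ft <- stats::fft(q) / n
  list(f0 = waveform$f0, q0 = Re(ft[1]), coef = 2 * ft[1 + seq_len(n_harmonics)])
}

#' Evaluate harmonics back into a waveform
#' @param harmonics list as returned by [waveform_harmonics].
#' @param times seconds.
#' @return numeric flow values, ml/s.
#' @keywords internal
harmonics_q <- function(harmonics, times) {
  q <- rep(harmonics$q0, length(times))
  w0 <- 2 * pi * harmonics$f0
  for (k in seq_along(harmonics$coef)) {
    q <- q + Re(harmonics$coef[k] * exp(1i * k * w0 * times))
  }
  q
}
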