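# Bessel functions J0, J1 for complex argument.
#
# The oscillatory (Womersley) pipe-flow solution needs J0 and J1 at
# z = i^{3/2} * alpha with alpha the Womersley number. Base R's besselJ is
# real-only, so these are evaluated by the ascending power series for
# moderate |z| and by Gauss-Legendre quadrature of the integral
# representation J_n(z) = (1/pi) Int_0^pi cos(n t - z sin t) dt otherwise.

.bessel_env <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch Jacobi matrix.
gauss_legendre <- function(n, a = -1, b = 1) {
  key <- sprintf("gl%d", n)
  if (is.null(.bessel_env[[key]])) {
    k <- seq_len(n - 1)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- beta
    J[cbind(k + 1, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    o <- order(x)
    .bessel_env[[key]] <- list(x = x[o], w = w[o])
  }
  gl <- .bessel_env[[key]]
  list(x = 0.5 * (b - a) * gl$x + 0.5 * (a + b), w = 0.5 * (b - a) * gl$w)
}

besselJ_series <- function(z, nu, m_max = 60) {
  # ascending series sum_m (-1)^m (z^2/4)^m / (m! (m+nu)!) * (z/2)^nu
  term <- (z / 2)^nu / factorial(nu)
  s <- term
  zz <- -(z * z) / 4
  for (m in seq_len(m_max)) {
    term <- term * zz / (m * (m + nu))
    s <- s + term
    if (all(abs(term) < 1e-17 * (abs(s) + 1e-300))) break
  }
  s
}

besselJ_integral <- function(z, nu, n_nodes = 160) {
  gl <- gauss_legendre(n_nodes, 0, pi)
  vapply(z, function(zi) {
    sum(gl$w * cos(nu * gl$x - zi * sin(gl$x))) / pi
  }, complex(1))
}

#' Bessel function of the first kind for complex argument
#'
#' @param z complex (or numeric) vector.
#' @param nu non-negative integer order (0 or 1 are used internally).
#' @return complex vector `J_nu(z)`.
#' @keywords internal
besselJ_complex <- function(z, nu = 0) {
  z <- as.complex(z)
  out <- complex(length(z))
  small <- abs(z) <= 14
  if (any(small)) out[small] <- besselJ_series(z[small], nu)
  if (any(!small)) out[!small] <- besselJ_integral(z[!small], nu)
  out
}
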