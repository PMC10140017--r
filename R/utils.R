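# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_positive <- function(...) {
  vals <- list(...)
  nms <- sapply(substitute(list(...))[-1], deparse)
  for (i in seq_along(vals)) {
    if (!all(is.finite(vals[[i]])) || any(vals[[i]] <= 0)) {
      stop(sprintf("'%s' must be strictly positive and finite", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Trilinear interpolation of a 3-D scalar grid at arbitrary points
#'
#' Values are interpolated on a cell-centred grid: the centre of voxel
#' `(1,1,1)` lies at `origin` and voxel centres are spaced by `spacing`.
#' Points outside the grid hull return `NA`.
#'
#' @param a 3-D numeric array.
#' @param origin numeric length 3, mm; centre of the first voxel.
#' @param spacing numeric length 3, mm.
#' @param pts n x 3 matrix of query points, mm.
#' @return numeric vector of length `nrow(pts)`.
#' @keywords internal
interp_trilinear <- function(a, origin, spacing, pts) {
  pts <- matrix(pts, ncol = 3)
  d <- dim(a)
  # continuous voxel index (1-based)
  fx <- (pts[, 1] - origin[1]) / spacing[1] + 1
  fy <- (pts[, 2] - origin[2]) / spacing[2] + 1
  fz <- (pts[, 3] - origin[3]) / spacing[3] + 1
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  ok <- i0 >= 1 & j0 >= 1 & k0 >= 1 & i0 <= d[1] - 1 & j0 <= d[2] - 1 & k0 <= d[3] - 1
  # points exactly on the far face
  hi_x <- fx == d[1]; hi_y <- fy == d[2]; hi_z <- fz == d[3]
  i0[hi_x] <- d[1] - 1; j0[hi_y] <- d[2] - 1; k0[hi_z] <- d[3] - 1
  ok <- ok | ((i0 >= 1 & j0 >= 1 & k0 >= 1) &
                (fx <= d[1] & fy <= d[2] & fz <= d[3]) &
                (fx >= 1 & fy >= 1 & fz >= 1))
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- pmin(pmax(i0[ok], 1), d[1] - 1)
  j0 <- pmin(pmax(j0[ok], 1), d[2] - 1)
  k0 <- pmin(pmax(k0[ok], 1), d[3] - 1)
  tx <- fx[ok] - i0; ty <- fy[ok] - j0; tz <- fz[ok] - k0
  idx <- function(i, j, k) i + d[1] * (j - 1) + d[1] * d[2] * (k - 1)
  v000 <- a[idx(i0, j0, k0)];     v100 <- a[idx(i0 + 1, j0, k0)]
  v010 <- a[idx(i0, j0 + 1, k0)]; v110 <- a[idx(i0 + 1, j0 + 1, k0)]
  v001 <- a[idx(i0, j0, k0 + 1)]; v101 <- a[idx(i0 + 1, j0, k0 + 1)]
  v011 <- a[idx(i0, j0 + 1, k0 + 1)]; v111 <- a[idx(i0 + 1, j0 + 1, k0 + 1)]
  c00 <- v000 * (1 - tx) + v100 * tx
  c10 <- v010 * (1 - tx) + v110 * tx
  c01 <- v001 * (1 - tx) + v101 * tx
  c11 <- v011 * (1 - tx) + v111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  out[ok] <- c0 * (1 - tz) + c1 * tz
  out
}

# Interpolate all 3 velocity components of one cardiac phase at points (mm).
interp_velocity <- function(field, pts, phase) {
  pts <- matrix(pts, ncol = 3)
  sapply(1:3, function(c3) {
    interp_trilinear(field$v[, , , c3, phase, drop = TRUE],
                     field$origin, field$spacing, pts)
  })
}

# Orthonormal completion: for unit vector n return t1, t2 with {t1,t2,n}
# right-handed.
tangent_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- ref - sum(ref * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  # t2 = n x t1 so that t1 x t2 = n (right-handed)
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

vnorm <- function(x) sqrt(sum(x^2))

rownorms <- function(m) sqrt(rowSums(m^2))
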