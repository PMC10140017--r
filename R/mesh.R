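# Triangulated surface container and mesh utilities.

#' Triangulated lumen surface
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param triangles m x 3 integer matrix of 1-based vertex indices with
#'   consistent (outward, counter-clockwise) winding.
#' @return Object of class `vessel_surface`.
#' @export
vessel_surface <- function(vertices, triangles) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  stopifnot(nrow(vertices) >= 3, nrow(triangles) >= 1,
            max(triangles) <= nrow(vertices), min(triangles) >= 1)
  structure(list(vertices = vertices, triangles = triangles),
            class = "vessel_surface")
}

#' @export
print.vessel_surface <- function(x, ...) {
  cat(sprintf("Vessel surface: %d vertices, %d triangles, area %.2f mm^2%s\n",
              nrow(x$vertices), nrow(x$triangles), surface_area(x),
              if (is_watertight(x)) ", watertight" else " (open)"))
  invisible(x)
}

# m x 3 matrix of triangle centroids
triangle_centroids <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
     v[tr[, 3], , drop = FALSE]) / 3
}

# per-triangle (non-normalised) normals = cross(e1, e2) / area doubled
triangle_cross <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

triangle_areas <- function(surface) rownorms(triangle_cross(surface)) / 2

#' Total surface area, mm^2
#' @param surface a [vessel_surface].
#' @export
surface_area <- function(surface) sum(triangle_areas(surface))

#' Enclosed volume by the divergence theorem, mm^3
#'
#' Requires a closed surface with outward winding; the signed tetrahedron
#' sum is returned as-is (negative volume indicates inward winding).
#' @param surface a [vessel_surface].
#' @export
enclosed_volume <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
        a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
        a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

# edge table: each row (i, j, triangle); i < j for keying
mesh_edges <- function(surface) {
  tr <- surface$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  data.frame(i = pmin(e[, 1], e[, 2]), j = pmax(e[, 1], e[, 2]),
             tri = rep(seq_len(nrow(tr)), 3))
}

#' Is the mesh watertight (every edge shared by exactly two triangles)?
#' @param surface a [vessel_surface].
#' @export
is_watertight <- function(surface) {
  e <- mesh_edges(surface)
  cnt <- table(paste(e$i, e$j))
  all(cnt == 2)
}

# boundary edges (appearing in exactly one triangle) as a 2-column matrix
boundary_edges <- function(surface) {
  e <- mesh_edges(surface)
  key <- paste(e$i, e$j)
  cnt <- table(key)
  bk <- names(cnt)[cnt == 1]
  e <- e[key %in% bk, c("i", "j")]
  as.matrix(e)
}

# order boundary vertices into cycles by walking the edge adjacency;
# returns the vertex ids of the longest loop
order_boundary_loop <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(integer(0))
  verts <- sort(unique(as.vector(edges)))
  nbrs <- lapply(verts, function(v) {
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
  })
  names(nbrs) <- as.character(verts)
  visited <- setNames(rep(FALSE, length(verts)), as.character(verts))
  best <- integer(0)
  for (s in verts) {
    if (visited[as.character(s)]) next
    loop <- integer(0)
    cur <- s; prev <- NA_integer_
    repeat {
      loop <- c(loop, cur)
      visited[as.character(cur)] <- TRUE
      nb <- nbrs[[as.character(cur)]]
      nxt <- nb[is.na(prev) | nb != prev][1]
      if (is.na(nxt) || nxt == s) break
      prev <- cur; cur <- nxt
      if (length(loop) > length(verts)) break
    }
    if (length(loop) > length(best)) best <- loop
  }
  best
}

# connected components of triangles (shared-edge adjacency);
# returns integer membership per triangle
triangle_components <- function(surface) {
  n_tri <- nrow(surface$triangles)
  e <- mesh_edges(surface)
  key <- paste(e$i, e$j)
  sp <- split(e$tri, key)
  sp <- sp[lengths(sp) >= 2]
  if (!length(sp)) return(seq_len(n_tri))
  pairs <- do.call(rbind, lapply(sp, function(t3) t(utils::combn(t3, 2))))
  g <- igraph::make_graph(edges = as.vector(t(pairs)), n = n_tri,
                          directed = FALSE)
  igraph::components(g)$membership
}

# sub-mesh from a logical/integer triangle selection (vertices re-indexed)
submesh <- function(surface, tri_keep) {
  tr <- surface$triangles[tri_keep, , drop = FALSE]
  used <- sort(unique(as.vector(tr)))
  remap <- integer(nrow(surface$vertices))
  remap[used] <- seq_along(used)
  out <- vessel_surface(surface$vertices[used, , drop = FALSE],
                        matrix(remap[tr], ncol = 3))
  attr(out, "parent_vertex_index") <- used
  out
}

#' Point-in-surface test by ray casting
#'
#' Counts crossings of an axis-parallel ray (+z) against every triangle;
#' an odd count means inside. The surface must be watertight.
#'
#' @param surface a [vessel_surface] (closed).
#' @param pts n x 3 matrix of query points, mm.
#' @param check_watertight verify closedness first (default TRUE).
#' @return logical vector.
#' @export
points_in_surface <- function(surface, pts, check_watertight = TRUE) {
  if (check_watertight && !is_watertight(surface)) {
    stop("surface is not watertight; point containment is undefined",
         call. = FALSE)
  }
  pts <- matrix(pts, ncol = 3)
  v <- surface$vertices; tr <- surface$triangles
  # nudge rays off lattice-aligned mesh edges so each crossing is counted
  # once (changes containment only within ~1e-7 mm of an edge)
  scale <- max(1, max(abs(v)))
  pts <- cbind(pts[, 1] + 1.234e-7 * scale, pts[, 2] + 2.345e-7 * scale,
               pts[, 3])
  cross_cnt <- integer(nrow(pts))
  for (t3 in seq_len(nrow(tr))) {
    a <- v[tr[t3, 1], ]; b <- v[tr[t3, 2], ]; c3 <- v[tr[t3, 3], ]
    xmin <- min(a[1], b[1], c3[1]); xmax <- max(a[1], b[1], c3[1])
    ymin <- min(a[2], b[2], c3[2]); ymax <- max(a[2], b[2], c3[2])
    cand <- which(pts[, 1] >= xmin & pts[, 1] <= xmax &
                    pts[, 2] >= ymin & pts[, 2] <= ymax)
    if (!length(cand)) next
    px <- pts[cand, 1]; py <- pts[cand, 2]
    # 2D barycentric in xy
    d <- (b[2] - c3[2]) * (a[1] - c3[1]) + (c3[1] - b[1]) * (a[2] - c3[2])
    if (abs(d) < 1e-14) next  # triangle vertical in z: ray parallel
    w1 <- ((b[2] - c3[2]) * (px - c3[1]) + (c3[1] - b[1]) * (py - c3[2])) / d
    w2 <- ((c3[2] - a[2]) * (px - c3[1]) + (a[1] - c3[1]) * (py - c3[2])) / d
    w3 <- 1 - w1 - w2
    # half-open rule avoids double counting on shared edges
    hit <- w1 > 0 & w2 >= 0 & w3 >= 0 & w2 < 1 & w3 < 1 & w1 <= 1
    if (!any(hit)) next
    zc <- w1[hit] * a[3] + w2[hit] * b[3] + w3[hit] * c3[3]
    above <- zc > pts[cand[hit], 3]
    cross_cnt[cand[hit][above]] <- cross_cnt[cand[hit][above]] + 1L
  }
  cross_cnt %% 2L == 1L
}

#' Taubin low-pass mesh smoothing
#'
#' Alternating umbrella-Laplacian passes with positive (`lambda_pass`) and
#' negative (`mu_pass`) step sizes; the negative pass counteracts the
#' shrinkage of plain Laplacian smoothing. Topology is unchanged.
#'
#' @param surface a [vessel_surface] (manifold).
#' @param n_iterations number of lambda/mu pass pairs (default 10).
#' @param lambda_pass positive step (default 0.5).
#' @param mu_pass negative step (default -0.53), `|mu| > lambda`.
#' @return smoothed [vessel_surface].
#' @export
taubin_smooth <- function(surface, n_iterations = 10, lambda_pass = 0.5,
                          mu_pass = -0.53) {
  e <- mesh_edges(surface)
  cnt <- table(paste(e$i, e$j))
  if (any(cnt > 2)) stop("non-manifold mesh (edge shared by >2 triangles)",
                         call. = FALSE)
  if (n_iterations == 0) return(surface)
  n <- nrow(surface$vertices)
  adj <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i), x = 1,
                              dims = c(n, n), use.last.ij = TRUE)
  deg <- Matrix::rowSums(adj)
  deg[deg == 0] <- 1
  avg <- adj / deg
  v <- surface$vertices
  for (it in seq_len(n_iterations)) {
    v <- v + lambda_pass * (as.matrix(avg %*% v) - v)
    v <- v + mu_pass * (as.matrix(avg %*% v) - v)
  }
  vessel_surface(v, surface$triangles)
}

#' Intersect a surface with a plane
#'
#' Returns the intersection polyline(s) chained into closed loops; the
#' largest loop is returned as an ordered point matrix.
#'
#' @param surface a [vessel_surface].
#' @param point point on the plane, mm.
#' @param normal plane normal (normalised internally).
#' @return n x 3 matrix of ordered loop points, or `NULL` if no
#'   intersection.
#' @export
surface_plane_section <- function(surface, point, normal) {
  normal <- normal / vnorm(normal)
  v <- surface$vertices
  d <- as.vector((v - matrix(point, nrow(v), 3, byrow = TRUE)) %*% normal)
  tr <- surface$triangles
  segs <- list()
  for (t3 in seq_len(nrow(tr))) {
    di <- d[tr[t3, ]]
    if (all(di > 0) || all(di < 0)) next
    pts <- list()
    idx <- tr[t3, ]
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- di[e[1]]; d2 <- di[e[2]]
      if ((d1 > 0) != (d2 > 0)) {
        t_ <- d1 / (d1 - d2)
        pts[[length(pts) + 1]] <- v[idx[e[1]], ] + t_ * (v[idx[e[2]], ] - v[idx[e[1]], ])
      }
    }
    if (length(pts) == 2) segs[[length(segs) + 1]] <- do.call(rbind, pts)
  }
  if (!length(segs)) return(NULL)
  # chain segments into loops by matching endpoints
  starts <- t(sapply(segs, function(s) s[1, ]))
  ends <- t(sapply(segs, function(s) s[2, ]))
  n_seg <- length(segs)
  used <- logical(n_seg)
  tol <- 1e-6 * max(1, max(abs(rbind(starts, ends))))
  loops <- list()
  for (s0 in seq_len(n_seg)) {
    if (used[s0]) next
    loop <- rbind(segs[[s0]][1, ], segs[[s0]][2, ])
    used[s0] <- TRUE
    repeat {
      tail_pt <- loop[nrow(loop), ]
      ds <- rowSums((starts - matrix(tail_pt, n_seg, 3, byrow = TRUE))^2)
      de <- rowSums((ends - matrix(tail_pt, n_seg, 3, byrow = TRUE))^2)
      ds[used] <- Inf; de[used] <- Inf
      if (min(ds) < tol^2) {
        k <- which.min(ds); loop <- rbind(loop, segs[[k]][2, ]); used[k] <- TRUE
      } else if (min(de) < tol^2) {
        k <- which.min(de); loop <- rbind(loop, segs[[k]][1, ]); used[k] <- TRUE
      } else break
    }
    loops[[length(loops) + 1]] <- loop
  }
  sizes <- sapply(loops, nrow)
  loop <- loops[[which.max(sizes)]]
  # drop duplicated closing point if present
  if (nrow(loop) > 1 && vnorm(loop[1, ] - loop[nrow(loop), ]) < tol) {
    loop <- loop[-nrow(loop), , drop = FALSE]
  }
  loop
}
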