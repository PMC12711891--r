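# Incremental 3-D convex hull with outward facet planes, plus point membership
# and ray clipping against the resulting half-space intersection. Written here
# because collision shapes need facet planes and an entry-distance query; the
# hull is triangulated (no coplanar-facet merging), which is sufficient for
# both queries.

#' Convex hull of a 3D point set
#'
#' Incremental hull construction: build an initial tetrahedron from extreme
#' points, then insert remaining points one at a time, replacing the facets
#' they see with a cone of new facets over the horizon edges. Facet normals
#' point outward (checked against an interior point), so the hull is also
#' available as the half-space intersection `n . x <= offset`.
#'
#' @param points N x 3 matrix.
#' @return object of class `convex_hull_3d`: list with `faces` (F x 3 indices
#'   into `points`), `normals` (F x 3 outward unit normals), `offsets`
#'   (length F), `vertices` (indices of hull vertices), `interior` (an interior
#'   point) and `degenerate` (TRUE when fewer than 4 non-coplanar points
#'   exist; all other fields NULL then).
#' @export
convex_hull_3d <- function(points) {
  points <- as.matrix(points)
  degenerate <- function() structure(list(faces = NULL, normals = NULL,
                                          offsets = NULL, vertices = NULL,
                                          interior = NULL, degenerate = TRUE),
                                     class = "convex_hull_3d")
  if (nrow(points) < 4) return(degenerate())
  diam <- max(apply(points, 2, function(x) diff(range(x))))
  if (diam < 1e-12) return(degenerate())
  eps <- 1e-9 * diam

  # initial tetrahedron from extreme points
  i1 <- order(points[, 1], points[, 2], points[, 3])[1]
  d1 <- rowSums(sweep(points, 2, points[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < eps^2) return(degenerate())
  ab <- points[i2, ] - points[i1, ]
  rel <- sweep(points, 2, points[i1, ])
  tpar <- (rel %*% ab) / sum(ab^2)
  dline2 <- rowSums((rel - outer(as.numeric(tpar), ab))^2)
  i3 <- which.max(dline2)
  if (dline2[i3] < eps^2) return(degenerate())
  n0 <- cross3(ab, points[i3, ] - points[i1, ])
  n0 <- n0 / vnorm(n0)
  dplane <- abs(as.numeric(rel %*% n0))
  i4 <- which.max(dplane)
  if (dplane[i4] < eps) return(degenerate())

  centroid <- colMeans(points[c(i1, i2, i3, i4), ])
  face_plane <- function(f) {
    a <- points[f[1], ]; n <- cross3(points[f[2], ] - a, points[f[3], ] - a)
    nn <- vnorm(n)
    if (nn < 1e-18) return(NULL)
    n <- n / nn
    off <- sum(n * a)
    if (sum(n * centroid) > off) { n <- -n; off <- -off; f <- f[c(1, 3, 2)] }
    list(f = f, n = n, off = off)
  }
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  planes <- lapply(faces, face_plane)
  faces <- lapply(planes, `[[`, "f")
  normals <- do.call(rbind, lapply(planes, `[[`, "n"))
  offsets <- vapply(planes, `[[`, 0, "off")

  remaining <- setdiff(seq_len(nrow(points)), c(i1, i2, i3, i4))
  for (p in remaining) {
    pt <- points[p, ]
    vis <- as.numeric(normals %*% pt) - offsets > eps
    if (!any(vis)) next
    # horizon: directed edges of visible faces whose twin is not visible
    edges <- do.call(rbind, lapply(faces[vis], function(f)
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])))
    keys <- paste(edges[, 1], edges[, 2])
    rev_keys <- paste(edges[, 2], edges[, 1])
    boundary <- edges[!(keys %in% rev_keys), , drop = FALSE]
    faces <- faces[!vis]
    normals <- normals[!vis, , drop = FALSE]
    offsets <- offsets[!vis]
    for (k in seq_len(nrow(boundary))) {
      pl <- face_plane(c(boundary[k, ], p))
      if (is.null(pl)) next
      faces[[length(faces) + 1]] <- pl$f
      normals <- rbind(normals, pl$n)
      offsets <- c(offsets, pl$off)
    }
  }
  fmat <- do.call(rbind, faces)
  structure(list(faces = fmat, normals = normals, offsets = offsets,
                 vertices = sort(unique(as.integer(fmat))), interior = centroid,
                 degenerate = FALSE),
            class = "convex_hull_3d")
}

#' Test points for membership in a convex hull
#' @param hull a `convex_hull_3d`.
#' @param pts 3-vector or N x 3 matrix.
#' @param tol boundary tolerance (m), points within `tol` outside still count.
#' @return logical vector.
#' @export
point_in_hull <- function(hull, pts, tol = 1e-9) {
  if (isTRUE(hull$degenerate)) stop("degenerate hull has no interior")
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  slack <- pts %*% t(hull$normals) - rep(hull$offsets, each = nrow(pts))
  apply(slack <= tol, 1, all)
}

# Clip the ray origin + t * dir (t in R) against the hull's half-spaces.
# Returns c(t_enter, t_exit) of the intersection with the full line, or NULL
# if the line misses the hull. dir need not be unit length; t is in units of
# |dir|.
ray_hull_interval <- function(hull, origin, dir, tol = 1e-12) {
  if (isTRUE(hull$degenerate)) return(NULL)
  denom <- as.numeric(hull$normals %*% dir)
  num <- hull$offsets - as.numeric(hull$normals %*% origin)
  t0 <- -Inf; t1 <- Inf
  par <- abs(denom) < tol
  if (any(par & num < -tol)) return(NULL)   # parallel and outside
  lo <- denom < -tol; hi <- denom > tol
  if (any(lo)) t0 <- max(num[lo] / denom[lo])
  if (any(hi)) t1 <- min(num[hi] / denom[hi])
  if (t0 > t1 + tol) return(NULL)
  c(t0, t1)
}

#' Hull volume (divergence theorem over triangular facets)
#' @param hull a `convex_hull_3d`.
#' @param points the point matrix the hull was built from.
#' @return volume in cubic input units.
#' @export
hull_volume <- function(hull, points) {
  if (isTRUE(hull$degenerate)) return(0)
  v <- 0
  for (i in seq_len(nrow(hull$faces))) {
    f <- hull$faces[i, ]
    a <- points[f[1], ]; b <- points[f[2], ]; c <- points[f[3], ]
    v <- v + sum(a * cross3(b, c)) / 6
  }
  abs(v)
}
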