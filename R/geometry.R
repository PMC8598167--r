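# 3-D Delaunay tetrahedralization (Bowyer-Watson) with alpha filtering.
# Used for fiber volumes: the alpha-shape volume of nucleosome centers, with
# alpha = Inf reducing to the convex hull. Input is jittered by a tiny
# deterministic amount before triangulation to break cospherical ties
# (regular lattices, cube corners); the volume error this introduces is
# O(1e-8) relative.

delaunay3d <- function(pts) {
  n <- nrow(pts)
  stopifnot(ncol(pts) == 3, n >= 4)
  ctr <- colMeans(pts)
  sc <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
  if (sc == 0) stop("degenerate point set: all points coincide")
  if (qr(sweep(pts, 2, ctr))$rank < 3)
    stop("degenerate (coplanar) point set")
  # deterministic jitter, fixed internal stream
  rng <- local_rng(973L)
  pts <- pts + matrix(rng$unif(3L * n, -1, 1), n, 3) * (1e-8 * sc)

  big <- 100 * sc
  sup <- rbind(ctr + c(0, 0, 3 * big),
               ctr + c(-2 * big, -big, -big),
               ctr + c(2 * big, -big, -big),
               ctr + c(0, 2 * big, -big))
  P <- rbind(sup, pts)                       # points 1:4 are the super-tetra
  tet <- matrix(c(1L, 2L, 3L, 4L), 1, 4)
  circ <- circumsphere(P, tet)

  for (ip in 5L:(n + 4L)) {
    p <- P[ip, ]
    dx <- circ$cx - p[1]; dy <- circ$cy - p[2]; dz <- circ$cz - p[3]
    bad <- which(dx * dx + dy * dy + dz * dz < circ$r2)
    if (length(bad) == 0) stop("triangulation failure (no containing sphere)")
    # boundary faces: faces of bad tetras appearing exactly once
    faces <- matrix(0L, length(bad) * 4L, 3L)
    k <- 0L
    for (t in bad) {
      v <- tet[t, ]
      faces[k + 1L, ] <- sort(v[-1]); faces[k + 2L, ] <- sort(v[-2])
      faces[k + 3L, ] <- sort(v[-3]); faces[k + 4L, ] <- sort(v[-4])
      k <- k + 4L
    }
    key <- paste(faces[, 1], faces[, 2], faces[, 3])
    once <- faces[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tet <- tet[-bad, , drop = FALSE]
    circ <- lapply(circ, function(v) v[-bad])
    newt <- cbind(once, ip)
    newc <- circumsphere(P, newt)
    tet <- rbind(tet, newt)
    circ <- Map(c, circ, newc)
  }
  keep <- rowSums(matrix(tet %in% 1:4, nrow(tet), 4)) == 0
  tet <- tet[keep, , drop = FALSE] - 4L
  list(points = pts, tetrahedra = tet)
}

# circumcenters and squared radii for a set of tetrahedra (rows of idx)
circumsphere <- function(P, idx) {
  m <- nrow(idx)
  cx <- cy <- cz <- r2 <- numeric(m)
  for (t in seq_len(m)) {
    v <- P[idx[t, ], , drop = FALSE]
    A <- 2 * sweep(v[2:4, , drop = FALSE], 2, v[1, ])
    b <- rowSums(v[2:4, , drop = FALSE]^2) - sum(v[1, ]^2)
    cc <- tryCatch(solve(A, b), error = function(e) rep(NA_real_, 3))
    if (anyNA(cc)) { # flat tetra: infinite circumsphere, never retained
      cx[t] <- cy[t] <- cz[t] <- 0; r2[t] <- Inf
    } else {
      cx[t] <- cc[1]; cy[t] <- cc[2]; cz[t] <- cc[3]
      r2[t] <- sum((cc - v[1, ])^2)
    }
  }
  list(cx = cx, cy = cy, cz = cz, r2 = r2)
}

tetra_volumes <- function(pts, tet) {
  apply(tet, 1, function(v) {
    a <- pts[v[2], ] - pts[v[1], ]
    b <- pts[v[3], ] - pts[v[1], ]
    c <- pts[v[4], ] - pts[v[1], ]
    abs(det(cbind(a, b, c))) / 6
  })
}

#' Alpha-shape volume of a 3-D point cloud
#'
#' Tetrahedralizes the points (Delaunay) and sums the volumes of tetrahedra
#' whose circumradius is at most `alpha`. `alpha = Inf` keeps every
#' tetrahedron and returns the convex-hull volume; smaller alpha carves a
#' tighter, possibly non-convex envelope. The volume is non-decreasing in
#' `alpha`.
#'
#' @param pts Numeric matrix (n x 3), n >= 4, not all coplanar.
#' @param alpha Alpha radius (same units as the coordinates); default `Inf`.
#' @return Volume (scalar, units cubed).
#' @export
alpha_shape_volume <- function(pts, alpha = Inf) {
  dt <- delaunay3d(pts)
  if (nrow(dt$tetrahedra) == 0) return(0)
  r <- sqrt(circumsphere(dt$points, dt$tetrahedra)$r2)
  keep <- r <= alpha
  if (!any(keep)) return(0)
  sum(tetra_volumes(dt$points, dt$tetrahedra[keep, , drop = FALSE]))
}

#' Density-based clustering of points (DBSCAN)
#'
#' Classic density-based clustering on Euclidean distances: a point with at
#' least `min_neighbors` other points within `eps` is a core point; clusters
#' are the connected components of core points at distance <= eps, plus any
#' non-core point within `eps` of a core point (assigned to the cluster of
#' its nearest core neighbor); everything else is noise (label 0).
#'
#' @param pts Numeric matrix (n x d) of coordinates.
#' @param eps Neighborhood radius.
#' @param min_neighbors Minimum number of neighbors (excluding the point
#'   itself) for a core point.
#' @return Integer vector of cluster labels (0 = noise), labels numbered in
#'   order of first appearance.
#' @export
dbscan_labels <- function(pts, eps, min_neighbors) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(pts))
  nb <- d <= eps & !diag(TRUE, n)
  core <- rowSums(nb) >= min_neighbors
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        reach <- which(nb[f, ] & labels == 0L)
        for (r in reach) {
          labels[r] <- cl
          if (core[r]) nxt <- c(nxt, r)
        }
      }
      frontier <- nxt
    }
  }
  # border points were labelled during expansion from whichever core reached
  # them first; re-assign to the nearest core neighbor for determinism
  border <- which(!core & labels != 0L)
  for (b in border) {
    cn <- which(nb[b, ] & core)
    labels[b] <- labels[cn[which.min(d[b, cn])]]
  }
  labels
}
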