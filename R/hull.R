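#' Volume of the 3-D convex hull of a point cloud
#'
#' Randomised-order incremental convex hull: starting from an extreme
#' tetrahedron, each point outside the current hull replaces its visible
#' faces with a fan to the horizon; the volume is accumulated from the
#' final outward-oriented faces. Duplicate points are removed and the
#' input is put into general position by a deterministic joggle of
#' relative magnitude ~1e-9 (the standard defence against sliver facets
#' on structured inputs such as smooth trajectories), so reported
#' volumes are exact to ~1e-8 relative.
#'
#' Point sets with fewer than 4 distinct points, or collinear/coplanar
#' within tolerance, have zero volume.
#'
#' @param points Numeric `n x 3` matrix (mm).
#' @param tol Relative degeneracy tolerance.
#' @return Hull volume in mm^3 (0 for degenerate input).
#' @export
convex_hull_volume <- function(points, tol = 1e-12) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  P <- P[stats::complete.cases(P), , drop = FALSE]
  P <- unique(P)
  n <- nrow(P)
  if (n < 4L) return(0)
  scale <- max(apply(P, 2, function(v) diff(range(v))))
  if (!is.finite(scale) || scale == 0) return(0)

  # deterministic joggle into general position (local RNG, caller's
  # stream untouched)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(881650123L)
  jog <- 1e-9 * scale
  Pj <- P + matrix(stats::runif(3 * n, -jog, jog), n, 3)
  perm <- sample.int(n)

  eps <- max(tol, 1e-12) * scale  # visibility tolerance (signed distance)

  cross3 <- function(u, v) {
    c(u[2] * v[3] - u[3] * v[2],
      u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
  }

  # initial simplex from the unjoggled cloud: extremes along x, then
  # farthest from the line, then from the plane
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  u <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2, P[i1, ])
  cr <- cbind(rel[, 2] * u[3] - rel[, 3] * u[2],
              rel[, 3] * u[1] - rel[, 1] * u[3],
              rel[, 1] * u[2] - rel[, 2] * u[1])
  dline <- rowSums(cr^2)
  i3 <- which.max(dline)
  if (sqrt(dline[i3]) <= 1e-9 * scale * sqrt(sum(u^2))) return(0)  # collinear
  nrm <- cross3(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  dplane <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(dplane)
  if (dplane[i4] <= 1e-9 * scale) return(0)  # coplanar

  centre <- colMeans(Pj[c(i1, i2, i3, i4), ])
  # unit outward normal + offset for a face given as vertex indices
  orient <- function(f) {
    a <- Pj[f[1], ]
    nn <- cross3(Pj[f[2], ] - a, Pj[f[3], ] - a)
    len <- sqrt(sum(nn^2))
    if (len == 0) return(c(0, 0, 0, 0))
    nn <- nn / len
    d <- sum(nn * a)
    if (sum(nn * centre) > d) { nn <- -nn; d <- -d }
    c(nn, d)
  }
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  nd <- t(apply(faces, 1, orient))

  for (ip in perm) {
    if (ip %in% c(i1, i2, i3, i4)) next
    p <- Pj[ip, ]
    excess <- nd[, 1:3, drop = FALSE] %*% p - nd[, 4]
    vis <- which(excess > eps)
    if (length(vis) == 0L) next
    vf <- faces[vis, , drop = FALSE]
    e1 <- pmin(vf[, 1], vf[, 2]); e2 <- pmax(vf[, 1], vf[, 2])
    f1 <- pmin(vf[, 2], vf[, 3]); f2 <- pmax(vf[, 2], vf[, 3])
    g1 <- pmin(vf[, 3], vf[, 1]); g2 <- pmax(vf[, 3], vf[, 1])
    lo <- c(e1, f1, g1); hi <- c(e2, f2, g2)
    key <- lo * (n + 1) + hi
    once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
    faces <- faces[-vis, , drop = FALSE]
    nd <- nd[-vis, , drop = FALSE]
    if (!any(once)) next
    newf <- cbind(lo[once], hi[once], ip)
    newnd <- t(apply(newf, 1, orient))
    ok <- newnd[, 1] != 0 | newnd[, 2] != 0 | newnd[, 3] != 0
    faces <- rbind(faces, newf[ok, , drop = FALSE])
    nd <- rbind(nd, newnd[ok, , drop = FALSE])
  }

  # V = sum over outward unit-normal faces of area * height / 3; with
  # unit normals this is sum of (d - n.c) * area / 3, area from the
  # vertex triangles
  areas <- vapply(seq_len(nrow(faces)), function(i) {
    a <- Pj[faces[i, 1], ]
    nn <- cross3(Pj[faces[i, 2], ] - a, Pj[faces[i, 3], ] - a)
    sqrt(sum(nn^2)) / 2
  }, numeric(1))
  heights <- nd[, 4] - nd[, 1:3, drop = FALSE] %*% centre
  max(sum(areas * heights) / 3, 0)
}
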