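#' Derive a child seed from a base seed
#'
#' Deterministic integer hash used everywhere the package needs several
#' independent random streams (restart attempts, per-subject scanpaths) from
#' one user-supplied seed. The result is always in `[1, 2^31 - 2]` so it is a
#' valid R integer seed.
#'
#' @param base_seed Integer base seed.
#' @param ... Further non-negative integers (e.g. state count, attempt index)
#'   mixed into the hash; order matters.
#' @return A single integer seed.
#' @export
derive_seed <- function(base_seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  mix <- c(104729, 1299709, 15485863, 32452843, 49979687)
  s <- (abs(as.numeric(base_seed)) * 7919) %% m
  extra <- c(...)
  for (i in seq_along(extra)) {
    k <- mix[((i - 1L) %% length(mix)) + 1L]
    s <- (s * 31 + abs(as.numeric(extra[i])) * k + 17) %% m
  }
  as.integer(s %% (m - 2)) + 1L
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Classifies points against a polygon using the even-odd (ray crossing)
#' rule. Points that lie exactly on a polygon edge or vertex count as inside,
#' which keeps the classification of fixations landing on an AOI border
#' deterministic and conservative for small AOIs.
#'
#' @param x,y Numeric vectors of point coordinates (pixels).
#' @param polygon Two-column numeric matrix of polygon vertices, in order;
#'   the polygon is closed implicitly.
#' @return Logical vector, `TRUE` where the point is inside or on the
#'   boundary.
#' @export
point_in_polygon <- function(x, y, polygon) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2, nrow(polygon) >= 3)
  px <- polygon[, 1]
  py <- polygon[, 2]
  n <- nrow(polygon)
  jj <- c(n, seq_len(n - 1L)) # previous vertex index
  eps <- 1e-9
  vapply(seq_along(x), function(k) {
    xp <- x[k]
    yp <- y[k]
    inside <- FALSE
    for (i in seq_len(n)) {
      j <- jj[i]
      x1 <- px[j]; y1 <- py[j]; x2 <- px[i]; y2 <- py[i]
      # on-segment check
      cross <- (x2 - x1) * (yp - y1) - (y2 - y1) * (xp - x1)
      if (abs(cross) < eps &&
          xp >= min(x1, x2) - eps && xp <= max(x1, x2) + eps &&
          yp >= min(y1, y2) - eps && yp <= max(y1, y2) + eps) {
        return(TRUE)
      }
      if ((y1 > yp) != (y2 > yp)) {
        xint <- x1 + (yp - y1) / (y2 - y1) * (x2 - x1)
        if (xp < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

# Strict-interior variant used for the AOI disjointness check: boundary
# contact alone (shared edge/vertex) does not count as overlapping area.
point_strictly_inside <- function(x, y, polygon) {
  px <- polygon[, 1]
  py <- polygon[, 2]
  n <- nrow(polygon)
  jj <- c(n, seq_len(n - 1L))
  eps <- 1e-9
  vapply(seq_along(x), function(k) {
    xp <- x[k]
    yp <- y[k]
    inside <- FALSE
    for (i in seq_len(n)) {
      j <- jj[i]
      x1 <- px[j]; y1 <- py[j]; x2 <- px[i]; y2 <- py[i]
      cross <- (x2 - x1) * (yp - y1) - (y2 - y1) * (xp - x1)
      if (abs(cross) < eps &&
          xp >= min(x1, x2) - eps && xp <= max(x1, x2) + eps &&
          yp >= min(y1, y2) - eps && yp <= max(y1, y2) + eps) {
        return(FALSE)
      }
      if ((y1 > yp) != (y2 > yp)) {
        xint <- x1 + (yp - y1) / (y2 - y1) * (x2 - x1)
        if (xp < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

polygon_area <- function(polygon) {
  x <- polygon[, 1]
  y <- polygon[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Proper segment intersection (excluding mere endpoint touching).
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1)
  d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1)
  d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# TRUE when two polygons share interior area (vertex strictly inside the
# other, or edges properly crossing).
polygons_overlap <- function(a, b) {
  # vertices, edge midpoints and centroid: aligned rectangles sharing area
  # can touch only at endpoints, which edge-crossing tests alone miss
  probe <- function(p) {
    rbind(p, (p + p[c(2:nrow(p), 1), ]) / 2, colMeans(p))
  }
  pa <- probe(a)
  pb <- probe(b)
  if (any(point_strictly_inside(pa[, 1], pa[, 2], b))) return(TRUE)
  if (any(point_strictly_inside(pb[, 1], pb[, 2], a))) return(TRUE)
  na <- nrow(a)
  nb <- nrow(b)
  for (i in seq_len(na)) {
    p1 <- a[i, ]
    p2 <- a[if (i == na) 1L else i + 1L, ]
    for (j in seq_len(nb)) {
      q1 <- b[j, ]
      q2 <- b[if (j == nb) 1L else j + 1L, ]
      if (segments_cross(p1, p2, q1, q2)) return(TRUE)
    }
  }
  FALSE
}

`%||%` <- function(x, y) if (is.null(x)) y else x
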