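# Low-level planar geometry on polylines and simple polygons.
# Conventions (asserted by round-trip tests): coordinates in mm, image y-axis
# pointing downward, polylines ordered lateral -> medial along increasing x.

#' Signed area of a simple polygon (shoelace formula)
#'
#' @param xy two-column numeric matrix of vertices, not necessarily closed.
#' @return Signed area; positive for counter-clockwise orientation in a
#'   conventional y-up frame (sign is irrelevant to callers, which take
#'   absolute values).
#' @keywords internal
polygon_area_signed <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Arc length of a polyline
#' @param xy two-column numeric matrix of ordered vertices.
#' @keywords internal
polyline_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  d <- diff(xy)
  sum(sqrt(rowSums(d^2)))
}

#' Clip a polygon to a half-plane x <= c or x >= c (Sutherland-Hodgman)
#'
#' Vertices are inserted exactly at the bound abscissa so that areas of
#' complementary clips sum to the original area to floating tolerance.
#'
#' @param xy polygon vertex matrix (open ring).
#' @param bound abscissa of the vertical clipping line.
#' @param keep "left" keeps x <= bound, "right" keeps x >= bound.
#' @keywords internal
clip_polygon_x <- function(xy, bound, keep = c("left", "right")) {
  keep <- match.arg(keep)
  n <- nrow(xy)
  if (n == 0L) return(xy)
  is_in <- if (keep == "left") xy[, 1L] <= bound else xy[, 1L] >= bound
  out <- matrix(NA_real_, 2L * n, 2L)
  m <- 0L
  prev <- xy[n, ]; prev_in <- is_in[n]
  for (i in seq_len(n)) {
    cur <- xy[i, ]; cur_in <- is_in[i]
    if (cur_in) {
      if (!prev_in) { m <- m + 1L; out[m, ] <- intersect_x(prev, cur, bound) }
      m <- m + 1L; out[m, ] <- cur
    } else if (prev_in) {
      m <- m + 1L; out[m, ] <- intersect_x(prev, cur, bound)
    }
    prev <- cur; prev_in <- cur_in
  }
  out[seq_len(m), , drop = FALSE]
}

# Intersection of segment p1-p2 with the vertical line x = bound.
intersect_x <- function(p1, p2, bound) {
  dx <- p2[1L] - p1[1L]
  t <- if (dx == 0) 0 else (bound - p1[1L]) / dx
  c(bound, p1[2L] + t * (p2[2L] - p1[2L]))
}

#' Clip a polygon to a vertical slab x in [lo, hi]
#' @keywords internal
clip_polygon_slab <- function(xy, lo, hi) {
  clip_polygon_x(clip_polygon_x(xy, lo, "right"), hi, "left")
}

#' Clip a polyline to a vertical slab, interpolating at the bounds
#'
#' Returns a list of polyline pieces (the polyline may leave and re-enter the
#' slab if it is not x-monotone).
#' @keywords internal
clip_polyline_slab <- function(xy, lo, hi) {
  n <- nrow(xy)
  pieces <- list()
  buf <- matrix(NA_real_, 2L * n, 2L)
  m <- 0L
  flush_piece <- function() {
    if (m >= 2L) pieces[[length(pieces) + 1L]] <<- buf[seq_len(m), , drop = FALSE]
    m <<- 0L
  }
  for (i in seq_len(n - 1L)) {
    seg <- clip_segment_slab(xy[i, ], xy[i + 1L, ], lo, hi)
    if (is.null(seg)) { flush_piece(); next }
    if (m == 0L) {
      m <- 1L; buf[1L, ] <- seg[1L, ]
    } else if (any(abs(buf[m, ] - seg[1L, ]) > 1e-12)) {
      flush_piece()
      m <- 1L; buf[1L, ] <- seg[1L, ]
    }
    m <- m + 1L; buf[m, ] <- seg[2L, ]
  }
  flush_piece()
  pieces
}

# Clip one segment to the slab [lo, hi] in x; NULL if fully outside.
clip_segment_slab <- function(p1, p2, lo, hi) {
  x1 <- p1[1L]; x2 <- p2[1L]
  if (max(x1, x2) < lo || min(x1, x2) > hi) return(NULL)
  t0 <- 0; t1 <- 1
  dx <- x2 - x1
  if (dx != 0) {
    ta <- (lo - x1) / dx; tb <- (hi - x1) / dx
    t0 <- max(0, min(ta, tb)); t1 <- min(1, max(ta, tb))
    if (t0 > t1) return(NULL)
  } else if (x1 < lo || x1 > hi) {
    return(NULL)
  }
  a <- p1 + t0 * (p2 - p1)
  b <- p1 + t1 * (p2 - p1)
  rbind(a, b)
}

#' Test whether a polyline is simple (no self-intersection)
#'
#' Polylines that are strictly monotone in x are function graphs and hence
#' simple; that fast path covers every boundary produced by the phantom
#' generator and the mask tracer. Otherwise each segment is tested against
#' all non-adjacent segments with a vectorised orientation test.
#' @keywords internal
is_simple_polyline <- function(xy) {
  n <- nrow(xy) - 1L
  if (n < 2L) return(TRUE)
  dx <- diff(xy[, 1L])
  if (all(dx > 0) || all(dx < 0)) return(TRUE)
  x1 <- xy[-nrow(xy), 1L]; y1 <- xy[-nrow(xy), 2L]
  x2 <- xy[-1L, 1L]; y2 <- xy[-1L, 2L]
  orient <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    o1 <- orient(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
    o2 <- orient(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
    o3 <- orient(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])
    o4 <- orient(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i])
    hit <- (o1 != o2 & o3 != o4) & !(o1 == 0 & o2 == 0)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Point-in-polygon test for a matrix of query points
#'
#' Even-odd rule; used when rasterising phantoms.
#' @param px,py query coordinates (equal-length vectors).
#' @param xy polygon vertex matrix.
#' @keywords internal
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1L]; yi <- xy[i, 2L]
    xj <- xy[j, 1L]; yj <- xy[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
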