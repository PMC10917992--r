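# Internal geometry and interpolation helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_glimap <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_glimap("'%s' must be a single positive number", name)
  invisible(x)
}

# Run expr with a temporary RNG state seeded by `seed`; restores global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Cumulative arc length of an n x 2 polyline (first column x, second y).
polyline_arclength <- function(pts) {
  d <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(d))
}

# Point on polyline at arc length s (vectorized over s), linear along segments.
polyline_point_at <- function(pts, s) {
  al <- polyline_arclength(pts)
  L <- al[length(al)]
  s <- pmin(pmax(s, 0), L)
  seg <- findInterval(s, al, rightmost.closed = TRUE)
  seg <- pmin(seg, nrow(pts) - 1L)
  t <- (s - al[seg]) / pmax(al[seg + 1L] - al[seg], .Machine$double.eps)
  pts[seg, , drop = FALSE] + (pts[seg + 1L, , drop = FALSE] - pts[seg, , drop = FALSE]) * t
}

# Minimum distance from each point (m x 2) to a polyline, plus the nearest
# point on the polyline. Vectorized over points, looped over segments.
polyline_distance <- function(pts, poly) {
  m <- nrow(pts)
  best <- rep(Inf, m)
  bx <- numeric(m); by <- numeric(m)
  for (k in seq_len(nrow(poly) - 1L)) {
    a <- poly[k, ]; b <- poly[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]
    py <- a[2] + t * ab[2]
    d <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
    upd <- d < best
    best[upd] <- d[upd]; bx[upd] <- px[upd]; by[upd] <- py[upd]
  }
  list(distance = best, nearest = cbind(bx, by))
}

# Do open polylines A and B properly cross (transversal interior
# intersection)? Vectorized all-pairs orientation test; touching without
# crossing is not flagged. Used for traverse non-crossing checks.
polylines_cross <- function(A, B) {
  a1 <- A[-nrow(A), , drop = FALSE]; a2 <- A[-1, , drop = FALSE]
  b1 <- B[-nrow(B), , drop = FALSE]; b2 <- B[-1, , drop = FALSE]
  d1x <- a2[, 1] - a1[, 1]; d1y <- a2[, 2] - a1[, 2]
  d2x <- b2[, 1] - b1[, 1]; d2y <- b2[, 2] - b1[, 2]
  # orientation of B endpoints relative to each A segment (m1 x m2)
  base1 <- d1x * a1[, 2] - d1y * a1[, 1]
  o1 <- outer(d1x, b1[, 2]) - outer(d1y, b1[, 1]) - base1
  o2 <- outer(d1x, b2[, 2]) - outer(d1y, b2[, 1]) - base1
  base2 <- d2x * b1[, 2] - d2y * b1[, 1]
  o3 <- t(outer(d2x, a1[, 2]) - outer(d2y, a1[, 1]) - base2)
  o4 <- t(outer(d2x, a2[, 2]) - outer(d2y, a2[, 1]) - base2)
  any(o1 * o2 < 0 & o3 * o4 < 0)
}

# Bilinear interpolation of matrix `z` (rows = y, cols = x) whose node (r, c)
# sits at x = (c-1)*step + x0, y = (r-1)*step + y0. NA nodes propagate NA.
bilinear <- function(z, x, y, x0 = 0, y0 = 0, step = 1) {
  gx <- (x - x0) / step + 1
  gy <- (y - y0) / step + 1
  nr <- nrow(z); nc <- ncol(z)
  gx <- pmin(pmax(gx, 1), nc)
  gy <- pmin(pmax(gy, 1), nr)
  c0 <- pmin(floor(gx), nc - 1L); r0 <- pmin(floor(gy), nr - 1L)
  fx <- gx - c0; fy <- gy - r0
  z00 <- z[cbind(r0, c0)]; z01 <- z[cbind(r0, c0 + 1L)]
  z10 <- z[cbind(r0 + 1L, c0)]; z11 <- z[cbind(r0 + 1L, c0 + 1L)]
  (1 - fy) * ((1 - fx) * z00 + fx * z01) + fy * ((1 - fx) * z10 + fx * z11)
}
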