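#' Outer/inner contour pair bounding a cortical ribbon
#'
#' The outer polyline follows the layer I/II boundary, the inner polyline the
#' layer VI/white-matter boundary. Both run in the same direction along the
#' ribbon; the band is closed laterally by the two straight edges joining
#' corresponding polyline ends.
#'
#' @param outer,inner n x 2 matrices of (x, y) coordinates in um.
#' @return an object of class `contour_pair`.
#' @export
contour_pair <- function(outer, inner) {
  outer <- as.matrix(outer); inner <- as.matrix(inner)
  if (ncol(outer) != 2L || ncol(inner) != 2L || nrow(outer) < 2L || nrow(inner) < 2L)
    stop_glimap("contours must be n x 2 polylines with n >= 2")
  d <- polyline_distance(outer, inner)$distance
  if (min(d) <= 0)
    stop_glimap("degenerate geometry: inner contour touches outer contour")
  structure(list(outer = outer, inner = inner), class = "contour_pair")
}

#' @export
print.contour_pair <- function(x, ...) {
  cat(sprintf("Contour pair: outer %d pts (L = %.0f um), inner %d pts (L = %.0f um)\n",
              nrow(x$outer), max(polyline_arclength(x$outer)),
              nrow(x$inner), max(polyline_arclength(x$inner))))
  invisible(x)
}

# Band polygon (outer, then inner reversed) with an edge label per segment.
band_polygon <- function(cp) {
  P <- rbind(cp$outer, cp$inner[rev(seq_len(nrow(cp$inner))), , drop = FALSE])
  no <- nrow(cp$outer); ni <- nrow(cp$inner)
  labels <- c(rep("outer", no - 1L), "lateral", rep("inner", ni - 1L), "lateral")
  list(points = P, labels = labels)
}

#' Solve the cortical Laplace field between two contours
#'
#' Computes the harmonic function that is 0 on the outer contour and 1 on
#' the inner contour, with reflecting (zero-flux) lateral edges — the
#' electric-field model whose equipotentials follow the cortical layers and
#' whose gradient streamlines define the traverses. Discretized on a regular
#' grid with Shortley-Weller shortened arms where grid links cross a
#' contour, and solved directly as a sparse linear system.
#'
#' @param contours a [contour_pair()].
#' @param grid_spacing grid step in um.
#' @return an object of class `laplace_field`: `field` (matrix, NA outside
#'   the band; nodes within half a grid step of a contour carry its boundary
#'   value), grid geometry (`x0`, `y0`, `spacing`), the contours, and the
#'   maximum linear-system residual.
#' @export
solve_laplace <- function(contours, grid_spacing = 1) {
  stopifnot(inherits(contours, "contour_pair"))
  assert_scalar_pos(grid_spacing, "grid_spacing")
  h <- grid_spacing
  bp <- band_polygon(contours)
  P <- bp$points
  xr <- range(P[, 1]); yr <- range(P[, 2])
  xs <- seq(xr[1] - h, xr[2] + h, by = h)
  ys <- seq(yr[1] - h, yr[2] + h, by = h)
  nc <- length(xs); nr <- length(ys)
  gx <- rep(xs, each = nr); gy <- rep(ys, times = nc)   # column-major over (row=y, col=x)
  inside <- matrix(mgcv::in.out(rbind(P, P[1, ]), cbind(gx, gy)), nr, nc)

  if (!any(inside))
    stop_glimap("no grid nodes fall inside the band; decrease grid_spacing")
  id <- matrix(0L, nr, nc)
  id[inside] <- seq_len(sum(inside))
  n_unk <- sum(inside)

  # distances used for boundary decoration and intersection fallbacks
  pts_all <- cbind(gx, gy)
  d_out <- matrix(polyline_distance(pts_all, contours$outer)$distance, nr, nc)
  d_in  <- matrix(polyline_distance(pts_all, contours$inner)$distance, nr, nc)

  edges <- list(ax = P[, 1], ay = P[, 2],
                bx = c(P[-1, 1], P[1, 1]), by = c(P[-1, 2], P[1, 2]),
                label = bp$labels)

  # Accumulators for the sparse system A u = b (A[k,k] > 0, off-diagonal <= 0)
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  diag_acc <- numeric(n_unk)
  b <- numeric(n_unk)

  dirs <- list(c(0L, -1L), c(0L, 1L), c(-1L, 0L), c(1L, 0L))  # (drow, dcol): W, E, N, S
  # arm description per direction: theta (fraction of h), type 0=unknown,
  # 1=dirichlet (value), 2=neumann
  arm <- vector("list", 4L)
  unk_rc <- which(inside, arr.ind = TRUE)
  for (d in 1:4) {
    dr <- dirs[[d]][1]; dc <- dirs[[d]][2]
    r2 <- unk_rc[, 1] + dr; c2 <- unk_rc[, 2] + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nbr_id <- integer(n_unk)
    nbr_id[ok] <- id[cbind(r2[ok], c2[ok])]
    theta <- rep(1, n_unk); typ <- integer(n_unk); val <- numeric(n_unk)
    crossing <- which(nbr_id == 0L)
    if (length(crossing)) {
      px <- xs[unk_rc[crossing, 2]]; py <- ys[unk_rc[crossing, 1]]
      hit <- ray_boundary_hits(px, py, dc * h, dr * h, edges)
      # fallback for rays that miss every edge (node exactly on a boundary,
      # or grazing discretization cases): nearest boundary feature decides
      miss <- is.na(hit$t)
      if (any(miss)) {
        rc <- cbind(unk_rc[crossing[miss], 1], unk_rc[crossing[miss], 2])
        io <- d_out[rc]
        ii <- d_in[rc]
        lat <- band_lateral_edges(contours)
        il <- polyline_distance(cbind(px[miss], py[miss]), lat$a)$distance
        il <- pmin(il, polyline_distance(cbind(px[miss], py[miss]), lat$b)$distance)
        # Dirichlet labels win exact ties (band corners sit on both a contour
        # and a lateral edge; the boundary value must be imposed there)
        lab <- c("outer", "inner", "lateral")[max.col(-cbind(io, ii, il),
                                                      ties.method = "first")]
        hit$t[miss] <- pmin(io, ii, il) / h   # node-to-boundary distance in steps
        hit$label[miss] <- lab
      }
      theta[crossing] <- pmin(pmax(hit$t, 0.05), 1)
      typ[crossing] <- ifelse(hit$label == "lateral", 2L, 1L)
      val[crossing] <- ifelse(hit$label == "inner", 1, 0)
    }
    arm[[d]] <- list(theta = theta, typ = typ, val = val, nbr = nbr_id)
  }

  add_dimension <- function(a1, a2) {
    # Shortley-Weller 3-point second derivative along one dimension.
    both_neu <- a1$typ == 2L & a2$typ == 2L
    for (pair in list(list(a1, a2), list(a2, a1))) {
      me <- pair[[1]]; other <- pair[[2]]
      # coefficient of `me` arm's node
      coef <- ifelse(other$typ == 2L,
                     2 / (me$theta * (1 + me$theta) * h^2),   # mirror on other side
                     2 / (me$theta * (me$theta + other$theta) * h^2))
      coef[me$typ == 2L | both_neu] <- 0
      diag_acc <<- diag_acc + coef
      is_unk <- me$typ == 0L & coef > 0
      if (any(is_unk)) {
        ti <<- c(ti, which(is_unk)); tj <<- c(tj, me$nbr[is_unk])
        tv <<- c(tv, -coef[is_unk])
      }
      is_dir <- me$typ == 1L & coef > 0
      if (any(is_dir)) b[is_dir] <<- b[is_dir] + coef[is_dir] * me$val[is_dir]
    }
  }
  add_dimension(arm[[1]], arm[[2]])   # x (west/east)
  add_dimension(arm[[3]], arm[[4]])   # y (north/south)

  A <- Matrix::sparseMatrix(i = c(seq_len(n_unk), ti), j = c(seq_len(n_unk), tj),
                            x = c(diag_acc, tv), dims = c(n_unk, n_unk))
  u <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e) stop_glimap("Laplace solve failed: %s", conditionMessage(e)))
  resid <- max(abs(as.numeric(A %*% u - b)))

  field <- matrix(NA_real_, nr, nc)
  field[inside] <- u
  # decorate near-contour nodes with their boundary values
  deco_out <- !inside & d_out <= 0.5 * h
  deco_in <- !inside & d_in <= 0.5 * h
  field[deco_out] <- 0
  field[deco_in] <- 1

  structure(list(field = field, inside = inside,
                 x0 = xs[1], y0 = ys[1], spacing = h,
                 contours = contours, residual = resid,
                 d_outer = d_out, d_inner = d_in),
            class = "laplace_field")
}

# The two straight segments closing the band laterally.
band_lateral_edges <- function(cp) {
  no <- nrow(cp$outer); ni <- nrow(cp$inner)
  list(a = rbind(cp$outer[no, ], cp$inner[ni, ]),
       b = rbind(cp$inner[1, ], cp$outer[1, ]))
}

# First boundary-edge hit of rays (px,py) + t*(dx,dy), t in (0, 1].
# Returns t (fraction of the step) and the label of the nearest edge hit.
ray_boundary_hits <- function(px, py, dx, dy, edges, chunk = 2048L) {
  m <- length(px)
  best_t <- rep(NA_real_, m)
  best_lab <- rep(NA_character_, m)
  sx <- edges$bx - edges$ax; sy <- edges$by - edges$ay
  for (start in seq(1L, m, by = chunk)) {
    ii <- start:min(start + chunk - 1L, m)
    qx <- outer(edges$ax, px[ii], `-`)   # e x n: a - p
    qy <- outer(edges$ay, py[ii], `-`)
    denom <- dx * sy - dy * sx           # length e
    tmat <- (qx * sy - qy * sx) / denom  # param along ray
    umat <- (qx * dy - qy * dx) / denom  # param along edge
    valid <- is.finite(tmat) & tmat > 1e-9 & tmat <= 1 + 1e-9 &
      umat >= -1e-9 & umat <= 1 + 1e-9
    tmat[!valid] <- Inf
    mins <- apply(tmat, 2, which.min)
    tv <- tmat[cbind(mins, seq_along(ii))]
    hit <- is.finite(tv)
    best_t[ii[hit]] <- pmin(tv[hit], 1)
    best_lab[ii[hit]] <- edges$label[mins[hit]]
  }
  list(t = best_t, label = best_lab)
}

#' @export
print.laplace_field <- function(x, ...) {
  cat(sprintf("Laplace field: %d x %d grid (%g um spacing), %d band nodes, residual %.2e\n",
              nrow(x$field), ncol(x$field), x$spacing, sum(x$inside), x$residual))
  invisible(x)
}
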