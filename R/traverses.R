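#' Trace equidistant cortical traverses through a Laplace field
#'
#' Seeds `n_traverses` points at equidistant arc-length positions along the
#' outer contour (at fractions (i - 1/2)/n, avoiding the lateral edges) and
#' integrates gradient-ascent streamlines of the harmonic field from the
#' outer contour (field 0) to the inner contour (field 1). Streamlines of a
#' harmonic field cannot cross; a traverse that leaves the band laterally is
#' flagged and excluded.
#'
#' @param field a [solve_laplace()] result.
#' @param n_traverses number of traverses.
#' @param step_frac integration step as a fraction of the grid spacing.
#' @param stop_level field level at which the streamline is joined to the
#'   inner contour by projection.
#' @return an object of class `traverse_set`: a list of traverses, each
#'   `list(points = <m x 2 um polyline>, index, ok)`.
#' @export
trace_traverses <- function(field, n_traverses, step_frac = 0.25,
                            stop_level = 0.985) {
  stopifnot(inherits(field, "laplace_field"))
  if (n_traverses < 1) stop_glimap("n_traverses must be >= 1")
  h <- field$spacing
  f <- field$field
  # fill boundary-adjacent NAs with contour values so interpolation near the
  # contours stays defined
  fill <- f
  fill[is.na(f) & field$d_outer <= 1.2 * h] <- 0
  fill[is.na(f) & field$d_inner <= 1.2 * h] <- 1
  grad <- field_gradient(fill, h)

  outer <- field$contours$outer
  inner <- field$contours$inner
  L <- max(polyline_arclength(outer))
  seeds <- polyline_point_at(outer, ((seq_len(n_traverses) - 0.5) / n_traverses) * L)
  step <- step_frac * h
  max_steps <- ceiling(6 * (nrow(f) + ncol(f)) / step_frac)

  traverses <- vector("list", n_traverses)
  for (i in seq_len(n_traverses)) {
    p <- seeds[i, ]
    pts <- matrix(p, 1L, 2L)
    ok <- TRUE
    for (s in seq_len(max_steps)) {
      val <- bilinear(fill, p[1], p[2], field$x0, field$y0, h)
      if (is.na(val)) { ok <- FALSE; break }
      if (val >= stop_level) break
      d1 <- grad_dir(grad, p, field)
      if (is.null(d1)) { ok <- FALSE; break }
      pm <- p + 0.5 * step * d1                      # midpoint (RK2)
      d2 <- grad_dir(grad, pm, field)
      if (is.null(d2)) d2 <- d1
      p <- p + step * d2
      pts <- rbind(pts, p)
      if (s == max_steps) ok <- FALSE
    }
    if (ok) {
      # close onto the inner contour
      prj <- polyline_distance(matrix(p, 1L, 2L), inner)
      pts <- rbind(pts, prj$nearest[1, ])
    }
    traverses[[i]] <- list(points = unname(pts), index = i, ok = ok)
  }
  structure(traverses, class = "traverse_set",
            excluded = which(!vapply(traverses, `[[`, TRUE, "ok")))
}

# central/one-sided finite-difference gradient of a matrix field (NA-aware)
field_gradient <- function(f, h) {
  nr <- nrow(f); nc <- ncol(f)
  gx <- matrix(NA_real_, nr, nc); gy <- gx
  fW <- cbind(NA, f[, -nc]); fE <- cbind(f[, -1], NA)
  fN <- rbind(NA, f[-nr, ]); fS <- rbind(f[-1, ], NA)
  gx <- (fE - fW) / (2 * h)
  one <- is.na(gx); gx[one] <- ((fE - f) / h)[one]
  one <- is.na(gx); gx[one] <- ((f - fW) / h)[one]
  gy <- (fS - fN) / (2 * h)
  one <- is.na(gy); gy[one] <- ((fS - f) / h)[one]
  one <- is.na(gy); gy[one] <- ((f - fN) / h)[one]
  list(gx = gx, gy = gy)
}

grad_dir <- function(grad, p, field) {
  gx <- bilinear(grad$gx, p[1], p[2], field$x0, field$y0, field$spacing)
  gy <- bilinear(grad$gy, p[1], p[2], field$x0, field$y0, field$spacing)
  if (is.na(gx) || is.na(gy)) return(NULL)
  nrm <- sqrt(gx^2 + gy^2)
  if (nrm < 1e-12) return(NULL)
  c(gx, gy) / nrm
}

#' @export
print.traverse_set <- function(x, ...) {
  exc <- attr(x, "excluded")
  cat(sprintf("Traverse set: %d traverse(s), %d excluded\n", length(x), length(exc)))
  invisible(x)
}

#' Sample a GLI image along a traverse
#'
#' Bilinear interpolation of the GLI image at equal arc-length steps along
#' the traverse polyline, from the outer to the inner contour.
#'
#' @param gli a [gli_image()] / [compute_gli()] result.
#' @param traverse one element of a [trace_traverses()] result (or any
#'   `list(points = <m x 2>)`).
#' @param step sampling step in um (default: half the GLI field step).
#' @return a `raw_profile`: `list(values, arclen)`.
#' @export
extract_profile <- function(gli, traverse, step = NULL) {
  stopifnot(inherits(gli, "gli_image"))
  pts <- traverse$points
  if (is.null(pts) || nrow(pts) < 2L) stop_glimap("traverse needs at least 2 points")
  step <- step %||% (gli$step / 2)
  # domain check: field centers plus one measuring field of slack (contours
  # can outreach the last complete field by a fraction of a field; sampling
  # there clamps to the nearest field)
  pad <- gli$field_size
  xr <- gli$origin[1] + c(0, (ncol(gli$values) - 1) * gli$step) + c(-pad, pad)
  yr <- gli$origin[2] + c(0, (nrow(gli$values) - 1) * gli$step) + c(-pad, pad)
  if (any(pts[, 1] < xr[1] | pts[, 1] > xr[2] | pts[, 2] < yr[1] | pts[, 2] > yr[2]))
    stop_glimap("traverse extends outside the GLI image domain")
  L <- max(polyline_arclength(pts))
  if (L <= 0) stop_glimap("zero-length traverse")
  s <- seq(0, L, by = step)
  if (s[length(s)] < L) s <- c(s, L)
  sp <- polyline_point_at(pts, s)
  v <- bilinear(gli$values, sp[, 1], sp[, 2], gli$origin[1], gli$origin[2], gli$step)
  structure(list(values = v, arclen = s), class = "raw_profile")
}

#' Extract and depth-normalize profiles for all traverses of a section
#'
#' @param gli a `gli_image`.
#' @param traverses a [trace_traverses()] result; excluded traverses are
#'   skipped.
#' @param D depth points for normalization.
#' @param section_id section identifier.
#' @param step sampling step in um passed to [extract_profile()].
#' @return a [gli_profiles()] with one row per usable traverse.
#' @export
profiles_from_image <- function(gli, traverses, D = 101L, section_id = 1L,
                                step = NULL) {
  keep <- Filter(function(t) isTRUE(t$ok), traverses)
  if (!length(keep)) stop_glimap("no usable traverses")
  ps <- lapply(keep, function(t)
    normalize_profile(extract_profile(gli, t, step = step), D = D,
                      section_id = section_id, traverse_index = t$index))
  bind_profiles(ps)
}
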