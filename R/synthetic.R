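#' Specification of a synthetic cortical ribbon
#'
#' A ribbon is a band of cortex between an outer (layer I/II) and an inner
#' (layer VI/white matter) contour, partitioned along its length into areas,
#' each with its own laminar architecture. Two geometries are supported:
#' a flat rectangle and an annulus sector (a curved gyral crown for which the
#' Laplace field has a radial closed form).
#'
#' @param areas list of areas, each `list(extent = <um along the outer
#'   contour>, model = <laminar_model>)`, in order along the ribbon.
#' @param geometry `list(type = "rectangle", thickness = <um>)` or
#'   `list(type = "annulus_sector", r_outer = <um>, r_inner = <um>)`.
#'   For the annulus sector the cortical thickness is `r_outer - r_inner` and
#'   the angular extent is `total extent / r_outer`.
#' @param noise_sd standard deviation of additive Gaussian noise applied to
#'   GLI profiles in the fast sampling path ([sample_profiles()]).
#' @param resolution image resolution in um/pixel for [render_ribbon()].
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return an object of class `ribbon_spec`.
#' @export
ribbon_spec <- function(areas,
                        geometry = list(type = "rectangle", thickness = 2500),
                        noise_sd = 0.05, resolution = 1, seed = 1L) {
  if (!length(areas)) stop_glimap("at least one area is required")
  for (a in areas) {
    if (!is.list(a) || is.null(a$extent) || !inherits(a$model, "laminar_model"))
      stop_glimap("each area must be list(extent=, model=<laminar_model>)")
    assert_scalar_pos(a$extent, "area extent")
  }
  assert_scalar_pos(resolution, "resolution")
  if (noise_sd < 0) stop_glimap("noise_sd must be nonnegative")
  geometry$type <- match.arg(geometry$type, c("rectangle", "annulus_sector"))
  if (geometry$type == "rectangle") {
    assert_scalar_pos(geometry$thickness, "thickness")
  } else {
    assert_scalar_pos(geometry$r_outer, "r_outer")
    assert_scalar_pos(geometry$r_inner, "r_inner")
    if (geometry$r_inner >= geometry$r_outer)
      stop_glimap("annulus sector requires r_inner < r_outer (inner contour inside)")
    total <- sum(vapply(areas, `[[`, 0, "extent"))
    if (total / geometry$r_outer >= 2 * pi)
      stop_glimap("annulus sector angular extent must be below 2*pi")
  }
  structure(list(areas = areas, geometry = geometry, noise_sd = noise_sd,
                 resolution = resolution, seed = as.integer(seed)),
            class = "ribbon_spec")
}

# Cumulative arc-length border positions (um along outer contour), excluding
# the ribbon ends.
ribbon_border_arclen <- function(spec) {
  ext <- vapply(spec$areas, `[[`, 0, "extent")
  head(cumsum(ext), -1L)
}

#' Ground truth accessors for synthetic ribbons
#'
#' `area_labels_from_borders()` expands border positions into a per-traverse
#' label vector; `border_positions_from_labels()` inverts it. The two
#' round-trip exactly. A border at position `p` separates traverse `p` from
#' traverse `p + 1`.
#'
#' @param borders strictly increasing integer border positions.
#' @param n total number of traverses.
#' @param labels per-traverse area labels (piecewise constant).
#' @return labels, resp. border positions.
#' @export
area_labels_from_borders <- function(borders, n) {
  if (is.unsorted(borders, strictly = TRUE)) stop_glimap("borders must be strictly increasing")
  rep(seq_len(length(borders) + 1L), diff(c(0L, as.integer(borders), n)))
}

#' @rdname area_labels_from_borders
#' @export
border_positions_from_labels <- function(labels) {
  which(diff(as.integer(factor(labels, levels = unique(labels)))) != 0L)
}

#' Map arc-length border positions to traverse-index units
#'
#' Traverse seeds sit at arc lengths `(i - 0.5) / n * L`; a border at arc
#' length `a` falls between traverses `floor(a / L * n + 0.5)` and the next.
#'
#' @param truth a `ribbon_truth` from [render_ribbon()].
#' @param n_traverses number of traverses spanning the ribbon.
#' @return integer border positions in traverse-index units.
#' @export
border_traverse_positions <- function(truth, n_traverses) {
  L <- truth$outer_length
  pmin(pmax(floor(truth$border_arclen / L * n_traverses + 0.5), 1L), n_traverses - 1L)
}

#' Render a synthetic cortical ribbon as a binary cell-body image
#'
#' Somata are disks of the model's radius whose centers follow an
#' inhomogeneous Poisson process: within each (area, layer) region the
#' intensity is that layer's cell density. A pixel is foreground when its
#' center lies within a soma disk, so the expected coverage of a layer is
#' exactly the Boolean-model value \eqn{1 - exp(-\lambda\pi r^2)}.
#'
#' @param spec a [ribbon_spec()].
#' @return `list(mask = <cell_mask>, truth = <ribbon_truth>)`; the truth
#'   carries the outer/inner contour polylines (um, image coordinates with
#'   pixel centers at integer multiples of the resolution) and exact border
#'   arc-length positions.
#' @export
render_ribbon <- function(spec) {
  stopifnot(inherits(spec, "ribbon_spec"))
  with_seed(spec$seed, {
    if (spec$geometry$type == "rectangle") render_rectangle(spec)
    else render_annulus(spec)
  })
}

render_rectangle <- function(spec) {
  res <- spec$resolution
  ext <- vapply(spec$areas, `[[`, 0, "extent")
  W <- sum(ext); H <- spec$geometry$thickness
  nc <- floor(W / res) + 1L; nr <- floor(H / res) + 1L
  img <- matrix(0L, nr, nc)
  x0 <- c(0, cumsum(ext))
  for (i in seq_along(spec$areas)) {
    m <- spec$areas[[i]]$model
    ycut <- c(0, cumsum(m$layer_fractions)) * H
    for (l in 1:6) {
      lam <- m$layer_intensities[l]
      area_um2 <- ext[i] * (ycut[l + 1] - ycut[l])
      n <- rpois(1L, lam * area_um2)
      if (n == 0) next
      cx <- runif(n, x0[i], x0[i + 1])
      cy <- runif(n, ycut[l], ycut[l + 1])
      img <- stamp_disks(img, cx, cy, m$soma_radius, res)
    }
  }
  truth <- structure(list(border_arclen = ribbon_border_arclen(spec),
                          outer = cbind(x = c(0, W), y = c(0, 0)),
                          inner = cbind(x = c(0, W), y = c(H, H)),
                          outer_length = W,
                          area_ids = seq_along(spec$areas)),
                     class = "ribbon_truth")
  list(mask = cell_mask(img, res), truth = truth)
}

render_annulus <- function(spec) {
  res <- spec$resolution
  g <- spec$geometry
  ext <- vapply(spec$areas, `[[`, 0, "extent")
  L <- sum(ext)
  dtheta <- L / g$r_outer
  th0 <- pi / 2 - dtheta / 2            # sector centered on the vertical axis
  th <- th0 + c(0, cumsum(ext)) / g$r_outer
  # place the sector in positive image coordinates with a small margin
  margin <- max(vapply(spec$areas, function(a) a$model$soma_radius, 0)) + 2 * res
  thg <- seq(th0, th0 + dtheta, length.out = 256)
  allx <- c(g$r_outer * cos(thg), g$r_inner * cos(thg))
  ally <- c(g$r_outer * sin(thg), g$r_inner * sin(thg))
  cx0 <- margin - min(allx); cy0 <- margin - min(ally)
  nc <- floor((max(allx) - min(allx) + 2 * margin) / res) + 1L
  nr <- floor((max(ally) - min(ally) + 2 * margin) / res) + 1L
  img <- matrix(0L, nr, nc)
  thick <- g$r_outer - g$r_inner
  for (i in seq_along(spec$areas)) {
    m <- spec$areas[[i]]$model
    rcut <- g$r_outer - c(0, cumsum(m$layer_fractions)) * thick  # outer -> inner
    for (l in 1:6) {
      lam <- m$layer_intensities[l]
      r1 <- rcut[l + 1]; r2 <- rcut[l]   # r1 < r2
      area_um2 <- 0.5 * (r2^2 - r1^2) * (th[i + 1] - th[i])
      n <- rpois(1L, lam * area_um2)
      if (n == 0) next
      rr <- sqrt(runif(n, r1^2, r2^2))   # uniform over the annular region
      tt <- runif(n, th[i], th[i + 1])
      img <- stamp_disks(img, cx0 + rr * cos(tt), cy0 + rr * sin(tt),
                         m$soma_radius, res)
    }
  }
  arc <- seq(0, 1, length.out = 512)
  outer <- cbind(x = cx0 + g$r_outer * cos(th0 + arc * dtheta),
                 y = cy0 + g$r_outer * sin(th0 + arc * dtheta))
  inner <- cbind(x = cx0 + g$r_inner * cos(th0 + arc * dtheta),
                 y = cy0 + g$r_inner * sin(th0 + arc * dtheta))
  truth <- structure(list(border_arclen = ribbon_border_arclen(spec),
                          outer = outer, inner = inner,
                          outer_length = L,
                          center = c(cx0, cy0),
                          r_outer = g$r_outer, r_inner = g$r_inner,
                          area_ids = seq_along(spec$areas)),
                     class = "ribbon_truth")
  list(mask = cell_mask(img, res), truth = truth)
}

# Set pixels whose centers lie within `radius` of any (cx, cy) to 1.
# Pixel (r, c) center is at ((c-1)*res, (r-1)*res).
stamp_disks <- function(img, cx, cy, radius, res) {
  nr <- nrow(img); nc <- ncol(img)
  r2 <- radius^2
  for (k in seq_along(cx)) {
    c_lo <- max(1L, ceiling((cx[k] - radius) / res) + 1L)
    c_hi <- min(nc, floor((cx[k] + radius) / res) + 1L)
    r_lo <- max(1L, ceiling((cy[k] - radius) / res) + 1L)
    r_hi <- min(nr, floor((cy[k] + radius) / res) + 1L)
    if (c_lo > c_hi || r_lo > r_hi) next
    dx2 <- ((c_lo:c_hi - 1) * res - cx[k])^2
    dy2 <- ((r_lo:r_hi - 1) * res - cy[k])^2
    img[r_lo:r_hi, c_lo:c_hi][outer(dy2, dx2, `+`) <= r2] <- 1L
  }
  img
}

#' Sample depth-normalized GLI profiles directly from a ribbon spec
#'
#' Fast path that skips rendering: each traverse's profile is the noiseless
#' laminar curve of its area plus i.i.d. Gaussian noise (sd = `noise_sd`),
#' clipped to \[0, 1\], on the standard depth grid. Profiles are ordered by
#' traverse index; area labels switch exactly at the ground-truth borders.
#'
#' @param spec a [ribbon_spec()].
#' @param n_per_area profiles per area (recycled across areas).
#' @param depth_points number of depth points (0-100% inclusive).
#' @param section_id identifier stored with the profiles.
#' @param seed optional override of `spec$seed`.
#' @return `list(profiles = <gli_profiles>, truth = <ribbon_truth>)` with
#'   `truth$border_positions` in traverse-index units and `truth$area_labels`
#'   per traverse.
#' @export
sample_profiles <- function(spec, n_per_area, depth_points = 101L,
                            section_id = 1L, seed = NULL) {
  stopifnot(inherits(spec, "ribbon_spec"))
  if (any(n_per_area < 1)) stop_glimap("n_per_area must be >= 1")
  n_per_area <- rep_len(as.integer(n_per_area), length(spec$areas))
  depth <- seq(0, 100, length.out = depth_points)
  with_seed(seed %||% spec$seed, {
    rows <- lapply(seq_along(spec$areas), function(i) {
      base <- laminar_curve(spec$areas[[i]]$model, depth)
      n <- n_per_area[i]
      v <- matrix(rep(base, each = n), n, depth_points)
      if (spec$noise_sd > 0)
        v <- v + matrix(rnorm(n * depth_points, sd = spec$noise_sd), n, depth_points)
      pmin(pmax(v, 0), 1)
    })
    values <- do.call(rbind, rows)
    borders <- head(cumsum(n_per_area), -1L)
    truth <- structure(list(border_positions = borders,
                            area_labels = area_labels_from_borders(borders, sum(n_per_area)),
                            border_arclen = ribbon_border_arclen(spec),
                            area_ids = seq_along(spec$areas)),
                       class = "ribbon_truth")
    list(profiles = gli_profiles(values, depth, section_id = section_id),
         truth = truth)
  })
}

#' Multi-subject jittered label volumes
#'
#' Emulates the inter-subject variability of area delineations on a shared
#' reference grid: each subject's volume is the base labels pulled back
#' through a smooth random displacement field of the given amplitude
#' (standard deviation in voxels). Labels are preserved (nearest-neighbor
#' resampling); `jitter_sd = 0` reproduces the base exactly.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base_labels a [label_volume()] or 3-D integer array.
#' @param jitter_sd displacement amplitude in voxels (>= 0).
#' @param seed integer seed.
#' @param smooth_iter box-filter passes shaping the deformation smoothness.
#' @return list of [label_volume()] objects.
#' @export
make_label_volumes <- function(n_subjects, base_labels, jitter_sd = 1,
                               seed = 1L, smooth_iter = 4L) {
  if (n_subjects < 1) stop_glimap("n_subjects must be >= 1")
  if (jitter_sd < 0) stop_glimap("jitter_sd must be nonnegative")
  base <- as_label_volume(base_labels)
  dm <- dim(base$voxels)
  idx <- list(slice.index(base$voxels, 1), slice.index(base$voxels, 2),
              slice.index(base$voxels, 3))
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      vox <- base$voxels
      if (jitter_sd > 0) {
        co <- lapply(1:3, function(a) {
          d <- smooth3d(array(rnorm(prod(dm)), dm), smooth_iter)
          sdd <- stats::sd(d)
          if (sdd > 0) d <- d / sdd * jitter_sd
          pmin(pmax(round(idx[[a]] + d), 1), dm[a])
        })
        vox <- array(base$voxels[cbind(c(co[[1]]), c(co[[2]]), c(co[[3]]))], dm)
      }
      label_volume(vox, voxel_mm = base$voxel_mm, affine = base$affine)
    })
  })
}

# Separable 3-voxel box filter applied `iter` times along each axis.
smooth3d <- function(a, iter = 4L) {
  dm <- dim(a)
  shift <- function(x, axis, by) {
    n <- dm[axis]
    i <- pmin(pmax(seq_len(n) + by, 1L), n)
    switch(axis, x[i, , , drop = FALSE], x[, i, , drop = FALSE], x[, , i, drop = FALSE])
  }
  for (k in seq_len(iter)) for (axis in 1:3)
    a <- (shift(a, axis, -1L) + a + shift(a, axis, 1L)) / 3
  a
}
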