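#' Subject-level area label volume on a shared reference grid
#'
#' @param voxels 3-D integer array of area labels (0 = background).
#' @param voxel_mm voxel size in mm (length 3).
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices);
#'   defaults to a diagonal scaling by `voxel_mm`.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(voxels, voxel_mm = c(1, 1, 1), affine = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop_glimap("label volume must be 3-D")
  if (any(voxels != round(voxels)) || any(voxels < 0))
    stop_glimap("labels must be nonnegative integers")
  if (any(voxel_mm <= 0)) stop_glimap("voxel size must be positive")
  affine <- affine %||% diag(c(voxel_mm, 1))
  structure(list(voxels = voxels, voxel_mm = voxel_mm, affine = affine),
            class = "label_volume")
}

as_label_volume <- function(x) {
  if (inherits(x, "label_volume")) x else label_volume(x)
}

check_same_grid <- function(volumes) {
  ref <- volumes[[1]]
  for (v in volumes[-1]) {
    if (!identical(dim(v$voxels), dim(ref$voxels)))
      stop_glimap("label volumes have mismatched shapes")
    if (max(abs(v$affine - ref$affine)) > 1e-9)
      stop_glimap("label volumes have mismatched affines")
  }
  ref
}

#' Per-area probability map across subjects
#'
#' The value at each voxel is the fraction of subjects whose delineation
#' assigns that voxel to the area — a direct measure of inter-subject
#' variability (with `n` subjects all values are exact multiples of `1/n`).
#'
#' @param volumes list of [label_volume()] objects on one grid.
#' @param area_id the area label to map.
#' @return an object of class `probability_map`.
#' @export
probability_map <- function(volumes, area_id) {
  volumes <- lapply(volumes, as_label_volume)
  ref <- check_same_grid(volumes)
  n <- length(volumes)
  counts <- Reduce(`+`, lapply(volumes, function(v) (v$voxels == area_id) * 1L))
  structure(list(voxels = counts / n, counts = counts,
                 area_id = area_id, n_subjects = n,
                 voxel_mm = ref$voxel_mm, affine = ref$affine),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("Probability map of area %s (%d subjects): %d voxels with support, max %.2f\n",
              format(x$area_id), x$n_subjects, sum(x$voxels > 0), max(x$voxels)))
  invisible(x)
}

#' Maximum probability map (MPM)
#'
#' Assigns each voxel to the area with the highest probability among the
#' given maps, producing a continuous, non-overlapping parcellation; voxels
#' where no area has support stay background (0). Exact ties are broken by
#' the higher mean probability in the 26-voxel neighborhood, then by the
#' lower area index — a deterministic rule.
#'
#' @param maps list of [probability_map()] objects on one grid, one per
#'   area (distinct `area_id`s).
#' @param threshold minimum probability for a voxel to be assigned
#'   (default 0: no thresholding; for display parity a 0.1 threshold mirrors
#'   typical atlas color scales).
#' @return list of class `max_probability_map`: `voxels` (label array),
#'   `area_ids`, grid geometry.
#' @export
maximum_probability_map <- function(maps, threshold = 0) {
  ids <- vapply(maps, `[[`, maps[[1]]$area_id, "area_id")
  if (anyDuplicated(ids)) stop_glimap("duplicate area ids across maps")
  ref <- check_same_grid(maps)
  dm <- dim(maps[[1]]$voxels)
  k <- length(maps)
  P <- vapply(maps, `[[`, numeric(prod(dm)), "voxels")   # voxels x areas
  pmax_v <- do.call(pmax, lapply(seq_len(k), function(j) P[, j]))
  arg <- max.col(P, ties.method = "first")
  n_at_max <- rowSums(P == pmax_v)
  lab <- ifelse(pmax_v > threshold, arg, 0L)
  ties <- which(pmax_v > threshold & n_at_max > 1L)
  if (length(ties)) {
    nb_mean <- function(vox, i, j, kk) {
      ii <- max(1, i - 1):min(dm[1], i + 1)
      jj <- max(1, j - 1):min(dm[2], j + 1)
      kz <- max(1, kk - 1):min(dm[3], kk + 1)
      block <- vox[ii, jj, kz]
      (sum(block) - vox[i, j, kk]) / (length(block) - 1)
    }
    idx3 <- arrayInd(ties, dm)
    for (t in seq_along(ties)) {
      v <- ties[t]
      tied <- which(P[v, ] == pmax_v[v])
      nbm <- vapply(tied, function(j)
        nb_mean(maps[[j]]$voxels, idx3[t, 1], idx3[t, 2], idx3[t, 3]), 0)
      best <- tied[nbm == max(nbm)]
      lab[v] <- min(best)          # lower area index as the final tie-break
    }
  }
  out <- array(0L, dm)
  assigned <- lab > 0L
  out[assigned] <- ids[lab[assigned]]
  structure(list(voxels = out, area_ids = ids, threshold = threshold,
                 voxel_mm = ref$voxel_mm, affine = ref$affine),
            class = "max_probability_map")
}

#' Center of gravity of a probability map
#'
#' Probability-weighted mean voxel coordinate, mapped to world (mm)
#' coordinates through the volume's affine.
#'
#' @param map a [probability_map()] (or any object with `voxels` and
#'   `affine`).
#' @return named numeric (x, y, z) in mm.
#' @export
center_of_gravity <- function(map) {
  w <- map$voxels
  tot <- sum(w)
  if (tot <= 0) stop_glimap("probability map has zero mass")
  dm <- dim(w)
  idx <- arrayInd(seq_along(w), dm) - 1   # 0-based voxel indices
  cog_vox <- colSums(idx * as.numeric(w)) / tot
  world <- map$affine %*% c(cog_vox, 1)
  setNames(as.numeric(world[1:3]), c("x", "y", "z"))
}

#' Centers of gravity for a set of probability maps
#'
#' @param maps list of [probability_map()] objects.
#' @param hemisphere optional label stored in the output.
#' @return data.frame: `area`, `hemisphere`, `x`, `y`, `z` (mm).
#' @export
cog_table <- function(maps, hemisphere = NA_character_) {
  rows <- lapply(maps, function(m) {
    cg <- center_of_gravity(m)
    data.frame(area = m$area_id, hemisphere = hemisphere,
               x = cg["x"], y = cg["y"], z = cg["z"], row.names = NULL)
  })
  do.call(rbind, rows)
}
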