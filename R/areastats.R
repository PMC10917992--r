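#' Mean areal GLI profile
#'
#' Pointwise mean over the profiles sampled for one area (typically 15-20
#' profiles in each of three sections per hemisphere), plus the scalar mean
#' GLI used for areal comparisons.
#'
#' @param profiles a [gli_profiles()] (all rows from one area) or a list of
#'   profile sets sharing the depth grid.
#' @return a single-row `gli_profiles`; the scalar mean GLI is in
#'   `attr(, "mean_gli")`.
#' @export
mean_area_profile <- function(profiles) {
  if (is.list(profiles) && !inherits(profiles, "gli_profiles"))
    profiles <- bind_profiles(profiles)
  if (!nrow(profiles$values)) stop_glimap("at least one profile is required")
  m <- colMeans(profiles$values)
  out <- gli_profiles(matrix(m, 1L), profiles$depth,
                      section_id = profiles$section_id)
  attr(out, "mean_gli") <- mean(m)
  out
}

#' Ward hierarchical clustering of mean areal profiles
#'
#' Agglomerative clustering of areas by the Euclidean distance between their
#' mean GLI profiles with Ward's minimum-variance linkage: a large distance
#' indicates a large cytoarchitectonic difference. Merge heights are
#' reported as error-sum-of-squares (ESS) increments, the quantity Ward's
#' criterion minimizes at each step.
#'
#' @param mean_profiles matrix (areas x depth points), or a named list of
#'   single-row [gli_profiles()] / numeric vectors.
#' @param labels area identifiers (must be unique); default rownames/names.
#' @return list of class `area_linkage`: `merge`, `height` (ESS
#'   increments), `labels`, and the underlying [stats::hclust] object
#'   (`hclust`, with Ward d2 heights) for plotting.
#' @export
cluster_areas <- function(mean_profiles, labels = NULL) {
  if (is.list(mean_profiles) && !is.data.frame(mean_profiles)) {
    rows <- lapply(mean_profiles, function(p)
      if (inherits(p, "gli_profiles")) p$values[1, ] else as.numeric(p))
    M <- do.call(rbind, rows)
    labels <- labels %||% names(mean_profiles)
  } else M <- as.matrix(mean_profiles)
  labels <- labels %||% rownames(M) %||% paste0("area", seq_len(nrow(M)))
  if (nrow(M) < 2L) stop_glimap("at least two areas are required")
  if (anyDuplicated(labels)) stop_glimap("duplicate area ids")
  hc <- hclust(dist(M), method = "ward.D2")
  hc$labels <- labels
  structure(list(merge = hc$merge, height = hc$height^2 / 2,
                 labels = labels, hclust = hc),
            class = "area_linkage")
}

#' @export
print.area_linkage <- function(x, ...) {
  cat(sprintf("Ward linkage of %d areas; ESS merge heights:\n", length(x$labels)))
  print(signif(x$height, 4))
  invisible(x)
}

#' Export an area dendrogram as Newick
#'
#' @param linkage an [cluster_areas()] result.
#' @param file path of the Newick file to write.
#' @return the [ape::phylo] tree, invisibly.
#' @export
write_dendrogram_newick <- function(linkage, file) {
  tree <- ape::as.phylo(linkage$hclust)
  ape::write.tree(tree, file = file)
  invisible(tree)
}

#' Canonical discriminant projection of areal feature vectors
#'
#' Projects per-area feature vectors onto the first two canonical axes that
#' maximize the between-area to within-area scatter ratio, for visualizing
#' areal separation (observations plus per-area centroids). The within-class
#' scatter is ridge-regularized when ill-conditioned; axis signs are fixed
#' by making each axis's largest-magnitude loading positive.
#'
#' @param feature_sets named list of numeric matrices (rows = observations,
#'   e.g. profile feature vectors), one per area; >= 3 areas with >= 2
#'   observations each.
#' @param ridge ridge coefficient relative to `mean(diag(Sw))`; `NULL`
#'   (default) applies `1e-8` only when `Sw` is numerically singular; `0`
#'   forbids regularization (singular scatter is then an error).
#' @return list: `scores` (data.frame area/LD1/LD2), `centroids`, `axes`
#'   (loadings), `eigenvalues`.
#' @export
discriminant_projection <- function(feature_sets, ridge = NULL) {
  if (length(feature_sets) < 3L) stop_glimap("at least 3 areas are required")
  if (any(vapply(feature_sets, nrow, 0L) < 2L))
    stop_glimap("every area needs at least 2 observations")
  X <- do.call(rbind, feature_sets)
  grp <- rep(names(feature_sets), vapply(feature_sets, nrow, 0L))
  p <- ncol(X)
  gm <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (g in unique(grp)) {
    Xg <- X[grp == g, , drop = FALSE]
    mg <- colMeans(Xg)
    Sw <- Sw + crossprod(sweep(Xg, 2, mg))
    Sb <- Sb + nrow(Xg) * tcrossprod(mg - gm)
  }
  ew <- eigen(Sw, symmetric = TRUE)
  tol <- max(ew$values) * 1e-10
  if (any(ew$values < tol)) {
    if (!is.null(ridge) && ridge == 0)
      stop_glimap("within-class scatter is singular (smallest eigenvalue %.3g); regularization disabled",
                  min(ew$values))
    lam <- (ridge %||% 1e-8) * mean(diag(Sw))
    ew <- eigen(Sw + diag(lam, p), symmetric = TRUE)
  } else if (!is.null(ridge) && ridge > 0) {
    ew <- eigen(Sw + diag(ridge * mean(diag(Sw)), p), symmetric = TRUE)
  }
  W <- ew$vectors %*% diag(1 / sqrt(ew$values), p)   # whitens Sw
  M <- crossprod(W, Sb) %*% W
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  k <- min(2L, length(unique(grp)) - 1L)
  axes <- W %*% em$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading of each axis is positive
  for (j in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  scores <- X %*% axes
  colnames(scores) <- paste0("LD", seq_len(ncol(scores)))
  cent <- apply(scores, 2, function(z) tapply(z, grp, mean))
  list(scores = data.frame(area = grp, scores, row.names = NULL),
       centroids = cent, axes = axes,
       eigenvalues = em$values[seq_len(k)])
}

#' Volumetric specification of one area in one brain
#'
#' @param s distance between analyzed sections (number of sections).
#' @param T section thickness in mm (20 um sections: 0.02).
#' @param x,y pixel width and height in mm (e.g. 0.02116).
#' @param N_counts per-section labeled pixel counts (nonnegative integers).
#' @param F brain shrinkage correction factor.
#' @return a `volume_spec` list.
#' @export
volume_spec <- function(s, T = 0.02, x = 0.02116, y = x, N_counts, F = 1) {
  for (nm in c("s", "T", "x", "y", "F"))
    assert_scalar_pos(get(nm), nm)
  if (any(N_counts < 0) || any(N_counts != round(N_counts)))
    stop_glimap("N_counts must be nonnegative integers")
  structure(list(s = s, T = T, x = x, y = y,
                 N_counts = as.numeric(N_counts), F = F),
            class = "volume_spec")
}

#' Section-based area volume with shrinkage correction
#'
#' \deqn{V = s \cdot T \cdot x \cdot y \cdot \sum_i N_i \cdot F}
#' where `s` is the section sampling interval, `T` the section thickness
#' (mm), `x`, `y` the pixel dimensions (mm), `N_i` the labeled pixel count
#' of section `i`, and `F` the shrinkage factor of the brain.
#'
#' @param spec a [volume_spec()].
#' @return volume in mm^3.
#' @export
area_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  spec$s * spec$T * spec$x * spec$y * sum(spec$N_counts) * spec$F
}

#' Normalize an area volume by total brain volume
#'
#' @param V area volume (mm^3).
#' @param total_brain_volume total brain volume (mm^3, > 0).
#' @return the volume fraction.
#' @export
normalize_volume <- function(V, total_brain_volume) {
  if (!is.numeric(total_brain_volume) || total_brain_volume <= 0)
    stop_glimap("total brain volume must be positive")
  V / total_brain_volume
}

#' Area volumes from a per-section pixel-count table
#'
#' @param counts data.frame with columns `subject`, `area`, `hemisphere`,
#'   `section`, `pixels`.
#' @param s,T,x,y volume parameters as in [volume_spec()].
#' @param shrinkage named vector of per-subject shrinkage factors F
#'   (default 1).
#' @return data.frame with one row per subject/area/hemisphere and `volume`
#'   in mm^3.
#' @export
volume_table <- function(counts, s, T = 0.02, x = 0.02116, y = x,
                         shrinkage = NULL) {
  need <- c("subject", "area", "hemisphere", "section", "pixels")
  if (!all(need %in% names(counts)))
    stop_glimap("counts must have columns %s", paste(need, collapse = ", "))
  agg <- aggregate(pixels ~ subject + area + hemisphere, counts, sum)
  Fv <- if (is.null(shrinkage)) rep(1, nrow(agg))
        else unname(shrinkage[as.character(agg$subject)])
  if (anyNA(Fv)) stop_glimap("missing shrinkage factor for some subject")
  agg$volume <- s * T * x * y * agg$pixels * Fv
  agg
}
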