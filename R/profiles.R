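#' Depth-normalized GLI profile set
#'
#' Container for one or more laminar GLI profiles on the standard depth grid
#' (0-100% cortical depth, equidistant). Stored as a matrix with one row per
#' traverse, which is the shape every downstream statistic consumes.
#'
#' @param values numeric matrix (traverses x depth points) with entries in
#'   \[0, 1\], or a single profile vector.
#' @param depth depth grid in percent; must span \[0, 100\] equidistantly.
#' @param section_id section identifier.
#' @param traverse_index integer positions of the traverses along the ribbon
#'   (defaults to 1..n).
#' @return an object of class `gli_profiles`.
#' @export
gli_profiles <- function(values, depth = seq(0, 100, length.out = ncol(values)),
                         section_id = 1L, traverse_index = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  if (any(values < -1e-12 | values > 1 + 1e-12))
    stop_glimap("profile values must lie in [0, 1]")
  if (length(depth) != ncol(values))
    stop_glimap("depth grid length (%d) != profile length (%d)",
                length(depth), ncol(values))
  if (abs(depth[1]) > 1e-9 || abs(depth[length(depth)] - 100) > 1e-9 ||
      max(abs(diff(depth) - diff(depth)[1])) > 1e-9)
    stop_glimap("depth grid must be equidistant over [0, 100]")
  structure(list(values = values, depth = depth,
                 section_id = section_id,
                 traverse_index = traverse_index %||% seq_len(nrow(values))),
            class = "gli_profiles")
}

#' @export
print.gli_profiles <- function(x, ...) {
  cat(sprintf("GLI profiles: %d traverse(s) x %d depth points, section %s\n",
              nrow(x$values), ncol(x$values), paste(x$section_id, collapse = ",")))
  invisible(x)
}

#' @export
`[.gli_profiles` <- function(x, i, ...) {
  gli_profiles(x$values[i, , drop = FALSE], x$depth,
               section_id = x$section_id,
               traverse_index = x$traverse_index[i])
}

# coerce matrix-or-profiles to the values matrix
profile_matrix <- function(x) {
  if (inherits(x, "gli_profiles")) x$values
  else if (is.matrix(x)) x
  else matrix(x, nrow = 1L)
}

#' Normalize a raw profile to 100% cortical depth
#'
#' Linearly resamples a profile sampled at arbitrary arc-length positions
#' onto `D` equidistant points covering 0-100% of the traverse length, so
#' cortices of different thickness become comparable. Resampling an already
#' normalized profile is the identity (idempotence).
#'
#' @param raw a `raw_profile` from [extract_profile()], or
#'   `list(values=, arclen=)` with at least two samples.
#' @param D number of depth points (default 101: integer percent grid).
#' @param section_id,traverse_index metadata stored with the result.
#' @return a single-row [gli_profiles()].
#' @export
normalize_profile <- function(raw, D = 101L, section_id = 1L, traverse_index = 1L) {
  v <- raw$values; s <- raw$arclen
  if (length(v) < 2L) stop_glimap("raw profile needs at least 2 samples")
  L <- s[length(s)] - s[1]
  if (L <= 0) stop_glimap("zero-length traverse")
  depth <- seq(0, 100, length.out = D)
  out <- approx((s - s[1]) / L * 100, v, xout = depth, rule = 2)$y
  gli_profiles(pmin(pmax(out, 0), 1), depth,
               section_id = section_id, traverse_index = traverse_index)
}

#' Combine profile sets row-wise
#'
#' @param ... `gli_profiles` objects sharing the depth grid.
#' @return a single `gli_profiles`.
#' @export
bind_profiles <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "gli_profiles"))
    ps <- ps[[1]]
  depth <- ps[[1]]$depth
  for (p in ps)
    if (length(p$depth) != length(depth) || max(abs(p$depth - depth)) > 1e-9)
      stop_glimap("profile sets have mismatched depth grids")
  gli_profiles(do.call(rbind, lapply(ps, `[[`, "values")), depth,
               section_id = ps[[1]]$section_id,
               traverse_index = unlist(lapply(ps, `[[`, "traverse_index")))
}
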