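# File-format frontends: PNG/TIFF images, JSON/CSV contours and profiles,
# NIfTI label and probability volumes.

#' Read and write binary cell-body masks as PNG
#'
#' @param mask a [cell_mask()].
#' @param file path to a single-channel PNG.
#' @param resolution um/pixel to attach on read.
#' @return `write_mask_png` returns the path invisibly; `read_mask_png` a
#'   [cell_mask()].
#' @export
write_mask_png <- function(mask, file) {
  stopifnot(inherits(mask, "cell_mask"))
  png::writePNG(mask$pixels * 1.0, target = file)
  invisible(file)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(file, resolution) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  cell_mask((img > 0.5) * 1L, resolution)
}

#' Write a GLI image as float TIFF plus JSON metadata
#'
#' The grid geometry (field size, step, origin, source resolution) goes to a
#' `.json` sidecar next to the TIFF.
#'
#' @param gli a `gli_image`.
#' @param file path of the TIFF to write.
#' @return the path, invisibly.
#' @export
write_gli_tiff <- function(gli, file) {
  stopifnot(inherits(gli, "gli_image"))
  tiff::writeTIFF(gli$values, file, bits.per.sample = 32L)
  meta <- list(field_size = gli$field_size, step = gli$step,
               origin = gli$origin, resolution = gli$resolution)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(file), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_gli_tiff
#' @export
read_gli_tiff <- function(file) {
  vals <- tiff::readTIFF(file)
  meta_path <- paste0(tools::file_path_sans_ext(file), ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
          else list(field_size = 16, step = 16, origin = c(0, 0))
  structure(list(values = vals, field_size = meta$field_size,
                 resolution = meta$resolution %||% NA_real_,
                 origin = as.numeric(meta$origin), step = meta$step),
            class = "gli_image")
}

#' Read and write contour pairs as JSON
#'
#' @param contours a [contour_pair()].
#' @param file JSON path; the file holds `outer` and `inner` as n x 2
#'   coordinate arrays in um.
#' @return the path (write) or a [contour_pair()] (read).
#' @export
write_contours_json <- function(contours, file) {
  stopifnot(inherits(contours, "contour_pair"))
  jsonlite::write_json(list(outer = unname(as.matrix(contours$outer)),
                            inner = unname(as.matrix(contours$inner))),
                       file, digits = NA)
  invisible(file)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  contour_pair(x$outer, x$inner)
}

#' Write profiles as long-format CSV
#'
#' One row per (traverse, depth point): `section_id`, `traverse_index`,
#' `depth`, `gli`.
#'
#' @param profiles a [gli_profiles()].
#' @param file CSV path.
#' @return the path (write) or a `gli_profiles` (read).
#' @export
write_profiles_csv <- function(profiles, file) {
  stopifnot(inherits(profiles, "gli_profiles"))
  n <- nrow(profiles$values); D <- ncol(profiles$values)
  df <- data.frame(section_id = rep(profiles$section_id[1], n * D),
                   traverse_index = rep(profiles$traverse_index, each = D),
                   depth = rep(profiles$depth, times = n),
                   gli = as.vector(t(profiles$values)))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(file) {
  df <- read.csv(file)
  ti <- unique(df$traverse_index)
  depth <- sort(unique(df$depth))
  vals <- matrix(NA_real_, length(ti), length(depth))
  for (i in seq_along(ti)) {
    sub <- df[df$traverse_index == ti[i], ]
    vals[i, ] <- sub$gli[order(sub$depth)]
  }
  gli_profiles(vals, depth, section_id = df$section_id[1], traverse_index = ti)
}

#' Read and write label volumes and probability maps as NIfTI-1
#'
#' Label volumes are written as int16, probability maps as float32; the
#' affine (voxel size) travels in the NIfTI header.
#'
#' @param vol a [label_volume()] or [probability_map()].
#' @param file `.nii` or `.nii.gz` path.
#' @return the path (write); a [label_volume()] (read).
#' @export
write_volume_nifti <- function(vol, file) {
  dat <- vol$voxels
  datatype <- if (inherits(vol, "probability_map")) "float" else "int16"
  attr(dat, "pixdim") <- vol$voxel_mm
  img <- RNifti::asNifti(dat, datatype = datatype)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_volume_nifti
#' @export
read_label_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  label_volume(array(as.integer(round(img)), dim(img)),
               voxel_mm = RNifti::pixdim(img)[1:3])
}
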