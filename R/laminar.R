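#' Laminar architecture model of a cortical area
#'
#' Describes an area by the relative thickness of cortical layers I-VI and the
#' planar density of cell bodies in each layer. Somata are modelled as disks
#' of fixed radius placed by a Poisson process (a Boolean model), so the
#' expected GLI of a layer has the closed form \eqn{1 - exp(-\lambda \pi r^2)}.
#'
#' @param layer_fractions numeric(6), relative thickness of layers I-VI;
#'   must be nonnegative and sum to 1.
#' @param layer_intensities numeric(6), cell density per layer (cells/um^2).
#' @param soma_radius soma disk radius in um.
#' @return an object of class `laminar_model`.
#' @seealso [intensity_for_gli()] to derive densities from target GLI levels,
#'   [laminar_curve()] for the noiseless depth profile.
#' @export
laminar_model <- function(layer_fractions = c(0.10, 0.08, 0.30, 0.10, 0.20, 0.22),
                          layer_intensities = intensity_for_gli(
                            c(0.10, 0.24, 0.16, 0.27, 0.17, 0.20), soma_radius),
                          soma_radius = 4) {
  assert_scalar_pos(soma_radius, "soma_radius")
  if (length(layer_fractions) != 6L || any(layer_fractions < 0))
    stop_glimap("layer_fractions must be 6 nonnegative values")
  if (abs(sum(layer_fractions) - 1) > 1e-9)
    stop_glimap("layer_fractions must sum to 1 (got %.12f)", sum(layer_fractions))
  if (length(layer_intensities) != 6L || any(layer_intensities < 0))
    stop_glimap("layer_intensities must be 6 nonnegative densities")
  structure(list(layer_fractions = as.numeric(layer_fractions),
                 layer_intensities = as.numeric(layer_intensities),
                 soma_radius = soma_radius),
            class = "laminar_model")
}

#' Poisson intensity achieving a target layer GLI
#'
#' Inverts the Boolean-model coverage formula: a Poisson disk process with
#' intensity lambda and radius r covers fraction `1 - exp(-lambda*pi*r^2)`.
#'
#' @param gli target coverage fraction(s) in \[0, 1).
#' @param soma_radius disk radius in um.
#' @return intensity in cells/um^2 (vectorized over `gli`).
#' @export
intensity_for_gli <- function(gli, soma_radius = 4) {
  if (any(gli < 0 | gli >= 1)) stop_glimap("target GLI must lie in [0, 1)")
  -log(1 - gli) / (pi * soma_radius^2)
}

#' Expected (noiseless) GLI at given cortical depths
#'
#' @param model a [laminar_model()].
#' @param depth depths in percent cortical depth (0 = layer I surface,
#'   100 = layer VI / white-matter boundary).
#' @return expected GLI values, piecewise constant across layers.
#' @export
laminar_curve <- function(model, depth = seq(0, 100, length.out = 101)) {
  stopifnot(inherits(model, "laminar_model"))
  layer <- depth_to_layer(model, depth)
  cov_frac <- 1 - exp(-model$layer_intensities * pi * model$soma_radius^2)
  cov_frac[layer]
}

# Layer index (1..6) containing each relative depth in [0, 100].
depth_to_layer <- function(model, depth) {
  cuts <- cumsum(model$layer_fractions) * 100
  idx <- findInterval(depth, c(0, head(cuts, -1)), rightmost.closed = FALSE)
  pmin(pmax(idx, 1L), 6L)
}

#' @export
print.laminar_model <- function(x, ...) {
  cat("Laminar model (6 layers)\n")
  cat("  thickness fractions:", paste(formatC(x$layer_fractions, digits = 3), collapse = " "), "\n")
  cat("  expected layer GLI :", paste(formatC(1 - exp(-x$layer_intensities * pi * x$soma_radius^2),
                                              digits = 3), collapse = " "), "\n")
  cat("  soma radius:", x$soma_radius, "um\n")
  invisible(x)
}
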