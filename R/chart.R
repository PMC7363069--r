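#' Construct a chip chart
#'
#' A chip chart is the universe of color stimuli the agents communicate
#' about: an ordered collection of chips, each with a 3-D CIELAB coordinate
#' (L*, a*, b*). Chips are indexed 0-based internally; external chip numbers
#' (e.g. the 1-based WCS chip number) are kept as metadata.
#'
#' @param coords numeric matrix or data.frame with 3 columns (L*, a*, b*),
#'   one row per chip.
#' @param name chart name, used to guard against mixing partitions from
#'   different charts.
#' @param wcs_chip optional integer vector of external (1-based) chip
#'   numbers.
#' @param munsell_hue,munsell_value optional character vectors of Munsell
#'   codes.
#' @return An object of class `chip_chart`: a data.frame with columns
#'   `chip_id` (0-based), `L`, `a`, `b` and any metadata columns.
#' @examples
#' ch <- chip_chart(rbind(c(50, 0, 0), c(60, 10, -10)))
#' n_chips(ch)
#' @export
chip_chart <- function(coords, name = "chart", wcs_chip = NULL,
                       munsell_hue = NULL, munsell_value = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("chip coordinates must have exactly 3 columns (L*, a*, b*)")
  if (nrow(coords) == 0L)
    stop("a chip chart must contain at least one chip")
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords)))
    stop("chip coordinates must be finite")
  df <- data.frame(
    chip_id = seq_len(nrow(coords)) - 1L,
    L = coords[, 1L], a = coords[, 2L], b = coords[, 3L]
  )
  if (!is.null(wcs_chip)) {
    wcs_chip <- as.integer(wcs_chip)
    if (anyDuplicated(wcs_chip))
      stop("duplicate external chip numbers")
    df$wcs_chip <- wcs_chip
  }
  if (!is.null(munsell_hue)) df$munsell_hue <- as.character(munsell_hue)
  if (!is.null(munsell_value)) df$munsell_value <- as.character(munsell_value)
  structure(df, name = as.character(name)[1L],
            class = c("chip_chart", "data.frame"))
}

#' Number of chips in a chart
#' @param chart a [chip_chart()].
#' @return integer chip count.
#' @export
n_chips <- function(chart) {
  stopifnot(inherits(chart, "chip_chart"))
  nrow(chart)
}

#' CIELAB coordinates of a chart as a matrix
#' @param chart a [chip_chart()].
#' @return n x 3 numeric matrix with columns L, a, b, ordered by `chip_id`.
#' @export
chip_coords <- function(chart) {
  stopifnot(inherits(chart, "chip_chart"))
  m <- as.matrix(chart[, c("L", "a", "b")])
  rownames(m) <- chart$chip_id
  m
}

#' @export
print.chip_chart <- function(x, ...) {
  cat(sprintf("<chip_chart '%s': %d chips>\n", attr(x, "name"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... (%d more chips)\n", nrow(x) - 6L))
  invisible(x)
}

#' Similarity-kernel parameters
#'
#' The similarity between two chips is `exp(-c * dist^2)` where `dist` is
#' the Euclidean CIELAB distance and `c` is a scaling factor. The default
#' `scale_c = 0.001` is the standard value in the color-naming literature:
#' it puts the half-similarity point at a CIELAB distance of about 26.3,
#' roughly the scale at which two chips stop looking like shades of the
#' same color.
#'
#' @param scale_c positive scaling factor of the squared distance.
#' @return An object of class `similarity_params`.
#' @export
similarity_params <- function(scale_c = 0.001) {
  scale_c <- as.numeric(scale_c)[1L]
  if (!is.finite(scale_c) || scale_c <= 0)
    stop("scale_c must be a positive finite number")
  structure(list(scale_c = scale_c), class = "similarity_params")
}

as_coords3 <- function(x) {
  # accept a chip row (data.frame), a 3-vector, or a 1x3 matrix
  if (is.data.frame(x)) x <- c(x$L, x$a, x$b)
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x)))
    stop("a chip coordinate must be a finite 3-vector")
  x
}

#' Euclidean distance between two chips in CIELAB space
#'
#' @param a,b chips: either rows of a [chip_chart()] or numeric 3-vectors
#'   of CIELAB coordinates.
#' @return nonnegative distance; 0 iff the coordinates are identical.
#' @export
cielab_distance <- function(a, b) {
  sqrt(sum((as_coords3(a) - as_coords3(b))^2))
}

#' Similarity between two chips
#'
#' `exp(-c * dist(a, b)^2)`: 1 for identical coordinates, falling rapidly
#' toward 0 as the chips become discriminably different.
#'
#' @inheritParams cielab_distance
#' @param params a [similarity_params()].
#' @return similarity in (0, 1].
#' @export
similarity <- function(a, b, params = similarity_params()) {
  stopifnot(inherits(params, "similarity_params"))
  exp(-params$scale_c * cielab_distance(a, b)^2)
}

#' Pairwise similarity matrix of a chart
#'
#' @param chart a [chip_chart()].
#' @param params a [similarity_params()].
#' @return symmetric n x n matrix with unit diagonal.
#' @export
similarity_matrix <- function(chart, params = similarity_params()) {
  xy <- chip_coords(chart)
  d2 <- as.matrix(stats::dist(xy))^2
  exp(-params$scale_c * d2)
}

#' Perturb chip coordinates with Gaussian environmental noise
#'
#' Adds independent zero-mean Gaussian noise of variance `sigma_e_sq` to
#' each CIELAB component. This is the "environmental" channel: the chip the
#' sender sees is a noisy version of the true stimulus. Variance 0 returns
#' the coordinates unchanged (no degenerate rnorm call).
#'
#' @param coords numeric 3-vector, or an n x 3 matrix of coordinates.
#' @param sigma_e_sq nonnegative noise variance per component.
#' @return perturbed coordinates with the same shape as `coords`.
#' @export
perturb_chip <- function(coords, sigma_e_sq) {
  if (!is.numeric(sigma_e_sq) || length(sigma_e_sq) != 1L ||
      !is.finite(sigma_e_sq) || sigma_e_sq < 0)
    stop("sigma_e_sq must be a single nonnegative finite number")
  m <- if (is.matrix(coords)) coords else matrix(as_coords3(coords), 1L)
  if (sigma_e_sq > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, sqrt(sigma_e_sq)),
                    nrow(m), ncol(m))
  if (is.matrix(coords)) m else drop(m)
}
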