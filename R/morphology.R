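# Binary morphology on logical masks. The engine is EBImage; pixels outside
# the image count as background, which EBImage's border replication does not
# give directly, so masks are padded with a background margin first. The
# structuring element is a Euclidean disk: offsets (dr, dc) with
# dr^2 + dc^2 <= radius^2 (radius 1 is the 4-neighborhood plus shape).

#' Disk structuring element
#'
#' @param radius nonnegative integer radius; pixels at Euclidean distance
#'   <= radius from the center are included.
#' @return A (2*radius+1) square 0/1 matrix.
#' @export
diskKernel <- function(radius) {
  stopifnot(radius >= 0)
  r <- as.integer(radius)
  d <- 2L * r + 1L
  off <- seq_len(d) - r - 1L
  k <- outer(off^2, off^2, "+") <= r^2
  matrix(as.integer(k), d, d)
}

padMask <- function(mask, r) {
  out <- matrix(0L, nrow(mask) + 2L * r, ncol(mask) + 2L * r)
  out[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))] <- as.integer(mask)
  out
}

unpadMask <- function(m, r, dims) {
  m[r + seq_len(dims[1]), r + seq_len(dims[2])] > 0
}

morphApply <- function(mask, radius, fun) {
  stopifnot(is.logical(mask))
  r <- as.integer(radius)
  if (r == 0L) return(mask)
  k <- diskKernel(r)
  # pad by 2r so opening/closing intermediates never touch the border
  p <- fun(padMask(mask, 2L * r), k)
  unpadMask(p, 2L * r, dim(mask))
}

#' Binary morphology with a disk structuring element
#'
#' Erosion, dilation, opening (erosion then dilation) and closing (dilation
#' then erosion) of a logical mask by [diskKernel()] of the given radius.
#' Pixels outside the image are treated as background.
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels.
#' @return Logical matrix of the same dimension.
#' @export
binaryErode <- function(mask, radius = 1)
  morphApply(mask, radius, EBImage::erode)

#' @rdname binaryErode
#' @export
binaryDilate <- function(mask, radius = 1)
  morphApply(mask, radius, EBImage::dilate)

#' @rdname binaryErode
#' @export
binaryOpen <- function(mask, radius = 1)
  morphApply(mask, radius, function(m, k) EBImage::dilate(EBImage::erode(m, k), k))

#' @rdname binaryErode
#' @export
binaryClose <- function(mask, radius = 1)
  morphApply(mask, radius, function(m, k) EBImage::erode(EBImage::dilate(m, k), k))

#' Connected components and component selection
#'
#' \code{labelComponents} labels 4-connected foreground components;
#' \code{largestComponent} keeps only the largest one (ties broken by the
#' lowest label, i.e. the component whose first pixel comes first in
#' column-major order).
#'
#' @param mask logical matrix.
#' @return \code{labelComponents}: integer matrix of labels (0 =
#'   background); \code{largestComponent}: logical matrix.
#' @export
labelComponents <- function(mask) {
  stopifnot(is.logical(mask))
  lab <- EBImage::bwlabel(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

#' @rdname labelComponents
#' @export
largestComponent <- function(mask) {
  lab <- labelComponents(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Fill interior holes of a binary mask
#'
#' Background regions not connected to the image border are set to
#' foreground.
#'
#' @param mask logical matrix.
#' @return Logical matrix.
#' @export
fillHoles <- function(mask) {
  stopifnot(is.logical(mask))
  f <- EBImage::fillHull(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  matrix(f > 0, nrow(mask), ncol(mask))
}
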