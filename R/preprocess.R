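# Preparation of a traced disc image for segmentation: intensity
# normalization, rasterization of the manual IVD contour, and the
# K-means-based crop that suppresses surrounding tissue so only the disc
# (annulus + nucleus) remains.

#' Rescale intensities to [0, 1]
#'
#' Linear min-max rescale; a constant image maps to all zeros. Needed so
#' cluster distances and the region-growing threshold (maxdis) are
#' scale-free.
#'
#' @param image numeric matrix with finite entries.
#' @return Numeric matrix with values in [0, 1].
#' @export
normalizeIntensity <- function(image) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (!all(is.finite(image))) stop("image contains non-finite values")
  rng <- range(image)
  if (rng[1] == rng[2]) return(image * 0)
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Rasterize a closed polygon to a pixel mask
#'
#' A pixel belongs to the mask when its center (integer matrix coordinates)
#' is inside the polygon by the even-odd rule, implemented as a scanline
#' parity fill. Pixel centers lying exactly under a polygon edge follow the
#' strict crossing rule of the horizontal ray cast to the right.
#'
#' @param verts numeric matrix n x 2 of (row, col) vertices; closed
#'   implicitly. Self-intersecting polygons are rejected.
#' @param dims integer(2), output mask dimension (rows, cols).
#' @return Logical matrix of dimension \code{dims}.
#' @export
rasterizeContour <- function(verts, dims) {
  stopifnot(is.matrix(verts), ncol(verts) == 2, nrow(verts) >= 3,
            length(dims) == 2)
  if (polygonSelfIntersects(verts))
    stop("contour polygon is self-intersecting")
  nr <- as.integer(dims[1]); nc <- as.integer(dims[2])
  mask <- matrix(FALSE, nr, nc)
  y1 <- verts[, 1]; x1 <- verts[, 2]
  nxt <- c(seq_len(nrow(verts))[-1], 1L)
  y2 <- y1[nxt]; x2 <- x1[nxt]
  keep <- y1 != y2                      # horizontal edges never cross a row
  y1 <- y1[keep]; x1 <- x1[keep]; y2 <- y2[keep]; x2 <- x2[keep]
  if (!length(y1)) return(mask)
  rlo <- max(1L, ceiling(min(y1, y2))); rhi <- min(nr, floor(max(y1, y2)))
  if (rlo > rhi) return(mask)
  for (r in rlo:rhi) {
    # half-open rule: edge crosses row r iff min(y) <= r < max(y)
    cr <- (pmin(y1, y2) <= r) & (r < pmax(y1, y2))
    if (!any(cr)) next
    xc <- x1[cr] + (r - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr])
    xc <- sort(xc)
    # pixel center (r, c) inside iff an odd number of crossings lie at x > c
    cols <- seq_len(nc)
    nRight <- length(xc) - findInterval(cols, xc)
    mask[r, ] <- (nRight %% 2L) == 1L
  }
  mask
}

#' Crop a traced image to the disc and suppress surrounding tissue
#'
#' Crops the image to the bounding box of the traced IVD contour, clusters
#' the box's intensities by seeded K-means (Lloyd iterations from a
#' k-means++ style initialization), and zeroes every pixel outside the
#' contour mask so that only the disc (AF + NP) remains. The contour, not
#' the clustering, is the authoritative disc boundary; the clustering
#' summarizes the intensity populations (background / annulus / nucleus
#' with the default \code{k = 3}) for downstream use such as automatic
#' seed proposal.
#'
#' @param image numeric matrix, intensities in [0, 1].
#' @param contour numeric matrix n x 2 (row, col), the traced closed IVD
#'   outline in full-image coordinates.
#' @param k number of intensity clusters (>= 2).
#' @param seed integer seed making the initialization deterministic.
#' @return A list with elements \code{image} (cropped disc-only image,
#'   zero outside the contour), \code{discMask} (logical, the rasterized
#'   contour within the crop), \code{centers} (sorted increasing K-means
#'   centers), \code{bbox} (integer(4): first/last row, first/last col of
#'   the crop in the original image).
#' @export
kmeansCrop <- function(image, contour, k = 3, seed = 1) {
  stopifnot(is.matrix(image), k >= 2)
  full <- rasterizeContour(contour, dim(image))
  if (!any(full)) stop("contour rasterizes to an empty mask")
  rr <- range(which(rowSums(full) > 0))
  cc <- range(which(colSums(full) > 0))
  sub <- image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  discMask <- full[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  x <- as.vector(sub)
  km <- withSeed(seed, {
    init <- kmeansPlusPlusInit(x, k)
    stats::kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd")
  })
  out <- sub
  out[!discMask] <- 0
  list(image = out, discMask = discMask, centers = sort(km$centers[, 1]),
       bbox = c(rr[1], rr[2], cc[1], cc[2]))
}
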