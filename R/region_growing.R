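# Seeded region growing of the nucleus. Growth is best-first: among all
# frontier pixels (4-neighbors of the region accumulated so far), the one
# whose gray value is closest to the running region mean is accepted next,
# provided the difference does not exceed the threshold maxdis; growth
# ends when every frontier difference exceeds maxdis. The running mean is
# updated incrementally as mean2 = (mean1*size + point)/(size + 1).

#' Incremental region-mean update
#'
#' \eqn{mean_2 = (mean_1 \cdot size + point) / (size + 1)}: the mean gray
#' value of the region after accepting one more pixel.
#'
#' @param mean1 current region mean.
#' @param size current number of region pixels (>= 1).
#' @param point gray value of the newly accepted pixel.
#' @return The updated mean.
#' @export
updateMean <- function(mean1, size, point) {
  if (size < 1) stop("region size must be >= 1")
  (mean1 * size + point) / (size + 1)
}

#' Best-first seeded region growing
#'
#' Grows a region from one or more seed pixels inside \code{domain}.
#' Seeds are processed sequentially into a single region set with a shared
#' running mean; each seed is accepted unconditionally, then frontier
#' pixels (4-neighbors of accepted pixels) are repeatedly scanned for the
#' one minimizing |gray - region mean|, accepted while that minimum
#' difference is <= \code{maxdis}. Ties break to the smallest (row, col).
#' Rejected frontier pixels remain candidates: the mean moves as the
#' region grows, so they may be admitted later; growth for a seed ends
#' only when every frontier difference exceeds maxdis.
#'
#' @param image numeric matrix of intensities on a [0, 1] scale (so
#'   maxdis values like 0.06 are meaningful).
#' @param seeds integer matrix k x 2 of (row, col) seed pixels, or a
#'   length-2 vector for a single seed.
#' @param maxdis acceptance threshold on |gray - region mean|.
#' @param domain optional logical matrix restricting growth (e.g. the
#'   rasterized IVD contour, so the nucleus cannot leak outside the
#'   traced disc); default the whole image.
#' @param trace when TRUE, attach attributes \code{order} (acceptance
#'   order, n x 2) and \code{means} (running mean after each acceptance)
#'   to the result.
#' @return Logical matrix: the grown region.
#' @export
regionGrow <- function(image, seeds, maxdis = 0.06, domain = NULL,
                       trace = FALSE) {
  stopifnot(is.matrix(image), maxdis >= 0)
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2)
  seeds <- matrix(as.integer(seeds), ncol = 2)
  if (nrow(seeds) == 0) stop("at least one seed pixel is required")
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(domain)) domain <- matrix(TRUE, nr, nc)
  ok <- seeds[, 1] >= 1 & seeds[, 1] <= nr & seeds[, 2] >= 1 & seeds[, 2] <= nc
  if (!all(ok)) stop("seed outside the image")
  if (!all(domain[seeds])) stop("seed outside the growth domain")

  # state: 0 unseen, 1 frontier, 2 accepted. The region mean is taken
  # over the accepted values with base mean()'s refined two-pass summation
  # so an equal-valued region has exactly zero difference (maxdis = 0 works).
  state <- matrix(0L, nr, nc)
  fr <- integer(0); fc <- integer(0)      # frontier coordinates
  regVals <- numeric(0); regN <- 0L
  ordR <- integer(0); ordC <- integer(0); meansTrace <- numeric(0)

  pushNeighbors <- function(r, c) {
    nbr <- c(r - 1L, r + 1L, r, r)
    nbc <- c(c, c, c - 1L, c + 1L)
    keep <- nbr >= 1L & nbr <= nr & nbc >= 1L & nbc <= nc
    nbr <- nbr[keep]; nbc <- nbc[keep]
    idx <- cbind(nbr, nbc)
    keep2 <- domain[idx] & state[idx] == 0L
    nbr <- nbr[keep2]; nbc <- nbc[keep2]
    if (length(nbr)) {
      state[cbind(nbr, nbc)] <<- 1L
      fr <<- c(fr, nbr); fc <<- c(fc, nbc)
    }
  }
  accept <- function(r, c) {
    state[r, c] <<- 2L
    regVals <<- c(regVals, image[r, c])
    regN <<- regN + 1L
    if (trace) {
      ordR <<- c(ordR, r); ordC <<- c(ordC, c)
      meansTrace <<- c(meansTrace, mean(regVals))
    }
    pushNeighbors(r, c)
  }

  for (s in seq_len(nrow(seeds))) {
    sr <- seeds[s, 1]; sc <- seeds[s, 2]
    if (state[sr, sc] == 2L) next
    if (state[sr, sc] == 1L) {            # was queued: remove from frontier
      drop <- which(fr == sr & fc == sc)
      fr <- fr[-drop]; fc <- fc[-drop]
    }
    accept(sr, sc)
    repeat {
      if (!length(fr)) break
      g <- image[cbind(fr, fc)]
      d <- abs(g - mean(regVals))
      dmin <- min(d)
      if (dmin > maxdis) break
      cand <- which(d == dmin)
      if (length(cand) > 1) {
        cand <- cand[order(fr[cand], fc[cand])]
      }
      i <- cand[1]
      r <- fr[i]; c <- fc[i]
      fr <- fr[-i]; fc <- fc[-i]
      accept(r, c)
    }
  }
  region <- state == 2L
  if (trace) {
    attr(region, "order") <- cbind(row = ordR, col = ordC)
    attr(region, "means") <- meansTrace
  }
  region
}

#' Propose region-growing seeds automatically
#'
#' Heuristic for the recommendation that seeds sit close to (but inside)
#' the blurred NP boundary, where the gray value is lower than at the
#' nucleus center. The disc-only image (zeroed surround, annulus,
#' nucleus) is clustered by intensity K-means with k = 3; disc pixels
#' are thresholded at the midpoint of the two brightest centers, the
#' largest 4-connected component is taken as a provisional nucleus,
#' eroded by \code{erodeRadius}, and pixels on the eroded mask's
#' boundary are returned.
#'
#' The default erosion radius of 2 px clears the blurred NP/AF
#' transition band: a seed placed in the band anchors the running region
#' mean at the band's intensity and best-first growth then crawls along
#' the iso-intensity rim instead of reaching the nucleus core. If the
#' erosion empties the provisional mask the radius falls back to 1, then
#' to the provisional mask itself.
#'
#' \code{proposeSeeds} returns \code{n} boundary pixels spread evenly by
#' angle around the provisional centroid (deterministic). Growing from
#' several restart points mirrors the procedure's repeat-from-new-seeds
#' loop and makes the growth robust to a single seed landing in a local
#' noise pocket whose neighborhood stalls. \code{proposeSeed} is the
#' single-seed form: the lexicographically smallest boundary pixel.
#'
#' @param image numeric matrix, the disc-only image on [0, 1].
#' @param discMask logical matrix of disc pixels.
#' @param seed integer seed for the K-means initialization.
#' @param erodeRadius erosion depth in pixels between the provisional
#'   boundary and the returned seeds.
#' @param n number of seeds requested.
#' @return \code{proposeSeed}: integer vector (row, col);
#'   \code{proposeSeeds}: integer matrix with up to \code{n} rows.
#'   Errors when no bright provisional nucleus exists (a manual seed is
#'   then required).
#' @export
proposeSeeds <- function(image, discMask, n = 4L, seed = 1L,
                         erodeRadius = 2) {
  stopifnot(is.matrix(image), is.logical(discMask), any(discMask), n >= 1)
  x <- as.vector(image)
  if (length(unique(x)) < 3)
    stop("no provisional NP found; provide a manual seed")
  km <- withSeed(seed, {
    init <- kmeansPlusPlusInit(x, 3L)
    stats::kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd")
  })
  ctr <- sort(km$centers[, 1])
  thr <- (ctr[2] + ctr[3]) / 2
  bright <- discMask & image >= thr
  if (!any(bright))
    stop("no provisional NP found; provide a manual seed")
  prov <- largestComponent(bright)
  er <- binaryErode(prov, erodeRadius)
  if (!any(er)) er <- binaryErode(prov, 1)
  base <- if (any(er)) er else prov
  boundary <- base & !binaryErode(base, 1)
  if (!any(boundary)) boundary <- base
  idx <- which(boundary, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  if (n == 1L || nrow(idx) <= n)
    return(matrix(as.integer(idx[seq_len(min(n, nrow(idx))), ]),
                  ncol = 2, dimnames = list(NULL, c("row", "col"))))
  ctd <- colMeans(idx)
  ang <- atan2(idx[, 1] - ctd[1], idx[, 2] - ctd[2])
  targets <- seq(-pi, pi, length.out = n + 1L)[seq_len(n)]
  pick <- vapply(targets, function(a)
    which.min(abs(((ang - a + pi) %% (2 * pi)) - pi)), 1L)
  out <- idx[unique(pick), , drop = FALSE]
  matrix(as.integer(out), ncol = 2, dimnames = list(NULL, c("row", "col")))
}

#' @rdname proposeSeeds
#' @export
proposeSeed <- function(image, discMask, seed = 1L, erodeRadius = 2) {
  as.integer(proposeSeeds(image, discMask, n = 1L, seed = seed,
                          erodeRadius = erodeRadius)[1, ])
}

#' Morphological cleanup of a grown region
#'
#' Closing then opening with a disk, retention of the largest 4-connected
#' component, and interior hole filling — the standard post-processing
#' before the region's outline is extracted.
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels.
#' @return Logical matrix. Errors when the result is empty.
#' @export
morphoCleanup <- function(mask, radius = 2) {
  stopifnot(is.logical(mask))
  out <- binaryOpen(binaryClose(mask, radius), radius)
  if (!any(out))
    stop("segmentation failure: empty mask after morphological cleanup")
  fillHoles(largestComponent(out))
}
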