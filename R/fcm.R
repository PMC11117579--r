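# Fuzzy C-means segmentation of the disc-only image. The algorithm
# alternates centroid and membership updates to minimize the fuzzy
# within-cluster objective J = sum_i sum_j u_ij^m d_ij^2 under the
# per-object constraint sum_i u_ij = 1, where d is the distance between a
# pixel intensity and a cluster center. Membership matrices here store
# objects in rows and clusters in columns.

#' Random initial membership matrix
#'
#' Uniform random entries, row-normalized so each object's memberships sum
#' to one. Deterministic given the seed (entries are drawn as
#' \code{matrix(runif(n*c), n, c)} before normalization).
#'
#' @param n number of objects (> c).
#' @param c number of clusters (>= 2).
#' @param seed integer seed.
#' @return n x c membership matrix with unit row sums.
#' @export
initMembership <- function(n, c, seed = 1L) {
  if (c < 2) stop("need at least 2 clusters")
  if (n <= c) stop("need more objects than clusters")
  U <- withSeed(seed, matrix(stats::runif(n * c), n, c))
  U / rowSums(U)
}

#' Fuzzy centroid update
#'
#' Each center is the membership-weighted mean
#' \eqn{c_i = \sum_j u_{ij}^m x_j / \sum_j u_{ij}^m}.
#'
#' @param U n x c membership matrix.
#' @param x numeric vector of n data values (intensities).
#' @param m fuzziness exponent (> 1).
#' @return Numeric vector of c cluster centers.
#' @export
updateCentroids <- function(U, x, m = 2) {
  stopifnot(is.matrix(U), nrow(U) == length(x), m > 1)
  W <- U^m
  denom <- colSums(W)
  if (any(denom == 0)) stop("empty fuzzy cluster (all-zero membership column)")
  colSums(W * x) / denom
}

# n x c matrix of |c_i - x_j| distances (objects in rows)
fcmDistances <- function(x, centers) abs(outer(x, centers, "-"))

#' Fuzzy membership update
#'
#' \eqn{u_{ij} = 1 / \sum_k (d_{ij}/d_{kj})^{2/(m-1)}}. An object
#' coinciding with one or more centers gets crisp membership 1 on the
#' first such center (the zero-distance limit of the update).
#'
#' @param x numeric vector of data values.
#' @param centers numeric vector of cluster centers.
#' @param m fuzziness exponent (> 1).
#' @return n x c membership matrix with unit row sums.
#' @export
updateMembership <- function(x, centers, m = 2) {
  stopifnot(m > 1)
  D <- fcmDistances(x, centers)
  U <- matrix(0, nrow(D), ncol(D))
  zero <- D == 0
  hasZero <- rowSums(zero) > 0
  if (any(hasZero))
    U[cbind(which(hasZero), max.col(zero[hasZero, , drop = FALSE],
                                    ties.method = "first"))] <- 1
  if (any(!hasZero)) {
    W <- D[!hasZero, , drop = FALSE]^(-2 / (m - 1))
    U[!hasZero, ] <- W / rowSums(W)
  }
  U
}

#' Fuzzy C-means objective
#'
#' \eqn{J = \sum_i \sum_j u_{ij}^m d_{ij}^2}.
#'
#' @inheritParams updateMembership
#' @param U n x c membership matrix.
#' @return Scalar objective value.
#' @export
fcmObjective <- function(U, centers, x, m = 2) {
  D <- fcmDistances(x, centers)
  sum(U^m * D^2)
}

#' Run fuzzy C-means clustering
#'
#' Alternates [updateCentroids()] and [updateMembership()] from a seeded
#' random initialization. Stops when the objective change falls below
#' \code{tol}, the objective itself falls below \code{tol}, or
#' \code{maxIter} is reached (the returned object is then flagged as not
#' converged rather than erroring).
#'
#' @param x numeric vector or matrix of intensities; a matrix is clustered
#'   as its vector of pixel values (column-major order).
#' @param c number of clusters; default 3 separates annulus, blurred
#'   transition band and nucleus on disc images.
#' @param m fuzziness exponent, conventional default 2.
#' @param tol convergence threshold on |change in J| (and on J itself).
#' @param maxIter iteration cap.
#' @param seed integer seed for the membership initialization.
#' @return A [FuzzyPartition-class].
#' @examples
#' p <- fcmCluster(c(rnorm(30, 0.2, 0.01), rnorm(30, 0.8, 0.01)), c = 2)
#' clusterCenters(p)
#' @export
fcmCluster <- function(x, c = 3, m = 2, tol = 1e-5, maxIter = 100L, seed = 1L) {
  x <- as.vector(x)
  if (length(unique(x)) < c)
    stop("image must contain at least c distinct values")
  U <- initMembership(length(x), c, seed)
  jPrev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  centers <- numeric(c)
  while (iter < maxIter) {
    iter <- iter + 1L
    centers <- updateCentroids(U, x, m)
    U <- updateMembership(x, centers, m)
    j <- fcmObjective(U, centers, x, m)
    trace <- c(trace, j)
    if (is.finite(jPrev) && abs(jPrev - j) < tol || j < tol) {
      converged <- TRUE
      jPrev <- j
      break
    }
    jPrev <- j
  }
  new("FuzzyPartition", membership = U, centers = centers,
      objective = trace[length(trace)], objectiveTrace = trace,
      nIter = iter, converged = converged, m = m)
}

#' Select the nucleus cluster from a fuzzy partition
#'
#' Hard-assigns each pixel to its maximum-membership cluster (ties to
#' the lowest cluster index) and returns the binary mask of the cluster
#' with the highest center intensity — the T2-bright nucleus — restricted
#' to the disc. The partition may have been fitted on every pixel of the
#' disc-only image (the usual case: its zeroed surround forms its own
#' cluster) or on the disc pixels alone; both layouts are recognized by
#' size, with pixels taken in column-major order.
#'
#' @param partition a [FuzzyPartition-class] over the image or disc
#'   pixels.
#' @param discMask logical matrix, the disc region of the clustered
#'   image.
#' @return Logical matrix: the raw NP cluster mask (before interference
#'   removal), restricted to \code{discMask}.
#' @export
selectNpCluster <- function(partition, discMask) {
  stopifnot(is(partition, "FuzzyPartition"), is.logical(discMask))
  U <- partition@membership
  hard <- max.col(U, ties.method = "first")
  npCluster <- which.max(partition@centers)
  mask <- discMask & FALSE
  if (nrow(U) == length(discMask)) {
    mask[] <- hard == npCluster
    mask <- mask & discMask
  } else if (nrow(U) == sum(discMask)) {
    mask[discMask] <- hard == npCluster
  } else {
    stop("partition size matches neither the image nor the disc mask")
  }
  mask
}

#' Remove interference clusters from a raw NP mask
#'
#' Morphological opening with a disk, then retention of the largest
#' 4-connected component; this discards the small spurious blobs that
#' share the nucleus cluster's intensity range.
#'
#' @param mask logical matrix, raw NP cluster mask.
#' @param radius opening disk radius in pixels.
#' @return Logical matrix. Errors when nothing survives the opening,
#'   signaling a failed segmentation.
#' @export
removeInterference <- function(mask, radius = 2) {
  stopifnot(is.logical(mask))
  opened <- binaryOpen(mask, radius)
  if (!any(opened))
    stop("segmentation failure: empty mask after interference removal")
  largestComponent(opened)
}
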