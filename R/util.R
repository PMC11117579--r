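# Internal helpers: localized RNG, polygon utilities, seeded k-means.

# Evaluate expr with a locally set seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Signed shoelace area of a closed polygon (n x 2, row/col); positive when
# the vertex order is counterclockwise in (x = col, y = row) axes.
signedArea <- function(verts) {
  y <- verts[, 1]; x <- verts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Area enclosed by a closed polygon
#'
#' Shoelace area of a closed vertex list in (row, col) pixel coordinates.
#'
#' @param verts numeric matrix, n x 2 (row, col); the polygon closes back
#'   to the first vertex implicitly.
#' @return Enclosed area in squared pixels.
#' @export
polygonArea <- function(verts) {
  stopifnot(is.matrix(verts), ncol(verts) == 2, nrow(verts) >= 3)
  abs(signedArea(verts))
}

# TRUE when any two non-adjacent polygon edges properly intersect.
polygonSelfIntersects <- function(verts) {
  n <- nrow(verts)
  if (n < 4) return(FALSE)
  y1 <- verts[, 1]; x1 <- verts[, 2]
  nxt <- c(2:n, 1)
  y2 <- y1[nxt]; x2 <- x1[nxt]
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    j <- j[!(i == 1 & j == n)]        # skip edges sharing a vertex
    if (!length(j)) next
    d1 <- cross(x2[i] - x1[i], y2[i] - y1[i], x1[j] - x1[i], y1[j] - y1[i])
    d2 <- cross(x2[i] - x1[i], y2[i] - y1[i], x2[j] - x1[i], y2[j] - y1[i])
    d3 <- cross(x2[j] - x1[j], y2[j] - y1[j], x1[i] - x1[j], y1[i] - y1[j])
    d4 <- cross(x2[j] - x1[j], y2[j] - y1[j], x2[i] - x1[j], y2[i] - y1[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# k-means++ seeding on a numeric vector; returns k distinct initial centers.
kmeansPlusPlusInit <- function(x, k) {
  ux <- unique(x)
  if (length(ux) < k)
    stop("fewer than k distinct intensity values; reduce k")
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1L)]
  d2 <- (x - centers[1])^2
  for (i in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {  # degenerate; fall back to unused distinct values
      centers[i:k] <- setdiff(ux, centers[seq_len(i - 1L)])[seq_len(k - i + 1L)]
      return(centers)
    }
    centers[i] <- x[sample.int(length(x), 1L, prob = d2)]
    d2 <- pmin(d2, (x - centers[i])^2)
  }
  centers
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}, the standard overlap score for
#' segmentation evaluation. Returns 1 when both masks are empty.
#'
#' @param a,b logical matrices of equal dimension.
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), all(dim(a) == dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
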