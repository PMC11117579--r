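# Contour extraction and parametric smoothing. A mask's outline is traced
# exactly along pixel boundaries (so contour and mask convert back and
# forth without loss), then optionally replaced by a truncated
# elliptic-Fourier curve: order 1 is the best-fit ellipse (the oval disc
# template), a few more harmonics admit the kidney concavity, and high
# frequencies (segmentation jaggedness) are discarded.

#' Extract the boundary contour of a binary mask
#'
#' Traces the outline of a single 4-connected component exactly along the
#' pixel edges: vertices lie at half-integer (row, col) coordinates and
#' the enclosed area equals the pixel count, so rasterizing the result
#' reproduces the mask bit for bit. Vertices are ordered with positive
#' shoelace orientation in (col, row) axes; collinear runs are merged, so
#' a 1-pixel mask yields the 4 corners of its unit square.
#'
#' @param mask logical matrix with exactly one 4-connected component and
#'   no interior holes (run [morphoCleanup()] first otherwise).
#' @return Numeric matrix n x 2 (row, col), a closed simple polygon.
#' @export
extractContour <- function(mask) {
  stopifnot(is.logical(mask), any(mask))
  if (max(labelComponents(mask)) > 1L)
    stop("mask has multiple components; run cleanup first")
  nr <- nrow(mask); nc <- ncol(mask)
  px <- which(mask, arr.ind = TRUE)
  r <- px[, 1]; c <- px[, 2]
  out <- function(rr, cc) {
    bad <- rr < 1L | rr > nr | cc < 1L | cc > nc
    res <- logical(length(rr))
    res[bad] <- TRUE
    res[!bad] <- !mask[cbind(rr[!bad], cc[!bad])]
    res
  }
  # directed boundary edges in doubled (integer) coordinates; interior on
  # the right of the walking direction
  sr <- integer(0); sc <- integer(0); er <- integer(0); ec <- integer(0)
  addEdges <- function(side, s1, s2, e1, e2) {
    k <- which(side)
    sr <<- c(sr, s1[k]); sc <<- c(sc, s2[k])
    er <<- c(er, e1[k]); ec <<- c(ec, e2[k])
  }
  r2 <- 2L * r; c2 <- 2L * c
  addEdges(out(r - 1L, c), r2 - 1L, c2 - 1L, r2 - 1L, c2 + 1L)  # top: +col
  addEdges(out(r, c + 1L), r2 - 1L, c2 + 1L, r2 + 1L, c2 + 1L)  # right: +row
  addEdges(out(r + 1L, c), r2 + 1L, c2 + 1L, r2 + 1L, c2 - 1L)  # bottom: -col
  addEdges(out(r, c - 1L), r2 + 1L, c2 - 1L, r2 - 1L, c2 - 1L)  # left: -row

  key <- function(a, b) a * (2L * nc + 3L) + b
  startKey <- key(sr, sc)
  used <- logical(length(sr))
  byStart <- split(seq_along(sr), startKey)

  loops <- list()
  while (any(!used)) {
    e <- which(!used)[1]
    loopR <- integer(0); loopC <- integer(0)
    cur <- e
    repeat {
      used[cur] <- TRUE
      loopR <- c(loopR, sr[cur]); loopC <- c(loopC, sc[cur])
      vk <- as.character(key(er[cur], ec[cur]))
      cand <- byStart[[vk]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # ambiguous (anti-diagonal) vertex: take the right turn, which
        # keeps the walk on its own lobe of the boundary
        d1r <- er[cur] - sr[cur]; d1c <- ec[cur] - sc[cur]
        turn <- d1r * (ec[cand] - sc[cand]) - d1c * (er[cand] - sr[cand])
        cand <- cand[which.min(turn)]
      }
      cur <- cand[1]
    }
    loops[[length(loops) + 1L]] <- cbind(loopR, loopC)
  }
  if (length(loops) > 1L)
    stop("mask has interior holes; run cleanup first")
  v <- loops[[1]] / 2
  # merge collinear runs
  n <- nrow(v)
  prv <- c(n, seq_len(n - 1L))
  nxt <- c(seq_len(n)[-1], 1L)
  keep <- !(
    (v[, 1] - v[prv, 1]) * (v[nxt, 2] - v[, 2]) ==
    (v[, 2] - v[prv, 2]) * (v[nxt, 1] - v[, 1]))
  v <- v[keep, , drop = FALSE]
  if (signedArea(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  dimnames(v) <- list(NULL, c("row", "col"))
  v
}

#' Resample a closed contour uniformly by arc length
#'
#' @param verts numeric matrix n x 2 (row, col), closed implicitly.
#' @param n number of output vertices.
#' @return n x 2 matrix of points at equal arc-length spacing, starting
#'   at the first input vertex.
#' @export
resampleContour <- function(verts, n = 128L) {
  stopifnot(is.matrix(verts), ncol(verts) == 2, nrow(verts) >= 3)
  closed <- rbind(verts, verts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L == 0) stop("degenerate (zero-length) contour")
  s <- (seq_len(n) - 1L) / n * L
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(closed) - 1L)
  t <- (s - cum[i]) / pmax(seg[i], .Machine$double.eps)
  closed[i, , drop = FALSE] * (1 - t) + closed[i + 1L, , drop = FALSE] * t
}

#' Smooth a contour with a truncated elliptic-Fourier curve
#'
#' Least-squares fit of a truncated Fourier parametric curve
#' \eqn{z(t) = \sum_{|k| \le H} c_k e^{2\pi i k t}} (z = col + i row) to
#' the boundary, resampled uniformly by arc length. With harmonics
#' \eqn{H = 1} the fit is the best-fit ellipse (pure oval); the default
#' \eqn{H = 4} keeps the oval-to-kidney morphology while discarding
#' pixel-level jaggedness.
#'
#' The fit is built up one order at a time: coefficients are solved by
#' least squares at the current sample parameterization, then each sample
#' is reassigned the curve parameter nearest to it (a guarded
#' reprojection, kept only when it lowers the residual). Freeing the
#' parameterization this way lets an order-1 fit reproduce an exact
#' ellipse even though arc length is not the ellipse's harmonic
#' parameter, and the order-by-order construction makes the reported
#' residual non-increasing in the order by construction.
#'
#' @param verts numeric matrix (>= 8 vertices), closed contour (row, col).
#' @param harmonics highest Fourier order retained.
#' @param nOut number of vertices of the returned fitted curve.
#' @param nSample number of arc-length-uniform samples used for the fit.
#' @return \code{nOut} x 2 matrix (row, col): the fitted closed curve,
#'   with attribute \code{"rss"} (mean squared planar residual at the
#'   sample points).
#' @export
fitParametricProfile <- function(verts, harmonics = 4L, nOut = 128L,
                                 nSample = 256L) {
  stopifnot(is.matrix(verts), ncol(verts) == 2)
  if (nrow(verts) < 8) stop("need at least 8 vertices to fit a profile")
  if (polygonArea(verts) == 0) stop("degenerate (zero-area) contour")
  H <- as.integer(harmonics)
  stopifnot(H >= 1, nSample > 2 * H + 1)
  p <- resampleContour(verts, nSample)
  z <- complex(real = p[, 2], imaginary = p[, 1])   # x = col, y = row
  t <- (seq_len(nSample) - 1L) / nSample            # arc-length start
  tGrid <- (seq_len(1024L) - 1L) / 1024L            # reprojection grid
  ck <- NULL; kfreq <- NULL; rss <- Inf
  for (h in seq_len(H)) {
    kfreqH <- c(0:h, -(h:1))
    E <- exp(2i * pi * outer(t, kfreqH))
    ckH <- qr.solve(E, z)
    rssH <- mean(Mod(E %*% ckH - z)^2)
    # guarded reprojection: reassign sample parameters to the nearest
    # curve point, refit, keep only while the residual drops
    for (it in 1:3) {
      zg <- as.vector(exp(2i * pi * outer(tGrid, kfreqH)) %*% ckH)
      tNew <- tGrid[max.col(-Mod(outer(z, zg, "-")), ties.method = "first")]
      Enew <- exp(2i * pi * outer(tNew, kfreqH))
      ckNew <- qr.solve(Enew, z)
      rssNew <- mean(Mod(Enew %*% ckNew - z)^2)
      if (rssNew >= rssH) break
      t <- tNew; E <- Enew; ckH <- ckNew; rssH <- rssNew
    }
    ck <- ckH; kfreq <- kfreqH; rss <- rssH
  }
  tOut <- (seq_len(nOut) - 1L) / nOut
  zo <- as.vector(exp(2i * pi * outer(tOut, kfreq)) %*% ck)
  out <- cbind(row = Im(zo), col = Re(zo))
  attr(out, "rss") <- rss
  out
}
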