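# Independent oracles: deliberately naive re-implementations used to
# cross-check the package's vectorized/engineered code paths. They share
# no code with the implementation beyond the documented conventions
# (1-based pixel centers, half-open even-odd rule, Euclidean-disk
# structuring element, smallest-(row, col) tie-breaks).

# Per-pixel even-odd point-in-polygon test (rightward ray, half-open rule)
pipOracle <- function(verts, dims) {
  n <- nrow(verts)
  mask <- matrix(FALSE, dims[1], dims[2])
  for (r in seq_len(dims[1])) for (cc in seq_len(dims[2])) {
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- verts[i, 1]; x1 <- verts[i, 2]
      y2 <- verts[j, 1]; x2 <- verts[j, 2]
      if (y1 == y2) next
      if ((min(y1, y2) <= r) && (r < max(y1, y2))) {
        xc <- x1 + (r - y1) * (x2 - x1) / (y2 - y1)
        if (xc > cc) crossings <- crossings + 1L
      }
    }
    mask[r, cc] <- crossings %% 2L == 1L
  }
  mask
}

# Loop-based fuzzy C-means sharing only the documented init layout
naiveFcm <- function(x, cc, m = 2, tol = 1e-5, maxIter = 100, seed = 1) {
  n <- length(x)
  set.seed(seed)
  U <- matrix(runif(n * cc), n, cc)
  for (j in seq_len(n)) U[j, ] <- U[j, ] / sum(U[j, ])
  jPrev <- Inf
  trace <- numeric(0)
  for (iter in seq_len(maxIter)) {
    ctr <- numeric(cc)
    for (i in seq_len(cc)) {
      num <- 0; den <- 0
      for (j in seq_len(n)) {
        w <- U[j, i]^m
        num <- num + w * x[j]; den <- den + w
      }
      ctr[i] <- num / den
    }
    for (j in seq_len(n)) {
      d <- abs(ctr - x[j])
      if (any(d == 0)) {
        U[j, ] <- 0
        U[j, which(d == 0)[1]] <- 1
      } else {
        for (i in seq_len(cc))
          U[j, i] <- 1 / sum((d[i] / d)^(2 / (m - 1)))
      }
    }
    J <- 0
    for (i in seq_len(cc)) for (j in seq_len(n))
      J <- J + U[j, i]^m * (ctr[i] - x[j])^2
    trace <- c(trace, J)
    if ((is.finite(jPrev) && abs(jPrev - J) < tol) || J < tol) break
    jPrev <- J
  }
  list(U = U, centers = ctr, J = trace[length(trace)], trace = trace)
}

# Exhaustive best-first region growing: each step rescans every
# unaccepted domain pixel 4-adjacent to the region
rgOracle <- function(image, seeds, maxdis, domain = NULL) {
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(domain)) domain <- matrix(TRUE, nr, nc)
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2)
  region <- matrix(FALSE, nr, nc)
  means <- numeric(0)
  adjacentCandidates <- function() {
    cand <- NULL
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (region[r, cc] || !domain[r, cc]) next
      nb <- rbind(c(r - 1, cc), c(r + 1, cc), c(r, cc - 1), c(r, cc + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc, ,
               drop = FALSE]
      if (nrow(nb) && any(region[nb])) cand <- rbind(cand, c(r, cc))
    }
    cand
  }
  for (s in seq_len(nrow(seeds))) {
    sr <- seeds[s, 1]; sc <- seeds[s, 2]
    if (region[sr, sc]) next
    region[sr, sc] <- TRUE
    means <- c(means, mean(image[region]))
    repeat {
      cand <- adjacentCandidates()
      if (is.null(cand)) break
      mu <- mean(image[region])
      d <- abs(image[cand] - mu)
      if (min(d) > maxdis) break
      best <- which(d == min(d))
      if (length(best) > 1)
        best <- best[order(cand[best, 1], cand[best, 2])[1]]
      region[cand[best, 1], cand[best, 2]] <- TRUE
      means <- c(means, mean(image[region]))
    }
  }
  list(region = region, means = means)
}

# Set-shifting binary morphology with the same Euclidean-disk element
diskOffsets <- function(radius) {
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off[off$dr^2 + off$dc^2 <= radius^2, ]
}

shiftOracle <- function(mask, dr, dc) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  vr <- rs >= 1 & rs <= nr; vc <- cs >= 1 & cs <= nc
  out[vr, vc] <- mask[rs[vr], cs[vc]]
  out
}

erodeOracle <- function(mask, radius) {
  off <- diskOffsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shiftOracle(mask, -off$dr[i], -off$dc[i])
  out
}

dilateOracle <- function(mask, radius) {
  off <- diskOffsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shiftOracle(mask, off$dr[i], off$dc[i])
  out
}

# Opening/closing as set algebra on the plane: pad so the dilation
# intermediate of the closing is not clipped at the image frame
padOracle <- function(mask, r) {
  out <- matrix(FALSE, nrow(mask) + 2 * r, ncol(mask) + 2 * r)
  out[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))] <- mask
  out
}
cropOracle <- function(mask, r, dims)
  mask[r + seq_len(dims[1]), r + seq_len(dims[2])]

openOracle <- function(mask, radius) {
  p <- padOracle(mask, 2 * radius)
  cropOracle(dilateOracle(erodeOracle(p, radius), radius), 2 * radius,
             dim(mask))
}
closeOracle <- function(mask, radius) {
  p <- padOracle(mask, 2 * radius)
  cropOracle(erodeOracle(dilateOracle(p, radius), radius), 2 * radius,
             dim(mask))
}

# A random single-component, hole-free blob (for round-trip tests)
randomBlob <- function(dims = c(24, 24), p = 0.45) {
  repeat {
    m <- matrix(runif(prod(dims)) < p, dims[1], dims[2])
    m[1, ] <- m[dims[1], ] <- m[, 1] <- m[, dims[2]] <- FALSE
    m <- binaryClose(m, 1)
    if (!any(m)) next
    m <- fillHoles(largestComponent(m))
    if (sum(m) >= 4) return(m)
  }
}

# Digital disk mask (radius R) centered in an n x n canvas
diskMask <- function(R, n = 2 * R + 5) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) (i - ctr)^2 + (j - ctr)^2 <= R^2)
}
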