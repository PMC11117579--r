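# Synthetic transverse disc phantoms. A phantom is a painted three-level
# image (background / annulus / nucleus) whose outer boundary is an oval or
# kidney-shaped curve, blurred and corrupted by noise, together with the
# exact ground-truth masks it was painted from. Every downstream stage of
# the package is testable against these phantoms without scan data.

#' Construct a phantom specification
#'
#' Defaults describe a plausible lumbar disc on a T2-weighted transverse
#' slice: a bright nucleus (NP) inside a darker annulus (AF) on a dark
#' background, nucleus occupying 30--50\% of the disc area, a blurred
#' NP/AF boundary, and mild additive noise. See [PhantomSpec-class] for
#' slot meanings.
#'
#' @param imageDim integer(2), canvas rows and columns.
#' @param semiAxes numeric(2), disc semi-axes in pixels (column axis
#'   first).
#' @param shape \code{"oval"} or \code{"kidney"}.
#' @param kidneyIndent posterior indentation depth in [0, 1).
#' @param npTargetRatio intended CSA_NP / CSA_IVD in (0, 1).
#' @param npCenterOffset numeric(2), NP center offset (row, col) px.
#' @param intensities named numeric(3): background, af, np on [0, 1].
#' @param blurSigma Gaussian blur sd in pixels.
#' @param noiseSd additive Gaussian noise sd.
#' @param seed integer RNG seed.
#' @param spacingMm numeric(2), physical pixel spacing (row, col) in mm.
#' @return A validated [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(npTargetRatio = 0.4, seed = 7)
#' ph <- generatePhantom(spec)
#' trueRatio(ph)
#' @export
phantomSpec <- function(imageDim = c(128L, 128L),
                        semiAxes = c(39, 28),
                        shape = c("oval", "kidney"),
                        kidneyIndent = 0.3,
                        npTargetRatio = 0.4,
                        npCenterOffset = c(0, 0),
                        intensities = c(background = 0.10, af = 0.35, np = 0.75),
                        blurSigma = 1,
                        noiseSd = 0.02,
                        seed = 1L,
                        spacingMm = c(0.69, 0.69)) {
  shape <- match.arg(shape)
  new("PhantomSpec",
      imageDim = as.integer(imageDim), semiAxes = as.numeric(semiAxes),
      shape = shape, kidneyIndent = as.numeric(kidneyIndent),
      npTargetRatio = as.numeric(npTargetRatio),
      npCenterOffset = as.numeric(npCenterOffset),
      intensities = intensities, blurSigma = as.numeric(blurSigma),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed),
      spacingMm = as.numeric(spacingMm))
}

#' Boundary curve of the phantom disc
#'
#' Points on the closed outer disc curve, relative to the disc center, as
#' (column, row) offsets. The oval template is the ellipse
#' \eqn{(a\cos\theta, b\sin\theta)}; the kidney template scales the
#' posterior half (\eqn{\cos\theta < 0}) radially by
#' \eqn{1 - d\cos^2\theta}, a cosine-windowed indentation of depth
#' \eqn{d} that tapers smoothly to the oval at \eqn{\theta = \pi/2} and
#' \eqn{3\pi/2}.
#'
#' @param spec a [PhantomSpec-class].
#' @param theta numeric vector of angles in radians.
#' @return Numeric matrix length(theta) x 2 with columns \code{dcol},
#'   \code{drow}: offsets from the disc center.
#' @export
boundaryCurve <- function(spec, theta) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  a <- spec@semiAxes[1]; b <- spec@semiAxes[2]
  s <- rep(1, length(theta))
  if (spec@shape == "kidney") {
    post <- cos(theta) < 0
    s[post] <- 1 - spec@kidneyIndent * cos(theta[post])^2
  }
  cbind(dcol = a * cos(theta) * s, drow = b * sin(theta) * s)
}

# Closed polygon (row, col) of the disc boundary scaled by `scale` about
# `center` (row, col).
phantomPolygon <- function(spec, center, scale = 1, nTheta = 192L) {
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  bc <- boundaryCurve(spec, th)
  cbind(center[1] + scale * bc[, "drow"], center[2] + scale * bc[, "dcol"])
}

#' Generate a synthetic disc phantom
#'
#' Paints background, annulus and nucleus at the spec's intensities, then
#' applies Gaussian blur and additive Gaussian noise (clipped to [0, 1]).
#' The nucleus boundary is a scaled, optionally offset copy of the outer
#' curve; its scale is searched so that the pixel-count area ratio lands
#' within 2 percentage points of \code{npTargetRatio} (the scaled-copy
#' construction guarantees NP \eqn{\subseteq} IVD). Deterministic given
#' the spec's seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [DiscPhantom-class] with the image, ground-truth masks, the
#'   outer contour polygon and the exact mask-derived ratio.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  dims <- spec@imageDim
  center <- (dims + 1) / 2
  ivdPoly <- phantomPolygon(spec, center)
  if (min(ivdPoly[, 1]) < 1 || max(ivdPoly[, 1]) > dims[1] ||
      min(ivdPoly[, 2]) < 1 || max(ivdPoly[, 2]) > dims[2])
    stop("disc does not fit in the image; reduce semiAxes or enlarge imageDim")
  ivd <- rasterizeContour(ivdPoly, dims)
  nIvd <- sum(ivd)
  npCenter <- center + spec@npCenterOffset

  npMaskAt <- function(s) rasterizeContour(phantomPolygon(spec, npCenter, s), dims)
  insideAt <- function(s) {
    m <- npMaskAt(s)
    list(mask = m, inside = !any(m & !ivd), ratio = sum(m) / nIvd)
  }
  # largest scale keeping the NP strictly inside the disc
  sHi <- 0.99
  while (sHi > 0.05 && !insideAt(sHi)$inside) sHi <- sHi - 0.02
  cand <- insideAt(sHi)
  if (cand$ratio < spec@npTargetRatio - 0.02)
    stop("npTargetRatio unreachable: NP would cross the IVD boundary ",
         "(max attainable ratio ", round(100 * cand$ratio, 1), "%)")
  # area scales ~ s^2, so start near the analytic guess and bisect
  lo <- 0.02; hi <- sHi
  s <- min(sHi, sqrt(spec@npTargetRatio))
  for (i in 1:24) {
    r <- insideAt(s)$ratio
    if (abs(r - spec@npTargetRatio) * 100 <= 0.5) break
    if (r > spec@npTargetRatio) hi <- s else lo <- s
    s <- (lo + hi) / 2
  }
  np <- npMaskAt(s)

  ints <- spec@intensities
  img <- matrix(ints[["background"]], dims[1], dims[2])
  img[ivd] <- ints[["af"]]
  img[np] <- ints[["np"]]
  img <- withSeed(spec@seed, {
    if (spec@blurSigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = spec@blurSigma))
    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec@noiseSd),
                          dims[1], dims[2])
    pmin(pmax(img, 0), 1)
  })

  new("DiscPhantom", image = img, ivdMask = ivd, npMask = np,
      ivdContour = ivdPoly, trueRatio = 100 * sum(np) / nIvd, spec = spec)
}

#' Generate the phantom validation study
#'
#' A fixed-condition batch of phantoms emulating the variability of a
#' transverse lumbar series: target NP ratios drawn uniformly from
#' 30--50\%, alternating oval and kidney outer shapes, disc semi-axes
#' spanning the reported adult lumbar range (about 50--58 mm wide and
#' 36--43 mm deep at the 0.69 mm pixel spacing), mildly varying NP
#' center offset, blur 1 px and noise sd 0.02.
#' These are the conditions under which the package's recovery claims
#' are evaluated. Deterministic given \code{seed}.
#'
#' @param n number of phantoms.
#' @param seed integer seed; per-phantom seeds are derived from it.
#' @param noiseSd,blurSigma noise and blur levels shared by the batch.
#' @return List of [DiscPhantom-class] objects.
#' @export
phantomStudy <- function(n = 50, seed = 1L, noiseSd = 0.02, blurSigma = 1) {
  pars <- withSeed(seed, data.frame(
    ratio = stats::runif(n, 0.30, 0.50),
    a = stats::runif(n, 36, 42),
    b = stats::runif(n, 26, 31),
    offR = stats::runif(n, -2, 2),
    offC = stats::runif(n, -2, 2),
    kidney = rep_len(c(FALSE, TRUE), n),
    indent = stats::runif(n, 0.15, 0.35),
    sub = sample.int(1e6, n)
  ))
  lapply(seq_len(n), function(i) {
    p <- pars[i, ]
    generatePhantom(phantomSpec(
      semiAxes = c(p$a, p$b),
      shape = if (p$kidney) "kidney" else "oval",
      kidneyIndent = p$indent,
      npTargetRatio = p$ratio,
      npCenterOffset = c(p$offR, p$offC),
      blurSigma = blurSigma, noiseSd = noiseSd,
      seed = p$sub))
  })
}
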