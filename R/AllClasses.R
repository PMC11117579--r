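#' @import methods
NULL

#' Specification of a synthetic disc phantom
#'
#' A \code{PhantomSpec} fixes everything needed to draw one synthetic
#' transverse disc image: canvas size, outer disc shape (oval or kidney),
#' the intended nucleus-to-disc area ratio, tissue intensities, blur and
#' noise levels, and the random seed. On T2-weighted images the nucleus
#' pulposus (NP) is hyperintense relative to the annulus fibrosus (AF),
#' which in turn is brighter than the suppressed background; the validity
#' method enforces that ordering.
#'
#' @slot imageDim integer(2), image height and width in pixels.
#' @slot semiAxes numeric(2), disc semi-axes in pixels; the first axis runs
#'   along columns (left-right), the second along rows.
#' @slot shape either \code{"oval"} or \code{"kidney"}.
#' @slot kidneyIndent indentation depth of the kidney concavity in
#'   \code{[0, 1)}; 0 degenerates to the oval.
#' @slot npTargetRatio intended CSA_NP / CSA_IVD in (0, 1).
#' @slot npCenterOffset numeric(2), NP center offset from the disc center
#'   in pixels (row, col).
#' @slot intensities named numeric(3) with elements \code{background},
#'   \code{af}, \code{np}, on a [0, 1] scale.
#' @slot blurSigma Gaussian blur standard deviation in pixels.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot seed integer RNG seed; phantoms are reproducible given the spec.
#' @slot spacingMm numeric(2), physical pixel spacing (row, col) in mm.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    imageDim = "integer",
    semiAxes = "numeric",
    shape = "character",
    kidneyIndent = "numeric",
    npTargetRatio = "numeric",
    npCenterOffset = "numeric",
    intensities = "numeric",
    blurSigma = "numeric",
    noiseSd = "numeric",
    seed = "integer",
    spacingMm = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@imageDim) != 2L || any(object@imageDim < 8L))
    msg <- c(msg, "imageDim must be two integers >= 8")
  if (length(object@semiAxes) != 2L || any(object@semiAxes <= 0))
    msg <- c(msg, "semiAxes must be two positive reals")
  if (!object@shape %in% c("oval", "kidney"))
    msg <- c(msg, "shape must be 'oval' or 'kidney'")
  if (object@kidneyIndent < 0 || object@kidneyIndent >= 1)
    msg <- c(msg, "kidneyIndent must lie in [0, 1)")
  if (object@npTargetRatio <= 0 || object@npTargetRatio >= 1)
    msg <- c(msg, "npTargetRatio must lie in (0, 1)")
  ints <- object@intensities
  if (!all(c("background", "af", "np") %in% names(ints)))
    msg <- c(msg, "intensities must be named background/af/np")
  else if (!(ints[["np"]] > ints[["af"]] && ints[["af"]] > ints[["background"]]))
    msg <- c(msg, "need intensity np > af > background (T2: NP hyperintense)")
  if (any(ints < 0) || any(ints > 1))
    msg <- c(msg, "intensities must lie in [0, 1]")
  if (object@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (any(object@spacingMm <= 0)) msg <- c(msg, "spacingMm must be positive")
  if (length(msg)) msg else TRUE
})

#' Synthetic disc phantom with ground truth
#'
#' The output of [generatePhantom()]: a grayscale image together with the
#' true disc (IVD) and nucleus (NP) masks it was painted from, the outer
#' IVD contour, and the true NP-to-CSA ratio. The true ratio is defined
#' from the masks themselves (pixel counts), so segmentation results can
#' be scored against an exact reference.
#'
#' @slot image numeric matrix, intensities in [0, 1].
#' @slot ivdMask,npMask logical matrices, ground-truth region masks.
#' @slot ivdContour numeric matrix (n x 2, row/col) of the closed outer
#'   disc polygon (last vertex connects back to the first implicitly).
#' @slot trueRatio true NP-to-CSA ratio in percent.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("DiscPhantom",
  representation(
    image = "matrix",
    ivdMask = "matrix",
    npMask = "matrix",
    ivdContour = "matrix",
    trueRatio = "numeric",
    spec = "PhantomSpec"
  )
)

setValidity("DiscPhantom", function(object) {
  msg <- character()
  if (!is.logical(object@ivdMask) || !is.logical(object@npMask))
    msg <- c(msg, "masks must be logical matrices")
  else {
    if (any(object@npMask & !object@ivdMask))
      msg <- c(msg, "np mask must be a subset of the ivd mask")
    r <- 100 * sum(object@npMask) / sum(object@ivdMask)
    if (abs(r - object@trueRatio) > 1e-9)
      msg <- c(msg, "trueRatio must equal 100*|NP|/|IVD| from the masks")
  }
  if (length(msg)) msg else TRUE
})

#' Fuzzy C-means partition
#'
#' State returned by [fcmCluster()]: the membership matrix U (objects in
#' rows, clusters in columns — note that each object's memberships across
#' clusters sum to one), the cluster centers in intensity space, the final
#' objective value and its per-iteration trace.
#'
#' @slot membership n x c membership matrix; rows sum to 1.
#' @slot centers numeric(c), cluster centers.
#' @slot objective final value of the fuzzy within-cluster objective.
#' @slot objectiveTrace objective value after each iteration.
#' @slot nIter iterations run.
#' @slot converged FALSE when the iteration cap was hit before the
#'   tolerance was met (flagged, not an error).
#' @slot m fuzziness exponent used.
#' @export
setClass("FuzzyPartition",
  representation(
    membership = "matrix",
    centers = "numeric",
    objective = "numeric",
    objectiveTrace = "numeric",
    nIter = "integer",
    converged = "logical",
    m = "numeric"
  )
)

setValidity("FuzzyPartition", function(object) {
  msg <- character()
  U <- object@membership
  if (ncol(U) != length(object@centers))
    msg <- c(msg, "ncol(membership) must match length(centers)")
  if (nrow(U) > 0 && max(abs(rowSums(U) - 1)) > 1e-9)
    msg <- c(msg, "membership rows must sum to 1 (tol 1e-9)")
  if (any(U < 0) || any(U > 1))
    msg <- c(msg, "memberships must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
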