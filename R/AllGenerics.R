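#' Accessors for discmorph S4 objects
#'
#' Small accessor generics for the [PhantomSpec-class], [DiscPhantom-class]
#' and [FuzzyPartition-class] objects. Prefer these over direct slot access.
#'
#' @param object a discmorph S4 object.
#' @return The corresponding component: a matrix for image/mask/membership
#'   accessors, a numeric for centers and ratios.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))
#' @rdname accessors
#' @export
setGeneric("ivdMask", function(object) standardGeneric("ivdMask"))
#' @rdname accessors
#' @export
setGeneric("npMask", function(object) standardGeneric("npMask"))
#' @rdname accessors
#' @export
setGeneric("ivdContour", function(object) standardGeneric("ivdContour"))
#' @rdname accessors
#' @export
setGeneric("trueRatio", function(object) standardGeneric("trueRatio"))
#' @rdname accessors
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(object) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @rdname accessors
setMethod("phantomImage", "DiscPhantom", function(object) object@image)
#' @rdname accessors
setMethod("ivdMask", "DiscPhantom", function(object) object@ivdMask)
#' @rdname accessors
setMethod("npMask", "DiscPhantom", function(object) object@npMask)
#' @rdname accessors
setMethod("ivdContour", "DiscPhantom", function(object) object@ivdContour)
#' @rdname accessors
setMethod("trueRatio", "DiscPhantom", function(object) object@trueRatio)
#' @rdname accessors
setMethod("membership", "FuzzyPartition", function(object) object@membership)
#' @rdname accessors
setMethod("clusterCenters", "FuzzyPartition", function(object) object@centers)
#' @rdname accessors
setMethod("objectiveTrace", "FuzzyPartition", function(object) object@objectiveTrace)

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@imageDim[1], "x", object@imageDim[2], "px,",
      object@shape, "disc\n")
  cat("  semi-axes (col,row):", paste(object@semiAxes, collapse = " x "),
      "px; target NP ratio:", sprintf("%.1f%%", 100 * object@npTargetRatio), "\n")
  cat("  intensities bg/af/np:",
      paste(sprintf("%.2f", object@intensities), collapse = "/"),
      "; blur:", object@blurSigma, "px; noise sd:", object@noiseSd,
      "; seed:", object@seed, "\n")
})

setMethod("show", "DiscPhantom", function(object) {
  cat("DiscPhantom:", nrow(object@image), "x", ncol(object@image), "px\n")
  cat("  CSA_IVD:", sum(object@ivdMask), "px; CSA_NP:", sum(object@npMask),
      "px; true NP-to-CSA ratio:", sprintf("%.2f%%", object@trueRatio), "\n")
})

setMethod("show", "FuzzyPartition", function(object) {
  cat("FuzzyPartition:", nrow(object@membership), "objects,",
      length(object@centers), "clusters (m =", object@m, ")\n")
  cat("  centers:", paste(sprintf("%.4f", object@centers), collapse = ", "), "\n")
  cat("  objective:", format(object@objective), "after", object@nIter,
      "iterations;", if (object@converged) "converged" else "NOT converged", "\n")
})
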