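# Cross-sectional areas and the NP-to-CSA ratio: the target morphometric
# is Ratio = CSA_NP / CSA_IVD * 100, the percentage of the transverse
# disc area occupied by the nucleus.

#' Area of a binary mask
#'
#' Pixel count, scaled to mm^2 when the physical pixel spacing is given.
#'
#' @param mask logical matrix (nonempty).
#' @param spacingMm optional numeric(2), pixel spacing (row, col) in mm;
#'   when NULL the area is in px^2.
#' @return Scalar area.
#' @examples
#' maskArea(matrix(TRUE, 10, 10), spacingMm = c(0.69, 0.69))  # 47.61 mm^2
#' @export
maskArea <- function(mask, spacingMm = NULL) {
  stopifnot(is.logical(mask))
  n <- sum(mask)
  if (n == 0) stop("empty mask has no area")
  if (is.null(spacingMm)) return(as.numeric(n))
  stopifnot(length(spacingMm) == 2, all(spacingMm > 0))
  n * spacingMm[1] * spacingMm[2]
}

#' NP-to-CSA ratio
#'
#' \eqn{Ratio = 100 \cdot CSA_{NP} / CSA_{IVD}}. The nucleus is contained
#' in the disc by anatomy, so \code{csaNp > csaIvd} indicates a
#' segmentation artifact: the ratio is then clipped to 100 with a
#' warning.
#'
#' @param csaNp nucleus area.
#' @param csaIvd disc area (> 0), in the same units.
#' @return Ratio in percent.
#' @export
npToCsaRatio <- function(csaNp, csaIvd) {
  if (csaIvd <= 0) stop("csaIvd must be positive")
  if (csaNp < 0) stop("csaNp must be nonnegative")
  if (csaNp > csaIvd) {
    warning("csaNp exceeds csaIvd; ratio clipped to 100%")
    return(100)
  }
  100 * csaNp / csaIvd
}

#' Assemble a ratio record
#'
#' One row of the statistical analysis table: areas, ratio, method and
#' disc metadata.
#'
#' @param csaNp,csaIvd areas (same units).
#' @param method one of \code{"manual"}, \code{"fcm"}, \code{"rg"}.
#' @param subjectId opaque subject label.
#' @param level disc level label (e.g. \code{"L4/L5"}).
#' @param gender \code{"F"}, \code{"M"} or \code{"unknown"}.
#' @return A one-row data.frame with columns subject_id, level, gender,
#'   method, csa_np, csa_ivd, ratio_percent.
#' @export
ratioRecord <- function(csaNp, csaIvd, method = c("manual", "fcm", "rg"),
                        subjectId = NA_character_, level = NA_character_,
                        gender = c("unknown", "F", "M")) {
  method <- match.arg(method)
  gender <- match.arg(gender)
  data.frame(subject_id = subjectId, level = level, gender = gender,
             method = method, csa_np = csaNp, csa_ivd = csaIvd,
             ratio_percent = npToCsaRatio(csaNp, csaIvd),
             stringsAsFactors = FALSE)
}
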