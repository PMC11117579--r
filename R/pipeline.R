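# End-to-end orchestration: normalize -> K-means crop -> segment (FCM
# and/or RG) -> morphological cleanup -> optional parametric refinement
# -> NP-to-CSA ratio, for one image or for a batch manifest.

#' Segment the nucleus of one traced disc image
#'
#' Runs the full measurement chain for a single transverse disc image
#' with its manually traced outer contour: intensity normalization,
#' K-means crop to the disc, nucleus segmentation by fuzzy C-means and/or
#' region growing, morphological cleanup, optional elliptic-Fourier
#' profile refinement, and the NP-to-CSA ratio.
#'
#' For the FCM route the raw nucleus cluster is cleaned with
#' [removeInterference()] and interior holes are filled before the
#' outline is taken; for the RG route growth starts from \code{rgSeeds}
#' (or an automatically proposed near-boundary seed) restricted to the
#' traced disc, followed by [morphoCleanup()]. When \code{refine} is
#' TRUE the mask outline is replaced by its order-\code{harmonics}
#' parametric fit and re-rasterized (clipped to the disc) before areas
#' are measured. When no manual seeds are given the RG route grows from
#' four automatically proposed near-boundary restart points
#' ([proposeSeeds()]), which makes it robust to a single seed landing in
#' a noise pocket.
#'
#' @param image numeric matrix, the grayscale image.
#' @param contour numeric matrix n x 2 (row, col), traced IVD outline.
#' @param methods subset of \code{c("fcm", "rg")}.
#' @param fcmClusters,fcmM,fcmTol,fcmMaxIter fuzzy C-means settings.
#' @param maxdis region-growing acceptance threshold.
#' @param rgSeeds optional seed pixels for RG in full-image (row, col)
#'   coordinates; NULL invokes [proposeSeeds()].
#' @param cleanupRadius disk radius for the morphological cleanup.
#' @param refine logical, apply the parametric profile constraint.
#' @param harmonics elliptic-Fourier order of the refinement.
#' @param seed integer seed for all stochastic stages.
#' @param spacingMm optional numeric(2) pixel spacing in mm.
#' @param subjectId,level,gender metadata copied into the records.
#' @return List with \code{records} (one data.frame row per method, see
#'   [ratioRecord()]), \code{masks} (named list of full-frame logical NP
#'   masks), \code{contours} (named list of refined or raw NP outlines in
#'   full-image coordinates) and \code{ivdMask}.
#' @examples
#' ph <- generatePhantom(phantomSpec(noiseSd = 0, blurSigma = 0))
#' res <- segmentDisc(phantomImage(ph), ivdContour(ph), methods = "fcm")
#' res$records$ratio_percent
#' @export
segmentDisc <- function(image, contour, methods = c("fcm", "rg"),
                        fcmClusters = 3, fcmM = 2, fcmTol = 1e-5,
                        fcmMaxIter = 100L, maxdis = 0.06, rgSeeds = NULL,
                        cleanupRadius = 2, refine = TRUE, harmonics = 4L,
                        seed = 1L, spacingMm = NULL,
                        subjectId = NA_character_, level = NA_character_,
                        gender = "unknown") {
  methods <- match.arg(methods, c("fcm", "rg"), several.ok = TRUE)
  img <- normalizeIntensity(image)
  crop <- kmeansCrop(img, contour, k = 3, seed = seed)
  ivdFull <- rasterizeContour(contour, dim(img))
  csaIvd <- maskArea(ivdFull, spacingMm)
  off <- c(crop$bbox[1] - 1L, crop$bbox[3] - 1L)

  toFull <- function(maskCrop) {
    full <- matrix(FALSE, nrow(img), ncol(img))
    full[off[1] + seq_len(nrow(maskCrop)), off[2] + seq_len(ncol(maskCrop))] <-
      maskCrop
    full
  }

  masks <- list(); contours <- list(); records <- list()
  for (method in methods) {
    cleaned <- if (method == "fcm") {
      part <- fcmCluster(crop$image, c = fcmClusters,
                         m = fcmM, tol = fcmTol, maxIter = fcmMaxIter,
                         seed = seed)
      raw <- selectNpCluster(part, crop$discMask)
      fillHoles(removeInterference(raw, cleanupRadius))
    } else {
      seeds <- if (is.null(rgSeeds)) {
        proposeSeeds(crop$image, crop$discMask, n = 4L, seed = seed)
      } else {
        s <- matrix(as.integer(rgSeeds), ncol = 2)
        cbind(s[, 1] - off[1], s[, 2] - off[2])
      }
      grown <- regionGrow(crop$image, seeds, maxdis = maxdis,
                          domain = crop$discMask)
      morphoCleanup(grown, cleanupRadius)
    }
    npContour <- extractContour(cleaned)
    npCrop <- cleaned
    if (refine) {
      fitted <- fitParametricProfile(npContour, harmonics = harmonics)
      refined <- rasterizeContour(fitted, dim(cleaned)) & crop$discMask
      if (any(refined)) {
        npCrop <- refined
        npContour <- fitted
      }
    }
    npFull <- toFull(npCrop) & ivdFull
    masks[[method]] <- npFull
    contours[[method]] <- cbind(row = npContour[, 1] + off[1],
                                col = npContour[, 2] + off[2])
    records[[method]] <- ratioRecord(
      csaNp = maskArea(npFull, spacingMm), csaIvd = csaIvd,
      method = method, subjectId = subjectId, level = level,
      gender = gender)
  }
  list(records = do.call(rbind, records), masks = masks,
       contours = contours, ivdMask = ivdFull)
}

#' Run the measurement pipeline over a batch manifest
#'
#' Processes each manifest row (an image file plus its traced contour and
#' metadata) through [segmentDisc()], writing per-image NP masks and
#' contours, a combined \code{ratios.csv} and a JSON run log of all
#' effective parameters. Rows that fail are logged and skipped; the
#' function errors only when every row fails. Deterministic given
#' \code{seed} (each row derives its own sub-seed).
#'
#' @param manifest data.frame with columns \code{image}, \code{contour}
#'   (file paths) and optional \code{subject_id}, \code{level},
#'   \code{gender}; or the path of such a CSV file.
#' @param outDir output directory (created if missing).
#' @param methods subset of \code{c("fcm", "rg")}.
#' @param seed global integer seed.
#' @param spacingMm optional numeric(2) pixel spacing in mm.
#' @param ... further arguments passed to [segmentDisc()].
#' @return The ratio table (also written to \code{ratios.csv}),
#'   invisibly.
#' @export
runPipeline <- function(manifest, outDir, methods = c("fcm", "rg"),
                        seed = 1L, spacingMm = NULL, ...) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stopifnot(all(c("image", "contour") %in% names(manifest)))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (col in c("subject_id", "level", "gender"))
    if (is.null(manifest[[col]]))
      manifest[[col]] <- if (col == "gender") "unknown" else NA_character_

  records <- list(); failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      img <- readGrayImage(row$image)
      ct <- readContour(row$contour)
      segmentDisc(img, ct, methods = methods, seed = seed + i,
                  spacingMm = spacingMm, subjectId = row$subject_id,
                  level = row$level, gender = row$gender, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("row %d (%s): %s", i, row$image,
                                      conditionMessage(res)))
      message("skipping ", row$image, ": ", conditionMessage(res))
      next
    }
    stem <- sprintf("%03d", i)
    for (method in names(res$masks)) {
      writeImagePNG(res$masks[[method]],
                    file.path(outDir, paste0("np_", method, "_", stem, ".png")))
      writeContour(res$contours[[method]],
                   file.path(outDir,
                             paste0("np_", method, "_", stem, ".json")))
    }
    records[[length(records) + 1L]] <- res$records
  }
  if (!length(records))
    stop("all manifest rows failed:\n", paste(failures, collapse = "\n"))
  ratios <- do.call(rbind, records)
  rownames(ratios) <- NULL
  utils::write.csv(ratios, file.path(outDir, "ratios.csv"), row.names = FALSE)
  log <- list(
    n_rows = nrow(manifest), n_processed = length(records),
    methods = methods, seed = seed, spacing_mm = spacingMm,
    extra_args = names(list(...)), failures = failures,
    timestamp_free = TRUE)
  jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(ratios)
}
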