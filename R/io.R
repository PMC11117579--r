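# Image and contour file I/O. Images are 8/16-bit PNG (read via the png
# package, intensities already on [0, 1]); contours are JSON vertex lists
# {"vertices": [[row, col], ...]} or two-column CSV with columns row, col.

#' Read a grayscale image from PNG
#'
#' Color images are converted to grayscale by channel averaging; an alpha
#' channel is ignored. Intensities are returned on [0, 1].
#'
#' @param path PNG file path.
#' @return Numeric matrix of intensities in [0, 1] (rows = image rows).
#' @export
readGrayImage <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    nc <- min(dim(a)[3], 3L)
    a <- apply(a[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  a
}

#' Write a grayscale image or binary mask to PNG
#'
#' Masks are written as 0/255 binary PNGs; images as 8-bit grayscale.
#'
#' @param x numeric matrix in [0, 1] (image) or logical matrix (mask).
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
writeImagePNG <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.numeric(x), nrow(x), ncol(x))
  stopifnot(is.matrix(x), all(x >= 0), all(x <= 1))
  png::writePNG(x, path)
  invisible(path)
}

#' Read and write closed contours
#'
#' A contour is an ordered list of (row, col) vertices describing a closed
#' polygon in pixel coordinates (pixel centers at integers, matrix frame).
#' JSON files hold \code{{"vertices": [[row, col], ...]}}; CSV files hold
#' two columns named row, col.
#'
#' @param path file path; format chosen by extension (.json/.csv).
#' @return \code{readContour}: numeric matrix n x 2 with columns row, col.
#' @export
readContour <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- if (ext == "json") {
    j <- jsonlite::fromJSON(path)
    if (is.null(j$vertices)) stop("contour JSON must contain 'vertices'")
    matrix(as.numeric(as.matrix(j$vertices)), ncol = 2)
  } else if (ext == "csv") {
    d <- utils::read.csv(path)
    if (!all(c("row", "col") %in% names(d)))
      stop("contour CSV must have columns 'row' and 'col'")
    cbind(d$row, d$col)
  } else stop("unsupported contour format: ", ext)
  if (nrow(v) < 3) stop("a closed contour needs at least 3 vertices")
  colnames(v) <- c("row", "col")
  v
}

#' @rdname readContour
#' @param verts numeric matrix n x 2 (row, col).
#' @export
writeContour <- function(verts, path) {
  stopifnot(is.matrix(verts), ncol(verts) == 2)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(vertices = unname(verts)), path, digits = NA)
  } else if (ext == "csv") {
    utils::write.csv(data.frame(row = verts[, 1], col = verts[, 2]),
                     path, row.names = FALSE)
  } else stop("unsupported contour format: ", ext)
  invisible(path)
}
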