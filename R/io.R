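.file_kind <- function(path) {
  magic <- readBin(path, "raw", n = 132L)
  if (length(magic) >= 132L && rawToChar(magic[129:132]) == "DICM")
    return("dicom")
  if (length(magic) >= 8L &&
      identical(as.integer(magic[1:8]),
                c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)))
    return("png")
  if (length(magic) >= 4L &&
      (identical(as.integer(magic[1:4]), c(73L, 73L, 42L, 0L)) ||
       identical(as.integer(magic[1:4]), c(77L, 77L, 0L, 42L))))
    return("tiff")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom", "ima")) return("dicom")
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("unrecognized image format: ", path, call. = FALSE)
}

.flatten_gray <- function(arr, path) {
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    chans <- lapply(seq_len(min(nch, 3L)), function(k) arr[, , k])
    spread <- max(vapply(seq_along(chans)[-1], function(k)
      max(abs(chans[[k]] - chans[[1]])), numeric(1)), 0)
    if (nch > 1L && spread > 1e-6)
      stop("color images are not supported: ", path, call. = FALSE)
    arr <- chans[[1]]
  }
  arr
}

#' Read a brain slice as a normalized grayscale image
#'
#' Accepts single-frame grayscale DICOM, PNG, or TIFF (format sniffed from
#' the file magic, falling back to the extension). DICOM pixel values pass
#' through Rescale Slope/Intercept and, when Window Center/Width tags are
#' present, the linear VOI window; PNG/TIFF and unwindowed DICOM are min-max
#' scaled. The result always lies in `[0, 1]`; a constant slice maps to the
#' all-0.5 image.
#'
#' @param path path to the image file.
#' @return numeric intensity matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image, file not found: ", path, call. = FALSE)
  kind <- .file_kind(path)
  img <- switch(kind,
    dicom = read_dicom(path),
    png   = normalize_gray(.flatten_gray(png::readPNG(path), path)),
    tiff  = normalize_gray(.flatten_gray(tiff::readTIFF(path), path))
  )
  as_gray_image(img)
}

#' Write a binary mask as an 8-bit PNG
#'
#' TRUE pixels become 255, FALSE pixels 0; [read_mask()] inverts the
#' encoding bit-exactly.
#'
#' @param mask logical matrix.
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  storage.mode(mask) <- "double"
  png::writePNG(mask, path, dpi = NULL)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path path to an 8-bit PNG mask.
#' @return logical matrix (`TRUE` where pixel > 127).
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop("cannot read mask, file not found: ", path, call. = FALSE)
  arr <- .flatten_gray(png::readPNG(path), path)
  arr > 0.5
}

#' Write a grayscale image as an 8-bit PNG
#'
#' Used by the CLI's verbose mode to export pipeline intermediates. Values
#' are clipped to `[0, 1]`.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  as_gray_image(image)
  png::writePNG(pmin(pmax(image, 0), 1), path, dpi = NULL)
  invisible(path)
}
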