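# Minimal single-frame DICOM codec.
#
# Scope: little-endian transfer syntaxes (implicit and explicit VR),
# single-frame grayscale (MONOCHROME1/2), 8- or 16-bit-allocated unsigned
# pixel data, which covers the routine MR export this package consumes.
# Sequences are skipped structurally; only the image-description and pixel
# tags below are retained.

.dcm_tags <- list(
  samples_per_pixel  = c(0x0028L, 0x0002L),
  photometric        = c(0x0028L, 0x0004L),
  n_frames           = c(0x0028L, 0x0008L),
  rows               = c(0x0028L, 0x0010L),
  cols               = c(0x0028L, 0x0011L),
  bits_allocated     = c(0x0028L, 0x0100L),
  bits_stored        = c(0x0028L, 0x0101L),
  high_bit           = c(0x0028L, 0x0102L),
  pixel_rep          = c(0x0028L, 0x0103L),
  window_center      = c(0x0028L, 0x1050L),
  window_width       = c(0x0028L, 0x1051L),
  rescale_intercept  = c(0x0028L, 0x1052L),
  rescale_slope      = c(0x0028L, 0x1053L),
  pixel_data         = c(0x7FE0L, 0x0010L)
)

.dcm_u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
.dcm_u32 <- function(raw4) {
  as.numeric(raw4[1]) + 256 * as.numeric(raw4[2]) +
    65536 * as.numeric(raw4[3]) + 16777216 * as.numeric(raw4[4])
}

# Parse a DICOM byte stream into the tag subset above.
.dcm_parse <- function(bytes) {
  n <- length(bytes)
  if (n > 132L && rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
  } else if (n > 4L) {
    pos <- 1L  # headerless stream, assume implicit VR LE
  } else stop("not a DICOM file", call. = FALSE)

  out <- list()
  explicit_vr <- NA  # decided per element; file meta group is always explicit
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

  while (pos + 8L <= n + 1L) {
    group <- .dcm_u16(bytes[pos:(pos + 1L)])
    elem  <- .dcm_u16(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    vr_guess <- rawToChar(bytes[pos:(pos + 1L)])
    is_explicit <- grepl("^[A-Z]{2}$", vr_guess)
    if (group == 0x0002L) is_explicit <- TRUE
    if (is_explicit) {
      vr <- vr_guess
      if (vr %in% long_vrs) {
        len <- .dcm_u32(bytes[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- .dcm_u16(bytes[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- .dcm_u32(bytes[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (!is.na(len) && len == 4294967295) {  # undefined length: skip to end
      stop("undefined-length DICOM elements are not supported", call. = FALSE)
    }
    if (pos + len - 1L > n) len <- n - pos + 1L
    value <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len

    for (nm in names(.dcm_tags)) {
      tg <- .dcm_tags[[nm]]
      if (group == tg[1] && elem == tg[2]) out[[nm]] <- value
    }
    if (group == 0x7FE0L && elem == 0x0010L) break  # pixel data is last
  }
  out
}

.dcm_str <- function(raw) if (is.null(raw)) NULL else trimws(rawToChar(raw))
.dcm_num <- function(raw) {
  s <- .dcm_str(raw)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]][1])
}
.dcm_us <- function(raw) if (is.null(raw)) NULL else .dcm_u16(raw[1:2])

#' Read a single-frame grayscale DICOM slice
#'
#' Applies, in order: Rescale Slope/Intercept (defaults 1/0 when absent),
#' then the linear VOI window defined by Window Center/Width when present
#' (clipped to `[0, 1]`), otherwise min-max scaling. MONOCHROME1 is inverted
#' to the MONOCHROME2 convention (bright = high).
#'
#' @param path path to a DICOM file.
#' @return numeric intensity matrix in `[0, 1]` (rows x cols).
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  el <- .dcm_parse(bytes)
  if (is.null(el$rows) || is.null(el$cols) || is.null(el$pixel_data))
    stop("DICOM file lacks Rows/Columns/PixelData: ", path, call. = FALSE)
  spp <- .dcm_us(el$samples_per_pixel)
  if (!is.null(spp) && spp != 1L)
    stop("unsupported DICOM: color (SamplesPerPixel != 1)", call. = FALSE)
  nf <- .dcm_num(el$n_frames)
  if (!is.null(nf) && nf > 1)
    stop("unsupported DICOM: multi-frame", call. = FALSE)
  rows <- .dcm_us(el$rows); cols <- .dcm_us(el$cols)
  bits <- .dcm_us(el$bits_allocated); if (is.null(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L))
    stop("unsupported DICOM: BitsAllocated = ", bits, call. = FALSE)
  npx <- rows * cols
  px <- el$pixel_data
  if (bits == 8L) {
    if (length(px) < npx) stop("truncated DICOM pixel data", call. = FALSE)
    v <- as.integer(px[seq_len(npx)])
  } else {
    if (length(px) < 2L * npx) stop("truncated DICOM pixel data", call. = FALSE)
    lo <- as.integer(px[seq(1L, 2L * npx, by = 2L)])
    hi <- as.integer(px[seq(2L, 2L * npx, by = 2L)])
    v <- lo + 256L * hi
    rep16 <- .dcm_us(el$pixel_rep)
    if (!is.null(rep16) && rep16 == 1L) v <- ifelse(v >= 32768L, v - 65536L, v)
  }
  # DICOM pixel data is row-major; fill by row.
  img <- matrix(as.numeric(v), nrow = rows, ncol = cols, byrow = TRUE)

  slope <- .dcm_num(el$rescale_slope); intercept <- .dcm_num(el$rescale_intercept)
  if (is.null(slope)) slope <- 1
  if (is.null(intercept)) intercept <- 0
  img <- img * slope + intercept

  wc <- .dcm_num(el$window_center); ww <- .dcm_num(el$window_width)
  if (!is.null(wc) && !is.null(ww) && ww > 0) {
    img <- (img - (wc - ww / 2)) / ww
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- c(rows, cols)
    if (diff(range(img)) <= 0) img[] <- 0.5
  } else {
    img <- normalize_gray(img)
  }
  phot <- .dcm_str(el$photometric)
  if (!is.null(phot) && toupper(phot) == "MONOCHROME1") img <- 1 - img
  img
}

.dcm_elem_explicit <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2L == 1L) {  # pad to even length per the standard
    pad <- if (vr %in% c("OB", "UI")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad); len <- len + 1L
  }
  head <- c(writeBin(c(group, elem), raw(), size = 2, endian = "little"))
  if (vr %in% c("OB", "OW")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(len), raw(), size = 4, endian = "little"), value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(as.integer(len), raw(), size = 2, endian = "little"), value_raw)
  }
}

#' Write a minimal synthetic DICOM slice
#'
#' Emits a single-frame explicit-VR little-endian MONOCHROME2 file carrying
#' only the image-description tags this package reads back. Intended for
#' synthetic phantoms and round-trip testing, not for clinical archives;
#' intensities in `[0, 1]` are quantized to the requested bit depth.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path.
#' @param bits_stored 8 or 12; 12-bit data is stored in 16 allocated bits.
#' @param window_center,window_width optional VOI window tags to embed.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(image, path, bits_stored = 8L,
                        window_center = NULL, window_width = NULL) {
  as_gray_image(image)
  if (!bits_stored %in% c(8L, 12L))
    stop("bits_stored must be 8 or 12", call. = FALSE)
  bits_alloc <- if (bits_stored == 8L) 8L else 16L
  vmax <- 2L^bits_stored - 1L
  v <- round(pmin(pmax(image, 0), 1) * vmax)
  v <- as.integer(t(v))  # row-major pixel order
  px <- if (bits_alloc == 8L) as.raw(v) else
    writeBin(v, raw(), size = 2, endian = "little")

  us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  ds <- function(x) charToRaw(format(x, digits = 10, scientific = FALSE))
  e <- .dcm_elem_explicit
  ts_uid <- charToRaw("1.2.840.10008.1.2.1")  # explicit VR little endian
  meta <- c(
    e(0x0002L, 0x0010L, "UI", ts_uid)
  )
  body <- c(
    e(0x0008L, 0x0060L, "CS", charToRaw("MR")),
    e(0x0028L, 0x0002L, "US", us(1L)),
    e(0x0028L, 0x0004L, "CS", charToRaw("MONOCHROME2")),
    e(0x0028L, 0x0010L, "US", us(nrow(image))),
    e(0x0028L, 0x0011L, "US", us(ncol(image))),
    e(0x0028L, 0x0100L, "US", us(bits_alloc)),
    e(0x0028L, 0x0101L, "US", us(bits_stored)),
    e(0x0028L, 0x0102L, "US", us(bits_stored - 1L)),
    e(0x0028L, 0x0103L, "US", us(0L))
  )
  if (!is.null(window_center))
    body <- c(body, e(0x0028L, 0x1050L, "DS", ds(window_center)))
  if (!is.null(window_width))
    body <- c(body, e(0x0028L, 0x1051L, "DS", ds(window_width)))
  pix_vr <- if (bits_alloc == 8L) "OB" else "OW"
  body <- c(body, e(0x7FE0L, 0x0010L, pix_vr, px))

  con <- file(path, "wb"); on.exit(close(con))
  writeBin(rep(as.raw(0L), 128L), con)
  writeBin(charToRaw("DICM"), con)
  meta_len <- e(0x0002L, 0x0000L, "UL",
                writeBin(as.integer(length(meta)), raw(), size = 4,
                         endian = "little"))
  writeBin(c(meta_len, meta, body), con)
  invisible(path)
}
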