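#' Calibrated top-view image
#'
#' Wraps an RGB raster together with its spatial calibration factor.  All
#' downstream geometry is reported in centimetres by dividing pixel
#' distances by `px_per_cm`; the calibration is always supplied explicitly
#' (measured from a target of known size), never inferred from metadata.
#'
#' @param pixels numeric array `H x W x 3` with values in \[0, 1\], or an
#'   `H x W` matrix (interpreted as grey and replicated to three channels).
#' @param px_per_cm pixels per centimetre, a positive scalar.
#' @return An object of class `"calibrated_image"`.
#' @export
calibrated_image <- function(pixels, px_per_cm) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (!is.numeric(px_per_cm) || length(px_per_cm) != 1 || px_per_cm <= 0) {
    stop("px_per_cm must be a positive scalar")
  }
  if (min(pixels) < 0 || max(pixels) > 1) stop("pixel values must lie in [0, 1]")
  if (any(dim(pixels)[1:2] < 32)) stop("image must be at least 32 x 32 pixels")
  structure(list(pixels = pixels, px_per_cm = px_per_cm),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("calibrated_image: %d x %d px, %.3g px/cm (%.2f x %.2f cm)\n",
              d[1], d[2], x$px_per_cm, d[1] / x$px_per_cm, d[2] / x$px_per_cm))
  invisible(x)
}

#' Binary object silhouette
#'
#' A cleaned single-object foreground mask with its calibration.  Normally
#' produced by [extract_silhouette()]; the constructor is exported so that
#' synthetic masks can enter the pipeline directly.
#'
#' @param mask logical `H x W` matrix, `TRUE` = object.
#' @param px_per_cm pixels per centimetre.
#' @param border_touch does the foreground touch the image border?
#' @return Object of class `"silhouette"`.
#' @export
silhouette <- function(mask, px_per_cm, border_touch = FALSE) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("silhouette(): empty mask")
  structure(list(mask = mask, px_per_cm = px_per_cm,
                 border_touch = isTRUE(border_touch)),
            class = "silhouette")
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf("silhouette: %d x %d px, %d foreground px (%.2f cm^2) at %.3g px/cm\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              sum(x$mask) / x$px_per_cm^2, x$px_per_cm))
  invisible(x)
}

#' Read a portable pixmap / greymap image
#'
#' Reads PNM images (plain `P2`/`P3` or raw `P5`/`P6`, 8-bit) into a numeric
#' raster scaled to \[0, 1\].  PNM is the interchange format used by this
#' package's renderer; convert camera PNG/JPEG frames externally, e.g.
#' `magick convert in.jpg out.ppm` or Python Pillow.
#'
#' @param path file path.
#' @param px_per_cm optional calibration; if given, a
#'   [calibrated_image()] is returned, otherwise a bare array.
#' @return numeric array `H x W x 3` (or `calibrated_image`).
#' @export
read_pnm <- function(path, px_per_cm = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("read_pnm(): unsupported or corrupt PNM file (magic '", magic, "')")
  }
  # header tokens: width, height, maxval; '#' comments allowed
  tok <- character(0)
  buf <- character(0)
  while (length(tok) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (length(ch) == 0 || ch == "") stop("read_pnm(): truncated header")
    if (ch == "#") {  # skip comment to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1))
        if (ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tok <- c(tok, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  w <- as.integer(tok[1]); h <- as.integer(tok[2]); maxval <- as.integer(tok[3])
  nchan <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nchan
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("read_pnm(): truncated pixel data")
  px <- vals / maxval
  # PNM stores row-major, R arrays are column-major
  if (nchan == 3L) {
    arr <- array(0, c(h, w, 3))
    for (k in 1:3) arr[, , k] <- matrix(px[seq(k, n, by = 3)], h, w, byrow = TRUE)
  } else {
    g <- matrix(px, h, w, byrow = TRUE)
    arr <- array(rep(g, 3), c(h, w, 3))
  }
  if (is.null(px_per_cm)) arr else calibrated_image(arr, px_per_cm)
}

#' Write a portable pixmap image
#'
#' Writes an RGB raster (or a `calibrated_image`) as 8-bit PPM, either raw
#' binary (`P6`, compact, default) or plain text (`P3`).
#'
#' @param image `calibrated_image`, `H x W x 3` array, or logical matrix
#'   (written as black/white).
#' @param path output file path.
#' @param ascii write plain-text `P3` instead of binary `P6`.
#' @return `path`, invisibly.
#' @export
write_pnm <- function(image, path, ascii = FALSE) {
  if (inherits(image, "calibrated_image")) image <- image$pixels
  if (is.logical(image)) image <- array(rep(as.numeric(image), 3), c(dim(image), 3))
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  image <- pmin(pmax(image, 0), 1)
  # interleave channels row-major
  inter <- integer(h * w * 3)
  for (k in 1:3) inter[seq(k, length(inter), by = 3)] <- as.integer(t(image[, , k]) * 255 + 0.5)
  if (ascii) {
    con <- file(path, "wb")  # binary mode: fixed "\n" eol on every platform
    on.exit(close(con))
    writeChar(sprintf("P3\n%d %d\n255\n", w, h), con, eos = NULL)
    writeChar(paste(inter, collapse = " "), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(inter), con)
  }
  invisible(path)
}
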