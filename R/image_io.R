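#' Read a raster image as a normalized grayscale intensity field
#'
#' Decodes a PNG, TIFF or JPEG file and canonicalizes it to the internal
#' representation used throughout the package: a plain numeric matrix of
#' intensities in \[0, 1\], one row per image row. Integer sample values are
#' divided by the dtype maximum (255 for 8-bit, 65535 for 16-bit), so the
#' output range is independent of bit depth. RGB images are collapsed to
#' luminance with Rec. 601 weights (0.299, 0.587, 0.114); an alpha channel,
#' if present, is ignored.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return A numeric matrix with values in \[0, 1\].
#' @seealso [load_mask()], [save_mask()]
#' @export
load_image <- function(path) {
  arr <- read_raster(path)
  img <- collapse_to_gray(arr)
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop("zero-area image: ", path, call. = FALSE)
  }
  # decoders already scale integer samples by the dtype maximum; clamp
  # against float TIFF inputs that may stray outside [0,1]
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Read a binary mask image
#'
#' Reads a single-channel (or channel-replicated) image and thresholds it at
#' half the dtype maximum: pixels strictly above 0.5 after normalization map
#' to 1, all others to 0. The threshold is deliberately at the midpoint so
#' that anti-aliased ground-truth masks binarize sensibly.
#'
#' @param path Path to a mask image (PNG/TIFF/JPEG).
#' @return An integer matrix of 0/1 values.
#' @export
load_mask <- function(path) {
  arr <- read_raster(path)
  if (length(dim(arr)) == 3L) {
    nch <- min(dim(arr)[3L], 3L)
    if (nch > 1L) {
      for (k in 2:nch) {
        if (any(abs(arr[, , k] - arr[, , 1L]) > 1e-9)) {
          stop("multi-channel mask with unequal channels: ", path,
               call. = FALSE)
        }
      }
    }
    arr <- arr[, , 1L]
  }
  mask <- matrix(0L, nrow(arr), ncol(arr))
  mask[arr > 0.5] <- 1L
  mask
}

#' Write a binary mask as an 8-bit PNG
#'
#' Writes values \{0, 255\}; `load_mask(save_mask(m))` reproduces `m`
#' exactly.
#'
#' @param mask An integer or logical matrix of 0/1 values.
#' @param path Output path (PNG).
#' @return The path, invisibly.
#' @export
save_mask <- function(mask, path) {
  mask <- validate_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# Decode by extension (falling back to magic-number sniffing for unknown
# extensions); returns a matrix or H x W x C array in [0,1].
read_raster <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("path must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("cannot read image, file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      sniff_raster(path)
    ),
    error = function(e) {
      stop("failed to decode image ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(dim(arr)) || length(dim(arr)) < 2L) {
    stop("not a 2-D raster image: ", path, call. = FALSE)
  }
  arr
}

sniff_raster <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4L && identical(magic[1:4],
      as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    return(png::readPNG(path))
  }
  if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    return(jpeg::readJPEG(path))
  }
  if (length(magic) >= 2L &&
      (identical(magic[1:2], charToRaw("II")) ||
       identical(magic[1:2], charToRaw("MM")))) {
    return(tiff::readTIFF(path))
  }
  stop("unrecognized image format")
}

collapse_to_gray <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  nch <- dim(arr)[3L]
  if (nch == 1L) return(arr[, , 1L])
  if (nch == 2L) return(arr[, , 1L])          # gray + alpha
  # RGB(A): Rec. 601 luminance
  0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
}

validate_mask <- function(mask) {
  if (is.logical(mask)) {
    m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
    return(m)
  }
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    stop("mask must be a matrix of 0/1 values", call. = FALSE)
  }
  matrix(as.integer(mask), nrow(mask), ncol(mask))
}

validate_image <- function(img, min_dim = 3L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(img))) stop("image contains non-finite values",
                                 call. = FALSE)
  if (min(img) < 0 || max(img) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop("image must be at least ", min_dim, "x", min_dim, call. = FALSE)
  }
  invisible(img)
}
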