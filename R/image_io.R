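# Class labels for segmentation masks. Integer codes are part of the mask
# contract: CSV exports, PNG palettes and tests all rely on them.

#' Segmentation class codes
#'
#' Integer codes used in [label_mask()] arrays: `CLASS_BACKGROUND` (soil /
#' non-plant), `CLASS_GREEN` (photosynthetically active leaf tissue) and
#' `CLASS_DEAD` (chlorotic or senescent tissue).
#'
#' @format Integer scalars.
#' @export
CLASS_BACKGROUND <- 0L

#' @rdname CLASS_BACKGROUND
#' @export
CLASS_GREEN <- 1L

#' @rdname CLASS_BACKGROUND
#' @export
CLASS_DEAD <- 2L

# PNG palette used by save_mask()/load_mask(): one distinct color per class.
# background = black, green = pure green, dead = yellow.
.mask_palette <- matrix(
  c(0, 0, 0,
    0, 255, 0,
    255, 255, 0),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("background", "green", "dead"), c("r", "g", "b"))
)

#' Construct an RGB image object
#'
#' An `rgb_image` is the unit of analysis: one plant photographed from above,
#' stored as an H x W x 3 array of 8-bit intensities (0-255), row-major with
#' the origin at the top-left pixel.
#'
#' @param pixels numeric or integer H x W x 3 array with values in \[0, 255\].
#' @param source_id free-text identifier (file name or plant id).
#' @return An object of class `rgb_image` with fields `pixels`, `width`,
#'   `height`, `source_id`.
#' @export
rgb_image <- function(pixels, source_id = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2],
         source_id = as.character(source_id)),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d px, source '%s'\n",
              x$width, x$height, x$source_id))
  invisible(x)
}

#' Construct a label mask
#'
#' @param labels integer H x W matrix over `CLASS_BACKGROUND`, `CLASS_GREEN`,
#'   `CLASS_DEAD`.
#' @param image_source_id identifier of the image the mask belongs to.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, image_source_id = "") {
  if (!is.matrix(labels))
    stop("labels must be a matrix", call. = FALSE)
  if (nrow(labels) < 1L || ncol(labels) < 1L)
    stop("mask must have at least one row and one column", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) ||
      !all(labels %in% c(CLASS_BACKGROUND, CLASS_GREEN, CLASS_DEAD)))
    stop("labels must be one of CLASS_BACKGROUND, CLASS_GREEN, CLASS_DEAD",
         call. = FALSE)
  structure(
    list(labels = labels, image_source_id = as.character(image_source_id)),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- count_pixels(x)
  cat(sprintf("<label_mask> %d x %d px: %d green, %d dead, %d background\n",
              ncol(x$labels), nrow(x$labels),
              tab$pixels_green, tab$pixels_dead, tab$pixels_background))
  invisible(x)
}

#' Pixel-to-area calibration
#'
#' The physical length of one pixel edge. The scale is a required user input:
#' it depends on camera height, sensor and lens, none of which the package
#' attempts to infer.
#'
#' @param mm_per_pixel physical edge length of one pixel, in millimetres;
#'   must be positive.
#' @param provenance free text recording how the scale was derived (e.g.
#'   "30 cm ruler in frame" or camera geometry).
#' @return An object of class `area_calibration`.
#' @export
area_calibration <- function(mm_per_pixel, provenance = "") {
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1L ||
      !is.finite(mm_per_pixel) || mm_per_pixel <= 0)
    stop("mm_per_pixel must be a single positive number", call. = FALSE)
  structure(list(mm_per_pixel = mm_per_pixel,
                 provenance = as.character(provenance)),
            class = "area_calibration")
}

#' Load an RGB image from a PNG or JPEG file
#'
#' Pixel values are preserved exactly as decoded (8-bit, no rescaling and no
#' color-profile transformation; files are interpreted as sRGB). Grayscale
#' images are promoted by channel replication; an alpha channel is dropped.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An [rgb_image()] whose `source_id` is the file name.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      # unknown extension: try PNG magic then JPEG
      tryCatch(png::readPNG(path), error = function(e) jpeg::readJPEG(path))
    ),
    error = function(e)
      stop("cannot decode image '", path, "': ", conditionMessage(e),
           call. = FALSE)
  )
  if (is.matrix(arr)) # grayscale -> replicate channels
    arr <- array(arr, dim = c(dim(arr), 3L))
  if (length(dim(arr)) != 3L)
    stop("unsupported raster layout in '", path, "'", call. = FALSE)
  nch <- dim(arr)[3]
  if (nch == 1L) {
    arr <- array(arr[, , 1L], dim = c(dim(arr)[1:2], 3L))
  } else if (nch == 2L) {
    stop("unsupported channel count (2) in '", path, "'", call. = FALSE)
  } else if (nch >= 4L) {
    arr <- arr[, , 1:3, drop = FALSE] # drop alpha
  }
  px <- round(arr * 255)
  storage.mode(px) <- "integer"
  rgb_image(px, source_id = basename(path))
}

#' Save a label mask as an indexed-color PNG
#'
#' One distinct color per class: background black (0,0,0), green leaf pure
#' green (0,255,0), dead leaf yellow (255,255,0). The encoding round-trips:
#' [load_mask()] recovers the identical label array.
#'
#' @param mask a [label_mask()].
#' @param path output file path (`.png`).
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  img <- array(0, dim = c(nrow(lab), ncol(lab), 3L))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(lab), ncol(lab))
    plane[lab == CLASS_BACKGROUND] <- .mask_palette["background", ch]
    plane[lab == CLASS_GREEN]      <- .mask_palette["green", ch]
    plane[lab == CLASS_DEAD]       <- .mask_palette["dead", ch]
    img[, , ch] <- plane
  }
  ok <- tryCatch({png::writePNG(img / 255, target = path); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write mask to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Reload a label mask written by [save_mask()]
#'
#' @param path path to a mask PNG.
#' @param image_source_id optional source id to attach.
#' @return A [label_mask()].
#' @export
load_mask <- function(path, image_source_id = "") {
  img <- load_image(path)
  px <- img$pixels
  lab <- matrix(NA_integer_, img$height, img$width)
  for (cls in rownames(.mask_palette)) {
    hit <- px[, , 1] == .mask_palette[cls, "r"] &
           px[, , 2] == .mask_palette[cls, "g"] &
           px[, , 3] == .mask_palette[cls, "b"]
    lab[hit] <- switch(cls, background = CLASS_BACKGROUND,
                       green = CLASS_GREEN, dead = CLASS_DEAD)
  }
  if (anyNA(lab))
    stop("'", path, "' contains colors outside the mask palette",
         call. = FALSE)
  label_mask(lab, image_source_id = image_source_id)
}
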