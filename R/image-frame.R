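# Image containers. Pixels are plain numeric matrices (row-major display
# convention: x = column index, y = row index, origin top-left). Angles are
# degrees counterclockwise from +x in [0, 180). All physical quantities at
# function boundaries are in micrometres / seconds / Pa / nN; pixel
# conversions happen here and nowhere else.

#' Create an image frame
#'
#' A single grayscale microscopy image with its physical pixel size.
#'
#' @param pixels Numeric matrix of non-negative intensities (detector units).
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param channel_label Free-text channel name, e.g. `"alpha-actinin"`.
#' @param bit_depth Detector bit depth, 8 or 16.
#' @return An `image_frame` object.
#' @export
image_frame <- function(pixels, pixel_size_um, channel_label = "",
                        bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop_contract("`pixels` must be a non-empty numeric matrix")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop_contract("image intensities must be finite and non-negative")
  }
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  if (!bit_depth %in% c(8L, 16L)) stop_contract("bit_depth must be 8 or 16")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel_label = channel_label, bit_depth = as.integer(bit_depth)),
    class = "image_frame"
  )
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px @ %.4g um/px, %d-bit%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$bit_depth,
              if (nzchar(x$channel_label)) paste0(" [", x$channel_label, "]") else ""))
  invisible(x)
}

#' @export
dim.image_frame <- function(x) dim(x$pixels)

#' Create an image stack
#'
#' An ordered sequence of frames sharing shape and pixel size, with a
#' uniform frame interval (e.g. a contraction video).
#'
#' @param frames List of [image_frame()] objects.
#' @param frame_interval_s Seconds between consecutive frames (> 0).
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, frame_interval_s) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_contract("`frames` must be a non-empty list of image_frame objects")
  }
  ok <- vapply(frames, inherits, logical(1), "image_frame")
  if (!all(ok)) stop_contract("all elements of `frames` must be image_frame")
  d1 <- dim(frames[[1]]$pixels)
  px1 <- frames[[1]]$pixel_size_um
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]$pixels), d1)) {
      stop_contract("frame %d has shape %s, expected %s", i,
                    paste(dim(frames[[i]]$pixels), collapse = "x"),
                    paste(d1, collapse = "x"))
    }
    if (frames[[i]]$pixel_size_um != px1) {
      stop_contract("frame %d pixel size differs from frame 1", i)
    }
  }
  check_number(frame_interval_s, "frame_interval_s", min = 0, strict_min = TRUE)
  structure(list(frames = frames, frame_interval_s = frame_interval_s),
            class = "image_stack")
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d frames, %d x %d px, dt = %.4g s\n",
              length(x$frames), nrow(x$frames[[1]]$pixels),
              ncol(x$frames[[1]]$pixels), x$frame_interval_s))
  invisible(x)
}

#' Read a TIFF file into an image stack
#'
#' Reads a single- or multi-page grayscale TIFF. Physical metadata (pixel
#' size, frame interval) always comes from `metadata`, never from TIFF
#' tags; pages must be grayscale.
#'
#' @param path Path to a TIFF file.
#' @param metadata An [assay_config()] providing `pixel_size_um` and
#'   `frame_interval_s`.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, metadata) {
  stopifnot(inherits(metadata, "assay_config"))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop_format("cannot read TIFF '%s': %s",
                                                    path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(seq_along(pages), function(i) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) {
      stop_format("page %d of '%s' is not grayscale (%d channels)",
                  i, path, dim(pg)[3])
    }
    bits <- if (max(pg) > 255) 16L else 8L
    image_frame(matrix(as.numeric(pg), nrow = nrow(pg)),
                pixel_size_um = metadata$pixel_size_um,
                bit_depth = bits)
  })
  image_stack(frames, frame_interval_s = metadata$frame_interval_s %||% 1)
}

#' Write an image stack (or single frame) to TIFF
#'
#' Intensities are stored at the frame's declared bit depth; values are
#' clipped to the representable range.
#'
#' @param x An [image_stack()] or [image_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(x, path) {
  if (inherits(x, "image_frame")) x <- image_stack(list(x), 1)
  stopifnot(inherits(x, "image_stack"))
  imgs <- lapply(x$frames, function(fr) {
    mx <- 2^fr$bit_depth - 1
    pmin(pmax(fr$pixels, 0), mx) / mx
  })
  bits <- x$frames[[1]]$bit_depth
  tiff::writeTIFF(imgs, path, bits.per.sample = bits)
  invisible(path)
}
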