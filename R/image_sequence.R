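#' Construct an image sequence
#'
#' Container for a time-lapse of 2D grayscale frames. Intensities are stored
#' as raw counts (doubles), `frames[row, col, t]` with `x = col - 1`,
#' `y = row - 1` and `t` 1-based internally (frame index `t - 1` in the API).
#'
#' @param frames numeric array `H x W x T` (a matrix is treated as `T = 1`),
#'   all values non-negative.
#' @param pixel_size_nm physical pixel edge in nanometres, or `NULL` when
#'   unknown.
#' @param frame_interval_s time between consecutive frames in seconds, or
#'   `NULL` when unknown.
#' @param bit_depth 8 or 16; intensities must fit the declared depth.
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, pixel_size_nm = NULL, frame_interval_s = NULL,
                           bit_depth = 16) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be an H x W x T array")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("frame intensities must be finite and non-negative")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (max(frames) > 2^bit_depth - 1)
    stop("intensities exceed the declared bit depth")
  if (!is.null(pixel_size_nm) && (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0))
    stop("pixel_size_nm must be a positive number")
  if (!is.null(frame_interval_s) && (!is.numeric(frame_interval_s) || frame_interval_s <= 0))
    stop("frame_interval_s must be a positive number")
  structure(list(frames = frames,
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 bit_depth = as.integer(bit_depth)),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_sequence: %d frame(s) of %d x %d, %d-bit\n",
              d[3], d[1], d[2], x$bit_depth))
  if (!is.null(x$pixel_size_nm))
    cat(sprintf("  pixel size: %g nm\n", x$pixel_size_nm))
  if (!is.null(x$frame_interval_s))
    cat(sprintf("  frame interval: %g s\n", x$frame_interval_s))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq an `image_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' Extract one frame as a matrix
#' @param seq an `image_sequence`.
#' @param frame 0-based frame index.
#' @return `H x W` numeric matrix.
#' @export
get_frame <- function(seq, frame) {
  stopifnot(frame >= 0, frame < n_frames(seq))
  seq$frames[, , frame + 1L]
}

#' Read a multi-page grayscale TIFF as an image sequence
#'
#' Pages are returned in file order. RGB or multi-channel pages are rejected
#' as an unsupported layout. Values are rescaled from the [0, 1] range used
#' by the TIFF reader back to integer counts at the file's bit depth.
#'
#' @param path path to a multi-page grayscale TIFF file.
#' @param pixel_size_nm,frame_interval_s optional metadata to attach.
#' @return An [image_sequence].
#' @export
read_sequence <- function(path, pixel_size_nm = NULL, frame_interval_s = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("unsupported layout: expected single-channel grayscale pages")
  d <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d), logical(1))))
    stop("all pages must share the same dimensions")
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits) || !bits %in% c(8L, 16L)) bits <- 16L
  scale <- 2^bits - 1
  frames <- array(0, c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- round(pages[[i]] * scale)
  image_sequence(frames, pixel_size_nm, frame_interval_s, bit_depth = bits)
}

#' Write an image sequence as a multi-page grayscale TIFF
#'
#' The writer is deterministic: identical sequences produce byte-identical
#' files. Counts are stored at the sequence's bit depth.
#'
#' @param seq an [image_sequence].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  scale <- 2^seq$bit_depth - 1
  pages <- lapply(seq_len(n_frames(seq)),
                  function(i) pmin(pmax(seq$frames[, , i], 0), scale) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = seq$bit_depth,
                  compression = "none")
  invisible(path)
}
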