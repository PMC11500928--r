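#' Media references
#'
#' A `media_ref` describes one source or segment media file: its path, kind
#' (video or image), pixel dimensions, frame count and — for videos — frame
#' rate. It is returned by [probe_media()] and consumed by the segmentation
#' and session machinery.
#'
#' @param path File path.
#' @param media_type `"video"` or `"image"`.
#' @param width,height Pixel dimensions.
#' @param frame_count Number of frames (1 for still images).
#' @param fps Frames per second, or `NA` for still images.
#' @return An object of class `media_ref`.
#' @keywords internal
media_ref <- function(path, media_type, width, height, frame_count, fps = NA_real_) {
  structure(
    list(path = path, media_type = media_type,
         width = as.integer(width), height = as.integer(height),
         frame_count = as.integer(frame_count), fps = as.numeric(fps)),
    class = "media_ref"
  )
}

#' @export
print.media_ref <- function(x, ...) {
  cat(sprintf("<media_ref> %s %s %dx%d, %d frame(s)%s\n",
              x$media_type, basename(x$path), x$width, x$height, x$frame_count,
              if (is.na(x$fps)) "" else sprintf(" @ %.3g fps", x$fps)))
  invisible(x)
}

VIDEO_EXTS <- c("mp4", "avi")
IMAGE_EXTS <- c("png", "jpg", "jpeg", "bmp")

media_ext <- function(path) tolower(tools::file_ext(path))

media_type_of <- function(path) {
  ext <- media_ext(path)
  if (ext %in% VIDEO_EXTS) "video"
  else if (ext %in% IMAGE_EXTS) "image"
  else stop_blindcut("blindcut_format_error",
                     sprintf("unsupported media format '.%s' (supported: %s)",
                             ext, paste0(".", c(VIDEO_EXTS, IMAGE_EXTS), collapse = ", ")))
}

read_image_int <- function(path) {
  ext <- media_ext(path)
  a <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           bmp = return(read_bmp(path))),
    error = function(e) {
      if (is_blindcut_error(e)) stop(e)
      stop_blindcut("blindcut_decode_error", sprintf("cannot decode '%s': %s", path, conditionMessage(e)))
    })
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  f <- round(a * 255)
  storage.mode(f) <- "integer"
  f
}

write_image_int <- function(frame, path) {
  ext <- media_ext(path)
  ok <- tryCatch({
    switch(ext,
           png = png::writePNG(frame / 255, target = path),
           jpg = ,
           jpeg = jpeg::writeJPEG(frame_to_rgb3(frame) / 255, target = path, quality = 0.95),
           bmp = write_bmp(frame, path))
    TRUE
  }, error = function(e) {
    if (is_blindcut_error(e)) stop(e)
    stop_blindcut("blindcut_io_error", sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  })
  invisible(path)
}

#' Probe a media file
#'
#' Identifies a supported media file and reports its type, pixel dimensions,
#' frame count and (for video) frame rate, without modifying it. Supported
#' formats are `.mp4`/`.avi` video and `.png`/`.jpg`/`.jpeg`/`.bmp` images
#' (case-insensitive extensions).
#'
#' @param path Path to the media file.
#' @return A [media_ref()].
#' @export
#' @examples
#' p <- tempfile(fileext = ".png")
#' png::writePNG(array(0.5, c(48, 64, 3)), p)
#' probe_media(p)
probe_media <- function(path) {
  type <- media_type_of(path) # format error before existence, matching ext contract
  if (!file.exists(path)) {
    stop_blindcut("blindcut_io_error", sprintf("file not found: '%s'", path))
  }
  ext <- media_ext(path)
  if (type == "image") {
    f <- read_image_int(path)
    media_ref(path, "image", dim(f)[2], dim(f)[1], 1L)
  } else if (ext == "avi") {
    info <- parse_avi(path, decode = FALSE)
    media_ref(path, "video", info$width, info$height, info$frame_count, info$fps)
  } else { # mp4: structural probe only
    info <- probe_mp4(path)
    media_ref(path, "video", info$width, info$height, info$frame_count, info$fps)
  }
}

#' Read frames from a media file
#'
#' `read_frames()` decodes every frame; `read_frame()` decodes one frame by
#' 1-based index. Frames are integer arrays `height x width x channels`
#' with values in 0..255. Still images have exactly one frame. Decoding is
#' supported for images and for AVI video written in raw DIB or MJPEG form;
#' compressed MP4 payloads cannot be decoded (probe only).
#'
#' @param media A [media_ref()] from [probe_media()], or a path.
#' @param index 1-based frame index, `1 <= index <= frame_count`.
#' @return `read_frame()`: one frame array; `read_frames()`: list of frames.
#' @export
read_frames <- function(media) {
  if (is.character(media)) media <- probe_media(media)
  stopifnot(inherits(media, "media_ref"))
  if (media$media_type == "image") {
    list(read_image_int(media$path))
  } else if (media_ext(media$path) == "avi") {
    parse_avi(media$path, decode = TRUE)$frames
  } else {
    stop_blindcut("blindcut_decode_error",
                  sprintf("'%s': decoding compressed MP4 video is not supported; convert to AVI",
                          media$path))
  }
}

#' @rdname read_frames
#' @export
read_frame <- function(media, index) {
  if (is.character(media)) media <- probe_media(media)
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 1L || index > media$frame_count) {
    stop_blindcut("blindcut_bounds_error",
                  sprintf("frame index %s out of range 1..%d", format(index), media$frame_count))
  }
  read_frames(media)[[index]]
}

#' Write a cropped segment to disk
#'
#' Writes a sequence of frames as a new media file, preserving pixel
#' resolution exactly (no resampling, ever). Image extensions (`.png`,
#' `.bmp`, `.jpg`/`.jpeg`) accept exactly one frame; `.avi` accepts any
#' number. `.png` and `.bmp` round-trip pixel values losslessly; `.jpg` and
#' MJPEG video are lossy and contract only on dimensions and frame count.
#' No metadata from any source file is carried over, so a written segment
#' cannot leak provenance.
#'
#' @param frames A single frame array or list of frame arrays, all with
#'   identical dimensions, integer 0..255.
#' @param out_path Output path; the extension selects the container.
#' @param fps Frames per second for video output (default 25, the fallback
#'   used when a source reports no rate).
#' @param codec Video codec: `"DIB"` (raw 24-bit, lossless) or `"MJPG"`.
#' @return The [media_ref()] of the written file (re-probed from disk).
#' @export
write_segment <- function(frames, out_path, fps = NULL, codec = c("DIB", "MJPG")) {
  codec <- match.arg(codec)
  if (is.array(frames)) frames <- list(frames)
  if (length(frames) == 0L) {
    stop_blindcut("blindcut_argument_error", "no frames to write (empty frame sequence)")
  }
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, function(d) identical(d[1:2], dims[[1]][1:2]), TRUE))) {
    stop_blindcut("blindcut_argument_error", "all frames must share identical dimensions")
  }
  ext <- media_ext(out_path)
  type <- media_type_of(out_path)
  if (type == "image") {
    if (length(frames) != 1L) {
      stop_blindcut("blindcut_argument_error",
                    sprintf("image format '.%s' holds exactly one frame; got %d", ext, length(frames)))
    }
    write_image_int(frames[[1]], out_path)
  } else if (ext == "avi") {
    write_avi(frames, out_path, fps = fps %||% 25, codec = codec)
  } else {
    stop_blindcut("blindcut_format_error",
                  "writing MP4 is not supported; use '.avi' for video segments")
  }
  probe_media(out_path)
}
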