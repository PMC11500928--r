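#' Rectangular regions of interest
#'
#' A `rect_spec` is an axis-aligned pixel rectangle in 0-based, half-open
#' coordinates: covered pixels are columns `[x, x + w)` and rows
#' `[y, y + h)` of the source frame. Rectangles must lie fully inside the
#' frame; out-of-bounds rectangles are rejected rather than clamped, since
#' silent clamping would change segment content invisibly.
#'
#' @param x,y Left and top edge, pixels (0-based, `>= 0`).
#' @param w,h Width and height in pixels (`>= 1`).
#' @return An object of class `rect_spec`.
#' @export
#' @examples
#' rect_spec(10, 20, 64, 48)
rect_spec <- function(x, y, w, h) {
  vals <- c(x = x, y = y, w = w, h = h)
  if (any(is.na(vals)) || any(vals != floor(vals))) {
    stop_blindcut("blindcut_geometry_error", "rectangle coordinates must be integers")
  }
  if (x < 0 || y < 0) {
    stop_blindcut("blindcut_geometry_error", sprintf("rectangle origin (%d, %d) must be >= 0", x, y))
  }
  if (w < 1 || h < 1) {
    stop_blindcut("blindcut_geometry_error", sprintf("rectangle size %dx%d must be >= 1x1", w, h))
  }
  structure(list(x = as.integer(x), y = as.integer(y), w = as.integer(w), h = as.integer(h)),
            class = "rect_spec")
}

check_rect_in_media <- function(rect, media) {
  if (rect$x + rect$w > media$width || rect$y + rect$h > media$height) {
    stop_blindcut("blindcut_geometry_error",
                  sprintf("rectangle [%d,%d)+%dx%d exceeds %dx%d frame of '%s'",
                          rect$x, rect$y, rect$w, rect$h,
                          media$width, media$height, basename(media$path)))
  }
  invisible(rect)
}

LABEL_REGEX <- "^[A-Z]([1-9]|[12][0-9]|3[0-6])$"

#' Validate a segment label
#'
#' Segment labels follow the well-plate convention: one uppercase letter
#' `A`-`Z` followed by a number `1`-`36` without leading zeros (`A1`,
#' `H12`, `Z36`). Labels must be unique across the whole analysis — all
#' batched source files pooled — because segments from every file are
#' shuffled together.
#'
#' @param label Candidate label string.
#' @param existing Character vector of labels already in use.
#' @return The validated label, invisibly usable.
#' @export
#' @examples
#' validate_label("A1", character())
validate_label <- function(label, existing = character()) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop_blindcut("blindcut_validation_error", "label must be a single string")
  }
  if (!grepl(LABEL_REGEX, label)) {
    stop_blindcut("blindcut_validation_error",
                  sprintf(paste0("invalid label '%s': must be one uppercase letter A-Z ",
                                 "followed by a number 1-36 with no leading zeros"), label))
  }
  if (label %in% existing) {
    stop_blindcut("blindcut_duplicate_label_error",
                  sprintf("duplicate label '%s': labels must be unique across the whole analysis", label))
  }
  label
}

#' Segment specifications
#'
#' A `segment_spec` binds a validated label and a rectangle to one source
#' media file. [add_segment()] appends to a list of specs, enforcing global
#' label uniqueness and rectangle bounds; definition order is preserved and
#' is independent of the later shuffle. A label, once added, is never
#' renamed.
#'
#' @param segments Existing list of `segment_spec`s (possibly empty).
#' @param label Segment label, see [validate_label()].
#' @param rect A [rect_spec()].
#' @param source A [media_ref()] for the source media.
#' @return The extended list of segments.
#' @export
add_segment <- function(segments, label, rect, source) {
  stopifnot(is.list(segments), inherits(rect, "rect_spec"), inherits(source, "media_ref"))
  validate_label(label, vapply(segments, function(s) s$label, ""))
  check_rect_in_media(rect, source)
  spec <- structure(list(label = label, rect = rect, source = source), class = "segment_spec")
  c(segments, list(spec))
}

#' Crop one segment out of its source
#'
#' Extracts the segment's rectangle from every frame of the source media.
#' Output frame `t`, pixel `(r, c)` equals source frame `t`, pixel
#' `(y + r, x + c)` — a pure subarray copy, bit-exact, never resampled.
#'
#' @param spec A `segment_spec` from [add_segment()].
#' @param frames Optional pre-read list of source frames (to avoid decoding
#'   the source once per segment); defaults to reading `spec$source`.
#' @return List of cropped frame arrays, one per source frame.
#' @export
crop_segment <- function(spec, frames = NULL) {
  stopifnot(inherits(spec, "segment_spec"))
  if (is.null(frames)) frames <- read_frames(spec$source)
  crop_frames(frames, spec$rect)
}

#' @rdname crop_segment
#' @param rect A [rect_spec()] applied to every frame in `frames`.
#' @export
crop_frames <- function(frames, rect) {
  rows <- rect$y + seq_len(rect$h)
  cols <- rect$x + seq_len(rect$w)
  lapply(frames, function(f) {
    if (rect$y + rect$h > dim(f)[1] || rect$x + rect$w > dim(f)[2]) {
      stop_blindcut("blindcut_geometry_error", "rectangle exceeds frame dimensions")
    }
    f[rows, cols, , drop = FALSE]
  })
}

#' Read a segmentation config
#'
#' The segmentation config is a JSON array of
#' `{"source": path, "segments": [{"label", "x", "y", "w", "h"}, ...]}`
#' entries, with rectangle coordinates 0-based as in [rect_spec()].
#'
#' @param path Path to the JSON config.
#' @return List of entries, each `list(source=, segments=list(...))`.
#' @export
read_segmentation_config <- function(path) {
  cfg <- tryCatch(jsonlite::read_json(path), error = function(e) {
    stop_blindcut("blindcut_config_error", sprintf("cannot parse segmentation config '%s': %s",
                                                   path, conditionMessage(e)))
  })
  if (!is.list(cfg) || length(cfg) == 0L) {
    stop_blindcut("blindcut_config_error", sprintf("segmentation config '%s' is empty", path))
  }
  lapply(cfg, function(entry) {
    if (is.null(entry$source) || is.null(entry$segments)) {
      stop_blindcut("blindcut_config_error",
                    "each config entry needs 'source' and 'segments' fields")
    }
    segs <- lapply(entry$segments, function(s) {
      need <- c("label", "x", "y", "w", "h")
      if (!all(need %in% names(s))) {
        stop_blindcut("blindcut_config_error",
                      sprintf("segment entry missing fields: %s",
                              paste(setdiff(need, names(s)), collapse = ", ")))
      }
      list(label = s$label, rect = rect_spec(s$x, s$y, s$w, s$h))
    })
    list(source = entry$source, segments = segs)
  })
}

#' Well-plate grid shorthand
#'
#' Generates the labeled rectangle grid of a multi-well plate: rows are
#' lettered `A`, `B`, ... top to bottom and columns numbered `1`, `2`, ...
#' left to right, so well `(r, c)` gets label `<LETTER[r]><c>` and rectangle
#' origin `origin + pitch * (c - 1, r - 1)`.
#'
#' @param rows,cols Plate dimensions (`rows <= 26`, `cols <= 36` so labels
#'   stay within the label grammar).
#' @param origin Length-2 integer `(x, y)` of well A1's top-left corner.
#' @param pitch Center-to-center well spacing, pixels (`>= well_size`).
#' @param well_size Side of the square well rectangle, pixels.
#' @return Named list of [rect_spec()]s keyed by well label, in row-major
#'   order.
#' @export
#' @examples
#' grid <- plate_grid(2, 3, origin = c(4, 4), pitch = 20, well_size = 16)
#' names(grid)
plate_grid <- function(rows, cols, origin = c(0, 0), pitch, well_size) {
  if (rows < 1 || rows > 26 || cols < 1 || cols > 36) {
    stop_blindcut("blindcut_config_error", "plate grid limited to 26 rows x 36 columns")
  }
  if (pitch < well_size) {
    stop_blindcut("blindcut_spec_error", "wells overlap: pitch must be >= well_size")
  }
  out <- list()
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      out[[paste0(LETTERS[r], cc)]] <-
        rect_spec(origin[1] + pitch * (cc - 1L), origin[2] + pitch * (r - 1L),
                  well_size, well_size)
    }
  }
  out
}
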