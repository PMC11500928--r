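#' Synthetic multi-well plate specification
#'
#' Describes a synthetic plate recording: a grid of square wells, each
#' containing one bright blob on a dark background performing a bounded
#' random walk whose per-frame step length is the well's assigned activity
#' level (pixels/frame). This emulates the kind of data the workflow is
#' built for — one animal per well of a multi-well plate, filmed from
#' above, with motion amplitude depending on an experimental condition —
#' while staying fully deterministic under a seed and carrying exact ground
#' truth.
#'
#' By default activity levels are assigned to whole rows, cycling through
#' `levels` (the analogue of dosing a plate by contiguous bands). Pass
#' `conditions` (named `well label -> level`) for full control.
#'
#' @param rows,cols Plate dimensions (default 3 x 4).
#' @param well_size Square well side, pixels (default 40).
#' @param pitch Well-to-well spacing, pixels (default 48; must be `>=
#'   well_size` or the wells would overlap, which is a spec error).
#' @param origin `(x, y)` of well A1's top-left corner (default `c(8, 8)`).
#' @param frame_count Number of frames (default 200).
#' @param fps Frame rate of the written video (default 25).
#' @param levels Activity levels cycled over rows (default `c(0, 2, 6)`
#'   pixels/frame: a stationary control plus two clearly separated motion
#'   amplitudes).
#' @param conditions Optional named numeric vector, `label -> activity`.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(rows = 3, cols = 4, well_size = 40, pitch = 48,
                       origin = c(8, 8), frame_count = 200, fps = 25,
                       levels = c(0, 2, 6), conditions = NULL, seed = 1L) {
  grid <- plate_grid(rows, cols, origin = origin, pitch = pitch, well_size = well_size)
  if (is.null(conditions)) {
    conditions <- numeric(0)
    for (r in seq_len(rows)) {
      lev <- levels[(r - 1L) %% length(levels) + 1L]
      for (cc in seq_len(cols)) conditions[paste0(LETTERS[r], cc)] <- lev
    }
  }
  if (!setequal(names(conditions), names(grid))) {
    stop_blindcut("blindcut_spec_error", "conditions must name every well of the grid exactly")
  }
  if (any(conditions < 0)) {
    stop_blindcut("blindcut_spec_error", "activity levels must be non-negative")
  }
  structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    well_size = as.integer(well_size), pitch = as.integer(pitch),
    origin = as.integer(origin), frame_count = as.integer(frame_count),
    fps = fps, grid = grid, conditions = conditions[names(grid)],
    seed = as.integer(seed),
    width = 2L * origin[1] + pitch * (cols - 1L) + well_size,
    height = 2L * origin[2] + pitch * (rows - 1L) + well_size
  ), class = "plate_spec")
}

reflect_interval <- function(p, lo, hi) {
  while (p < lo || p > hi) {
    if (p < lo) p <- 2 * lo - p else p <- 2 * hi - p
  }
  p
}

draw_disk <- function(frame, cx, cy, radius, value) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  r0 <- max(0L, floor(cy - radius)); r1 <- min(h - 1L, ceiling(cy + radius))
  c0 <- max(0L, floor(cx - radius)); c1 <- min(w - 1L, ceiling(cx + radius))
  rr <- r0:r1; cc <- c0:c1
  mask <- outer((rr - cy)^2, (cc - cx)^2, `+`) <= radius^2
  sub <- frame[rr + 1L, cc + 1L, , drop = FALSE]
  for (ch in seq_len(dim(frame)[3])) {
    plane <- sub[, , ch]
    plane[mask] <- value
    sub[, , ch] <- plane
  }
  frame[rr + 1L, cc + 1L, ] <- sub
  frame
}

#' Generate a synthetic plate video with ground truth
#'
#' Simulates the plate described by a [plate_spec()]: each well holds one
#' filled bright disk (radius `well_size / 8`) whose center performs a
#' random walk with uniform direction and fixed step length equal to the
#' well's activity level, reflecting off the well walls so the blob never
#' leaves its well. Activity 0 yields a stationary blob (all frames
#' identical within that well). Bit-identical output for identical spec and
#' seed.
#'
#' @param spec A [plate_spec()].
#' @param out_path Optional `.avi` path; when given, the frames are written
#'   (raw lossless codec) and the returned `media` is the probed file.
#' @return `list(frames =, media =, ground_truth =)`. `ground_truth$wells`
#'   maps each well label to `list(rect =, activity =, trajectory =)` with
#'   the trajectory an `frame_count x 2` matrix of (x, y) blob centers in
#'   0-based pixel coordinates.
#' @export
generate_plate_video <- function(spec, out_path = NULL) {
  stopifnot(inherits(spec, "plate_spec"))
  radius <- max(2, spec$well_size / 8)
  labels <- names(spec$grid)

  trajectories <- with_rng_seed(spec$seed, {
    out <- list()
    for (lab in labels) {
      rect <- spec$grid[[lab]]
      a <- spec$conditions[[lab]]
      lo_x <- rect$x + radius; hi_x <- rect$x + rect$w - 1 - radius
      lo_y <- rect$y + radius; hi_y <- rect$y + rect$h - 1 - radius
      pos <- matrix(0, spec$frame_count, 2, dimnames = list(NULL, c("x", "y")))
      pos[1, ] <- c(rect$x + (rect$w - 1) / 2, rect$y + (rect$h - 1) / 2)
      if (spec$frame_count > 1) {
        theta <- stats::runif(spec$frame_count - 1, 0, 2 * pi)
        for (t in 2:spec$frame_count) {
          pos[t, 1] <- reflect_interval(pos[t - 1, 1] + a * cos(theta[t - 1]), lo_x, hi_x)
          pos[t, 2] <- reflect_interval(pos[t - 1, 2] + a * sin(theta[t - 1]), lo_y, hi_y)
        }
      }
      out[[lab]] <- pos
    }
    out
  })

  # static plate background: dark field with faint well outlines
  base <- array(16L, c(spec$height, spec$width, 3L))
  for (rect in spec$grid) {
    rr <- rect$y + c(1L, rect$h); cc <- rect$x + c(1L, rect$w)
    base[rect$y + seq_len(rect$h), cc, ] <- 70L
    base[rr, rect$x + seq_len(rect$w), ] <- 70L
  }

  frames <- vector("list", spec$frame_count)
  for (t in seq_len(spec$frame_count)) {
    f <- base
    for (lab in labels) {
      f <- draw_disk(f, trajectories[[lab]][t, 1], trajectories[[lab]][t, 2], radius, 230L)
    }
    frames[[t]] <- f
  }

  ground_truth <- list(wells = stats::setNames(lapply(labels, function(lab) {
    list(rect = spec$grid[[lab]], activity = spec$conditions[[lab]],
         trajectory = trajectories[[lab]])
  }), labels))

  media <- NULL
  if (!is.null(out_path)) {
    media <- write_segment(frames, out_path, fps = spec$fps, codec = "DIB")
  }
  list(frames = frames, media = media, ground_truth = ground_truth)
}

#' Frame-differencing activity score
#'
#' A deterministic automated stand-in for a human scorer: the mean, over
#' consecutive frame pairs, of the mean absolute per-pixel intensity
#' difference. Identical frames score exactly 0; a well whose blob moves
#' more scores higher.
#'
#' @param frames List of >= 2 frame arrays of identical dimensions.
#' @return A non-negative number.
#' @export
activity_score <- function(frames) {
  if (!is.list(frames) || length(frames) < 2L) {
    stop_blindcut("blindcut_argument_error", "activity_score needs at least 2 frames")
  }
  diffs <- vapply(seq_len(length(frames) - 1L), function(t) {
    mean(abs(frames[[t + 1L]] - frames[[t]]))
  }, 0)
  mean(diffs)
}
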