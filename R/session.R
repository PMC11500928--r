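#' Fisher-Yates shuffle
#'
#' The explicit backward Fisher-Yates loop: for `i` from `n` down to 2,
#' draw `j` uniformly on `1..i` and swap positions `i` and `j`. Each of the
#' `n!` permutations is produced with equal probability, regardless of any
#' order present in the input. Deterministic given `seed`.
#'
#' @param n Number of elements (`n >= 0`).
#' @param seed Optional integer seed; when `NULL` the caller's RNG stream
#'   is used (and left advanced).
#' @return An integer permutation of `1..n`.
#' @export
#' @examples
#' fisher_yates_shuffle(5, seed = 42)
fisher_yates_shuffle <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) {
    stop_blindcut("blindcut_argument_error", "n must be a non-negative integer")
  }
  run <- function() {
    perm <- seq_len(n)
    if (n >= 2L) {
      for (i in n:2L) {
        j <- sample.int(i, 1L)
        tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
      }
    }
    perm
  }
  if (is.null(seed)) run() else with_rng_seed(seed, run())
}

SESSION_SCHEMA_VERSION <- 1L

blinded_id_width <- function(n) max(3L, nchar(as.character(n)) + 1L)

# Blinded IDs are "S" + zero-padded presentation rank. The pad width
# guarantees a leading zero for every ID, so no ID can ever contain a valid
# label (labels never carry leading zeros) as a substring.
make_blinded_ids <- function(order) {
  n <- length(order)
  ids <- character(n)
  ids[order] <- sprintf("S%0*d", blinded_id_width(n), seq_len(n))
  ids
}

source_stem <- function(path) tools::file_path_sans_ext(basename(path))

assert_no_leak <- function(ids, labels, sources) {
  forbidden <- unique(c(labels, source_stem(sources)))
  for (id in ids) {
    hit <- forbidden[vapply(forbidden, function(f) grepl(f, id, fixed = TRUE), TRUE)]
    if (length(hit)) {
      stop_blindcut("blindcut_validation_error",
                    sprintf("blinded ID '%s' would contain identifying string '%s'; rename the source file",
                            id, hit[1]))
    }
  }
  invisible(TRUE)
}

#' Create a blinded scoring session
#'
#' Pools the segments (from one or many source files), shuffles them once
#' with [fisher_yates_shuffle()], and assigns blinded IDs `"S001"`,
#' `"S002"`, ... in *shuffled* order, so an ID encodes only presentation
#' rank and nothing about labels or sources. The shuffle happens exactly
#' once, here, after all segmentation is complete; the order and IDs are
#' immutable for the life of the session and resuming never reshuffles.
#'
#' @param segments List of segment specs from [add_segment()] (>= 1).
#' @param stage_names Ordered character vector of user-named scoring stages
#'   (>= 1).
#' @param seed Optional integer RNG seed; when `NULL`, one is drawn from
#'   the ambient RNG and recorded in the session for audit.
#' @param state_path Optional path of the session state JSON; when given,
#'   the session is persisted immediately and after every score.
#' @return An object of class `blindcut_session`.
#' @export
create_session <- function(segments, stage_names, seed = NULL, state_path = NULL) {
  if (!is.list(segments) || length(segments) == 0L) {
    stop_blindcut("blindcut_argument_error", "a session needs at least one segment")
  }
  if (!is.character(stage_names) || length(stage_names) == 0L ||
      anyNA(stage_names) || any(!nzchar(stage_names))) {
    stop_blindcut("blindcut_argument_error", "a session needs at least one non-empty stage name")
  }
  if (anyDuplicated(stage_names)) {
    stop_blindcut("blindcut_argument_error", "stage names must be distinct")
  }
  labels <- vapply(segments, function(s) s$label, "")
  if (anyDuplicated(labels)) {
    stop_blindcut("blindcut_duplicate_label_error",
                  sprintf("duplicate segment label '%s'", labels[duplicated(labels)][1]))
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  n <- length(segments)
  ord <- fisher_yates_shuffle(n, seed = seed)
  ids <- make_blinded_ids(ord)
  sources <- unique(vapply(segments, function(s) s$source$path, ""))
  assert_no_leak(ids, labels, sources)

  session <- structure(list(
    schema_version = SESSION_SCHEMA_VERSION,
    session_id = substr(digest::digest(list(seed, n, labels)), 1L, 12L),
    seed = seed,
    stage_names = stage_names,
    segments = segments,
    order = ord,
    blinded_ids = ids,
    media_files = stats::setNames(list(), character()),
    scores = stats::setNames(list(), character()),
    cursor = 0L,
    state_path = state_path
  ), class = "blindcut_session")
  if (!is.null(state_path)) save_session(session, state_path)
  session
}

#' @export
print.blindcut_session <- function(x, ...) {
  cat(sprintf("<blindcut_session %s> %d segment(s), %d stage(s), %d/%d scored\n",
              x$session_id, length(x$segments), length(x$stage_names),
              x$cursor, length(x$segments)))
  invisible(x)
}

session_n <- function(session) length(session$segments)

#' Next segment to score
#'
#' Returns the blinded presentation bundle for the segment at the current
#' cursor position of the randomized order, or a done-marker when every
#' segment is scored. The bundle exposes only the blinded ID and the path
#' of the blinded media file — never the label or the source filename.
#'
#' @param session A `blindcut_session`.
#' @return `list(done = TRUE)` past the end; otherwise `list(done = FALSE,
#'   blinded_id =, media_rel =, media_path =)` where `media_rel` is the
#'   blinded file's path relative to the results folder (`NULL` for
#'   sessions without cropped media).
#' @export
next_segment <- function(session) {
  stopifnot(inherits(session, "blindcut_session"))
  n <- session_n(session)
  if (session$cursor >= n) return(list(done = TRUE))
  idx <- session$order[session$cursor + 1L]
  id <- session$blinded_ids[idx]
  rel <- session$media_files[[id]]
  path <- if (!is.null(rel) && !is.null(session$state_path)) {
    file.path(dirname(session$state_path), rel)
  }
  list(done = FALSE, blinded_id = id, media_rel = rel, media_path = path)
}

#' Record the score for the current segment
#'
#' Stores the free-text notes for every stage of the segment currently
#' presented by [next_segment()], advances the cursor, and — for persisted
#' sessions — rewrites the state file atomically so an interrupted analysis
#' loses at most the in-progress segment.
#'
#' @param session A `blindcut_session`.
#' @param blinded_id The blinded ID of the *current* segment (scoring out
#'   of presentation order is a sequencing error).
#' @param notes Named character vector or list with exactly one entry per
#'   stage name (empty strings allowed).
#' @return The updated session.
#' @export
record_score <- function(session, blinded_id, notes) {
  nxt <- next_segment(session)
  if (isTRUE(nxt$done)) {
    stop_blindcut("blindcut_sequencing_error", "session is complete; nothing left to score")
  }
  if (!identical(blinded_id, nxt$blinded_id)) {
    stop_blindcut("blindcut_sequencing_error",
                  sprintf("out-of-turn score for '%s'; the current segment is '%s'",
                          blinded_id, nxt$blinded_id))
  }
  notes <- as.list(notes)
  missing <- setdiff(session$stage_names, names(notes))
  extra <- setdiff(names(notes), session$stage_names)
  if (length(missing) || length(extra)) {
    stop_blindcut("blindcut_validation_error",
                  sprintf("notes must cover exactly the stages {%s}%s%s",
                          paste(session$stage_names, collapse = ", "),
                          if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
                          if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")) else ""))
  }
  notes <- lapply(session$stage_names, function(s) as.character(notes[[s]]))
  names(notes) <- session$stage_names
  session$scores[[blinded_id]] <- list(
    blinded_id = blinded_id,
    notes = notes,
    completed_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  )
  session$cursor <- session$cursor + 1L
  if (!is.null(session$state_path)) save_session(session, session$state_path)
  session
}

serialize_session <- function(session) {
  segs <- lapply(session$segments, function(s) {
    list(label = s$label,
         x = s$rect$x, y = s$rect$y, w = s$rect$w, h = s$rect$h,
         source = list(path = s$source$path, media_type = s$source$media_type,
                       width = s$source$width, height = s$source$height,
                       frame_count = s$source$frame_count,
                       fps = if (is.na(s$source$fps)) NULL else s$source$fps))
  })
  list(schema_version = session$schema_version,
       session_id = session$session_id,
       seed = session$seed,
       stage_names = as.list(session$stage_names),
       segments = segs,
       order = as.list(session$order), # 1-based permutation
       blinded_ids = as.list(session$blinded_ids),
       media_files = session$media_files,
       scores = session$scores,
       cursor = session$cursor)
}

#' Persist a session
#'
#' Writes the full session state as one JSON document, atomically
#' (write-temp-then-rename), so a crash mid-write never corrupts the state
#' file.
#'
#' @param session A `blindcut_session`.
#' @param path Target path (default: the session's own `state_path`).
#' @return The path, invisibly.
#' @export
save_session <- function(session, path = session$state_path) {
  if (is.null(path)) {
    stop_blindcut("blindcut_argument_error", "no state path for this session")
  }
  json <- jsonlite::toJSON(serialize_session(session), auto_unbox = TRUE,
                           null = "null", digits = NA, pretty = TRUE)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  ok <- tryCatch({ writeLines(json, tmp, useBytes = TRUE); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    stop_blindcut("blindcut_io_error", sprintf("cannot write session state '%s'", path))
  }
  invisible(path)
}

load_fail <- function(path, why) {
  stop_blindcut("blindcut_load_error",
                sprintf("cannot resume from '%s': %s (re-randomization is never performed)", path, why))
}

#' Resume a persisted session
#'
#' Restores a session from its state file with the identical order, blinded
#' IDs, scores and cursor, so analysis can be halted and restarted without
#' compromising the original random order. Every structural invariant is
#' re-validated; a corrupt or tampered state file is a load error — the
#' session is never silently re-randomized.
#'
#' @param state_path Path to `session.json`.
#' @return A `blindcut_session`.
#' @export
resume_session <- function(state_path) {
  if (!file.exists(state_path)) load_fail(state_path, "state file does not exist")
  raw <- tryCatch(jsonlite::read_json(state_path),
                  error = function(e) load_fail(state_path, conditionMessage(e)))
  need <- c("schema_version", "session_id", "seed", "stage_names", "segments",
            "order", "blinded_ids", "media_files", "scores", "cursor")
  if (!all(need %in% names(raw))) {
    load_fail(state_path, sprintf("missing fields: %s", paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  if (!identical(as.integer(raw$schema_version), SESSION_SCHEMA_VERSION)) {
    load_fail(state_path, sprintf("unsupported schema version %s", raw$schema_version))
  }
  n <- length(raw$segments)
  ord <- vapply(raw$order, as.integer, 0L)
  if (length(ord) != n || !identical(sort(ord), seq_len(n))) {
    load_fail(state_path, "order is not a permutation of the segments")
  }
  ids <- vapply(raw$blinded_ids, as.character, "")
  if (length(ids) != n || anyDuplicated(ids)) {
    load_fail(state_path, "blinded IDs are not distinct")
  }
  cursor <- as.integer(raw$cursor)
  if (is.na(cursor) || cursor < 0L || cursor > n) load_fail(state_path, "cursor out of range")
  stages <- vapply(raw$stage_names, as.character, "")
  if (length(stages) == 0L) load_fail(state_path, "no stage names")

  segments <- lapply(raw$segments, function(s) {
    src <- s$source
    structure(list(
      label = as.character(s$label),
      rect = rect_spec(s$x, s$y, s$w, s$h),
      source = media_ref(src$path, src$media_type, src$width, src$height,
                         src$frame_count, src$fps %||% NA_real_)
    ), class = "segment_spec")
  })
  labels <- vapply(segments, function(s) s$label, "")
  if (anyDuplicated(labels)) load_fail(state_path, "duplicate segment labels")

  expected_scored <- ids[ord[seq_len(cursor)]]
  scores <- raw$scores
  if (length(scores) != cursor || !setequal(names(scores), expected_scored)) {
    load_fail(state_path, "scores do not match the cursor position")
  }
  scores <- lapply(scores, function(sc) {
    nt <- sc$notes
    if (!setequal(names(nt), stages)) load_fail(state_path, "a score record does not cover every stage")
    list(blinded_id = as.character(sc$blinded_id),
         notes = stats::setNames(lapply(stages, function(st) as.character(nt[[st]])), stages),
         completed_at = as.character(sc$completed_at %||% ""))
  })

  media_files <- raw$media_files
  media_files <- stats::setNames(lapply(media_files, as.character), names(media_files))

  structure(list(
    schema_version = SESSION_SCHEMA_VERSION,
    session_id = as.character(raw$session_id),
    seed = as.integer(raw$seed),
    stage_names = stages,
    segments = segments,
    order = ord,
    blinded_ids = ids,
    media_files = media_files,
    scores = scores,
    cursor = cursor,
    state_path = state_path
  ), class = "blindcut_session")
}
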