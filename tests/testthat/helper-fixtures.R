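# Fixtures are generated in code at test time; nothing binary ships with
# the package.

rand_frame <- function(h, w, channels = 3L) {
  a <- array(sample.int(256L, h * w * channels, replace = TRUE) - 1L, c(h, w, channels))
  storage.mode(a) <- "integer"
  a
}

rand_frames <- function(n, h, w) lapply(seq_len(n), function(i) rand_frame(h, w))

# Minimal synthetic ISO BMFF (MP4) byte stream: ftyp + moov with one video
# trak carrying tkhd dimensions, mdhd timescale/duration and an stsz sample
# table. Built from the published box layout, independently of the parser
# under test. No codec payload — structural probing only.
write_synthetic_mp4 <- function(path, width, height, frame_count, fps) {
  be32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")
  be16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "big")
  box <- function(type, payload) c(be32(length(payload) + 8L), charToRaw(type), payload)
  fullbox <- function(type, payload) box(type, c(raw(4), payload)) # version 0, flags 0

  ftyp <- box("ftyp", c(charToRaw("isom"), be32(0L), charToRaw("isom")))
  tkhd <- fullbox("tkhd", c(
    be32(0L), be32(0L), be32(1L), be32(0L), be32(frame_count), # times, id, duration
    raw(8), be16(0L), be16(0L), be16(0L), be16(0L),
    be32(65536L), be32(0L), be32(0L), be32(0L), be32(65536L), be32(0L),
    be32(0L), be32(0L), be32(1073741824L),                     # identity matrix
    be32(width * 65536L), be32(height * 65536L)
  ))
  mdhd <- fullbox("mdhd", c(be32(0L), be32(0L), be32(as.integer(fps)),
                            be32(frame_count), be16(0x55c4L), be16(0L)))
  stsz <- fullbox("stsz", c(be32(0L), be32(frame_count),
                            do.call(c, lapply(seq_len(frame_count), function(i) be32(100L)))))
  stbl <- box("stbl", stsz)
  minf <- box("minf", stbl)
  mdia <- box("mdia", c(mdhd, minf))
  trak <- box("trak", c(tkhd, mdia))
  moov <- box("moov", trak)
  writeBin(c(ftyp, moov), path)
  invisible(path)
}

# label -> deterministic note, the test-side ledger used as the join oracle
ledger_note <- function(label, stage) sprintf("obs[%s|%s]", label, stage)

# a 60-segment image-backed session: labels A1..E12 over a 5x12 grid
make_grid_session <- function(dir, stages = c("behavior"), seed = 101L,
                              rows = 5L, cols = 12L, persist = TRUE) {
  src_path <- file.path(dir, "plate.png")
  write_segment(rand_frame(rows * 10L, cols * 10L), src_path)
  src <- probe_media(src_path)
  grid <- plate_grid(rows, cols, origin = c(0, 0), pitch = 10, well_size = 10)
  segs <- list()
  for (lab in names(grid)) segs <- add_segment(segs, lab, grid[[lab]], src)
  create_session(segs, stages, seed = seed,
                 state_path = if (persist) file.path(dir, "session.json"))
}

# score every remaining segment, notes drawn from the ledger
score_all <- function(session) {
  while (!isTRUE((nxt <- next_segment(session))$done)) {
    idx <- session$order[session$cursor + 1L]
    lab <- session$segments[[idx]]$label
    notes <- lapply(session$stage_names, function(st) ledger_note(lab, st))
    names(notes) <- session$stage_names
    session <- record_score(session, nxt$blinded_id, notes)
  }
  session
}

# substring leak scan: which forbidden strings occur in any of `strings`?
leak_hits <- function(strings, forbidden) {
  unique(unlist(lapply(forbidden, function(f) {
    if (any(grepl(f, strings, fixed = TRUE))) f else character(0)
  })))
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}
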