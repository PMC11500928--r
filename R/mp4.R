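# MP4 (ISO base media) structural probe: walks the box tree and extracts
# track dimensions, sample count and timescale/duration from
# moov/trak/{tkhd, mdia/{mdhd, minf/stbl/stsz}}. Payload decoding of
# compressed MP4 video is not supported anywhere in this package; the probe
# exists so batch selection can report dimensions and frame counts.

rd_u32be <- function(buf, off) {
  sum(as.integer(buf[off + 1:4]) * c(16777216, 65536, 256, 1))
}

probe_mp4 <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop_blindcut("blindcut_io_error", sprintf("cannot read '%s'", path))
  buf <- readBin(path, "raw", n = sz)

  info <- list(width = NULL, height = NULL, timescale = NULL,
               duration = NULL, sample_count = NULL)
  container <- c("moov", "trak", "mdia", "minf", "stbl")

  walk <- function(off, end) {
    while (off + 8 <= end) {
      size <- rd_u32be(buf, off)
      type <- rawToChar(buf[off + 5:8])
      hdr <- 8
      if (size == 1) { # 64-bit size; high word assumed 0 at these file sizes
        if (off + 16 > end) break
        size <- rd_u32be(buf, off + 12)
        hdr <- 16
      } else if (size == 0) {
        size <- end - off
      }
      if (size < hdr || off + size > end) {
        stop_blindcut("blindcut_decode_error", sprintf("corrupt box at offset %d in '%s'", off, path))
      }
      body <- off + hdr
      if (type %in% container) {
        walk(body, off + size)
      } else if (type == "tkhd" && is.null(info$width)) {
        ver <- as.integer(buf[body + 1])
        wo <- body + (if (ver == 1) 88 else 76) # fixed 16.16 width after matrix
        width <- rd_u32be(buf, wo) / 65536
        height <- rd_u32be(buf, wo + 4) / 65536
        if (width > 0 && height > 0) { info$width <<- round(width); info$height <<- round(height) }
      } else if (type == "mdhd" && is.null(info$timescale)) {
        ver <- as.integer(buf[body + 1])
        if (ver == 1) {
          info$timescale <<- rd_u32be(buf, body + 20)
          info$duration <<- rd_u32be(buf, body + 28) # low word
        } else {
          info$timescale <<- rd_u32be(buf, body + 12)
          info$duration <<- rd_u32be(buf, body + 16)
        }
      } else if (type == "stsz" && is.null(info$sample_count)) {
        info$sample_count <<- rd_u32be(buf, body + 8)
      }
      off <- off + size
    }
  }
  walk(0L, length(buf))

  if (is.null(info$width) || is.null(info$sample_count)) {
    stop_blindcut("blindcut_decode_error",
                  sprintf("'%s': no parseable video track (tkhd/stsz) found", path))
  }
  fps <- NULL
  if (!is.null(info$timescale) && !is.null(info$duration) && info$duration > 0) {
    fps <- info$sample_count * info$timescale / info$duration
  }
  list(width = info$width, height = info$height,
       frame_count = info$sample_count, fps = fps %||% 25)
}
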