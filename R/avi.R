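# Minimal AVI (RIFF) container support: raw 24-bit DIB frames (lossless)
# and MJPEG frames (each chunk a JPEG image, decoded via the jpeg package).
# Only single-video-stream files produced by this package or other writers
# of the same subset are supported; anything else raises a decode error.

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
fourcc <- function(s) charToRaw(s)

rd_u32 <- function(buf, off) readBin(buf[off + 1:4], "integer", size = 4, endian = "little")
rd_u16 <- function(buf, off) readBin(buf[off + 1:2], "integer", size = 2, signed = FALSE, endian = "little")
rd_4cc <- function(buf, off) rawToChar(buf[off + 1:4])

riff_chunk <- function(id, data) {
  out <- c(fourcc(id), u32le(length(data)), data)
  if (length(data) %% 2L == 1L) out <- c(out, as.raw(0L)) # word alignment
  out
}
riff_list <- function(type, data) riff_chunk("LIST", c(fourcc(type), data))

# Frame arrays are integer [h, w, channels] in 0..255. DIB payload is
# bottom-up BGR with rows padded to a 4-byte boundary.
frame_to_rgb3 <- function(frame) {
  d <- dim(frame)
  if (is.null(d) || length(d) == 2L) frame <- array(frame, c(dim(frame) %||% c(length(frame), 1L), 1L))
  ch <- dim(frame)[3]
  if (ch == 1L) frame <- frame[, , c(1L, 1L, 1L), drop = FALSE]
  else if (ch == 2L) frame <- frame[, , c(1L, 1L, 1L), drop = FALSE] # gray+alpha: drop alpha
  else if (ch == 4L) frame <- frame[, , 1:3, drop = FALSE]           # drop alpha
  frame
}

dib_encode <- function(frame) {
  frame <- frame_to_rgb3(frame)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  bgr <- frame[h:1, , c(3L, 2L, 1L), drop = FALSE]
  bytes <- as.raw(aperm(bgr, c(3L, 2L, 1L)))
  rowbytes <- 3L * w
  pad <- (4L - rowbytes %% 4L) %% 4L
  if (pad > 0L) {
    m <- matrix(bytes, nrow = rowbytes)
    m <- rbind(m, matrix(as.raw(0L), nrow = pad, ncol = h))
    bytes <- as.raw(m)
  }
  bytes
}

dib_decode <- function(bytes, w, h) {
  rowbytes <- 3L * w
  stride <- rowbytes + (4L - rowbytes %% 4L) %% 4L
  if (length(bytes) < stride * h) {
    stop_blindcut("blindcut_decode_error", "truncated DIB frame payload")
  }
  m <- matrix(as.integer(bytes[seq_len(stride * h)]), nrow = stride)[seq_len(rowbytes), , drop = FALSE]
  arr <- array(m, c(3L, w, h))                 # [BGR, col, bottom-up row]
  fr <- aperm(arr, c(3L, 2L, 1L))[h:1, , c(3L, 2L, 1L), drop = FALSE]
  storage.mode(fr) <- "integer"
  fr
}

write_avi <- function(frames, path, fps = 25, codec = c("DIB", "MJPG")) {
  codec <- match.arg(codec)
  h <- dim(frames[[1]])[1]; w <- dim(frames[[1]])[2]
  n <- length(frames)
  payloads <- lapply(frames, function(f) {
    if (codec == "DIB") dib_encode(f)
    else jpeg::writeJPEG(frame_to_rgb3(f) / 255, quality = 0.95)
  })
  chunk_id <- if (codec == "DIB") "00db" else "00dc"
  rowbytes <- 3L * w
  imgsize <- (rowbytes + (4L - rowbytes %% 4L) %% 4L) * h
  bufsize <- max(vapply(payloads, length, 0L))

  avih <- c(
    u32le(round(1e6 / fps)), u32le(0L), u32le(0L), u32le(0x10L), # AVIF_HASINDEX
    u32le(n), u32le(0L), u32le(1L), u32le(bufsize),
    u32le(w), u32le(h), u32le(0L), u32le(0L), u32le(0L), u32le(0L)
  )
  strh <- c(
    fourcc("vids"), fourcc(if (codec == "DIB") "DIB " else "MJPG"),
    u32le(0L), u16le(0L), u16le(0L), u32le(0L),
    u32le(1000L), u32le(round(fps * 1000)),        # dwScale / dwRate
    u32le(0L), u32le(n), u32le(bufsize), u32le(-1L), u32le(0L),
    u16le(0L), u16le(0L), u16le(w), u16le(h)
  )
  strf <- c(
    u32le(40L), u32le(w), u32le(h), u16le(1L), u16le(24L),
    if (codec == "DIB") u32le(0L) else fourcc("MJPG"),
    u32le(imgsize), u32le(0L), u32le(0L), u32le(0L), u32le(0L)
  )
  hdrl <- riff_list("hdrl", c(
    riff_chunk("avih", avih),
    riff_list("strl", c(riff_chunk("strh", strh), riff_chunk("strf", strf)))
  ))

  movi_chunks <- lapply(payloads, function(p) riff_chunk(chunk_id, p))
  # idx1 offsets are relative to the 'movi' fourcc; first chunk sits at 4
  offs <- integer(n); pos <- 4L
  for (i in seq_len(n)) {
    offs[i] <- pos
    pos <- pos + 8L + length(payloads[[i]]) + length(payloads[[i]]) %% 2L
  }
  idx <- do.call(c, lapply(seq_len(n), function(i) {
    c(fourcc(chunk_id), u32le(0x10L), u32le(offs[i]), u32le(length(payloads[[i]])))
  }))
  movi <- riff_list("movi", do.call(c, movi_chunks))
  body <- c(fourcc("AVI "), hdrl, movi, riff_chunk("idx1", idx))

  con <- tryCatch(file(path, "wb"), condition = function(e) {
    stop_blindcut("blindcut_io_error", sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32le(length(body)), body), con)
  invisible(path)
}

# Walks the RIFF tree; returns header info and (optionally) decoded frames.
parse_avi <- function(path, decode = TRUE) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop_blindcut("blindcut_io_error", sprintf("cannot read '%s'", path))
  buf <- readBin(path, "raw", n = sz)
  if (length(buf) < 12 || rd_4cc(buf, 0) != "RIFF" || rd_4cc(buf, 8) != "AVI ") {
    stop_blindcut("blindcut_decode_error", sprintf("'%s' is not a RIFF/AVI file", path))
  }

  hdr <- list(width = NULL, height = NULL, fps = NULL, compression = NULL, bitcount = NULL)
  frame_payloads <- list()

  walk <- function(off, end, in_strl_vids = FALSE) {
    while (off + 8 <= end) {
      id <- rd_4cc(buf, off); size <- rd_u32(buf, off + 4); data <- off + 8
      if (size < 0 || data + size > length(buf)) {
        stop_blindcut("blindcut_decode_error", sprintf("corrupt chunk at offset %d in '%s'", off, path))
      }
      if (id == "LIST") {
        ltype <- rd_4cc(buf, data)
        if (ltype %in% c("hdrl", "strl", "movi")) walk(data + 4, data + size)
      } else if (id == "strh") {
        if (rd_4cc(buf, data) == "vids" && is.null(hdr$fps)) {
          scale <- rd_u32(buf, data + 20); rate <- rd_u32(buf, data + 24)
          if (scale > 0 && rate > 0) hdr$fps <<- rate / scale
          hdr$handler <<- rd_4cc(buf, data + 4)
        }
      } else if (id == "strf") {
        if (is.null(hdr$width)) {
          hdr$width <<- rd_u32(buf, data + 4)
          hdr$height <<- rd_u32(buf, data + 8)
          hdr$bitcount <<- rd_u16(buf, data + 14)
          hdr$compression <<- buf[data + 17:20]
        }
      } else if (grepl("^[0-9]{2}d[bc]$", id)) {
        frame_payloads[[length(frame_payloads) + 1L]] <<- buf[data + seq_len(size)]
      }
      off <- data + size + size %% 2L
    }
  }
  walk(12L, length(buf))

  if (is.null(hdr$width) || hdr$width <= 0 || is.null(hdr$height)) {
    stop_blindcut("blindcut_decode_error", sprintf("no video stream header found in '%s'", path))
  }
  comp <- hdr$compression
  is_dib <- all(comp == as.raw(0L))
  is_mjpg <- identical(rawToChar(comp), "MJPG")
  frames <- NULL
  if (decode) {
    if (is_dib) {
      if (hdr$bitcount != 24L) {
        stop_blindcut("blindcut_decode_error",
                      sprintf("unsupported DIB bit depth %d in '%s' (only 24-bit)", hdr$bitcount, path))
      }
      frames <- lapply(frame_payloads, dib_decode, w = hdr$width, h = hdr$height)
    } else if (is_mjpg) {
      frames <- lapply(frame_payloads, function(p) {
        a <- jpeg::readJPEG(p)
        if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
        storage.mode(a) <- "double"
        f <- round(a * 255)
        storage.mode(f) <- "integer"
        frame_to_rgb3(f)
      })
    } else {
      stop_blindcut("blindcut_decode_error",
                    sprintf("unsupported AVI codec '%s' in '%s' (supported: raw DIB, MJPG)",
                            rawToChar(comp[comp != as.raw(0)]), path))
    }
  }
  list(width = hdr$width, height = hdr$height,
       fps = hdr$fps %||% 25, frame_count = length(frame_payloads), frames = frames)
}
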