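# 24-bit uncompressed Windows BMP (BITMAPINFOHEADER, bottom-up). The pixel
# payload is the same bottom-up padded BGR layout as a raw AVI frame, so the
# DIB codec helpers are reused.

write_bmp <- function(frame, path) {
  frame <- frame_to_rgb3(frame)
  pix <- dib_encode(frame)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  header <- c(
    charToRaw("BM"), u32le(14L + 40L + length(pix)), u32le(0L), u32le(54L),
    u32le(40L), u32le(w), u32le(h), u16le(1L), u16le(24L),
    u32le(0L), u32le(length(pix)), u32le(2835L), u32le(2835L), u32le(0L), u32le(0L)
  )
  con <- tryCatch(file(path, "wb"), condition = function(e) {
    stop_blindcut("blindcut_io_error", sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeBin(c(header, pix), con)
  invisible(path)
}

read_bmp <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop_blindcut("blindcut_io_error", sprintf("cannot read '%s'", path))
  buf <- readBin(path, "raw", n = sz)
  if (length(buf) < 54 || rawToChar(buf[1:2]) != "BM") {
    stop_blindcut("blindcut_decode_error", sprintf("'%s' is not a BMP file", path))
  }
  data_off <- rd_u32(buf, 10)
  w <- rd_u32(buf, 18); h <- rd_u32(buf, 22)
  bitcount <- rd_u16(buf, 28); compression <- rd_u32(buf, 30)
  if (bitcount != 24L || compression != 0L || h <= 0L) {
    stop_blindcut("blindcut_decode_error",
                  sprintf("unsupported BMP variant in '%s' (only 24-bit uncompressed bottom-up)", path))
  }
  dib_decode(buf[(data_off + 1L):length(buf)], w, h)
}
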