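test_that("probe_media reports type, dimensions and frame count for generated fixtures", {
  set.seed(11)
  td <- withr::local_tempdir()

  p_png <- file.path(td, "im.png")
  write_segment(rand_frame(48, 64), p_png)
  m <- probe_media(p_png)
  expect_equal(m$media_type, "image")
  expect_equal(c(m$width, m$height, m$frame_count), c(64, 48, 1))

  p_avi <- file.path(td, "clip.AVI") # case-insensitive extension
  write_segment(rand_frames(10, 96, 128), p_avi, fps = 20)
  v <- probe_media(p_avi)
  expect_equal(v$media_type, "video")
  expect_equal(c(v$width, v$height, v$frame_count), c(128, 96, 10))
  expect_equal(v$fps, 20)
})

test_that("unsupported extensions give a format error; unreadable files a decode/io error", {
  expect_error(probe_media("clip.mov"), class = "blindcut_format_error")
  expect_error(probe_media("slide.tiff"), class = "blindcut_format_error")
  expect_error(probe_media("absent.png"), class = "blindcut_io_error")
  garbage <- withr::local_tempfile(fileext = ".avi")
  writeBin(as.raw(sample.int(256, 200, TRUE) - 1L), garbage)
  expect_error(probe_media(garbage), class = "blindcut_decode_error")
})

test_that("read_frame honors 1-based bounds and returns stored ground-truth frames", {
  set.seed(12)
  td <- withr::local_tempdir()
  truth <- rand_frames(6, 40, 30)
  p <- file.path(td, "v.avi")
  m <- write_segment(truth, p, fps = 25)
  expect_identical(read_frame(m, 4), truth[[4]])
  expect_error(read_frame(m, 0), class = "blindcut_bounds_error")
  expect_error(read_frame(m, 7), class = "blindcut_bounds_error")

  col <- array(17L, c(20, 20, 3))
  pi_ <- file.path(td, "c.png")
  mi <- write_segment(col, pi_)
  expect_identical(read_frame(mi, 1), col)
  expect_error(read_frame(mi, 2), class = "blindcut_bounds_error")
})

test_that("lossless formats round-trip pixel values bit-exactly", {
  set.seed(13)
  td <- withr::local_tempdir()
  img <- rand_frame(33, 57) # odd width exercises BMP row padding
  for (ext in c(".png", ".bmp")) {
    p <- file.path(td, paste0("x", ext))
    m <- write_segment(img, p)
    expect_equal(c(m$width, m$height, m$frame_count), c(57, 33, 1))
    expect_identical(read_frames(m)[[1]], img, label = ext)
  }
  frames <- rand_frames(5, 21, 35)
  p <- file.path(td, "x.avi")
  m <- write_segment(frames, p, fps = 10)
  expect_equal(m$frame_count, 5)
  expect_identical(read_frames(m), frames)
})

test_that("lossy formats preserve dimensions and frame count", {
  set.seed(14)
  td <- withr::local_tempdir()
  img <- rand_frame(24, 36)
  mj <- write_segment(img, file.path(td, "x.jpg"))
  expect_equal(c(mj$width, mj$height, mj$frame_count), c(36, 24, 1))
  mv <- write_segment(rand_frames(4, 24, 36), file.path(td, "x.avi"), fps = 5, codec = "MJPG")
  expect_equal(c(mv$width, mv$height, mv$frame_count), c(36, 24, 4))
  expect_equal(dim(read_frames(mv)[[2]]), c(24L, 36L, 3L))
})

test_that("write_segment validates its inputs", {
  td <- withr::local_tempdir()
  expect_error(write_segment(list(), file.path(td, "x.png")),
               class = "blindcut_argument_error")
  expect_error(write_segment(rand_frames(2, 8, 8), file.path(td, "x.png")),
               class = "blindcut_argument_error")
  expect_error(write_segment(list(rand_frame(8, 8), rand_frame(9, 8)), file.path(td, "x.avi")),
               class = "blindcut_argument_error")
  expect_error(write_segment(rand_frames(2, 8, 8), file.path(td, "x.mp4")),
               class = "blindcut_format_error")
  expect_error(write_segment(rand_frame(8, 8), file.path(td, "no", "such", "dir", "x.avi")),
               class = "blindcut_io_error")
})

test_that("mp4 files are probed structurally but frame decoding is refused", {
  td <- withr::local_tempdir()
  p <- file.path(td, "synthetic.mp4")
  write_synthetic_mp4(p, width = 320, height = 240, frame_count = 48, fps = 24)
  m <- probe_media(p)
  expect_equal(m$media_type, "video")
  expect_equal(c(m$width, m$height, m$frame_count), c(320, 240, 48))
  expect_equal(m$fps, 24)
  expect_error(read_frames(m), class = "blindcut_decode_error")
})

test_that("grayscale and alpha-channel images survive the write path", {
  td <- withr::local_tempdir()
  gray <- array(sample(0:255, 30 * 20, TRUE), c(20, 30, 1)); storage.mode(gray) <- "integer"
  m <- write_segment(gray, file.path(td, "g.png"))
  expect_identical(read_frames(m)[[1]], gray) # PNG keeps single channel
  mb <- write_segment(gray, file.path(td, "g.bmp")) # BMP promotes to 3 channels
  back <- read_frames(mb)[[1]]
  expect_equal(dim(back), c(20L, 30L, 3L))
  expect_identical(back[, , 1], gray[, , 1])
  rgba <- rand_frame(12, 12, channels = 4L)
  ma <- write_segment(rgba, file.path(td, "a.png"))
  expect_identical(read_frames(ma)[[1]], rgba)
})
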