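test_that("fisher_yates_shuffle returns valid permutations, deterministic under seed", {
  expect_identical(fisher_yates_shuffle(0, seed = 1), integer(0))
  expect_identical(fisher_yates_shuffle(1, seed = 1), 1L)
  for (n in c(2, 3, 5, 8, 40)) {
    for (s in c(1L, 999L, 2^30)) {
      p <- fisher_yates_shuffle(n, seed = s)
      expect_identical(sort(p), seq_len(n))
    }
  }
  expect_identical(fisher_yates_shuffle(20, seed = 7), fisher_yates_shuffle(20, seed = 7))
  expect_false(identical(fisher_yates_shuffle(20, seed = 7), fisher_yates_shuffle(20, seed = 8)))
  expect_error(fisher_yates_shuffle(-1), class = "blindcut_argument_error")
})

test_that("shuffling leaves the caller's RNG stream untouched", {
  set.seed(555)
  a <- runif(1)
  set.seed(555)
  invisible(fisher_yates_shuffle(50, seed = 9))
  expect_identical(runif(1), a)
})

test_that("create_session assigns rank-ordered blinded IDs that leak nothing", {
  td <- withr::local_tempdir()
  ses <- make_grid_session(td, seed = 31L, persist = FALSE)
  n <- length(ses$segments)
  expect_equal(n, 60)
  expect_identical(sort(ses$blinded_ids), sprintf("S%03d", 1:60))
  # rank k of the shuffled order carries ID S00k
  expect_identical(ses$blinded_ids[ses$order], sprintf("S%03d", 1:60))
  labels <- vapply(ses$segments, function(s) s$label, "")
  expect_length(leak_hits(ses$blinded_ids, labels), 0)
  # determinism: same segments + seed => same order
  ses2 <- create_session(ses$segments, ses$stage_names, seed = 31L)
  expect_identical(ses2$order, ses$order)

  expect_error(create_session(list(), "stage"), class = "blindcut_argument_error")
  expect_error(create_session(ses$segments, character()), class = "blindcut_argument_error")
})

test_that("single-segment session gets ID S001 and completes after one score", {
  td <- withr::local_tempdir()
  p <- file.path(td, "i.png"); write_segment(rand_frame(10, 10), p)
  segs <- add_segment(list(), "A1", rect_spec(0, 0, 10, 10), probe_media(p))
  ses <- create_session(segs, c("s1"), seed = 5)
  expect_identical(ses$order, 1L)
  expect_identical(ses$blinded_ids, "S001")
  nxt <- next_segment(ses)
  expect_false(nxt$done)
  expect_equal(nxt$blinded_id, "S001")
  ses <- record_score(ses, "S001", list(s1 = "fine"))
  expect_true(next_segment(ses)$done)
})

test_that("record_score enforces presentation order and complete stage coverage", {
  td <- withr::local_tempdir()
  ses <- make_grid_session(td, stages = c("stage A", "stage B"), seed = 32L, persist = FALSE)
  cur <- next_segment(ses)$blinded_id
  other <- setdiff(ses$blinded_ids, cur)[1]
  expect_error(record_score(ses, other, list(`stage A` = "x", `stage B` = "y")),
               class = "blindcut_sequencing_error")
  expect_error(record_score(ses, cur, list(`stage A` = "x")),
               class = "blindcut_validation_error")
  expect_error(record_score(ses, cur, list(`stage A` = "x", `stage B` = "y", rogue = "z")),
               class = "blindcut_validation_error")
  ses <- record_score(ses, cur, list(`stage A` = "x", `stage B` = ""))
  expect_equal(ses$cursor, 1L)
  ses <- score_all(ses)
  expect_equal(ses$cursor, 60L)
  expect_error(record_score(ses, cur, list(`stage A` = "x", `stage B` = "y")),
               class = "blindcut_sequencing_error")
})

test_that("session state round-trips field-for-field through save and resume", {
  td <- withr::local_tempdir()
  ses <- make_grid_session(td, stages = c("s1", "s2"), seed = 33L)
  for (k in 1:7) {
    nxt <- next_segment(ses)
    ses <- record_score(ses, nxt$blinded_id, list(s1 = sprintf("n%d", k), s2 = "q\"uo,te\nline"))
  }
  back <- resume_session(file.path(td, "session.json"))
  expect_identical(back$order, ses$order)
  expect_identical(back$blinded_ids, ses$blinded_ids)
  expect_identical(back$cursor, 7L)
  expect_identical(back$stage_names, ses$stage_names)
  expect_identical(lapply(back$scores, `[[`, "notes"), lapply(ses$scores, `[[`, "notes"))
  expect_identical(vapply(back$segments, function(s) s$label, ""),
                   vapply(ses$segments, function(s) s$label, ""))
  expect_identical(next_segment(back)$blinded_id, next_segment(ses)$blinded_id)
})

test_that("tampered or corrupt state files are a load error, never a silent reshuffle", {
  td <- withr::local_tempdir()
  ses <- make_grid_session(td, seed = 34L)
  sp <- file.path(td, "session.json")

  st <- jsonlite::read_json(sp)
  st$order[[2]] <- st$order[[1]] # duplicate index: not a permutation
  jsonlite::write_json(st, sp, auto_unbox = TRUE)
  expect_error(resume_session(sp), class = "blindcut_load_error")

  writeLines("{ not json", sp)
  expect_error(resume_session(sp), class = "blindcut_load_error")
  expect_error(resume_session(file.path(td, "absent.json")), class = "blindcut_load_error")

  save_session(ses, sp)
  st <- jsonlite::read_json(sp)
  st$cursor <- 3 # cursor without matching scores
  jsonlite::write_json(st, sp, auto_unbox = TRUE)
  expect_error(resume_session(sp), class = "blindcut_load_error")
})

test_that("resuming after k scorings continues at element k+1 of the original order", {
  td <- withr::local_tempdir()
  ses <- make_grid_session(td, seed = 35L)
  order_log <- ses$blinded_ids[ses$order] # uninterrupted presentation log
  for (k in 1:30) {
    nxt <- next_segment(ses)
    expect_identical(nxt$blinded_id, order_log[k])
    ses <- record_score(ses, nxt$blinded_id,
                        stats::setNames(list("x"), ses$stage_names))
  }
  back <- resume_session(file.path(td, "session.json"))
  expect_identical(next_segment(back)$blinded_id, order_log[31])
})
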