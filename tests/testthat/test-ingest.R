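test_that("record filtering excludes signal-less records and errors when empty", {
  usable <- usable_records(afdb_records())
  expect_equal(nrow(usable), 23)
  expect_false(any(c("00735", "03665") %in% usable$record))
  all_good <- tibble::tibble(record = c("a", "b"), has_signal = TRUE)
  expect_identical(usable_records(all_good)$record, c("a", "b"))
  none <- tibble::tibble(record = "a", has_signal = FALSE)
  expect_error(usable_records(none), "no usable records")
})

test_that("rhythm labels open half-open segments closed by the next label", {
  labs <- tibble::tibble(time_s = c(0, 100, 250),
                         label = c("(N", "(AFIB", "(N"))
  seg <- rhythm_segments(labs, duration_s = 300)
  expect_equal(seg$start_s, c(0, 100, 250))
  expect_equal(seg$end_s, c(100, 250, 300))
  expect_equal(seg$rhythm, c("SR", "AF", "SR"))

  one <- rhythm_segments(tibble::tibble(time_s = 0, label = "(AFL"), 50)
  expect_equal(one$rhythm, "OTHER")

  mixed <- rhythm_segments(
    tibble::tibble(time_s = c(0, 10, 20), label = c("(N", "(J", "(AFIB")), 30)
  expect_equal(mixed$rhythm, c("SR", "OTHER", "AF"))

  expect_warning(
    rhythm_segments(tibble::tibble(time_s = 0, label = "(WEIRD"), 10),
    "unknown rhythm")
  expect_error(
    rhythm_segments(tibble::tibble(time_s = c(5, 1), label = c("(N", "(N")), 10),
    "ordered")
})

test_that("RR extraction differences beats within the requested rhythm", {
  seg <- rhythm_segments(tibble::tibble(time_s = 0, label = "(N"), 10)
  beats <- tibble::tibble(time_s = c(1.0, 1.8, 2.6))
  expect_equal(extract_rr(beats, seg, "SR")$rr_s, c(0.8, 0.8))
  # one qualifying beat -> empty
  expect_equal(nrow(extract_rr(tibble::tibble(time_s = 1), seg, "SR")), 0)
})

test_that("cross-segment concatenation yields a long interval the filter removes", {
  labs <- tibble::tibble(time_s = c(0, 100, 250),
                         label = c("(N", "(AFIB", "(N"))
  seg <- rhythm_segments(labs, duration_s = 300)
  beats <- tibble::tibble(time_s = c(98, 99, 100, 170, 250, 251))
  # beat at 100 s sits on the boundary and belongs to the AF segment, so the
  # last SR beat before the gap is 99 s and the next SR beat is 250 s
  rr <- extract_rr(beats, seg, "SR")
  expect_true(151 %in% rr$rr_s) # spurious interval spanning the AF segment
  kept <- filter_rr_range(rr)
  expect_false(151 %in% kept$rr_s)
  expect_equal(kept$rr_s, c(1, 1))
  # strict within-segment mode never crosses the gap
  rr_strict <- extract_rr(beats, seg, "SR", within_segment = TRUE)
  expect_equal(rr_strict$rr_s, c(1, 1))
})

test_that("every beat lands in exactly one rhythm stream (partition property)", {
  labs <- tibble::tibble(time_s = c(0, 50, 120, 200),
                         label = c("(N", "(AFIB", "(AFL", "(N"))
  seg <- rhythm_segments(labs, duration_s = 300)
  set.seed(2)
  beats <- tibble::tibble(time_s = sort(runif(200, 0, 300)))
  in_seg <- function(rh) {
    s <- seg[seg$rhythm == rh, ]
    sum(vapply(beats$time_s, function(t)
      any(t >= s$start_s & t < s$end_s), logical(1)))
  }
  expect_equal(in_seg("SR") + in_seg("AF") + in_seg("OTHER"), nrow(beats))
  # boundary beat belongs to the later segment
  b <- tibble::tibble(time_s = c(49, 50, 51))
  expect_equal(nrow(extract_rr(b, seg, "AF")), 1) # 50 and 51 are AF beats
})

test_that("range filter keeps closed-interval endpoints and is idempotent", {
  rr <- tibble::tibble(rr_s = c(0.8, 0.24, 1.99, 2.01, 150.0))
  expect_equal(filter_rr_range(rr)$rr_s, c(0.8, 1.99))
  expect_equal(nrow(filter_rr_range(tibble::tibble(rr_s = numeric(0)))), 0)
  ends <- tibble::tibble(rr_s = c(0.25, 2.0))
  expect_equal(filter_rr_range(ends)$rr_s, c(0.25, 2.0))
  once <- filter_rr_range(rr)
  expect_identical(filter_rr_range(once), once)
  expect_lte(nrow(once), nrow(rr))
})

test_that("RR-to-bpm maps the filter bounds to the 30-240 bpm range", {
  expect_equal(rr_to_bpm(0.25), 240)
  expect_equal(rr_to_bpm(2.0), 30)
  expect_equal(rr_to_bpm(1.0), 60)
  expect_error(rr_to_bpm(0), "positive")
})

test_that("RR series round-trip through per-subject CSVs", {
  co <- simulate_rr_cohort(n_subjects = 3, beats_per_subject = 200, seed = 5)
  dir <- withr::local_tempdir()
  man <- write_rr_series(co, dir)
  expect_equal(nrow(man), 6) # 3 subjects x 2 rhythms
  back <- read_rr_series(dir)
  back <- back[order(back$subject_id, back$rhythm), ]
  orig <- co[order(co$subject_id, co$rhythm), ]
  expect_equal(back$rr_s, orig$rr_s, tolerance = 1e-9)
})
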