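fs <- 16000

test_that("frames_from_boundaries tiles and merges sub-minimum frames forward", {
  fr <- frames_from_boundaries(c(0, 50, 100), 100)
  expect_identical(fr$start, c(0L, 50L))
  expect_identical(fr$end, c(50L, 100L))

  expect_identical(nrow(frames_from_boundaries(c(0, 100), 100)), 2L - 1L)
  expect_identical(nrow(frames_from_boundaries(integer(0), 100)), 1L)

  # greedy forward merge: boundaries too close to the previous kept one drop
  fr2 <- frames_from_boundaries(c(0, 40, 50, 100), 100, min_len = 32)
  expect_identical(fr2$start, c(0L, 40L))
  expect_identical(fr2$end, c(40L, 100L))

  # chained short frames collapse entirely
  fr3 <- frames_from_boundaries(c(0, 10, 12, 100), 100, min_len = 32)
  expect_identical(fr3$start, 0L)
  expect_identical(fr3$end, 100L)

  # trailing short frame merges backward
  fr4 <- frames_from_boundaries(c(0, 40, 90), 100, min_len = 32)
  expect_identical(fr4$start, c(0L, 40L))
  expect_identical(fr4$end, c(40L, 100L))
})

test_that("frame energy, mean and thresholds follow the printed arithmetic", {
  fr <- frames_from_boundaries(c(0, 2, 4), 4)
  ep <- frame_energy(c(1, 1, 2, 2), fr, fs)
  expect_equal(ep$E, c(2, 8))
  expect_equal(ep$d, 5)
  expect_equal(ep$theta_lower, 1.6)
  expect_equal(ep$theta_upper, 4.0)
  expect_identical(select_substitution_frames(ep), c(TRUE, FALSE))

  ep0 <- frame_energy(numeric(4), fr, fs)
  expect_equal(ep0$E, c(0, 0))
  expect_equal(ep0$d, 0)

  # scaling leaves the selection mask unchanged
  set.seed(9)
  x <- rnorm(1000)
  frx <- frames_from_boundaries(c(0, 130, 400, 720, 1000), 1000)
  m1 <- select_substitution_frames(frame_energy(x, frx, fs))
  m2 <- select_substitution_frames(frame_energy(3 * x, frx, fs))
  expect_identical(m1, m2)
  expect_equal(frame_energy(3 * x, frx, fs)$E,
               9 * frame_energy(x, frx, fs)$E, tolerance = 1e-12)

  # boundary-exact energies are selected (inclusive window)
  ep_edge <- frame_energy(c(1, 1, 2, 2), fr, fs, alpha = 2 / 5, beta = 0.7)
  expect_true(select_substitution_frames(ep_edge)[1]) # E = theta_lower exactly
})

test_that("FFSR produces the conventional overlapping grid", {
  fr <- ffsr_segment(16000, fs)
  expect_identical(nrow(fr), 98L)
  expect_true(all(fr$end - fr$start == 400L))
  expect_true(all(diff(fr$start) == 160L))
  expect_identical(attr(fr, "mode"), "overlapping")

  expect_identical(nrow(ffsr_segment(400, fs)), 1L)
  expect_warning(fr_short <- ffsr_segment(300, fs), "shorter")
  expect_identical(fr_short$end, 300L)

  fr_tile <- ffsr_segment(16000, fs, frame_ms = 25, shift_ms = 25)
  expect_identical(attr(fr_tile, "mode"), "contiguous")
  expect_identical(fr_tile$end[nrow(fr_tile)], 16000L)
})

test_that("random segmentation is a seeded contiguous partition", {
  expect_identical(nrow(random_segment(16000, 1, seed = 4)), 1L)
  expect_identical(as.data.frame(random_segment(16000, 9, seed = 5)),
                   as.data.frame(random_segment(16000, 9, seed = 5)))
  for (s in 1:25) {
    fr <- random_segment(16000, 9, seed = s)
    expect_identical(nrow(fr), 9L)
    expect_identical(fr$start[1], 0L)
    expect_identical(fr$end[9], 16000L)
    expect_true(all(fr$start[-1] == fr$end[-9]))
    expect_true(all(fr$end - fr$start >= 32L))
  }
  expect_error(random_segment(100, 10, seed = 1, min_len = 32), "infeasible")
})

test_that("reversing frame order preserves the length multiset", {
  fr <- frames_from_boundaries(c(0, 10, 40, 100), 100)
  rv <- reverse_frame_order(fr)
  expect_identical(rv$end - rv$start, c(60L, 30L, 10L))
  expect_identical(rv$start[1], 0L)
  expect_identical(rv$end[3], 100L)

  pal <- frames_from_boundaries(c(0, 10, 40, 70, 80), 80)
  expect_identical(as.data.frame(reverse_frame_order(pal))[c("start", "end")],
                   as.data.frame(pal)[c("start", "end")])

  set.seed(8)
  for (s in 1:10) {
    fr <- random_segment(5000, 7, seed = s)
    rv <- reverse_frame_order(fr)
    expect_identical(sort(rv$end - rv$start), sort(fr$end - fr$start))
    expect_identical(sum(rv$end - rv$start), sum(fr$end - fr$start))
  }
})

test_that("label files round-trip the frame set at 6-decimal seconds", {
  fr <- frames_from_boundaries(c(0, 841, 1831, 2717), 2717)
  path <- tempfile(fileext = ".tsv")
  write_labels(fr, fs, path)
  rt <- read_labels(path, fs, n = 2717)
  expect_identical(as.data.frame(rt), as.data.frame(fr))
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(names(tab), c("start_sec", "end_sec", "source"))
})
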