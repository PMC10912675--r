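## straight-line track of n frames for one cell
line_track <- function(id, n, cond = "custom", step = 1, t0_frame = 0L) {
  data.frame(cell_id = id, condition = cond, frame = t0_frame + seq_len(n) - 1L,
             x_um = step * (seq_len(n) - 1), y_um = 0, stringsAsFactors = FALSE)
}

test_that("segment counts follow the sliding-window formula", {
  cfg <- pipeline_config()
  L <- cfg$segment_len_frames

  s1 <- make_segments(track_set(line_track("a", L), cfg))
  expect_identical(n_segments(s1), 1L)

  s2 <- make_segments(track_set(line_track("a", 40), cfg))
  expect_identical(n_segments(s2), 10L)  # 40 - 31 + 1

  # formula matches brute-force enumeration for random lengths in [L, 5L]
  set.seed(12)
  for (n in sample(L:(5 * L), 6)) {
    s <- make_segments(track_set(line_track("a", n), cfg))
    brute <- sum(vapply(seq_len(n), function(st) st + L - 1 <= n, logical(1)))
    expect_identical(n_segments(s), as.integer(brute))
  }

  # stationary cell: every motility entry is zero
  still <- line_track("a", L, step = 0)
  s3 <- make_segments(track_set(still, cfg))
  expect_true(all(s3$dx == 0) && all(s3$dy == 0))
  expect_identical(ncol(s3$dx), L - 1L)

  # short tracks are skipped with a warning; gaps are an error
  both <- rbind(line_track("a", L), line_track("b", 10))
  expect_warning(sb <- make_segments(track_set(both, cfg)), "shorter")
  expect_identical(unique(sb$meta$cell_id), "a")
  gap <- line_track("a", 40)[-5, ]
  expect_error(make_segments(track_set(gap, cfg)), "missing frames")
})

test_that("displacement series reconstruct the original positions", {
  ts <- small_study()$ts_train
  segs <- suppressWarnings(make_segments(ts))
  set.seed(5)
  for (i in sample(n_segments(segs), 20)) {
    cell <- segs$meta$cell_id[i]
    tr <- ts$tracks[ts$tracks$cell_id == cell, ]
    at <- match(segs$meta$start_frame[i], tr$frame)
    xs <- tr$x_um[at] + cumsum(c(0, segs$dx[i, ]))
    expect_equal(xs, tr$x_um[at:(at + segs$L - 1)], tolerance = 1e-9)
  }
})

test_that("training labels obey the window and condition rules", {
  cfg <- pipeline_config()
  L <- cfg$segment_len_frames

  # differentiating cells: one positive segment, spanning the label window
  ts <- small_study()$ts_train
  segs <- assign_training_labels(suppressWarnings(make_segments(ts, cfg)), cfg)
  pos <- segs$meta[segs$meta$label %in% "differentiated", ]
  expect_identical(nrow(pos), 25L)  # one per differentiating cell
  expect_true(all(pos$condition == "ERKi"))
  expect_true(all(abs(pos$t_start_h - cfg$label_window_hours[1]) <= 5 / 60))
  expect_true(all(abs(pos$t_end_h - cfg$label_window_hours[2]) <= 5 / 60))

  # control tiling: 93 frames -> exactly 3 non-overlapping negatives
  dmso <- track_set(line_track("c", 93, cond = "DMSO"), cfg)
  sd93 <- assign_training_labels(make_segments(dmso, cfg), cfg,
                                 label_window_hours = c(2, 4.5))
  neg <- sd93$meta[sd93$meta$label %in% "undifferentiated", ]
  expect_identical(nrow(neg), 3L)
  expect_identical(neg$start_frame, c(0L, 31L, 62L))

  # perturbation conditions are never labelled
  p38 <- track_set(line_track("p", 93, cond = "p38i"), cfg)
  sp <- assign_training_labels(make_segments(p38, cfg),
                               label_window_hours = c(2, 4.5))
  expect_true(all(is.na(sp$meta$label)))

  # a label window outside the imaged span errors
  expect_error(assign_training_labels(make_segments(dmso, cfg), cfg,
                                      label_window_hours = c(30, 32.5)),
               "outside")

  # the first-fusion anchor labels the window ending at the fusion time
  anchored <- assign_training_labels(suppressWarnings(make_segments(ts, cfg)), cfg,
                                     first_fusion_time_h = 13)
  apos <- anchored$meta[anchored$meta$label %in% "differentiated", ]
  expect_true(all(abs(apos$t_end_h - 13) <= 5 / 120 + 1e-9))
})

test_that("training sets are balanced to the requested class ratio", {
  ts <- small_study()$ts_train
  segs <- assign_training_labels(suppressWarnings(make_segments(ts)))
  train <- make_training_set(segs, neg_pos_ratio = 1.75, seed = 3)
  n_pos <- sum(train$meta$label == "differentiated")
  n_neg <- sum(train$meta$label == "undifferentiated")
  expect_identical(n_pos, 25L)
  expect_lte(n_neg, ceiling(1.75 * n_pos))
  expect_true(all(!is.na(train$meta$label)))
  # deterministic under a fixed seed
  train2 <- make_training_set(segs, neg_pos_ratio = 1.75, seed = 3)
  expect_identical(train$meta, train2$meta)
})

test_that("segment sets survive a CSV round-trip", {
  cfg <- pipeline_config(segment_len_frames = 5)
  ts <- small_study()$ts_train
  ts$tracks <- ts$tracks[ts$tracks$cell_id %in% c("ERKi_001", "DMSO_001"), ]
  segs <- suppressWarnings(make_segments(ts, cfg))
  segs <- subset_segments(segs, 1:50)
  p <- withr::local_tempfile(fileext = ".csv")
  write_segments(segs, p)
  back <- read_segments(p, cfg)
  expect_equal(back$dx, segs$dx, tolerance = 1e-12)
  expect_equal(back$actin$actin_mean, segs$actin$actin_mean, tolerance = 1e-12)
  expect_identical(back$meta$cell_id, segs$meta$cell_id)
  expect_identical(back$L, segs$L)
})
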