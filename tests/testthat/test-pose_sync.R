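make_tracking_fixture <- function(n_frames = 100, n_fish = 2) {
  poses <- tidyr::expand_grid(frame = seq_len(n_frames),
                              fish_id = paste0("fish", seq_len(n_fish)),
                              node = skeleton_nodes)
  # dyadic-rational coordinates survive decimal CSV round-trips bit-exactly
  poses$x_cm <- 10 + poses$frame * 0.125 +
    match(poses$node, skeleton_nodes) + (poses$fish_id == "fish2") * 20
  poses$y_cm <- 20 + poses$frame * 0.0625
  poses$visible <- TRUE
  tracked_sequence(poses, frame_times = (seq_len(n_frames) - 1) / 30)
}

test_that("tracking CSV round-trips bit-exactly and restores node order", {
  seqc <- make_tracking_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_csv(seqc, path)
  back <- load_tracking(path, frame_rate = 30)
  expect_identical(back$poses$x_cm, seqc$poses$x_cm)
  expect_identical(back$poses$y_cm, seqc$poses$y_cm)
  expect_equal(nrow(back$poses), 100 * 2 * 6)
  # shuffled node order in the file comes back canonical
  raw <- read.csv(path)
  raw <- raw[order(rev(seq_len(nrow(raw)))), ]
  write.csv(raw, path, row.names = FALSE)
  shuffled <- load_tracking(path, frame_rate = 30)
  expect_equal(shuffled$poses$node[1:6], skeleton_nodes)
  expect_identical(shuffled$poses$x_cm, seqc$poses$x_cm)
})

test_that("schema violations and animal counts are rejected", {
  seqc <- make_tracking_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_csv(seqc, path)
  raw <- read.csv(path)
  bad <- raw[raw$node != "tail", ]
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_tracking(path), class = "pulseid_schema_error")
  three <- rbind(raw, transform(raw[raw$track == "fish1", ], track = "fish3"))
  write.csv(three, path, row.names = FALSE)
  expect_error(load_tracking(path), class = "pulseid_unsupported_count")
})

test_that("an undetected node becomes invisible while the others stay intact", {
  seqc <- make_tracking_fixture(n_frames = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_csv(seqc, path)
  raw <- read.csv(path)
  drop <- raw$frame == 5 & raw$track == "fish1" & raw$node == "mid1"
  raw$x[drop] <- NA; raw$y[drop] <- NA
  write.csv(raw, path, row.names = FALSE)
  back <- load_tracking(path)
  p5 <- back$poses[back$poses$frame == 5, ]
  expect_false(p5$visible[p5$fish_id == "fish1" & p5$node == "mid1"])
  expect_true(all(p5$visible[!(p5$fish_id == "fish1" & p5$node == "mid1")]))
})

test_that("the HDF5 analysis export converts through the bundled script", {
  h5 <- withr::local_tempfile(fileext = ".h5")
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import h5py, numpy as np",
    "t = np.full((2, 2, 6, 4), np.nan)",
    "for f in range(4):",
    "    for ti in range(2):",
    "        for ni in range(6):",
    "            t[ti, 0, ni, f] = 10*ti + f + ni",
    "            t[ti, 1, ni, f] = 5 + f",
    "t[1, :, 2, 3] = np.nan",
    sprintf("with h5py.File(%s, 'w') as h:", deparse(h5)),
    "    h['tracks'] = t",
    "    h['node_names'] = np.array(['Schnauzenorgan','head1','head2','mid1','mid2','tail'], dtype='S')",
    "    h['track_names'] = np.array(['fish1','fish2'], dtype='S')"), py)
  res <- system2(Sys.which("python"), py)
  expect_equal(res, 0L)
  csv <- withr::local_tempfile(fileext = ".csv")
  convert_tracking_h5(h5, csv)
  seqc <- load_tracking(csv, frame_rate = 30)
  expect_equal(length(seqc$frame_times), 4)
  p <- seqc$poses
  expect_equal(p$x_cm[p$frame == 2 & p$fish_id == "fish1" &
                        p$node == "head2"], 3)
  expect_false(p$visible[p$frame == 4 & p$fish_id == "fish2" &
                           p$node == "head2"])
})

test_that("TTL edges give one frame time per exposure", {
  fs <- 125000
  n <- fs  # 1 s
  ttl <- numeric(n)
  idx <- round(seq(0, 0.99, by = 1 / 30) * fs) + 1
  for (k in 0:9) ttl[idx + k] <- 5
  rec <- multichannel_recording(matrix(0, n, 1), ttl = ttl)
  clock <- sync_frames(rec, length(idx))
  expect_length(clock$ttl_times, 30)
  expect_equal(diff(clock$ttl_times), rep(1 / 30, 29), tolerance = 1e-3)
  # recovered within one sample of the true pulse starts
  expect_true(all(abs(clock$ttl_times - (idx - 1) / fs) <= 1 / fs))
  # missing final pulse is a sync error that reports both counts
  ttl2 <- ttl; ttl2[idx[30]:(idx[30] + 9)] <- 0
  rec2 <- multichannel_recording(matrix(0, n, 1), ttl = ttl2)
  expect_error(sync_frames(rec2, 30), class = "pulseid_sync_error")
  expect_error(sync_frames(multichannel_recording(matrix(0, 10, 1)), 1),
               class = "pulseid_sync_error")
})

test_that("pose interpolation is exact at frames, linear between them", {
  seqc <- make_tracking_fixture(n_frames = 20)
  # exactly at a frame time: that frame's pose
  p <- poses_at_times(seqc, seqc$frame_times[7])
  truth <- seqc$poses[seqc$poses$frame == 7, ]
  merged <- dplyr::left_join(p, truth, by = c("fish_id", "node"),
                             suffix = c("", "_t"))
  expect_equal(merged$x_cm, merged$x_cm_t)
  # midpoint of two frames: nodewise midpoint
  tm <- mean(seqc$frame_times[7:8])
  pm <- poses_at_times(seqc, tm)
  t7 <- seqc$poses[seqc$poses$frame == 7, ]
  t8 <- seqc$poses[seqc$poses$frame == 8, ]
  expect_equal(pm$x_cm, (t7$x_cm + t8$x_cm) / 2)
  # out of range errors
  expect_error(poses_at_times(seqc, -1), class = "pulseid_range_error")
})

test_that("invisible flanking nodes fall back to the visible frame", {
  seqc <- make_tracking_fixture(n_frames = 5)
  sel <- seqc$poses$frame == 4 & seqc$poses$fish_id == "fish1" &
    seqc$poses$node == "tail"
  seqc$poses$visible[sel] <- FALSE
  tm <- mean(seqc$frame_times[3:4])
  p <- poses_at_times(seqc, tm)
  v3 <- seqc$poses[seqc$poses$frame == 3 & seqc$poses$fish_id == "fish1" &
                     seqc$poses$node == "tail", ]
  got <- p[p$fish_id == "fish1" & p$node == "tail", ]
  expect_equal(got$x_cm, v3$x_cm)  # previous frame used, not interpolated
})

test_that("interpolated poses are continuous in time", {
  seqc <- make_tracking_fixture(n_frames = 10)
  tt <- seq(seqc$frame_times[2], seqc$frame_times[9], by = 0.001)
  p <- poses_at_times(seqc, tt)
  one <- p[p$fish_id == "fish1" & p$node == "head2", ]
  one <- one[order(one$t), ]
  expect_true(all(abs(diff(one$x_cm)) < 0.01))
  expect_true(all(abs(diff(one$y_cm)) < 0.01))
})

test_that("identity-swap jumps raise a warning", {
  poses <- tidyr::expand_grid(frame = 1:3, fish_id = "fish1",
                              node = skeleton_nodes)
  poses$x_cm <- c(rep(10, 6), rep(10.5, 6), rep(40, 6))
  poses$y_cm <- 20
  poses$visible <- TRUE
  expect_warning(tracked_sequence(poses, frame_times = (0:2) / 30),
                 "identity")
})
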