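make_single_pulse_rec <- function(fs = 125000, amp = c(0.5, -0.3, 0.2, 0, 0, 0, 0.1),
                                  at_s = 0.01, dur_s = 0.02, noise = 0,
                                  seed = 1) {
  tpl <- make_biphasic_pulse(fs)
  n <- round(dur_s * fs)
  x <- matrix(0, n, length(amp))
  if (noise > 0) {
    x <- pulseid:::with_seed(seed, matrix(rnorm(n * length(amp), 0, noise),
                                          n, length(amp)))
  }
  i0 <- round(at_s * fs) - which.max(abs(tpl)) + 1
  idx <- i0:(i0 + length(tpl) - 1)
  x[idx, ] <- x[idx, ] + outer(tpl, amp)
  multichannel_recording(x, sampling_rate = fs)
}

test_that("threshold detection finds single pulses and rejects noise", {
  rec <- make_single_pulse_rec()
  det <- detect_eods(rec, rep(0.1, 7))
  expect_equal(nrow(det), 1)
  expect_true(abs(det$time_s - 0.01) < 300e-6)
  # pure noise below threshold: no events
  quiet <- multichannel_recording(
    pulseid:::with_seed(2, matrix(rnorm(5000 * 7, 0, 0.01), 5000, 7)))
  expect_equal(nrow(detect_eods(quiet, rep(0.1, 7))), 0)
  expect_error(detect_eods(rec, rep(-1, 7)), class = "pulseid_parameter_error")
})

test_that("the refractory rule keeps the earlier of two close pulses", {
  fs <- 125000
  tpl <- make_biphasic_pulse(fs)
  x <- matrix(0, 5000, 7)
  i1 <- 2000
  i2 <- i1 + round(300e-6 * fs)  # 300 us later
  x[i1:(i1 + 49), 1] <- tpl
  x[i2:(i2 + 49), 2] <- tpl
  rec <- multichannel_recording(x)
  det <- detect_eods(rec, rep(0.3, 7))
  expect_equal(nrow(det), 1)
  # the surviving event is the earlier pulse, refined to its peak
  expect_equal(det$sample, i1 + which.max(abs(tpl)) - 1L)
  # 500 us apart: both kept, strictly increasing, no refractory violation
  x2 <- matrix(0, 5000, 7)
  i3 <- i1 + round(500e-6 * fs)
  x2[i1:(i1 + 49), 1] <- tpl
  x2[i3:(i3 + 49), 2] <- tpl
  det2 <- detect_eods(multichannel_recording(x2), rep(0.3, 7))
  expect_equal(nrow(det2), 2)
  expect_true(all(diff(det2$time_s) >= 400e-6))
})

test_that("alignment re-centres the peak and fixes the window layout", {
  rec <- make_single_pulse_rec()
  # jitter the detection time by +/- 2 samples: identical window
  fs <- rec$sampling_rate
  ev0 <- align_and_extract(rec, 0.01)
  for (j in c(-2, 2)) {
    evj <- align_and_extract(rec, 0.01 + j / fs)
    expect_identical(evj$window, ev0$window)
  }
  # at 125 kHz the defaults give 34 + 1 + 16 = 51 samples
  expect_equal(nrow(ev0$window), 51)
  expect_equal(ev0$pre_samples, 34)
  expect_equal(ev0$post_samples, 16)
  # the mean-absolute-trace peak sits at index 35 (pre_samples + 1)
  expect_equal(which.max(rowMeans(abs(ev0$window))), 35)
  # boundary windows are rejected / dropped
  expect_error(align_and_extract(rec, 0.0001),
               class = "pulseid_boundary_error")
  expect_message(
    evs <- extract_events(rec, c(0.0001, 0.01)), "dropped")
  expect_length(evs, 1)
})

test_that("waveform vectors are normalized, scale-invariant and idempotent", {
  rec <- make_single_pulse_rec()
  ev <- align_and_extract(rec, 0.01)
  v <- build_vector(ev)
  expect_length(as.numeric(v), 7 * 51)
  expect_equal(max(abs(v)), 1)
  # scaling the input by 10 changes nothing after normalization
  rec10 <- multichannel_recording(rec$samples * 10,
                                  sampling_rate = rec$sampling_rate)
  v10 <- build_vector(align_and_extract(rec10, 0.01))
  expect_equal(as.numeric(v10), as.numeric(v))
  # re-normalizing an already normalized window is the identity
  ev_norm <- ev
  ev_norm$window <- ev$window / max(abs(ev$window))
  expect_equal(as.numeric(build_vector(ev_norm)), as.numeric(v))
  # single nonzero channel: the rest of the vector is zero
  x <- matrix(0, 3000, 7)
  x[1000:1049, 3] <- make_biphasic_pulse(125000)
  one <- build_vector(align_and_extract(multichannel_recording(x), 1000 / 125000))
  expect_equal(sum(abs(one) > 0), sum(abs(one[(2 * 51 + 1):(3 * 51)]) > 0))
  # all-zero windows cannot be normalized
  ev0 <- ev
  ev0$window[] <- 0
  expect_error(build_vector(ev0), class = "pulseid_normalization_error")
})

test_that("the average waveform is the normalized mean absolute trace", {
  rec <- make_single_pulse_rec()
  ev <- align_and_extract(rec, 0.01)
  avg1 <- average_waveform(list(ev, ev, ev))
  expect_equal(max(avg1), 1)
  expect_equal(avg1, rowMeans(abs(ev$window)) / max(rowMeans(abs(ev$window))))
  expect_error(average_waveform(list()), class = "pulseid_data_error")
  # symmetric jitter broadens the average relative to the template
  fs <- 125000
  tpl <- make_biphasic_pulse(fs)
  evs <- lapply(c(-2, 0, 2), function(j) {
    x <- matrix(0, 3000, 7)
    x[(1000 + j):(1049 + j), 1] <- tpl
    ev <- align_and_extract(multichannel_recording(x), 1000 / fs,
                            search_us = 1)  # force the jitter to persist
    ev
  })
  broad <- average_waveform(evs)
  narrow <- rowMeans(abs(evs[[2]]$window)) / max(rowMeans(abs(evs[[2]]$window)))
  # explicit-averaging oracle
  oracle <- Reduce(`+`, lapply(evs, function(e) rowMeans(abs(e$window)))) / 3
  oracle <- oracle / max(oracle)
  expect_equal(broad, oracle)
  expect_gt(sum(broad > 0.25), sum(narrow > 0.25))
})

test_that("doublet screening flags the quantile tail and planted overlaps", {
  made <- doublet_fixture()
  det <- detect_eods(made$recording, suggest_thresholds(made))
  evs <- extract_events(made$recording, det$time_s)
  scr <- doublet_screen(evs)
  expect_s3_class(scr, "doublet_screen")
  # flags are the > (1 - f) quantile tail, sorted descending
  expect_true(all(diff(scr$residual_score) <= 0))
  expect_true(all(scr$residual_score[scr$flagged] > scr$threshold_used[1]))
  # quantile arithmetic: 1% of n events
  expect_equal(sum(scr$flagged),
               sum(scr$residual_score >
                     quantile(scr$residual_score, 0.99, names = FALSE)))
  # every planted overlap is captured in the top-1% queue
  flagged_times <- scr$time_s[scr$flagged]
  for (t in made$planted_times) {
    expect_true(any(abs(flagged_times - t) < 500e-6))
  }
  # an event identical to the average never scores above zero
  avg <- average_waveform(evs)
  scores0 <- abs(sum(pulseid:::event_trace(evs[[1]]) - avg))
  expect_gte(min(scr$residual_score), 0)
  expect_lt(scores0, Inf)
})

test_that("doublet confirmation needs complete decisions and exports times", {
  made <- doublet_fixture()
  det <- detect_eods(made$recording, suggest_thresholds(made))
  evs <- extract_events(made$recording, det$time_s)
  scr <- doublet_screen(evs)
  flagged <- scr$event_id[scr$flagged]
  expect_error(confirm_doublets(scr, data.frame(event_id = flagged[-1],
                                                doublet = TRUE)),
               class = "pulseid_pending_review")
  all_clean <- data.frame(event_id = flagged, doublet = FALSE)
  expect_equal(nrow(confirm_doublets(scr, all_clean)), 0)
  all_doub <- data.frame(event_id = flagged, doublet = TRUE)
  expect_equal(nrow(confirm_doublets(scr, all_doub)), length(flagged))
  # mixed decisions from fixture ground truth confirm only real overlaps
  truth_doublet <- vapply(flagged, function(id) {
    any(abs(scr$time_s[scr$event_id == id] - made$planted_times) < 500e-6)
  }, logical(1))
  confirmed <- confirm_doublets(scr, data.frame(event_id = flagged,
                                                doublet = truth_doublet))
  expect_equal(nrow(confirmed), sum(truth_doublet))
  expect_s3_class(plot_doublet_capture(scr, confirmed$event_id), "ggplot")
})

test_that("detection and extraction recover planted events precisely", {
  made <- cached("snr_fixture", {
    make_recording(scenario(seed = 12, duration_s = 6))
  })
  det <- detect_eods(made$recording, suggest_thresholds(made))
  evs <- extract_events(made$recording, det$time_s)
  tms <- vapply(evs, `[[`, numeric(1), "time_s")
  expect_true(all(diff(tms) > 0))
  expect_true(all(diff(det$time_s) >= 400e-6))
  # >= 99% of events whose peak is at least 10 noise SDs are recovered
  # within 2 samples
  strong <- made$truth[made$truth$peak_amp_V >= 10 * made$noise_sigma, ]
  err <- vapply(strong$time_s, function(t) min(abs(tms - t)), numeric(1))
  expect_gte(mean(err <= 2.5 / 125000), 0.99)
})

test_that("recordings round-trip through WAV and raw float formats", {
  rec <- make_single_pulse_rec(at_s = 0.002, dur_s = 0.005, noise = 0.01)
  wav <- withr::local_tempfile(fileext = ".wav")
  write_recording_wav(rec, wav)
  back <- read_recording_wav(wav)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$samples, rec$samples, tolerance = 1e-6)  # float32
  pcm <- withr::local_tempfile(fileext = ".wav")
  write_recording_wav(rec, pcm, format = "pcm16", scale = 1)
  back16 <- read_recording_wav(pcm, scale = 1)
  expect_equal(back16$samples, rec$samples, tolerance = 1e-3)
  raw <- withr::local_tempfile()
  write_recording_raw(rec, raw)
  back_raw <- read_recording_raw(raw)
  expect_equal(back_raw$samples, rec$samples, tolerance = 1e-6)
  # events/vector CSV writers produce parseable files
  evs <- extract_events(rec, detect_eods(rec, rep(0.1, 7))$time_s)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(evs, f1)
  expect_equal(nrow(read.csv(f1)), length(evs))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_vectors_csv(build_vectors(evs), f2)
  expect_equal(ncol(read.csv(f2)), 357)
})
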