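#' Multichannel electrode recording
#'
#' @param samples Numeric T x n_channels matrix of voltages (V); rows are
#'   samples, columns channels.
#' @param sampling_rate Sampling rate, Hz (the rig digitizes at 125 kHz).
#' @param start_time Recording-clock time of the first sample, s.
#' @param ttl Optional TTL frame-sync trace (length T).
#'
#' @return A `multichannel_recording` object.
#' @export
multichannel_recording <- function(samples, sampling_rate = 125000,
                                   start_time = 0, ttl = NULL) {
  samples <- as.matrix(samples)
  if (sampling_rate <= 0) {
    abort_pulseid("sampling_rate must be positive", "pulseid_parameter_error")
  }
  if (any(!is.finite(samples))) {
    abort_pulseid("recording contains non-finite samples", "pulseid_data_error")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 n_channels = ncol(samples), start_time = start_time,
                 ttl = ttl),
            class = "multichannel_recording")
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("<multichannel_recording> %d ch x %d samples @ %g kHz (%.2f s)%s\n",
              x$n_channels, nrow(x$samples), x$sampling_rate / 1000,
              nrow(x$samples) / x$sampling_rate,
              if (!is.null(x$ttl)) " + TTL" else ""))
  invisible(x)
}

#' Detect EOD events by per-channel threshold crossing
#'
#' An event is registered whenever the absolute value of any channel crosses
#' its threshold (thresholds are set per channel, clearly above that
#' channel's noise). Crossings within the refractory period of a previous
#' event are discarded, keeping the earlier event; at the default 400 us
#' this both merges the multiple crossings of one discharge and drops the
#' later pulse of two near-simultaneous fish (recovered later by the
#' doublet screen).
#'
#' @param rec A [multichannel_recording()].
#' @param thresholds Positive per-channel absolute thresholds (V); a scalar
#'   is recycled.
#' @param refractory_us Refractory period, microseconds (default 400).
#'
#' @return Tibble: `event` (id), `time_s` (strictly increasing, recording
#'   clock), `sample`, `detect_channel` (first channel crossing).
#' @export
detect_eods <- function(rec, thresholds, refractory_us = 400) {
  stopifnot(inherits(rec, "multichannel_recording"))
  thresholds <- rep_len(thresholds, rec$n_channels)
  if (any(thresholds <= 0)) {
    abort_pulseid("thresholds must be positive", "pulseid_parameter_error")
  }
  above <- sweep(abs(rec$samples), 2, thresholds, ">")
  any_above <- rowSums(above) > 0
  onsets <- which(diff(c(FALSE, any_above)) == 1L)
  if (length(onsets) == 0) {
    return(tibble::tibble(event = integer(), time_s = numeric(),
                          sample = integer(), detect_channel = integer()))
  }
  refractory_n <- refractory_us * 1e-6 * rec$sampling_rate
  # refine each crossing to the nearby waveform peak, so the refractory
  # rule compares discharge times rather than threshold-crossing times
  n_samp <- nrow(rec$samples)
  half <- as.integer(refractory_n)
  peaks <- vapply(onsets, function(s) {
    win <- max(1L, s - half):min(n_samp, s + half)
    win[which.max(rowSums(abs(rec$samples[win, , drop = FALSE])))]
  }, numeric(1))
  ord <- order(peaks)
  onsets <- onsets[ord]; peaks <- peaks[ord]
  keep <- rep(TRUE, length(peaks))
  last <- peaks[1]
  for (i in seq_along(peaks)[-1]) {
    if (peaks[i] - last < refractory_n) keep[i] <- FALSE else last <- peaks[i]
  }
  onsets <- onsets[keep]; peaks <- as.integer(peaks[keep])
  dup <- duplicated(peaks)
  onsets <- onsets[!dup]; peaks <- peaks[!dup]
  tibble::tibble(
    event = seq_along(peaks),
    time_s = rec$start_time + (peaks - 1) / rec$sampling_rate,
    sample = peaks,
    detect_channel = vapply(onsets, function(s) which(above[s, ])[1], 1L)
  )
}

us_to_samples <- function(us, fs) as.integer(round(us * 1e-6 * fs))

#' Align and extract one EOD window
#'
#' Alignment uses the mean of the absolute values across all channels: the
#' event is re-centred on the peak of this trace in a local neighbourhood of
#' the detection time, and every channel is cut with the same indices,
#' 272 us before to 128 us after the peak (34 + 1 + 16 = 51 samples at
#' 125 kHz).
#'
#' @param rec A [multichannel_recording()].
#' @param t Detection time, s (recording clock).
#' @param pre_us,post_us Window extent before/after the peak, microseconds.
#' @param search_us Half-width of the peak-search neighbourhood around `t`.
#'
#' @return An `eod_event`: list with `window` (W x n_channels raw voltages),
#'   `peak_index` (sample index into the recording), `pre_samples`,
#'   `post_samples`, `detect_channel` (strongest channel at the peak).
#' @export
align_and_extract <- function(rec, t, pre_us = 272, post_us = 128,
                              search_us = 200) {
  fs <- rec$sampling_rate
  pre_n <- us_to_samples(pre_us, fs)
  post_n <- us_to_samples(post_us, fs)
  s0 <- as.integer(round((t - rec$start_time) * fs)) + 1L
  half <- us_to_samples(search_us, fs)
  lo <- max(1L, s0 - half); hi <- min(nrow(rec$samples), s0 + half)
  mat <- rowMeans(abs(rec$samples[lo:hi, , drop = FALSE]))
  peak <- lo + which.max(mat) - 1L
  a <- peak - pre_n; b <- peak + post_n
  if (a < 1L || b > nrow(rec$samples)) {
    abort_pulseid("EOD window crosses the recording boundary",
                  "pulseid_boundary_error")
  }
  win <- rec$samples[a:b, , drop = FALSE]
  structure(
    list(window = win, peak_index = peak, pre_samples = pre_n,
         post_samples = post_n,
         detect_channel = which.max(abs(win[pre_n + 1L, ])),
         sampling_rate = fs,
         time_s = rec$start_time + (peak - 1L) / fs),
    class = "eod_event"
  )
}

#' Extract all detected events from a recording
#'
#' Events whose window would cross a recording boundary are dropped with a
#' message (not padded).
#'
#' @param rec A [multichannel_recording()].
#' @param times Detection times (s), e.g. `detect_eods(...)$time_s`.
#' @inheritParams align_and_extract
#' @return List of `eod_event` objects.
#' @export
extract_events <- function(rec, times, pre_us = 272, post_us = 128,
                           search_us = 200) {
  events <- list(); dropped <- 0L
  for (t in times) {
    ev <- tryCatch(align_and_extract(rec, t, pre_us, post_us, search_us),
                   pulseid_boundary_error = function(e) NULL)
    if (is.null(ev)) dropped <- dropped + 1L else events[[length(events) + 1L]] <- ev
  }
  if (dropped > 0) {
    message(sprintf("dropped %d event(s) at recording boundaries", dropped))
  }
  events
}

#' Normalized EOD waveform vector
#'
#' Concatenates the channels of an event window in fixed channel order and
#' divides by the global absolute maximum, so the vector spans exactly
#' +/-1 V regardless of fish size or distance: max |value| = 1.
#'
#' @param ev An `eod_event`.
#' @return Numeric vector of length `n_channels * W` with attributes
#'   `n_channels`, `window_length` and `time_s`; max absolute entry is 1.
#' @export
build_vector <- function(ev) {
  m <- max(abs(ev$window))
  if (m == 0) {
    abort_pulseid("all-zero window cannot be normalized",
                  "pulseid_normalization_error")
  }
  v <- as.numeric(ev$window) / m  # column-major: ch1 window, ch2 window, ...
  structure(v, n_channels = ncol(ev$window), window_length = nrow(ev$window),
            time_s = ev$time_s)
}

#' @rdname build_vector
#' @param events List of `eod_event` objects.
#' @return For `build_vectors`, an n_events x (n_channels * W) matrix.
#' @export
build_vectors <- function(events) {
  do.call(rbind, lapply(events, function(e) as.numeric(build_vector(e))))
}

# Normalized mean-absolute trace of one event (length W, peak <= 1).
event_trace <- function(ev) {
  tr <- rowMeans(abs(ev$window))
  tr / max(tr)
}

#' Average normalized EOD waveform
#'
#' Averages the absolute values of the event windows across all detections
#' and channels, then normalizes by the peak: the template against which
#' individual discharges are compared in the doublet screen.
#'
#' @param events Non-empty list of `eod_event` objects.
#' @return Numeric length-W trace with peak exactly 1.
#' @export
average_waveform <- function(events) {
  if (length(events) == 0) {
    abort_pulseid("no events to average", "pulseid_data_error")
  }
  acc <- Reduce(`+`, lapply(events, function(e) rowMeans(abs(e$window))))
  avg <- acc / length(events)
  avg / max(avg)
}

#' Screen for temporally overlapping EODs (doublets)
#'
#' Two fish discharging within one extraction window produce a waveform
#' that deviates from the average template. Each event's normalized
#' mean-absolute trace is compared to the average trace; events whose
#' residual exceeds the `1 - flag_fraction` quantile of all residuals are
#' flagged for inspection, sorted by descending score.
#'
#' @param events List of `eod_event` objects.
#' @param avg Average trace from [average_waveform()] (recomputed if NULL).
#' @param flag_fraction Fraction of events to flag (default 0.01; the
#'   long-tailed residual histogram concentrates doublets here).
#' @param metric `"l1"` (sum of absolute deviations, default) or `"l2"`.
#'
#' @return A `doublet_screen` tibble: `event_id`, `time_s`,
#'   `residual_score`, `threshold_used`, `flagged`, `confirmed`
#'   (`"pending"` for flagged rows, `"clean"` otherwise), ordered by
#'   descending score.
#' @export
doublet_screen <- function(events, avg = NULL, flag_fraction = 0.01,
                           metric = c("l1", "l2")) {
  metric <- match.arg(metric)
  if (flag_fraction <= 0 || flag_fraction >= 1) {
    abort_pulseid("flag_fraction must be in (0, 1)", "pulseid_parameter_error")
  }
  avg <- avg %||% average_waveform(events)
  scores <- vapply(events, function(e) {
    d <- event_trace(e) - avg
    if (metric == "l1") sum(abs(d)) else sqrt(sum(d^2))
  }, numeric(1))
  thr <- stats::quantile(scores, 1 - flag_fraction, names = FALSE)
  out <- tibble::tibble(
    event_id = seq_along(events),
    time_s = vapply(events, `[[`, numeric(1), "time_s"),
    residual_score = scores,
    threshold_used = thr,
    flagged = scores > thr
  )
  out$confirmed <- ifelse(out$flagged, "pending", "clean")
  out <- dplyr::arrange(out, dplyr::desc(.data$residual_score))
  class(out) <- c("doublet_screen", class(out))
  out
}

#' Diagnostic curve for the doublet screen
#'
#' Capture-versus-inspected curve: sorting events by descending residual,
#' the fraction of true doublets captured as a function of the fraction of
#' events inspected (requires truth labels, e.g. from the synthetic
#' generator).
#'
#' @param screen A [doublet_screen()] result.
#' @param truth_ids Event ids that are true doublets.
#' @return A ggplot object.
#' @export
plot_doublet_capture <- function(screen, truth_ids) {
  df <- tibble::tibble(
    inspected = seq_len(nrow(screen)) / nrow(screen),
    captured = cumsum(screen$event_id %in% truth_ids) /
      max(1L, length(truth_ids)))
  ggplot2::ggplot(df, ggplot2::aes(.data$inspected, .data$captured)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "fraction of events inspected",
                  y = "fraction of doublets captured")
}

#' Resolve flagged doublets against review decisions
#'
#' @param screen A [doublet_screen()] result.
#' @param decisions Tibble/data frame with columns `event_id` and `doublet`
#'   (logical), covering every flagged event (the review file round-trips
#'   via CSV).
#'
#' @return Tibble of confirmed doublets: `event_id`, `time_s`.
#' @export
confirm_doublets <- function(screen, decisions) {
  flagged <- screen[screen$flagged, ]
  missing <- setdiff(flagged$event_id, decisions$event_id)
  if (length(missing) > 0) {
    abort_pulseid(sprintf("%d flagged event(s) lack review decisions",
                          length(missing)), "pulseid_pending_review")
  }
  dec <- decisions[match(flagged$event_id, decisions$event_id), ]
  out <- flagged[dec$doublet %in% TRUE, c("event_id", "time_s")]
  dplyr::arrange(out, .data$time_s)
}

# ---- readers / writers ----------------------------------------------------

#' Read and write multichannel recordings
#'
#' Two interchangeable on-disk forms are supported: RIFF WAV (IEEE float32
#' or PCM16 with a stated full-scale voltage) and raw little-endian float32
#' with a JSON metadata sidecar (`fs`, `n_channels`, optional
#' `ttl_channel`). Channels are interleaved in both forms.
#'
#' @param rec A [multichannel_recording()].
#' @param path Output file path (`.wav` or raw binary; the raw writer puts
#'   metadata in `<path>.json`).
#' @param format `"float"` (IEEE 32-bit) or `"pcm16"`.
#' @param scale Full-scale voltage for `"pcm16"`.
#' @return The path (writers, invisibly) or a [multichannel_recording()]
#'   (readers).
#' @export
write_recording_wav <- function(rec, path, format = c("float", "pcm16"),
                                scale = 1) {
  format <- match.arg(format)
  x <- rec$samples
  n_ch <- ncol(x); n <- nrow(x)
  bytes_per <- if (format == "float") 4L else 2L
  data_bytes <- n * n_ch * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "float") 3L else 1L, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(rec$sampling_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sampling_rate * n_ch * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(n_ch * bytes_per), con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  inter <- as.numeric(t(x))  # interleave channels
  if (format == "float") {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(-32768, pmin(32767, round(inter / scale * 32767)))),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_recording_wav
#' @export
read_recording_wav <- function(path, scale = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4); readBin(con, integer(), size = 4)
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") {
    abort_pulseid("not a RIFF/WAVE file", "pulseid_io_error")
  }
  fmt <- NULL; fs <- NULL; n_ch <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) {
      abort_pulseid("no data chunk found", "pulseid_io_error")
    }
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      n_ch <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  n_vals <- size %/% (bits %/% 8L)
  vals <- if (fmt == 3L) {
    readBin(con, numeric(), n = n_vals, size = 4, endian = "little")
  } else {
    readBin(con, integer(), n = n_vals, size = 2, endian = "little") /
      32767 * scale
  }
  multichannel_recording(matrix(vals, ncol = n_ch, byrow = TRUE),
                         sampling_rate = fs)
}

#' @rdname write_recording_wav
#' @export
write_recording_raw <- function(rec, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(t(rec$samples)), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(
    list(fs = rec$sampling_rate, n_channels = rec$n_channels,
         start_time = rec$start_time, dtype = "float32"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_wav
#' @export
read_recording_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = file.size(path) / 4, size = 4,
                  endian = "little")
  multichannel_recording(matrix(vals, ncol = meta$n_channels, byrow = TRUE),
                         sampling_rate = meta$fs,
                         start_time = meta$start_time %||% 0)
}

#' Write detected events / waveform vectors / screen flags as CSV
#'
#' @param events List of `eod_event` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  df <- tibble::tibble(
    peak_sample = vapply(events, `[[`, 1L, "peak_index"),
    peak_time_s = vapply(events, `[[`, numeric(1), "time_s"),
    detect_channel = vapply(events, `[[`, 1L, "detect_channel"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param vectors Matrix from [build_vectors()].
#' @export
write_vectors_csv <- function(vectors, path) {
  utils::write.csv(as.data.frame(vectors), path, row.names = FALSE)
  invisible(path)
}
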