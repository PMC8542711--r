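#' Canonical skeleton node names
#'
#' The six-midline-node skeleton used throughout: chin appendage
#' (Schnauzenorgan), two head nodes, two mid-body nodes and the tail. The
#' second head node (`head2`, the midpoint between the pectoral fins) is the
#' anchor part used to localize an animal.
#'
#' @export
skeleton_nodes <- c("Schnauzenorgan", "head1", "head2", "mid1", "mid2", "tail")

#' @rdname skeleton_nodes
#' @export
anchor_node <- "head2"

#' Tracked multi-animal skeleton sequence
#'
#' Container for per-frame, per-animal six-node poses, time-synced to the
#' electrode recording clock.
#'
#' @param poses Long tibble with columns `frame` (1-based), `fish_id`,
#'   `node` (one of [skeleton_nodes]), `x_cm`, `y_cm`, `visible` (logical).
#' @param frame_times Numeric vector of frame times (s), strictly
#'   increasing, one per frame.
#' @param frame_rate Nominal frame rate, Hz (30 or 10 in the recordings).
#' @param px_to_cm Pixel-to-cm scale already applied to the coordinates.
#' @param jump_warn_cm Warn if the anchor node of any animal jumps more
#'   than this many cm between consecutive frames (possible identity swap).
#'
#' @return A `tracked_sequence` object.
#' @export
tracked_sequence <- function(poses, frame_times, frame_rate = 30,
                             px_to_cm = 1, jump_warn_cm = 15) {
  stopifnot(all(c("frame", "fish_id", "node", "x_cm", "y_cm", "visible")
                %in% names(poses)))
  if (length(unique(poses$fish_id)) > 2) {
    abort_pulseid("more than 2 animals are not supported",
                  "pulseid_unsupported_count")
  }
  if (!all(poses$node %in% skeleton_nodes)) {
    abort_pulseid("unknown skeleton node names", "pulseid_schema_error")
  }
  if (any(diff(frame_times) <= 0)) {
    abort_pulseid("frame_times must be strictly increasing",
                  "pulseid_schema_error")
  }
  poses$node <- factor(poses$node, levels = skeleton_nodes)
  poses <- dplyr::arrange(poses, .data$frame, .data$fish_id, .data$node)
  poses$node <- as.character(poses$node)
  # identity-continuity heuristic on the anchor node
  anch <- poses[poses$node == anchor_node & poses$visible, ]
  for (id in unique(anch$fish_id)) {
    a <- anch[anch$fish_id == id, ]
    if (nrow(a) > 1) {
      jump <- sqrt(diff(a$x_cm)^2 + diff(a$y_cm)^2) / pmax(diff(a$frame), 1)
      if (any(jump > jump_warn_cm, na.rm = TRUE)) {
        warning(sprintf(
          "anchor of animal '%s' jumps > %g cm/frame; check identity labels",
          id, jump_warn_cm), call. = FALSE)
      }
    }
  }
  structure(
    list(poses = tibble::as_tibble(poses), frame_times = frame_times,
         frame_rate = frame_rate, px_to_cm = px_to_cm),
    class = "tracked_sequence"
  )
}

#' @export
print.tracked_sequence <- function(x, ...) {
  cat(sprintf("<tracked_sequence> %d frames, %d animal(s), %g Hz\n",
              length(x$frame_times), length(unique(x$poses$fish_id)),
              x$frame_rate))
  invisible(x)
}

#' Load a skeleton-tracking export
#'
#' Reads the documented plain-text tracking layout: a CSV with columns
#' `frame`, `track`, `node`, `x`, `y` (pixel or cm) and optionally
#' `visible`. Missing detections (`NA` coordinates) become invisible nodes;
#' node rows are remapped to the canonical six-name order. HDF5 analysis
#' exports from the pose-estimation tool can be converted to this layout
#' with [convert_tracking_h5()].
#'
#' @param path CSV file path.
#' @param px_to_cm Scale factor applied to `x`/`y` (calibrate from the known
#'   tank width in the image).
#' @param frame_rate Video frame rate, Hz.
#' @param frame_times Optional recording-clock frame times (e.g. from
#'   [sync_frames()]); defaults to `(frame - 1) / frame_rate`.
#'
#' @return A [tracked_sequence()].
#' @export
load_tracking <- function(path, px_to_cm = 1, frame_rate = 30,
                          frame_times = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "track", "node", "x", "y")
  if (!all(need %in% names(raw))) {
    abort_pulseid(paste("tracking file must contain columns:",
                        paste(need, collapse = ", ")),
                  "pulseid_schema_error")
  }
  if (!all(skeleton_nodes %in% unique(raw$node))) {
    abort_pulseid("tracking file is missing canonical node names",
                  "pulseid_schema_error")
  }
  if (length(unique(raw$track)) > 2) {
    abort_pulseid("more than 2 animals are not supported",
                  "pulseid_unsupported_count")
  }
  n_frames <- max(raw$frame)
  # complete the grid so undetected nodes become invisible rows
  grid <- tidyr::expand_grid(frame = seq_len(n_frames),
                             fish_id = sort(unique(raw$track)),
                             node = skeleton_nodes)
  poses <- dplyr::left_join(
    grid,
    dplyr::transmute(raw, frame = .data$frame, fish_id = .data$track,
                     node = .data$node, x_cm = .data$x * px_to_cm,
                     y_cm = .data$y * px_to_cm),
    by = c("frame", "fish_id", "node"))
  poses$visible <- is.finite(poses$x_cm) & is.finite(poses$y_cm)
  tracked_sequence(poses,
                   frame_times %||% ((seq_len(n_frames) - 1) / frame_rate),
                   frame_rate = frame_rate, px_to_cm = px_to_cm)
}

#' Write a tracked sequence to the CSV exchange layout
#'
#' @param seq A [tracked_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(seq, path) {
  out <- dplyr::transmute(seq$poses, frame = .data$frame,
                          track = .data$fish_id, node = .data$node,
                          x = ifelse(.data$visible, .data$x_cm, NA_real_),
                          y = ifelse(.data$visible, .data$y_cm, NA_real_))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Convert an HDF5 pose-tracking analysis export to the CSV layout
#'
#' Shells out to the bundled Python converter (requires `python` with
#' `h5py` on the PATH). The expected HDF5 layout is the analysis export of
#' the pose-estimation tool: datasets `tracks` (n_tracks x 2 x n_nodes x
#' n_frames), `node_names` and `track_names`.
#'
#' @param h5_path Input HDF5 file.
#' @param csv_path Output CSV file.
#' @param python Python interpreter to use.
#' @return `csv_path`, invisibly.
#' @export
convert_tracking_h5 <- function(h5_path, csv_path,
                                python = Sys.which("python")) {
  script <- system.file("python", "sleap_h5_to_csv.py", package = "pulseid")
  if (script == "") {
    script <- file.path("inst", "python", "sleap_h5_to_csv.py")
  }
  status <- system2(python, c(script, shQuote(h5_path), shQuote(csv_path)))
  if (status != 0) {
    abort_pulseid("HDF5 conversion failed", "pulseid_io_error")
  }
  invisible(csv_path)
}

#' Frame clock from the TTL sync channel
#'
#' Each video exposure triggers a TTL pulse on a dedicated channel of the
#' electrode recording; the rising edges give the exact time of every frame
#' in the recording clock.
#'
#' @param rec A [multichannel_recording()] whose `ttl` field holds the sync
#'   channel trace.
#' @param n_video_frames Expected number of video frames.
#' @param level Threshold as a fraction of the TTL peak (default 0.5).
#'
#' @return A `frame_clock`: list with `ttl_times` (s, one per frame) and
#'   `offset` (s).
#' @export
sync_frames <- function(rec, n_video_frames, level = 0.5) {
  if (is.null(rec$ttl)) {
    abort_pulseid("recording has no TTL channel", "pulseid_sync_error")
  }
  thr <- level * max(rec$ttl)
  high <- rec$ttl > thr
  edges <- which(diff(c(FALSE, high)) == 1L)
  if (length(edges) != n_video_frames) {
    abort_pulseid(sprintf(
      "TTL pulse count (%d) does not match video frame count (%d)",
      length(edges), n_video_frames), "pulseid_sync_error")
  }
  structure(list(ttl_times = rec$start_time + (edges - 1) / rec$sampling_rate,
                 offset = rec$start_time),
            class = "frame_clock")
}

#' Interpolated poses at arbitrary times
#'
#' Linearly interpolates every visible node of every animal between the two
#' flanking video frames; when a node is invisible on either side the
#' nearest visible frame is used instead. Used to pair each detected EOD
#' (rates can exceed 100 Hz) with a pose despite the 10-30 Hz video.
#'
#' @param seq A [tracked_sequence()].
#' @param t Query time(s), s, within the span of `seq$frame_times`.
#' @param method `"linear"` (default) or `"nearest"`.
#'
#' @return Tibble: `t`, `fish_id`, `node`, `x_cm`, `y_cm`, `visible`,
#'   `method`.
#' @export
poses_at_times <- function(seq, t, method = c("linear", "nearest")) {
  method <- match.arg(method)
  ft <- seq$frame_times
  if (any(t < ft[1] - 1e-12 | t > ft[length(ft)] + 1e-12)) {
    abort_pulseid("query time outside the tracked span", "pulseid_range_error")
  }
  t <- pmin(pmax(t, ft[1]), ft[length(ft)])
  f0 <- pmin(pmax(findInterval(t, ft), 1L), length(ft) - 1L)
  f1 <- f0 + 1L
  w <- (t - ft[f0]) / (ft[f1] - ft[f0])
  purrr::map_dfr(split(seq$poses, seq$poses$fish_id), function(pf) {
    purrr::map_dfr(split(pf, pf$node), function(pn) {
      pn <- pn[order(pn$frame), ]
      vis0 <- pn$visible[f0]; vis1 <- pn$visible[f1]
      ww <- if (method == "nearest") round(w) else w
      blend <- function(v) {
        v0 <- v[f0]; v1 <- v[f1]
        # linear between two visible flanking frames; nearest visible flank
        # when the other side is undetected; NA when both are
        ifelse(vis0 & vis1, (1 - ww) * v0 + ww * v1,
               ifelse(vis0, v0, ifelse(vis1, v1, NA_real_)))
      }
      tibble::tibble(t = t, fish_id = pn$fish_id[1], node = pn$node[1],
                     x_cm = blend(pn$x_cm), y_cm = blend(pn$y_cm),
                     visible = vis0 | vis1, method = method)
    })
  })
}

#' @rdname poses_at_times
#' @export
pose_at_time <- function(seq, t, method = c("linear", "nearest")) {
  stopifnot(length(t) == 1)
  poses_at_times(seq, t, method)
}

#' Export a frame clock as CSV
#' @param clock A `frame_clock` from [sync_frames()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_clock <- function(clock, path) {
  utils::write.csv(
    data.frame(frame = seq_along(clock$ttl_times), time_s = clock$ttl_times),
    path, row.names = FALSE)
  invisible(path)
}
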