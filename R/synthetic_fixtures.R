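#' Synthetic recording scenario
#'
#' Parameters of the ground-truthed generator that emulates the acquisition
#' rig: one or two fish swim smoothly through the tank while discharging
#' with gamma-distributed inter-pulse intervals; each discharge injects a
#' biphasic template into the simulated electrode channels (dipole field
#' model) on top of Gaussian noise, and every video frame leaves a TTL
#' pulse on the sync channel.
#'
#' @param seed Integer seed; the whole scenario is deterministic given it.
#' @param tank A [tank_geometry()].
#' @param fish_lengths Body lengths, cm (one per fish, at most 2).
#' @param speed_cm_s Mean swimming speed, cm/s.
#' @param heading_diffusion Heading random-walk scale, rad/sqrt(s).
#' @param ipi_mean_ms Mean inter-pulse interval, ms (pulse-type fish span
#'   roughly 10-100 ms).
#' @param ipi_shape Gamma shape of the renewal process (default 3: regular
#'   but variable pulsing).
#' @param target_snr Median event peak amplitude over noise SD (default 10).
#' @param duration_s Recording length, s.
#' @param frame_rate Video frame rate, Hz (30 or 10).
#' @param sampling_rate Electrode sampling rate, Hz.
#' @param pulse_us Biphasic template support, microseconds.
#' @param phase2_width Per-fish second-phase width factors (mild individual
#'   waveform differences, about +/-10%).
#'
#' @return A `pulseid_scenario` list.
#' @export
scenario <- function(seed = 1L, tank = tank_geometry(),
                     fish_lengths = c(12, 12), speed_cm_s = 5,
                     heading_diffusion = 1.5, ipi_mean_ms = 40,
                     ipi_shape = 3, target_snr = 10, duration_s = 20,
                     frame_rate = 30, sampling_rate = 125000,
                     pulse_us = 400,
                     phase2_width = c(1, 1.1)[seq_along(fish_lengths)]) {
  if (length(fish_lengths) > 2) {
    abort_pulseid("at most 2 fish are supported", "pulseid_unsupported_count")
  }
  structure(
    list(seed = as.integer(seed), tank = tank, fish_lengths = fish_lengths,
         n_fish = length(fish_lengths), speed_cm_s = speed_cm_s,
         heading_diffusion = heading_diffusion, ipi_mean_ms = ipi_mean_ms,
         ipi_shape = ipi_shape, target_snr = target_snr,
         duration_s = duration_s, frame_rate = frame_rate,
         sampling_rate = sampling_rate, pulse_us = pulse_us,
         phase2_width = phase2_width),
    class = "pulseid_scenario"
  )
}

#' Biphasic EOD pulse template
#'
#' Difference of two Gaussians with the second (repolarizing) phase wider
#' and weaker; weights are balanced so the template integrates to zero, and
#' the peak is normalized to 1.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_us Template support, microseconds (>= 4 samples).
#' @param phase2_width Relative width factor of the second phase (individual
#'   waveform differences).
#'
#' @return Numeric waveform of `round(duration_us * 1e-6 * fs)` samples.
#' @export
make_biphasic_pulse <- function(fs, duration_us = 400, phase2_width = 1) {
  n <- as.integer(round(duration_us * 1e-6 * fs))
  if (n < 4) {
    abort_pulseid("pulse duration must span at least 4 samples",
                  "pulseid_parameter_error")
  }
  t <- seq(0, 1, length.out = n)
  s1 <- 0.08
  s2 <- 0.13 * phase2_width
  g1 <- exp(-(t - 0.40)^2 / (2 * s1^2))
  g2 <- exp(-(t - 0.62)^2 / (2 * s2^2))
  w <- sum(g1) / sum(g2)  # zero net area
  p <- g1 - w * g2
  p / max(abs(p))
}

node_fractions <- c(Schnauzenorgan = 0, head1 = 0.12, head2 = 0.3,
                    mid1 = 0.55, mid2 = 0.75, tail = 1)

# 6-node skeleton laid along the heading for a fish of length L whose
# centre is at (x, y).
skeleton_from_state <- function(x, y, theta, L) {
  dirx <- cos(theta); diry <- sin(theta)
  tipx <- x + L / 2 * dirx; tipy <- y + L / 2 * diry
  tibble::tibble(node = names(node_fractions),
                 x_cm = tipx - node_fractions * L * dirx,
                 y_cm = tipy - node_fractions * L * diry)
}

#' Simulate smooth fish trajectories
#'
#' Heading follows a reflected random walk (diffusion `heading_diffusion`)
#' at constant speed; the centre is reflected at the tank's wall margin.
#' The 6-node skeleton is laid along the heading with fixed per-length node
#' spacing.
#'
#' @param scn A [scenario()].
#' @return A [tracked_sequence()]; the per-frame continuous state (centre,
#'   heading) is attached as attribute `"state"` (tibble: frame, time_s,
#'   fish_id, x, y, theta, length).
#' @export
make_trajectories <- function(scn) {
  stopifnot(inherits(scn, "pulseid_scenario"))
  dt <- 1 / scn$frame_rate
  n_frames <- as.integer(ceiling(scn$duration_s * scn$frame_rate)) + 1L
  m <- scn$tank$wall_margin
  xmin <- m; xmax <- scn$tank$width - m
  ymin <- m; ymax <- scn$tank$depth_y - m
  states <- with_seed(child_seed(scn$seed, 101L), {
    purrr::map_dfr(seq_len(scn$n_fish), function(f) {
      x <- stats::runif(1, xmin, xmax); y <- stats::runif(1, ymin, ymax)
      th <- stats::runif(1, 0, 2 * pi)
      out <- matrix(0, n_frames, 3)
      for (i in seq_len(n_frames)) {
        out[i, ] <- c(x, y, th)
        th <- th + stats::rnorm(1, 0, scn$heading_diffusion * sqrt(dt))
        x <- x + scn$speed_cm_s * dt * cos(th)
        y <- y + scn$speed_cm_s * dt * sin(th)
        if (x < xmin) { x <- 2 * xmin - x; th <- pi - th }
        if (x > xmax) { x <- 2 * xmax - x; th <- pi - th }
        if (y < ymin) { y <- 2 * ymin - y; th <- -th }
        if (y > ymax) { y <- 2 * ymax - y; th <- -th }
      }
      tibble::tibble(frame = seq_len(n_frames),
                     time_s = (seq_len(n_frames) - 1) * dt,
                     fish_id = paste0("fish", f),
                     x = out[, 1], y = out[, 2], theta = out[, 3],
                     length = scn$fish_lengths[f])
    })
  })
  poses <- states |>
    dplyr::rowwise() |>
    dplyr::reframe(skeleton_from_state(.data$x, .data$y, .data$theta,
                                       .data$length),
                   frame = .data$frame, fish_id = .data$fish_id) |>
    dplyr::mutate(visible = TRUE)
  seqc <- tracked_sequence(poses, frame_times = sort(unique(states$time_s)),
                           frame_rate = scn$frame_rate)
  attr(seqc, "state") <- states
  seqc
}

# Interpolate the continuous state at arbitrary times for one fish.
state_at <- function(states, fish, t) {
  s <- states[states$fish_id == fish, ]
  th_unwrap <- s$theta  # already continuous (never wrapped)
  tibble::tibble(
    t = t,
    x = stats::approx(s$time_s, s$x, t, rule = 2)$y,
    y = stats::approx(s$time_s, s$y, t, rule = 2)$y,
    theta = stats::approx(s$time_s, th_unwrap, t, rule = 2)$y,
    length = s$length[1]
  )
}

#' Synthesize a multichannel recording with ground truth
#'
#' Draws EOD times for each fish from a gamma renewal process, injects the
#' fish's biphasic template scaled by the simulated channel potentials at
#' its interpolated pose, adds Gaussian noise calibrated to the scenario's
#' target SNR, and writes TTL pulses at the video frame times.
#' Cross-fish events within `doublet_window_us` of each other are recorded
#' as true doublet candidates.
#'
#' @param scn A [scenario()].
#' @param config An [electrode_configuration()].
#' @param traj Optional precomputed [make_trajectories()] result.
#' @param doublet_window_us Window defining true overlaps (default 400).
#'
#' @return List: `recording` ([multichannel_recording()] with TTL),
#'   `tracking` (the [tracked_sequence()]), `truth` (tibble: fish_id,
#'   time_s, sample, x, y, theta, length, peak_amp_V, doublet), `templates`,
#'   `noise_sigma`, `scenario`.
#' @export
make_recording <- function(scn, config = electrode_configuration(1, scn$tank),
                           traj = NULL, doublet_window_us = 400) {
  stopifnot(inherits(scn, "pulseid_scenario"))
  traj <- traj %||% make_trajectories(scn)
  states <- attr(traj, "state")
  fs <- scn$sampling_rate
  n_samp <- as.integer(ceiling(scn$duration_s * fs))
  templates <- purrr::map(seq_len(scn$n_fish), function(f) {
    make_biphasic_pulse(fs, scn$pulse_us, scn$phase2_width[f])
  })
  tpl_peak <- purrr::map_int(templates, which.max)

  # gamma renewal EOD times per fish
  eod_times <- with_seed(child_seed(scn$seed, 202L), {
    purrr::map(seq_len(scn$n_fish), function(f) {
      mean_s <- scn$ipi_mean_ms / 1000
      n_max <- as.integer(scn$duration_s / mean_s * 2 + 50)
      ipis <- stats::rgamma(n_max, shape = scn$ipi_shape,
                            scale = mean_s / scn$ipi_shape)
      tt <- cumsum(c(stats::runif(1, 0, mean_s), ipis))
      tt[tt > 0.005 & tt < scn$duration_s - 0.005]
    })
  })

  truth <- purrr::map_dfr(seq_len(scn$n_fish), function(f) {
    st <- state_at(states, paste0("fish", f), eod_times[[f]])
    amps <- t(vapply(seq_len(nrow(st)), function(i) {
      fish <- virtual_fish(st$length[i], c(st$x[i], st$y[i]), st$theta[i])
      record_channels(fish, scn$tank, config)
    }, numeric(config$n_channels)))
    start <- as.integer(round(eod_times[[f]] * fs)) + 1L - tpl_peak[f] + 1L
    tibble::tibble(fish_id = paste0("fish", f), time_s = eod_times[[f]],
                   sample = as.integer(round(eod_times[[f]] * fs)) + 1L,
                   start_sample = start,
                   x = st$x, y = st$y, theta = st$theta, length = st$length,
                   peak_amp_V = apply(abs(amps), 1, max),
                   amp = asplit(amps, 1))
  })
  truth <- dplyr::arrange(truth, .data$time_s)

  noise_sigma <- stats::median(truth$peak_amp_V) / scn$target_snr
  samples <- with_seed(child_seed(scn$seed, 303L), {
    matrix(stats::rnorm(n_samp * config$n_channels, 0, noise_sigma),
           n_samp, config$n_channels)
  })
  for (i in seq_len(nrow(truth))) {
    f <- as.integer(sub("fish", "", truth$fish_id[i]))
    tpl <- templates[[f]]
    idx <- truth$start_sample[i]:(truth$start_sample[i] + length(tpl) - 1L)
    ok <- idx >= 1L & idx <= n_samp
    samples[idx[ok], ] <- samples[idx[ok], ] +
      outer(tpl[ok], as.numeric(truth$amp[[i]]))
  }

  # true doublets: cross-fish events closer than the window
  dt_w <- doublet_window_us * 1e-6
  doublet <- rep(FALSE, nrow(truth))
  if (scn$n_fish == 2) {
    gap_prev <- c(Inf, diff(truth$time_s))
    gap_next <- c(diff(truth$time_s), Inf)
    other_prev <- c(FALSE, truth$fish_id[-1] != truth$fish_id[-nrow(truth)])
    other_next <- c(truth$fish_id[-1] != truth$fish_id[-nrow(truth)], FALSE)
    doublet <- (gap_prev < dt_w & other_prev) | (gap_next < dt_w & other_next)
  }
  truth$doublet <- doublet
  truth$amp <- NULL

  ttl <- numeric(n_samp)
  fr_idx <- as.integer(round(traj$frame_times * fs)) + 1L
  fr_idx <- fr_idx[fr_idx <= n_samp - 10L]
  for (k in 0:9) ttl[fr_idx + k] <- 5
  rec <- multichannel_recording(samples, sampling_rate = fs, ttl = ttl)
  list(recording = rec, tracking = traj, truth = truth,
       templates = templates, noise_sigma = noise_sigma, scenario = scn)
}

#' Synthetic dyadic approach: a sequence of two-fish scenes
#'
#' Emulates the initial approach phase of a staged encounter: two fish face
#' each other head-on and the gap shrinks linearly from `start_distance_cm`
#' to `end_distance_cm` (first contact). Each fish discharges as a gamma
#' renewal process; every EOD before contact yields one conductivity scene
#' with that fish discharging, built from the fish's skeleton via the
#' midline-polynomial mesh pipeline.
#'
#' @param size_ratio Length of fish 2 relative to fish 1, in (0, 1].
#' @param base_length_cm Length of fish 1 (default 13; with
#'   `size_ratio = 10/13` this gives the 13 vs 10 cm example pair).
#' @param duration_s Approach duration up to first contact.
#' @param start_distance_cm,end_distance_cm Snout-to-snout gap at start and
#'   contact.
#' @param ipi_mean_ms,ipi_shape Discharge renewal parameters per fish.
#' @param n_rings,n_nodes Mesh resolution (49 x 17 default).
#' @param seed Integer seed.
#' @param tank Tank geometry (fish approach along the tank mid-line).
#'
#' @return A `dyad_scenes` tibble: `time_s`, `emitter`, `distance_cm`
#'   (anchor-to-anchor), `scene` (list column of
#'   [conductivity_scene()]), plus attributes `fish_ids`, `lengths`.
#' @export
make_dyad_scene <- function(size_ratio = 1, base_length_cm = 13,
                            duration_s = 10, start_distance_cm = 40,
                            end_distance_cm = 3, ipi_mean_ms = 100,
                            ipi_shape = 3, n_rings = 49, n_nodes = 17,
                            seed = 1L, tank = tank_geometry()) {
  if (size_ratio <= 0 || size_ratio > 1) {
    abort_pulseid("size_ratio must be in (0, 1]", "pulseid_parameter_error")
  }
  lens <- c(base_length_cm, base_length_cm * size_ratio)
  cx <- tank$width / 2
  cy <- tank$depth_y / 2
  eod_times <- with_seed(child_seed(seed, 404L), {
    purrr::map(1:2, function(f) {
      mean_s <- ipi_mean_ms / 1000
      ipis <- stats::rgamma(ceiling(duration_s / mean_s * 2 + 20),
                            shape = ipi_shape, scale = mean_s / ipi_shape)
      tt <- cumsum(c(stats::runif(1, 0, mean_s), ipis))
      tt[tt < duration_s]
    })
  })
  events <- dplyr::arrange(
    tibble::tibble(time_s = unlist(eod_times),
                   emitter = rep(c("fish1", "fish2"),
                                 lengths(eod_times))),
    .data$time_s)
  gap_at <- function(t) {
    start_distance_cm + (end_distance_cm - start_distance_cm) * t / duration_s
  }
  build_at <- function(t) {
    gap <- gap_at(t)
    # fish1 heads +y, fish2 heads -y; snouts gap apart, centred on (cx, cy)
    s1 <- skeleton_from_state(cx, cy - gap / 2 - lens[1] / 2, pi / 2, lens[1])
    s2 <- skeleton_from_state(cx, cy + gap / 2 + lens[2] / 2, -pi / 2, lens[2])
    m1 <- build_mesh(fit_midline(s1), lens[1], body_profile(n_rings),
                     n_nodes = n_nodes)
    m2 <- build_mesh(fit_midline(s2), lens[2], body_profile(n_rings),
                     n_nodes = n_nodes)
    list(m1 = m1, m2 = m2, s1 = s1, s2 = s2)
  }
  rows <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    t <- events$time_s[i]
    em <- events$emitter[i]
    g <- build_at(t)
    if (gap_at(t) <= 0.5) return(tibble::tibble())  # fish touching: skip
    mesh_em <- if (em == "fish1") g$m1 else g$m2
    scn <- conductivity_scene(
      bodies = list(list(mesh = g$m1, id = "fish1"),
                    list(mesh = g$m2, id = "fish2")),
      sources = tail_dipole_sources(mesh_em, em),
      discharging = em)
    a1 <- g$s1[g$s1$node == anchor_node, ]
    a2 <- g$s2[g$s2$node == anchor_node, ]
    tibble::tibble(time_s = t, emitter = em,
                   distance_cm = sqrt((a1$x_cm - a2$x_cm)^2 +
                                        (a1$y_cm - a2$y_cm)^2),
                   scene = list(scn))
  })
  attr(rows, "fish_ids") <- c("fish1", "fish2")
  attr(rows, "lengths") <- lens
  class(rows) <- c("dyad_scenes", class(rows))
  rows
}

#' Suggested detection thresholds for a synthetic recording
#'
#' 6.5 noise standard deviations (clearly above noise: the false-crossing
#' rate over millions of samples is negligible), capped at half the median
#' event peak so every EOD still crosses on at least one channel.
#'
#' @param made Result of [make_recording()].
#' @return Per-channel threshold vector (V).
#' @export
suggest_thresholds <- function(made) {
  rep(min(6.5 * made$noise_sigma, 0.5 * stats::median(made$truth$peak_amp_V)),
      made$recording$n_channels)
}
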