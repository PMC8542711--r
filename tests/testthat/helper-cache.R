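# Shared fixtures, computed once per test run and reused across files (the
# simulation study and the closed-loop pipeline are the expensive parts).
.pulseid_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .pulseid_cache)) {
    assign(name, force(expr), envir = .pulseid_cache)
  }
  get(name, envir = .pulseid_cache)
}

# The electrode-configuration simulation study at the study conditions:
# 2,500 placements, configuration 1, 75/25 split, 25 trees, 25 tuning
# candidates.
sim_study <- function() {
  cached("sim_study", {
    ds <- sample_placements(2500, seed = 1)
    model <- train_localizer(ds, localizer_spec(seed = 1), seed = 1)
    list(data = ds, model = model, report = spatial_error(model))
  })
}

# Closed-loop pipeline at the default scenario: two single-fish training
# segments, one dyadic segment (SNR 10, ~1,000 EODs), detection ->
# vectorization -> training -> assignment, with ground-truth matching.
closed_loop <- function() {
  cached("closed_loop", {
    fs <- 125000
    train_parts <- lapply(1:2, function(f) {
      scn <- scenario(seed = 300 + f, fish_lengths = 12, duration_s = 20,
                      phase2_width = c(1, 1.1)[f])
      made <- make_recording(scn)
      det <- detect_eods(made$recording, suggest_thresholds(made))
      evs <- extract_events(made$recording, det$time_s)
      tms <- vapply(evs, `[[`, numeric(1), "time_s")
      pw <- poses_wide(
        dplyr::filter(poses_at_times(made$tracking, tms),
                      .data$fish_id == "fish1"))
      list(vectors = build_vectors(evs), poses = pw)
    })
    model <- train_eod_model(
      rbind(train_parts[[1]]$vectors, train_parts[[2]]$vectors),
      dplyr::bind_rows(train_parts[[1]]$poses, train_parts[[2]]$poses),
      seed = 7)
    dyad <- make_recording(scenario(seed = 310))
    det <- detect_eods(dyad$recording, suggest_thresholds(dyad))
    evs <- extract_events(dyad$recording, det$time_s)
    tms <- vapply(evs, `[[`, numeric(1), "time_s")
    vecs <- build_vectors(evs)
    records <- assign_ids(model, vecs, tms, dyad$tracking)
    idx <- vapply(tms, function(t) which.min(abs(dyad$truth$time_s - t)), 1L)
    matched <- abs(dyad$truth$time_s[idx] - tms) <= 2.5 / fs
    truth_id <- dyad$truth$fish_id[idx]
    # inter-fish anchor distance at each EOD, for the distance-accuracy law
    anch <- poses_at_times(dyad$tracking, tms)
    anch <- anch[anch$node == anchor_node, ]
    d12 <- anch |>
      tidyr::pivot_wider(id_cols = "t", names_from = "fish_id",
                         values_from = c("x_cm", "y_cm"))
    dist_cm <- sqrt((d12$x_cm_fish1 - d12$x_cm_fish2)^2 +
                    (d12$y_cm_fish1 - d12$y_cm_fish2)^2)
    list(model = model, records = records, truth_id = truth_id,
         matched = matched, dist_cm = dist_cm, times = tms,
         accuracy = mean(records$assigned_id[matched] == truth_id[matched]))
  })
}

# Insulating-sphere scene at a given ring resolution (default-resolution
# oracle for the solver).
sphere_enhancement <- function(n_rings) {
  cached(paste0("sphere_", n_rings), {
    sm <- sphere_mesh(radius = 2, n_rings = n_rings, n_nodes = 17)
    sc <- conductivity_scene(
      bodies = list(list(mesh = sm, id = "s", skin_ohm_cm2 = 1e7)),
      water_uS_cm = 120, background_E = c(100, 0, 0))
    sf <- surface_field(assemble_and_solve(sc), "s")
    max(sf$magnitude) / 100
  })
}

# High-SNR single-fish recording with two planted cross-fish overlaps
# (constructed doublets) for the doublet screen.
doublet_fixture <- function() {
  cached("doublet_fixture", {
    scn <- scenario(seed = 11, fish_lengths = 12, duration_s = 8,
                    target_snr = 300, phase2_width = 1)
    out <- make_recording(scn)
    fs <- scn$sampling_rate
    tpl <- make_biphasic_pulse(fs, phase2_width = 1.1)
    # the second discharge peaks 100 us after the host peak: whichever of
    # the two peaks the extraction aligns on, the other stays inside the
    # 272/128 us window
    strong <- which(out$truth$peak_amp_V >=
                      stats::quantile(out$truth$peak_amp_V, 0.6))
    planted <- out$truth[strong[c(10, 40)], ]
    for (i in seq_len(nrow(planted))) {
      st <- planted$sample[i] + round(100e-6 * fs) - which.max(abs(tpl)) + 1
      f2 <- virtual_fish(12, c(planted$x[i] + 6, planted$y[i]),
                         planted$theta[i] + pi / 3)
      amp <- record_channels(f2, scn$tank, electrode_configuration(1, scn$tank))
      amp <- amp * 1.2 * planted$peak_amp_V[i] / max(abs(amp))
      idx <- st:(st + length(tpl) - 1)
      out$recording$samples[idx, ] <- out$recording$samples[idx, ] +
        outer(tpl, amp)
    }
    out$planted_times <- planted$time_s
    out
  })
}

# Coarse two-fish scenes at three separations (conservation + decay).
two_fish_scan <- function() {
  cached("two_fish_scan", {
    prof <- body_profile(13)
    m1 <- build_mesh(length_cm = 12, profile = prof, n_nodes = 8)
    src <- tail_dipole_sources(m1, "f1")
    lapply(c(12, 24, 36), function(d) {
      m2 <- translate_mesh(build_mesh(length_cm = 12, profile = prof,
                                      n_nodes = 8), c(0, d, 0))
      sc <- conductivity_scene(
        bodies = list(list(mesh = m1, id = "f1"), list(mesh = m2, id = "f2")),
        sources = src, discharging = "f1")
      sol <- assemble_and_solve(sc)
      list(distance = d, sol = sol,
           active = active_image(sc, sol),
           passive = passive_image(sc, "f2", sol))
    })
  })
}
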