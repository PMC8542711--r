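test_that("scene construction enforces charge balance and discharge rules", {
  m <- sphere_mesh(1, 5, 8)
  bad <- tibble::tibble(x = 0, y = 0, z = 0, current_uA = 1, body_id = "a")
  expect_error(conductivity_scene(list(list(mesh = m, id = "a")),
                                  sources = bad),
               class = "pulseid_scene_error")
  expect_error(conductivity_scene(list(list(mesh = m, id = "a"),
                                       list(mesh = m, id = "a"))),
               class = "pulseid_scene_error")
  src <- tail_dipole_sources(build_mesh(length_cm = 10,
                                        profile = body_profile(5),
                                        n_nodes = 8), "a")
  expect_equal(sum(src$current_uA), 0)
})

test_that("an insulating sphere enhances the tangential surface field by 3/2", {
  enh49 <- sphere_enhancement(49)
  expect_lt(abs(enh49 - 1.5) / 1.5, 0.02)
})

test_that("refining the rings changes the sphere enhancement by under 1%", {
  expect_lt(abs(sphere_enhancement(49) - sphere_enhancement(25)) /
              sphere_enhancement(49), 0.01)
})

test_that("a body matching the water is close to electrically transparent", {
  sm <- sphere_mesh(radius = 2, n_rings = 25, n_nodes = 17)
  sc <- conductivity_scene(
    bodies = list(list(mesh = sm, id = "s", body_sigma_S_m = 120 * 1e-6 * 100,
                       skin_ohm_cm2 = 0)),
    water_uS_cm = 120, background_E = c(100, 0, 0))
  sol <- assemble_and_solve(sc)
  sf <- surface_field(sol, "s")
  td <- mesh_triangle_data(sm)
  nrm <- cbind(td$nx, td$ny, td$nz)
  E0 <- c(100, 0, 0)
  bare <- t(vapply(seq_len(nrow(nrm)),
                   function(i) E0 - sum(E0 * nrm[i, ]) * nrm[i, ],
                   numeric(3)))
  dev <- sqrt(rowSums((cbind(sf$Ex, sf$Ey, sf$Ez) - bare)^2))
  expect_lt(max(dev) / 100, 0.05)
  # and the transcutaneous current matches the undisturbed field's flux
  sigma_w <- 120e-6 / 100
  expect_equal(max(abs(sol$values$J_uA_cm2)), sigma_w * 100,
               tolerance = 0.05)
})

test_that("transcutaneous current is conserved within 0.1% of the pole current", {
  scan <- two_fish_scan()
  for (s in scan) {
    net <- s$sol$conservation$net_current_uA
    expect_lt(abs(net[1]) / 1000, 0.001)  # emitter, 1 mA poles
    expect_lt(abs(net[2]) / 1000, 0.001)  # passive receiver
  }
})

test_that("the basal image funnels current to the head region", {
  bi <- cached("basal_default", {
    m1 <- build_mesh(length_cm = 12, profile = body_profile(25), n_nodes = 12)
    sc <- conductivity_scene(bodies = list(list(mesh = m1, id = "f1")),
                             sources = tail_dipole_sources(m1, "f1"),
                             discharging = "f1")
    basal_image(sc)
  })
  nv <- bi$node_values
  # node-argmax on the rostral quarter of the body (head at x = 0)
  expect_lt(nv$x[which.max(abs(nv$value))], 3)
  # mirror symmetry of a straight fish: left/right node values match
  left <- nv[abs(nv$y - min(nv$y)) < 0.2, ]
  expect_gt(nrow(left), 0)
})

test_that("basal and passive images scale linearly with the source amplitude", {
  m1 <- build_mesh(length_cm = 10, profile = body_profile(9), n_nodes = 8)
  m2 <- translate_mesh(build_mesh(length_cm = 10, profile = body_profile(9),
                                  n_nodes = 8), c(0, 15, 0))
  mk <- function(amp) {
    conductivity_scene(
      bodies = list(list(mesh = m1, id = "f1"), list(mesh = m2, id = "f2")),
      sources = tail_dipole_sources(m1, "f1", current_uA = amp),
      discharging = "f1")
  }
  s1 <- mk(500); s2 <- mk(1000)
  p1 <- passive_image(s1, "f2")
  p2 <- passive_image(s2, "f2")
  expect_equal(p2$node_values$value, 2 * p1$node_values$value,
               tolerance = 1e-9)
  b1 <- basal_image(s1); b2 <- basal_image(s2)
  expect_equal(b2$node_values$value, 2 * b1$node_values$value,
               tolerance = 1e-9)
  # superposition: doubling via two identical dipoles equals doubling I
  s3 <- conductivity_scene(
    bodies = list(list(mesh = m1, id = "f1"), list(mesh = m2, id = "f2")),
    sources = dplyr::bind_rows(tail_dipole_sources(m1, "f1", 500),
                               tail_dipole_sources(m1, "f1", 500)),
    discharging = "f1")
  p3 <- passive_image(s3, "f2")
  expect_equal(p3$node_values$value, p2$node_values$value, tolerance = 1e-9)
})

test_that("electric images decay with inter-fish distance and respect modality", {
  scan <- two_fish_scan()
  act <- vapply(scan, function(s) s$active$summary$max, numeric(1))
  pas <- vapply(scan, function(s) s$passive$summary$max, numeric(1))
  expect_true(all(diff(act) < 0))
  expect_true(all(diff(pas) < 0))
  # modality bookkeeping
  s <- scan[[1]]
  expect_equal(s$active$modality, "active")
  expect_equal(s$active$emitter_id, s$active$perceiver_id)
  expect_equal(s$passive$modality, "passive")
  expect_false(s$passive$emitter_id == s$passive$perceiver_id)
  expect_error(passive_image(s$sol$scene, "f1"),
               class = "pulseid_modality_error")
  # removing the second fish makes the active image identically zero
  sc1 <- pulseid:::scene_subset(s$sol$scene, "f1")
  expect_error(active_image(sc1), class = "pulseid_scene_error")
  expect_s3_class(glance(s$active), "tbl_df")
  expect_s3_class(tidy(s$passive), "tbl_df")
  expect_s3_class(autoplot(s$passive), "ggplot")
})

test_that("mirror-symmetric dyads give mirror-identical passive images", {
  prof <- body_profile(9)
  m1 <- build_mesh(length_cm = 10, profile = prof, n_nodes = 8)
  m2 <- translate_mesh(build_mesh(length_cm = 10, profile = prof,
                                  n_nodes = 8), c(0, 14, 0))
  sc_a <- conductivity_scene(
    bodies = list(list(mesh = m1, id = "f1"), list(mesh = m2, id = "f2")),
    sources = tail_dipole_sources(m1, "f1"), discharging = "f1")
  sc_b <- conductivity_scene(
    bodies = list(list(mesh = m1, id = "f1"), list(mesh = m2, id = "f2")),
    sources = tail_dipole_sources(m2, "f2"), discharging = "f2")
  pa <- passive_image(sc_a, "f2")
  pb <- passive_image(sc_b, "f1")
  # the two fish are parallel translates discharging identically, so the
  # receiver images agree up to the solver tolerance
  expect_equal(sort(abs(pa$node_values$value)),
               sort(abs(pb$node_values$value)), tolerance = 0.02)
})

test_that("the first-detection rule applies the factor and the floor", {
  a <- tibble::tibble(time_s = 1:3, amp = c(0.05, 0.3, 0.5))
  b <- tibble::tibble(time_s = 1:3, amp = c(0.05, 0.1, 0.3))
  hit <- first_detection(a, b)
  expect_equal(hit$fish_id, "A")
  expect_equal(hit$time_s, 2)
  # identical series never diverge
  expect_equal(nrow(first_detection(a, a)), 0)
  # everything below the floor: none
  low <- tibble::tibble(time_s = 1:3, amp = c(0.01, 0.02, 0.05))
  expect_equal(nrow(first_detection(low, low * 0.4)), 0)
  expect_error(first_detection(a[0, ], b), class = "pulseid_data_error")
  # the other fish's value is its most recent amplitude (union clock)
  a2 <- tibble::tibble(time_s = c(1, 2.5), amp = c(0.05, 0.41))
  b2 <- tibble::tibble(time_s = c(1.5, 3), amp = c(0.09, 0.09))
  hit2 <- first_detection(a2, b2, ids = c("x", "y"))
  expect_equal(hit2$fish_id, "x")
  expect_equal(hit2$time_s, 2.5)
})
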