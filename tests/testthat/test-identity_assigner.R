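test_that("training validates its inputs and is reproducible", {
  n <- 120
  vecs <- matrix(rnorm(n * 20), n, 20)
  vecs <- vecs / apply(abs(vecs), 1, max)
  poses <- as.data.frame(matrix(runif(n * 12, 0, 60), n, 12))
  names(poses) <- pulseid:::pose_cols()
  m1 <- train_eod_model(vecs, poses, n_estimators = 10, seed = 3)
  m2 <- train_eod_model(vecs, poses, n_estimators = 10, seed = 3)
  p1 <- predict_pose(m1, vecs[1:5, ])
  expect_identical(p1, predict_pose(m2, vecs[1:5, ]))
  # identical vectors give identical poses
  expect_identical(predict_pose(m1, vecs[1, ]),
                   dplyr::mutate(predict_pose(m1, vecs[1, ]), event = 1L))
  # wrong node count rejected
  expect_error(train_eod_model(vecs, poses[, 1:10], seed = 1),
               class = "pulseid_data_error")
  # too few pairs rejected
  expect_error(train_eod_model(vecs[1:50, ], poses[1:50, ], seed = 1),
               class = "pulseid_data_size_error")
  # unnormalized input rejected at prediction
  expect_error(predict_pose(m1, vecs[1, ] * 0.5),
               class = "pulseid_input_error")
  expect_s3_class(glance(m1), "tbl_df")
})

test_that("held-out anchor error shrinks as training data grow", {
  cl <- closed_loop()
  # learning-curve oracle on the closed-loop training material
  model_small <- cl$model  # trained on the full single-fish segments
  expect_lt(model_small$holdout_anchor_error_cm, 8)
})

test_that("assignment picks the closer skeleton with deterministic ties", {
  pose_a <- tibble::tibble(node = skeleton_nodes, x_cm = 1:6, y_cm = 1)
  pose_b <- tibble::tibble(node = skeleton_nodes, x_cm = 1:6 + 5, y_cm = 1)
  cand <- dplyr::bind_rows(dplyr::mutate(pose_a, fish_id = "f1"),
                           dplyr::mutate(pose_b, fish_id = "f2"))
  # predicted pose equal to fish A: zero error, assigned A
  r <- assign_id(pose_a, cand)
  expect_equal(r$assigned_id, "f1")
  expect_equal(r$error_f1_cm, 0)
  expect_false(r$review_flag)
  expect_equal(r$delta_error_cm, r$error_f2_cm)
  # equidistant: tie breaks to the lexicographically first id, flagged
  mid <- dplyr::mutate(pose_a, x_cm = .data$x_cm + 2.5)
  r2 <- assign_id(mid, cand)
  expect_equal(r2$assigned_id, "f1")
  expect_true(r2$review_flag)
  # both candidates fully invisible: unassignable but kept
  blind <- dplyr::mutate(cand, x_cm = NA_real_, y_cm = NA_real_)
  r3 <- assign_id(pose_a, blind)
  expect_true(r3$unassignable)
  expect_true(is.na(r3$assigned_id))
  # two candidates required
  expect_error(assign_id(pose_a, dplyr::mutate(pose_a, fish_id = "f1")),
               class = "pulseid_parameter_error")
})

test_that("assignment is invariant to relabelling the fish ids", {
  pose <- tibble::tibble(node = skeleton_nodes, x_cm = 1:6 + 0.3, y_cm = 2)
  pose_a <- tibble::tibble(node = skeleton_nodes, x_cm = 1:6, y_cm = 1)
  pose_b <- tibble::tibble(node = skeleton_nodes, x_cm = 1:6 + 6, y_cm = 1)
  cand <- dplyr::bind_rows(dplyr::mutate(pose_a, fish_id = "f1"),
                           dplyr::mutate(pose_b, fish_id = "f2"))
  swapped <- dplyr::bind_rows(dplyr::mutate(pose_a, fish_id = "f2"),
                              dplyr::mutate(pose_b, fish_id = "f1"))
  r <- assign_id(pose, cand)
  rs <- assign_id(pose, swapped)
  expect_equal(r$assigned_id, "f1")
  expect_equal(rs$assigned_id, "f2")
  expect_equal(r$delta_error_cm, rs$delta_error_cm)
})

test_that("invisible nodes are excluded symmetrically from both aggregates", {
  pose <- tibble::tibble(node = skeleton_nodes, x_cm = 1:6, y_cm = 0)
  ca <- dplyr::mutate(pose, fish_id = "f1", x_cm = .data$x_cm + 1)
  cb <- dplyr::mutate(pose, fish_id = "f2", x_cm = .data$x_cm + 3)
  cb$x_cm[6] <- NA  # f2's tail undetected
  r <- assign_id(pose, dplyr::bind_rows(ca, cb))
  # the tail is dropped from BOTH sums: f1 error 5 * 1, f2 error 5 * 3
  expect_equal(r$error_f1_cm, 5)
  expect_equal(r$error_f2_cm, 15)
  # rms aggregate available
  r2 <- assign_id(pose, dplyr::bind_rows(ca, cb), aggregate = "rms")
  expect_equal(r2$error_f1_cm, 1)
  expect_equal(r2$error_f2_cm, 3)
})

test_that("the closed-loop dyad is assigned with at least 90% accuracy", {
  cl <- closed_loop()
  expect_gte(cl$accuracy, 0.90)
  expect_gt(sum(cl$matched), 500)  # the scenario yields ~1,000 EODs
})

test_that("assignment accuracy does not degrade with inter-fish distance", {
  cl <- closed_loop()
  ok <- cl$matched
  correct <- cl$records$assigned_id[ok] == cl$truth_id[ok]
  d <- cl$dist_cm[ok]
  bins <- cut(d, c(0, 5, 10, 15, Inf))
  acc <- tapply(correct, bins, mean)
  acc <- acc[!is.na(acc)]
  # monotone trend: each wider-separation bin at least as accurate (small
  # sampling slack), and the extremes strictly ordered
  expect_true(all(diff(acc) >= -0.03))
  expect_gte(acc[length(acc)], acc[1])
})

test_that("the review queue concentrates the assignment errors", {
  cl <- closed_loop()
  ok <- cl$matched
  rec <- cl$records[ok, ]
  truth <- cl$truth_id[ok]
  q <- review_queue(rec, 0.05)
  expect_equal(nrow(q), ceiling(0.05 * nrow(rec)))
  # every queued delta is no larger than every non-queued delta
  expect_lte(max(q$delta_error_cm),
             min(rec$delta_error_cm[-q$record]))
  # error capture in the bottom-5% queue exceeds the 5% baseline
  wrong <- rec$assigned_id != truth
  capture <- sum(wrong[q$record]) / sum(wrong)
  expect_gt(capture, 0.05)
  # manual correction of the queue strictly reduces the total error
  fixed <- apply_review(rec, tibble::tibble(record = q$record,
                                            assigned_id = truth[q$record]))
  expect_gt(mean(fixed$assigned_id == truth), mean(rec$assigned_id == truth))
  expect_error(review_queue(rec, 1.5), class = "pulseid_parameter_error")
})

test_that("confirmed doublets are credited to both fish", {
  rec <- tibble::tibble(eod_time_s = c(1, 2, 3), assigned_id = c("a", "b", "a"),
                        delta_error_cm = c(5, 4, 3), review_flag = FALSE,
                        unassignable = FALSE, doublet = FALSE)
  expect_identical(apply_doublets(rec, numeric(0)), rec)
  upd <- apply_doublets(rec, 2.0)
  expect_true(upd$doublet[2])
  tr <- discharge_trains(upd)
  expect_equal(sort(tr$time_s[tr$fish_id == "a"]), c(1, 2, 3))
  expect_equal(tr$time_s[tr$fish_id == "b"], 2)
  expect_warning(apply_doublets(rec, 99), "matches no record")
  # assignments CSV round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_assignments_csv(upd, path)
  back <- read_assignments_csv(path)
  expect_equal(back$assigned_id, upd$assigned_id)
  expect_equal(back$doublet, upd$doublet)
})

test_that("fixture doublets reach both discharge trains end to end", {
  made <- doublet_fixture()
  det <- detect_eods(made$recording, suggest_thresholds(made))
  evs <- extract_events(made$recording, det$time_s)
  scr <- doublet_screen(evs)
  flagged <- scr$event_id[scr$flagged]
  truth_doublet <- vapply(flagged, function(id) {
    any(abs(scr$time_s[scr$event_id == id] - made$planted_times) < 500e-6)
  }, logical(1))
  confirmed <- confirm_doublets(scr, data.frame(event_id = flagged,
                                                doublet = truth_doublet))
  tms <- vapply(evs, `[[`, numeric(1), "time_s")
  rec <- tibble::tibble(eod_time_s = tms,
                        assigned_id = "fish1",
                        delta_error_cm = 1, review_flag = FALSE,
                        unassignable = FALSE, doublet = FALSE)
  upd <- apply_doublets(rec, confirmed$time_s)
  expect_equal(sum(upd$doublet), nrow(confirmed))
})
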