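#' Convert long pose records to the wide per-event layout
#'
#' @param poses_long Tibble with columns `t` (or `event`), `node`, `x_cm`,
#'   `y_cm` (one row per node), e.g. from [poses_at_times()] filtered to one
#'   animal.
#' @return Wide tibble, one row per event, columns `<node>_x`, `<node>_y`
#'   in canonical node order.
#' @export
poses_wide <- function(poses_long) {
  key <- if ("t" %in% names(poses_long)) "t" else "event"
  poses_long |>
    dplyr::mutate(node = factor(.data$node, levels = skeleton_nodes)) |>
    dplyr::arrange(.data[[key]], .data$node) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(key),
                       names_from = "node",
                       values_from = c("x_cm", "y_cm"),
                       names_glue = "{node}_{substr(.value, 1, 1)}")
}

pose_cols <- function() {
  as.vector(t(outer(skeleton_nodes, c("x", "y"), paste, sep = "_")))
}

#' Train the waveform-to-pose regressor
#'
#' Fits a tree-ensemble (100 trees per output) mapping normalized
#' 7-channel EOD waveform vectors to the 12 coordinates of the six skeleton
#' nodes. Training data must come from single-fish segments where identity
#' is unambiguous. A 75/25 split is used to report the held-out anchor
#' (head2) error.
#'
#' @param vectors n x (n_channels * W) matrix from [build_vectors()].
#' @param poses Wide pose tibble/matrix (n rows, columns `<node>_x`,
#'   `<node>_y`; see [poses_wide()]).
#' @param n_estimators Trees per output forest (default 100).
#' @param seed Integer seed.
#' @param min_pairs Minimum training pairs required.
#'
#' @return An `eod_position_model` with `$holdout_anchor_error_cm`.
#' @export
train_eod_model <- function(vectors, poses, n_estimators = 100, seed = 1L,
                            min_pairs = 100) {
  vectors <- as.matrix(vectors)
  want <- pose_cols()
  if (!all(want %in% colnames(poses))) {
    abort_pulseid("poses must have <node>_x / <node>_y columns for all six nodes",
                  "pulseid_data_error")
  }
  y <- as.matrix(poses[, want])
  if (nrow(vectors) != nrow(y)) {
    abort_pulseid("vectors and poses must have equal row counts",
                  "pulseid_data_error")
  }
  if (nrow(vectors) < min_pairs) {
    abort_pulseid(sprintf("need at least %d training pairs", min_pairs),
                  "pulseid_data_size_error")
  }
  keep <- stats::complete.cases(y)
  vectors <- vectors[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  n <- nrow(vectors)
  idx_tr <- with_seed(child_seed(seed, 1L), sample.int(n, floor(0.75 * n)))
  xdf <- as.data.frame(vectors)
  names(xdf) <- paste0("v", seq_len(ncol(xdf)))
  fits <- purrr::imap(stats::setNames(want, want), function(cn, nm) {
    df <- xdf[idx_tr, ]
    df$.y <- y[idx_tr, cn]
    ranger::ranger(dependent.variable.name = ".y", data = df,
                   num.trees = n_estimators,
                   seed = child_seed(seed, 10L + match(nm, want)),
                   num.threads = 1)
  })
  model <- structure(
    list(fits = fits, input_dim = ncol(vectors), output_dim = length(want),
         n_estimators = n_estimators, seed = as.integer(seed),
         feature_names = names(xdf), fitted = TRUE),
    class = "eod_position_model")
  ho <- predict_pose_matrix(model, vectors[-idx_tr, , drop = FALSE])
  ax <- paste0(anchor_node, "_x"); ay <- paste0(anchor_node, "_y")
  model$holdout_anchor_error_cm <-
    stats::median(sqrt((ho[, ax] - y[-idx_tr, ax])^2 +
                       (ho[, ay] - y[-idx_tr, ay])^2))
  model
}

#' @export
print.eod_position_model <- function(x, ...) {
  cat(sprintf(
    "<eod_position_model> %d trees/output, %d -> %d, held-out anchor error %.2f cm\n",
    x$n_estimators, x$input_dim, x$output_dim, x$holdout_anchor_error_cm))
  invisible(x)
}

#' @method glance eod_position_model
#' @export
glance.eod_position_model <- function(x, ...) {
  tibble::tibble(n_estimators = x$n_estimators, input_dim = x$input_dim,
                 output_dim = x$output_dim,
                 holdout_anchor_error_cm = x$holdout_anchor_error_cm)
}

predict_pose_matrix <- function(model, vectors) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != model$input_dim) {
    abort_pulseid("vector dimension does not match the model",
                  "pulseid_data_error")
  }
  mx <- apply(abs(vectors), 1, max)
  if (any(abs(mx - 1) > 1e-6)) {
    abort_pulseid("waveform vectors must be normalized to max |v| = 1",
                  "pulseid_input_error")
  }
  xdf <- as.data.frame(vectors)
  names(xdf) <- model$feature_names
  out <- vapply(model$fits,
                function(f) stats::predict(f, data = xdf,
                                           num.threads = 1)$predictions,
                numeric(nrow(xdf)))
  if (nrow(xdf) == 1) out <- matrix(out, nrow = 1,
                                    dimnames = list(NULL, names(model$fits)))
  out
}

#' Predict a skeleton pose from a waveform vector
#'
#' @param model A fitted `eod_position_model`.
#' @param vector Normalized waveform vector (max |v| = 1), or a matrix of
#'   them (one per row).
#' @return Long tibble: `event`, `node`, `x_cm`, `y_cm`.
#' @export
predict_pose <- function(model, vector) {
  if (!isTRUE(model$fitted)) {
    abort_pulseid("model is not fitted", "pulseid_fit_state_error")
  }
  m <- if (is.matrix(vector)) vector else matrix(vector, nrow = 1)
  out <- predict_pose_matrix(model, m)
  purrr::map_dfr(seq_len(nrow(out)), function(i) {
    tibble::tibble(event = i, node = skeleton_nodes,
                   x_cm = out[i, paste0(skeleton_nodes, "_x")],
                   y_cm = out[i, paste0(skeleton_nodes, "_y")])
  })
}

# Aggregate node-to-node distance between a predicted and a candidate pose.
# Invisible nodes (NA on either side) are excluded pairwise.
pose_distance <- function(px, py, cx, cy, aggregate) {
  ok <- is.finite(px) & is.finite(py) & is.finite(cx) & is.finite(cy)
  if (!any(ok)) return(NA_real_)
  d <- sqrt((px[ok] - cx[ok])^2 + (py[ok] - cy[ok])^2)
  if (aggregate == "rms") sqrt(mean(d^2)) else sum(d)
}

#' Assign one EOD to the best-matching tracked fish
#'
#' Compares the model-predicted skeleton to the tracked skeleton of each
#' candidate fish (aggregate over the six node-to-node Euclidean distances,
#' default the sum; RMS available) and assigns the EOD to the fish with the
#' smallest error. Exact ties break deterministically to the
#' lexicographically first fish id and set the review flag.
#'
#' @param predicted Long pose tibble (`node`, `x_cm`, `y_cm`) from
#'   [predict_pose()].
#' @param candidates Long tibble of tracked poses with columns `fish_id`,
#'   `node`, `x_cm`, `y_cm` (exactly 2 fish); invisible nodes as NA
#'   coordinates or `visible = FALSE`.
#' @param aggregate `"sum"` (default) or `"rms"`.
#'
#' @return One-row tibble: `assigned_id`, `error_<id>_cm` per candidate,
#'   `delta_error_cm`, `review_flag`, `unassignable`, `doublet`.
#' @export
assign_id <- function(predicted, candidates, aggregate = c("sum", "rms")) {
  aggregate <- match.arg(aggregate)
  ids <- sort(unique(candidates$fish_id))
  if (length(ids) != 2) {
    abort_pulseid("exactly 2 candidate fish are required",
                  "pulseid_parameter_error")
  }
  p <- predicted[match(skeleton_nodes, predicted$node), ]
  if ("visible" %in% names(candidates)) {
    candidates <- dplyr::mutate(
      candidates,
      x_cm = ifelse(.data$visible, .data$x_cm, NA_real_),
      y_cm = ifelse(.data$visible, .data$y_cm, NA_real_))
  }
  cand_nodes <- purrr::map(stats::setNames(ids, ids), function(id) {
    cc <- candidates[candidates$fish_id == id, ]
    cc[match(skeleton_nodes, cc$node), ]
  })
  # nodes undetected for either candidate are dropped from both aggregates
  joint <- is.finite(p$x_cm) & is.finite(p$y_cm)
  for (cc in cand_nodes) joint <- joint & is.finite(cc$x_cm) & is.finite(cc$y_cm)
  errs <- purrr::map_dbl(cand_nodes, function(cc) {
    if (!any(joint)) return(NA_real_)
    pose_distance(p$x_cm[joint], p$y_cm[joint],
                  cc$x_cm[joint], cc$y_cm[joint], aggregate)
  })
  unassignable <- all(!is.finite(errs))
  if (unassignable) {
    assigned <- NA_character_; delta <- NA_real_; tie <- TRUE
  } else {
    finite_errs <- ifelse(is.finite(errs), errs, Inf)
    assigned <- ids[which.min(finite_errs)]  # which.min takes the first: tie
    tie <- sum(finite_errs == min(finite_errs)) > 1
    delta <- if (all(is.finite(errs))) abs(errs[1] - errs[2]) else NA_real_
  }
  out <- tibble::tibble(assigned_id = assigned,
                        delta_error_cm = as.numeric(delta),
                        review_flag = tie || unassignable,
                        unassignable = unassignable, doublet = FALSE)
  for (id in ids) out[[paste0("error_", id, "_cm")]] <- as.numeric(errs[[id]])
  out
}

#' Assign every EOD of a recording to a tracked fish
#'
#' Batch wrapper: predicts a pose from every waveform vector, interpolates
#' both tracked skeletons at the EOD times and applies [assign_id()].
#'
#' @param model Fitted `eod_position_model`.
#' @param vectors Matrix of normalized waveform vectors (one per row).
#' @param times EOD times (s), one per vector.
#' @param tracking A [tracked_sequence()] with both fish.
#' @param aggregate Error aggregate, `"sum"` or `"rms"`.
#'
#' @return Assignment tibble: `eod_time_s`, `assigned_id`,
#'   `error_<id>_cm` (per fish), `delta_error_cm`, `review_flag`,
#'   `unassignable`, `doublet`.
#' @export
assign_ids <- function(model, vectors, times, tracking,
                       aggregate = c("sum", "rms")) {
  aggregate <- match.arg(aggregate)
  stopifnot(nrow(vectors) == length(times))
  pred <- predict_pose_matrix(model, vectors)
  cand <- poses_at_times(tracking, times)
  ids <- sort(unique(cand$fish_id))
  rows <- purrr::map_dfr(seq_along(times), function(i) {
    pi <- tibble::tibble(node = skeleton_nodes,
                         x_cm = pred[i, paste0(skeleton_nodes, "_x")],
                         y_cm = pred[i, paste0(skeleton_nodes, "_y")])
    ci <- cand[cand$t == times[i], ]
    assign_id(pi, ci[, c("fish_id", "node", "x_cm", "y_cm", "visible")],
              aggregate = aggregate)
  })
  dplyr::bind_cols(tibble::tibble(eod_time_s = times), rows)
}

#' Review queue of the least-separable assignments
#'
#' The assignments with the smallest difference between the two fish's
#' estimation errors are the most likely to be wrong; inspecting the bottom
#' 5-10% captures a disproportionate share of all errors.
#'
#' @param records Assignment tibble from [assign_ids()].
#' @param fraction Fraction of records to queue (defaults offered: 0.05 and
#'   0.10).
#' @return The `ceiling(fraction * n)` records with smallest
#'   `delta_error_cm`, ascending, with their row index in `record`.
#' @export
review_queue <- function(records, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) {
    abort_pulseid("fraction must be in (0, 1)", "pulseid_parameter_error")
  }
  n <- nrow(records)
  k <- ceiling(fraction * n)
  records$record <- seq_len(n)
  ord <- order(records$delta_error_cm)
  records[ord[seq_len(k)], ]
}

#' Apply manual review decisions to assignments
#'
#' @param records Assignment tibble.
#' @param decisions Tibble with `record` (row index) and `assigned_id`
#'   (corrected id), e.g. a [review_queue()] export round-tripped via CSV.
#' @return Updated records.
#' @export
apply_review <- function(records, decisions) {
  stopifnot(all(c("record", "assigned_id") %in% names(decisions)))
  records$assigned_id[decisions$record] <- decisions$assigned_id
  records
}

#' Credit confirmed doublets to both fish
#'
#' Marks assignment records matching a confirmed doublet time; in the
#' per-fish discharge trains ([discharge_trains()]) these events are
#' credited to both fish.
#'
#' @param records Assignment tibble.
#' @param doublet_times Confirmed doublet times (s), from
#'   [confirm_doublets()].
#' @param tol_s Matching tolerance, s (default half the extraction window).
#' @return Updated records with `doublet = TRUE` on matches.
#' @export
apply_doublets <- function(records, doublet_times, tol_s = 200e-6) {
  if (length(doublet_times) == 0) return(records)
  for (t in doublet_times) {
    hit <- which(abs(records$eod_time_s - t) <= tol_s)
    if (length(hit) == 0) {
      warning(sprintf("doublet at t = %.6f s matches no record", t),
              call. = FALSE)
    } else {
      records$doublet[hit[1]] <- TRUE
    }
  }
  records
}

#' Per-fish discharge trains
#'
#' @param records Assignment tibble (after [apply_doublets()]).
#' @return Tibble `fish_id`, `time_s`; doublet events appear under both
#'   fish.
#' @export
discharge_trains <- function(records) {
  ids <- sort(unique(stats::na.omit(records$assigned_id)))
  purrr::map_dfr(ids, function(id) {
    keep <- (!is.na(records$assigned_id) & records$assigned_id == id) |
      records$doublet
    tibble::tibble(fish_id = id, time_s = sort(records$eod_time_s[keep]))
  })
}

#' Write / read assignment records
#' @param records Assignment tibble.
#' @param path CSV path.
#' @return `path` (writer, invisibly) or a tibble (reader).
#' @export
write_assignments_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments_csv
#' @export
read_assignments_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
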