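#' Localizer model specification
#'
#' Describes the supervised regressor used to predict virtual-fish position,
#' orientation and size from simulated channel potentials. The primary model
#' is a random-forest (tree-ensemble) regressor with 25 trees; a single
#' hidden-layer perceptron is available as a baseline for comparison.
#'
#' @param algorithm `"tree_ensemble"` (default) or `"mlp_baseline"`.
#' @param n_trees Trees per forest (default 25, the study setting).
#' @param hidden_size Hidden-layer width for the baseline (50, 100 or 200).
#' @param max_iter Iteration cap for the baseline optimiser.
#' @param seed Integer seed controlling all fitting randomness.
#'
#' @return A `localizer_spec` list.
#' @export
localizer_spec <- function(algorithm = c("tree_ensemble", "mlp_baseline"),
                           n_trees = 25, hidden_size = 100,
                           max_iter = 10000, seed = 1L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, n_trees = n_trees,
                 hidden_size = hidden_size, max_iter = max_iter,
                 seed = as.integer(seed)),
            class = "localizer_spec")
}

target_cols <- c("x", "y", "sin", "cos", "length")

split_features_targets <- function(data) {
  feat <- grep("^ch[0-9]+$", names(data), value = TRUE)
  targ <- intersect(target_cols, names(data))
  if (length(feat) == 0 || length(targ) == 0) {
    abort_pulseid("dataset must contain ch* feature and target columns",
                  "pulseid_data_error")
  }
  list(features = feat, targets = targ)
}

#' Train a localizer on a labelled field dataset
#'
#' Splits the dataset into a training and held-out test set (75/25 by
#' default), tunes the tree ensemble by a randomized search over a declared
#' hyperparameter grid (`tune_budget` candidates, default 25, scored by
#' 3-fold cross-validation on the training split only) and fits one forest
#' per target variable.
#'
#' @param data Tibble from [sample_placements()] with `ch*` features and
#'   `x, y, sin, cos, length` targets.
#' @param model_spec A [localizer_spec()].
#' @param train_fraction Fraction of rows used for training, in (0, 1).
#' @param tune_budget Number of hyperparameter candidates evaluated
#'   (0 disables tuning and uses package defaults).
#' @param seed Integer seed for the split, the candidate sampling and the
#'   forests.
#'
#' @return A fitted `localizer_model` with the held-out split attached
#'   (`$test`), the tuning table (`$tuning`) and the chosen candidate
#'   (`$params`).
#' @export
train_localizer <- function(data, model_spec = localizer_spec(),
                            train_fraction = 0.75, tune_budget = 25,
                            seed = model_spec$seed) {
  stopifnot(inherits(model_spec, "localizer_spec"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_pulseid("train_fraction must be in (0, 1)", "pulseid_parameter_error")
  }
  n <- nrow(data)
  n_train <- floor(n * train_fraction)
  if (n < 8 || n_train < 4 || n_train >= n) {
    abort_pulseid("dataset too small for the requested split",
                  "pulseid_data_size_error")
  }
  cols <- split_features_targets(data)
  idx_train <- with_seed(child_seed(seed, 1L), sample.int(n, n_train))
  train <- data[idx_train, ]
  test <- data[-idx_train, ]

  tuning <- NULL
  params <- list(mtry = length(cols$features), min_node_size = 1L,
                 max_depth = 0L, splitrule = "variance")
  if (model_spec$algorithm == "tree_ensemble" && tune_budget > 0) {
    grid <- expand.grid(
      mtry = unique(pmin(c(3L, 5L, 7L), length(cols$features))),
      min_node_size = c(1L, 2L, 5L),
      max_depth = c(0L, 12L),
      splitrule = c("variance", "extratrees"),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    k <- min(tune_budget, nrow(grid))
    cand <- grid[with_seed(child_seed(seed, 2L), sample.int(nrow(grid), k)), ]
    folds <- with_seed(child_seed(seed, 3L),
                       sample(rep_len(1:3, nrow(train))))
    # Candidates are compared on the cross-validated median spatial error of
    # the position targets: localization is the quantity the workflow
    # consumes downstream and the statistic used to rank electrode layouts.
    pos <- intersect(c("x", "y"), cols$targets)
    tune_targets <- if (length(pos) == 2) pos else cols$targets
    scores <- purrr::map_dbl(seq_len(nrow(cand)), function(i) {
      p <- as.list(cand[i, ])
      cv_err <- purrr::map(1:3, function(f) {
        tr <- train[folds != f, ]; va <- train[folds == f, ]
        cols_t <- list(features = cols$features, targets = tune_targets)
        fit <- fit_forests(tr, cols_t, model_spec, p, child_seed(seed, 10L + f))
        pred <- predict_targets(fit, va, cols_t)
        if (length(pos) == 2) {
          sqrt((va$x - pred$x)^2 + (va$y - pred$y)^2)
        } else {
          sqrt(rowSums(purrr::map_dfc(tune_targets,
                                      ~ (va[[.x]] - pred[[.x]])^2)))
        }
      })
      stats::median(unlist(cv_err))
    })
    tuning <- tibble::as_tibble(cand)
    tuning$cv_median_error <- scores
    best <- which.min(scores)
    params <- as.list(cand[best, ])
  }

  fits <- if (model_spec$algorithm == "tree_ensemble") {
    fit_forests(train, cols, model_spec, params, child_seed(seed, 4L))
  } else {
    fit_mlp(train, cols, model_spec, child_seed(seed, 4L))
  }

  structure(
    list(spec = model_spec, fits = fits, cols = cols, params = params,
         tuning = tuning, train = train, test = test,
         fitted = TRUE, seed = as.integer(seed)),
    class = "localizer_model"
  )
}

# One ranger forest per target (no installed forest supports joint
# multi-output regression); seeds are derived per target so refits are
# reproducible.
fit_forests <- function(train, cols, spec, params, seed) {
  x <- as.data.frame(train[cols$features])
  purrr::imap(stats::setNames(cols$targets, cols$targets), function(tg, nm) {
    df <- x
    df$.y <- train[[tg]]
    sr <- params$splitrule %||% "variance"
    ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = spec$n_trees,
      mtry = min(params$mtry, length(cols$features)),
      min.node.size = params$min_node_size,
      max.depth = if (params$max_depth == 0) NULL else params$max_depth,
      splitrule = sr,
      num.random.splits = if (sr == "extratrees") 5L else 1L,
      seed = child_seed(seed, match(nm, cols$targets)),
      num.threads = 1
    )
  })
}

fit_mlp <- function(train, cols, spec, seed) {
  x <- scale(as.matrix(train[cols$features]))
  ctr <- attr(x, "scaled:center"); scl <- attr(x, "scaled:scale")
  nets <- with_seed(seed, {
    purrr::map(stats::setNames(cols$targets, cols$targets), function(tg) {
      nnet::nnet(x, train[[tg]], size = spec$hidden_size, linout = TRUE,
                 maxit = spec$max_iter, trace = FALSE,
                 MaxNWts = 100000, decay = 1e-4)
    })
  })
  structure(list(nets = nets, center = ctr, scale = scl), class = "pulseid_mlp")
}

predict_targets <- function(fits, newdata, cols) {
  if (inherits(fits, "pulseid_mlp")) {
    x <- sweep(sweep(as.matrix(newdata[cols$features]), 2, fits$center),
               2, fits$scale, "/")
    out <- purrr::map(fits$nets, ~ as.numeric(stats::predict(.x, x)))
  } else {
    x <- as.data.frame(newdata[cols$features])
    out <- purrr::map(fits, ~ stats::predict(.x, data = x,
                                             num.threads = 1)$predictions)
  }
  tibble::as_tibble(out)
}

mean_r2 <- function(truth, pred, targets) {
  mean(purrr::map_dbl(targets, function(tg) {
    u <- sum((truth[[tg]] - pred[[tg]])^2)
    v <- sum((truth[[tg]] - mean(truth[[tg]]))^2)
    1 - u / v
  }))
}

#' @export
predict.localizer_model <- function(object, newdata = object$test, ...) {
  if (!isTRUE(object$fitted)) {
    abort_pulseid("model is not fitted", "pulseid_fit_state_error")
  }
  predict_targets(object$fits, newdata, object$cols)
}

#' Coefficient of determination on a held-out set
#'
#' Computes `R^2 = 1 - u/v` per target, with `u` the residual sum of squares
#' and `v` the total sum of squares, and returns their uniform average (the
#' multi-output convention of the reference scorer).
#'
#' @param model A fitted `localizer_model`.
#' @param test Tibble with feature and target columns (defaults to the
#'   model's held-out split).
#'
#' @return The average R^2 (numeric scalar) with the per-target scores in
#'   attribute `"per_target"`.
#' @export
score_r2 <- function(model, test = model$test) {
  if (!isTRUE(model$fitted)) {
    abort_pulseid("model is not fitted", "pulseid_fit_state_error")
  }
  if (nrow(test) == 0) abort_pulseid("empty test set", "pulseid_data_error")
  tg <- model$cols$targets
  vars <- purrr::map_dbl(tg, ~ stats::var(test[[.x]]))
  if (any(vars == 0)) {
    abort_pulseid("zero-variance target: R^2 undefined",
                  "pulseid_undefined_score")
  }
  pred <- predict(model, test)
  per <- purrr::map_dbl(stats::setNames(tg, tg), function(t1) {
    u <- sum((test[[t1]] - pred[[t1]])^2)
    v <- sum((test[[t1]] - mean(test[[t1]]))^2)
    1 - u / v
  })
  out <- mean(per)
  attr(out, "per_target") <- per
  out
}

#' Spatial localization error report
#'
#' Per-sample Euclidean distance between true and predicted (x, y), the
#' median error, per-target R^2, and a tank-grid error map marking cells
#' whose mean error exceeds `map_threshold` (default 3 cm, the map threshold
#' used to visualise weak regions of an electrode layout).
#'
#' @param model Fitted `localizer_model`.
#' @param test Held-out tibble (defaults to the model's split).
#' @param map_threshold Error-map threshold, cm.
#' @param cell_cm Error-map cell size, cm (default 2).
#'
#' @return An `eval_report`: list with `errors` (tibble: x, y, error_cm),
#'   `median_error`, `r2_per_target`, `r2`, `error_map` (tibble of flagged
#'   cells) and the threshold used.
#' @export
spatial_error <- function(model, test = model$test, map_threshold = 3,
                          cell_cm = 2) {
  pred <- predict(model, test)
  err <- sqrt((test$x - pred$x)^2 + (test$y - pred$y)^2)
  errors <- tibble::tibble(x = test$x, y = test$y,
                           pred_x = pred$x, pred_y = pred$y, error_cm = err)
  r2 <- score_r2(model, test)
  map <- errors |>
    dplyr::mutate(cx = floor(.data$x / cell_cm) * cell_cm + cell_cm / 2,
                  cy = floor(.data$y / cell_cm) * cell_cm + cell_cm / 2) |>
    dplyr::group_by(.data$cx, .data$cy) |>
    dplyr::summarise(mean_error_cm = mean(.data$error_cm), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$mean_error_cm > map_threshold)
  structure(
    list(errors = errors, median_error = stats::median(err),
         r2 = as.numeric(r2), r2_per_target = attr(r2, "per_target"),
         error_map = map, map_threshold = map_threshold, cell_cm = cell_cm),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d, R^2 = %.3f, median spatial error = %.2f cm, %d map cells > %g cm\n",
    nrow(x$errors), x$r2, x$median_error, nrow(x$error_map), x$map_threshold))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy localizer_model
#' @export
tidy.localizer_model <- function(x, ...) {
  r2 <- score_r2(x)
  tibble::tibble(target = names(attr(r2, "per_target")),
                 r2 = as.numeric(attr(r2, "per_target")))
}

#' @method glance localizer_model
#' @export
glance.localizer_model <- function(x, ...) {
  rep <- spatial_error(x)
  tibble::tibble(algorithm = x$spec$algorithm, n_trees = x$spec$n_trees,
                 n_train = nrow(x$train), n_test = nrow(x$test),
                 r2 = rep$r2, median_error_cm = rep$median_error)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$errors

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = nrow(x$errors), r2 = x$r2,
                 median_error_cm = x$median_error,
                 q1_error_cm = stats::quantile(x$errors$error_cm, 0.25),
                 q3_error_cm = stats::quantile(x$errors$error_cm, 0.75))
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$error_map,
                  ggplot2::aes(x = .data$cx, y = .data$cy,
                               fill = .data$mean_error_cm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean error (cm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)",
                  title = sprintf("Cells with mean error > %g cm",
                                  object$map_threshold))
}

#' Rank electrode configurations by localization performance
#'
#' Reuses one identical placement sample across all candidate layouts (same
#' fish positions, orientations and lengths; only the recorded channels
#' differ), trains a localizer per layout and tabulates held-out R^2 and
#' spatial-error quartiles, ranked by median error.
#'
#' @param config_ids Integer vector of layout ids (>= 2 entries), or a list
#'   of `electrode_config` objects.
#' @param tank A [tank_geometry()].
#' @param n Placements per layout (shared).
#' @param seed Integer seed shared by sampling and training.
#' @param tune_budget Hyperparameter candidates per layout.
#'
#' @return Tibble: config_id, r2, median_error_cm, q1/q3, rank.
#' @export
compare_configurations <- function(config_ids, tank = tank_geometry(),
                                   n = 2500, seed = 1L, tune_budget = 25) {
  configs <- if (is.list(config_ids) && inherits(config_ids[[1]], "electrode_config")) {
    config_ids
  } else {
    purrr::map(config_ids, ~ electrode_configuration(.x, tank))
  }
  if (length(configs) < 2) {
    abort_pulseid("need at least 2 configurations", "pulseid_parameter_error")
  }
  base <- sample_placements(n, tank, configs[[1]], seed = seed)
  targets <- base[target_cols]
  rows <- purrr::imap(configs, function(cfg, i) {
    ds <- if (i == 1) base else rechannel(targets, tank, cfg)
    model <- train_localizer(ds, localizer_spec(seed = seed),
                             tune_budget = tune_budget, seed = seed)
    g <- glance(spatial_error(model))
    tibble::tibble(config_id = cfg$config_id, r2 = g$r2,
                   median_error_cm = g$median_error_cm,
                   q1_error_cm = g$q1_error_cm, q3_error_cm = g$q3_error_cm)
  })
  out <- dplyr::bind_rows(rows)
  out$rank <- rank(out$median_error_cm, ties.method = "first")
  dplyr::arrange(out, .data$rank)
}

# Recompute channel potentials for fixed fish placements under a different
# electrode layout.
rechannel <- function(targets, tank, config) {
  ch <- t(apply(as.matrix(targets), 1, function(r) {
    fish <- virtual_fish(r[["length"]], c(r[["x"]], r[["y"]]),
                         c(r[["sin"]], r[["cos"]]))
    record_channels(fish, tank, config)
  }))
  colnames(ch) <- paste0("ch", seq_len(config$n_channels))
  dplyr::bind_cols(tibble::as_tibble(as.data.frame(ch)), targets)
}
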