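#' Tank geometry
#'
#' Describes the experimental arena in which fish swim and electrodes are
#' mounted: a rectangular tank (default 66 x 72 cm) with a safety margin
#' inside which simulated fish are placed. All distances are in cm.
#'
#' @param width Tank extent along x, cm.
#' @param depth_y Tank extent along y, cm.
#' @param wall_margin Minimum distance of any simulated fish pole from every
#'   wall, cm. Must satisfy `0 <= wall_margin < min(width, depth_y) / 2`.
#' @param electrode_positions Optional n x 2 matrix of electrode (x, y)
#'   positions in cm; electrodes must lie on or inside the tank boundary.
#'
#' @return An object of class `tank_geometry`.
#' @export
tank_geometry <- function(width = 66, depth_y = 72, wall_margin = 10,
                          electrode_positions = NULL) {
  if (!is.numeric(width) || width <= 0 || !is.numeric(depth_y) || depth_y <= 0) {
    abort_pulseid("tank dimensions must be positive", "pulseid_geometry_error")
  }
  if (wall_margin < 0 || wall_margin >= min(width, depth_y) / 2) {
    abort_pulseid("wall_margin must be in [0, min(width, depth_y)/2)",
                  "pulseid_geometry_error")
  }
  if (!is.null(electrode_positions)) {
    electrode_positions <- as.matrix(electrode_positions)
    stopifnot(ncol(electrode_positions) == 2)
    inside <- electrode_positions[, 1] >= 0 & electrode_positions[, 1] <= width &
      electrode_positions[, 2] >= 0 & electrode_positions[, 2] <= depth_y
    if (!all(inside)) {
      abort_pulseid("all electrodes must lie on or inside the tank boundary",
                    "pulseid_geometry_error")
    }
  }
  structure(
    list(width = width, depth_y = depth_y, wall_margin = wall_margin,
         electrode_positions = electrode_positions),
    class = "tank_geometry"
  )
}

#' @export
print.tank_geometry <- function(x, ...) {
  cat(sprintf("<tank_geometry> %g x %g cm, wall margin %g cm\n",
              x$width, x$depth_y, x$wall_margin))
  invisible(x)
}

#' Electrode configurations
#'
#' Builds one of six wall-mounted electrode layouts for a rectangular tank,
#' mirroring the arrangements screened in the simulation study:
#'
#' * 1 - seven short-baseline differential pairs hugging the walls: one
#'   inward-pointing pair near each corner, one at the middle of the short
#'   walls, plus one corner-to-corner diagonal pair. The layout used for the
#'   behavioural work.
#' * 2 - seven long-baseline pairs of diametrically opposite perimeter
#'   electrodes; the differential axis rotates from pair to pair and there
#'   is no central reference (good resolution mid-tank, poor at the walls).
#' * 3 - seven single-ended electrodes around the perimeter referenced to a
#'   ground electrode in the middle of the tank.
#' * 4 - as 1 but with a tighter 2 cm pair baseline and a third mid-wall
#'   pair instead of the diagonal.
#' * 5 - seven parallel bottom-top pairs (single-axis layout).
#' * 6 - five pairs forming a perpendicular net plus two corner-to-corner
#'   diagonal pairs.
#'
#' @param config_id Integer 1-6 selecting the layout.
#' @param tank A [tank_geometry()]. Electrode coordinates are scaled to its
#'   dimensions.
#'
#' @return An object of class `electrode_config` with fields `config_id`,
#'   `mode` (`"differential"` or `"single_ended"`), `electrodes` (m x 2
#'   matrix, cm), `channels` (n_channels x 2 index matrix; for single-ended
#'   the second column is `NA` and `reference` holds the ground position)
#'   and `n_channels`.
#' @export
electrode_configuration <- function(config_id, tank = tank_geometry()) {
  stopifnot(inherits(tank, "tank_geometry"))
  config_id <- as.integer(config_id)
  if (!config_id %in% 1:6) {
    abort_pulseid("config_id must be an integer in 1..6", "pulseid_config_error")
  }
  w <- tank$width; d <- tank$depth_y
  mode <- if (config_id == 3L) "single_ended" else "differential"
  reference <- NULL

  if (config_id == 1L) {
    el <- corner_wall_pairs(w, d, gap = 4, diagonal = TRUE)
    ch <- cbind(seq(1, 13, by = 2), seq(2, 14, by = 2))
  } else if (config_id == 2L) {
    # 14 electrodes evenly spaced along the perimeter, paired with the
    # diametrically opposite electrode: the differential axis rotates from
    # one pair to the next and every baseline crosses mid-tank.
    el <- perimeter_points(w, d, 14)
    ch <- cbind(1:7, 8:14)
  } else if (config_id == 3L) {
    el <- perimeter_points(w, d, 7)
    ch <- cbind(1:7, NA_integer_)
    reference <- c(w / 2, d / 2)
  } else if (config_id == 4L) {
    el <- corner_wall_pairs(w, d, gap = 2, diagonal = FALSE)
    ch <- cbind(seq(1, 13, by = 2), seq(2, 14, by = 2))
  } else if (config_id == 5L) {
    xs <- w * seq(0.125, 0.875, length.out = 7)
    el <- rbind(cbind(xs, 0), cbind(xs, d))
    ch <- cbind(1:7, 8:14)
  } else {
    el <- rbind(
      c(0, d * 0.33), c(w, d * 0.33),
      c(0, d * 0.67), c(w, d * 0.67),
      c(w * 0.33, 0), c(w * 0.33, d),
      c(w * 0.67, 0), c(w * 0.67, d),
      c(w * 0.5, 0), c(w * 0.5, d),
      c(0, 0), c(w, d),
      c(0, d), c(w, 0))
    ch <- cbind(seq(1, 13, by = 2), seq(2, 14, by = 2))
  }

  colnames(el) <- c("x", "y")
  if (mode == "differential" && any(ch[, 1] == ch[, 2])) {
    abort_pulseid("a channel may not pair an electrode with itself",
                  "pulseid_config_error")
  }
  structure(
    list(config_id = config_id, mode = mode, electrodes = el,
         channels = ch, n_channels = nrow(ch), reference = reference),
    class = "electrode_config"
  )
}

# Short-baseline wall layout shared by configurations 1 and 4: one
# inward-pointing pair near each corner, pairs at the middle of the short
# (bottom/top) walls, plus either a corner-to-corner diagonal pair or a
# third mid-wall pair.
corner_wall_pairs <- function(w, d, gap, diagonal) {
  centre <- c(w / 2, d / 2)
  corner_pair <- function(p) {
    dirv <- centre - p
    dirv <- dirv / sqrt(sum(dirv^2))
    rbind(p, p + gap * dirv)
  }
  norm_pair <- function(p) {
    nrm <- if (p[2] == 0) c(0, 1) else if (p[2] == d) c(0, -1)
           else if (p[1] == 0) c(1, 0) else c(-1, 0)
    rbind(p, p + gap * nrm)
  }
  el <- rbind(
    corner_pair(c(2, 2)), corner_pair(c(w - 2, 2)),
    corner_pair(c(w - 2, d - 2)), corner_pair(c(2, d - 2)),
    norm_pair(c(w / 2, 0)), norm_pair(c(w / 2, d)))
  if (diagonal) rbind(el, c(0, 0), c(w, d)) else rbind(el, norm_pair(c(0, d / 2)))
}

# n points evenly spaced along the rectangle perimeter, starting at the
# middle of the bottom wall, counter-clockwise.
perimeter_points <- function(w, d, n) {
  per <- 2 * (w + d)
  s <- (seq_len(n) - 1) / n * per + w / 2
  s <- s %% per
  t(vapply(s, function(si) {
    if (si < w) c(si, 0)
    else if (si < w + d) c(w, si - w)
    else if (si < 2 * w + d) c(2 * w + d - si, d)
    else c(0, per - si)
  }, numeric(2)))
}

#' @export
print.electrode_config <- function(x, ...) {
  cat(sprintf("<electrode_config> id %d, %s, %d channels, %d electrodes\n",
              x$config_id, x$mode, x$n_channels, nrow(x$electrodes)))
  invisible(x)
}

#' Virtual dipole fish
#'
#' A fish mimic for field simulation: a current dipole with poles at the
#' head and tail, separated by the body length. The heading is stored as
#' (sin, cos) of the orientation angle, the encoding also used as a
#' regression target to avoid angular wrap-around.
#'
#' @param length_cm Body length, cm (the study simulated 8-15 cm fish).
#' @param center Fish midpoint, numeric (x, y) in cm.
#' @param heading Orientation angle in radians, or a numeric pair
#'   `c(sin, cos)` (must be unit length).
#' @param kq Dipole scale: the product of the proportionality constant and
#'   the pole charge. The default 1 corresponds to setting the charge to the
#'   reciprocal of the constant, which bounds wall-mounted electrode
#'   potentials to roughly +/-1 V for a 10 cm wall margin.
#'
#' @return An object of class `virtual_fish` with derived `head_pos` and
#'   `tail_pos`.
#' @export
virtual_fish <- function(length_cm, center, heading, kq = 1) {
  stopifnot(is.numeric(length_cm), length_cm > 0, length(center) == 2)
  if (length(heading) == 1) {
    sc <- c(sin(heading), cos(heading))
  } else if (length(heading) == 2) {
    sc <- as.numeric(heading)
    if (abs(sum(sc^2) - 1) > 1e-9) {
      abort_pulseid("heading (sin, cos) must be unit length",
                    "pulseid_geometry_error")
    }
  } else {
    abort_pulseid("heading must be an angle or a (sin, cos) pair",
                  "pulseid_geometry_error")
  }
  # direction of travel: (cos theta, sin theta)
  dir <- c(sc[2], sc[1])
  head_pos <- center + length_cm / 2 * dir
  tail_pos <- center - length_cm / 2 * dir
  structure(
    list(length_cm = length_cm, center = as.numeric(center),
         sin_theta = sc[1], cos_theta = sc[2], kq = kq,
         head_pos = head_pos, tail_pos = tail_pos),
    class = "virtual_fish"
  )
}

#' Electric dipole potential of a virtual fish
#'
#' Evaluates `V = kq * (1/R1 - 1/R2)` where `R1` and `R2` are the distances
#' from the query point to the head (positive) and tail (negative) pole.
#' With distances in cm and `kq = 1` the result is in volts on the scale
#' used throughout the simulation study.
#'
#' @param fish A [virtual_fish()].
#' @param point Numeric (x, y) in cm, or an n x 2 matrix of points.
#'
#' @return Potential(s) in V, one per query point.
#' @export
dipole_potential <- function(fish, point) {
  stopifnot(inherits(fish, "virtual_fish"))
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2, byrow = TRUE)
  r1 <- row_norms(sweep(pts, 2, fish$head_pos))
  r2 <- row_norms(sweep(pts, 2, fish$tail_pos))
  if (any(r1 == 0 | r2 == 0)) {
    abort_pulseid("query point coincides with a dipole pole",
                  "pulseid_degenerate_geometry")
  }
  fish$kq * (1 / r1 - 1 / r2)
}

#' Simulated electrode channel potentials
#'
#' Evaluates the dipole potential of a virtual fish at every electrode of a
#' configuration and forms the recorded channels: differential channels are
#' the potential difference of their electrode pair, single-ended channels
#' are referenced to the ground electrode position.
#'
#' @param fish A [virtual_fish()]; both poles must lie strictly inside the
#'   tank.
#' @param tank A [tank_geometry()].
#' @param config An [electrode_configuration()].
#'
#' @return Numeric vector of `config$n_channels` potentials in V.
#' @export
record_channels <- function(fish, tank, config) {
  stopifnot(inherits(tank, "tank_geometry"), inherits(config, "electrode_config"))
  for (pole in list(fish$head_pos, fish$tail_pos)) {
    if (pole[1] <= 0 || pole[1] >= tank$width ||
        pole[2] <= 0 || pole[2] >= tank$depth_y) {
      abort_pulseid("fish pole outside the tank", "pulseid_placement_error")
    }
  }
  v <- dipole_potential(fish, config$electrodes)
  if (config$mode == "differential") {
    out <- v[config$channels[, 1]] - v[config$channels[, 2]]
  } else {
    vref <- dipole_potential(fish, config$reference)
    out <- v[config$channels[, 1]] - vref
  }
  as.numeric(out)
}

#' Sample random fish placements and their channel potentials
#'
#' Draws `n` random placements of virtual dipole fish in the tank (uniform
#' position and orientation, whole fish at least `wall_margin` from every
#' wall) and records the simulated channel potentials, producing the
#' labelled dataset used to train and rank electrode configurations.
#' Fish lengths are drawn uniformly from `n_fish` fixed, evenly spaced
#' lengths spanning `length_range`.
#'
#' @param n Number of placements (the study used 2,500).
#' @param tank,config Geometry and electrode layout.
#' @param n_fish Number of distinct simulated fish lengths (default 20).
#' @param length_range Length interval in cm (default `c(8, 15)`).
#' @param kq Dipole scale passed to [virtual_fish()].
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#'
#' @return A tibble with columns `ch1..chN`, `x`, `y`, `sin`, `cos`,
#'   `length` and attributes `seed`, `tank`, `config`.
#' @export
sample_placements <- function(n, tank = tank_geometry(),
                              config = electrode_configuration(1, tank),
                              n_fish = 20, length_range = c(8, 15),
                              kq = 1, seed = 1L) {
  stopifnot(n >= 1, n_fish >= 1, length(length_range) == 2)
  m <- tank$wall_margin
  lengths <- if (n_fish == 1) mean(length_range) else
    seq(length_range[1], length_range[2], length.out = n_fish)
  # feasibility: the inset box must be able to hold the longest fish pole
  if (tank$width - 2 * m <= 0 || tank$depth_y - 2 * m <= 0) {
    abort_pulseid("wall margin leaves no room for any placement",
                  "pulseid_infeasible_geometry")
  }
  rows <- with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      len <- sample(lengths, 1)
      attempts <- 0L
      repeat {
        attempts <- attempts + 1L
        if (attempts > 10000L) {
          abort_pulseid("no feasible placement found for the wall margin",
                        "pulseid_infeasible_geometry")
        }
        cx <- stats::runif(1, m, tank$width - m)
        cy <- stats::runif(1, m, tank$depth_y - m)
        th <- stats::runif(1, 0, 2 * pi)
        fish <- virtual_fish(len, c(cx, cy), th, kq = kq)
        ok <- all(c(fish$head_pos, fish$tail_pos) >=
                    c(m, m, m, m) - 1e-12) &&
          fish$head_pos[1] <= tank$width - m && fish$tail_pos[1] <= tank$width - m &&
          fish$head_pos[2] <= tank$depth_y - m && fish$tail_pos[2] <= tank$depth_y - m
        if (ok) break
      }
      ch <- record_channels(fish, tank, config)
      out[[i]] <- c(ch, cx, cy, sin(th), cos(th), len)
    }
    do.call(rbind, out)
  })
  nm <- c(paste0("ch", seq_len(config$n_channels)), "x", "y", "sin", "cos", "length")
  colnames(rows) <- nm
  ds <- tibble::as_tibble(as.data.frame(rows))
  if (any(!is.finite(as.matrix(ds)))) {
    abort_pulseid("non-finite entries in sampled dataset", "pulseid_data_error")
  }
  attr(ds, "seed") <- as.integer(seed)
  attr(ds, "tank") <- tank
  attr(ds, "config") <- config
  ds
}

#' Write / read a labelled field dataset
#'
#' The dataset is stored as a plain CSV (`ch1..chN, x, y, sin, cos, length`)
#' with a JSON sidecar (`<path>.json`) recording the seed and geometry so a
#' run can be reproduced.
#'
#' @param data Tibble from [sample_placements()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_field_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  tank <- attr(data, "tank")
  config <- attr(data, "config")
  meta <- list(
    seed = attr(data, "seed"),
    tank = if (!is.null(tank)) list(width = tank$width, depth_y = tank$depth_y,
                                    wall_margin = tank$wall_margin),
    config_id = if (!is.null(config)) config$config_id,
    n_channels = if (!is.null(config)) config$n_channels
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_field_dataset
#' @export
read_field_dataset <- function(path) {
  ds <- tibble::as_tibble(utils::read.csv(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(ds, "seed") <- meta$seed
  }
  ds
}

#' Read tank/electrode geometry from a YAML or JSON config file
#'
#' The file may contain `width`, `depth_y`, `wall_margin` and either
#' `config_id` (1-6, built-in layout) or an explicit `electrode_positions`
#' list.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `tank` and (if `config_id` given) `config`.
#' @export
read_geometry <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  tank <- tank_geometry(
    width = cfg$width %||% 66, depth_y = cfg$depth_y %||% 72,
    wall_margin = cfg$wall_margin %||% 10,
    electrode_positions = cfg$electrode_positions
  )
  out <- list(tank = tank)
  if (!is.null(cfg$config_id)) {
    out$config <- electrode_configuration(cfg$config_id, tank)
  }
  out
}
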