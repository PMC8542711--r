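#' Encounter annotation
#'
#' Manually scored behavioural events of one staged dyadic encounter:
#' attacks (contacts that change at least one fish's posture), chase
#' intervals, the first contact, its initiator and the targeted body
#' region. The package never infers these from video; they come from an
#' annotation file.
#'
#' @param pair_id Encounter identifier.
#' @param lengths Named numeric: body length (cm) per fish id (exactly 2).
#' @param first_contact_s Time of first physical contact, s.
#' @param initiator_id Fish initiating the first contact.
#' @param target_region `"head"` or `"tail"`.
#' @param attacks Tibble with `time_s`, `actor_id`.
#' @param chases Optional tibble with `start_s`, `end_s`, `chaser_id`.
#' @param recording_span_s Optional length-2 recording span for validation.
#'
#' @return An `encounter_annotation`.
#' @export
encounter_annotation <- function(pair_id, lengths, first_contact_s,
                                 initiator_id,
                                 target_region = c("head", "tail"),
                                 attacks = NULL, chases = NULL,
                                 recording_span_s = NULL) {
  target_region <- match.arg(target_region)
  if (length(lengths) != 2 || is.null(names(lengths))) {
    abort_pulseid("lengths must be a named vector of 2 fish lengths",
                  "pulseid_annotation_error")
  }
  attacks <- attacks %||% tibble::tibble(time_s = numeric(),
                                         actor_id = character())
  if (nrow(attacks) > 0 && !all(attacks$actor_id %in% names(lengths))) {
    abort_pulseid("attack actors must be one of the two fish ids",
                  "pulseid_annotation_error")
  }
  if (!is.null(recording_span_s) &&
      (first_contact_s < recording_span_s[1] ||
       first_contact_s > recording_span_s[2])) {
    abort_pulseid("first contact outside the recording span",
                  "pulseid_annotation_error")
  }
  structure(list(pair_id = pair_id, lengths = lengths,
                 first_contact_s = first_contact_s,
                 initiator_id = initiator_id, target_region = target_region,
                 attacks = attacks,
                 chases = chases %||% tibble::tibble(start_s = numeric(),
                                                     end_s = numeric(),
                                                     chaser_id = character())),
            class = "encounter_annotation")
}

#' Read / write encounter annotations (CSV)
#'
#' One CSV per cohort with a `record` column: `meta` rows carry
#' `pair_id, fish1_id, fish2_id, length1_cm, length2_cm, first_contact_s,
#' initiator_id, target_region`; `attack` rows carry `pair_id, time_s,
#' actor_id`; `chase` rows carry `pair_id, time_s` (start), `end_s`,
#' `actor_id`.
#'
#' @param path CSV path.
#' @return List of `encounter_annotation`, one per pair.
#' @export
read_annotations_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  purrr::map(split(raw, raw$pair_id), function(g) {
    meta <- g[g$record == "meta", ]
    if (nrow(meta) != 1) {
      abort_pulseid("each pair needs exactly one meta row",
                    "pulseid_annotation_error")
    }
    at <- g[g$record == "attack", ]
    ch <- g[g$record == "chase", ]
    encounter_annotation(
      pair_id = meta$pair_id,
      lengths = stats::setNames(c(meta$length1_cm, meta$length2_cm),
                                c(meta$fish1_id, meta$fish2_id)),
      first_contact_s = meta$first_contact_s,
      initiator_id = meta$initiator_id,
      target_region = meta$target_region,
      attacks = tibble::tibble(time_s = at$time_s, actor_id = at$actor_id),
      chases = tibble::tibble(start_s = ch$time_s, end_s = ch$end_s,
                              chaser_id = ch$actor_id))
  })
}

#' Dominance from attack counts
#'
#' The dominant fish is the one with strictly more attacks; equal counts
#' (or no attacks) leave the encounter undetermined. The relative size
#' difference `100 * (L_big - L_small) / L_big` classifies the pair as
#' `"large"` (> 20%) or `"small"` (<= 20%; the boundary itself is small).
#'
#' @param ann An [encounter_annotation()].
#' @return One-row tibble: `pair_id`, `dominant_id` (NA if undetermined),
#'   `attacks_<n>` counts, `size_difference_pct`, `size_class`,
#'   `larger_id`, `larger_is_dominant`.
#' @export
dominance <- function(ann) {
  ids <- names(ann$lengths)
  counts <- purrr::map_int(ids, ~ sum(ann$attacks$actor_id == .x))
  dominant <- if (sum(counts == max(counts)) == 1 && max(counts) > 0) {
    ids[which.max(counts)]
  } else {
    NA_character_
  }
  lb <- max(ann$lengths); ls <- min(ann$lengths)
  sd_pct <- 100 * (lb - ls) / lb
  larger <- ids[which.max(ann$lengths)]
  tibble::tibble(
    pair_id = ann$pair_id, dominant_id = dominant,
    attacks_fish1 = counts[1], attacks_fish2 = counts[2],
    size_difference_pct = sd_pct,
    size_class = ifelse(sd_pct > 20, "large", "small"),
    larger_id = larger,
    larger_is_dominant = !is.na(dominant) & dominant == larger)
}

#' One-sided exact binomial test
#'
#' Exact upper-tail probability of observing `k` or more successes in `n`
#' trials at success probability `p0`:
#' `sum_{i=k}^{n} C(n,i) p0^i (1-p0)^(n-i)`. Reproduces the printed
#' dominance tests (5/5 -> 0.03125, 9/13 -> 0.1334, 4/8 -> 0.6367).
#'
#' @param k Successes (0..n).
#' @param n Trials (>= 1).
#' @param p0 Null probability (default 0.5).
#' @param two_sided Use the two-sided exact test instead.
#' @return The p-value.
#' @export
binom_onesided <- function(k, n, p0 = 0.5, two_sided = FALSE) {
  if (n < 1 || k < 0 || k > n) {
    abort_pulseid("need 0 <= k <= n and n >= 1", "pulseid_parameter_error")
  }
  stats::binom.test(k, n, p = p0,
                    alternative = if (two_sided) "two.sided" else "greater"
                    )$p.value
}

#' Electric-image time course of one encounter
#'
#' Time-ordered per-EOD electric-image summaries up to first contact, with
#' the inter-fish anchor distance, and the first-detection analysis
#' (passive and active) attached.
#'
#' @param ei_tab Tibble with one row per EOD: `time_s`, `emitter`,
#'   `active_max`, `active_rms`, `passive_max`, `passive_rms` (uA/cm^2)
#'   and optionally `distance_cm`.
#' @param tracking Optional [tracked_sequence()] used to (re)compute the
#'   anchor distance at each EOD time.
#' @param first_contact_s Truncation time (first physical contact).
#' @param factor,floor Passed to [first_detection()].
#'
#' @return Tibble ordered by time with a `first_detection` attribute: list
#'   with `passive` and `active` one-row results (which fish detected the
#'   other first, and when).
#' @export
ei_timecourse <- function(ei_tab, tracking = NULL, first_contact_s = Inf,
                          factor = 2, floor = 0.1) {
  need <- c("time_s", "emitter", "active_max", "passive_max")
  if (!all(need %in% names(ei_tab))) {
    abort_pulseid(paste("ei_tab must contain:", paste(need, collapse = ", ")),
                  "pulseid_completeness_error")
  }
  tab <- dplyr::arrange(dplyr::filter(ei_tab, .data$time_s <= first_contact_s),
                        .data$time_s)
  if (nrow(tab) == 0) {
    abort_pulseid("no EODs before first contact", "pulseid_data_error")
  }
  if (!is.null(tracking)) {
    anch <- poses_at_times(tracking, tab$time_s)
    anch <- anch[anch$node == anchor_node, ]
    wide <- tidyr::pivot_wider(anch[, c("t", "fish_id", "x_cm", "y_cm")],
                               names_from = "fish_id",
                               values_from = c("x_cm", "y_cm"))
    ids <- sort(unique(anch$fish_id))
    tab$distance_cm <- sqrt(
      (wide[[paste0("x_cm_", ids[1])]] - wide[[paste0("x_cm_", ids[2])]])^2 +
      (wide[[paste0("y_cm_", ids[1])]] - wide[[paste0("y_cm_", ids[2])]])^2)
  }
  ids <- sort(unique(tab$emitter))
  # the image RECEIVED by a fish: passive when the other fish discharges,
  # active (self-image modulation) when it discharges itself
  series <- function(col, receiver) {
    src <- if (col == "passive_max") tab$emitter != receiver
           else tab$emitter == receiver
    tibble::tibble(time_s = tab$time_s[src], amp = tab[[col]][src])
  }
  fd <- list(
    passive = first_detection(series("passive_max", ids[1]),
                              series("passive_max", ids[2]),
                              factor = factor, floor = floor, ids = ids),
    active = first_detection(series("active_max", ids[1]),
                             series("active_max", ids[2]),
                             factor = factor, floor = floor, ids = ids))
  attr(tab, "first_detection") <- fd
  tab
}

#' Plot an encounter's electric-image time course
#' @param object Result of [ei_timecourse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ei_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              cols = c("active_max", "passive_max"),
                              names_to = "modality", values_to = "amp")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$amp,
                                     colour = .data$emitter)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~modality, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "EI maximum (uA/cm2)")
}

#' Electric-image series for a synthetic dyadic approach
#'
#' Runs the boundary element solver for every scene of a
#' [make_dyad_scene()] sequence and summarises the discharger's active
#' image and the receiver's passive image.
#'
#' @param dyad A `dyad_scenes` tibble.
#' @return Tibble: `time_s`, `emitter`, `distance_cm`, `active_max`,
#'   `active_rms`, `passive_max`, `passive_rms`.
#' @export
dyad_ei_series <- function(dyad) {
  purrr::map_dfr(seq_len(nrow(dyad)), function(i) {
    scn <- dyad$scene[[i]]
    sol <- assemble_and_solve(scn)
    em <- scn$discharging
    rc <- setdiff(purrr::map_chr(scn$bodies, "id"), em)
    ai <- active_image(scn, sol)
    pim <- passive_image(scn, rc, sol)
    tibble::tibble(time_s = dyad$time_s[i], emitter = em,
                   distance_cm = dyad$distance_cm[i],
                   active_max = ai$summary$max, active_rms = ai$summary$rms,
                   passive_max = pim$summary$max,
                   passive_rms = pim$summary$rms)
  })
}

#' Cohort-level first-approach predictor summary
#'
#' For a set of encounters, counts in how many the initiating fish is the
#' one predicted (by the first-detection analysis) to have perceived the
#' other first — separately for the passive and active modalities — with
#' one-sided exact binomial p-values, overall and stratified by size
#' class.
#'
#' @param pairs Tibble with one row per encounter: `pair_id`,
#'   `initiator_id`, `passive_first_id`, `active_first_id` (NA if the
#'   criterion was never met) and `size_class`.
#' @return Tibble with rows per (modality x stratum): `n`, `matches`,
#'   `p_value`.
#' @export
approach_predictor_summary <- function(pairs) {
  if (nrow(pairs) == 0) {
    abort_pulseid("empty pair list", "pulseid_data_error")
  }
  strata <- list(all = rep(TRUE, nrow(pairs)),
                 large = pairs$size_class == "large",
                 small = pairs$size_class == "small")
  purrr::map_dfr(c("passive", "active"), function(mod) {
    col <- paste0(mod, "_first_id")
    purrr::map_dfr(names(strata), function(st) {
      sel <- pairs[strata[[st]] & !is.na(pairs[[col]]), ]
      n <- nrow(sel)
      k <- sum(sel$initiator_id == sel[[col]])
      tibble::tibble(modality = mod, stratum = st, n = n, matches = k,
                     p_value = if (n > 0) binom_onesided(k, n) else NA_real_)
    })
  })
}
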