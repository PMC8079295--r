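#' Residence time in the hypoxic compartment
#'
#' Percentage of an interval spent in the compartment where hypoxia is
#' induced. Seconds in the passage count to neither compartment but stay in
#' the denominator, so left + right + passage percentages total 100.
#'
#' @param records A data frame of zone-labelled per-second records (column
#'   `zone` with levels left/right/passage).
#' @param hypoxic_side `"left"` or `"right"`.
#' @return Percentage in \[0, 100\].
#' @export
residence_hypoxic <- function(records, hypoxic_side) {
  hypoxic_side <- match.arg(hypoxic_side, c("left", "right"))
  if (!nrow(records)) stop("undefined metric: empty interval", call. = FALSE)
  100 * mean(records$zone == hypoxic_side)
}

#' Shelter occupancy
#'
#' Percentage of an interval spent inside either shelter zone.
#'
#' @param records Zone-labelled records with logical column `in_shelter`.
#' @return Percentage in \[0, 100\].
#' @export
shelter_time <- function(records) {
  if (!nrow(records)) stop("undefined metric: empty interval", call. = FALSE)
  100 * mean(records$in_shelter)
}

#' Count compartment changes
#'
#' Number of left/right compartment transitions. Passage dwell between two
#' entries of the same compartment does not count; passage dwell between
#' different compartments counts as one change.
#'
#' @param records Zone-labelled records, or a character/factor vector of zone
#'   labels.
#' @return Non-negative integer count.
#' @examples
#' count_side_changes(c("left", "left", "right", "right", "left"))  # 2
#' count_side_changes(c("left", "passage", "left"))                 # 0
#' @export
count_side_changes <- function(records) {
  zone <- if (is.data.frame(records)) records$zone else records
  zone <- as.character(zone)
  sides <- zone[zone != "passage"]
  if (length(sides) < 2) return(0L)
  sum(sides[-1] != sides[-length(sides)])
}

#' Distance travelled and size-normalised velocity
#'
#' @param records Per-second records with `dist_cm` and `vel_cm_s`.
#' @param sbl_cm Standard body length (cm).
#' @return A tibble with `distance_m` (sum of step distances, m) and
#'   `velocity_median_bls` (median per-second velocity in body lengths per
#'   second).
#' @export
distance_and_velocity <- function(records, sbl_cm) {
  if (!is.numeric(sbl_cm) || sbl_cm <= 0) stop("sbl_cm must be > 0", call. = FALSE)
  if (!nrow(records)) stop("undefined metric: empty interval", call. = FALSE)
  tibble::tibble(distance_m = sum(records$dist_cm) / 100,
                 velocity_median_bls = stats::median(records$vel_cm_s) / sbl_cm)
}

#' Baseline side preference
#'
#' The compartment occupied for the larger share of the baseline interval
#' and its occupancy percentage. Ties break toward `left` with a warning.
#'
#' @param records Zone-labelled baseline records.
#' @return A tibble with `preferred_side` and `occupancy_pct`.
#' @export
side_preference <- function(records) {
  if (!nrow(records)) stop("undefined metric: empty interval", call. = FALSE)
  occ_left <- 100 * mean(records$zone == "left")
  occ_right <- 100 * mean(records$zone == "right")
  if (occ_left == occ_right) {
    warning("side preference tie; resolved to left", call. = FALSE)
  }
  if (occ_left >= occ_right) {
    tibble::tibble(preferred_side = "left", occupancy_pct = occ_left)
  } else {
    tibble::tibble(preferred_side = "right", occupancy_pct = occ_right)
  }
}

#' Interval summaries of a trial
#'
#' Cuts a position log into the analysis grid of its protocol (the whole
#' baseline, then 10-min bins) and computes the behavioural metrics per
#' interval: mean measured DO on the hypoxic side, residence in the hypoxic
#' compartment, shelter occupancy, side changes, distance travelled and
#' median velocity in body lengths per second.
#'
#' @param log A [position_log()].
#' @param protocol The [trial_protocol()] the log was recorded under.
#' @param geometry The [arena_geometry()] for zone assignment.
#' @param bin_min Post-baseline bin width (min).
#' @return A tibble with one row per interval: `fish_id`, `interval_id`,
#'   `interval_kind`, `nominal_do`, `measured_do_mean`, `residence_hypoxic`,
#'   `shelter_time`, `side_changes`, `distance_m`, `velocity_median_bls`.
#' @export
bin_intervals <- function(log, protocol, geometry, bin_min = 10) {
  stopifnot(inherits(log, "position_log"), inherits(protocol, "trial_protocol"))
  meta <- log_meta(log)
  intervals <- protocol_intervals(protocol, bin_min = bin_min)
  covered <- log$t_s[nrow(log)] + 1
  missing_bins <- intervals$interval_id[intervals$end_s > covered]
  if (length(missing_bins)) {
    stop("log shorter than protocol; missing bins: ",
         paste(missing_bins, collapse = ", "), call. = FALSE)
  }
  zones <- assign_zone(log$x_cm, log$y_cm, geometry)
  rec <- dplyr::bind_cols(tibble::as_tibble(log), zones)
  do_hyp <- if (meta$hypoxic_side == "left") rec$do_left else rec$do_right
  rec$do_hyp <- do_hyp
  purrr::pmap_dfr(intervals, function(interval_id, interval_kind, start_s,
                                      end_s, nominal_do) {
    ri <- rec[rec$t_s >= start_s & rec$t_s < end_s, ]
    dv <- distance_and_velocity(ri, meta$sbl_cm)
    tibble::tibble(
      fish_id = meta$fish_id,
      interval_id = interval_id,
      interval_kind = interval_kind,
      nominal_do = nominal_do,
      measured_do_mean = mean(ri$do_hyp),
      residence_hypoxic = residence_hypoxic(ri, meta$hypoxic_side),
      shelter_time = shelter_time(ri),
      side_changes = count_side_changes(ri),
      distance_m = dv$distance_m,
      velocity_median_bls = dv$velocity_median_bls
    )
  })
}

#' Residence-vs-DO dataset for threshold estimation
#'
#' Reduces interval summaries to one row per fish per established
#' air-saturation level: the baseline interval coded at the normoxic level
#' and each hold bin at its step target. Ramp (and reoxygenation-excluded)
#' bins can be included at their mean scheduled DO, which densifies the
#' x-axis around the threshold.
#'
#' @param summaries Output of [bin_intervals()], possibly for many fish.
#' @param include_baseline Include the baseline interval at DO = 100?
#' @param include_ramps Include ramp bins at their mean scheduled DO?
#' @return A tibble (`fish_id`, `do`, `residence`) suitable for
#'   [broken_stick_search()].
#' @export
residence_dataset <- function(summaries, include_baseline = TRUE,
                              include_ramps = FALSE) {
  kinds <- c("hold", if (include_baseline) "baseline", if (include_ramps) "ramp")
  summaries |>
    dplyr::filter(.data$interval_kind %in% kinds) |>
    dplyr::transmute(fish_id = .data$fish_id, do = .data$nominal_do,
                     residence = .data$residence_hypoxic)
}
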