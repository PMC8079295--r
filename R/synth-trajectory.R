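# Two-state (shelter/roam) per-second behavioural model with a DO-dependent
# side-attachment chain. The generator's purpose is statistical structure,
# not mechanism: it reproduces shelter-resting at normoxia, a strong baseline
# side preference, threshold-triggered roaming with brief excursions back
# into hypoxia, and high between-fish variation.

# Target occupancy of the hypoxic side while avoiding: linear decline from
# the individual's threshold theta down to zero at avoid_floor_do, so the
# population broken-stick intersection sits at the population theta.
pi_target <- function(do, theta, base, floor_do) {
  base * pmin(1, pmax(0, (do - floor_do) / (theta - floor_do)))
}

#' Simulate one fish's shuttle-box trajectory
#'
#' Generates a per-second [position_log()] for one fish under a trial
#' protocol. Behaviour follows a two-state Markov model (sheltering vs
#' roaming) plus a side-attachment chain: while the hypoxic-side target DO is
#' at or above the fish's threshold the fish clings to its preferred side and
#' rests in its shelter; once DO falls below threshold (responders only) the
#' attachment shifts toward the normoxic side in proportion to avoidance
#' depth, with brief geometric-duration excursions back into hypoxia, and
#' roaming activity rises. Paths are continuous with bounded step length, and
#' logged DO columns follow the protocol targets plus measurement noise.
#'
#' @param fish One row of [sample_cohort()] (or a list with the same fields).
#' @param config A [sim_config()].
#' @return A [position_log()] covering the protocol duration; hypoxia is
#'   induced on the fish's preferred side.
#' @export
simulate_trajectory <- function(fish, config) {
  stopifnot(inherits(config, "sim_config"))
  fish <- as.list(fish)
  geom <- config$geometry
  protocol <- config$protocol
  sched <- protocol_schedule(protocol)
  T_s <- nrow(sched)
  i <- as.integer(sub("^F", "", fish$fish_id))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((fish_seed(config$seed, i) + 777L) %% 2147483629L)

  hyp_side <- fish$preferred_side
  other_side <- if (hyp_side == "left") "right" else "left"
  shelter_ctr <- function(side) {
    z <- geom$shelter_zones[[side]]
    c(mean(z[c("xmin", "xmax")]), mean(z[c("ymin", "ymax")]))
  }
  comp_ctr <- function(side) geom$compartment_centers[[side]]
  r <- geom$compartment_radius

  intervals <- protocol_intervals(protocol)
  bin_noise <- stats::rnorm(nrow(intervals), 0, config$residence_noise_sd)
  bin_of <- findInterval(sched$t_s, intervals$start_s)

  # pre-generated draws
  u_side <- stats::runif(T_s); u_act <- stats::runif(T_s)
  u_pause <- stats::runif(T_s); u_way <- stats::runif(T_s)
  n_speed <- pmax(0, stats::rnorm(T_s, config$roam_speed_mean, config$roam_speed_sd))
  n_head <- matrix(stats::rnorm(2 * T_s, 0, 0.15), ncol = 2)
  n_jit <- matrix(stats::rnorm(2 * T_s, 0, 0.2), ncol = 2)
  u_wr <- stats::runif(T_s); u_wa <- stats::runif(T_s)

  do_h <- sched$do_hypoxic
  x <- numeric(T_s); y <- numeric(T_s); dist <- numeric(T_s)
  pos <- shelter_ctr(hyp_side)
  side <- "hyp"; act <- "shelter"
  waypoint <- comp_ctr(hyp_side)

  # keep every position a small margin inside the arena so that logging
  # coordinates at 0.01 cm cannot round a wall-hugging point out of bounds
  clamp_arena <- function(p) {
    if (abs(p[1]) <= geom$passage_length / 2) {
      p[2] <- sign(p[2]) * min(abs(p[2]), geom$passage_width / 2 - 0.05)
      return(p)
    }
    cc <- comp_ctr(if (p[1] < 0) "left" else "right")
    v <- p - cc
    d <- sqrt(sum(v^2))
    if (d > r - 0.05) p <- cc + v / d * (r - 0.05)
    p
  }

  for (t in seq_len(T_s)) {
    avoiding <- isTRUE(fish$responder) && do_h[t] < fish$theta
    # side-attachment transitions
    if (avoiding) {
      p_occ <- pi_target(do_h[t], fish$theta, config$base_preference,
                         config$avoid_floor_do) + bin_noise[bin_of[t]]
      p_occ <- min(0.995, max(0.02, p_occ))
      q_hn <- fish$excursion_rate * (1 - p_occ)
      q_nh <- fish$excursion_rate * p_occ
    } else {
      q_hn <- config$baseline_leave_rate
      q_nh <- config$baseline_return_rate
    }
    if (side == "hyp" && u_side[t] < q_hn) side <- "norm"
    else if (side == "norm" && u_side[t] < q_nh) side <- "hyp"
    # activity transitions
    p_roam <- if (avoiding) fish$roam_rate_hypoxic else fish$roam_rate_base
    p_rest <- if (avoiding) config$rest_rate_avoid else config$rest_rate_base
    if (act == "shelter" && u_act[t] < p_roam) act <- "roam"
    else if (act == "roam" && u_act[t] < p_rest) act <- "shelter"

    cur_side_name <- if (side == "hyp") hyp_side else other_side
    goal <- if (act == "shelter") {
      shelter_ctr(cur_side_name)
    } else {
      if (u_way[t] < 0.05 ||
          sqrt(sum((waypoint - pos)^2)) < 2 ||
          sign(waypoint[1]) != sign(comp_ctr(cur_side_name)[1])) {
        ang <- 2 * pi * u_wa[t]; rad <- 0.8 * r * sqrt(u_wr[t])
        waypoint <- comp_ctr(cur_side_name) + rad * c(cos(ang), sin(ang))
      }
      waypoint
    }
    # route through the passage when the goal is on the other side
    in_pass <- abs(pos[1]) <= geom$passage_length / 2 &&
      abs(pos[2]) <= geom$passage_width / 2
    subgoal <- if (!in_pass && sign(pos[1]) != sign(goal[1])) c(0, 0) else goal
    d <- subgoal - pos
    dd <- sqrt(sum(d^2))
    at_shelter <- act == "shelter" && dd < 1.2
    new_pos <- if (at_shelter) {
      pos + n_jit[t, ]
    } else {
      speed <- if (act == "roam" && u_pause[t] < 0.35) 0.2 else n_speed[t]
      step <- min(speed, dd)
      pos + (if (dd > 0) step * d / dd else c(0, 0)) + n_head[t, ]
    }
    new_pos <- clamp_arena(new_pos)
    dist[t] <- sqrt(sum((new_pos - pos)^2))
    x[t] <- new_pos[1]; y[t] <- new_pos[2]
    pos <- new_pos
  }
  dist[1] <- 0

  temp <- config$temperature_start +
    config$temperature_drift * (sched$t_s / max(sched$t_s))
  do_meas_h <- pmin(110, pmax(0, do_h + stats::rnorm(T_s, 0, config$do_noise_sd)))
  do_meas_n <- pmin(110, pmax(0, sched$do_normoxic +
                                stats::rnorm(T_s, 0, config$do_noise_sd)))
  df <- tibble::tibble(
    t_s = sched$t_s, x_cm = round(x, 2), y_cm = round(y, 2),
    dist_cm = round(dist, 2), vel_cm_s = round(dist, 2),
    do_left = round(if (hyp_side == "left") do_meas_h else do_meas_n, 1),
    do_right = round(if (hyp_side == "right") do_meas_h else do_meas_n, 1),
    temp_c = round(temp, 3)
  )
  # rounding x/y decouples dist from coordinates slightly; keep dist authoritative
  position_log(df, fish_id = fish$fish_id, sbl_cm = fish$sbl_cm,
               hypoxic_side = hyp_side)
}

#' Simulate a whole cohort
#'
#' Samples a cohort and simulates one trajectory per fish.
#'
#' @param config A [sim_config()].
#' @return A list with `params` (the [sample_cohort()] tibble) and `logs`
#'   (named list of [position_log()]s).
#' @export
simulate_cohort <- function(config) {
  params <- sample_cohort(config)
  logs <- purrr::map(seq_len(nrow(params)),
                     function(i) simulate_trajectory(params[i, ], config))
  names(logs) <- params$fish_id
  list(params = params, logs = logs)
}
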