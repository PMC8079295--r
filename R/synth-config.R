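#' Simulation configuration
#'
#' Bundles everything the synthetic-trial generator needs: cohort size and
#' seed, the trial protocol and arena geometry, the population distribution
#' of fish parameters, temperature drift, and EOD synthesis settings.
#'
#' Defaults emulate the study conditions the generator is meant to stand in
#' for: 16 fish with standard body lengths of 7.6-10.4 cm and baseline EOD
#' frequencies of 807-1151 Hz, a strong baseline side preference, one
#' non-responder per 16-fish cohort, a population avoidance threshold around
#' 22 % air saturation with marked inter-individual variation, and a slight
#' linear cooling of -0.15 degC over the trial with a Q10 of 1.55 coupling
#' EOD frequency to temperature.
#'
#' @param n_fish Number of fish in the cohort.
#' @param seed Integer seed; every per-fish stream is derived from it.
#' @param protocol A [trial_protocol()].
#' @param geometry An [arena_geometry()].
#' @param theta_mean,theta_sd Population mean and SD of the individual
#'   avoidance threshold (% air saturation).
#' @param n_nonresponders Number of fish whose avoidance response is disabled.
#' @param f0_range Range of baseline EOD frequencies (Hz).
#' @param sbl_range Range of standard body lengths (cm).
#' @param base_preference Long-run baseline occupancy of the preferred side
#'   (fraction).
#' @param avoid_floor_do Air saturation (%) at which a responder's occupancy
#'   of the hypoxic side would extrapolate to zero; together with the
#'   individual threshold this sets the slope of the post-threshold decline.
#' @param roam_rate_base,roam_rate_hypoxic Per-second shelter-to-roam switch
#'   probabilities at normoxia and during avoidance.
#' @param rest_rate_base,rest_rate_avoid Per-second roam-to-shelter switch
#'   probabilities.
#' @param excursion_rate Per-second scale of side-switching during avoidance;
#'   its inverse, scaled by the occupancy deficit, sets the mean duration of
#'   brief excursions into hypoxia (about 20 s in deep hypoxia).
#' @param baseline_leave_rate,baseline_return_rate Per-second probabilities of
#'   leaving/returning to the preferred side outside avoidance.
#' @param roam_speed_mean,roam_speed_sd Swimming speed (cm/s) while moving.
#' @param do_noise_sd Measurement noise on logged DO (% air saturation).
#' @param residence_noise_sd Per-fish, per-interval jitter on the target
#'   occupancy (fraction), producing the high between-fish scatter seen in
#'   residence data.
#' @param temperature_start Water temperature at trial start (degC).
#' @param temperature_drift Linear temperature change over the trial (degC).
#' @param q10 Q10 of EOD frequency vs temperature.
#' @param eod_sample_rate EOD digitisation rate (Hz).
#' @param eod_harmonics Relative amplitudes of harmonics 2, 3, ... of the
#'   quasi-sinusoidal discharge.
#' @param eod_noise_sd Gaussian noise SD added to the synthesised voltage.
#' @param eod_stride_s Synthesise one 1-s EOD window every `eod_stride_s`
#'   trial seconds (1 = full-length synthesis).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_fish = 16,
                       seed = 1,
                       protocol = trial_protocol(),
                       geometry = arena_geometry(),
                       theta_mean = 22,
                       theta_sd = 2.5,
                       n_nonresponders = 1,
                       f0_range = c(807, 1151),
                       sbl_range = c(7.6, 10.4),
                       base_preference = 0.97,
                       avoid_floor_do = 7,
                       roam_rate_base = 1 / 600,
                       roam_rate_hypoxic = 1 / 40,
                       rest_rate_base = 1 / 30,
                       rest_rate_avoid = 1 / 120,
                       excursion_rate = 0.06,
                       baseline_leave_rate = 1e-4,
                       baseline_return_rate = 1 / 120,
                       roam_speed_mean = 2.5,
                       roam_speed_sd = 0.8,
                       do_noise_sd = 0.5,
                       residence_noise_sd = 0.08,
                       temperature_start = 26,
                       temperature_drift = -0.15,
                       q10 = 1.55,
                       eod_sample_rate = 20000,
                       eod_harmonics = c(0.35, 0.12),
                       eod_noise_sd = 0.05,
                       eod_stride_s = 60) {
  stopifnot(n_fish >= 1, q10 > 0, eod_noise_sd >= 0, do_noise_sd >= 0,
            theta_mean >= 0, theta_sd >= 0,
            inherits(protocol, "trial_protocol"),
            inherits(geometry, "arena_geometry"))
  if (n_nonresponders > n_fish) stop("more non-responders than fish", call. = FALSE)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# One RNG stream per fish, derived from (seed, fish index) so cohorts are
# extensible without reshuffling earlier fish. Kept below 2^31.
fish_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 7919) %% 2147483629)
}

#' Sample a cohort of fish parameters
#'
#' Draws per-fish body size, baseline EOD frequency, preferred side (balanced
#' to within one fish), individual avoidance threshold and responder status.
#' Reproducible: the same config yields the same cohort, and each fish's
#' parameters depend only on the seed and its index.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per fish: `fish_id`, `sbl_cm`, `body_mass_g`,
#'   `base_eod_freq_hz`, `preferred_side`, `theta`, `responder`, and the
#'   behavioural rates inherited from the config.
#' @examples
#' sample_cohort(sim_config(n_fish = 4, seed = 1))
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_fish
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(fish_seed(config$seed, 0))
  sides <- sample(rep(c("left", "right"), length.out = n))
  nonresp <- if (config$n_nonresponders > 0) {
    sample.int(n, config$n_nonresponders)
  } else integer(0)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    set.seed(fish_seed(config$seed, i))
    sbl <- stats::runif(1, config$sbl_range[1], config$sbl_range[2])
    theta <- -1
    while (theta < 5) theta <- stats::rnorm(1, config$theta_mean, config$theta_sd)
    tibble::tibble(
      fish_id = sprintf("F%02d", i),
      sbl_cm = sbl,
      body_mass_g = round(0.011 * sbl^3, 2),  # cubic length-mass allometry
      base_eod_freq_hz = stats::runif(1, config$f0_range[1], config$f0_range[2]),
      preferred_side = sides[i],
      theta = theta,
      responder = !(i %in% nonresp),
      roam_rate_base = config$roam_rate_base,
      roam_rate_hypoxic = config$roam_rate_hypoxic,
      excursion_rate = config$excursion_rate
    )
  })
  rows
}
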