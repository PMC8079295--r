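#' Run the full avoidance analysis on a simulated cohort
#'
#' Convenience wrapper chaining the whole pipeline on synthetic data: sample
#' a cohort, simulate each fish's trajectory, summarise intervals, build the
#' residence-vs-DO dataset and estimate the broken-stick threshold.
#'
#' @param config A [sim_config()].
#' @param include_ramps Include ramp bins in the threshold dataset at their
#'   mean scheduled DO (densifies the x-axis around the threshold).
#' @param mode,random Passed to [broken_stick_search()].
#' @return A list: `params`, `summaries` (all fish), `residence` (the
#'   threshold dataset), `fit` (the `broken_stick_fit`).
#' @examples
#' \donttest{
#' res <- run_avoidance_pipeline(sim_config(n_fish = 6, seed = 42))
#' glance(res$fit)
#' }
#' @export
run_avoidance_pipeline <- function(config, include_ramps = TRUE,
                                   mode = "lmm", random = "intercept") {
  cohort <- simulate_cohort(config)
  summaries <- purrr::map_dfr(cohort$logs, bin_intervals,
                              protocol = config$protocol,
                              geometry = config$geometry)
  residence <- residence_dataset(summaries, include_baseline = TRUE,
                                 include_ramps = include_ramps)
  fit <- broken_stick_search(residence, mode = mode, random = random)
  list(params = cohort$params, summaries = summaries,
       residence = residence, fit = fit)
}

#' Write a simulated cohort to disk
#'
#' Simulates a cohort and writes one position-log CSV and one (decimated)
#' EOD recording per fish plus a `manifest.csv` of cohort parameters and
#' file names, and the trial configuration YAML.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_simulated_cohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  manifest <- cohort$params
  manifest$log_file <- paste0(manifest$fish_id, "_log.csv")
  manifest$eod_file <- paste0(manifest$fish_id, "_eod.f32")
  for (i in seq_len(nrow(manifest))) {
    log <- cohort$logs[[manifest$fish_id[i]]]
    write_position_log(log, file.path(dir, manifest$log_file[i]))
    rec <- simulate_eod(manifest[i, ], log, config)
    write_eod_recording(rec, file.path(dir, manifest$eod_file[i]))
  }
  write_trial_config(config$geometry, config$protocol,
                     file.path(dir, "trial_config.yml"))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Behavioural test report for a cohort
#'
#' Runs the hypothesis-test suite on a cohort's interval summaries: the
#' one-sample Wilcoxon test of baseline side preference against 50 %, and
#' for each behavioural metric a Friedman test across intervals followed
#' (when significant) by Holm-corrected paired Wilcoxon tests of each
#' post-baseline interval against baseline.
#'
#' @param summaries Output of [bin_intervals()] for a cohort.
#' @param baseline_occupancy Per-fish baseline occupancy of the preferred
#'   side (%); defaults to baseline `residence_hypoxic` (hypoxia is induced
#'   on the preferred side).
#' @param alpha Significance level gating the post-hoc tests.
#' @return A list: `side_preference` (one-row tibble), `friedman` (one row
#'   per metric), `posthoc` (Holm-adjusted per-interval tests, per metric).
#' @export
behavior_report <- function(summaries, baseline_occupancy = NULL,
                            alpha = 0.05) {
  metrics <- c("residence_hypoxic", "shelter_time", "side_changes",
               "distance_m", "velocity_median_bls")
  base <- summaries[summaries$interval_id == "baseline", ]
  post <- summaries[summaries$interval_id != "baseline", ]
  if (is.null(baseline_occupancy)) baseline_occupancy <- base$residence_hypoxic
  side_pref <- one_sample_wilcoxon(baseline_occupancy, mu = 50)

  fish <- sort(unique(summaries$fish_id))
  ivs <- unique(post$interval_id)
  friedman <- purrr::map_dfr(metrics, function(m) {
    mat <- matrix(NA_real_, length(fish), length(ivs) + 1,
                  dimnames = list(fish, c("baseline", ivs)))
    mat[cbind(match(base$fish_id, fish), 1L)] <- base[[m]]
    mat[cbind(match(post$fish_id, fish), 1L + match(post$interval_id, ivs))] <- post[[m]]
    dplyr::mutate(friedman_test(mat), term = m)
  })
  posthoc <- purrr::map(stats::setNames(metrics, metrics), function(m) {
    if (friedman$p_value[friedman$term == m] > alpha) return(NULL)
    mat <- matrix(NA_real_, length(fish), length(ivs),
                  dimnames = list(fish, ivs))
    mat[cbind(match(post$fish_id, fish), match(post$interval_id, ivs))] <- post[[m]]
    bl <- base[[m]][match(fish, base$fish_id)]
    suppressWarnings(pairwise_wilcoxon_holm(bl, mat, family = m))
  })
  list(side_preference = side_pref, friedman = friedman,
       posthoc = posthoc[!vapply(posthoc, is.null, logical(1))])
}

#' EOD frequency analysis for one fish
#'
#' Chains the EOD pipeline: synthesise (or accept) a recording, track the
#' per-second frequency, reduce to interval medians normalised to baseline,
#' and attach the interval's DO and residence so the frequency mixed model
#' can be fitted.
#'
#' @param recording An [eod_recording()].
#' @param summaries The fish's [bin_intervals()] output.
#' @param protocol The [trial_protocol()].
#' @param bin_min Post-baseline bin width (min); must match the one used for
#'   `summaries`.
#' @return The [normalize_track()] tibble joined with `residence_hypoxic`
#'   and a `time` (interval index) column.
#' @export
eod_interval_changes <- function(recording, summaries, protocol, bin_min = 10) {
  track <- track_frequency(recording)
  intervals <- protocol_intervals(protocol, bin_min = bin_min)
  norm <- normalize_track(track, intervals)
  norm |>
    dplyr::left_join(summaries[, c("interval_id", "residence_hypoxic")],
                     by = "interval_id") |>
    dplyr::mutate(time = dplyr::row_number() - 1,
                  residence_frac = .data$residence_hypoxic / 100,
                  fish_id = summaries$fish_id[1])
}
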