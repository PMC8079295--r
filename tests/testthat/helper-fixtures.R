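# Shared fixtures: small protocols and configs keep simulation-backed tests
# fast while preserving the default study structure where it matters.

short_protocol <- function() {
  trial_protocol(baseline_min = 4, step_targets = c(50, 25, 10),
                 ramp_min = 2, hold_min = 2, reox_min = 4)
}

short_config <- function(seed = 1, n_fish = 2, ...) {
  sim_config(n_fish = n_fish, seed = seed, protocol = short_protocol(), ...)
}

# per-second records with explicit zone labels, for metric arithmetic tests
zone_records <- function(zones, in_shelter = rep(FALSE, length(zones))) {
  tibble::tibble(zone = factor(zones, levels = c("left", "right", "passage")),
                 in_shelter = in_shelter)
}

# residence-vs-DO rows from a known two-segment population curve
segmented_rows <- function(n_fish = 2, levels = c(10, 15, 20, 25, 30, 50, 70, 100),
                           flat = 95, knee = 25, slope = 5, noise_sd = 0,
                           fish_sd = 0, seed = 1) {
  set.seed(seed)
  fish_eff <- stats::rnorm(n_fish, 0, fish_sd)
  purrr::map_dfr(seq_len(n_fish), function(i) {
    mu <- ifelse(levels >= knee, flat, flat - slope * (knee - levels))
    tibble::tibble(fish_id = sprintf("F%02d", i), do = levels,
                   residence = mu + fish_eff[i] +
                     stats::rnorm(length(levels), 0, noise_sd))
  })
}

# truly linear residence-vs-DO rows with per-fish intercept shifts
linear_rows <- function(n_fish = 16, levels = c(100, 70, 50, 30, 25, 20, 15, 10),
                        b0 = 90, b1 = 0.05, fish_sd = 5, noise_sd = 8, seed = 1) {
  set.seed(seed)
  fish_eff <- stats::rnorm(n_fish, 0, fish_sd)
  purrr::map_dfr(seq_len(n_fish), function(i)
    tibble::tibble(fish_id = sprintf("F%02d", i), do = levels,
                   residence = b0 + b1 * levels + fish_eff[i] +
                     stats::rnorm(length(levels), 0, noise_sd)))
}

# a pure tone packaged as an eod_recording
tone_recording <- function(freq, n_sec = 3, fs = 20000, amplitude = 1) {
  eod_recording(amplitude * sin(2 * pi * freq / fs * seq_len(n_sec * fs)),
                sample_rate = fs)
}
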